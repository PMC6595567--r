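# Default normalization rules for Cochrane-style characteristics tables.
# Rules are matched case-insensitively against the plain-text projection of
# the named field; the lowest-priority-number match wins. `variable` directs
# the label into that slot of the normalized record (defaults to the field
# name). Replace this file to adapt the engine to another review group's
# conventions.
name: default
fallback: unclassified
codes:
  double: 2
  single: 1
  open: 0
rules:
  # blinding (from the methods field)
  - {variable: blinding, field: methods, pattern: "doubl[ey][- ]?blind(ed)?|double[- ]?dummy|doubly\\s+blind(ed)?", label: double, priority: 10}
  - {variable: blinding, field: methods, pattern: "triple[- ]?blind(ed)?", label: double, priority: 11}
  - {variable: blinding, field: methods, pattern: "single[- ]?blind(ed)?|rater[- ]?blind(ed)?|assessor[- ]?blind(ed)?|observer[- ]?blind(ed)?", label: single, priority: 12}
  - {variable: blinding, field: methods, pattern: "open[- ]?label|non[- ]?blind(ed)?|unblinded|no\\s+blinding|not\\s+blinded", label: open, priority: 13}
  # allocation (from the methods field)
  - {variable: allocation, field: methods, pattern: "quasi[- ]?random|alternat(e|ion)|by\\s+date\\s+of\\s+birth|case\\s+record\\s+number", label: quasi, priority: 30}
  - {variable: allocation, field: methods, pattern: "randomi[sz](ed|ation)|random\\s+allocation|randomly\\s+(allocated|assigned)", label: randomised, priority: 31}
  - {variable: allocation, field: methods, pattern: "allocation\\s*:?\\s*(unclear|not\\s+(stated|described))", label: unclear, priority: 32}
  # trial setting (an example of an extra variable; lands in `extras`)
  - {variable: setting, field: participants, pattern: "inpatients?|hospitali[sz]ed", label: inpatient, priority: 50}
  - {variable: setting, field: participants, pattern: "outpatients?|community", label: outpatient, priority: 51}
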
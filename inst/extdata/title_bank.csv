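base_id,title
T01,Mental state
T02,Global state: relapse
T03,Global state: clinically important change
T04,Leaving the study early
T05,Adverse effects: extrapyramidal symptoms
T06,Adverse effects: weight gain
T07,Adverse effects: sedation
T08,Service use: hospital admission
T09,Service use: days in hospital
T10,Behaviour: aggression
T11,Quality of life
T12,Social functioning
T13,Cognitive functioning
T14,Death: all causes
T15,Death: suicide
T16,Mental state: average endpoint score (BPRS)
T17,Mental state: average endpoint score (PANSS)
T18,Mental state: depression
T19,Mental state: anxiety
T20,Compliance with medication
T21,Satisfaction with treatment
T22,Economic outcomes: direct costs
T23,Adverse effects: anticholinergic
T24,Adverse effects: cardiovascular
T25,Adverse effects: seizures
T26,Relapse by one year
T27,Employment status
T28,Carer burden
T29,General functioning: average score (GAF)
T30,Insight
T31,Substance use
T32,Adverse effects: prolactin-related
T33,Sleep: insomnia
T34,Weight: average change
T35,Global state: use of additional medication
T36,Mental state: positive symptoms
T37,Mental state: negative symptoms
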
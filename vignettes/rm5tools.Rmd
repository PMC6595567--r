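---
title: "rm5tools: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{rm5tools: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rm5tools)
```

## The problem

RevMan `.rm5` save files hold the most reliably extracted trial data in
evidence synthesis — study references, semi-structured characteristics
tables, risk-of-bias judgements, and labelled numeric outcome tables — but
they hold them one review at a time, in a format built for authoring, not
reuse. rm5tools treats a directory of such files as a corpus: it parses them
into tidy tables, normalises their free text, curates their outcome
vocabulary, marshals everything into one queryable dataset, and feeds
curated content back into the source files without disturbing anything else.

This vignette explains how each stage works, the choices that were genuinely
open, and what the shipped tests do and do not demonstrate.

## The data model and dialect

RevMan's full schema is large; rm5tools supports a documented subset
(`docs/rm5-dialect.md`) modelled on the public RevMan 5.3 layout and keeps
every element path in one mapping table, `rm5_dialect()`, so the dialect can
be re-pointed at a variant without code changes. A parsed review is a set of
tibbles (studies, references, characteristics, risk of bias, comparisons,
outcomes, outcome rows) rather than an object tree, because every downstream
computation is tabular.

Three decisions shape the I/O layer:

- **Lossless retention.** Subtrees outside the subset (excluded-studies
  sections, figures, analysis results) are kept opaquely with their parent
  and child position, and re-emitted in place on write. Retained fragments
  are stored in canonical serialization so the model is independent of any
  serializer's whitespace habits.
- **Markup preservation with a plain-text projection.** Characteristics
  fields keep their inline markup verbatim (`<P>`, emphasis, even comments);
  matching and export use `plain_text()` — tags stripped, entities decoded,
  whitespace collapsed. This gives lossless round trips *and* clean
  matching, instead of trading one for the other.
- **Canonical-XML equality as the round-trip contract.** Serializers
  legitimately differ in attribute order, indentation and self-closing
  tags, so "unchanged" is defined as equality after canonicalisation
  (sorted attributes, whitespace-only text nodes dropped, uniform
  escaping, comments preserved) — never byte equality. Field-for-field
  model equality (`rm5_identical()`) is the stricter contract for
  `read(write(r))`.

Reading is `lenient` by default (missing optional blocks become empty tables
with one warning per file; data invariant violations warn); `strict` mode —
used to hold the synthetic generator to account and available for CI —
turns both into classed errors. Validation (`validate_review()`) enforces
the structural invariants listed in the dialect document, and `write_review()`
runs it before any bytes are written, writing to a temporary sibling and
moving atomically.

Only included studies are parsed into the model; awaiting-classification and
excluded tables are deliberately retained as opaque subtrees, since their
internal structure varies and nothing downstream consumes them.

Numeric attributes are serialized with 17 significant digits, so doubles
survive the text round trip exactly; integers are written as plain integers.

## The rule engine

Free-text normalisation is ordered regular expressions and nothing more — no
tokenizers, no learned models — because predictable, auditable behaviour is
what makes bulk auto-curation acceptable to a review group. Semantics:

- Rules are `(variable, field, pattern, label, priority)`. Matching is
  case-insensitive, Perl-flavoured, against the plain-text projection of the
  named characteristics field.
- **First match by ascending priority wins**; ties are impossible because
  priorities must be unique within a field. When nothing matches the result
  is the rule set's fallback label (default `"unclassified"`), so
  `apply_rules()` is total: it never errors on content.
- The rule file is YAML data, not code. The shipped default covers blinding
  (`double`/`single`/`open`), allocation (`randomised`/`quasi`/`unclear`)
  and an example extra variable; replacing the file adapts the engine to
  another group's conventions.
- Canonical labels are lowercase text. A label → numeric code table can ride
  along in the rule file (`codes:`) for users who want coded exports; the
  engine itself works in labels, which are self-describing.
- The `variable` key (defaulting to the field name) is how several
  independently-labelled variables can draw on the same field — blinding and
  allocation both live in the methods text. `apply_rules()` can be scoped to
  one variable or run field-wide; `normalize_studies()` uses the per-variable
  scoping and gathers non-standard variables into an `extras` list-column,
  keeping the variable inventory open without guessing it.

Numeric extraction prefers precision over recall: a participant total is
accepted only when cue-anchored (`N=120`, `120 participants`), an explicit
`N=` beats a looser cue when both occur, and bare numbers or written-out
numbers are never guessed — a wrong auto-filled total is worse than an
absent one. Durations are recognised in weeks only; other units are left
absent rather than converted with an assumed calendar.

The priority semantics are verified two ways: directly, and against a
brute-force oracle that evaluates *all* rules and takes the minimum-priority
match, over 1,000 randomized (rule set, string) pairs.

## Outcome-title curation

"Unique title" means exact string equality after UTF-8/NFC normalisation and
trimming — raw titles are never altered. Grouping happens only at the
clustering step, via a canonical form: casefold, strip one leading
enumeration token (`"1.1 "`), remove punctuation, collapse whitespace.
Canonical-form equality is the entire clustering criterion; there is no
edit-distance or embedding similarity, because the target of the output is a
human curator who must be able to see *why* two titles were grouped.
Clusters are numbered by descending total count with ties broken
alphabetically, so output order is deterministic.

The category list itself is user data: the worksheet export leaves
`category`/`subcategory` blank, the curator fills them (typically in a
spreadsheet), and `import_mapping()` validates the result — unknown
categories are rejected with row numbers when a category list is declared,
and untouched rows are absent from the mapping rather than null-mapped.
Applying a mapping tags unmapped occurrences `"UNMAPPED"` and reports the
unmapped fraction, so curation coverage is always visible.

## The central dataset

`build_central()` flattens a batch into a studies table and an outcome-rows
table, each carrying raw plain text and canonical labels side by side, and
serializes to a versioned XML schema of our own (plus CSV/JSON). Choices:

- **Determinism.** Records are sorted by review, study, comparison, outcome;
  the creation timestamp is injectable. Identical inputs with a pinned
  timestamp give byte-identical XML, which makes the dataset diffable and
  cacheable in CI.
- **Study year resolution.** The rightmost 4-digit token in 1800–2100 of the
  study id (tolerating a trailing disambiguation letter, "Smith 1999a"),
  falling back to the earliest reference year — the first report of the
  study — and otherwise excluded-with-count. The publication-year histogram
  sums to the dated studies, and dated + excluded equals all studies.
- **Counting unit.** A study appearing in several reviews counts once per
  (review, study) pair, matching the dataset's grain; a duplicated pair
  within a batch is a hard error naming the collision, since it signals the
  same review read twice.
- Participant totals are summed only over parsed counts; studies without one
  are counted as missing, never imputed.

`tidy()`/`glance()` methods expose the tables and one-row summaries;
`autoplot()` on the year summary draws the corpus-age histogram.

## Write-back

The injected "Contributing to outcomes" block is delimited by sentinel XML
comments carrying a tool tag and version. Re-running the injection strips
any existing sentinel block before appending the regenerated one, so the
operation is idempotent under canonical equality — the failure mode of
hand-maintained lists (drift and duplication) is designed out rather than
warned about. Stripping the sentinels recovers the original file exactly
(canonically). The block lands in the outcomes field by default,
configurable to notes; in-place editing writes a `.bak` copy first, and all
writes are atomic.

## The synthetic corpus and what the tests show

Real review corpora are not distributable, so the generator is first-class,
tested code and the ground truth for everything else. It emulates the
structures the model supports: 2–8 studies per review (drawn uniformly),
each with 1–3 references (the many-to-one report relationship), five-field
characteristics assembled from templated sentences that embed a blinding
phrase from a labelled bank of 14 surface forms, an allocation phrase, the
true `N=` total (a multiple of 4 between 12 and 120) and a duration in
weeks; risk-of-bias entries over six standard domains; and 1–3 comparisons
of 1–4 outcome tables whose titles are (base title, surface variant) pairs —
37 base titles, up to 4 case/punctuation/enumeration variants — with
dichotomous rows satisfying events ≤ total by construction. Publication
years are uniform over 1960–2015, wide enough that corpus-age queries have
non-trivial answers. A fifth of files carry an awaiting-classification
subtree outside the dialect, exercising opaque retention. Same seed,
byte-identical corpus; the caller's RNG state is untouched.

The manifest records every planted truth and is itself validated for
self-consistency. The system-level test generates 200 reviews, runs the full
pipeline, and requires *exact* equality with the manifest: study and row
counts, every blinding/allocation label, every participant total, distinct
titles, cluster count (exactly the 37 planted bases), and the year
histogram. Round-trip losslessness is checked over 100 randomized in-memory
reviews (seeded with XML-hostile characters) plus write-stability over all
200 files, and injection idempotence over 20.

What the generator does **not** emulate — and therefore what passing tests
do not show — is the true messiness of authored reviews: free text that
contradicts itself, blinding described in the participants field, nested
markup several levels deep, study ids that break the naming convention,
non-Latin scripts, or dialect drift across RevMan versions. The rule engine
run on real files should be expected to leave far more text `unclassified`
than it does here; that is the designed failure mode (fallback, never a
guess), but the agreement rates from synthetic runs are upper bounds, not
field estimates.

Problem sizes in the shipped suite (200-review corpus, 100 round trips,
1,000 rule-oracle pairs, 20 injection fixtures) were chosen to exercise the
properties at a scale where coverage of all 37 title bases and all 14
phrases is essentially certain, while the whole suite stays in the
low minutes on a laptop.

## Known limitations

- The dialect is a subset: footnotes, subgroup trees beyond one level and
  sensitivity analyses round-trip opaquely but are not modelled.
- Written-out numbers ("one hundred participants") and non-week durations
  are not extracted.
- Clustering will not merge true synonyms with different canonical forms
  ("Mental state" vs "Psychiatric symptoms"); that judgement is left to the
  curator on purpose.
- The title-uniqueness definition (trim + NFC, before casefolding) is one of
  several defensible choices; it is documented and the canonicalisation is a
  single function, `canonical_title()`, if a group prefers another.
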
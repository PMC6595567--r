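# The supported .rm5 dialect (version 5.3), schema description

rm5tools reads and writes a documented subset of the RevMan 5.3 XML save
format. Element paths live in a single mapping table (`rm5_dialect()`), so the
reader/writer can be re-pointed at another RevMan flavour without code
changes. Everything outside this subset is retained opaquely on read and
re-emitted on write in original document order.

Encoding is UTF-8 throughout; XML entities are decoded on read. Missing
optional elements are omitted on write, never emitted empty.

## Structure

```
COCHRANE_REVIEW                      @REVIEW_ID (required, unique per batch)
│                                    @VERSION   (dialect version, "5.3")
├── COVER_SHEET
│   └── TITLE                        text: review title
├── STUDIES_AND_REFERENCES
│   └── STUDIES
│       └── INCLUDED_STUDIES
│           └── STUDY*               @ID = @NAME = study id ("Surname YYYY")
│               └── REFERENCE+       @ID: citation id  (>= 1 per study:
│                   ├── TI           text: report title       many-to-one
│                   ├── SO?          text: journal             reports)
│                   └── YR?          integer: year, 1800..2100
├── CHARACTERISTICS_OF_STUDIES
│   └── CHARACTERISTICS_OF_INCLUDED_STUDIES
│       └── INCLUDED_CHAR*           @STUDY_ID
│           ├── CHAR_METHODS?        ┐ free text, inline markup
│           ├── CHAR_PARTICIPANTS?   │ (P / B / I ...) preserved
│           ├── CHAR_INTERVENTIONS?  │ verbatim; the model exposes
│           ├── CHAR_OUTCOMES?       │ a plain-text projection for
│           └── CHAR_NOTES?          ┘ matching
├── QUALITY_ITEMS                    (risk-of-bias table)
│   └── QUALITY_ITEM*                @NAME: bias domain
│       └── QUALITY_ITEM_DATA_ENTRY* @STUDY_ID, @RESULT in {LOW, HIGH, UNCLEAR}
│           └── DESCRIPTION?         text: supporting quote
└── ANALYSES_AND_DATA
    └── COMPARISON*                  @ID (unique per review), @NAME
        ├── DICH_OUTCOME*            @ID, @NAME: outcome title (non-empty)
        │   └── DICH_DATA*           @STUDY_ID, @EVENTS_1, @TOTAL_1,
        │                            @EVENTS_2, @TOTAL_2   (events <= total)
        └── CONT_OUTCOME*            @ID, @NAME
            └── CONT_DATA*           @STUDY_ID, @MEAN_1, @SD_1, @TOTAL_1,
                                     @MEAN_2, @SD_2, @TOTAL_2  (sd, n >= 0)
```

`*` = zero or more, `+` = one or more, `?` = optional.

## Invariants enforced by `validate_review()`

- `review_id` non-empty; study ids non-empty and unique within the review;
  comparison ids unique within the review; outcome titles non-empty.
- Every study has at least one reference; reference years in 1800–2100.
- Risk-of-bias judgements drawn from exactly {low, high, unclear}
  (serialized upper-case).
- Dichotomous rows: `events <= total`, counts non-negative. Continuous rows:
  `sd >= 0`, `n >= 0`.
- Every outcome data row's `STUDY_ID` resolves to exactly one included study.

## Round-trip contract

Equality of a file before and after an unedited read/write cycle is stated
over *canonical XML*: attribute order sorted, whitespace-only text nodes
dropped, entities re-escaped uniformly, comments preserved (serializers
legitimately differ in byte layout). `read_review(write_review(r))`
reproduces `r` field for field.

Unknown subtrees (excluded/awaiting studies sections, PRISMA figures,
meta-analysis results) are retained opaquely with their parent and child
position and re-emitted in place.

See `examples/` for three annotated instances.
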
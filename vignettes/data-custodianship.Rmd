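---
title: "Managing the translational research data lifecycle with custodian"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Managing the translational research data lifecycle with custodian}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(custodian)
```

## The problem

A translational study produces data in successive forms: planned *data
elements*, raw files from collection systems, validated *primary datasets*,
*integrated* observations in a warehouse, and finally *analysis-ready*
extracts.  Each transition loses information unless metadata carries it
across.  `custodian` implements that metadata spine as four cooperating
layers — data-element definitions, a common observation model, a dataset
meta-model, and a project domain graph — and the pipeline they drive.

This vignette records the model, the defaults and the design decisions,
including the places where a choice had to be made that the problem itself
does not dictate.

## Data elements and tri-state validation

A data element pairs a concept with a value domain: either an enumerated
term list of (code, label) pairs, or a datatype with an optional inclusive
valid range and a unit of measure.  `validate_value()` is deliberately
tri-state: an empty or all-whitespace cell is *missing* — neither a pass
nor a failure.  Clinical delimited files routinely use blanks for "not
collected", so collapsing blanks into violations would reject essentially
every real file, while treating them as passes would hide absent mandatory
values.  Missing mandatory cells are load errors; missing optional cells
simply drop that property from the decomposed observation.

Further conventions, chosen once:

* Dates parse as ISO-8601 with partial dates (`YYYY`, `YYYY-MM`) accepted
  and kept as text with a completeness flag — clinical dates are routinely
  partial and fabricating a day would be worse than recording less.
* Enumerated matching is case-insensitive on codes but exact on labels
  (codes are controlled identifiers; labels are prose), and the verdict
  records which matched.
* Units are plain strings compared after trimming and lowercasing.  There
  is **no unit conversion** anywhere in the package: conversion is a
  curation act that needs human sign-off, so `mg/dL` and `mmol/L` versions
  of a variable remain distinct (and flagged — see harmonization).

## The dataset meta-model

Descriptors form a strict hierarchy.  The generic model fixes the role
vocabulary a field may take: `subject-identifier`, `sample-identifier`,
`study-identifier`, `topic`, `result-qualifier`, `unit-qualifier`,
`grouping-qualifier`, `temporal-timing`, `series-timing`,
`other-qualifier`.  This is our rendering of the SDTM
identifier/topic/qualifier/timing variable classes, split finely enough
that mapping a column into the observation model is mechanical.  Fixed
meta-descriptors then say which roles each dataset kind must bind — a
findings dataset needs a subject, a topic and a result; an assay matrix
needs a feature axis and a sample axis — and concrete descriptors
(templates, or your customisations of them) bind those roles to real
column names.

Because integration reads roles and display labels, never column names,
two descriptors with identical role bindings produce identical observation
multisets from content-equivalent files.  That property is tested
explicitly with a renamed-columns clone of the laboratory template.

Governance edits (`customize()`) cover excluding and adding fields,
mandatory flags, vocabulary restrictions, and `bind_element()`, which
attaches a data element (hence a datatype/range rule) to a field.  Edits
that would break the meta-contract are refused by name: you cannot exclude
the only binding of a required role, and you cannot put a term list on a
numeric-typed field.  Every applied edit lands in the descriptor's change
log, which survives serialization.

Unknown-purpose extra columns can always be added with role
`other-qualifier`; their values flow into observation properties verbatim.
Nothing is dropped silently — an unannotated column in a file is a
reported warning, not a deletion.

## The domain graph

Projects are `single-study`, `multi-study` (planned, related) or
`meta-study` (unrelated studies brought together).  Subject identity is
**never merged across studies**: a meta-study combining independent
consortia will contain subjects with colliding local identifiers, and any
automatic merge would be wrong far more often than right, so subject keys
are always `(study, local id)` pairs.  Visits match by exact label within
a study; cross-study alignment relies on the planned study day where one
is recorded, otherwise visit structure stays study-local.

## Ingest: validation and atomic loads

Parsing maps the file header to descriptor fields case-insensitively;
a column missing for a required role is fatal, an unknown column is a
warning.  Validation then applies, per row: mandatory checks, vocabulary
checks, element datatype/range checks, a duplicate-key check on the
(subject, topic, series-timing) tuple, and dangling-link checks of subject
and sample references against the consolidated indexes.  All findings are
report entries with row, field, severity and a stable reason code.

Loads are strictly atomic at file granularity.  A single error-severity
issue blocks the entire file: the repository is the project's single
source of truth, and a partially loaded dataset silently corrupts every
downstream count.  Row-skipping was considered and rejected for that
reason.  Reloading a file for the same (activity, domain, study) replaces
the previous dataset — the audit trail implies versioning, and
"replace, don't accumulate" is the only rule that keeps warehouse counts
stable under correction cycles.  Demographics must be consolidated before
the clinical and sample files that reference their subjects; the loading
plans the generator emits order files accordingly.

## Integration and harmonization

Every validated clinical row becomes exactly one observation instance;
every non-blank matrix cell becomes one molecular observation whose
subject is inherited from its sample.  An instance separates observed
properties (result, unit, severity, dose, …) from temporal attributes
(collection date, start, end) and series keys (visit, study day,
timepoint) — the separation that makes longitudinal queries and the
metadata/value access split possible.

Cross-study harmonization needs a computable identity for "the same
variable".  The key used is

```
feature_key = (observation class, domain code, OBJECT CODE, unit)
```

with the object code uppercased and the unit normalised.  Including the
unit is a deliberate safety choice: a weight in kilograms and a weight in
pounds are *not* one feature, and the harmonization report flags every
such `UNIT_MISMATCH` group for human attention rather than merging or
converting.  The count of distinct clinical feature keys is what the
warehouse summary reports as "harmonized clinical variables".

The warehouse itself is long-format (entity–attribute–value), with feature
metadata in a separate registry so facet panels can be served without
touching measured values.  State persists as plain-text tables in the
workspace tree — transparent, diffable, and trivially auditable, which we
value over the compactness of a binary embedded store at desk scale.

## Query semantics

The boolean algebra is: **conjunction across filters, disjunction within
a categorical value set**.  A subject satisfies a feature filter if *at
least one* of its observations of that feature passes (existential
semantics) — the natural reading of "find subjects with diastolic blood
pressure in this range".  Series filters (visit, study day, timepoint)
both constrain subjects and *scope* the feature filters evaluated
alongside them, so "DIABP in [90, 200] and visit = V1" means the V1
reading must qualify, not any reading.  Two series filters on the same
key intersect, like every other pair of filters; this keeps the engine
monotone (adding a filter can never enlarge the cohort) and
order-independent, both of which are property-tested against a
brute-force oracle that scans the long-format export.

Chart summaries are computed over the current cohort only.  Numeric
histograms use Freedman–Diaconis bin widths with a Sturges fallback when
the IQR is zero, and a single half-unit bin for constant data, so a chart
is a pure function of (warehouse, cohort, feature).

Checkout stores the query and the selected columns, never the rows.
Exports are regenerated on demand: same warehouse state and query give
byte-identical files (stable subject/visit row order, facet-tree column
order), and new matching data appears as exactly the differential rows.
The flip side, accepted knowingly: an analysis dataset is **not** a frozen
snapshot — if reproducibility of a specific extract matters, keep the
exported files.

## The synthetic generator

`generate_project()` writes a complete loadable project — metadata
document, SDTM-dialect clinical CSVs per study, ISA-style triplets per
assay, a loading plan, and a ground-truth manifest — so every pipeline
stage is testable without any external download.  Determinism is per
file: each file's pseudo-random stream derives from (seed, file name),
so extending a config never perturbs existing files.

The presets model the two programme shapes the package targets:

* `preset_ers_like()` — a meta-study of two independent respiratory
  studies of 647 subjects each (1,294 total), four findings-class
  clinical activities (laboratory 20 variables, vital signs 6,
  spirometry 8, reversibility 5 — 39 variables, all shared by both
  studies so they harmonize to 39 features), and one gene-expression
  assay of 30 features on 20 subjects per study.  Values are normal
  draws truncated to plausible ranges; 5% of collection dates are blank.
* `preset_biovacsafe_like()` — five vaccine trials covering seven arms,
  haematology/vital-sign findings, solicited adverse events, and three
  assay types (expression, cytokine panel, flow cytometry).
* `preset_tiny()` — the same structure at 10 subjects, used throughout
  the unit tests.

The generator can inject deliberate vocabulary, range and duplicate-key
violations, recorded in the manifest ledger, to exercise the rejection
path.  What it does **not** emulate — and therefore what passing tests do
not show about real data: biologically realistic expression values,
longitudinal correlation (each visit is an independent draw), informative
missingness, free-text messiness in identifiers, or files that deviate
from their declared descriptor.  The generator demonstrates that the
pipeline recovers ground truth from well-formed inputs and rejects
declared violations; it cannot certify behaviour on arbitrarily
malformed real-world files.

## Problem sizes and numerical choices

The test suite runs the tiny preset for unit coverage, the two large
presets once each end to end (about 52,000 and 5,000 observations), and
200 randomized queries across eight seeded 10-subject warehouses for the
oracle properties.  Ties and degenerate inputs are handled by fixed
rules: empty categorical filter sets and inverted numeric ranges are
construction errors; an all-blank matrix column yields no assay event; a
constant numeric chart gets one centred bin; visit ordering in exports is
by planned study day, then label.

## Known limitations

* No unit conversion, derived variables, or statistical summaries beyond
  counts — curation concerns, out of scope by design.
* No SAS transport (XPT) ingestion; the physical format is delimited
  text.  The descriptor layer is format-neutral, so an XPT reader would
  slot in at `parse_delimited()`.
* Access control is role *tags* only (manager/curator/researcher,
  analysis-dataset visibility); there is no enforcement layer.
* Terminology is stored inline per descriptor; there is no external
  ontology-service resolution.
* Analysis datasets do not pin warehouse state (see above).
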
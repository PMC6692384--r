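# custodian

Data custodianship for translational research studies, at desk scale.

Translational medicine projects collect clinical observations (demographics,
laboratory tests, vital signs, adverse events, medications) and molecular
assay data (expression matrices, cytokine panels, flow cytometry) across
several studies at once, then need to find, validate, integrate, query and
re-share all of it.  Most tooling concentrates on the analysis end; the
stretch between data collection and data analysis — validating files against
agreed structures, consolidating them into a trustworthy repository,
integrating their content for cohort queries — is usually managed by hand.
`custodian` is an R toolkit for exactly that stretch, aimed at data managers
and bioinformaticians running multi-study projects.

## What is in the box

The package is organised as a metadata-driven lifecycle pipeline:

* **Data-element registry** — ISO/IEC 11179-style definitions: a concept
  (e.g. *Age*) paired with a value domain (datatype, valid range, unit, or an
  enumerated term list).  Every raw value can be validated against one, with
  a tri-state verdict: `ok`, `violation` (with a reason code) or `missing`.
* **Dataset descriptors** — a four-layer meta-model.  A generic descriptor
  model constrains field *roles* (subject identifier, topic, result
  qualifier, unit qualifier, temporal timing, series timing, …); fixed
  meta-descriptors name the core dataset kinds (study, subject, clinical
  observation, biosample, feature, assay measurement) and the roles each
  must bind; shipped templates implement them in SDTM-dialect
  (`DM`, `LB`, `VS`, `AE`, `CM`, `MH`) and ISA-style (`SAMPLE`, `FEATURE`,
  `MEASUREMENT-*`) layouts.  Templates are customised per activity:
  exclude/add fields, set mandatory flags, restrict vocabularies, bind
  data elements.  Two descriptors with different column names but the same
  role bindings integrate identically.
* **Domain graph** — project → studies (arms, visits) → activities
  (clinical assessments or molecular assays), with project-wide subject and
  biosample indexes.  Subject identity is always study-scoped.
* **Ingest & repository** — descriptor-driven parsing and validation
  (mandatory fields, vocabularies, datatype/range, duplicate keys, dangling
  subject/sample links), with an audit trail per file.  Loads are atomic: a
  file with any error changes nothing; a clean load persists an annotated
  primary dataset and immediately integrates it — no separate ETL step.
  Reloading replaces rather than duplicates.
* **Observation warehouse** — every dataset row (or matrix cell) becomes an
  observation instance decomposed into object-of-observation, subject,
  observed properties, temporal attributes and series keys.  Features are
  harmonised across studies by the key
  `(class, domain, object code, unit)`; same-named variables in different
  units are kept apart and flagged, never silently merged.
* **Query engine & data cart** — three-panel facets (subject/study,
  clinical by class and domain, molecular by assay), conjunctive filters
  with existential subject semantics, synchronized chart summaries, and
  checkout into analysis datasets that store *the query, not the rows*:
  exports are regenerated from the live warehouse, byte-identically when
  nothing changed.
* **Synthetic project generator** — seeded, manifest-backed multi-study
  fixtures shaped like real programmes (`preset_tiny()`,
  `preset_ers_like()`, `preset_biovacsafe_like()`), including deliberate
  violation injection for testing the validation path.
* **CLI** — `inst/cli/custodian`, a thin wrapper over `run_cli()`, with
  workspace persistence as a plain-text directory tree.

## Worked example

```r
library(custodian)

dir <- file.path(tempdir(), "demo")
generate_project(preset_tiny(), dir)     # 2 studies, LB/VS/AE + expression
res <- ingest_simulated(dir)             # validate + load + integrate
str(warehouse_summary(res$project))
#> List of 6
#>  $ subjects          : int 10
#>  $ samples           : int 4
#>  $ assays            : int 4
#>  $ clinical_features : int 7
#>  $ molecular_features: int 4
#>  $ observations      : int 122
```

Ten subjects across the two studies; seven harmonized clinical features
(3 lab tests + 2 vital signs shared by both studies, plus 2 adverse-event
terms); 122 observation instances, one per validated clinical row or
non-blank matrix cell.  Now a cohort: subjects whose baseline diastolic
blood pressure reached 75 mmHg —

```r
dia <- feature_key("finding", "VS", "DIABP", "mmHg")
q <- cohort_query(filter_feature(dia, "result", range = c(75, 200)),
                  filter_series("visit", "V1"))
evaluate_query(res$project, q)
#> <cohort> 4 subjects, 2 samples, 2 assays

ad <- checkout(res$project, "alice", q, title = "raised diastolic at baseline")
render_export(res$project, ad)$clinical
#>   subject_key study_id visit DIABP.result
#> 1  S2/S2-0002       S2    V1           88
#> 2  S2/S2-0002       S2    V2           69
#> 3  S2/S2-0003       S2    V1           84
#> ...
```

The count panel says 4 of the 10 subjects qualify, and the filter cascades
to their 2 biosamples and 2 assay events.  The export is one row per
subject and visit, one column per selected feature-property, and comes with
a field-metadata sheet; rerunning it after another load picks up exactly
the new rows, because the analysis dataset stores the query.

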
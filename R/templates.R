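# Shipped descriptor templates.  Clinical templates follow SDTM v1.x
# variable-name conventions in delimited text; assay templates follow an
# ISA-style sample/feature/measurement triplet.  Templates are plain
# descriptor values, so get_template() hands out independently customizable
# copies.

fd <- field_descriptor   # local alias, template table reads better

build_template <- function(id, kind, obs_class, domain, fields,
                           layout = "long-per-observation") {
  dataset_descriptor(id, meta_descriptor(kind, obs_class), domain, fields,
                     layout)
}

template_table <- function() {
  list(
    DM = build_template("tpl-DM", "subject", NULL, "DM", list(
      fd("STUDYID", "study", "study-identifier"),
      fd("USUBJID", "subject id", "subject-identifier", mandatory = TRUE),
      fd("AGE", "age", "other-qualifier"),
      fd("SEX", "sex", "other-qualifier"),
      fd("ARMCD", "arm", "grouping-qualifier"),
      fd("COUNTRY", "country", "other-qualifier"))),
    LB = build_template("tpl-LB", "clinical-observation", "finding", "LB", list(
      fd("STUDYID", "study", "study-identifier"),
      fd("USUBJID", "subject id", "subject-identifier", mandatory = TRUE),
      fd("LBTESTCD", "test code", "topic", mandatory = TRUE),
      fd("LBTEST", "test name", "other-qualifier"),
      fd("LBORRES", "result", "result-qualifier", mandatory = TRUE),
      fd("LBORRESU", "unit", "unit-qualifier"),
      fd("LBDTC", "collection date", "temporal-timing"),
      fd("VISIT", "visit", "series-timing"),
      fd("VISITDY", "study day", "series-timing"))),
    VS = build_template("tpl-VS", "clinical-observation", "finding", "VS", list(
      fd("STUDYID", "study", "study-identifier"),
      fd("USUBJID", "subject id", "subject-identifier", mandatory = TRUE),
      fd("VSTESTCD", "test code", "topic", mandatory = TRUE),
      fd("VSTEST", "test name", "other-qualifier"),
      fd("VSORRES", "result", "result-qualifier", mandatory = TRUE),
      fd("VSORRESU", "unit", "unit-qualifier"),
      fd("VSDTC", "collection date", "temporal-timing"),
      fd("VISIT", "visit", "series-timing"))),
    AE = build_template("tpl-AE", "clinical-observation", "event", "AE", list(
      fd("STUDYID", "study", "study-identifier"),
      fd("USUBJID", "subject id", "subject-identifier", mandatory = TRUE),
      fd("AETERM", "term", "topic", mandatory = TRUE),
      fd("AEDECOD", "coded term", "other-qualifier"),
      fd("AESEV", "severity", "result-qualifier",
         vocabulary = c("MILD", "MODERATE", "SEVERE")),
      fd("AESTDTC", "start", "temporal-timing"),
      fd("AEENDTC", "end", "temporal-timing"))),
    CM = build_template("tpl-CM", "clinical-observation", "intervention", "CM",
      list(
      fd("STUDYID", "study", "study-identifier"),
      fd("USUBJID", "subject id", "subject-identifier", mandatory = TRUE),
      fd("CMTRT", "treatment", "topic", mandatory = TRUE),
      fd("CMDOSE", "dose", "result-qualifier"),
      fd("CMDOSU", "unit", "unit-qualifier"),
      fd("CMSTDTC", "start", "temporal-timing"),
      fd("CMENDTC", "end", "temporal-timing"))),
    MH = build_template("tpl-MH", "clinical-observation", "event", "MH", list(
      fd("STUDYID", "study", "study-identifier"),
      fd("USUBJID", "subject id", "subject-identifier", mandatory = TRUE),
      fd("MHTERM", "term", "topic", mandatory = TRUE),
      fd("MHDECOD", "coded term", "other-qualifier"),
      fd("MHSTDTC", "start", "temporal-timing"))),
    SAMPLE = build_template("tpl-SAMPLE", "biosample", NULL, "SAMPLE", list(
      fd("STUDYID", "study", "study-identifier"),
      fd("SAMPLEID", "sample id", "sample-identifier", mandatory = TRUE),
      fd("USUBJID", "subject id", "subject-identifier", mandatory = TRUE),
      fd("SPECTYPE", "specimen type", "other-qualifier"),
      fd("VISIT", "visit", "series-timing"))),
    FEATURE = build_template("tpl-FEATURE", "feature", NULL, "FEATURE", list(
      fd("FEATUREID", "feature id", "topic", mandatory = TRUE),
      fd("SYMBOL", "symbol", "other-qualifier"),
      fd("NAME", "name", "other-qualifier"))),
    `MEASUREMENT-MA` = build_template(
      "tpl-MEASUREMENT-MA", "assay-measurement", NULL, "MA", list(
        fd("FEATUREID", "feature id", "topic", mandatory = TRUE),
        fd("*", "sample", "sample-identifier")),
      layout = "matrix-feature-by-sample"),
    `MEASUREMENT-CYT` = build_template(
      "tpl-MEASUREMENT-CYT", "assay-measurement", NULL, "CYT", list(
        fd("FEATUREID", "feature id", "topic", mandatory = TRUE),
        fd("*", "sample", "sample-identifier")),
      layout = "matrix-feature-by-sample"),
    `MEASUREMENT-FACS` = build_template(
      "tpl-MEASUREMENT-FACS", "assay-measurement", NULL, "FACS", list(
        fd("FEATUREID", "feature id", "topic", mandatory = TRUE),
        fd("*", "sample", "sample-identifier")),
      layout = "matrix-feature-by-sample")
  )
}

#' List shipped descriptor template codes
#' @return Character vector of domain codes accepted by [get_template()].
#' @export
list_templates <- function() names(template_table())

#' Fetch a shipped descriptor template
#'
#' The registry preloads SDTM-dialect templates for the core clinical
#' domains (DM, LB, VS, AE, CM, MH) and ISA-style SAMPLE / FEATURE /
#' MEASUREMENT templates for microarray expression (`MEASUREMENT-MA`),
#' cytokine panel (`MEASUREMENT-CYT`) and flow cytometry
#' (`MEASUREMENT-FACS`) assays.
#'
#' @param domain_code a code from [list_templates()] (case-insensitive).
#' @return A deep, independently customizable copy of the template
#'   descriptor.
#' @export
#' @examples
#' lb <- get_template("LB")
#' lb$domain_code
get_template <- function(domain_code) {
  tbl <- template_table()
  hit <- match(toupper(domain_code), toupper(names(tbl)))
  if (is.na(hit))
    tm_stop(sprintf("no template for '%s'; available: %s", domain_code,
                    paste(names(tbl), collapse = ", ")),
            class = "custodian_not_found")
  tbl[[hit]]
}
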
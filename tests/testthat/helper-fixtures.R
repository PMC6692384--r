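# Fixtures are built in code at test time; nothing is read from disk that a
# test did not itself write.

write_fixture <- function(lines, ext = ".csv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

lb_header <- "STUDYID,USUBJID,LBTESTCD,LBTEST,LBORRES,LBORRESU,LBDTC,VISIT"
vs_header <- "STUDYID,USUBJID,VSTESTCD,VSTEST,VSORRES,VSORRESU,VSDTC,VISIT"
dm_header <- "STUDYID,USUBJID,AGE,SEX,ARMCD,COUNTRY"

# two-study toy project with one clinical and one assay activity
toy_project <- function() {
  p <- create_project("meta-study", "Toy project", "toy")
  add_study(p, study("SA", arms = c("A", "B"),
                     visits = data.frame(label = c("V1", "V2"),
                                         day = c(1, 8))))
  add_study(p, study("SB", arms = "A",
                     visits = data.frame(label = c("V1", "V2"),
                                         day = c(1, 8))))
  add_activity(p, activity("clin", "clinical-assessment", "clinical"))
  add_activity(p, activity("expr", "molecular-assay", "expression",
                           technology = "microarray gene expression"))
  p
}

# register a template-derived descriptor under a unique id
register_template <- function(p, activity_id, code, id = NULL, ...) {
  d <- get_template(code)
  edits <- list(...)
  if (length(edits)) d <- do.call(customize, c(list(d), edits))
  if (!is.null(id)) d$descriptor_id <- id
  register_descriptor(p, activity_id, d)
  d
}

load_fixture <- function(p, lines, descriptor_id, study_id = NULL,
                         ext = ".csv", user = "tester") {
  f <- write_fixture(lines, ext)
  fid <- upload_file(p, f, user)
  load_dataset(p, fid, descriptor_id, user, study_id = study_id)
}

descriptor_field_names_helper <- function(d, name) {
  for (f in d$fields) if (f$name == name) return(f)
  NULL
}

# loads DM for both toy studies (2 subjects each) so clinical loads resolve
load_toy_dm <- function(p) {
  register_template(p, "clin", "DM")
  load_fixture(p, c(dm_header,
                    "SA,001,34,F,A,GBR",
                    "SA,002,41,M,B,GBR"), "tpl-DM", "SA")
  load_fixture(p, c(dm_header,
                    "SB,001,55,M,A,DEU",
                    "SB,002,62,F,A,DEU"), "tpl-DM", "SB")
  p
}
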
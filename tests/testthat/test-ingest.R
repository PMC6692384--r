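test_that("parsing maps header to roles and reports unknown columns", {
  p <- toy_project()
  lb <- get_template("LB")
  f <- write_fixture(c(lb_header,
                       "SA,001,ALB,Albumin,4.1,g/dL,2016-01-05,V1",
                       "SA,001,GLUC,Glucose,5.2,mmol/L,2016-01-05,V1",
                       "SA,002,ALB,Albumin,3.9,g/dL,2016-01-06,V1"))
  parsed <- parse_delimited(f, lb)
  expect_identical(nrow(parsed$records), 3L)
  expect_identical(nrow(parsed$diagnostics), 0L)

  # extra column: one warning, not fatal
  f2 <- write_fixture(c(paste0(lb_header, ",COMMENT"),
                        "SA,001,ALB,Albumin,4.1,g/dL,2016-01-05,V1,fine"))
  parsed2 <- parse_delimited(f2, lb)
  expect_identical(parsed2$diagnostics$code, "UNKNOWN_COLUMN")
  expect_identical(parsed2$diagnostics$severity, "warning")

  # missing topic column is fatal, naming the role
  f3 <- write_fixture(c("STUDYID,USUBJID,LBORRES", "SA,001,4.1"))
  expect_error(parse_delimited(f3, lb), "topic",
               class = "custodian_parse_error")
  f4 <- write_fixture(character(0))
  expect_error(parse_delimited(f4, lb), class = "custodian_parse_error")
})

test_that("row validation covers mandatory, duplicate-key and clean files", {
  p <- toy_project()
  load_toy_dm(p)
  lb <- register_template(p, "clin", "LB")
  clean <- c(lb_header,
             "SA,001,ALB,Albumin,4.1,g/dL,2016-01-05,V1",
             "SA,001,ALB,Albumin,4.3,g/dL,2016-02-01,V2",
             "SA,002,ALB,Albumin,3.9,g/dL,2016-01-06,V1")
  f <- write_fixture(clean)
  rep0 <- validate_dataset(parse_delimited(f, lb), lb, p, "SA")
  expect_identical(nrow(rep0$issues), 0L)

  # duplicate (subject, topic, visit) key
  f2 <- write_fixture(c(clean, "SA,001,ALB,Albumin,4.2,g/dL,2016-01-07,V1"))
  rep2 <- validate_dataset(parse_delimited(f2, lb), lb, p, "SA")
  expect_identical(rep2$issues$code, "DUPLICATE_KEY")
  expect_identical(rep2$issues$row, 4L)

  # missing mandatory result
  f3 <- write_fixture(c(lb_header, "SA,001,ALB,Albumin,,g/dL,2016-01-05,V1"))
  rep3 <- validate_dataset(parse_delimited(f3, lb), lb, p, "SA")
  expect_identical(rep3$issues$code, "MISSING_MANDATORY")

  # summary counts equal tallies over issues
  f4 <- write_fixture(c(clean,
                        "SA,001,ALB,Albumin,4.2,g/dL,2016-01-07,V1",
                        "SA,009,ALB,Albumin,4.0,g/dL,2016-01-07,V1"))
  rep4 <- validate_dataset(parse_delimited(f4, lb), lb, p, "SA")
  tall <- table(rep4$issues$code)
  for (i in seq_len(nrow(rep4$summary)))
    expect_identical(rep4$summary$n[i],
                     as.integer(tall[rep4$summary$code[i]]))
})

test_that("loads are atomic and audited; failures leave the warehouse alone", {
  p <- toy_project()
  load_toy_dm(p)
  reg <- element_registry()
  el <- define_data_element(reg, "Lab result",
    value_domain("continuous", datatype = "decimal", range = c(0, 10)))
  register_template(p, "clin", "LB", id = "lb-ranged",
                    bind_element("LBORRES", el))
  before <- warehouse_summary(p)

  bad <- load_fixture(p, c(lb_header,
                           "SA,001,ALB,Albumin,4.1,g/dL,2016-01-05,V1",
                           "SA,002,ALB,Albumin,99,g/dL,2016-01-05,V1"),
                      "lb-ranged", "SA")
  expect_identical(bad$status, "failed")
  expect_identical(bad$report$issues$code, "RANGE_VIOLATION")
  expect_identical(warehouse_summary(p), before)
  frec <- p$files[p$files$status == "failed", ]
  expect_identical(nrow(frec), 1L)

  ok <- load_fixture(p, c(lb_header,
                          "SA,001,ALB,Albumin,4.1,g/dL,2016-01-05,V1",
                          "SA,001,GLUC,Glucose,5.0,mmol/L,2016-01-05,V1",
                          "SA,002,ALB,Albumin,3.9,g/dL,2016-01-06,V1"),
                     "lb-ranged", "SA")
  expect_identical(ok$status, "loaded")
  expect_identical(warehouse_summary(p)$observations,
                   before$observations + 3L)

  # audit completeness: every load transition has its record
  aud <- p$audit[p$audit$file_id %in% p$files$file_id, ]
  for (fid in p$files$file_id) {
    acts <- aud$action[aud$file_id == fid]
    expect_true("created" %in% acts)
    expect_identical(sum(acts == "load-started"),
                     sum(acts %in% c("load-succeeded", "load-failed")))
    ts <- aud$timestamp[aud$file_id == fid]
    expect_true(all(diff(order(ts)) > 0) || !is.unsorted(ts))
  }
})

test_that("reloading a file replaces the previous dataset", {
  p <- toy_project()
  load_toy_dm(p)
  register_template(p, "clin", "LB")
  lines <- c(lb_header,
             "SA,001,ALB,Albumin,4.1,g/dL,2016-01-05,V1",
             "SA,002,ALB,Albumin,3.9,g/dL,2016-01-06,V1")
  load_fixture(p, lines, "tpl-LB", "SA")
  s1 <- warehouse_summary(p)
  load_fixture(p, lines, "tpl-LB", "SA")
  s2 <- warehouse_summary(p)
  expect_identical(s1, s2)
  expect_identical(nrow(list_datasets(p)[
    list_datasets(p)$domain_code == "LB", ]), 1L)
})

test_that("export of a primary dataset round-trips record for record", {
  p <- toy_project()
  load_toy_dm(p)
  register_template(p, "clin", "LB")
  res <- load_fixture(p, c(lb_header,
                           "SA,001,ALB,Albumin,4.1,g/dL,2016-01-05,V1",
                           "SA,002,ALB,\"Albumin, serum\",3.9,g/dL,,V1"),
                      "tpl-LB", "SA")
  out <- tempfile(fileext = ".csv")
  export_primary_dataset(p, res$dataset_id, out)
  reparsed <- parse_delimited(out, get_template("LB"))
  expect_identical(reparsed$records,
                   p$datasets[[res$dataset_id]]$records)
  expect_error(export_primary_dataset(p, "DS9999"),
               class = "custodian_not_found")
  lst <- list_datasets(p)
  expect_true(res$dataset_id %in% lst$dataset_id)
  expect_true(all(c("domain_code", "descriptor_id", "n_records") %in%
                    names(lst)))
})
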
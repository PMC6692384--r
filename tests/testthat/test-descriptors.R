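test_that("shipped templates bind the roles their meta-descriptors require", {
  lb <- get_template("LB")
  expect_identical(lb$meta$kind, "clinical-observation")
  expect_identical(lb$meta$obs_class, "finding")
  roles <- vapply(lb$fields, function(f) f$role, "")
  names(roles) <- vapply(lb$fields, function(f) f$name, "")
  expect_identical(unname(roles["LBTESTCD"]), "topic")
  expect_identical(unname(roles["LBORRES"]), "result-qualifier")
  expect_identical(unname(roles["LBORRESU"]), "unit-qualifier")
  expect_identical(unname(roles["VISIT"]), "series-timing")

  ae <- get_template("AE")
  expect_identical(ae$meta$obs_class, "event")
  roles <- stats::setNames(vapply(ae$fields, function(f) f$role, ""),
                           vapply(ae$fields, function(f) f$name, ""))
  expect_identical(unname(roles["AETERM"]), "topic")
  expect_identical(unname(roles["AESEV"]), "result-qualifier")
  expect_true("AEDECOD" %in% names(roles))

  expect_error(get_template("ZZ"), "available",
               class = "custodian_not_found")
  # templates are independent copies
  a <- get_template("LB"); b <- get_template("LB")
  a$fields[[1]]$name <- "MUTATED"
  expect_identical(b$fields[[1]]$name, "STUDYID")
})

test_that("every template satisfies the layer discipline", {
  for (code in list_templates()) {
    d <- get_template(code)
    expect_s3_class(d$meta, "tm_meta")
    expect_true(d$meta$kind %in% c("study", "subject", "clinical-observation",
                                   "biosample", "feature",
                                   "assay-measurement"))
    bound <- vapply(d$fields, function(f) f$role, "")
    expect_true(all(d$meta$required_roles %in% bound), label = code)
    if (d$layout == "matrix-feature-by-sample")
      expect_identical(d$meta$kind, "assay-measurement")
  }
})

test_that("customization edits are applied, logged, and guarded", {
  lb <- get_template("LB")
  # excluding a non-required field is fine
  d <- customize(lb, exclude_field("LBORRESU"))
  expect_null(descriptor_field_names_helper(d, "LBORRESU"))
  expect_length(d$change_log, 1)
  # excluding the only topic binding is refused, naming the role
  expect_error(customize(lb, exclude_field("LBTESTCD")), "topic",
               class = "custodian_refused")
  # vocabulary + mandatory + new field
  d2 <- customize(lb,
                  set_vocabulary("LBTESTCD", c("ALB", "GLUC")),
                  set_mandatory("LBDTC", TRUE),
                  add_field(field_descriptor("COMMENT", "comment",
                                             "other-qualifier")))
  expect_identical(d2$fields[[which(vapply(d2$fields, function(f) f$name, "")
                                    == "LBTESTCD")]]$vocabulary,
                   c("ALB", "GLUC"))
  expect_length(d2$change_log, 3)
  expect_error(customize(d2, add_field(field_descriptor("COMMENT", "x",
                                                        "other-qualifier"))),
               class = "custodian_conflict")
  # vocabulary on a numeric-typed field is refused
  reg <- element_registry()
  num <- define_data_element(reg, "Lab result",
    value_domain("continuous", datatype = "decimal", range = c(0, 100)))
  d3 <- customize(lb, bind_element("LBORRES", num))
  expect_error(customize(d3, set_vocabulary("LBORRES", c("HIGH", "LOW"))),
               class = "custodian_refused")
})

test_that("a vocabulary override restricts an otherwise clean file", {
  p <- toy_project()
  load_toy_dm(p)
  register_template(p, "clin", "VS", id = "vs-restricted",
                    set_vocabulary("VSTESTCD", c("SYSBP", "DIABP", "PULSE")))
  f <- write_fixture(c(vs_header,
                       "SA,001,SYSBP,Systolic,120,mmHg,2016-01-05,V1",
                       "SA,001,DIABP,Diastolic,80,mmHg,2016-01-05,V1",
                       "SA,002,TEMP,Temperature,36.8,C,2016-01-05,V1",
                       "SA,002,PULSE,Pulse,64,beats/min,2016-01-05,V1"))
  d <- p$descriptors[["vs-restricted"]]$descriptor
  parsed <- parse_delimited(f, d)
  report <- validate_dataset(parsed, d, p, "SA")
  vio <- report$issues[report$issues$code == "VOCAB_VIOLATION", ]
  expect_identical(nrow(vio), 1L)
  expect_identical(vio$row, 3L)
})

test_that("descriptors round-trip through their JSON documents", {
  lb <- get_template("LB")
  expect_equal(deserialize_descriptor(serialize_descriptor(lb)), lb)
  reg <- element_registry()
  el <- define_data_element(reg, "VS result",
    value_domain("continuous", datatype = "decimal", range = c(0, 300)))
  d <- customize(get_template("VS"),
                 set_vocabulary("VSTESTCD", c("SYSBP", "DIABP")),
                 bind_element("VSORRES", el))
  d2 <- deserialize_descriptor(serialize_descriptor(d))
  expect_equal(d2$fields, d$fields)
  expect_length(d2$change_log, 2)
  expect_equal(d2$elements$VSORRES$value_domain$range, c(0, 300))
  expect_error(deserialize_descriptor("{\"broken\": tru"),
               class = "custodian_parse_error")
  expect_error(deserialize_descriptor("{\"x\": 1}"),
               class = "custodian_parse_error")
})
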
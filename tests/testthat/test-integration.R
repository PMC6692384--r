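test_that("a finding row decomposes by role into the observation model", {
  p <- toy_project()
  load_toy_dm(p)
  obs <- decompose_record(
    list(STUDYID = "SA", USUBJID = "001", LBTESTCD = "ALB",
         LBTEST = "Albumin", LBORRES = "4.1", LBORRESU = "g/dL",
         LBDTC = "2016-01-05", VISIT = "V1"),
    get_template("LB"), p, "SA")
  expect_identical(obs$feature$object_code, "ALB")
  expect_identical(obs$feature$obs_class, "finding")
  expect_identical(obs$subject_key, "SA/001")
  expect_identical(obs$properties$result, "4.1")
  expect_identical(obs$properties$unit, "g/dL")
  expect_identical(obs$series$visit, "V1")
  expect_identical(obs$temporal$collection_date, "2016-01-05")
  # each bound value lands in exactly one bucket
  expect_false("visit" %in% names(obs$properties))
  expect_false("collection_date" %in% names(obs$series))

  ev <- decompose_record(
    list(STUDYID = "SA", USUBJID = "001", AETERM = "headache",
         AEDECOD = "HEADACHE", AESEV = "MODERATE",
         AESTDTC = "2016-01-10", AEENDTC = ""),
    get_template("AE"), p, "SA")
  expect_identical(ev$feature$obs_class, "event")
  expect_identical(ev$feature$object_code, "HEADACHE")
  expect_identical(ev$properties$severity, "MODERATE")
  expect_identical(ev$temporal$start, "2016-01-10")
  expect_false("end" %in% names(ev$temporal))  # blank optional drops out
})

test_that("feature keys are deterministic pure functions of their parts", {
  k1 <- feature_key("finding", "LB", "alb", "g/dL")
  k2 <- feature_key("finding", "LB", "ALB ", " G/DL")
  expect_identical(k1, k2)
  expect_false(identical(k1, feature_key("finding", "VS", "ALB", "g/dL")))
  expect_false(identical(k1, feature_key("finding", "LB", "ALB", "mg/dL")))
})

test_that("a matrix dataset yields one molecular observation per cell", {
  p <- toy_project()
  load_toy_dm(p)
  register_template(p, "expr", "SAMPLE")
  samples <- c("STUDYID\tSAMPLEID\tUSUBJID\tSPECTYPE\tVISIT",
               "SA\tSMP1\t001\tblood\tV1", "SA\tSMP2\t002\tblood\tV1",
               "SB\tSMP3\t001\tblood\tV1", "SB\tSMP4\t002\tblood\tV1")
  load_fixture(p, samples, "tpl-SAMPLE", ext = ".tsv")
  register_template(p, "expr", "MEASUREMENT-MA")
  mat <- c(paste(c("FEATUREID", paste0("SMP", 1:4)), collapse = "\t"),
           vapply(1:10, function(i)
             paste(c(sprintf("F%02d", i), round(stats::rnorm(4, 8), 3)),
                   collapse = "\t"), ""))
  res <- load_fixture(p, mat, "tpl-MEASUREMENT-MA", ext = ".tsv")
  expect_identical(res$status, "loaded")
  mol <- p$obs[p$obs$obs_class == "molecular", ]
  expect_identical(nrow(mol), 40L)
  expect_true(all(nzchar(mol$sample_key)))
  expect_identical(sort(unique(mol$subject_key)),
                   c("SA/001", "SA/002", "SB/001", "SB/002"))
  # one assay event per sample
  expect_identical(nrow(p$assays), 4L)
  # provenance totality: every observation points at a repository record
  ds <- p$datasets[[res$dataset_id]]
  expect_true(all(mol$row_index >= 1 & mol$row_index <= nrow(ds$records)))
})

test_that("blank matrix cells emit no observation (conservation)", {
  p <- toy_project()
  load_toy_dm(p)
  register_template(p, "expr", "SAMPLE")
  load_fixture(p, c("STUDYID\tSAMPLEID\tUSUBJID\tSPECTYPE\tVISIT",
                    "SA\tSMP1\t001\tblood\tV1",
                    "SA\tSMP2\t002\tblood\tV1"),
               "tpl-SAMPLE", ext = ".tsv")
  register_template(p, "expr", "MEASUREMENT-MA")
  load_fixture(p, c("FEATUREID\tSMP1\tSMP2",
                    "F01\t7.1\t",
                    "F02\t\t6.2",
                    "F03\t5.5\t5.9"), "tpl-MEASUREMENT-MA", ext = ".tsv")
  expect_identical(warehouse_summary(p)$observations, 4L)
})

test_that("overlapping variables harmonize to one feature across studies", {
  p <- toy_project()
  load_toy_dm(p)
  register_template(p, "clin", "VS")
  load_fixture(p, c(vs_header,
                    "SA,001,DIABP,Diastolic,82,mmHg,2016-01-05,V1",
                    "SA,002,DIABP,Diastolic,77,mmHg,2016-01-05,V1"),
               "tpl-VS", "SA")
  load_fixture(p, c(vs_header,
                    "SB,001,DIABP,Diastolic,91,mmHg,2016-01-05,V1",
                    "SB,002,DIABP,Diastolic,85,mmHg,2016-01-05,V1"),
               "tpl-VS", "SB")
  s <- warehouse_summary(p)
  expect_identical(s$clinical_features, 1L)
  key <- feature_key("finding", "VS", "DIABP", "mmHg")
  expect_identical(length(unique(
    p$obs$subject_key[p$obs$feature_key == key])), 4L)
  # contributing datasets accumulate on the merged feature
  expect_identical(length(strsplit(
    p$features$datasets[p$features$feature_key == key], ";")[[1]]), 2L)
})

test_that("unit mismatches split features and are flagged, never merged", {
  p <- toy_project()
  load_toy_dm(p)
  register_template(p, "clin", "VS")
  load_fixture(p, c(vs_header,
                    "SA,001,WEIGHT,Weight,71,kg,2016-01-05,V1"),
               "tpl-VS", "SA")
  load_fixture(p, c(vs_header,
                    "SB,001,WEIGHT,Weight,180,lb,2016-01-05,V1"),
               "tpl-VS", "SB")
  expect_identical(warehouse_summary(p)$clinical_features, 2L)
  rep <- harmonization_report(p)
  expect_identical(rep$flag, "UNIT_MISMATCH")
  expect_identical(rep$object_code, "WEIGHT")
})

test_that("re-registering an identical feature leaves the registry unchanged", {
  p <- toy_project()
  cand <- list(feature_key = feature_key("finding", "LB", "ALB", "g/dL"),
               obs_class = "finding", domain_code = "LB",
               object_code = "ALB", object_label = "Albumin",
               unit = "g/dl", properties = "result", dataset_id = "DSx")
  harmonize_feature(p, cand)
  n <- nrow(p$features)
  harmonize_feature(p, cand)
  expect_identical(nrow(p$features), n)
})

test_that("warehouse summaries are exact: empty, per-load, and per-study", {
  p <- toy_project()
  expect_identical(unlist(warehouse_summary(p)),
                   c(subjects = 0L, samples = 0L, assays = 0L,
                     clinical_features = 0L, molecular_features = 0L,
                     observations = 0L))
  load_toy_dm(p)
  register_template(p, "clin", "LB")
  load_fixture(p, c(lb_header,
                    "SA,001,ALB,Albumin,4.1,g/dL,2016-01-05,V1",
                    "SA,001,GLUC,Glucose,5.0,mmol/L,2016-01-05,V1",
                    "SA,002,ALB,Albumin,3.9,g/dL,2016-01-06,V1"),
               "tpl-LB", "SA")
  expect_identical(warehouse_summary(p)$observations, 3L)
  expect_identical(warehouse_summary(p, "SA")$subjects, 2L)
  expect_identical(warehouse_summary(p, "SB")$observations, 0L)
})

test_that("integration is idempotent under remove-and-reintegrate", {
  p <- toy_project()
  load_toy_dm(p)
  register_template(p, "clin", "LB")
  lines <- c(lb_header,
             "SA,001,ALB,Albumin,4.1,g/dL,2016-01-05,V1",
             "SA,002,GLUC,Glucose,5.0,mmol/L,2016-01-06,V1")
  res <- load_fixture(p, lines, "tpl-LB", "SA")
  snap <- list(obs = p$obs[order(p$obs$obs_uid), ],
               feats = p$features[order(p$features$feature_key), ])
  ds <- p$datasets[[res$dataset_id]]
  custodian:::remove_dataset(p, res$dataset_id)
  expect_identical(nrow(p$obs), 0L)
  expect_identical(nrow(p$features), 0L)
  p$datasets[[ds$dataset_id]] <- ds
  custodian:::integrate_dataset(p, ds)
  expect_identical(p$obs[order(p$obs$obs_uid), ], snap$obs)
  expect_identical(p$features[order(p$features$feature_key), ]$feature_key,
                   snap$feats$feature_key)
})
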
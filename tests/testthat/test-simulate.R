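# independent recount of a generated directory, straight off the files
recount_manifest <- function(dir) {
  doc <- jsonlite::fromJSON(file.path(dir, "project.json"),
                            simplifyVector = FALSE)
  subjects <- 0L
  feat <- character()
  obs <- 0L
  samples <- 0L
  events <- 0L
  for (step in doc$plan) {
    path <- file.path(dir, step$file)
    if (step$template == "DM") {
      subjects <- subjects + nrow(utils::read.csv(path,
                                                  colClasses = "character"))
    } else if (step$template %in% c("LB", "VS", "AE") &&
               !isTRUE(step$expect_fail)) {
      df <- utils::read.csv(path, colClasses = "character")
      obs <- obs + nrow(df)
      if (step$template == "AE") {
        feat <- union(feat, feature_key("event", step$domain,
                                        unique(df$AETERM)))
      } else {
        pre <- if (step$template == "LB") "LB" else "VS"
        feat <- union(feat, unique(feature_key(
          "finding", step$domain, df[[paste0(pre, "TESTCD")]],
          df[[paste0(pre, "ORRESU")]])))
      }
    } else if (step$template == "SAMPLE") {
      samples <- samples + nrow(utils::read.delim(path,
                                                  colClasses = "character"))
    } else if (startsWith(step$template, "MEASUREMENT")) {
      df <- utils::read.delim(path, colClasses = "character",
                              check.names = FALSE)
      cells <- as.matrix(df[-1])
      obs <- obs + sum(cells != "")
      events <- events + sum(colSums(cells != "") > 0)
    }
  }
  list(subjects = subjects, samples = samples, assays = events,
       clinical_features = length(feat), observations = obs)
}

test_that("the same seed and config reproduce identical bytes", {
  d1 <- tempfile(); d2 <- tempfile()
  m1 <- generate_project(preset_tiny(), d1)
  m2 <- generate_project(preset_tiny(), d2)
  expect_identical(m1, m2)
  files <- list.files(d1)
  expect_identical(files, list.files(d2))
  for (f in files)
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7))
  m3 <- generate_project(preset_tiny(seed = 999L), tempfile())
  expect_false(identical(m1$observations, m3$observations))
})

test_that("the manifest equals an independent recount of the files", {
  dir <- tempfile()
  m <- generate_project(preset_tiny(), dir)
  rc <- recount_manifest(dir)
  expect_identical(rc$subjects, m$subjects)
  expect_identical(rc$samples, m$samples)
  expect_identical(rc$assays, m$assays)
  expect_identical(rc$clinical_features, m$clinical_features)
  expect_identical(rc$observations, m$observations)
})

test_that("injected violations surface as exactly the promised issues", {
  dir <- tempfile()
  m <- generate_project(preset_tiny(inject = list(range = 2)), dir)
  expect_identical(m$injected[["S1_LB.csv"]]$RANGE_VIOLATION, 2L)
  res <- ingest_simulated(dir)
  bad <- res$results[["S1_LB.csv"]]
  expect_identical(bad$status, "failed")
  rng <- bad$report$issues[bad$report$issues$code == "RANGE_VIOLATION", ]
  expect_identical(nrow(rng), 2L)
  # failed file contributes nothing: summary still equals the manifest
  s <- warehouse_summary(res$project)
  expect_identical(s$observations, m$observations)
  expect_identical(s$clinical_features, m$clinical_features)
})

test_that("vocabulary and duplicate injections are caught too", {
  dir <- tempfile()
  m <- generate_project(preset_tiny(inject = list(vocab = 1,
                                                  duplicate = 1)), dir)
  res <- ingest_simulated(dir)
  bad <- res$results[["S1_LB.csv"]]
  expect_identical(bad$status, "failed")
  codes <- table(bad$report$issues$code)
  expect_identical(as.integer(codes[["VOCAB_VIOLATION"]]), 1L)
  expect_identical(as.integer(codes[["DUPLICATE_KEY"]]), 1L)
})

test_that("infeasible configs are rejected up front", {
  expect_error(generator_config(
    1L, "x", "multi-study", "x",
    studies = list(list(study_id = "S1", n_subjects = 2L, arms = "A",
                        visits = data.frame(label = "V1", day = 1))),
    domains = list(list(domain = "LB", activity = "a", template = "LB",
                        kind = "finding",
                        vars = list(list(code = "T1", label = "t", unit = "u",
                                         mu = 5, sigma = 1, lo = 0, hi = 10,
                                         valid = c(0, 8), digits = 1L))))),
    "infeasible")
  expect_error(generator_config(
    1L, "x", "multi-study", "x",
    studies = list(list(study_id = "S1", n_subjects = 2L, arms = "A",
                        visits = data.frame(label = "V1", day = 1))),
    domains = list(list(domain = "AE", activity = "a", template = "AE",
                        kind = "event",
                        terms = list(list(code = "X", label = "x",
                                          p = 1.4))))),
    "probabilities")
})

test_that("the vaccine-programme preset loads end to end", {
  dir <- tempfile()
  m <- generate_project(preset_biovacsafe_like(), dir)
  res <- ingest_simulated(dir)
  expect_true(all(vapply(res$results, function(r) r$status, "") == "loaded"))
  expect_length(res$project$studies, 5)
  arms <- unique(res$project$subjects$arm)
  expect_identical(length(arms), 7L)
  s <- warehouse_summary(res$project)
  expect_identical(s$subjects, m$subjects)
  expect_identical(s$observations, m$observations)
})
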
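tiny_warehouse <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- tempfile()
      generate_project(preset_tiny(), dir)
      cache <<- ingest_simulated(dir)$project
    }
    cache
  }
})

test_that("facet panels cover the warehouse metadata, and only metadata", {
  p <- tiny_warehouse()
  facets <- build_facets(p)
  expect_identical(names(facets$clinical$finding), c("LB", "VS"))
  expect_identical(names(facets$clinical$event), "AE")
  expect_identical(names(facets$molecular), "expression")
  leaves <- c(unlist(lapply(facets$clinical, function(doms)
    lapply(doms, function(fs) vapply(fs, `[[`, "", "feature_key")))),
    unlist(lapply(facets$molecular, function(fs)
      vapply(fs, `[[`, "", "feature_key"))))
  expect_setequal(unname(leaves), p$features$feature_key)
  expect_true(all(c("age", "sex") %in% facets$subject$characteristics))

  empty <- create_project("single-study", "nothing")
  f0 <- build_facets(empty)
  expect_length(f0$clinical, 0)
  expect_length(f0$molecular, 0)
})

test_that("rebuilding facets after a new load only adds leaves", {
  dir <- tempfile()
  generate_project(preset_tiny(), dir)
  p <- ingest_simulated(dir)$project
  before <- p$features$feature_key
  register_template(p, "lab-tests", "CM")
  load_fixture(p, c("STUDYID,USUBJID,CMTRT,CMDOSE,CMDOSU,CMSTDTC,CMENDTC",
                    "S1,S1-0001,PARACETAMOL,500,mg,2016-01-05,"),
               "tpl-CM", "S1")
  after <- build_facets(p)
  leaves <- unlist(lapply(after$clinical, function(doms)
    lapply(doms, function(fs) vapply(fs, `[[`, "", "feature_key"))))
  expect_true(all(before[!grepl("molecular", before)] %in%
                    c(leaves, p$features$feature_key)))
  expect_true(feature_key("intervention", "CM", "PARACETAMOL", "mg") %in%
                leaves)
})

test_that("filters validate their invariants at construction", {
  expect_error(filter_feature("x", range = c(10, 5)), "lo <= hi")
  expect_error(filter_characteristic("sex", values = character()),
               "non-empty")
  expect_error(filter_series("visit", values = NULL), "non-empty")
})

test_that("query evaluation matches the brute-force oracle", {
  p <- tiny_warehouse()
  # empty query: everyone, everything
  all <- evaluate_query(p, cohort_query())
  expect_identical(length(all$subjects), 10L)
  expect_identical(all$samples, sort(unique(p$samples$sample_key)))
  expect_identical(all$assays, sort(unique(p$assays$assay_id)))

  dia <- feature_key("finding", "VS", "DIABP", "mmHg")
  q <- cohort_query(filter_feature(dia, "result", range = c(75, 200)),
                    filter_series("visit", "V1"))
  got <- evaluate_query(p, q)
  want <- oracle_evaluate(p, q)
  expect_identical(got$subjects, want$subjects)
  expect_identical(got$samples, want$samples)
  expect_identical(got$assays, want$assays)
  # the series filter scopes the value filter: V2-only high readings excluded
  q2 <- cohort_query(filter_feature(dia, "result", range = c(75, 200)))
  expect_true(length(evaluate_query(p, q2)$subjects) >=
                length(got$subjects))

  expect_error(evaluate_query(p, cohort_query(
    filter_feature("finding|XX|NOPE|", "result", range = c(0, 1)))),
    "unknown facet", class = "custodian_not_found")
})

test_that("filters commute and never enlarge the cohort", {
  p <- tiny_warehouse()
  set.seed(7)
  for (trial in 1:25) {
    q <- random_query(p)
    full <- evaluate_query(p, q)
    # monotonicity against every strict sub-query
    for (drop in seq_along(q$filters)) {
      sub <- cohort_query(q$filters[-drop])
      subres <- evaluate_query(p, sub)
      expect_true(length(full$subjects) <= length(subres$subjects))
      expect_true(length(full$samples) <= length(subres$samples))
      expect_true(length(full$assays) <= length(subres$assays))
    }
    # commutativity
    perm <- cohort_query(q$filters[sample(length(q$filters))])
    expect_identical(evaluate_query(p, perm)$subjects, full$subjects)
  }
})

test_that("charts are cohort-synchronized and conserve counts", {
  p <- tiny_warehouse()
  sexes <- p$subject_chars[p$subject_chars$name == "sex", ]
  # characteristics are charted off the subject index
  dia <- feature_key("finding", "VS", "DIABP", "mmHg")
  full <- feature_chart(p, dia, "result")
  expect_identical(full$type, "numeric")
  expect_identical(sum(full$counts), full$total)
  expect_identical(full$total,
                   sum(p$obs$feature_key == dia))
  # an impossible cohort zeroes the chart
  q <- cohort_query(filter_feature(dia, "result", range = c(1e5, 2e5)))
  none <- feature_chart(p, dia, "result", evaluate_query(p, q))
  expect_identical(none$total, 0L)
  # categorical chart: severity counts over everyone
  ae <- p$features$feature_key[p$features$obs_class == "event"][1]
  ch <- feature_chart(p, ae, "severity")
  expect_identical(ch$type, "categorical")
  expect_identical(sum(ch$counts), ch$total)
})

test_that("checkout stores the query, not the rows; libraries are scoped", {
  dir <- tempfile()
  generate_project(preset_tiny(), dir)
  p <- ingest_simulated(dir)$project
  dia <- feature_key("finding", "VS", "DIABP", "mmHg")
  q <- cohort_query(filter_feature(dia, "result", range = c(60, 200)),
                    filter_series("visit", "V1"))
  ad1 <- checkout(p, "alice", q, title = "dbp cohort")
  ad2 <- checkout(p, "bob", q, title = "same query, other user")
  expect_false(identical(ad1$dataset_id, ad2$dataset_id))
  re <- evaluate_query(p, ad1$query)
  expect_identical(re$subjects, evaluate_query(p, q)$subjects)

  priv <- checkout(p, "alice", cohort_query(), title = "mine",
                   visibility = "private")
  shared <- checkout(p, "bob", cohort_query(), title = "theirs",
                     visibility = "shared")
  lst <- list_analyses(p, "alice")
  expect_true(priv$dataset_id %in% lst$dataset_id)
  expect_true(shared$dataset_id %in% lst$dataset_id)
  lst_bob <- list_analyses(p, "bob")
  expect_false(priv$dataset_id %in% lst_bob$dataset_id)

  expect_error(checkout(p, "alice", cohort_query(
    filter_feature("finding|ZZ|GONE|", "result", range = c(0, 1)))),
    class = "custodian_not_found")
})

test_that("exports regenerate deterministically and track new loads", {
  p <- toy_project()
  load_toy_dm(p)
  register_template(p, "clin", "VS")
  load_fixture(p, c(vs_header,
                    "SA,001,DIABP,Diastolic,82,mmHg,2016-01-05,V1",
                    "SA,002,DIABP,Diastolic,95,mmHg,2016-01-05,V1"),
               "tpl-VS", "SA")
  dia <- feature_key("finding", "VS", "DIABP", "mmHg")
  q <- cohort_query(filter_feature(dia, "result", range = c(90, 200)))
  ad <- checkout(p, "alice", q, title = "high dbp")

  out1 <- render_export(p, ad)
  expect_identical(nrow(out1$clinical), 1L)
  expect_identical(out1$clinical$subject_key, "SA/002")
  expect_true("DIABP.result" %in% names(out1$clinical))
  expect_identical(out1$metadata$feature_key[1], dia)

  d1 <- tempfile(); d2 <- tempfile()
  write_export(p, ad, d1)
  write_export(p, ad, d2)
  for (f in list.files(d1))
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))

  # one more matching subject arrives -> exactly one more row
  load_fixture(p, c(vs_header,
                    "SB,001,DIABP,Diastolic,93,mmHg,2016-01-05,V1"),
               "tpl-VS", "SB")
  out2 <- render_export(p, ad)
  expect_identical(nrow(out2$clinical), nrow(out1$clinical) + 1L)

  # deleting the source data makes the stored query name its missing facet
  for (id in names(p$datasets))
    if (p$datasets[[id]]$descriptor$domain_code == "VS")
      custodian:::remove_dataset(p, id)
  expect_error(render_export(p, ad), "missing facets",
               class = "custodian_not_found")
})

test_that("query documents round-trip", {
  dia <- feature_key("finding", "VS", "DIABP", "mmHg")
  q <- cohort_query(filter_feature(dia, "result", range = c(90, 200)),
                    filter_characteristic("sex", values = c("F")),
                    filter_series("visit", c("V1", "V2")))
  q2 <- deserialize_query(serialize_query(q))
  expect_identical(length(q2$filters), 3L)
  expect_identical(q2$filters[[1]]$range, c(90, 200))
  expect_identical(q2$filters[[3]]$values, c("V1", "V2"))
})
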
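# Independent brute-force query oracle.  It works row by row over the
# long-format warehouse export and the subject/sample index tables, never
# through the query engine's own code paths.

oracle_pass <- function(vals, flt) {
  if (flt$kind == "categorical-in") {
    toupper(trimws(vals)) %in% toupper(flt$values)
  } else {
    num <- suppressWarnings(as.numeric(vals))
    !is.na(num) & num >= flt$range[1] & num <= flt$range[2]
  }
}

oracle_evaluate <- function(project, query) {
  long <- export_long(project)
  all_subjects <- unique(project$subjects$subject_key)
  series_allow <- list()
  for (f in query$filters)
    if (f$scope == "series")
      series_allow[[f$name]] <- if (is.null(series_allow[[f$name]]))
        f$values else intersect(series_allow[[f$name]], f$values)

  keep <- all_subjects
  for (f in query$filters) {
    ok <- if (f$scope == "feature") {
      sel <- long[long$feature_key == f$feature_key &
                    long$property == f$property, , drop = FALSE]
      for (k in names(series_allow))
        sel <- sel[toupper(trimws(sel[[k]])) %in%
                     toupper(series_allow[[k]]), , drop = FALSE]
      unique(sel$subject_key[oracle_pass(sel$value, f)])
    } else if (f$scope == "characteristic") {
      if (f$name == "arm") {
        unique(project$subjects$subject_key[
          oracle_pass(project$subjects$arm, f)])
      } else if (f$name == "study") {
        unique(project$subjects$subject_key[
          oracle_pass(project$subjects$study_id, f)])
      } else {
        ch <- project$subject_chars
        ch <- ch[ch$name == f$name, , drop = FALSE]
        unique(ch$subject_key[oracle_pass(ch$value, f)])
      }
    } else if (f$scope == "series") {
      inst <- unique(long[c("subject_key", f$name)])
      unique(inst$subject_key[toupper(trimws(inst[[f$name]])) %in%
                                toupper(f$values)])
    } else all_subjects
    keep <- intersect(keep, ok)
  }
  samp <- project$samples[project$samples$subject_key %in% keep, ,
                          drop = FALSE]
  for (f in query$filters)
    if (f$scope == "sample")
      samp <- samp[oracle_pass(samp[[f$name]], f), , drop = FALSE]
  assays <- project$assays[project$assays$sample_key %in% samp$sample_key, ,
                           drop = FALSE]
  list(subjects = sort(unique(keep)),
       samples = sort(unique(samp$sample_key)),
       assays = sort(unique(assays$assay_id)))
}

# draw a random (but always well-formed) query against a project
random_query <- function(project) {
  filters <- list()
  nf <- sample(1:3, 1)
  clin <- project$features[project$features$obs_class == "finding", ,
                           drop = FALSE]
  for (i in seq_len(nf)) {
    kind <- sample(c("feature_num", "feature_cat", "char", "series", "arm"),
                   1)
    filters[[i]] <- switch(kind,
      feature_num = {
        key <- sample(clin$feature_key, 1)
        long <- export_long(project)
        v <- suppressWarnings(as.numeric(
          long$value[long$feature_key == key & long$property == "result"]))
        v <- v[!is.na(v)]
        if (!length(v)) v <- c(0, 1)
        rg <- sort(sample(v, 2, replace = TRUE))
        filter_feature(key, "result", range = rg)
      },
      feature_cat = {
        ev <- project$features[project$features$obs_class == "event", ,
                               drop = FALSE]
        if (nrow(ev)) {
          filter_feature(sample(ev$feature_key, 1), "severity",
                         values = sample(c("MILD", "MODERATE", "SEVERE"),
                                         sample(1:2, 1)))
        } else filter_characteristic("sex", values = sample(c("M", "F"), 1))
      },
      char = {
        pick <- sample(c("sex", "age"), 1)
        if (pick == "sex")
          filter_characteristic("sex", values = sample(c("M", "F"),
                                                       sample(1:2, 1)))
        else filter_characteristic("age", range = sort(sample(18:80, 2)))
      },
      series = {
        visits <- unique(project$obs$visit[nzchar(project$obs$visit)])
        filter_series("visit", sample(visits, 1))
      },
      arm = {
        arms <- unique(project$subjects$arm[nzchar(project$subjects$arm)])
        filter_characteristic("arm", values = sample(arms, 1))
      })
  }
  cohort_query(filters)
}
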
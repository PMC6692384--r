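# Faceted cohort query engine.  Facets are served from warehouse metadata
# only (the feature registry and subject characteristics index), never from
# observation values, mirroring the metadata/value access split.  Query
# semantics: conjunction across filters, disjunction within a categorical
# value set; a subject-level feature filter is existential over that
# subject's observations, scoped by any series filters in the same query.

#' Build the three-panel facet tree
#'
#' Panel one holds subject and study facets (demographics, arms, visits);
#' panel two the clinical observation features organized by general
#' observation class and domain; panel three the molecular features
#' organized by assay activity.  Leaves exactly cover the harmonized
#' features and subject characteristics present in the warehouse.
#'
#' @param project a project.
#' @return A list of class `tm_facets` with elements `subject`, `clinical`,
#'   `molecular`.
#' @export
build_facets <- function(project) {
  subject <- list(
    characteristics = sort(unique(project$subject_chars$name)),
    arms = sort(unique(project$subjects$arm[nzchar(project$subjects$arm)])),
    studies = names(project$studies),
    visits = sort(unique(project$obs$visit[nzchar(project$obs$visit)])))
  f <- project$features
  clinical <- list()
  for (cls in TM_OBS_CLASSES) {
    fc <- f[f$obs_class == cls, , drop = FALSE]
    if (!nrow(fc)) next
    doms <- list()
    for (dm in unique(fc$domain_code)) {
      fd <- fc[fc$domain_code == dm, , drop = FALSE]
      doms[[dm]] <- lapply(seq_len(nrow(fd)), function(i)
        list(feature_key = fd$feature_key[i], label = fd$object_label[i],
             object_code = fd$object_code[i], unit = fd$unit[i],
             properties = strsplit(fd$properties[i], ";")[[1]]))
    }
    clinical[[cls]] <- doms
  }
  molecular <- list()
  fm <- f[f$obs_class == "molecular", , drop = FALSE]
  if (nrow(fm)) {
    key2act <- unique(project$obs[project$obs$obs_class == "molecular",
                                  c("feature_key", "activity_id")])
    for (act in unique(key2act$activity_id)) {
      keys <- key2act$feature_key[key2act$activity_id == act]
      fa <- fm[fm$feature_key %in% keys, , drop = FALSE]
      molecular[[act]] <- lapply(seq_len(nrow(fa)), function(i)
        list(feature_key = fa$feature_key[i], label = fa$object_label[i]))
    }
  }
  structure(list(subject = subject, clinical = clinical,
                 molecular = molecular), class = "tm_facets")
}

# ---- filters ------------------------------------------------------------

new_filter <- function(scope, kind, values = NULL, range = NULL, ...) {
  if (kind == "categorical-in") {
    values <- as.character(values)
    if (!length(values)) tm_stop("categorical filter needs a non-empty set")
  } else if (kind == "numeric-range") {
    range <- as.numeric(range)
    if (length(range) != 2 || anyNA(range) || range[1] > range[2])
      tm_stop("numeric filter needs c(lo, hi) with lo <= hi")
  } else tm_stop("kind must be 'categorical-in' or 'numeric-range'")
  structure(list(scope = scope, kind = kind, values = values, range = range,
                 ...), class = "tm_filter")
}

#' Query filters
#'
#' `filter_feature()` targets a (feature, property) pair,
#' `filter_characteristic()` a subject characteristic (including `"arm"`
#' and `"study"`), `filter_series()` a longitudinal key such as the visit,
#' and `filter_sample()` a biosample attribute.  Categorical filters keep a
#' value in a selected set (disjunction); numeric filters keep values in an
#' inclusive range.
#'
#' @param feature_key a harmonized feature key ([feature_key()]).
#' @param property the observed property to filter on (default
#'   `"result"`; assays use `"value"`).
#' @param values character set for categorical filters.
#' @param range numeric `c(lo, hi)` for range filters.
#' @return A `tm_filter`.
#' @export
filter_feature <- function(feature_key, property = "result", values = NULL,
                           range = NULL) {
  new_filter("feature", if (is.null(range)) "categorical-in" else
    "numeric-range", values, range,
    feature_key = feature_key, property = property)
}

#' @rdname filter_feature
#' @param name characteristic / series key / sample attribute name.
#' @export
filter_characteristic <- function(name, values = NULL, range = NULL) {
  new_filter("characteristic", if (is.null(range)) "categorical-in" else
    "numeric-range", values, range, name = name)
}

#' @rdname filter_feature
#' @export
filter_series <- function(name = "visit", values) {
  name <- match.arg(name, c("visit", "study_day", "timepoint"))
  new_filter("series", "categorical-in", values, name = name)
}

#' @rdname filter_feature
#' @export
filter_sample <- function(name = "specimen_type", values) {
  new_filter("sample", "categorical-in", values, name = name)
}

#' Assemble a query
#'
#' Filters combine by conjunction; their order is display metadata only —
#' any permutation evaluates to the same cohort.
#'
#' @param ... `tm_filter` objects.
#' @return A `tm_query`.
#' @export
cohort_query <- function(...) {
  filters <- list(...)
  if (length(filters) == 1 && is.list(filters[[1]]) &&
      !inherits(filters[[1]], "tm_filter"))
    filters <- filters[[1]]
  for (f in filters) stopifnot(inherits(f, "tm_filter"))
  structure(list(filters = filters), class = "tm_query")
}

check_target <- function(project, flt) {
  if (flt$scope == "feature") {
    if (!flt$feature_key %in% project$features$feature_key)
      tm_stop(sprintf("unknown facet: feature '%s'", flt$feature_key),
              class = "custodian_not_found")
  } else if (flt$scope == "characteristic") {
    known <- c("arm", "study", unique(project$subject_chars$name))
    if (!flt$name %in% known)
      tm_stop(sprintf("unknown facet: subject characteristic '%s'", flt$name),
              class = "custodian_not_found")
  } else if (flt$scope == "sample") {
    if (!flt$name %in% c("specimen_type", "visit"))
      tm_stop(sprintf("unknown facet: sample attribute '%s'", flt$name),
              class = "custodian_not_found")
  }
  invisible(TRUE)
}

in_filter <- function(values, flt) {
  if (flt$kind == "categorical-in") {
    toupper(trimws(values)) %in% toupper(flt$values)
  } else {
    num <- suppressWarnings(as.numeric(values))
    !is.na(num) & num >= flt$range[1] & num <= flt$range[2]
  }
}

subjects_for_characteristic <- function(project, flt) {
  if (flt$name == "arm")
    return(unique(project$subjects$subject_key[
      in_filter(project$subjects$arm, flt)]))
  if (flt$name == "study")
    return(unique(project$subjects$subject_key[
      in_filter(project$subjects$study_id, flt)]))
  ch <- project$subject_chars[project$subject_chars$name == flt$name, ,
                              drop = FALSE]
  unique(ch$subject_key[in_filter(ch$value, flt)])
}

subjects_for_feature <- function(project, flt, series_restr) {
  inst <- project$obs[project$obs$feature_key == flt$feature_key, ,
                      drop = FALSE]
  for (key in names(series_restr)) {
    inst <- inst[toupper(trimws(inst[[key]])) %in%
                   toupper(series_restr[[key]]), , drop = FALSE]
  }
  pr <- project$obs_props[project$obs_props$obs_uid %in% inst$obs_uid &
                            project$obs_props$property == flt$property, ,
                          drop = FALSE]
  hit <- pr$obs_uid[in_filter(pr$value, flt)]
  unique(inst$subject_key[inst$obs_uid %in% hit])
}

#' Evaluate a query against the warehouse
#'
#' A subject satisfies a feature filter iff at least one of its
#' observations of that feature — restricted to any series filters in the
#' same query — has the property value in the filter's set or range.  The
#' cohort is the set of subjects satisfying all filters; its samples are
#' the samples of those subjects further restricted by sample-level
#' filters, and its assay events those of the remaining samples.
#'
#' @param project a project.
#' @param query a [cohort_query()].
#' @return A list of class `tm_cohort` with `subjects`, `samples`,
#'   `assays` (sorted character vectors) and `counts`.
#' @export
evaluate_query <- function(project, query) {
  stopifnot(inherits(query, "tm_query"))
  for (f in query$filters) check_target(project, f)
  # series filters on the same key conjoin (intersection), like all other
  # filters; this keeps adding a filter monotone
  series_restr <- list()
  for (f in query$filters)
    if (f$scope == "series")
      series_restr[[f$name]] <- if (is.null(series_restr[[f$name]]))
        f$values else intersect(series_restr[[f$name]], f$values)
  subjects <- unique(project$subjects$subject_key)
  for (f in query$filters) {
    keep <- switch(f$scope,
      characteristic = subjects_for_characteristic(project, f),
      feature = subjects_for_feature(project, f, series_restr),
      series = {
        inst <- project$obs
        unique(inst$subject_key[toupper(trimws(inst[[f$name]])) %in%
                                  toupper(f$values)])
      },
      sample = subjects)   # sample filters restrict samples, not subjects
    subjects <- intersect(subjects, keep)
  }
  samp <- project$samples[project$samples$subject_key %in% subjects, ,
                          drop = FALSE]
  for (f in query$filters)
    if (f$scope == "sample")
      samp <- samp[in_filter(samp[[f$name]], f), , drop = FALSE]
  assays <- project$assays[project$assays$sample_key %in% samp$sample_key, ,
                           drop = FALSE]
  structure(list(subjects = sort(unique(subjects)),
                 samples = sort(unique(samp$sample_key)),
                 assays = sort(unique(assays$assay_id)),
                 counts = c(subjects = length(unique(subjects)),
                            samples = length(unique(samp$sample_key)),
                            assays = length(unique(assays$assay_id)))),
            class = "tm_cohort")
}

#' @export
print.tm_cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects, %d samples, %d assays\n",
              x$counts["subjects"], x$counts["samples"], x$counts["assays"]))
  invisible(x)
}

#' Chart summary for one facet, synchronized to a cohort
#'
#' Categorical values yield category counts; numeric values a histogram
#' with Freedman-Diaconis bin widths (Sturges fallback when the IQR is
#' zero), with stated bin edges so summaries are reproducible.  Counts run
#' over the cohort's observations only; bin/category totals equal the
#' number of cohort observations of the feature.
#'
#' @param project a project.
#' @param feature_key a harmonized feature key.
#' @param property observed property (default `"result"`).
#' @param cohort optional `tm_cohort`; default is everyone.
#' @return A list: `type` (`"categorical"`/`"numeric"`), `counts`, and for
#'   numeric charts `breaks`; `total` is the observation count.
#' @export
feature_chart <- function(project, feature_key, property = "result",
                          cohort = NULL) {
  inst <- project$obs[project$obs$feature_key == feature_key, , drop = FALSE]
  if (!is.null(cohort))
    inst <- inst[inst$subject_key %in% cohort$subjects, , drop = FALSE]
  pr <- project$obs_props[project$obs_props$obs_uid %in% inst$obs_uid &
                            project$obs_props$property == property, ,
                          drop = FALSE]
  v <- pr$value
  num <- suppressWarnings(as.numeric(v))
  if (length(v) && !anyNA(num)) {
    if (length(unique(num)) == 1) {
      breaks <- c(num[1] - 0.5, num[1] + 0.5)
    } else {
      h <- 2 * stats::IQR(num) / length(num)^(1 / 3)
      nb <- if (h > 0) max(1L, ceiling(diff(range(num)) / h))
            else grDevices::nclass.Sturges(num)
      breaks <- seq(min(num), max(num), length.out = nb + 1L)
    }
    counts <- as.integer(table(cut(num, breaks, include.lowest = TRUE)))
    return(list(type = "numeric", breaks = breaks, counts = counts,
                total = length(num)))
  }
  counts <- table(v)
  list(type = "categorical",
       counts = stats::setNames(as.integer(counts), names(counts)),
       total = length(v))
}

# ---- data cart ----------------------------------------------------------

query_to_list <- function(q)
  list(filters = lapply(q$filters, unclass))

query_from_list <- function(x) {
  filters <- lapply(x$filters, function(f) {
    structure(list(scope = f$scope, kind = f$kind,
                   values = if (!is.null(f$values))
                     as.character(unlist(f$values)),
                   range = if (!is.null(f$range))
                     as.numeric(unlist(f$range)),
                   feature_key = f$feature_key, property = f$property,
                   name = f$name), class = "tm_filter")
  })
  structure(list(filters = filters), class = "tm_query")
}

#' Serialize / deserialize a query document
#' @param query a [cohort_query()].
#' @return JSON text / a `tm_query`.
#' @export
serialize_query <- function(query)
  jsonlite::toJSON(query_to_list(query), auto_unbox = TRUE, null = "null",
                   digits = NA, pretty = TRUE)

#' @rdname serialize_query
#' @param text JSON produced by `serialize_query()`.
#' @export
deserialize_query <- function(text)
  query_from_list(jsonlite::fromJSON(text, simplifyVector = FALSE))

#' Save a query, or check it out as an analysis dataset
#'
#' An analysis dataset stores the query, never the materialized result:
#' its export files are regenerated from the live warehouse on demand, so
#' they track later loads.  Datasets live in a user-scoped library separate
#' from project storage and carry a visibility flag.
#'
#' @param project a project.
#' @param user owning user.
#' @param query a [cohort_query()]; must evaluate without error.
#' @param title,description,tags descriptive metadata.
#' @param visibility `"private"`, `"shared"` or `"published"`.
#' @param select optional list of targets to export, each
#'   `list(feature_key=, property=)`; defaults to the query's feature
#'   filters.
#' @return The stored entry (class `tm_analysis`), with a unique id.
#' @export
checkout <- function(project, user, query, title = "analysis",
                     description = "", tags = character(),
                     visibility = c("private", "shared", "published"),
                     select = NULL) {
  visibility <- match.arg(visibility)
  evaluate_query(project, query)   # refuse unknown-target queries
  if (is.null(select)) {
    select <- lapply(Filter(function(f) f$scope == "feature", query$filters),
                     function(f) list(feature_key = f$feature_key,
                                      property = f$property))
  }
  project$analysis_counter <- project$analysis_counter + 1L
  id <- fresh_id("AD", project$analysis_counter)
  entry <- structure(list(dataset_id = id, owner = user, title = title,
                          description = description, tags = tags,
                          query = query, select = select,
                          visibility = visibility), class = "tm_analysis")
  project$analyses[[id]] <- entry
  entry
}

#' @rdname checkout
#' @export
save_query <- function(project, user, query, title = "saved query") {
  checkout(project, user, query, title = title, visibility = "private",
           select = list())
}

#' List the analysis datasets visible to a user
#'
#' A user sees their own datasets plus anything shared or published by
#' others.
#'
#' @param project a project.
#' @param user the requesting user.
#' @return Data frame of dataset metadata.
#' @export
list_analyses <- function(project, user) {
  vis <- Filter(function(a)
    a$owner == user || a$visibility %in% c("shared", "published"),
    project$analyses)
  if (!length(vis))
    return(data.frame(dataset_id = character(), owner = character(),
                      title = character(), visibility = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(unname(vis), function(a)
    data.frame(dataset_id = a$dataset_id, owner = a$owner, title = a$title,
               visibility = a$visibility, stringsAsFactors = FALSE)))
}

visit_order <- function(project, visits) {
  days <- rep(NA_real_, length(visits))
  for (s in project$studies) {
    hit <- match(visits, s$visits$label)
    days[!is.na(hit)] <- s$visits$day[hit[!is.na(hit)]]
  }
  order(days, visits, na.last = TRUE)
}

#' Regenerate the export tables of an analysis dataset
#'
#' Re-evaluates the stored query against the warehouse *now* and emits (a)
#' a subject-level clinical table, one row per subject-visit pair and one
#' column per selected clinical feature-property, (b) one matrix per
#' selected assay restricted to cohort samples, and (c) a field-metadata
#' sheet describing every exported column.  The same warehouse state and
#' query always produce byte-identical output (stable row and column
#' order).
#'
#' @param project a project.
#' @param analysis a `tm_analysis` or its id.
#' @return A list with `clinical` (data frame), `assays` (named list of
#'   data frames) and `metadata` (data frame).
#' @export
render_export <- function(project, analysis) {
  if (is.character(analysis)) analysis <- project$analyses[[analysis]]
  if (is.null(analysis)) tm_stop("unknown analysis dataset",
                                 class = "custodian_not_found")
  missing <- character()
  for (s in analysis$select)
    if (!s$feature_key %in% project$features$feature_key)
      missing <- c(missing, s$feature_key)
  for (f in analysis$query$filters)
    if (f$scope == "feature" &&
        !f$feature_key %in% project$features$feature_key)
      missing <- c(missing, f$feature_key)
  if (length(missing))
    tm_stop(paste("export error; missing facets:",
                  paste(unique(missing), collapse = ", ")),
            class = "custodian_not_found")
  cohort <- evaluate_query(project, analysis$query)

  # order selected targets by feature-registry (facet tree) order
  sel <- analysis$select
  if (length(sel)) {
    ord <- order(match(vapply(sel, `[[`, "", "feature_key"),
                       project$features$feature_key))
    sel <- sel[ord]
  }
  clin_sel <- Filter(function(s) {
    cls <- project$features$obs_class[
      match(s$feature_key, project$features$feature_key)]
    cls != "molecular"
  }, sel)
  mol_sel <- Filter(function(s) {
    cls <- project$features$obs_class[
      match(s$feature_key, project$features$feature_key)]
    cls == "molecular"
  }, sel)

  meta_rows <- list()
  clinical <- data.frame(subject_key = character(), study_id = character(),
                         visit = character(), stringsAsFactors = FALSE)
  if (length(clin_sel)) {
    keys <- vapply(clin_sel, `[[`, "", "feature_key")
    inst <- project$obs[project$obs$feature_key %in% keys &
                          project$obs$subject_key %in% cohort$subjects, ,
                        drop = FALSE]
    base <- unique(inst[c("subject_key", "study_id", "visit")])
    base <- base[order(base$subject_key, base$visit), , drop = FALSE]
    rownames(base) <- NULL
    clinical <- base
    for (s in clin_sel) {
      fidx <- match(s$feature_key, project$features$feature_key)
      colname <- paste0(project$features$object_code[fidx], ".", s$property)
      sub <- inst[inst$feature_key == s$feature_key, , drop = FALSE]
      pr <- project$obs_props[project$obs_props$obs_uid %in% sub$obs_uid &
                                project$obs_props$property == s$property, ,
                              drop = FALSE]
      m <- match(pr$obs_uid, sub$obs_uid)
      cellkey <- paste_key(sub$subject_key[m], sub$visit[m])
      rowkey <- paste_key(clinical$subject_key, clinical$visit)
      clinical[[colname]] <- pr$value[match(rowkey, cellkey)]
      meta_rows[[colname]] <- data.frame(
        table = "clinical", column = colname,
        feature_key = s$feature_key,
        label = project$features$object_label[fidx], property = s$property,
        domain = project$features$domain_code[fidx],
        class = project$features$obs_class[fidx],
        unit = project$features$unit[fidx], stringsAsFactors = FALSE)
    }
  }

  assays <- list()
  mol_acts <- unique(project$obs$activity_id[
    project$obs$feature_key %in% vapply(mol_sel, `[[`, "", "feature_key")])
  for (act in sort(mol_acts)) {
    inst <- project$obs[project$obs$activity_id == act &
                          project$obs$sample_key %in% cohort$samples, ,
                        drop = FALSE]
    pr <- project$obs_props[match(inst$obs_uid, project$obs_props$obs_uid), ]
    feats <- sort(unique(inst$object_code))
    samps <- sort(unique(inst$sample_key))
    mat <- data.frame(FEATUREID = feats, stringsAsFactors = FALSE)
    for (sk in samps) {
      sel_i <- inst$sample_key == sk
      mat[[sk]] <- pr$value[sel_i][match(feats, inst$object_code[sel_i])]
    }
    assays[[act]] <- mat
    meta_rows[[paste0("assay:", act)]] <- data.frame(
      table = act, column = "matrix", feature_key = "",
      label = sprintf("%d features x %d samples", length(feats),
                      length(samps)),
      property = "value", domain = unique(inst$domain_code)[1] %||% "",
      class = "molecular", unit = "", stringsAsFactors = FALSE)
  }
  metadata <- if (length(meta_rows)) do.call(rbind, c(meta_rows,
                                                      make.row.names = FALSE))
    else data.frame(table = character(), column = character(),
                    feature_key = character(), label = character(),
                    property = character(), domain = character(),
                    class = character(), unit = character(),
                    stringsAsFactors = FALSE)
  list(clinical = clinical, assays = assays, metadata = metadata)
}

#' Write an analysis export to disk as delimited text
#'
#' @param project a project.
#' @param analysis a `tm_analysis` or id.
#' @param dir output directory (created if needed).
#' @return Paths of the files written, invisibly.
#' @export
write_export <- function(project, analysis, dir) {
  out <- render_export(project, analysis)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  p <- file.path(dir, "clinical.csv")
  utils::write.csv(out$clinical, p, row.names = FALSE, quote = TRUE)
  paths <- c(paths, p)
  for (act in names(out$assays)) {
    p <- file.path(dir, paste0("assay-", act, ".tsv"))
    utils::write.table(out$assays[[act]], p, sep = "\t", row.names = FALSE,
                       qmethod = "double")
    paths <- c(paths, p)
  }
  p <- file.path(dir, "field-metadata.csv")
  utils::write.csv(out$metadata, p, row.names = FALSE, quote = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}
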
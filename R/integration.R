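# Integration: extract primary-dataset content into the common observation
# model and maintain the warehouse.  An observation instance decomposes a
# fact into object-of-observation, subject-of-observation, observed
# properties, temporal properties and time-series properties; instances are
# stored long (EAV) with the feature metadata split from the measured
# values.  Mapping is driven entirely by descriptor field *roles* and
# *labels*, never by column names, which is what makes differently named
# but role-equivalent descriptors interchangeable.

prop_name <- function(label) gsub("[^a-z0-9]+", "_", tolower(trimws(label)))

#' Canonical harmonization key of an observation feature
#'
#' Two variables from different studies are the same warehouse feature iff
#' they agree on observation class, dataset domain, object code
#' (case-insensitively) and unit (trimmed, lowercased; no conversion).
#'
#' @param obs_class `"finding"`, `"event"`, `"intervention"` or
#'   `"molecular"`.
#' @param domain_code dataset domain (e.g. `"LB"`).
#' @param object_code the observed thing (e.g. `"ALB"`, `"headache"`).
#' @param unit optional unit string.
#' @return Character key; a pure function of its inputs.
#' @export
feature_key <- function(obs_class, domain_code, object_code, unit = "") {
  paste(obs_class, toupper(domain_code), toupper(trimws(object_code)),
        norm_unit(unit), sep = "|")
}

# per-row "; "-joined "name=value" string for temporal fields
join_timing <- function(parts) {
  out <- rep("", length(parts[[1]]))
  for (p in parts) {
    live <- !is.na(p)
    out[live] <- ifelse(out[live] == "", p[live],
                        paste0(out[live], "; ", p[live]))
  }
  out
}

qualifier_roles <- c("result-qualifier", "unit-qualifier",
                     "grouping-qualifier", "other-qualifier")

# Extraction for long-layout clinical-observation datasets: one instance per
# validated row.
extract_clinical <- function(project, dataset) {
  d <- dataset$descriptor
  records <- dataset$records
  n <- nrow(records)
  colmap <- dataset$colmap
  getcol <- function(f) {
    col <- colmap[[f$name]]
    if (is.null(col) || is.na(col)) rep("", n) else as.character(records[[col]])
  }
  sids <- row_study_ids(list(records = records, colmap = colmap), d,
                        dataset$study_ids[1] %||% NA_character_)
  subj <- trimws(getcol(fields_with_role(d, "subject-identifier")[[1]]))
  subject_key <- paste(sids, subj, sep = "/")
  topic <- trimws(getcol(fields_with_role(d, "topic")[[1]]))
  unitf <- fields_with_role(d, "unit-qualifier")
  unit <- if (length(unitf)) norm_unit(getcol(unitf[[1]])) else rep("", n)
  obs_class <- d$meta$obs_class

  visit <- rep("", n); study_day <- rep("", n); timepoint <- rep("", n)
  extra_series <- list()
  for (f in fields_with_role(d, "series-timing")) {
    v <- trimws(getcol(f)); pn <- prop_name(f$label)
    if (pn == "visit") visit <- v
    else if (pn == "study_day") study_day <- v
    else if (pn %in% c("timepoint", "time_point")) timepoint <- v
    else extra_series[[pn]] <- v
  }
  tparts <- list()
  for (f in fields_with_role(d, "temporal-timing")) {
    v <- trimws(getcol(f))
    tparts[[prop_name(f$label)]] <-
      ifelse(is_blank(v), NA, paste0(prop_name(f$label), "=", v))
  }
  for (pn in names(extra_series)) {
    v <- extra_series[[pn]]
    tparts[[pn]] <- ifelse(is_blank(v), NA, paste0(pn, "=", v))
  }
  timing <- if (length(tparts)) join_timing(tparts) else rep("", n)

  uid <- paste(dataset$dataset_id, seq_len(n), sep = ":")
  instances <- data.frame(
    obs_uid = uid, study_id = sids, subject_key = subject_key,
    sample_key = NA_character_, obs_class = obs_class,
    domain_code = d$domain_code, object_code = toupper(topic), unit = unit,
    feature_key = feature_key(obs_class, d$domain_code, topic, unit),
    visit = visit, study_day = study_day, timepoint = timepoint,
    timing = timing, dataset_id = dataset$dataset_id, row_index = seq_len(n),
    activity_id = dataset$activity_id, stringsAsFactors = FALSE)

  props <- list()
  skip_roles <- c("subject-identifier", "study-identifier", "topic",
                  "temporal-timing", "series-timing", "sample-identifier")
  for (f in d$fields) {
    if (f$name == "*" || f$role %in% skip_roles) next
    v <- getcol(f)
    live <- !is_blank(v)
    if (!any(live)) next
    pn <- if (f$role == "unit-qualifier") "unit" else prop_name(f$label)
    props[[length(props) + 1L]] <- data.frame(
      obs_uid = uid[live], dataset_id = dataset$dataset_id, property = pn,
      value = trimws(v[live]), stringsAsFactors = FALSE)
  }
  properties <- if (length(props)) do.call(rbind, props) else empty_props()

  # display labels, when the descriptor carries a companion label field
  labf <- Filter(function(f) prop_name(f$label) %in%
                   c("test_name", "coded_term", "name"), d$fields)
  labels <- NULL
  if (length(labf)) {
    lv <- trimws(getcol(labf[[1]]))
    keep <- !is_blank(lv) & !duplicated(instances$feature_key)
    labels <- stats::setNames(lv[keep], instances$feature_key[keep])
  }
  list(instances = instances, properties = properties, labels = labels)
}

# Extraction for matrix-layout assay datasets: one molecular observation per
# non-blank (feature row, sample column) cell; the subject is inherited from
# the sample.
extract_matrix <- function(project, dataset) {
  d <- dataset$descriptor
  records <- dataset$records
  topicf <- fields_with_role(d, "topic")[[1]]
  featcol <- dataset$colmap[[topicf$name]]
  feats <- trimws(records[[featcol]])
  cells <- list()
  for (sc in dataset$sample_columns) {
    hit <- match(sc, project$samples$sample_id)
    if (is.na(hit)) hit <- match(sc, project$samples$sample_key)
    skey <- project$samples$sample_key[hit]
    subj <- project$samples$subject_key[hit]
    sid <- project$samples$study_id[hit]
    v <- as.character(records[[sc]])
    live <- !is_blank(v)
    if (!any(live)) next
    cells[[sc]] <- data.frame(
      row_index = which(live), object_code = feats[live],
      value = trimws(v[live]), sample_key = skey, subject_key = subj,
      study_id = sid, stringsAsFactors = FALSE)
  }
  if (!length(cells))
    return(list(instances = empty_obs(), properties = empty_props(),
                labels = NULL))
  cells <- do.call(rbind, cells)
  uid <- paste(dataset$dataset_id, cells$row_index, cells$sample_key,
               sep = ":")
  instances <- data.frame(
    obs_uid = uid, study_id = cells$study_id,
    subject_key = cells$subject_key, sample_key = cells$sample_key,
    obs_class = "molecular", domain_code = d$domain_code,
    object_code = toupper(cells$object_code), unit = "",
    feature_key = feature_key("molecular", d$domain_code, cells$object_code),
    visit = "", study_day = "", timepoint = "", timing = "",
    dataset_id = dataset$dataset_id, row_index = cells$row_index,
    activity_id = dataset$activity_id, stringsAsFactors = FALSE)
  properties <- data.frame(obs_uid = uid, dataset_id = dataset$dataset_id,
                           property = "value", value = cells$value,
                           stringsAsFactors = FALSE)
  fm <- project$feature_meta[[dataset$activity_id]]
  labels <- NULL
  if (!is.null(fm)) {
    keep <- !duplicated(instances$feature_key)
    lab <- fm$label[match(toupper(instances$object_code[keep]),
                          toupper(fm$feature_id))]
    live <- !is.na(lab)
    labels <- stats::setNames(lab[live], instances$feature_key[keep][live])
  }
  list(instances = instances, properties = properties, labels = labels)
}

#' Extract a primary dataset's content into the observation model
#'
#' Long clinical layouts yield exactly one observation instance per row;
#' matrix layouts yield one molecular observation per non-blank cell, with
#' the subject inherited from the sample.  Subject (DM) datasets update the
#' subject index and emit no observations; biosample datasets create
#' biosample records; feature datasets register assay feature metadata.
#'
#' @param project the project (supplies subject/sample resolution).
#' @param dataset a loaded `tm_dataset`.
#' @return A list with data frames `instances` (one row per observation)
#'   and `properties` (one row per observed property value).
#' @export
extract_observations <- function(project, dataset) {
  kind <- dataset$descriptor$meta$kind
  out <- switch(kind,
    "clinical-observation" = extract_clinical(project, dataset),
    "assay-measurement" = extract_matrix(project, dataset),
    list(instances = empty_obs(), properties = empty_props(), labels = NULL))
  out[c("instances", "properties")]
}

#' Decompose a single record into an observation instance
#'
#' The record's values partition by descriptor role: identifiers resolve
#' the subject, the topic names the object-of-observation, qualifier values
#' become observed properties, temporal-timing values become temporal
#' attributes and series-timing values become longitudinal keys.
#'
#' @param record a one-row data frame or named list of raw values.
#' @param descriptor a long-layout clinical `tm_descriptor`.
#' @param project the project (for subject resolution).
#' @param study_id fallback study id.
#' @return A `tm_observation` with fields `feature`, `subject_key`,
#'   `sample_key`, `properties`, `temporal`, `series`, `provenance`.
#' @export
decompose_record <- function(record, descriptor, project, study_id = NULL) {
  rec <- as.data.frame(as.list(record), check.names = FALSE,
                       stringsAsFactors = FALSE)
  named <- Filter(function(f) f$name != "*", descriptor$fields)
  fnames <- vapply(named, function(f) f$name, "")
  colmap <- stats::setNames(names(rec)[match(toupper(fnames),
                                             toupper(names(rec)))], fnames)
  ds <- structure(list(dataset_id = "adhoc", descriptor = descriptor,
                       activity_id = NA_character_, study_ids = study_id,
                       records = rec, colmap = colmap,
                       sample_columns = character()), class = "tm_dataset")
  ext <- extract_clinical(project, ds)
  inst <- ext$instances[1, ]
  pr <- ext$properties
  series <- Filter(nzchar, list(visit = inst$visit, study_day = inst$study_day,
                                timepoint = inst$timepoint))
  temporal <- list()
  if (nzchar(inst$timing)) {
    for (kv in strsplit(inst$timing, "; ", fixed = TRUE)[[1]]) {
      bits <- strsplit(kv, "=", fixed = TRUE)[[1]]
      temporal[[bits[1]]] <- paste(bits[-1], collapse = "=")
    }
  }
  structure(list(
    feature = list(feature_key = inst$feature_key, obs_class = inst$obs_class,
                   domain_code = inst$domain_code,
                   object_code = inst$object_code, unit = inst$unit),
    subject_key = inst$subject_key, sample_key = inst$sample_key,
    properties = stats::setNames(as.list(pr$value), pr$property),
    temporal = temporal, series = series,
    provenance = list(dataset_id = ds$dataset_id, row_index = 1L)),
    class = "tm_observation")
}

#' Register a candidate feature, merging on the harmonization key
#'
#' If the registry already holds a feature with the same [feature_key()],
#' the candidate is merged into it (contributing datasets and property
#' names accumulate) and the registry size is unchanged; otherwise the
#' candidate is registered.  Same-named features with different units are
#' deliberately kept apart and flagged by [harmonization_report()].
#'
#' @param project the project whose warehouse holds the feature registry.
#' @param candidate a list with `feature_key`, `obs_class`, `domain_code`,
#'   `object_code`, `object_label`, `unit`, `properties` (character
#'   vector), `dataset_id`.
#' @return The registered feature row as a list.
#' @export
harmonize_feature <- function(project, candidate) {
  idx <- match(candidate$feature_key, project$features$feature_key)
  if (!is.na(idx)) {
    ds <- union(strsplit(project$features$datasets[idx], ";")[[1]],
                candidate$dataset_id)
    project$features$datasets[idx] <- paste(ds, collapse = ";")
    pr <- union(strsplit(project$features$properties[idx], ";")[[1]],
                candidate$properties)
    project$features$properties[idx] <- paste(pr, collapse = ";")
    if (!nzchar(project$features$object_label[idx]) &&
        length(candidate$object_label) && nzchar(candidate$object_label))
      project$features$object_label[idx] <- candidate$object_label
    return(as.list(project$features[idx, ]))
  }
  row <- data.frame(
    feature_key = candidate$feature_key, obs_class = candidate$obs_class,
    domain_code = candidate$domain_code, object_code = candidate$object_code,
    object_label = candidate$object_label %||% candidate$object_code,
    unit = candidate$unit %||% "",
    properties = paste(candidate$properties, collapse = ";"),
    datasets = candidate$dataset_id, stringsAsFactors = FALSE)
  project$features <- rbind(project$features, row)
  as.list(row)
}

# integrate one loaded dataset (called by load_dataset after validation)
integrate_dataset <- function(project, dataset) {
  d <- dataset$descriptor
  kind <- d$meta$kind
  records <- dataset$records
  colmap <- dataset$colmap
  getcol <- function(role_or_name, by = c("role", "name")) {
    by <- match.arg(by)
    f <- if (by == "role") {
      fl <- fields_with_role(d, role_or_name)
      if (!length(fl)) return(NULL) else fl[[1]]
    } else descriptor_field(d, role_or_name)
    if (is.null(f)) return(NULL)
    col <- colmap[[f$name]]
    if (is.null(col) || is.na(col)) NULL else as.character(records[[col]])
  }

  if (kind == "subject") {
    sids <- row_study_ids(list(records = records, colmap = colmap), d,
                          dataset$study_ids[1] %||% NA_character_)
    subj <- trimws(getcol("subject-identifier"))
    arm <- getcol("grouping-qualifier") %||% rep("", nrow(records))
    project$subjects <- rbind(project$subjects, data.frame(
      subject_key = paste(sids, subj, sep = "/"), study_id = sids,
      subject_id = subj, arm = trimws(arm), origin = dataset$dataset_id,
      stringsAsFactors = FALSE))
    chars <- list()
    for (f in d$fields) {
      if (!f$role %in% c("other-qualifier", "grouping-qualifier")) next
      col <- colmap[[f$name]]
      if (is.na(col)) next
      v <- as.character(records[[col]])
      live <- !is_blank(v)
      if (!any(live)) next
      chars[[f$name]] <- data.frame(
        subject_key = paste(sids, subj, sep = "/")[live],
        name = prop_name(f$label), value = trimws(v[live]),
        origin = dataset$dataset_id, stringsAsFactors = FALSE)
    }
    if (length(chars))
      project$subject_chars <- rbind(project$subject_chars,
                                     do.call(rbind, chars))
    return(invisible(project))
  }

  if (kind == "biosample") {
    sids <- row_study_ids(list(records = records, colmap = colmap), d,
                          dataset$study_ids[1] %||% NA_character_)
    samp <- trimws(getcol("sample-identifier"))
    subj <- trimws(getcol("subject-identifier"))
    specf <- Filter(function(f) prop_name(f$label) == "specimen_type",
                    d$fields)
    spec <- if (length(specf)) getcol(specf[[1]]$name, by = "name") else NULL
    spec <- spec %||% rep("", nrow(records))
    visit <- getcol("series-timing") %||% rep("", nrow(records))
    project$samples <- rbind(project$samples, data.frame(
      sample_key = paste(sids, samp, sep = "/"), sample_id = samp,
      subject_key = paste(sids, subj, sep = "/"), study_id = sids,
      specimen_type = trimws(spec), visit = trimws(visit),
      origin = dataset$dataset_id, stringsAsFactors = FALSE))
    return(invisible(project))
  }

  if (kind == "feature") {
    fid <- trimws(getcol("topic"))
    lab <- getcol("SYMBOL", by = "name") %||% getcol("NAME", by = "name") %||%
      fid
    lab <- ifelse(is_blank(lab), fid, trimws(lab))
    project$feature_meta[[dataset$activity_id]] <- data.frame(
      feature_id = fid, label = lab, stringsAsFactors = FALSE)
    return(invisible(project))
  }

  if (kind == "study") return(invisible(project))

  ext <- switch(kind,
    "clinical-observation" = extract_clinical(project, dataset),
    "assay-measurement" = extract_matrix(project, dataset))
  inst <- ext$instances
  project$obs <- rbind(project$obs, inst)
  project$obs_props <- rbind(project$obs_props, ext$properties)

  if (kind == "assay-measurement" && nrow(inst)) {
    samples <- unique(inst$sample_key)
    project$assays <- rbind(project$assays, data.frame(
      assay_id = paste(dataset$activity_id, samples, sep = "@"),
      activity_id = dataset$activity_id, sample_key = samples,
      dataset_id = dataset$dataset_id, stringsAsFactors = FALSE))
  }

  if (nrow(inst)) {
    firsts <- !duplicated(inst$feature_key)
    prop_by_key <- split(ext$properties$property,
                         inst$feature_key[match(ext$properties$obs_uid,
                                                inst$obs_uid)])
    for (i in which(firsts)) {
      key <- inst$feature_key[i]
      lab <- if (!is.null(ext$labels) && key %in% names(ext$labels))
        unname(ext$labels[[key]]) else NULL
      harmonize_feature(project, list(
        feature_key = key, obs_class = inst$obs_class[i],
        domain_code = inst$domain_code[i], object_code = inst$object_code[i],
        object_label = lab %||% inst$object_code[i],
        unit = inst$unit[i],
        properties = unique(prop_by_key[[key]]) %||% character(),
        dataset_id = dataset$dataset_id))
    }
  }
  invisible(project)
}

#' Harmonization report: unit mismatches across studies
#'
#' Features sharing observation class, domain and object code but differing
#' in unit are never merged silently; this report flags each such group as
#' `UNIT_MISMATCH`.
#'
#' @param project a project.
#' @return Data frame of flags (zero rows when the registry is clean).
#' @export
harmonization_report <- function(project) {
  f <- project$features
  if (!nrow(f)) return(empty_harmonization())
  grp <- paste_key(f$obs_class, f$domain_code, f$object_code)
  out <- list()
  for (g in unique(grp)) {
    units <- unique(f$unit[grp == g])
    if (length(units) > 1) {
      bits <- strsplit(g, "\r", fixed = TRUE)[[1]]
      out[[g]] <- data.frame(
        flag = "UNIT_MISMATCH", obs_class = bits[1], domain_code = bits[2],
        object_code = bits[3], units = paste(units, collapse = " vs "),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else empty_harmonization()
}

#' Summarise the observation warehouse
#'
#' @param project a project.
#' @param study_id optional study scope; default is the whole project.
#' @return A list of counts: `subjects` (distinct subject keys with a
#'   consolidated record), `samples`, `assays` (distinct assay events),
#'   `clinical_features` (distinct harmonized finding/event/intervention
#'   feature keys), `molecular_features`, `observations` (observation
#'   instances).
#' @export
warehouse_summary <- function(project, study_id = NULL) {
  obs <- project$obs
  subjects <- project$subjects
  samples <- project$samples
  assays <- project$assays
  if (!is.null(study_id)) {
    obs <- obs[obs$study_id %in% study_id, , drop = FALSE]
    subjects <- subjects[subjects$study_id %in% study_id, , drop = FALSE]
    samples <- samples[samples$study_id %in% study_id, , drop = FALSE]
    assays <- assays[assays$sample_key %in% samples$sample_key, ,
                     drop = FALSE]
    ck <- unique(obs$feature_key[obs$obs_class != "molecular"])
    mk <- unique(obs$feature_key[obs$obs_class == "molecular"])
  } else {
    ck <- unique(project$features$feature_key[
      project$features$obs_class %in% TM_OBS_CLASSES])
    mk <- unique(project$features$feature_key[
      project$features$obs_class == "molecular"])
  }
  list(subjects = length(unique(subjects$subject_key)),
       samples = length(unique(samples$sample_key)),
       assays = length(unique(assays$assay_id)),
       clinical_features = length(ck),
       molecular_features = length(mk),
       observations = nrow(obs))
}

#' Export the warehouse in long format
#'
#' One row per observed property value: subject, sample, class, domain,
#' object, property, value, series keys, timing and provenance.  This is
#' the shape the query engine's brute-force oracle runs over.
#'
#' @param project a project.
#' @param path optional path; when given, written as tab-separated text.
#' @return The long-format data frame (invisibly when `path` is given).
#' @export
export_long <- function(project, path = NULL) {
  m <- match(project$obs_props$obs_uid, project$obs$obs_uid)
  long <- cbind(project$obs[m, c("study_id", "subject_key", "sample_key",
                                 "obs_class", "domain_code", "object_code",
                                 "feature_key", "visit", "study_day",
                                 "timepoint", "timing", "dataset_id",
                                 "row_index")],
                project$obs_props[c("property", "value")])
  rownames(long) <- NULL
  if (!is.null(path)) {
    utils::write.table(long, path, sep = "\t", row.names = FALSE,
                       qmethod = "double")
    return(invisible(long))
  }
  long
}
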
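# File management, descriptor-driven validation, and the primary-dataset
# repository.  Loads are strictly atomic: a file with any error-severity
# issue changes nothing; a clean load persists the dataset and immediately
# integrates it into the warehouse (no separate ETL step).

now_stamp <- local({
  last <- ""
  function() {
    t <- format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3", tz = "UTC")
    if (t < last) t <- last   # audit timestamps are non-decreasing
    last <<- t
    t
  }
})

append_audit <- function(project, file_id, action, user) {
  project$audit <- rbind(project$audit,
    data.frame(file_id = file_id, action = action, user = user,
               timestamp = now_stamp(), stringsAsFactors = FALSE))
  invisible(project)
}

#' Register a data file with the project drive
#'
#' Re-uploading a file with the same name updates its checksum and appends
#' a `modified` audit record rather than creating a second entry.
#'
#' @param project a project.
#' @param path path to a delimited text file.
#' @param user acting user (recorded in the audit trail).
#' @return The file id.
#' @export
upload_file <- function(project, path, user = "anonymous") {
  if (!file.exists(path)) tm_stop(sprintf("no such file: %s", path),
                                  class = "custodian_not_found")
  checksum <- unname(tools::md5sum(path))
  name <- basename(path)
  idx <- which(project$files$name == name)
  if (length(idx)) {
    fid <- project$files$file_id[idx]
    project$files$path[idx] <- path
    project$files$checksum[idx] <- checksum
    project$files$status[idx] <- "uploaded"
    append_audit(project, fid, "modified", user)
    return(fid)
  }
  project$file_counter <- project$file_counter + 1L
  fid <- fresh_id("F", project$file_counter)
  project$files <- rbind(project$files,
    data.frame(file_id = fid, name = name, path = path, checksum = checksum,
               status = "uploaded", stringsAsFactors = FALSE))
  append_audit(project, fid, "created", user)
  fid
}

set_file_status <- function(project, file_id, status) {
  idx <- which(project$files$file_id == file_id)
  project$files$status[idx] <- status
  invisible(project)
}

file_record <- function(project, file_id) {
  file_id <- as.character(file_id)
  idx <- which(project$files$file_id == file_id)
  if (!length(idx)) tm_stop(sprintf("unknown file id '%s'", file_id),
                            class = "custodian_not_found")
  as.list(project$files[idx, ])
}

descriptor_delim <- function(descriptor) {
  if (descriptor$meta$kind %in% c("biosample", "feature", "assay-measurement"))
    "\t" else ","
}

#' Parse a delimited file against a descriptor
#'
#' Columns are mapped to descriptor fields by exact, case-insensitive name
#' match.  Unknown columns are reported as warnings but do not block the
#' load; a missing column for a required role is fatal.  For matrix layout
#' every column after the feature-id column is a sample column.
#'
#' @param path file path.
#' @param descriptor a `tm_descriptor`.
#' @return A list with `records` (character data frame, untrimmed values,
#'   original header), `colmap` (field name -> column name),
#'   `sample_columns` (matrix layout only) and `diagnostics` (issue rows).
#' @export
parse_delimited <- function(path, descriptor) {
  delim <- descriptor_delim(descriptor)
  records <- tryCatch(
    utils::read.table(path, sep = delim, header = TRUE, colClasses = "character",
                      check.names = FALSE, na.strings = character(),
                      quote = "\"", comment.char = "", encoding = "UTF-8"),
    error = function(e) tm_stop(paste("parse error:", conditionMessage(e)),
                                class = "custodian_parse_error"))
  if (nrow(records) == 0 && ncol(records) == 0)
    tm_stop("empty file", class = "custodian_parse_error")
  diagnostics <- data.frame(severity = character(), code = character(),
                            row = integer(), field = character(),
                            message = character(), stringsAsFactors = FALSE)
  header <- names(records)
  named_fields <- Filter(function(f) f$name != "*", descriptor$fields)
  fnames <- vapply(named_fields, function(f) f$name, "")
  hit <- match(toupper(fnames), toupper(header))
  colmap <- stats::setNames(header[hit], fnames)
  sample_columns <- character()
  if (descriptor$layout == "matrix-feature-by-sample") {
    topic <- fields_with_role(descriptor, "topic")[[1]]
    if (is.na(colmap[[topic$name]]))
      tm_stop(sprintf("column for required role 'topic' ('%s') not found",
                      topic$name), class = "custodian_parse_error")
    sample_columns <- setdiff(header, colmap[!is.na(colmap)])
    if (!length(sample_columns))
      tm_stop("matrix file has no sample columns (required role 'sample-identifier')",
              class = "custodian_parse_error")
  } else {
    for (role in descriptor$meta$required_roles) {
      bound <- fields_with_role(descriptor, role)
      ok <- any(vapply(bound, function(f) !is.na(colmap[[f$name]]), NA))
      if (!ok)
        tm_stop(sprintf(
          "column for required role '%s' (expected one of: %s) not found",
          role, paste(vapply(bound, function(f) f$name, ""), collapse = ", ")),
          class = "custodian_parse_error")
    }
    unknown <- setdiff(header, colmap[!is.na(colmap)])
    for (u in unknown)
      diagnostics <- rbind(diagnostics, data.frame(
        severity = "warning", code = "UNKNOWN_COLUMN", row = NA_integer_,
        field = u, message = sprintf("column '%s' is not described by descriptor '%s'",
                                     u, descriptor$descriptor_id),
        stringsAsFactors = FALSE))
  }
  list(records = records, colmap = colmap, sample_columns = sample_columns,
       diagnostics = diagnostics)
}

issue_row <- function(severity, code, row, field, message)
  data.frame(severity = severity, code = code, row = as.integer(row),
             field = field, message = message, stringsAsFactors = FALSE)

new_report <- function(issues) {
  if (!nrow(issues)) {
    summary <- data.frame(code = character(), severity = character(),
                          n = integer(), stringsAsFactors = FALSE)
  } else {
    summary <- as.data.frame(table(code = issues$code), stringsAsFactors = FALSE)
    names(summary)[2] <- "n"
    summary$severity <- vapply(summary$code, function(cd)
      issues$severity[match(cd, issues$code)], "")
    summary <- summary[c("code", "severity", "n")]
  }
  structure(list(issues = issues, summary = summary), class = "tm_report")
}

#' @export
print.tm_report <- function(x, ...) {
  cat(sprintf("<validation report> %d issue(s), %d error(s)\n",
              nrow(x$issues), n_errors(x)))
  if (nrow(x$summary)) print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Count error-severity issues in a validation report
#' @param report a `tm_report`.
#' @return Integer count.
#' @export
n_errors <- function(report) sum(report$issues$severity == "error")

# study id per row: the study-identifier column when bound, else the
# study_id given at load time.
row_study_ids <- function(parsed, descriptor, study_id) {
  sf <- fields_with_role(descriptor, "study-identifier")
  if (length(sf)) {
    col <- parsed$colmap[[sf[[1]]$name]]
    if (!is.na(col)) {
      v <- trimws(parsed$records[[col]])
      v[is_blank(v)] <- study_id %||% NA_character_
      return(v)
    }
  }
  rep(study_id %||% NA_character_, nrow(parsed$records))
}

#' Validate parsed records against their descriptor and project context
#'
#' Applies, per row: mandatory-field checks, vocabulary checks, data-element
#' datatype/range checks, a duplicate-key check on the (subject, topic,
#' series-timing) tuple, and dangling-link checks of subject and sample
#' references against the consolidated project indexes.  All findings are
#' report entries; nothing is thrown.
#'
#' @param parsed result of [parse_delimited()].
#' @param descriptor the `tm_descriptor` used.
#' @param project the project (for subject/sample/study resolution).
#' @param study_id fallback study when the file has no study column.
#' @return A `tm_report`.
#' @export
validate_dataset <- function(parsed, descriptor, project, study_id = NULL) {
  records <- parsed$records
  issues <- parsed$diagnostics
  kind <- descriptor$meta$kind
  n <- nrow(records)

  for (f in descriptor$fields) {
    if (f$name == "*") next
    col <- parsed$colmap[[f$name]]
    if (is.na(col)) next
    v <- records[[col]]
    blank <- is_blank(v)
    if (f$mandatory && any(blank))
      issues <- rbind(issues, issue_row("error", "MISSING_MANDATORY",
        which(blank), f$name,
        sprintf("mandatory field '%s' is missing", f$name)))
    if (!is.null(f$vocabulary)) {
      bad <- !blank & !(toupper(trimws(v)) %in% toupper(f$vocabulary))
      if (any(bad))
        issues <- rbind(issues, issue_row("error", "VOCAB_VIOLATION",
          which(bad), f$name,
          sprintf("value '%s' not in vocabulary of '%s'", trimws(v[bad]), f$name)))
    }
    el <- descriptor$elements[[f$name]]
    if (!is.null(el)) {
      verdicts <- validate_values(el, v)
      bad <- verdicts$status == "violation"
      if (any(bad))
        issues <- rbind(issues, issue_row("error", verdicts$code[bad],
          which(bad), f$name,
          sprintf("value '%s' violates element '%s' (%s)", trimws(v[bad]),
                  el$concept_label, verdicts$code[bad])))
    }
  }

  if (kind %in% c("clinical-observation", "biosample", "subject")) {
    sids <- row_study_ids(parsed, descriptor, study_id)
    unknown_study <- !is.na(sids) & !(sids %in% names(project$studies))
    if (any(unknown_study))
      issues <- rbind(issues, issue_row("error", "DANGLING_LINK",
        which(unknown_study), "STUDYID",
        sprintf("study '%s' is not defined in the project",
                sids[unknown_study])))
    subf <- fields_with_role(descriptor, "subject-identifier")
    subcol <- if (length(subf)) parsed$colmap[[subf[[1]]$name]] else NA
    if (!is.na(subcol) && kind != "subject") {
      keys <- paste(sids, trimws(records[[subcol]]), sep = "/")
      known <- keys %in% project$subjects$subject_key
      dangling <- !known & !is_blank(records[[subcol]]) & !unknown_study
      if (any(dangling))
        issues <- rbind(issues, issue_row("error", "DANGLING_LINK",
          which(dangling), subf[[1]]$name,
          sprintf("subject '%s' not found in consolidated subjects",
                  trimws(records[[subcol]][dangling]))))
    }
    if (kind == "clinical-observation" && !is.na(subcol)) {
      topf <- fields_with_role(descriptor, "topic")[[1]]
      topcol <- parsed$colmap[[topf$name]]
      series <- fields_with_role(descriptor, "series-timing")
      skey <- rep("", n)
      for (sf in series) {
        col <- parsed$colmap[[sf$name]]
        if (!is.na(col)) skey <- paste_key(skey, trimws(records[[col]]))
      }
      key <- paste_key(sids, trimws(records[[subcol]]),
                       toupper(trimws(records[[topcol]])), skey)
      dup <- duplicated(key)
      if (any(dup))
        issues <- rbind(issues, issue_row("error", "DUPLICATE_KEY",
          which(dup), topf$name,
          "duplicate (subject, topic, series-timing) key"))
    }
  }

  if (descriptor$layout == "matrix-feature-by-sample") {
    known <- parsed$sample_columns %in% project$samples$sample_id |
      parsed$sample_columns %in% project$samples$sample_key
    if (any(!known))
      issues <- rbind(issues, lapply(parsed$sample_columns[!known], function(sc)
        issue_row("error", "DANGLING_LINK", NA_integer_, sc,
                  sprintf("sample column '%s' not found in consolidated samples",
                          sc)))[[1]])
    if (sum(!known) > 1)
      for (sc in parsed$sample_columns[!known][-1])
        issues <- rbind(issues, issue_row("error", "DANGLING_LINK",
          NA_integer_, sc,
          sprintf("sample column '%s' not found in consolidated samples", sc)))
  }
  new_report(issues)
}

replace_key <- function(activity_id, domain_code, study_ids)
  paste(activity_id, domain_code,
        paste(sort(unique(study_ids)), collapse = "+"), sep = "|")

#' Load a file into the primary-dataset repository
#'
#' Runs the loading wizard's pipeline: parse under the chosen descriptor,
#' validate, and — only when no error-severity issue was found — persist
#' the file as an annotated primary dataset, append to the audit trail, and
#' integrate its content into the observation warehouse.  Loads are atomic:
#' on any error nothing is persisted and the file is marked `failed`.
#' Reloading a file for the same (activity, domain, study) replaces the
#' previous dataset rather than duplicating it.
#'
#' @param project a project.
#' @param file_id id from [upload_file()].
#' @param descriptor_id a descriptor registered via [register_descriptor()].
#' @param user acting user.
#' @param study_id study context for files without a study column.
#' @return A list with `status` (`"loaded"`/`"failed"`), `dataset_id` (on
#'   success) and the validation `report`.
#' @export
load_dataset <- function(project, file_id, descriptor_id, user = "anonymous",
                         study_id = NULL) {
  force(file_id)   # an upload_file() call in this slot must run first
  reg <- project$descriptors[[descriptor_id]]
  if (is.null(reg))
    tm_stop(sprintf("descriptor '%s' is not registered to any activity",
                    descriptor_id), class = "custodian_not_found")
  descriptor <- reg$descriptor
  frec <- file_record(project, file_id)
  set_file_status(project, file_id, "loading")
  append_audit(project, file_id, "load-started", user)

  parsed <- tryCatch(parse_delimited(frec$path, descriptor),
                     custodian_parse_error = function(e) e)
  if (inherits(parsed, "condition")) {
    set_file_status(project, file_id, "failed")
    append_audit(project, file_id, "load-failed", user)
    return(list(status = "failed", dataset_id = NULL,
                report = new_report(issue_row("error", "TYPE_ERROR",
                  NA_integer_, "", conditionMessage(parsed)))))
  }
  report <- validate_dataset(parsed, descriptor, project, study_id)
  if (n_errors(report) > 0) {
    set_file_status(project, file_id, "failed")
    append_audit(project, file_id, "load-failed", user)
    return(list(status = "failed", dataset_id = NULL, report = report))
  }

  study_ids <- unique(stats::na.omit(row_study_ids(parsed, descriptor,
                                                   study_id)))
  project$dataset_counter <- project$dataset_counter + 1L
  dataset_id <- fresh_id("DS", project$dataset_counter)
  dataset <- structure(list(
    dataset_id = dataset_id, descriptor = descriptor,
    descriptor_id = descriptor_id, activity_id = reg$activity_id,
    study_ids = study_ids, records = parsed$records, colmap = parsed$colmap,
    sample_columns = parsed$sample_columns, file_id = file_id,
    replace_key = replace_key(reg$activity_id, descriptor$domain_code,
                              study_ids)), class = "tm_dataset")

  old <- Filter(function(d) d$replace_key == dataset$replace_key,
                project$datasets)
  for (d in old) remove_dataset(project, d$dataset_id)

  project$datasets[[dataset_id]] <- dataset
  integrate_dataset(project, dataset)
  set_file_status(project, file_id, "loaded")
  append_audit(project, file_id, "load-succeeded", user)
  list(status = "loaded", dataset_id = dataset_id, report = report)
}

# Remove a dataset and every warehouse contribution it made.
remove_dataset <- function(project, dataset_id) {
  project$datasets[[dataset_id]] <- NULL
  project$obs <- project$obs[project$obs$dataset_id != dataset_id, ,
                             drop = FALSE]
  project$obs_props <- project$obs_props[
    project$obs_props$dataset_id != dataset_id, , drop = FALSE]
  project$assays <- project$assays[project$assays$dataset_id != dataset_id, ,
                                   drop = FALSE]
  project$subjects <- project$subjects[
    project$subjects$origin != dataset_id, , drop = FALSE]
  project$subject_chars <- project$subject_chars[
    project$subject_chars$origin != dataset_id, , drop = FALSE]
  project$samples <- project$samples[
    project$samples$origin != dataset_id, , drop = FALSE]
  # prune the feature registry of entries no longer backed by any dataset
  keep <- vapply(seq_len(nrow(project$features)), function(i) {
    ids <- strsplit(project$features$datasets[i], ";", fixed = TRUE)[[1]]
    ids <- setdiff(ids, dataset_id)
    project$features$datasets[i] <<- paste(ids, collapse = ";")
    length(ids) > 0
  }, NA)
  if (nrow(project$features))
    project$features <- project$features[keep, , drop = FALSE]
  invisible(project)
}

#' List and export primary datasets
#'
#' @param project a project.
#' @return `list_datasets()` returns a summary data frame (one row per
#'   consolidated dataset, with descriptor metadata and source file).
#' @export
list_datasets <- function(project) {
  if (!length(project$datasets))
    return(data.frame(dataset_id = character(), domain_code = character(),
                      descriptor_id = character(), activity_id = character(),
                      studies = character(), n_records = integer(),
                      file = character(), stringsAsFactors = FALSE))
  do.call(rbind, lapply(unname(project$datasets), function(d)
    data.frame(dataset_id = d$dataset_id, domain_code = d$descriptor$domain_code,
               descriptor_id = d$descriptor_id, activity_id = d$activity_id,
               studies = paste(d$study_ids, collapse = "+"),
               n_records = nrow(d$records),
               file = file_record(project, d$file_id)$name,
               stringsAsFactors = FALSE)))
}

#' @rdname list_datasets
#' @param dataset_id a loaded dataset id.
#' @param path optional output path; when `NULL` the delimited text is
#'   returned as a character scalar.
#' @return `export_primary_dataset()` writes/returns the dataset's records
#'   as delimited text; a re-parse of the export reproduces the records
#'   exactly.
#' @export
export_primary_dataset <- function(project, dataset_id, path = NULL) {
  d <- project$datasets[[dataset_id]]
  if (is.null(d)) tm_stop(sprintf("no loaded dataset '%s'", dataset_id),
                          class = "custodian_not_found")
  delim <- descriptor_delim(d$descriptor)
  con <- textConnection("out", "w", local = TRUE)
  utils::write.table(d$records, con, sep = delim, row.names = FALSE,
                     qmethod = "double")
  close(con)
  text <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(path))
  }
  text
}
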
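# Workspace persistence.  A workspace is a transparent, diffable directory
# tree (the "project drive" metaphor): files/ holds upload bookkeeping,
# repository/ the annotated primary datasets, warehouse/ the long-format
# observation store, analyses/ the user-scoped analysis datasets.  Reload
# reproduces an isomorphic project graph.

write_df <- function(df, path)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     qmethod = "double")

read_df <- function(path, template) {
  if (!file.exists(path)) return(template)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          na.strings = character(), quote = "\"",
                          comment.char = "")
  if (!nrow(df)) return(template)
  for (nm in names(template)) {
    if (is.integer(template[[nm]])) df[[nm]] <- as.integer(df[[nm]])
    if (is.numeric(template[[nm]]) && !is.integer(template[[nm]]))
      df[[nm]] <- as.numeric(df[[nm]])
    # empty strings round-trip as NA markers for key columns that allow NA
    if (nm == "sample_key" && "obs_uid" %in% names(template))
      df[[nm]][df[[nm]] == ""] <- NA_character_
  }
  df
}

dataset_to_disk <- function(project, d, dir) {
  delim <- descriptor_delim(d$descriptor)
  utils::write.table(d$records, file.path(dir, paste0(d$dataset_id, ".dat")),
                     sep = delim, row.names = FALSE, qmethod = "double")
  meta <- list(dataset_id = d$dataset_id,
               descriptor = descriptor_to_list(d$descriptor),
               descriptor_id = d$descriptor_id, activity_id = d$activity_id,
               study_ids = d$study_ids, colmap = as.list(d$colmap),
               sample_columns = d$sample_columns, file_id = d$file_id,
               replace_key = d$replace_key)
  jsonlite::write_json(meta, file.path(dir, paste0(d$dataset_id, ".json")),
                       auto_unbox = TRUE, null = "null", digits = NA,
                       pretty = TRUE)
}

dataset_from_disk <- function(dir, dataset_id) {
  meta <- jsonlite::fromJSON(file.path(dir, paste0(dataset_id, ".json")),
                             simplifyVector = FALSE)
  descriptor <- descriptor_from_list(meta$descriptor)
  delim <- descriptor_delim(descriptor)
  records <- utils::read.table(file.path(dir, paste0(dataset_id, ".dat")),
                               sep = delim, header = TRUE,
                               colClasses = "character", check.names = FALSE,
                               na.strings = character(), quote = "\"",
                               comment.char = "")
  colmap <- unlist(lapply(meta$colmap, function(x) x %||% NA_character_))
  structure(list(dataset_id = meta$dataset_id, descriptor = descriptor,
                 descriptor_id = meta$descriptor_id,
                 activity_id = meta$activity_id,
                 study_ids = unlist(meta$study_ids),
                 records = records, colmap = colmap,
                 sample_columns = unlist(meta$sample_columns) %||%
                   character(),
                 file_id = meta$file_id, replace_key = meta$replace_key),
            class = "tm_dataset")
}

#' Persist a project to a workspace directory
#'
#' @param project a project.
#' @param dir workspace root (created if needed).
#' @return `dir`, invisibly.
#' @export
save_workspace <- function(project, dir) {
  for (sub in c("files", "repository", "warehouse", "analyses"))
    dir.create(file.path(dir, sub), recursive = TRUE, showWarnings = FALSE)
  meta <- list(
    format_version = 1L,
    project_id = project$project_id, kind = project$kind,
    title = project$title,
    studies = lapply(unname(project$studies), function(s)
      list(study_id = s$study_id, title = s$title, arms = s$arms,
           visits = list(label = s$visits$label, day = s$visits$day),
           design = s$design, eligibility = s$eligibility,
           objectives = s$objectives)),
    activities = lapply(unname(project$activities), function(a)
      list(activity_id = a$activity_id, kind = a$kind, name = a$name,
           technology = a$technology,
           descriptor_refs = a$descriptor_refs)),
    members = project$members,
    descriptors = lapply(unname(project$descriptors), function(x)
      list(descriptor = descriptor_to_list(x$descriptor),
           activity_id = x$activity_id)),
    feature_meta = project$feature_meta,
    counters = list(file = project$file_counter,
                    dataset = project$dataset_counter,
                    analysis = project$analysis_counter),
    datasets = names(project$datasets))
  jsonlite::write_json(meta, file.path(dir, "project-meta.json"),
                       auto_unbox = TRUE, null = "null", digits = NA,
                       pretty = TRUE)
  write_df(project$files, file.path(dir, "files", "files.tsv"))
  write_df(project$audit, file.path(dir, "files", "audit.tsv"))
  for (old in list.files(file.path(dir, "repository"), full.names = TRUE))
    unlink(old)
  for (d in project$datasets)
    dataset_to_disk(project, d, file.path(dir, "repository"))
  wh <- file.path(dir, "warehouse")
  write_df(project$obs, file.path(wh, "observations.tsv"))
  write_df(project$obs_props, file.path(wh, "observation-values.tsv"))
  write_df(project$subjects, file.path(wh, "subjects.tsv"))
  write_df(project$subject_chars, file.path(wh, "subject-characteristics.tsv"))
  write_df(project$samples, file.path(wh, "samples.tsv"))
  write_df(project$assays, file.path(wh, "assay-events.tsv"))
  write_df(project$features, file.path(wh, "features.tsv"))
  for (old in list.files(file.path(dir, "analyses"), full.names = TRUE))
    unlink(old)
  for (a in project$analyses) {
    jsonlite::write_json(
      list(dataset_id = a$dataset_id, owner = a$owner, title = a$title,
           description = a$description, tags = a$tags,
           query = query_to_list(a$query), select = a$select,
           visibility = a$visibility),
      file.path(dir, "analyses", paste0(a$dataset_id, ".json")),
      auto_unbox = TRUE, null = "null", digits = NA, pretty = TRUE)
  }
  invisible(dir)
}

#' Reload a project from a workspace directory
#'
#' @param dir a directory written by [save_workspace()].
#' @return The reconstructed `tm_project`.
#' @export
load_workspace <- function(dir) {
  path <- file.path(dir, "project-meta.json")
  if (!file.exists(path))
    tm_stop(sprintf("no workspace at '%s' (missing project-meta.json)", dir),
            class = "custodian_not_found")
  meta <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  project <- create_project(meta$kind, meta$title, meta$project_id)
  for (s in meta$studies)
    add_study(project, study(
      s$study_id, s$title %||% s$study_id, arms = unlist(s$arms) %||%
        character(),
      visits = data.frame(label = unlist(s$visits$label) %||% character(),
                          day = unlist(s$visits$day) %||% numeric()),
      design = s$design %||% "", eligibility = s$eligibility %||% "",
      objectives = s$objectives %||% ""))
  for (a in meta$activities) {
    act <- activity(a$activity_id, a$kind, a$name, technology = a$technology)
    act$descriptor_refs <- unlist(a$descriptor_refs) %||% character()
    project$activities[[act$activity_id]] <- act
  }
  if (length(meta$members))
    project$members <- data.frame(
      user = vapply(meta$members$user, identity, ""),
      role = vapply(meta$members$role, identity, ""),
      stringsAsFactors = FALSE)
  for (x in meta$descriptors) {
    d <- descriptor_from_list(x$descriptor)
    project$descriptors[[d$descriptor_id]] <-
      list(descriptor = d, activity_id = x$activity_id)
  }
  project$feature_meta <- lapply(meta$feature_meta, function(fm)
    data.frame(feature_id = unlist(fm$feature_id),
               label = unlist(fm$label), stringsAsFactors = FALSE))
  project$file_counter <- as.integer(meta$counters$file)
  project$dataset_counter <- as.integer(meta$counters$dataset)
  project$analysis_counter <- as.integer(meta$counters$analysis)
  project$files <- read_df(file.path(dir, "files", "files.tsv"),
                           empty_files())
  project$audit <- read_df(file.path(dir, "files", "audit.tsv"),
                           empty_audit())
  for (id in unlist(meta$datasets))
    project$datasets[[id]] <- dataset_from_disk(file.path(dir, "repository"),
                                                id)
  wh <- file.path(dir, "warehouse")
  project$obs <- read_df(file.path(wh, "observations.tsv"), empty_obs())
  project$obs_props <- read_df(file.path(wh, "observation-values.tsv"),
                               empty_props())
  project$subjects <- read_df(file.path(wh, "subjects.tsv"),
                              empty_subjects())
  project$subject_chars <- read_df(
    file.path(wh, "subject-characteristics.tsv"), empty_chars())
  project$samples <- read_df(file.path(wh, "samples.tsv"), empty_samples())
  project$assays <- read_df(file.path(wh, "assay-events.tsv"),
                            empty_assays())
  project$features <- read_df(file.path(wh, "features.tsv"),
                              empty_features())
  for (f in list.files(file.path(dir, "analyses"), pattern = "\\.json$",
                       full.names = TRUE)) {
    a <- jsonlite::fromJSON(f, simplifyVector = FALSE)
    project$analyses[[a$dataset_id]] <- structure(
      list(dataset_id = a$dataset_id, owner = a$owner, title = a$title,
           description = a$description, tags = unlist(a$tags) %||%
             character(),
           query = query_from_list(a$query), select = a$select,
           visibility = a$visibility), class = "tm_analysis")
  }
  project
}
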
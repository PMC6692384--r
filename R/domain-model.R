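# Domain graph: project -> studies -> (arms, visits); activities own
# descriptors and datasets; subjects and biosamples are indexed
# project-wide.  A project is an environment so that loading and
# integration update it in place, mirroring how the repository and
# warehouse live side by side.

empty_subjects <- function()
  data.frame(subject_key = character(), study_id = character(),
             subject_id = character(), arm = character(),
             origin = character(), stringsAsFactors = FALSE)

empty_chars <- function()
  data.frame(subject_key = character(), name = character(),
             value = character(), origin = character(),
             stringsAsFactors = FALSE)

empty_samples <- function()
  data.frame(sample_key = character(), sample_id = character(),
             subject_key = character(), study_id = character(),
             specimen_type = character(), visit = character(),
             origin = character(), stringsAsFactors = FALSE)

# observation instances (one row per observed fact)
empty_obs <- function()
  data.frame(obs_uid = character(), study_id = character(),
             subject_key = character(), sample_key = character(),
             obs_class = character(), domain_code = character(),
             object_code = character(), unit = character(),
             feature_key = character(), visit = character(),
             study_day = character(), timepoint = character(),
             timing = character(), dataset_id = character(),
             row_index = integer(), activity_id = character(),
             stringsAsFactors = FALSE)

# observed property values (EAV; >=0 rows per instance)
empty_props <- function()
  data.frame(obs_uid = character(), dataset_id = character(),
             property = character(), value = character(),
             stringsAsFactors = FALSE)

empty_features <- function()
  data.frame(feature_key = character(), obs_class = character(),
             domain_code = character(), object_code = character(),
             object_label = character(), unit = character(),
             properties = character(), datasets = character(),
             stringsAsFactors = FALSE)

empty_assays <- function()
  data.frame(assay_id = character(), activity_id = character(),
             sample_key = character(), dataset_id = character(),
             stringsAsFactors = FALSE)

empty_files <- function()
  data.frame(file_id = character(), name = character(), path = character(),
             checksum = character(), status = character(),
             stringsAsFactors = FALSE)

empty_audit <- function()
  data.frame(file_id = character(), action = character(), user = character(),
             timestamp = character(), stringsAsFactors = FALSE)

empty_harmonization <- function()
  data.frame(flag = character(), obs_class = character(),
             domain_code = character(), object_code = character(),
             units = character(), stringsAsFactors = FALSE)

#' Create a translational research project
#'
#' A project is the top of the domain graph: it holds studies, activities
#' (clinical assessments or molecular assays), members, the file area, the
#' primary-dataset repository and the observation warehouse.
#'
#' @param kind `"single-study"`, `"multi-study"` (planned related studies)
#'   or `"meta-study"` (unrelated studies).
#' @param title project title.
#' @param project_id identifier (defaults to a slug of the title).
#' @return An environment of class `tm_project`.
#' @export
create_project <- function(kind = c("single-study", "multi-study",
                                    "meta-study"),
                           title, project_id = NULL) {
  kind <- match.arg(kind)
  p <- new.env(parent = emptyenv())
  p$project_id <- project_id %||% gsub("[^A-Za-z0-9]+", "-", tolower(title))
  p$kind <- kind
  p$title <- title
  p$studies <- list()
  p$activities <- list()
  p$members <- data.frame(user = character(), role = character(),
                          stringsAsFactors = FALSE)
  p$subjects <- empty_subjects()
  p$subject_chars <- empty_chars()
  p$samples <- empty_samples()
  p$files <- empty_files()
  p$audit <- empty_audit()
  p$file_counter <- 0L
  p$dataset_counter <- 0L
  p$datasets <- list()
  p$descriptors <- list()
  p$obs <- empty_obs()
  p$obs_props <- empty_props()
  p$features <- empty_features()
  p$assays <- empty_assays()
  p$feature_meta <- list()
  p$harmonization <- empty_harmonization()
  p$analyses <- list()
  p$analysis_counter <- 0L
  class(p) <- "tm_project"
  p
}

#' @export
print.tm_project <- function(x, ...) {
  cat(sprintf("<project> %s (%s): %d studies, %d activities, %d datasets\n",
              x$project_id, x$kind, length(x$studies), length(x$activities),
              length(x$datasets)))
  invisible(x)
}

#' Define a study
#'
#' @param study_id unique id within the project.
#' @param title study title.
#' @param arms character vector of arm labels.
#' @param visits data frame with columns `label` and `day` (planned study
#'   day, may be `NA`); labels must be unique.
#' @param design,eligibility,objectives free-text study metadata.
#' @return A `tm_study` object.
#' @export
study <- function(study_id, title = study_id, arms = character(),
                  visits = data.frame(label = character(), day = numeric()),
                  design = "", eligibility = "", objectives = "") {
  visits <- data.frame(label = as.character(visits$label),
                       day = as.numeric(visits$day),
                       stringsAsFactors = FALSE)
  if (anyDuplicated(visits$label)) tm_stop("visit labels must be unique")
  structure(list(study_id = study_id, title = title,
                 arms = as.character(arms), visits = visits, design = design,
                 eligibility = eligibility, objectives = objectives),
            class = "tm_study")
}

#' Define an activity
#'
#' All data generated from an activity is modelled as a dataset; clinical
#' assessments produce SDTM-dialect files, molecular assays produce
#' ISA-style sample/feature/measurement triplets.
#'
#' @param activity_id unique id within the project.
#' @param kind `"clinical-assessment"` or `"molecular-assay"`.
#' @param name display name.
#' @param technology for assays, a technology label (e.g. `"microarray
#'   gene expression"`).
#' @return A `tm_activity` object.
#' @export
activity <- function(activity_id, kind = c("clinical-assessment",
                                           "molecular-assay"),
                     name = activity_id, technology = NULL) {
  kind <- match.arg(kind)
  structure(list(activity_id = activity_id, kind = kind, name = name,
                 technology = technology, descriptor_refs = character()),
            class = "tm_activity")
}

#' Grow the project graph
#'
#' @param project a [create_project()] environment.
#' @param study a [study()].
#' @return The project, invisibly; duplicate ids and a second study on a
#'   single-study project are refused.
#' @export
add_study <- function(project, study) {
  stopifnot(inherits(project, "tm_project"), inherits(study, "tm_study"))
  if (study$study_id %in% names(project$studies))
    tm_stop(sprintf("study '%s' already exists", study$study_id),
            class = "custodian_conflict")
  if (project$kind == "single-study" && length(project$studies) >= 1)
    tm_stop("a single-study project can hold exactly one study",
            class = "custodian_refused")
  project$studies[[study$study_id]] <- study
  invisible(project)
}

#' @rdname add_study
#' @param activity a [activity()].
#' @export
add_activity <- function(project, activity) {
  stopifnot(inherits(project, "tm_project"), inherits(activity, "tm_activity"))
  if (activity$activity_id %in% names(project$activities))
    tm_stop(sprintf("activity '%s' already exists", activity$activity_id),
            class = "custodian_conflict")
  project$activities[[activity$activity_id]] <- activity
  invisible(project)
}

#' @rdname add_study
#' @param user user name.
#' @param role `"manager"`, `"curator"` or `"researcher"`.
#' @export
add_member <- function(project, user, role = c("manager", "curator",
                                               "researcher")) {
  role <- match.arg(role)
  project$members <- rbind(project$members,
                           data.frame(user = user, role = role,
                                      stringsAsFactors = FALSE))
  invisible(project)
}

#' Register a descriptor with a project activity
#'
#' @param project a project.
#' @param activity_id owning activity.
#' @param descriptor a `tm_descriptor`.
#' @return The descriptor id, invisibly.
#' @export
register_descriptor <- function(project, activity_id, descriptor) {
  if (!activity_id %in% names(project$activities))
    tm_stop(sprintf("unknown activity '%s'", activity_id),
            class = "custodian_not_found")
  id <- descriptor$descriptor_id
  project$descriptors[[id]] <- list(descriptor = descriptor,
                                    activity_id = activity_id)
  a <- project$activities[[activity_id]]
  a$descriptor_refs <- union(a$descriptor_refs, id)
  project$activities[[activity_id]] <- a
  invisible(id)
}

#' Resolve a project-wide subject key
#'
#' Subject identity is scoped by study and never merged across studies:
#' subjects of a meta-study with equal in-study ids remain distinct.
#' Resolution is idempotent — the same (study, subject) pair always yields
#' the same key.
#'
#' @param project a project.
#' @param study_id study the subject belongs to (must exist).
#' @param subject_id in-study subject identifier.
#' @return The subject key string.
#' @export
resolve_subject <- function(project, study_id, subject_id) {
  if (!study_id %in% names(project$studies))
    tm_stop(sprintf("unknown study '%s'", study_id),
            class = "custodian_not_found")
  paste(study_id, subject_id, sep = "/")
}

#' @rdname resolve_subject
#' @param sample_id in-study biosample identifier.
#' @export
resolve_sample <- function(project, study_id, sample_id) {
  if (!study_id %in% names(project$studies))
    tm_stop(sprintf("unknown study '%s'", study_id),
            class = "custodian_not_found")
  paste(study_id, sample_id, sep = "/")
}

subject_known <- function(project, subject_key)
  subject_key %in% project$subjects$subject_key

sample_known <- function(project, sample_key)
  sample_key %in% project$samples$sample_key

#' Walk the project graph and verify referential closure
#'
#' Checks that every observation's subject/sample/dataset/activity
#' references resolve, every sample links to a known subject, and every
#' dataset belongs to a registered activity.
#'
#' @param project a project.
#' @return Character vector of problems (empty when the graph is closed).
#' @export
check_referential_closure <- function(project) {
  problems <- character()
  bad_sub <- setdiff(project$obs$subject_key, project$subjects$subject_key)
  if (length(bad_sub))
    problems <- c(problems, paste("unresolved subject:", bad_sub))
  used_samples <- setdiff(project$obs$sample_key, c(NA, ""))
  bad_sam <- setdiff(used_samples, project$samples$sample_key)
  if (length(bad_sam))
    problems <- c(problems, paste("unresolved sample:", bad_sam))
  bad_sam_sub <- setdiff(project$samples$subject_key,
                         project$subjects$subject_key)
  if (length(bad_sam_sub))
    problems <- c(problems, paste("sample with unknown subject:", bad_sam_sub))
  for (ds in project$datasets) {
    if (!ds$activity_id %in% names(project$activities))
      problems <- c(problems,
                    paste("dataset with unknown activity:", ds$dataset_id))
  }
  bad_ds <- setdiff(project$obs$dataset_id, names(project$datasets))
  if (length(bad_ds))
    problems <- c(problems, paste("observation from unknown dataset:", bad_ds))
  problems
}
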
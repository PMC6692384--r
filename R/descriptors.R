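# Dataset meta-model: the generic descriptor (M3) constrains field roles; a
# fixed set of meta-descriptors (M2) names the core elements any
# translational study carries (study, subject, clinical observation,
# biosample, feature, assay measurement); concrete descriptors (M1) annotate
# the columns of real files.  Two M1 descriptors bound to the same M2 kind
# are semantically interchangeable: integration maps columns by role, never
# by name.

#' Field roles recognised by the generic dataset descriptor
#'
#' This package's rendering of the SDTM identifier/topic/qualifier/timing
#' variable classes, split so that mapping a column into the common
#' observation model is mechanical.
#' @export
TM_ROLES <- c("subject-identifier", "sample-identifier", "study-identifier",
              "topic", "result-qualifier", "unit-qualifier",
              "grouping-qualifier", "temporal-timing", "series-timing",
              "other-qualifier")

TM_META_KINDS <- c("study", "subject", "clinical-observation", "biosample",
                   "feature", "assay-measurement")

TM_OBS_CLASSES <- c("finding", "event", "intervention")

#' Describe one column of a dataset
#'
#' @param name column name as it appears in files.
#' @param label display name; also the canonical property name qualifier
#'   values are stored under, so content-equivalent files with renamed
#'   columns integrate identically.
#' @param role one of [TM_ROLES].
#' @param element_ref optional id of a registered data element whose domain
#'   (datatype, range, terms) validates this column.
#' @param mandatory must every row carry a non-missing value?
#' @param vocabulary optional character vector of permitted codes; it
#'   *replaces* (never extends) the element's permissible values for this
#'   field.
#' @return A `tm_field` object.
#' @export
field_descriptor <- function(name, label = name, role, element_ref = NULL,
                             mandatory = FALSE, vocabulary = NULL) {
  role <- match.arg(role, TM_ROLES)
  if (is_blank(name)) tm_stop("field name must be non-empty")
  structure(list(name = as.character(name), label = as.character(label),
                 role = role, element_ref = element_ref,
                 mandatory = isTRUE(mandatory),
                 vocabulary = if (!is.null(vocabulary)) as.character(vocabulary)),
            class = "tm_field")
}

#' Meta-descriptors (M2): the interoperability layer
#'
#' A meta-descriptor fixes which roles any conforming concrete descriptor
#' must bind: e.g. a finding needs a subject identifier, a topic and a
#' result qualifier; an assay measurement needs a sample axis and a feature
#' axis.
#'
#' @param kind one of `"study"`, `"subject"`, `"clinical-observation"`,
#'   `"biosample"`, `"feature"`, `"assay-measurement"`.
#' @param obs_class for clinical observations, one of `"finding"`,
#'   `"event"`, `"intervention"`.
#' @return A `tm_meta` object with its `required_roles`.
#' @export
meta_descriptor <- function(kind, obs_class = NULL) {
  kind <- match.arg(kind, TM_META_KINDS)
  if (kind == "clinical-observation") {
    obs_class <- match.arg(obs_class, TM_OBS_CLASSES)
  } else if (!is.null(obs_class)) {
    tm_stop("obs_class only applies to clinical-observation meta-descriptors")
  }
  required <- switch(kind,
    "study" = "study-identifier",
    "subject" = "subject-identifier",
    "clinical-observation" = if (identical(obs_class, "finding"))
      c("subject-identifier", "topic", "result-qualifier")
    else c("subject-identifier", "topic"),
    "biosample" = c("sample-identifier", "subject-identifier"),
    "feature" = "topic",
    "assay-measurement" = c("sample-identifier", "topic"))
  structure(list(kind = kind, obs_class = obs_class, required_roles = required),
            class = "tm_meta")
}

#' Concrete dataset descriptors (M1)
#'
#' @param descriptor_id unique id.
#' @param meta the [meta_descriptor()] this descriptor conforms to.
#' @param domain_code dataset domain, e.g. `"DM"`, `"LB"`, `"VS"`, `"AE"`.
#' @param fields list of [field_descriptor()]s; names must be unique.  For
#'   matrix layout, a field named `"*"` with role `sample-identifier`
#'   stands for the sample columns (every column after the feature-id
#'   column).
#' @param layout `"long-per-observation"` or `"matrix-feature-by-sample"`
#'   (matrix only for assay-measurement descriptors).
#' @param elements named list (by field name) of inline `tm_data_element`s
#'   backing `element_ref`s; normally populated via [bind_element()].
#' @return A `tm_descriptor`; construction fails unless every required role
#'   of the meta-descriptor is bound by at least one field.
#' @export
dataset_descriptor <- function(descriptor_id, meta, domain_code, fields,
                               layout = c("long-per-observation",
                                          "matrix-feature-by-sample"),
                               elements = list()) {
  layout <- match.arg(layout)
  stopifnot(inherits(meta, "tm_meta"))
  if (layout == "matrix-feature-by-sample" && meta$kind != "assay-measurement")
    tm_stop("matrix layout is only valid for assay-measurement descriptors")
  nm <- vapply(fields, function(f) f$name, "")
  if (anyDuplicated(toupper(nm))) tm_stop("field names must be unique")
  d <- structure(list(descriptor_id = descriptor_id, meta = meta,
                      domain_code = domain_code, fields = fields,
                      layout = layout, elements = elements,
                      change_log = list(), format_version = 1L),
                 class = "tm_descriptor")
  check_required_roles(d)
  d
}

check_required_roles <- function(d) {
  bound <- vapply(d$fields, function(f) f$role, "")
  missing <- setdiff(d$meta$required_roles, bound)
  if (length(missing))
    tm_stop(sprintf("descriptor '%s' does not bind required role(s): %s",
                    d$descriptor_id, paste(missing, collapse = ", ")))
  invisible(d)
}

descriptor_field <- function(d, name) {
  for (f in d$fields) if (toupper(f$name) == toupper(name)) return(f)
  NULL
}

fields_with_role <- function(d, role) {
  Filter(function(f) f$role == role, d$fields)
}

#' @export
print.tm_descriptor <- function(x, ...) {
  cat(sprintf("<dataset descriptor> %s (%s/%s, %s)\n", x$descriptor_id,
              x$meta$kind, x$meta$obs_class %||% "-", x$layout))
  for (f in x$fields)
    cat(sprintf("  %-12s %-18s%s%s\n", f$name, f$role,
                if (f$mandatory) " mandatory" else "",
                if (!is.null(f$vocabulary))
                  paste0(" {", paste(f$vocabulary, collapse = ","), "}") else ""))
  invisible(x)
}

# ---- customization (metadata governance) --------------------------------

#' Customize a dataset descriptor
#'
#' `customize()` applies governance edits to a descriptor copy and records
#' each edit in the descriptor's change log.  Edits are built with
#' `exclude_field()`, `set_mandatory()`, `set_vocabulary()`, `add_field()`
#' and `bind_element()`.
#'
#' @param descriptor a `tm_descriptor` (templates are already independent
#'   copies).
#' @param ... one or more edit objects.
#' @return The edited descriptor; edits that would break the descriptor's
#'   meta-contract (excluding the only binding of a required role, putting a
#'   vocabulary on a numeric-typed field) are refused.
#' @export
customize <- function(descriptor, ...) {
  edits <- list(...)
  d <- descriptor
  for (e in edits) {
    stopifnot(inherits(e, "tm_edit"))
    d <- apply_edit(d, e)
    d$change_log <- c(d$change_log, list(edit_to_log(e)))
  }
  d
}

# change-log entries are JSON-safe plain lists
edit_to_log <- function(e) {
  x <- unclass(e)
  if (identical(x$op, "bind_element")) {
    el <- x$element
    x$element <- list(element_id = el$element_id,
                      concept_label = el$concept_label,
                      value_domain = domain_to_list(
                        structure(el$value_domain,
                                  class = "tm_value_domain")))
  }
  x
}

#' @rdname customize
#' @param name field name the edit applies to.
#' @export
exclude_field <- function(name)
  structure(list(op = "exclude_field", name = name), class = "tm_edit")

#' @rdname customize
#' @param flag logical.
#' @export
set_mandatory <- function(name, flag = TRUE)
  structure(list(op = "set_mandatory", name = name, flag = isTRUE(flag)),
            class = "tm_edit")

#' @rdname customize
#' @param terms character vector of permitted codes.
#' @export
set_vocabulary <- function(name, terms)
  structure(list(op = "set_vocabulary", name = name,
                 terms = as.character(terms)), class = "tm_edit")

#' @rdname customize
#' @param field a [field_descriptor()] to append.
#' @export
add_field <- function(field) {
  stopifnot(inherits(field, "tm_field"))
  structure(list(op = "add_field", field = unclass(field)), class = "tm_edit")
}

#' @rdname customize
#' @param element a `tm_data_element` whose value domain should validate the
#'   field (stored inline on the descriptor).
#' @export
bind_element <- function(name, element) {
  stopifnot(inherits(element, "tm_data_element"))
  structure(list(op = "bind_element", name = name, element = unclass(element)),
            class = "tm_edit")
}

apply_edit <- function(d, e) {
  idx <- which(vapply(d$fields, function(f) toupper(f$name), "") ==
                 toupper(e$name %||% ""))
  need_field <- e$op != "add_field"
  if (need_field && !length(idx))
    tm_stop(sprintf("no field named '%s' in descriptor '%s'",
                    e$name, d$descriptor_id), class = "custodian_not_found")
  switch(e$op,
    exclude_field = {
      f <- d$fields[[idx]]
      others <- vapply(d$fields[-idx], function(x) x$role, "")
      if (f$role %in% d$meta$required_roles && !(f$role %in% others))
        tm_stop(sprintf(
          "cannot exclude '%s': it is the only binding of required role '%s'",
          f$name, f$role), class = "custodian_refused")
      d$fields[[idx]] <- NULL
    },
    set_mandatory = d$fields[[idx]]$mandatory <- e$flag,
    set_vocabulary = {
      f <- d$fields[[idx]]
      el <- d$elements[[f$name]]
      if (!is.null(el) &&
          el$value_domain$datatype %in% c("integer", "decimal"))
        tm_stop(sprintf(
          "cannot set a vocabulary on numeric-typed field '%s'", f$name),
          class = "custodian_refused")
      d$fields[[idx]]$vocabulary <- e$terms
    },
    add_field = {
      f <- structure(e$field, class = "tm_field")
      if (!is.null(descriptor_field(d, f$name)))
        tm_stop(sprintf("field '%s' already present", f$name),
                class = "custodian_conflict")
      d$fields <- c(d$fields, list(f))
    },
    bind_element = {
      el <- structure(e$element, class = "tm_data_element")
      el$value_domain <- structure(el$value_domain, class = "tm_value_domain")
      d$elements[[d$fields[[idx]]$name]] <- el
      d$fields[[idx]]$element_ref <- el$element_id
    },
    tm_stop(sprintf("unknown edit op '%s'", e$op)))
  d
}

# ---- serialization ------------------------------------------------------

descriptor_to_list <- function(d) {
  list(format_version = d$format_version,
       descriptor_id = d$descriptor_id,
       meta = list(kind = d$meta$kind, obs_class = d$meta$obs_class),
       domain_code = d$domain_code,
       layout = d$layout,
       fields = lapply(d$fields, unclass),
       elements = lapply(d$elements, function(e)
         list(element_id = e$element_id, concept_label = e$concept_label,
              value_domain = domain_to_list(e$value_domain))),
       change_log = d$change_log)
}

descriptor_from_list <- function(x) {
  fields <- lapply(x$fields, function(f)
    field_descriptor(f$name, f$label %||% f$name, f$role,
                     element_ref = f$element_ref,
                     mandatory = isTRUE(f$mandatory),
                     vocabulary = if (!is.null(f$vocabulary))
                       unlist(f$vocabulary)))
  elements <- lapply(x$elements, function(e)
    structure(list(element_id = e$element_id,
                   concept_label = e$concept_label,
                   value_domain = domain_from_list(e$value_domain)),
              class = "tm_data_element"))
  d <- dataset_descriptor(x$descriptor_id,
                          meta_descriptor(x$meta$kind, x$meta$obs_class),
                          x$domain_code, fields, x$layout,
                          elements = elements)
  d$change_log <- x$change_log %||% list()
  d$format_version <- as.integer(x$format_version %||% 1L)
  d
}

#' Serialize / deserialize a dataset descriptor
#'
#' Descriptors exchange as versioned JSON documents; the round trip is the
#' structural identity and preserves the change log.
#'
#' @param descriptor a `tm_descriptor`.
#' @return `serialize_descriptor()` returns a JSON string;
#'   `deserialize_descriptor()` parses one (malformed input raises a parse
#'   error).
#' @export
serialize_descriptor <- function(descriptor) {
  jsonlite::toJSON(descriptor_to_list(descriptor), auto_unbox = TRUE,
                   null = "null", digits = NA, pretty = TRUE)
}

#' @rdname serialize_descriptor
#' @param text a JSON document.
#' @export
deserialize_descriptor <- function(text) {
  doc <- tryCatch(jsonlite::fromJSON(text, simplifyVector = FALSE),
                  error = function(e)
                    tm_stop(paste("descriptor parse error:", conditionMessage(e)),
                            class = "custodian_parse_error"))
  if (is.null(doc$descriptor_id) || is.null(doc$meta))
    tm_stop("descriptor parse error: missing descriptor_id/meta",
            class = "custodian_parse_error")
  descriptor_from_list(doc)
}
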
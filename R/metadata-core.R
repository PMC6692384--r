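#' Value domains
#'
#' A value domain describes the permissible values of a data element, in the
#' ISO/IEC 11179 sense: an enumerated domain lists its permissible terms as
#' (code, label) pairs, while continuous and free-text domains are described
#' by a datatype, an optional inclusive valid range and an optional unit of
#' measure.
#'
#' @param kind one of `"enumerated"`, `"continuous"`, `"free-text"`.
#' @param terms for enumerated domains, a data frame with columns `code` and
#'   `label` (codes must be unique), or a character vector of codes.
#' @param datatype for continuous/free-text domains, one of `"integer"`,
#'   `"decimal"`, `"text"`, `"date"`.
#' @param range optional numeric `c(min, max)`, inclusive; only valid for
#'   numeric datatypes.
#' @param unit optional unit-of-measure string.
#'
#' @return An object of class `tm_value_domain`.
#' @export
#' @examples
#' value_domain("continuous", datatype = "integer", range = c(0, 120),
#'              unit = "years")
#' value_domain("enumerated", terms = c("M", "F", "U"))
value_domain <- function(kind = c("enumerated", "continuous", "free-text"),
                         terms = NULL, datatype = NULL, range = NULL,
                         unit = NULL) {
  kind <- match.arg(kind)
  if (kind == "enumerated") {
    if (is.null(terms)) tm_stop("enumerated domain needs at least one term")
    if (is.character(terms)) terms <- data.frame(code = terms, label = terms)
    terms <- data.frame(code = as.character(terms$code),
                        label = as.character(terms$label %||% terms$code),
                        stringsAsFactors = FALSE)
    if (nrow(terms) < 1) tm_stop("enumerated domain needs at least one term")
    if (anyDuplicated(toupper(terms$code)))
      tm_stop("permissible term codes must be unique")
    datatype <- "text"
    if (!is.null(range)) tm_stop("valid_range not allowed on enumerated domains")
  } else {
    datatype <- match.arg(datatype, c("integer", "decimal", "text", "date"))
    if (!is.null(range)) {
      if (!datatype %in% c("integer", "decimal"))
        tm_stop("valid_range only allowed on numeric datatypes")
      range <- as.numeric(range)
      if (length(range) != 2 || anyNA(range) || range[1] > range[2])
        tm_stop("valid_range must be c(min, max) with min <= max")
    }
  }
  structure(
    list(kind = kind, terms = terms, datatype = datatype,
         range = range, unit = if (is.null(unit)) NULL else as.character(unit)),
    class = "tm_value_domain"
  )
}

#' @export
print.tm_value_domain <- function(x, ...) {
  if (x$kind == "enumerated") {
    cat("<value domain> enumerated {", paste(x$terms$code, collapse = ", "),
        "}\n", sep = "")
  } else {
    cat("<value domain> ", x$kind, " ", x$datatype,
        if (!is.null(x$range)) sprintf(" [%g, %g]", x$range[1], x$range[2]),
        if (!is.null(x$unit)) paste0(" (", x$unit, ")"), "\n", sep = "")
  }
  invisible(x)
}

#' Create an empty data-element registry
#'
#' The registry is the layer-1 store of data elements: each entry pairs a
#' concept with a value domain and is addressable by a fresh unique element
#' id.  Identity is by id, never by concept label, so the same concept may be
#' registered with different units as distinct elements.
#'
#' @return An environment of class `tm_element_registry`.
#' @export
element_registry <- function() {
  reg <- new.env(parent = emptyenv())
  reg$elements <- list()
  reg$counter <- 0L
  class(reg) <- "tm_element_registry"
  reg
}

#' Define and register a data element
#'
#' @param registry a [element_registry()].
#' @param concept_label human-readable concept name (e.g. `"Age"`); must be
#'   non-empty.
#' @param domain a [value_domain()].
#'
#' @return The registered element (class `tm_data_element`) carrying a fresh
#'   `element_id`.  Registering the same concept label with the same unit
#'   twice is rejected with a conflict error; the same concept with a
#'   different unit yields a distinct element.
#' @export
define_data_element <- function(registry, concept_label, domain) {
  stopifnot(inherits(registry, "tm_element_registry"),
            inherits(domain, "tm_value_domain"))
  concept_label <- as.character(concept_label)
  if (length(concept_label) != 1 || is_blank(concept_label))
    tm_stop("concept_label must be a non-empty string")
  key <- paste_key(tolower(concept_label), norm_unit(domain$unit))
  existing <- vapply(registry$elements, function(e)
    paste_key(tolower(e$concept_label), norm_unit(e$value_domain$unit)), "")
  if (key %in% existing) {
    tm_stop(sprintf(
      "conflict: concept '%s' with unit '%s' is already registered as %s",
      concept_label, norm_unit(domain$unit) , names(which(existing == key))[1]),
      class = "custodian_conflict")
  }
  registry$counter <- registry$counter + 1L
  id <- fresh_id("DE", registry$counter)
  el <- structure(list(element_id = id, concept_label = concept_label,
                       value_domain = domain),
                  class = "tm_data_element")
  registry$elements[[id]] <- el
  el
}

#' Look up a registered data element by id
#' @param registry a [element_registry()].
#' @param element_id the id returned by [define_data_element()].
#' @return The `tm_data_element`, or an error if unknown.
#' @export
get_element <- function(registry, element_id) {
  el <- registry$elements[[element_id]]
  if (is.null(el)) tm_stop(sprintf("unknown element id '%s'", element_id),
                           class = "custodian_not_found")
  el
}

# Vectorised validation workhorse: returns a data.frame with columns
# status ("ok" | "violation" | "missing") and code (reason for violations:
# TYPE_ERROR, RANGE_VIOLATION, VOCAB_VIOLATION) plus matched ("code"/"label")
# for enumerated hits.
validate_values <- function(element, raw) {
  dom <- element$value_domain
  raw <- as.character(raw)
  n <- length(raw)
  status <- rep("ok", n)
  code <- rep(NA_character_, n)
  matched <- rep(NA_character_, n)
  miss <- is_blank(raw)
  status[miss] <- "missing"
  v <- trimws(raw)
  live <- !miss
  if (dom$kind == "enumerated") {
    hit_code <- toupper(v) %in% toupper(dom$terms$code)
    hit_label <- v %in% dom$terms$label
    bad <- live & !hit_code & !hit_label
    status[bad] <- "violation"
    code[bad] <- "VOCAB_VIOLATION"
    matched[live & hit_code] <- "code"
    matched[live & !hit_code & hit_label] <- "label"
  } else if (dom$datatype %in% c("integer", "decimal")) {
    pat <- if (dom$datatype == "integer") "^[+-]?\\d+$" else
      "^[+-]?(\\d+\\.?\\d*|\\.\\d+)([eE][+-]?\\d+)?$"
    ok_type <- grepl(pat, v)
    bad <- live & !ok_type
    status[bad] <- "violation"
    code[bad] <- "TYPE_ERROR"
    if (!is.null(dom$range)) {
      num <- suppressWarnings(as.numeric(v))
      out <- live & ok_type & (num < dom$range[1] | num > dom$range[2])
      status[out] <- "violation"
      code[out] <- "RANGE_VIOLATION"
    }
  } else if (dom$datatype == "date") {
    ok_date <- parse_iso_date(v)$ok
    bad <- live & !ok_date
    status[bad] <- "violation"
    code[bad] <- "TYPE_ERROR"
  }
  data.frame(status = status, code = code, matched = matched,
             stringsAsFactors = FALSE)
}

#' Validate a raw value against a data element
#'
#' Validation is tri-state: an empty or all-whitespace string is *missing*
#' (neither ok nor violation); otherwise the value is *ok* iff it parses
#' under the domain's datatype, lies inside the valid range when one is
#' declared, and — for enumerated domains — matches a permissible term
#' (case-insensitively on code, exactly on label).
#'
#' @param element a `tm_data_element`.
#' @param raw a single raw string as read from a file.
#' @return A list of class `tm_verdict` with fields `status` (`"ok"`,
#'   `"violation"` or `"missing"`), `code` (reason code for violations) and
#'   `matched` (`"code"` or `"label"` for enumerated hits).
#' @export
#' @examples
#' reg <- element_registry()
#' age <- define_data_element(reg, "Age",
#'   value_domain("continuous", datatype = "integer", range = c(0, 120),
#'                unit = "years"))
#' validate_value(age, "27")$status   # "ok"
#' validate_value(age, "150")$code    # "RANGE_VIOLATION"
#' validate_value(age, "")$status     # "missing"
validate_value <- function(element, raw) {
  stopifnot(inherits(element, "tm_data_element"), length(raw) == 1)
  row <- validate_values(element, raw)
  structure(list(status = row$status, code = row$code, matched = row$matched),
            class = "tm_verdict")
}

#' @export
print.tm_verdict <- function(x, ...) {
  cat("<verdict>", x$status,
      if (!is.na(x$code)) paste0("(", x$code, ")"), "\n")
  invisible(x)
}

# ---- registry serialization --------------------------------------------

domain_to_list <- function(dom) {
  list(kind = dom$kind,
       terms = if (!is.null(dom$terms)) dom$terms,
       datatype = dom$datatype, range = dom$range, unit = dom$unit)
}

domain_from_list <- function(x) {
  terms <- NULL
  if (!is.null(x$terms) && length(x$terms)) {
    t <- x$terms
    terms <- if (is.data.frame(t)) t else
      data.frame(code = vapply(t, function(r) r$code, ""),
                 label = vapply(t, function(r) r$label %||% r$code, ""),
                 stringsAsFactors = FALSE)
  }
  value_domain(x$kind, terms = terms, datatype = x$datatype,
               range = if (!is.null(x$range)) as.numeric(unlist(x$range)),
               unit = x$unit)
}

#' Serialize / deserialize a data-element registry
#'
#' The registry serialises to a versioned JSON document with one record per
#' element (id, concept, domain kind, terms or datatype/range/unit); the
#' round trip is stable.
#'
#' @param registry a [element_registry()].
#' @return `serialize_registry()` returns a JSON string;
#'   `deserialize_registry()` rebuilds the registry from one.
#' @export
serialize_registry <- function(registry) {
  recs <- lapply(registry$elements, function(e) {
    list(element_id = e$element_id, concept_label = e$concept_label,
         value_domain = domain_to_list(e$value_domain))
  })
  jsonlite::toJSON(list(format_version = 1L, counter = registry$counter,
                        elements = unname(recs)),
                   auto_unbox = TRUE, null = "null", digits = NA, pretty = TRUE)
}

#' @rdname serialize_registry
#' @param text JSON produced by `serialize_registry()`.
#' @export
deserialize_registry <- function(text) {
  doc <- jsonlite::fromJSON(text, simplifyDataFrame = FALSE)
  reg <- element_registry()
  reg$counter <- as.integer(doc$counter)
  for (rec in doc$elements) {
    el <- structure(list(element_id = rec$element_id,
                         concept_label = rec$concept_label,
                         value_domain = domain_from_list(rec$value_domain)),
                    class = "tm_data_element")
    reg$elements[[el$element_id]] <- el
  }
  reg
}
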
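# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
is_blank <- function(x) {
  x <- as.character(x)
  is.na(x) | !nzchar(trimws(x))
}

# Deterministic 31-bit string hash (polynomial rolling hash).  Used to derive
# one pseudo-random stream per generated file so fixtures are stable when new
# files are added to a config.
hash_string <- function(x) {
  ints <- utf8ToInt(enc2utf8(as.character(x)))
  h <- 0
  for (i in ints) h <- (h * 31 + i) %% 2147483647
  as.integer(h)
}

# Unit strings are compared after trimming and lowercasing; no conversion.
norm_unit <- function(u) {
  if (is.null(u) || length(u) == 0) return("")
  u <- as.character(u)
  u[is.na(u)] <- ""
  tolower(trimws(u))
}

# Condition helper: all user-facing contract violations are classed errors so
# the CLI can map them to exit statuses.
tm_stop <- function(msg, class = "custodian_error", data = NULL) {
  cond <- structure(
    class = c(class, "custodian_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), data = data)
  )
  stop(cond)
}

fresh_id <- function(prefix, n) sprintf("%s%04d", prefix, n)

# ISO-8601 date parsing with partial dates (YYYY, YYYY-MM) allowed.  Values
# are kept as text; completeness records how much of the date was given.
parse_iso_date <- function(x) {
  x <- trimws(as.character(x))
  pat_y  <- "^\\d{4}$"
  pat_ym <- "^\\d{4}-(0[1-9]|1[0-2])$"
  pat_ymd <- "^\\d{4}-(0[1-9]|1[0-2])-(0[1-9]|[12]\\d|3[01])$"
  pat_full <- "^\\d{4}-(0[1-9]|1[0-2])-(0[1-9]|[12]\\d|3[01])T\\d{2}:\\d{2}(:\\d{2})?$"
  completeness <- rep(NA_character_, length(x))
  completeness[grepl(pat_y, x)] <- "year"
  completeness[grepl(pat_ym, x)] <- "month"
  completeness[grepl(pat_ymd, x)] <- "day"
  completeness[grepl(pat_full, x)] <- "time"
  list(ok = !is.na(completeness), completeness = completeness)
}

# Stable key used for set-comparison of observation multisets.
paste_key <- function(...) paste(..., sep = "\r")
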
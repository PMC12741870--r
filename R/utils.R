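# Internal helpers: structured conditions, JSON IO, small assertions.

oartex_error <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "oartex_error")))
}

oartex_warn <- function(msg, class, ...) {
  warning(warningCondition(msg, ..., class = c(class, "oartex_warning")))
}

assert_scalar_number <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    oartex_error(sprintf("'%s' must be a finite numeric scalar", name),
                 "oartex_domain_error")
  }
  bad <- if (strict_min) x <= min else x < min
  if (bad) {
    oartex_error(sprintf("'%s' must be %s %s, got %s", name,
                         if (strict_min) ">" else ">=", min, x),
                 "oartex_domain_error")
  }
  invisible(x)
}

assert_probability <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    oartex_error(sprintf("'%s' must be a probability in [0, 1]", name),
                 "oartex_config_error")
  }
  invisible(x)
}

# Serialize an R list to JSON text deterministically (stable key order as
# constructed, full double precision so identical inputs give identical bytes).
to_json <- function(x) {
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                   na = "null", pretty = FALSE)
}

write_json_file <- function(x, path) {
  writeLines(to_json(x), path, useBytes = TRUE)
  invisible(path)
}

read_json_file <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                     simplifyMatrix = FALSE)
}

# ISO-8601 timestamps are compared lexicographically throughout: the fixture
# dialect always emits "YYYY-MM-DDTHH:MM:SS", for which string order is time
# order. Avoids timezone ambiguity entirely.
iso_timestamp <- function(date, hour = 8L, minute = 0L, second = 0L) {
  sprintf("%sT%02d:%02d:%02d", format(date, "%Y-%m-%d"), hour, minute, second)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
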
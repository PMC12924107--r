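# internal helpers shared across modules

# round half up at k decimals (printed clinical tables round 0.5 upward)
round_half_up <- function(x, digits = 0) {
  floor(x * 10^digits + 0.5 + 1e-12) / 10^digits
}

# number of decimal places in a printed value (79.51 -> 2, 39 -> 0)
decimal_places <- function(v) {
  s <- sprintf("%.10f", v)
  s <- sub("0+$", "", s)
  s <- sub("\\.$", "", s)
  if (!grepl(".", s, fixed = TRUE)) return(0L)
  nchar(sub(".*\\.", "", s))
}

# coerce CSV-style boolean columns: accepts logical, {0,1}, {no,yes},
# {false,true} case-insensitively
as_flag <- function(x, field = deparse(substitute(x))) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1) | is.na(x)))
      stop("field '", field, "' must be 0/1, got values outside {0,1}",
           call. = FALSE)
    return(x == 1)
  }
  s <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(s))
  out[s %in% c("1", "yes", "true", "y", "t")] <- TRUE
  out[s %in% c("0", "no", "false", "n", "f")] <- FALSE
  bad <- !is.na(s) & is.na(out)
  if (any(bad))
    stop("field '", field, "' has unrecognized boolean value(s): ",
         paste(unique(s[bad]), collapse = ", "), call. = FALSE)
  out
}

stopifnot_scalar_prob <- function(x, name, open_left = TRUE, open_right = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop("'", name, "' must be a single number", call. = FALSE)
  lo_ok <- if (open_left) x > 0 else x >= 0
  hi_ok <- if (open_right) x < 1 else x <= 1
  if (!lo_ok || !hi_ok)
    stop("'", name, "' must lie in ", if (open_left) "(" else "[", "0, 1",
         if (open_right) ")" else "]", call. = FALSE)
  invisible(x)
}

# build a stats-style htest result so print() behaves like base R tests
make_htest <- function(method, p.value, statistic = NULL, parameter = NULL,
                       estimate = NULL, alternative = "two.sided",
                       data.name = "table", note = NULL) {
  out <- list(method = method, p.value = p.value,
              alternative = alternative, data.name = data.name)
  if (!is.null(statistic)) out$statistic <- statistic
  if (!is.null(parameter)) out$parameter <- parameter
  if (!is.null(estimate)) out$estimate <- estimate
  if (!is.null(note)) out$note <- note
  class(out) <- "htest"
  out
}
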
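`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
stop2 <- function(...) stop(..., call. = FALSE)

#' @keywords internal
is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

#' @keywords internal
as_date_strict <- function(x, what = "date", file = NULL) {
  if (inherits(x, "Date")) return(x)
  out <- as.Date(rep(NA_real_, length(x)), origin = "1970-01-01")
  ok <- !is.na(x) & nzchar(trimws(as.character(x)))
  parsed <- as.Date(as.character(x[ok]), format = "%Y-%m-%d")
  bad <- which(ok)[is.na(parsed)]
  if (length(bad)) {
    stop2(sprintf("unparseable %s %s%s", what, dQuote(as.character(x)[bad[1L]]),
                  if (is.null(file)) "" else sprintf(" in %s line %d", file, bad[1L] + 1L)))
  }
  out[ok] <- parsed
  out
}

#' @keywords internal
year_of <- function(d) as.POSIXlt(d)$year + 1900L

# truncated gaussian noise used by the simulator's guard margins
#' @keywords internal
tnorm <- function(n, sd, trunc_sd = 2.5) {
  x <- stats::rnorm(n, 0, sd)
  pmin(pmax(x, -trunc_sd * sd), trunc_sd * sd)
}

#' @keywords internal
md5_of_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null"), f)
  unname(tools::md5sum(f))
}
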
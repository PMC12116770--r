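`%||%` <- function(a, b) if (is.null(a)) b else a

#' Shift dates by whole calendar months
#'
#' Calendar-month arithmetic with day-of-month clamping (e.g. Jan 31 + 1 month
#' is Feb 28/29), the convention used for all pre-/post-index windows.
#'
#' @param dates a `Date` vector.
#' @param n integer number of months (may be negative).
#' @return A `Date` vector of the same length.
#' @export
add_months <- function(dates, n) {
  dates <- as.Date(dates)
  out <- rep(as.Date(NA), length(dates))
  ok <- which(!is.na(dates))
  if (!length(ok)) return(out)
  lt <- as.POSIXlt(dates[ok])
  total <- lt$year * 12L + lt$mon + as.integer(n)
  yr <- total %/% 12L + 1900L
  mo <- total %% 12L
  dim <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)[mo + 1L]
  leap <- yr %% 4L == 0L & (yr %% 100L != 0L | yr %% 400L == 0L)
  dim[mo == 1L & leap] <- 29L
  day <- pmin(lt$mday, dim)
  out[ok] <- as.Date(sprintf("%04d-%02d-%02d", yr, mo + 1L, day))
  out
}

#' Normalize ICD codes for prefix matching
#'
#' Uppercases and removes dots/whitespace, so `"F20.9"` and `"f209"` compare
#' equal under prefix matching. Both ICD-9 and ICD-10-CM codes pass through.
#'
#' @param codes character vector of diagnosis codes.
#' @return Normalized character vector.
#' @export
normalize_icd <- function(codes) {
  toupper(gsub("[.[:space:]]", "", as.character(codes)))
}

#' Match ICD codes against a set of code prefixes
#'
#' @param codes character vector of diagnosis codes (any dotting).
#' @param prefixes character vector of code prefixes (any dotting).
#' @return Logical vector: does each code start with any prefix?
#' @export
icd_prefix_match <- function(codes, prefixes) {
  codes <- normalize_icd(codes)
  prefixes <- normalize_icd(prefixes)
  out <- rep(FALSE, length(codes))
  for (p in prefixes) out <- out | startsWith(codes, p)
  out
}

#' Percentage of a numerator over a denominator, rounded for reporting
#'
#' The rounding convention used in all report tables: one decimal place by
#' default. Returns `NA` (never divides) when the denominator is zero.
#'
#' @param n numerator count(s).
#' @param d denominator count(s).
#' @param digits decimal places (default 1).
#' @return Numeric percentage(s) in `[0, 100]`, `NA` on zero denominator.
#' @export
#' @examples
#' prevalence_pct(2, 3)
prevalence_pct <- function(n, d, digits = 1) {
  out <- ifelse(d > 0, round(100 * n / d, digits), NA_real_)
  as.numeric(out)
}

# Run code with a private RNG state, restoring the caller's stream.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stop_cogehr <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}
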
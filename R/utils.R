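#' @keywords internal
"_PACKAGE"

# Round half away from zero; calendar arithmetic on ages needs a deterministic
# rule and base round() is round-half-even.
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

as_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  as.Date(x)
}

#' Austral-year label of a calendar date
#'
#' Austral years run July 1 to June 30 so the southern-hemisphere summer
#' spawning season is not split across labels. The label is the calendar year
#' of the July 1 anchor: 2020-08-01 and 2021-03-01 both belong to austral
#' year 2020.
#'
#' @param date a `Date` vector.
#' @return integer vector of starting calendar years.
#' @export
#' @examples
#' austral_year(as.Date(c("2020-08-01", "2021-03-01", "2021-07-01")))
austral_year <- function(date) {
  date <- as_date(date)
  y <- as.integer(format(date, "%Y"))
  m <- as.integer(format(date, "%m"))
  ifelse(m >= 7L, y, y - 1L)
}

austral_year_start <- function(label) as.Date(sprintf("%d-07-01", label))
austral_year_end <- function(label) as.Date(sprintf("%d-06-30", label + 1L))

# Stratified derived seeds: every stochastic helper takes `seed` and builds a
# local RNG state so callers are bit-reproducible and independent of the
# global stream.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Sub-seed derivation that stays inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  (as.integer(seed) * 7919L + as.integer(offset)) %% 2147483L + 1L
}

# Small-sample-corrected Akaike criterion from a fitted mgcv model; k is the
# effective number of parameters (total edf including scale/power).
aicc <- function(fit) {
  ll <- stats::logLik(fit)
  k <- attr(ll, "df")
  n <- stats::nobs(fit)
  aic <- -2 * as.numeric(ll) + 2 * k
  if (n - k - 1 > 0) aic + 2 * k * (k + 1) / (n - k - 1) else Inf
}
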
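#' Age bands of the population model
#'
#' The population is stratified into four age bands: under 60, 60--64,
#' 65--69, and 70 or above. The two middle bands are five years wide; the
#' youngest and oldest are open-ended. All banded quantities in the package
#' (counts, rates, shares) are named numeric vectors in this order.
#'
#' @return Character vector of the four band labels.
#' @export
age_bands <- function() EHCV_BANDS

EHCV_BANDS <- c("under60", "b60_64", "b65_69", "b70plus")

# lower age bound of each band; used for voucher eligibility gating
EHCV_BAND_LOWER_AGE <- c(under60 = 0, b60_64 = 60, b65_69 = 65, b70plus = 70)

# band widths in years (NA = open ended); 5-year bands drive aging outflow
EHCV_BAND_WIDTH <- c(under60 = NA_real_, b60_64 = 5, b65_69 = 5, b70plus = NA_real_)

#' Voucher service categories
#'
#' Voucher claims are split into five service categories: non-preventive
#' consultations, chronic-condition follow-up, dentistry, vaccination and
#' other services.
#'
#' @return Character vector of the five category labels.
#' @export
service_categories <- function() EHCV_CATEGORIES

EHCV_CATEGORIES <- c("non_preventive", "chronic_follow_up", "dentistry",
                     "vaccination", "other")

# coerce x to a named vector over `names`, recycling a scalar
as_band_vector <- function(x, what = "value", names = EHCV_BANDS) {
  if (length(x) == 1L) x <- rep(x, length(names))
  if (length(x) != length(names)) {
    stop(sprintf("'%s' must have length 1 or %d", what, length(names)),
         call. = FALSE)
  }
  if (!is.null(names(x))) {
    if (!setequal(names(x), names)) {
      stop(sprintf("'%s' has names %s; expected %s", what,
                   paste(names(x), collapse = ", "),
                   paste(names, collapse = ", ")), call. = FALSE)
    }
    x <- x[names]
  }
  stats::setNames(as.numeric(x), names)
}

check_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    stop(sprintf("'%s' must be finite", what), call. = FALSE)
  }
  invisible(x)
}

check_nonneg <- function(x, what) {
  check_finite(x, what)
  if (any(x < 0)) stop(sprintf("'%s' must be >= 0", what), call. = FALSE)
  invisible(x)
}

check_fraction <- function(x, what) {
  check_finite(x, what)
  if (any(x < 0 | x > 1)) {
    stop(sprintf("'%s' must lie in [0, 1]", what), call. = FALSE)
  }
  invisible(x)
}
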
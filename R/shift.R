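#' Substitution fractions for voucher visits
#'
#' Where a voucher-funded visit comes from: a fraction replaces a visit
#' that would have happened in the public sector (the shift the scheme
#' aims for), a fraction replaces an already-private visit, and the rest is
#' induced new demand. The three fractions sum to 1.
#'
#' @param from_public Fraction replacing a public visit, in `[0, 1]`.
#' @param from_private Fraction replacing a private visit.
#' @param induced Fraction that is new demand.
#' @return An object of class `ehcv_substitution`.
#' @export
substitution_params <- function(from_public, from_private, induced) {
  check_fraction(from_public, "from_public")
  check_fraction(from_private, "from_private")
  check_fraction(induced, "induced")
  if (abs(from_public + from_private + induced - 1) > 1e-9) {
    stop("substitution fractions must sum to 1", call. = FALSE)
  }
  structure(list(from_public = as.numeric(from_public),
                 from_private = as.numeric(from_private),
                 induced = as.numeric(induced)),
            class = "ehcv_substitution")
}

#' Net sector utilization after voucher visits
#'
#' Voucher visits remove `from_public * V` visits from the public sector
#' and add `(from_public + induced) * V` to the private sector; the
#' `from_private` share is already counted in the private baseline and
#' moves nothing. A shift exceeding the public baseline is truncated at
#' zero public visits with a warning (aggregate flows can transiently
#' overshoot in extreme scenarios).
#'
#' @param public_base Baseline public visits (>= 0).
#' @param private_base Baseline private visits (>= 0).
#' @param voucher_visits Voucher-funded visits V (>= 0).
#' @param sub An [substitution_params()].
#' @return Named numeric vector `c(public = , private = )`.
#' @export
#' @examples
#' net_shift(100, 100, 20, substitution_params(0.5, 0.3, 0.2))
net_shift <- function(public_base, private_base, voucher_visits, sub) {
  check_nonneg(public_base, "public_base")
  check_nonneg(private_base, "private_base")
  check_nonneg(voucher_visits, "voucher_visits")
  stopifnot(inherits(sub, "ehcv_substitution"))
  shift <- sub$from_public * voucher_visits
  if (shift > public_base) {
    warning(sprintf(
      "public-to-private shift (%.4g) exceeds the public baseline (%.4g); truncated",
      shift, public_base), call. = FALSE)
    shift <- public_base
  }
  c(public = public_base - shift,
    private = private_base + shift + sub$induced * voucher_visits)
}

#' Public-to-private visit ratio
#'
#' The study's reliance metric: annual public-sector visits divided by
#' private-sector visits.
#'
#' @param public Public visits (>= 0).
#' @param private Private visits (> 0).
#' @return Dimensionless ratio.
#' @export
public_private_ratio <- function(public, private) {
  check_nonneg(public, "public")
  check_nonneg(private, "private")
  if (any(private == 0)) {
    stop("public-to-private ratio is undefined when private visits are 0",
         call. = FALSE)
  }
  public / private
}
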
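#' Round half away from zero
#'
#' Commercial rounding: ties are rounded away from zero, so 0.25 at one
#' decimal becomes 0.3 and -0.25 becomes -0.3. Used for all reported
#' fold changes and percentages, where banker's rounding (the base R
#' default) would be surprising.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded to `digits` decimals.
#' @export
#' @examples
#' round_half_up(2.85, 1)   # 2.9
#' round_half_up(0.456, 2)  # 0.46
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x), is.numeric(digits), length(digits) == 1L)
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Format a fold change for reporting
#'
#' Fold changes of at least 1 are reported to one decimal, fold changes
#' below 1 to two decimals (so 0.46 is not flattened to 0.5). Rounding is
#' half-away-from-zero. Internal arithmetic is never performed on these
#' strings; they are emitted at report time only.
#'
#' @param x Numeric vector of fold changes (> 0).
#' @return Character vector.
#' @export
#' @examples
#' format_fold(c(24.24, 0.4568))  # "24.2" "0.46"
format_fold <- function(x) {
  ifelse(is.na(x), NA_character_,
    ifelse(x >= 1,
      sprintf("%.1f", round_half_up(x, 1)),
      sprintf("%.2f", round_half_up(x, 2))
    )
  )
}

#' Format a fraction as a percentage to one decimal
#'
#' @param x Numeric vector of fractions in \[0, 1\].
#' @return Character vector such as "95.9%".
#' @export
format_pct <- function(x) {
  ifelse(is.na(x), NA_character_,
    sprintf("%.1f%%", round_half_up(100 * x, 1))
  )
}

# Derive a reproducible substream seed from a top-level seed. Distinct
# streams (chase simulation, intensity noise, sequence generation, ...)
# get distinct, deterministic seeds; results stay within 32-bit range.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(seed) * 48271 + 101 * stream) %% 2147483629) + 1L
}

# Shared argument validation: scalar positive finite number.
check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("`%s` must be finite and strictly positive", name),
         call. = FALSE)
  }
  invisible(x)
}
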
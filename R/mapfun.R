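#' Map functions and the selfed-RIL recombination correction
#'
#' `kosambi()` converts a meiotic recombination fraction r into a map distance
#' d = 25 * ln((1 + 2r) / (1 - 2r)) cM; `kosambi_inv()` is its exact inverse,
#' d -> tanh(d / 50) / 2. `ril_correct()` undoes the map expansion observed in
#' selfed recombinant inbred lines: with R the observed RIL genotype
#' recombination frequency, the Haldane-Waddington relation R = 2r / (1 + 2r)
#' gives r = R / (2 * (1 - R)). `ril_expand()` is the forward relation.
#'
#' @param r Meiotic recombination fraction(s) in `[0, 0.5)`.
#' @param d Map distance(s) in cM.
#' @param R Observed RIL recombination frequency in `[0, 1]`; values above
#'   `rmax` are clamped (adjacent markers cannot legitimately exceed it).
#' @param rmax Clamp for the observed frequency before correction
#'   (default 0.49).
#'
#' @return Numeric vector (cM for `kosambi`, fractions otherwise).
#' @examples
#' kosambi(0.1)                       # ~10.14 cM
#' kosambi_inv(kosambi(0.25))         # 0.25
#' ril_correct(0.2)                   # 0.125
#' @export
kosambi <- function(r) {
  if (any(r < 0 | r >= 0.5, na.rm = TRUE)) {
    abort("recombination fraction must lie in [0, 0.5)")
  }
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' @rdname kosambi
#' @export
kosambi_inv <- function(d) {
  if (any(d < 0, na.rm = TRUE)) abort("map distance must be non-negative")
  tanh(d / 50) / 2
}

#' @rdname kosambi
#' @export
ril_correct <- function(R, rmax = 0.49) {
  if (any(R < 0, na.rm = TRUE)) abort("observed recombination frequency must be >= 0")
  R <- pmin(R, rmax)
  pmin(R / (2 * (1 - R)), 0.4999)
}

#' @rdname kosambi
#' @export
ril_expand <- function(r) {
  if (any(r < 0 | r > 0.5, na.rm = TRUE)) abort("r must lie in [0, 0.5]")
  2 * r / (1 + 2 * r)
}
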
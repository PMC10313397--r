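#' Canonical condition and taste vocabularies
#'
#' The four chocolate shapes are always handled in the fixed order
#' (Bouba-A6, Kiki-A6, Bouba-S6, Kiki-A10) = (mu1, mu2, mu3, mu4):
#' the basic rounded shape, the basic angular shape, a rounded shape with a
#' minor geometry change, and an angular shape with a minor geometry change.
#' All pivoting, parameter naming and probability matrices use this order.
#'
#' @return Character vector of the four shape labels in canonical order.
#' @export
shape_levels <- function() {
  c("Bouba-A6", "Kiki-A6", "Bouba-S6", "Kiki-A10")
}

#' @rdname shape_levels
#' @return `taste_levels()`: the three rated tastes.
#' @export
taste_levels <- function() {
  c("sweetness", "sourness", "bitterness")
}

#' Reference condition means for the study-like generator
#'
#' Per-taste EAP point estimates of the population mean VAS score reported
#' for the original study's four shapes; used as generator truth by
#' [make_study_dataset()] and as a sanity anchor in tests.
#'
#' @return Named list with one 4-vector (canonical shape order) per taste.
#' @export
reference_means <- function() {
  list(
    sweetness  = c(38.52, 28.90, 40.63, 30.67),
    sourness   = c(28.49, 33.45, 25.75, 28.91),
    bitterness = c(54.29, 55.21, 49.14, 54.40)
  )
}

#' Reference directional-probability tables
#'
#' The reported 4x4 matrices of directional probabilities
#' P(row shape rated higher than column shape) for sweetness, sourness and
#' bitterness, with the zero diagonal convention. These are inputs for the
#' compound (group-level) probability arithmetic, not outputs of this
#' package's fits.
#'
#' @return Named list of three 4x4 matrices with shape-label dimnames.
#' @export
reference_probability_tables <- function() {
  lv <- shape_levels()
  mk <- function(x) matrix(x, 4, 4, byrow = TRUE, dimnames = list(lv, lv))
  list(
    sweetness = mk(c(
      0,     0.987, 0.345, 0.956,
      0.013, 0,     0.013, 0.349,
      0.655, 0.987, 0,     0.966,
      0.044, 0.651, 0.034, 0
    )),
    sourness = mk(c(
      0,     0.180, 0.705, 0.465,
      0.820, 0,     0.917, 0.779,
      0.295, 0.083, 0,     0.272,
      0.535, 0.221, 0.728, 0
    )),
    bitterness = mk(c(
      0,     0.427, 0.822, 0.494,
      0.573, 0,     0.851, 0.563,
      0.178, 0.149, 0,     0.206,
      0.506, 0.437, 0.794, 0
    ))
  )
}

# internal: canonical parameter names of one 4-condition fit
param_names <- function() {
  c(paste0("mu", 1:4), paste0("sigma", 1:4),
    "corr21", "corr31", "corr32", "corr41", "corr42", "corr43")
}
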
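#' Published calibration values for five-layer forest-soil profiles
#'
#' Summary statistics from a field survey of 39 forest-soil profiles
#' (south-western Poland, Opole Anomaly region) in which 137Cs specific
#' activities of the first five horizons from the surface were closed to
#' relative activities over layers `w1..w5`. These are the defaults the
#' synthetic generator is calibrated to, and the inputs for reconstructing
#' the published balance-variance ranking without the (undeposited) raw
#' data.
#'
#' `reference_layer_center()` returns the closed geometric means of the
#' relative activities per layer. `reference_vr_matrix()` returns the
#' published matrix of pairwise log-ratio variances. `reference_layer_stats()`
#' returns the full published summary table (min, quartiles, median, means,
#' max per layer, as printed, i.e. not re-closed).
#'
#' @return See above; `reference_layer_center()` gives a `composition`,
#'   `reference_vr_matrix()` a `variation_matrix`,
#'   `reference_layer_stats()` a data frame.
#' @export
reference_layer_center <- function() {
  closure(c(0.034, 0.379, 0.365, 0.031, 0.003), labels = layer_labels())
}

#' @rdname reference_layer_center
#' @export
reference_vr_matrix <- function() {
  # strict lower triangle, column-major: (2,1)(3,1)(4,1)(5,1)(3,2)(4,2)(5,2)(4,3)(5,3)(5,4)
  vr_matrix(c(0.85, 1.2, 5.1, 3.8, 1.1, 6.2, 4.1, 5.2, 4.4, 3.8),
            labels = layer_labels())
}

#' @rdname reference_layer_center
#' @export
reference_layer_stats <- function() {
  data.frame(
    layer  = layer_labels(),
    min    = c(0.003, 0.113, 0.020, 0.000, 0.000),
    q1     = c(0.026, 0.275, 0.302, 0.011, 0.002),
    median = c(0.035, 0.365, 0.449, 0.051, 0.003),
    mean   = c(0.046, 0.420, 0.421, 0.103, 0.010),
    gmean  = c(0.034, 0.379, 0.365, 0.031, 0.003),
    q3     = c(0.063, 0.523, 0.516, 0.161, 0.009),
    max    = c(0.258, 0.971, 0.769, 0.404, 0.120),
    stringsAsFactors = FALSE
  )
}

layer_labels <- function(layers = 5L) paste0("w", seq_len(layers))

#' @rdname reference_layer_center
#' @export
soil_type_codes <- function() c("PZ", "CM", "GLm", "PLp", "GLs", "LV", "LC", "RB")
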
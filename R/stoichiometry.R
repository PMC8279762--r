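#' Calibrate per-fluorophore burst brightness from a monomeric control
#'
#' The burst-brightness distribution of a monomeric single-label control
#' (e.g. free GFP) calibrates the photon yield of one fluorophore per
#' transit. The median is used as the summary because burst brightness is
#' right-skewed by trajectory-through-focus variation; a bootstrap standard
#' error of the median is attached.
#'
#' @param control_brightness numeric vector of green-channel burst
#'   brightness values from the monomeric control.
#' @param min_events minimum acceptable number of control events
#'   (default 100).
#' @param n_boot bootstrap replicates for the SE of the median.
#' @param seed optional RNG seed for the bootstrap.
#' @return object of class `brightness_calibration`: `monomer_median`,
#'   `median_se`, `n_control_events`, `histogram`.
#' @export
calibrate_monomer <- function(control_brightness, min_events = 100L,
                              n_boot = 200L, seed = NULL) {
  b <- control_brightness[is.finite(control_brightness)]
  if (length(b) < min_events) {
    stop_param("only ", length(b), " control events (need >= ", min_events,
               "); acquire a longer control trace")
  }
  if (!is.null(seed)) set.seed(seed)
  med <- stats::median(b)
  if (med <= 0) stop_param("monomer median brightness must be positive")
  boot <- replicate(n_boot, stats::median(sample(b, replace = TRUE)))
  h <- graphics::hist(b, breaks = "Sturges", plot = FALSE)
  structure(list(monomer_median = med, median_se = stats::sd(boot),
                 n_control_events = length(b),
                 histogram = list(breaks = h$breaks, counts = h$counts)),
            class = "brightness_calibration")
}

#' Estimate labeled-protein copy number per complex
#'
#' The ratio of sample to monomer median burst brightness estimates the
#' number of fluorophores (hence labeled protein copies) per particle;
#' the copy number is the nearest positive integer, with a bootstrap
#' percentile interval on the ratio and an ambiguity flag when the interval
#' spans more than one integer.
#'
#' @param sample_brightness numeric vector of burst brightness values for the
#'   sample, measured under identical acquisition settings as the control.
#' @param calibration a [calibrate_monomer()] result.
#' @param n_boot bootstrap replicates.
#' @param conf confidence level of the percentile interval.
#' @param seed optional RNG seed.
#' @return object of class `copy_number_estimate`: `ratio`, `n_copies`,
#'   `ci` (length 2), `ambiguous`, `n_sample_events`.
#' @export
estimate_copy_number <- function(sample_brightness, calibration,
                                 n_boot = 200L, conf = 0.95, seed = NULL) {
  stopifnot(inherits(calibration, "brightness_calibration"))
  b <- sample_brightness[is.finite(sample_brightness)]
  if (length(b) == 0) stop_param("empty sample: no burst brightness values")
  if (!is.null(seed)) set.seed(seed)
  ratio <- stats::median(b) / calibration$monomer_median
  boot <- replicate(n_boot, stats::median(sample(b, replace = TRUE)) /
                      calibration$monomer_median)
  ci <- unname(stats::quantile(boot, c((1 - conf) / 2, 1 - (1 - conf) / 2)))
  n_copies <- max(1L, as.integer(round(ratio)))
  ambiguous <- floor(ci[1] + 0.5) != floor(ci[2] + 0.5)
  structure(list(ratio = ratio, n_copies = n_copies, ci = ci,
                 ambiguous = ambiguous, n_sample_events = length(b)),
            class = "copy_number_estimate")
}

#' @export
print.copy_number_estimate <- function(x, ...) {
  cat(sprintf("Copy-number estimate: %d copies per complex\n", x$n_copies))
  cat(sprintf("  median brightness ratio %.2f (%.0f%% CI %.2f-%.2f)%s\n",
              x$ratio, 100 * 0.95, x$ci[1], x$ci[2],
              if (x$ambiguous) " [ambiguous: CI spans two integers]" else ""))
  invisible(x)
}
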
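#' Describe a fluorescent species transiting the confocal volume
#'
#' A species is defined by how many GFP and mCherry labels it carries and how
#' often it transits the detection volume. The canonical complex preset of
#' the package is 2 GFP : 1 mCherry (a GFP-tagged dimer bound to one
#' mCherry-tagged partner).
#'
#' @param name species label used in ground-truth records.
#' @param n_green,n_red number of GFP / mCherry labels per particle (not both
#'   zero).
#' @param event_rate expected transits per second (>= 0).
#' @return object of class `species_model`.
#' @export
species_model <- function(name, n_green, n_red, event_rate) {
  check_number(n_green, "n_green", lower = 0)
  check_number(n_red, "n_red", lower = 0)
  if (n_green == 0 && n_red == 0) stop_param("species must carry at least one label")
  check_number(event_rate, "event_rate", lower = 0)
  structure(list(name = as.character(name), n_green = n_green, n_red = n_red,
                 event_rate = event_rate), class = "species_model")
}

#' Describe the acquisition settings of a simulated experiment
#'
#' Defaults emulate the dilute (~1 nM) single-molecule regime with 1 ms
#' binning: sparse, mostly non-overlapping diffusive transits with a Gaussian
#' temporal profile, 6% spectral leakage of GFP photons into the red channel,
#' and Poisson backgrounds.
#'
#' @param duration acquisition length in seconds.
#' @param bin_width bin width in ms.
#' @param brightness_green,brightness_red mean detected photons per
#'   fluorophore per ms at the focus.
#' @param transit_sigma Gaussian temporal width of a transit, ms.
#' @param crosstalk fraction of emitted GFP photons registered in the red
#'   channel (0 <= crosstalk < 1).
#' @param background_green,background_red background rates, photons/ms.
#' @param seed optional RNG seed for reproducible simulation.
#' @return object of class `acquisition_model`.
#' @export
acquisition_model <- function(duration = 180, bin_width = 1,
                              brightness_green = 250, brightness_red = 250,
                              transit_sigma = 1.5, crosstalk = 0.06,
                              background_green = 1, background_red = 1,
                              seed = NULL) {
  check_number(duration, "duration", lower = 1e-9)
  check_number(bin_width, "bin_width", lower = 1e-9)
  check_number(brightness_green, "brightness_green", lower = 0)
  check_number(brightness_red, "brightness_red", lower = 0)
  check_number(transit_sigma, "transit_sigma", lower = 1e-9)
  check_number(crosstalk, "crosstalk", lower = 0, upper = 1 - 1e-12)
  check_number(background_green, "background_green", lower = 0)
  check_number(background_red, "background_red", lower = 0)
  structure(list(duration = duration, bin_width = bin_width,
                 brightness_green = brightness_green,
                 brightness_red = brightness_red,
                 transit_sigma = transit_sigma, crosstalk = crosstalk,
                 background_green = background_green,
                 background_red = background_red, seed = seed),
            class = "acquisition_model")
}

# Accumulate expected per-bin photon rates for a set of events.
# centers in ms; amp = expected TOTAL photons of the event in that channel.
# Each event spreads amp over bins by the Gaussian transit profile.
accumulate_lambda <- function(n_bins, bin_width, centers, amps, sigma) {
  lam <- numeric(n_bins)
  if (length(centers) == 0) return(lam)
  half <- ceiling(6 * sigma / bin_width)
  offs <- -half:half
  center_bin <- floor(centers / bin_width) + 1L
  idx <- outer(center_bin, offs, `+`)            # events x offsets
  lower <- (idx - 1L) * bin_width                # bin left edges, ms
  z_lo <- (lower - centers) / sigma
  z_hi <- (lower + bin_width - centers) / sigma
  w <- (stats::pnorm(z_hi) - stats::pnorm(z_lo)) * amps
  keep <- idx >= 1L & idx <= n_bins
  agg <- rowsum(w[keep], group = idx[keep])
  lam[as.integer(rownames(agg))] <- lam[as.integer(rownames(agg))] + agg[, 1]
  lam
}

# expected total detected photons per label per transit
transit_yield <- function(brightness, sigma) brightness * sigma * sqrt(2 * pi)

#' Simulate a two-channel photon trace from a set of species
#'
#' Event centers follow a Poisson process in time (overlapping transits are
#' allowed and recorded). Per bin, channel counts are Poisson with rate
#' background + the summed Gaussian transit profiles of all events; each
#' emitted green photon is independently rerouted to the red channel with
#' probability `crosstalk`, so the expected spectral leakage is exactly the
#' crosstalk parameter.
#'
#' @param species a `species_model` or list of them.
#' @param acq an [acquisition_model()].
#' @param metadata extra metadata stored in the trace header.
#' @return list with `trace` (a [trace_file()]) and `truth` (ground-truth
#'   list: per-event data.frame `events` with species, center time and
#'   expected per-channel emitted photons, plus the acquisition settings).
#' @export
simulate_trace <- function(species, acq = acquisition_model(),
                           metadata = list()) {
  if (inherits(species, "species_model")) species <- list(species)
  if (length(species) && !all(vapply(species, inherits, TRUE, "species_model"))) {
    stop_param("'species' must be species_model objects")
  }
  if (!is.null(acq$seed)) set.seed(acq$seed)
  n_bins <- max(1L, round(acq$duration * 1000 / acq$bin_width))
  duration_ms <- n_bins * acq$bin_width

  events <- data.frame(species = character(0), center_ms = numeric(0),
                       n_green = numeric(0), n_red = numeric(0),
                       expected_green = numeric(0), expected_red = numeric(0))
  for (sp in species) {
    n_ev <- stats::rpois(1, sp$event_rate * acq$duration)
    if (n_ev == 0) next
    centers <- sort(stats::runif(n_ev, 0, duration_ms))
    events <- rbind(events, data.frame(
      species = sp$name, center_ms = centers,
      n_green = sp$n_green, n_red = sp$n_red,
      expected_green = sp$n_green * transit_yield(acq$brightness_green, acq$transit_sigma),
      expected_red = sp$n_red * transit_yield(acq$brightness_red, acq$transit_sigma)))
  }
  sim_trace_from_events(events, acq, n_bins, metadata)
}

# shared back end: given an event table, realize the photon trace
sim_trace_from_events <- function(events, acq, n_bins, metadata = list()) {
  lam_g <- accumulate_lambda(n_bins, acq$bin_width, events$center_ms,
                             events$expected_green, acq$transit_sigma)
  lam_r <- accumulate_lambda(n_bins, acq$bin_width, events$center_ms,
                             events$expected_red, acq$transit_sigma)
  bg_g <- acq$background_green * acq$bin_width
  bg_r <- acq$background_red * acq$bin_width

  green_emit <- stats::rpois(n_bins, lam_g)
  reroute <- stats::rbinom(n_bins, green_emit, acq$crosstalk)
  green <- green_emit - reroute +
    if (bg_g > 0) stats::rpois(n_bins, bg_g) else 0L
  red <- reroute + stats::rpois(n_bins, lam_r) +
    if (bg_r > 0) stats::rpois(n_bins, bg_r) else 0L

  md <- c(metadata, list(seed = acq$seed %||% "none"))
  trace <- trace_file(green, red, bin_width = acq$bin_width, metadata = md)
  truth <- list(events = events, acquisition = unclass(acq),
                crosstalk_rerouted_photons = sum(reroute),
                green_emitted_photons = sum(green_emit))
  list(trace = trace, truth = truth)
}

#' Simulate a two-species association experiment
#'
#' Generates `n_events` GFP-bearing transits of which a fraction `f_assoc`
#' are complexes (default 2 GFP : 1 mCherry) and the rest GFP-only
#' monomers; an equal number of unbound mCherry-only singletons as GFP-only
#' singletons is appended so all three event classes appear, as in a real
#' coexpression lysate. `f_assoc` is therefore exactly the associated
#' fraction of the GFP species that the window estimator of
#' [coincidence_pipeline()] targets.
#'
#' @param f_assoc true associated fraction of GFP-bearing events, in [0,1].
#' @param n_events number of GFP-bearing transits to generate.
#' @param acq an [acquisition_model()] supplying the optics (brightness,
#'   crosstalk, backgrounds, bin width) and seed. The acquisition length is
#'   derived from `n_events` and `event_rate`, not taken from `acq`: asking
#'   for more events means acquiring longer at constant dilution, as in a
#'   real experiment.
#' @param event_rate total transit rate across all species, per second.
#'   The default (5/s) keeps the sparse single-molecule regime where
#'   transit pile-up (two particles co-occupying the confocal volume, which
#'   mimics coincidence) stays at the few-percent level.
#' @param complex_n_green,complex_n_red label stoichiometry of the complex.
#' @return list with `trace` and `truth`; `truth$class_counts` holds the true
#'   per-class event counts.
#' @export
simulate_mixture <- function(f_assoc, n_events, acq = acquisition_model(),
                             event_rate = 5, complex_n_green = 2,
                             complex_n_red = 1) {
  check_number(f_assoc, "f_assoc", lower = 0, upper = 1)
  check_number(n_events, "n_events", lower = 1)
  check_number(event_rate, "event_rate", lower = 1e-9)
  if (!is.null(acq$seed)) set.seed(acq$seed)
  n_complex <- stats::rbinom(1, n_events, f_assoc)
  n_gfp_only <- n_events - n_complex
  n_red_only <- n_gfp_only
  n_total <- n_complex + n_gfp_only + n_red_only
  duration <- ceiling(n_total / event_rate)
  n_bins <- max(1L, round(duration * 1000 / acq$bin_width))
  duration_ms <- n_bins * acq$bin_width
  yg <- transit_yield(acq$brightness_green, acq$transit_sigma)
  yr <- transit_yield(acq$brightness_red, acq$transit_sigma)
  events <- data.frame(
    species = rep(c("complex", "gfp_only", "mcherry_only"),
                  c(n_complex, n_gfp_only, n_red_only)),
    center_ms = stats::runif(n_complex + n_gfp_only + n_red_only, 0, duration_ms),
    n_green = rep(c(complex_n_green, 1, 0), c(n_complex, n_gfp_only, n_red_only)),
    n_red = rep(c(complex_n_red, 0, 1), c(n_complex, n_gfp_only, n_red_only)))
  events$expected_green <- events$n_green * yg
  events$expected_red <- events$n_red * yr
  events <- events[order(events$center_ms), , drop = FALSE]
  rownames(events) <- NULL

  out <- sim_trace_from_events(events, acq, n_bins,
                               metadata = list(f_assoc = f_assoc))
  out$truth$f_assoc <- f_assoc
  out$truth$class_counts <- c(complex = n_complex, gfp_only = n_gfp_only,
                              mcherry_only = n_red_only)
  out
}
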
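#' Simulate a PrestoBlue absorbance plate
#'
#' Test wells draw their true 570/600 nm absorbances around condition means
#' with Gaussian well-to-well noise; media-only blanks are included in
#' triplicate (the background-correction convention of the assay).
#'
#' @param n_test number of test wells.
#' @param A570,A600 mean test-well absorbances.
#' @param N570,N600 mean media-only absorbances.
#' @param cv coefficient of variation of well noise.
#' @param n_media number of media-only wells (default 3).
#' @param seed optional RNG seed.
#' @return list: `plate` (a `plate_table` data.frame) and `truth` (the
#'   noiseless parameters and the noiseless as-printed percent reduction).
#' @export
simulate_plate <- function(n_test = 8, A570 = 1.2, A600 = 0.45,
                           N570 = 0.35, N600 = 0.3, cv = 0.02,
                           n_media = 3, seed = NULL) {
  check_number(n_test, "n_test", lower = 1)
  check_number(n_media, "n_media", lower = 1)
  check_number(cv, "cv", lower = 0)
  if (!is.null(seed)) set.seed(seed)
  noisy <- function(mu, n) pmax(mu * (1 + stats::rnorm(n, 0, cv)), 1e-6)
  plate <- data.frame(
    well = c(sprintf("T%02d", seq_len(n_test)), sprintf("M%02d", seq_len(n_media))),
    role = rep(c("test", "media_only"), c(n_test, n_media)),
    A570 = c(noisy(A570, n_test), noisy(N570, n_media)),
    A600 = c(noisy(A600, n_test), noisy(N600, n_media)))
  class(plate) <- c("plate_table", "data.frame")
  truth <- list(A570 = A570, A600 = A600, N570 = N570, N600 = N600,
                percent_reduction_as_printed =
                  presto_blue_reduction(A570, A600, mode = "as_printed"))
  list(plate = plate, truth = truth)
}

#' Simulate a label-free proteome table with spiked effects
#'
#' Generates a proteins x (control + knockout) log-normal LFQ table: base
#' log2 abundances are drawn per protein, knockout samples receive an
#' additive log2 effect for the spiked subset, Gaussian replicate noise is
#' added on the log2 scale, and values drop out missing-at-random. Optional
#' decoy rows (flagged or low-peptide) exercise the filtering rules.
#'
#' @param n_proteins number of protein rows (before decoys).
#' @param n_per_group replicates per group (default 3, as in a 3 WT vs 3 KO
#'   design).
#' @param effects numeric vector of true log2 effects (KO - WT); either
#'   length `n_proteins` or a short vector applied to the first proteins
#'   (rest 0). Empty means global null.
#' @param residual_sd replicate noise SD on the log2 scale.
#' @param missing_rate missing-at-random dropout probability per cell.
#' @param base_mean,base_sd mean and SD of base log2 abundances.
#' @param n_flagged,n_low_peptide numbers of decoy rows added with quality
#'   flags set / unique peptides < 2.
#' @param groups group names, length 2 (control first).
#' @param seed optional RNG seed.
#' @return list: `table` (a [protein_groups()] table), `truth` (data.frame
#'   `effects` with per-protein true log2 effect, plus the group layout).
#' @export
simulate_proteome <- function(n_proteins = 1000, n_per_group = 3,
                              effects = numeric(0), residual_sd = 0.3,
                              missing_rate = 0.1, base_mean = 25,
                              base_sd = 2, n_flagged = 0, n_low_peptide = 0,
                              groups = c("WT", "KO"), seed = NULL) {
  check_number(n_proteins, "n_proteins", lower = 1)
  check_number(n_per_group, "n_per_group", lower = 2)
  check_number(missing_rate, "missing_rate", lower = 0, upper = 1)
  check_number(residual_sd, "residual_sd", lower = 0)
  if (length(groups) != 2) stop_param("exactly two groups are required")
  if (!is.null(seed)) set.seed(seed)

  eff <- numeric(n_proteins)
  if (length(effects)) {
    if (length(effects) > n_proteins) stop_param("more effects than proteins")
    eff[seq_along(effects)] <- effects
  }
  samples <- c(paste0(groups[1], "_", seq_len(n_per_group)),
               paste0(groups[2], "_", seq_len(n_per_group)))
  base <- stats::rnorm(n_proteins, base_mean, base_sd)
  mu <- cbind(matrix(base, n_proteins, n_per_group),
              matrix(base + eff, n_proteins, n_per_group))
  log2x <- mu + matrix(stats::rnorm(length(mu), 0, residual_sd),
                       n_proteins, 2 * n_per_group)
  x <- 2^log2x
  drop <- matrix(stats::runif(length(x)) < missing_rate,
                 n_proteins, 2 * n_per_group)
  x[drop] <- NA_real_

  n_extra <- n_flagged + n_low_peptide
  if (n_extra > 0) {
    xb <- 2^matrix(stats::rnorm(n_extra * 2 * n_per_group, base_mean, base_sd),
                   n_extra, 2 * n_per_group)
    x <- rbind(x, xb)
  }
  n_total <- nrow(x)
  colnames(x) <- samples
  flag_kind <- if (n_flagged > 0) {
    sample(c("only_identified_by_site", "reverse", "potential_contaminant"),
           n_flagged, replace = TRUE)
  } else character(0)
  flags <- data.frame(
    only_identified_by_site = c(rep(FALSE, n_proteins),
                                flag_kind == "only_identified_by_site",
                                rep(FALSE, n_low_peptide)),
    reverse = c(rep(FALSE, n_proteins), flag_kind == "reverse",
                rep(FALSE, n_low_peptide)),
    potential_contaminant = c(rep(FALSE, n_proteins),
                              flag_kind == "potential_contaminant",
                              rep(FALSE, n_low_peptide)))
  peptides <- c(pmax(2L, stats::rpois(n_proteins, 8)),
                pmax(2L, stats::rpois(n_flagged, 8)),
                rep(1L, n_low_peptide))
  table <- protein_groups(
    ids = sprintf("P%05d", seq_len(n_total)),
    gene_names = sprintf("GENE%05d", seq_len(n_total)),
    unique_peptides = peptides,
    flags = flags,
    intensities = x)
  truth <- list(effects = data.frame(ids = sprintf("P%05d", seq_len(n_proteins)),
                                     true_log2fc = eff),
                groups = stats::setNames(
                  list(samples[seq_len(n_per_group)],
                       samples[n_per_group + seq_len(n_per_group)]), groups))
  list(table = table, truth = truth)
}
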
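#' Differential-proteome configuration
#'
#' @param min_unique_peptides rows with fewer unique peptides than this are
#'   removed (default 2; "< 2" is the removal rule, so 2 is retained).
#' @param min_valid_per_group minimum observed values required in each group
#'   (default 2 of 3).
#' @param s0 additive variance-fudge constant of the SAM-style d-statistic
#'   (default 1).
#' @param fdr target permutation FDR (default 0.05).
#' @param n_permutations cap on sampled label permutations; all are
#'   enumerated when the number of relabelings is at most this (default
#'   1000).
#' @param seed RNG seed used only when permutations must be sampled.
#' @return object of class `diff_config`.
#' @export
diff_config <- function(min_unique_peptides = 2L, min_valid_per_group = 2L,
                        s0 = 1.0, fdr = 0.05, n_permutations = 1000L,
                        seed = NULL) {
  check_number(min_unique_peptides, "min_unique_peptides", lower = 0)
  check_number(min_valid_per_group, "min_valid_per_group", lower = 2)
  check_number(s0, "s0", lower = 0)
  check_number(fdr, "fdr", lower = 1e-9, upper = 1 - 1e-9)
  check_number(n_permutations, "n_permutations", lower = 1)
  structure(list(min_unique_peptides = as.integer(min_unique_peptides),
                 min_valid_per_group = as.integer(min_valid_per_group),
                 s0 = s0, fdr = fdr,
                 n_permutations = as.integer(n_permutations), seed = seed),
            class = "diff_config")
}

#' Filter a protein-groups table for quantitative analysis
#'
#' Drops rows flagged "Only identified by site", "Reverse" or "Potential
#' contaminant", rows identified with fewer than `min_unique_peptides`
#' unique peptides, and rows lacking at least `min_valid_per_group` observed
#' intensities in either group. Idempotent.
#'
#' @param table a [protein_groups()] table.
#' @param groups named list of length 2 mapping group name to its sample
#'   names (each of size >= 2).
#' @param cfg a [diff_config()].
#' @return the retained [protein_groups()] table.
#' @export
filter_table <- function(table, groups, cfg = diff_config()) {
  stopifnot(inherits(table, "protein_groups"))
  check_groups(table, groups)
  inten <- intensity_matrix(table)
  keep <- !table$only_identified_by_site & !table$reverse &
    !table$potential_contaminant &
    table$unique_peptides >= cfg$min_unique_peptides
  for (g in groups) {
    keep <- keep & rowSums(!is.na(inten[, g, drop = FALSE])) >=
      cfg$min_valid_per_group
  }
  out <- table[keep, , drop = FALSE]
  attr(out, "samples") <- attr(table, "samples")
  class(out) <- class(table)
  rownames(out) <- NULL
  out
}

check_groups <- function(table, groups) {
  if (!is.list(groups) || length(groups) != 2 || is.null(names(groups))) {
    stop_param("'groups' must be a named list of two sample-name vectors")
  }
  if (any(lengths(groups) < 2)) {
    stop_param("each group needs at least 2 samples")
  }
  absent <- setdiff(unlist(groups), attr(table, "samples"))
  if (length(absent)) {
    stop_param("unknown sample(s): ", paste(absent, collapse = ", "))
  }
  invisible(groups)
}

#' Log2-transform an LFQ intensity matrix
#'
#' Elementwise log2 preserving missingness; non-positive intensities are an
#' error identifying the offending cell.
#'
#' @param x numeric matrix of LFQ intensities (`NA` = missing).
#' @return log2 matrix of the same shape.
#' @export
log2_transform <- function(x) {
  bad <- which(!is.na(x) & x <= 0, arr.ind = TRUE)
  if (nrow(bad <- as.matrix(bad)) > 0) {
    stop_param("non-positive intensity at row ", bad[1, 1], ", column ",
               bad[1, 2])
  }
  log2(x)
}

#' Per-protein z-scores
#'
#' Each row is centered and scaled over its observed values. Constant rows
#' (zero variance) are emitted as all zeros and flagged in the `degenerate`
#' attribute rather than dropped, preserving the matrix shape for heatmaps.
#'
#' @param x numeric matrix (proteins x samples), `NA` allowed.
#' @return z-score matrix with logical attribute `degenerate` per row.
#' @export
zscore <- function(x) {
  mu <- rowMeans(x, na.rm = TRUE)
  sd <- apply(x, 1, stats::sd, na.rm = TRUE)
  degenerate <- !is.finite(sd) | sd == 0
  z <- (x - mu) / ifelse(degenerate, 1, sd)
  z[degenerate & !is.na(z)] <- 0   # recycles row-wise over columns
  attr(z, "degenerate") <- degenerate
  z
}

# Vectorized SAM-style d and pooled-t statistics over matrix rows.
# Returns d, t, p (two-sided pooled-variance t-test), per-group means and ns.
row_stats <- function(x, idx1, idx2, s0) {
  x1 <- x[, idx1, drop = FALSE]; x2 <- x[, idx2, drop = FALSE]
  n1 <- rowSums(!is.na(x1)); n2 <- rowSums(!is.na(x2))
  m1 <- rowMeans(x1, na.rm = TRUE); m2 <- rowMeans(x2, na.rm = TRUE)
  v1 <- apply(x1, 1, stats::var, na.rm = TRUE)
  v2 <- apply(x2, 1, stats::var, na.rm = TRUE)
  ok <- n1 >= 2 & n2 >= 2
  sp <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / pmax(n1 + n2 - 2, 1))
  se <- sp * sqrt(1 / n1 + 1 / n2)
  diff <- m2 - m1
  d <- ifelse(ok, diff / (se + s0), NA_real_)
  tstat <- ifelse(ok & se > 0, diff / se, ifelse(ok & diff == 0, 0, Inf * sign(diff)))
  p <- ifelse(ok, 2 * stats::pt(-abs(tstat), df = n1 + n2 - 2), NA_real_)
  p[ok & !is.finite(tstat)] <- 0
  p[ok & se == 0 & diff == 0] <- 1
  list(d = d, t = tstat, p = p, mean1 = m1, mean2 = m2, log2fc = diff,
       n1 = n1, n2 = n2)
}

#' SAM-style moderated difference statistic
#'
#' `d = (mean(KO) - mean(WT)) / (s_pooled * sqrt(1/n1 + 1/n2) + s0)`; the
#' additive fudge constant s0 damps the significance of low-variance
#' proteins.
#'
#' @param x_wt,x_ko numeric vectors of observed log2 intensities (>= 2 each).
#' @param s0 additive fudge constant (>= 0).
#' @return the d statistic.
#' @export
d_statistic <- function(x_wt, x_ko, s0 = 1.0) {
  x_wt <- x_wt[!is.na(x_wt)]; x_ko <- x_ko[!is.na(x_ko)]
  if (length(x_wt) < 2 || length(x_ko) < 2) {
    stop_param("need at least 2 observed values per group")
  }
  check_number(s0, "s0", lower = 0)
  n1 <- length(x_wt); n2 <- length(x_ko)
  sp <- sqrt(((n1 - 1) * stats::var(x_wt) + (n2 - 1) * stats::var(x_ko)) /
               (n1 + n2 - 2))
  den <- sp * sqrt(1 / n1 + 1 / n2) + s0
  if (den == 0) stop_param("zero variance with s0 = 0: d undefined")
  (mean(x_ko) - mean(x_wt)) / den
}

# all group-1 index sets for the permutation null, excluding the identity
# and its complement (both reproduce the observed |d| exactly)
permutation_sets <- function(n_samples, idx1, cap, seed = NULL) {
  all_sets <- utils::combn(n_samples, length(idx1), simplify = FALSE)
  trivial <- vapply(all_sets, function(s) {
    setequal(s, idx1) || setequal(s, setdiff(seq_len(n_samples), idx1))
  }, TRUE)
  sets <- all_sets[!trivial]
  if (length(sets) > cap) {
    if (!is.null(seed)) set.seed(seed)
    sets <- sets[sample.int(length(sets), cap)]
  }
  sets
}

#' Permutation-based FDR significance calls
#'
#' Computes observed |d| per protein, recomputes |d| under group-label
#' relabelings, and for each candidate cutoff t estimates
#' `FDR(t) = mean_perm #\{|d_perm| >= t\} / max(1, #\{|d_obs| >= t\})`.
#' The significance threshold is the smallest cutoff with FDR at or below
#' the target; proteins with `|d_obs|` at or above it are called
#' significant.
#'
#' @param x log2 intensity matrix (proteins x samples), `NA` = missing.
#' @param groups named list of two sample-name vectors (columns of `x`).
#' @param cfg a [diff_config()].
#' @return list: `significant` (logical), `d` (observed), `threshold`,
#'   `achieved_fdr`, `n_permutations`, `granularity_warning`.
#' @export
permutation_fdr <- function(x, groups, cfg = diff_config()) {
  idx1 <- match(groups[[1]], colnames(x))
  idx2 <- match(groups[[2]], colnames(x))
  if (any(is.na(c(idx1, idx2)))) stop_param("group samples must name columns of x")
  obs <- row_stats(x, idx1, idx2, cfg$s0)
  d_obs <- abs(obs$d)
  sets <- permutation_sets(ncol(x), idx1, cfg$n_permutations, cfg$seed)
  granularity_warning <- length(sets) < 10
  if (granularity_warning) {
    warning("only ", length(sets), " distinct permutations: FDR estimates are coarse")
  }
  d_perm <- lapply(sets, function(s) {
    abs(row_stats(x, s, setdiff(seq_len(ncol(x)), s), cfg$s0)$d)
  })
  d_perm_all <- sort(unlist(d_perm))
  n_perm <- length(sets)
  # candidate cutoffs: the observed |d| values (ascending)
  cand <- sort(unique(d_obs[is.finite(d_obs)]))
  d_obs_sorted <- sort(d_obs[is.finite(d_obs)])
  n_obs_ge <- length(d_obs_sorted) -
    findInterval(cand, d_obs_sorted, left.open = TRUE)
  n_perm_ge <- (length(d_perm_all) -
                  findInterval(cand, d_perm_all, left.open = TRUE)) / n_perm
  fdr_hat <- n_perm_ge / pmax(1, n_obs_ge)
  ok <- fdr_hat <= cfg$fdr
  if (any(ok)) {
    threshold <- cand[which(ok)[1]]
    achieved <- fdr_hat[which(ok)[1]]
  } else {
    threshold <- Inf
    achieved <- NA_real_
  }
  list(significant = is.finite(d_obs) & d_obs >= threshold, d = obs$d,
       threshold = threshold, achieved_fdr = achieved,
       n_permutations = n_perm, granularity_warning = granularity_warning)
}

#' Differential-abundance analysis of a label-free proteome
#'
#' Full downstream pipeline: quality filtering, log2 transform, SAM-style
#' moderated d with additive s0, pooled two-sample two-sided t-test
#' p-values, and permutation-based FDR significance calls. No missing-value
#' imputation is performed anywhere: every statistic uses observed values
#' only.
#'
#' @param table a [protein_groups()] table.
#' @param groups named list of two sample-name vectors, control group first
#'   (log2 fold changes are second minus first).
#' @param cfg a [diff_config()].
#' @return object of class `diff_result`: `proteins` data.frame (`ids`,
#'   `gene_name`, group means, `log2fc`, `d`, `p`, `significant`),
#'   `n_quantified`, `threshold`, `achieved_fdr`, `groups`, `config`.
#' @export
diff_proteome <- function(table, groups, cfg = diff_config()) {
  retained <- filter_table(table, groups, cfg)
  if (nrow(retained) == 0) stop_param("no proteins pass the filters")
  x <- log2_transform(intensity_matrix(retained))
  idx1 <- match(groups[[1]], colnames(x))
  idx2 <- match(groups[[2]], colnames(x))
  obs <- row_stats(x, idx1, idx2, cfg$s0)
  fdr <- permutation_fdr(x, groups, cfg)
  proteins <- data.frame(ids = retained$ids, gene_name = retained$gene_name,
                         mean_1 = obs$mean1, mean_2 = obs$mean2,
                         log2fc = obs$log2fc, d = obs$d, p = obs$p,
                         significant = fdr$significant,
                         stringsAsFactors = FALSE)
  names(proteins)[3:4] <- paste0("mean_", names(groups))
  structure(list(proteins = proteins, n_quantified = nrow(retained),
                 threshold = fdr$threshold, achieved_fdr = fdr$achieved_fdr,
                 n_permutations = fdr$n_permutations,
                 groups = groups, config = unclass(cfg)),
            class = "diff_result")
}

#' @export
print.diff_result <- function(x, ...) {
  cat("Label-free differential proteome analysis\n")
  cat("  groups:", paste(names(x$groups), lengths(x$groups), sep = ":",
                         collapse = " vs "), "\n")
  cat("  proteins quantified:", x$n_quantified, "\n")
  cat(sprintf("  permutation FDR %.0f%% (S0 = %g, %d permutations): |d| >= %s\n",
              100 * x$config$fdr, x$config$s0, x$n_permutations,
              format(x$threshold, digits = 3)))
  cat("  significant:", sum(x$proteins$significant), "\n")
  invisible(x)
}

#' @export
summary.diff_result <- function(object, ...) {
  print(object)
  sig <- object$proteins[object$proteins$significant, ]
  if (nrow(sig)) {
    cat("top changes:\n")
    print(utils::head(sig[order(-abs(sig$d)),
                          c("ids", "gene_name", "log2fc", "d", "p")], 10),
          row.names = FALSE)
  }
  invisible(object)
}

#' Volcano-plot table
#'
#' @param result a `diff_result`.
#' @return data.frame with `ids`, `gene_name`, `log2fc`, `neg_log10_p`,
#'   `significant`, ready for plotting.
#' @export
volcano_table <- function(result) {
  stopifnot(inherits(result, "diff_result"))
  p <- result$proteins
  data.frame(ids = p$ids, gene_name = p$gene_name, log2fc = p$log2fc,
             neg_log10_p = -log10(p$p), significant = p$significant,
             stringsAsFactors = FALSE)
}
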
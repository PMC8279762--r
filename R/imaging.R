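#' Maximum-entropy (Kapur) gray-level threshold
#'
#' Finds the threshold maximizing the sum of the Shannon entropies of the
#' normalized foreground and background gray-level histograms (the
#' Kapur-Sahoo-Wong criterion, the "Maximum Entropy" method of ImageJ).
#' Pixels strictly above the returned level are foreground.
#'
#' @param x an integer image matrix of gray levels, or a named numeric
#'   vector of histogram counts whose names are the gray levels.
#' @return the threshold gray level (foreground = `image > threshold`).
#' @export
max_entropy_threshold <- function(x) {
  if (is.matrix(x)) {
    levels <- sort(unique(as.vector(x)))
    counts <- as.numeric(table(factor(as.vector(x), levels = levels)))
  } else {
    if (is.null(names(x))) stop_param("histogram input must have gray-level names")
    levels <- as.numeric(names(x))
    counts <- as.numeric(x)
    keep <- counts > 0
    levels <- levels[keep]; counts <- counts[keep]
  }
  if (length(levels) < 2) stop_param("no threshold exists: constant image")
  p <- counts / sum(counts)
  # cumulative probability and cumulative entropy term, vectorized
  P <- cumsum(p)
  ent <- cumsum(-p * log(p))            # p > 0 by construction
  H_T <- ent[length(ent)]
  k <- seq_len(length(levels) - 1L)     # candidate split after level k
  Pk <- P[k]
  valid <- Pk > 0 & Pk < 1
  crit <- rep(-Inf, length(k))
  crit[valid] <- log(Pk[valid] * (1 - Pk[valid])) +
    ent[k][valid] / Pk[valid] + (H_T - ent[k][valid]) / (1 - Pk[valid])
  levels[which.max(crit)]
}

# 8-connected component labeling of a logical mask via a pixel-adjacency
# graph; returns an integer matrix of component labels (0 = background).
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  idx <- which(mask)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  if (length(idx) == 0) return(lab)
  nr <- nrow(mask)
  pos <- match(idx, idx)
  row <- (idx - 1L) %% nr + 1L
  col <- (idx - 1L) %/% nr + 1L
  edges <- integer(0)
  for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- row + d[1]; c2 <- col + d[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= ncol(mask)
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    j <- match(nb, idx)
    keep <- !is.na(j)
    edges <- c(edges, rbind(pos[ok][keep], j[keep]))
  }
  g <- igraph::make_graph(edges = edges, n = length(idx), directed = FALSE)
  comp <- igraph::components(g)$membership
  lab[idx] <- as.integer(comp)
  lab
}

#' Puncta / particle-analysis configuration
#'
#' @param min_particle_px,max_particle_px inclusive particle area limits in
#'   pixels (defaults 2 and 200; excludes single-pixel noise and merged
#'   clusters).
#' @param connectivity pixel connectivity; only 8 is supported.
#' @return object of class `puncta_config`.
#' @export
puncta_config <- function(min_particle_px = 2L, max_particle_px = 200L,
                          connectivity = 8L) {
  check_number(min_particle_px, "min_particle_px", lower = 1)
  check_number(max_particle_px, "max_particle_px", lower = min_particle_px)
  if (!identical(as.integer(connectivity), 8L)) {
    stop_param("only 8-connectivity is supported")
  }
  structure(list(min_particle_px = as.integer(min_particle_px),
                 max_particle_px = as.integer(max_particle_px),
                 connectivity = 8L),
            class = "puncta_config")
}

#' Count PLA puncta per cell with a nuclear/cytosolic split
#'
#' Binarizes the image at the maximum-entropy threshold, labels 8-connected
#' components, keeps those with area within the configured limits, and
#' assigns each punctum to the cell containing its centroid; a punctum is
#' nuclear iff its centroid lies in the nucleus mask (so nuclear + cytosolic
#' always equals total).
#'
#' @param image integer image matrix.
#' @param cell_mask integer matrix of cell labels (0 = background).
#' @param nucleus_mask integer matrix, non-zero inside nuclei.
#' @param cfg a [puncta_config()].
#' @return data.frame of class `puncta_result` with one row per cell:
#'   `cell`, `total`, `nuclear`, `cytosolic`; attribute `threshold` holds
#'   the gray level used.
#' @export
count_puncta <- function(image, cell_mask, nucleus_mask,
                         cfg = puncta_config()) {
  if (missing(cell_mask) || missing(nucleus_mask) ||
      is.null(cell_mask) || is.null(nucleus_mask)) {
    stop_param("cell and nucleus masks are required")
  }
  if (!all(dim(image) == dim(cell_mask)) ||
      !all(dim(image) == dim(nucleus_mask))) {
    stop_param("masks must match the image shape")
  }
  cells <- sort(setdiff(unique(as.vector(cell_mask)), 0))
  out <- data.frame(cell = cells, total = 0L, nuclear = 0L, cytosolic = 0L)
  thr <- tryCatch(max_entropy_threshold(image), smc_param_error = function(e) NA)
  if (!is.na(thr)) {
    lab <- label_components(image > thr)
    nlab <- max(lab)
    if (nlab > 0) {
      areas <- tabulate(lab[lab > 0], nbins = nlab)
      for (id in which(areas >= cfg$min_particle_px &
                       areas <= cfg$max_particle_px)) {
        px <- which(lab == id)
        nr <- nrow(image)
        cy <- round(mean((px - 1L) %% nr + 1L))
        cx <- round(mean((px - 1L) %/% nr + 1L))
        cell <- cell_mask[cy, cx]
        if (cell == 0) next
        i <- match(cell, out$cell)
        out$total[i] <- out$total[i] + 1L
        if (nucleus_mask[cy, cx] > 0) {
          out$nuclear[i] <- out$nuclear[i] + 1L
        } else {
          out$cytosolic[i] <- out$cytosolic[i] + 1L
        }
      }
    }
  }
  attr(out, "threshold") <- thr
  class(out) <- c("puncta_result", "data.frame")
  out
}

#' Fraction of nuclei scored focus-positive
#'
#' A nucleus is positive when its focus count is strictly greater than the
#' cutoff (default: more than 5 foci per nucleus).
#'
#' @param counts non-negative integer vector of per-nucleus focus counts.
#' @param cutoff positivity cutoff (strict inequality), default 5.
#' @return list of class `foci_result`: `counts`, `cutoff`,
#'   `fraction_positive`.
#' @export
foci_fraction <- function(counts, cutoff = 5) {
  if (length(counts) == 0) stop_param("empty focus-count input")
  check_counts(counts, "counts")
  structure(list(counts = as.integer(counts), cutoff = cutoff,
                 fraction_positive = mean(counts > cutoff)),
            class = "foci_result")
}
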
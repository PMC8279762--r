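# Gaussian spot accumulated onto an intensity matrix
add_spot <- function(img, y0, x0, amplitude, sigma) {
  half <- ceiling(4 * sigma)
  ys <- max(1, round(y0) - half):min(nrow(img), round(y0) + half)
  xs <- max(1, round(x0) - half):min(ncol(img), round(x0) + half)
  g <- outer(exp(-(ys - y0)^2 / (2 * sigma^2)),
             exp(-(xs - x0)^2 / (2 * sigma^2)))
  img[ys, xs] <- img[ys, xs] + amplitude * g
  img
}

#' Simulate a PLA-puncta image with cell and nucleus masks
#'
#' Cells are disks laid out on a grid with a smaller concentric nuclear
#' disk; puncta are diffraction-limited 2-D Gaussian spots at recorded
#' coordinates, uniform within the cell. Poisson shot noise plus additive
#' Gaussian read noise is applied. A warning is recorded in the metadata
#' when the requested puncta density implies substantial spot overlap.
#'
#' @param n_cells number of cells.
#' @param puncta_per_cell integer vector (recycled) of puncta per cell, or a
#'   single Poisson mean when `poisson = TRUE`.
#' @param psf_sigma spot standard deviation in pixels.
#' @param amplitude peak spot intensity in counts.
#' @param background mean background counts per pixel.
#' @param read_noise_sd additive Gaussian noise SD in counts.
#' @param cell_radius,nucleus_radius disk radii in pixels.
#' @param min_separation minimum distance between puncta centers in pixels
#'   (PLA signals are distinct diffraction-limited spots); placement falls
#'   back to unconstrained with a recorded warning when a cell is too
#'   crowded.
#' @param poisson draw per-cell puncta counts from a Poisson distribution.
#' @param seed optional RNG seed.
#' @return list: `image` (integer matrix), `cell_mask`, `nucleus_mask`
#'   (integer label matrices), `truth` (per-punctum coordinates, cell id,
#'   nuclear flag, and any `overlap_warning`).
#' @export
simulate_puncta_image <- function(n_cells = 1, puncta_per_cell = 10,
                                  psf_sigma = 1.2, amplitude = 300,
                                  background = 10, read_noise_sd = 2,
                                  cell_radius = 40, nucleus_radius = 16,
                                  min_separation = 7, poisson = FALSE,
                                  seed = NULL) {
  check_number(n_cells, "n_cells", lower = 1)
  if (!is.null(seed)) set.seed(seed)
  ncol_grid <- ceiling(sqrt(n_cells))
  nrow_grid <- ceiling(n_cells / ncol_grid)
  pitch <- 2 * cell_radius + 12
  h <- nrow_grid * pitch; w <- ncol_grid * pitch
  img <- matrix(0, h, w)
  cell_mask <- matrix(0L, h, w)
  nucleus_mask <- matrix(0L, h, w)
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)

  counts <- if (poisson) stats::rpois(n_cells, puncta_per_cell[1]) else
    rep_len(as.integer(puncta_per_cell), n_cells)
  truth <- data.frame(cell = integer(0), y = numeric(0), x = numeric(0),
                      nuclear = logical(0))
  overlap_warning <- NULL
  for (i in seq_len(n_cells)) {
    gy <- (i - 1) %/% ncol_grid; gx <- (i - 1) %% ncol_grid
    cy <- gy * pitch + pitch / 2; cx <- gx * pitch + pitch / 2
    inside <- (yy - cy)^2 + (xx - cx)^2 <= cell_radius^2
    cell_mask[inside] <- i
    nucleus_mask[(yy - cy)^2 + (xx - cx)^2 <= nucleus_radius^2] <- i
    k <- counts[i]
    placed <- 0
    ys <- xs <- numeric(0)
    attempts <- 0
    while (placed < k) {
      py <- stats::runif(1, cy - cell_radius, cy + cell_radius)
      px <- stats::runif(1, cx - cell_radius, cx + cell_radius)
      attempts <- attempts + 1
      if ((py - cy)^2 + (px - cx)^2 > (cell_radius - 3)^2) next
      crowded <- attempts > 200 * k
      if (!crowded && length(ys) &&
          min((ys - py)^2 + (xs - px)^2) < min_separation^2) next
      if (crowded && is.null(overlap_warning)) {
        overlap_warning <- sprintf(
          "cell %d too crowded for min_separation %.1f px: spots may merge",
          i, min_separation)
      }
      ys <- c(ys, py); xs <- c(xs, px)
      img <- add_spot(img, py, px, amplitude, psf_sigma)
      truth <- rbind(truth, data.frame(
        cell = i, y = py, x = px,
        nuclear = (py - cy)^2 + (px - cx)^2 <= nucleus_radius^2))
      placed <- placed + 1
    }
  }
  noisy <- stats::rpois(length(img), as.vector(img) + background) +
    round(stats::rnorm(length(img), 0, read_noise_sd))
  image <- matrix(pmax(as.integer(noisy), 0L), h, w)
  list(image = image, cell_mask = cell_mask, nucleus_mask = nucleus_mask,
       truth = list(puncta = truth, counts = counts,
                    overlap_warning = overlap_warning))
}

#' Simulate a single-comet image with a known tail fraction
#'
#' The comet is a Gaussian head disc plus an exponentially decaying tail
#' streak along +x starting at the head center, constructed so that exactly
#' `tail_fraction` of the total noiseless intensity lies in the tail.
#' Poisson shot noise is applied.
#'
#' @param tail_fraction fraction of DNA (intensity) in the tail, in [0,1].
#' @param tail_length exponential decay length of the tail in pixels.
#' @param total_intensity total noiseless comet intensity in counts.
#' @param head_sigma Gaussian radius of the head in pixels.
#' @param width,height image size in pixels.
#' @param background mean background counts per pixel.
#' @param seed optional RNG seed.
#' @return list: `image` (integer matrix) and `truth` (constructed head and
#'   tail intensities, tail centroid offset, parameters).
#' @export
simulate_comet_image <- function(tail_fraction, tail_length = 40,
                                 total_intensity = 2e5, head_sigma = 6,
                                 width = 200, height = 80, background = 2,
                                 seed = NULL) {
  check_number(tail_fraction, "tail_fraction", lower = 0, upper = 1)
  check_number(tail_length, "tail_length", lower = 1)
  if (!is.null(seed)) set.seed(seed)
  x0 <- 40; y0 <- height / 2
  yy <- matrix(seq_len(height), height, width)
  xx <- matrix(seq_len(width), height, width, byrow = TRUE)

  head_img <- exp(-((yy - y0)^2 + (xx - x0)^2) / (2 * head_sigma^2))
  head_img <- head_img / sum(head_img) * total_intensity * (1 - tail_fraction)

  tail_img <- matrix(0, height, width)
  right <- xx >= x0
  tail_img[right] <- exp(-(xx[right] - x0) / tail_length) *
    exp(-(yy[right] - y0)^2 / (2 * (head_sigma * 0.8)^2))
  if (tail_fraction > 0) {
    tail_img <- tail_img / sum(tail_img) * total_intensity * tail_fraction
  } else {
    tail_img[] <- 0
  }
  clean <- head_img + tail_img
  tail_centroid <- if (tail_fraction > 0) {
    sum(xx * tail_img) / sum(tail_img) - x0
  } else 0
  image <- matrix(stats::rpois(length(clean), as.vector(clean) + background),
                  height, width)
  storage.mode(image) <- "integer"
  list(image = image,
       truth = list(head_intensity = sum(head_img),
                    tail_intensity = sum(tail_img),
                    tail_fraction = tail_fraction,
                    tail_centroid_offset = tail_centroid,
                    tail_length = tail_length, head_x = x0))
}
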
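#' Burst-calling configuration
#'
#' A bin is "positive" when its photon count reaches the threshold, expressed
#' in photons per ms and rescaled by the bin width. The default rule applies
#' the threshold to the green+red channel sum, so events detected in either
#' color are admitted; `either_channel` thresholds each channel separately
#' (a bin is positive if either channel reaches threshold) and is offered for
#' sensitivity analysis. The comparison is inclusive (>=).
#'
#' @param threshold photons per ms (default 50).
#' @param threshold_rule `"sum_channels"` (default) or `"either_channel"`.
#' @param min_bins minimum run length in bins for a burst (default 1).
#' @return object of class `burst_config`.
#' @export
burst_config <- function(threshold = 50,
                         threshold_rule = c("sum_channels", "either_channel"),
                         min_bins = 1L) {
  check_number(threshold, "threshold", lower = .Machine$double.xmin)
  check_number(min_bins, "min_bins", lower = 1)
  structure(list(threshold = threshold,
                 threshold_rule = match.arg(threshold_rule),
                 min_bins = as.integer(min_bins)),
            class = "burst_config")
}

#' Detect fluorescence bursts in a two-channel trace
#'
#' Maximal runs of at least `min_bins` consecutive positive bins become
#' bursts; bursts are disjoint and ordered, and per-burst channel counts are
#' sums over the run. Adjacent bursts separated by a single sub-threshold
#' bin are not merged.
#'
#' @param trace a [trace_file()].
#' @param cfg a [burst_config()].
#' @return data.frame of class `burst_table` with columns `start_bin`,
#'   `end_bin` (1-based, inclusive), `green_counts`, `red_counts`,
#'   `brightness` (= green + red).
#' @export
detect_bursts <- function(trace, cfg = burst_config()) {
  stopifnot(inherits(trace, "trace_file"))
  if (!inherits(cfg, "burst_config")) stop_param("'cfg' must be a burst_config")
  thr <- cfg$threshold * trace$bin_width   # photons per bin
  positive <- if (cfg$threshold_rule == "sum_channels") {
    (trace$green + trace$red) >= thr
  } else {
    trace$green >= thr | trace$red >= thr
  }
  bursts_from_positive(trace, positive, cfg$min_bins)
}

bursts_from_positive <- function(trace, positive, min_bins) {
  empty <- data.frame(start_bin = integer(0), end_bin = integer(0),
                      green_counts = integer(0), red_counts = integer(0),
                      brightness = integer(0))
  class(empty) <- c("burst_table", "data.frame")
  if (!any(positive)) return(empty)
  r <- rle(positive)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_bins
  if (!any(keep)) return(empty)
  starts <- starts[keep]; ends <- ends[keep]
  # sum channel counts over each run via cumulative sums
  cg <- cumsum(c(0L, trace$green)); cr <- cumsum(c(0L, trace$red))
  g <- cg[ends + 1L] - cg[starts]
  rd <- cr[ends + 1L] - cr[starts]
  out <- data.frame(start_bin = starts, end_bin = ends,
                    green_counts = as.integer(g), red_counts = as.integer(rd),
                    brightness = as.integer(g + rd))
  class(out) <- c("burst_table", "data.frame")
  out
}

#' Summarize the burst-brightness distribution
#'
#' Burst brightness (total photons, green + red) reflects the number of
#' fluorophores in the transiting particle and is the basis for
#' stoichiometry calibration.
#'
#' @param bursts a `burst_table` from [detect_bursts()].
#' @param breaks histogram breaks passed to [graphics::hist()] semantics
#'   (default `"Sturges"`).
#' @return list of class `brightness_distribution` with `n`, `median`,
#'   `mean`, and `histogram` (`breaks`, `counts`, `mids`).
#' @export
brightness_distribution <- function(bursts, breaks = "Sturges") {
  if (nrow(bursts) == 0) stop_param("no events detected")
  b <- bursts$brightness
  h <- graphics::hist(b, breaks = breaks, plot = FALSE)
  structure(list(n = length(b), median = stats::median(b), mean = mean(b),
                 histogram = list(breaks = h$breaks, counts = h$counts,
                                  mids = h$mids)),
            class = "brightness_distribution")
}

#' Write / read a burst table as TSV
#'
#' @param bursts a `burst_table`.
#' @param path output path.
#' @return `path` (write) or a `burst_table` (read).
#' @export
write_bursts <- function(bursts, path) {
  utils::write.table(as.data.frame(bursts), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_bursts
#' @export
read_bursts <- function(path) {
  if (!file.exists(path)) stop_format("burst file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("start_bin", "end_bin", "green_counts", "red_counts", "brightness")
  absent <- setdiff(need, names(df))
  if (length(absent)) {
    stop_format("burst table missing column(s): ", paste(absent, collapse = ", "))
  }
  class(df) <- c("burst_table", "data.frame")
  df
}
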
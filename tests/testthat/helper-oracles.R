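# Independent oracles kept deliberately naive: they re-derive expected
# results by direct enumeration, not by calling the implementation paths
# they check.

# brute-force burst scan: walk the bins one by one
oracle_bursts <- function(green, red, threshold_per_bin,
                          rule = c("sum_channels", "either_channel"),
                          min_bins = 1L) {
  rule <- match.arg(rule)
  n <- length(green)
  positive <- logical(n)
  for (i in seq_len(n)) {
    positive[i] <- if (rule == "sum_channels") {
      green[i] + red[i] >= threshold_per_bin
    } else {
      green[i] >= threshold_per_bin || red[i] >= threshold_per_bin
    }
  }
  out <- NULL
  i <- 1
  while (i <= n) {
    if (positive[i]) {
      j <- i
      while (j < n && positive[j + 1]) j <- j + 1
      if (j - i + 1 >= min_bins) {
        out <- rbind(out, data.frame(
          start_bin = i, end_bin = j,
          green_counts = sum(green[i:j]), red_counts = sum(red[i:j]),
          brightness = sum(green[i:j]) + sum(red[i:j])))
      }
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  if (is.null(out)) {
    out <- data.frame(start_bin = integer(0), end_bin = integer(0),
                      green_counts = integer(0), red_counts = integer(0),
                      brightness = integer(0))
  }
  out
}

# exhaustive Kapur criterion over every candidate split of a histogram
oracle_max_entropy <- function(levels, counts) {
  p <- counts / sum(counts)
  best <- -Inf; best_level <- NA
  for (k in seq_len(length(levels) - 1)) {
    P1 <- sum(p[1:k]); P2 <- 1 - P1
    if (P1 <= 0 || P2 <= 0) next
    p1 <- p[1:k][p[1:k] > 0] / P1
    p2 <- p[(k + 1):length(p)][p[(k + 1):length(p)] > 0] / P2
    H <- -sum(p1 * log(p1)) - sum(p2 * log(p2))
    if (H > best) { best <- H; best_level <- levels[k] }
  }
  best_level
}

# rejection-sample a 3-component Gaussian mixture truncated to [0,1]
sample_c_mixture <- function(n, weights, means, sds) {
  comp <- sample.int(3, n, replace = TRUE, prob = weights)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- rnorm(1, means[comp[i]], sds[comp[i]])
      if (x >= 0 && x <= 1) { out[i] <- x; break }
    }
  }
  out
}

# tiny in-memory trace
make_trace <- function(green, red = rep(0L, length(green)), bin_width = 1) {
  trace_file(green, red, bin_width = bin_width)
}
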
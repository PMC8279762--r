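test_that("burst detection matches direct per-bin scanning on small cases", {
  tr <- make_trace(c(10L, 60L, 70L, 20L))
  b <- detect_bursts(tr, burst_config(threshold = 50))
  expect_equal(nrow(b), 1)
  expect_equal(b$start_bin, 2)
  expect_equal(b$end_bin, 3)
  expect_equal(b$brightness, 130)

  expect_equal(nrow(detect_bursts(make_trace(rep(0L, 100)))), 0)

  # threshold is inclusive: a single bin summing exactly to 50 is a burst
  one <- detect_bursts(make_trace(c(0L, 30L, 20L, 0L), c(0L, 20L, 10L, 0L)),
                       burst_config(threshold = 50))
  expect_equal(nrow(one), 1)
  expect_equal(one$start_bin, 2)
  expect_equal(one$end_bin, 2)      # the 30-photon bin after it stays out
  expect_equal(one$brightness, 50)

  # threshold is per ms and rescales with the bin width
  tr2 <- make_trace(c(40L, 60L), bin_width = 2)   # 2 ms bins: need >= 100
  expect_equal(nrow(detect_bursts(tr2, burst_config(threshold = 50))), 0)
  tr3 <- make_trace(c(40L, 120L), bin_width = 2)
  expect_equal(detect_bursts(tr3, burst_config(threshold = 50))$start_bin, 2)
})

test_that("burst caller equals the brute-force oracle on random traces", {
  set.seed(101)
  for (i in 1:1000) {
    n <- sample(5:60, 1)
    green <- as.integer(rpois(n, sample(c(2, 20, 40), 1)))
    red <- as.integer(rpois(n, sample(c(2, 20, 40), 1)))
    thr <- sample(c(20, 50, 80), 1)
    rule <- sample(c("sum_channels", "either_channel"), 1)
    min_bins <- sample(1:2, 1)
    got <- detect_bursts(trace_file(green, red),
                         burst_config(thr, rule, min_bins))
    want <- oracle_bursts(green, red, thr, rule, min_bins)
    expect_equal(as.data.frame(got), want, ignore_attr = TRUE)
  }
})

test_that("bursts partition the positive bins and respect monotonicity", {
  set.seed(202)
  for (i in 1:50) {
    green <- as.integer(rpois(200, 30))
    red <- as.integer(rpois(200, 30))
    tr <- trace_file(green, red)
    b <- detect_bursts(tr, burst_config(threshold = 60))
    covered <- unlist(Map(seq, b$start_bin, b$end_bin))
    positive <- which(green + red >= 60)
    expect_identical(sort(covered), positive)      # exactly the positive bins
    if (nrow(b) > 1) {
      expect_true(all(b$start_bin[-1] > b$end_bin[-nrow(b)] + 1))  # disjoint
    }
    n_pos_hi <- sum(green + red >= 80)
    expect_lte(n_pos_hi, length(positive))          # monotone in threshold
  }
})

test_that("brightness summaries track the generator brightness linearly", {
  b <- data.frame(start_bin = 1:3, end_bin = 1:3,
                  green_counts = c(100L, 100L, 100L),
                  red_counts = c(0L, 0L, 0L), brightness = c(100L, 100L, 100L))
  class(b) <- c("burst_table", "data.frame")
  expect_equal(brightness_distribution(b)$median, 100)
  empty <- b[0, ]
  expect_error(brightness_distribution(empty), "no events",
               class = "smc_param_error")

  sim1 <- simulate_trace(species_model("gfp", 1, 0, 10),
                         acquisition_model(duration = 40, seed = 21))
  sim2 <- simulate_trace(species_model("gfp", 1, 0, 10),
                         acquisition_model(duration = 40,
                                           brightness_green = 500, seed = 22))
  m1 <- brightness_distribution(detect_bursts(sim1$trace))$median
  m2 <- brightness_distribution(detect_bursts(sim2$trace))$median
  # doubling the per-fluorophore brightness roughly doubles the burst
  # median; threshold truncation makes the ratio slightly exceed 2
  expect_gt(m2 / m1, 1.8)
  expect_lt(m2 / m1, 2.5)
  # unimodal monomer distribution: median close to mean
  expect_lt(abs(m1 - brightness_distribution(detect_bursts(sim1$trace))$mean) /
              m1, 0.25)
})
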
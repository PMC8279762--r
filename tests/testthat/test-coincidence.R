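test_that("leakage correction follows the 6% subtraction rule", {
  expect_equal(correct_leakage(100, 20, 0.06), 14)
  expect_equal(correct_leakage(100, 3, 0.06), 0)     # clipped at zero
  expect_equal(correct_leakage(0, 10, 0.06), 10)
  expect_equal(correct_leakage(c(100, 0), c(20, 10), 0.06), c(14, 10))
  expect_error(correct_leakage(-1, 5), class = "smc_param_error")

  # exactness in expectation: pure-GFP bursts corrected at the true
  # crosstalk have mean residual red ~ 0
  set.seed(31)
  g_emit <- rpois(4000, 400)
  reroute <- rbinom(4000, g_emit, 0.06)
  resid <- correct_leakage(g_emit - reroute, reroute, 0.06 / 0.94)
  expect_lt(mean(resid), 2.5)  # clipping leaves a small positive remnant
})

test_that("coincidence ratio and window classification behave at boundaries", {
  expect_equal(coincidence_ratio(50, 50), 0.5)
  expect_equal(coincidence_ratio(10, 0), 0)
  expect_equal(coincidence_ratio(0, 10), 1)
  expect_error(coincidence_ratio(0, 0), class = "smc_param_error")

  cfg <- coincidence_config()
  expect_equal(as.character(classify_coincidence(0.5, cfg)), "coincident")
  expect_equal(as.character(classify_coincidence(0.10, cfg)), "gfp_only")
  expect_equal(as.character(classify_coincidence(0.25, cfg)), "coincident")
  expect_equal(as.character(classify_coincidence(0.75, cfg)), "coincident")
  expect_equal(as.character(classify_coincidence(0.76, cfg)), "mcherry_only")
})

test_that("the C histogram is normalized and flags under-sampling", {
  h <- build_histogram(c(0.1, 0.1, 0.9, 0.9),
                       coincidence_config(n_hist_bins = 2))
  expect_equal(h$frequencies, c(0.5, 0.5))

  set.seed(41)
  for (i in 1:20) {
    C <- runif(sample(5:500, 1))
    h <- build_histogram(C)
    expect_equal(sum(h$frequencies), 1)
    expect_equal(sum(h$counts), h$n_events)
  }
  expect_true(build_histogram(runif(999))$under_sampled)
  expect_false(build_histogram(runif(1000))$under_sampled)
})

test_that("the three-Gaussian fit recovers known mixtures", {
  # single tight cluster at 0.5: essentially all weight in the middle
  set.seed(51)
  C <- pmin(pmax(rnorm(3000, 0.5, 0.03), 0), 1)
  f <- fit_three_gaussians(build_histogram(C))
  expect_gt(f$weights[2], 0.95)

  # generating parameters as oracle
  C <- sample_c_mixture(5000, c(0.3, 0.4, 0.3), c(0.05, 0.5, 0.95),
                        c(0.05, 0.05, 0.05))
  f <- fit_three_gaussians(build_histogram(C))
  expect_true(f$converged)
  expect_lt(max(abs(f$weights - c(0.3, 0.4, 0.3))), 0.05)
  expect_lt(max(abs(f$means - c(0.05, 0.5, 0.95))), 0.03)
  expect_true(all(diff(f$means) > 0))
  expect_equal(sum(f$weights), 1, tolerance = 1e-6)

  # fixed point: refitting the fitted model's own expected histogram
  # reproduces the parameters
  edges <- seq(0, 1, length.out = 51)
  y <- 0
  for (k in 1:3) {
    y <- y + f$weights[k] * diff(pnorm((edges - f$means[k]) / f$sds[k]))
  }
  h2 <- structure(list(edges = edges,
                       mids = (edges[-1] + edges[-51]) / 2,
                       frequencies = y / sum(y), counts = round(5000 * y),
                       n_events = 5000, under_sampled = FALSE),
                  class = "c_histogram")
  f2 <- fit_three_gaussians(h2)
  expect_lt(max(abs(f2$weights - f$weights)), 0.02)
  expect_lt(max(abs(f2$means - f$means)), 0.02)

  # degenerate histogram: all mass in one bin
  hd <- build_histogram(rep(0.5, 50))
  fd <- fit_three_gaussians(hd)
  expect_true(fd$degenerate)
})

test_that("the full pipeline recovers the associated fraction", {
  sim <- simulate_mixture(0.6, 2000, acquisition_model(seed = 1))
  res <- coincidence_pipeline(sim$trace)
  expect_equal(res$f_assoc_window, 0.6, tolerance = 0.05 / 0.6)
  expect_equal(sum(res$class_counts), res$n_events)
  expect_gte(res$n_events, 1000)

  # no association: residual coincidence is small with leakage correction on
  sim0 <- simulate_mixture(0, 2000, acquisition_model(seed = 2))
  res0 <- coincidence_pipeline(sim0$trace)
  expect_lt(res0$f_assoc_window, 0.05)

  # turning leakage correction off inflates apparent coincidence: at the
  # default 6% crosstalk the shift shows in the C values of GFP-side bursts
  # (too small to cross the 0.25 window), and in the window count once the
  # crosstalk is large enough to reach the window
  res0_raw <- coincidence_pipeline(sim0$trace,
                                   cfg = coincidence_config(leakage = 0))
  expect_gte(res0_raw$f_assoc_window, res0$f_assoc_window)
  gfp_raw <- res0_raw$bursts$C[res0_raw$bursts$C < 0.25]
  gfp_cor <- res0$bursts$C[res0$bursts$C < 0.25]
  expect_gt(mean(gfp_raw), mean(gfp_cor))
  simx <- simulate_mixture(0, 1000,
                           acquisition_model(crosstalk = 0.25, seed = 9))
  resx_cor <- coincidence_pipeline(simx$trace,
                                   cfg = coincidence_config(leakage = 0.25))
  resx_raw <- coincidence_pipeline(simx$trace,
                                   cfg = coincidence_config(leakage = 0))
  expect_gt(resx_raw$f_assoc_window, resx_cor$f_assoc_window)

  # the two estimators agree on well-separated data
  expect_lt(abs(res$f_assoc_window - res$f_assoc_mixture), 0.05)

  expect_error(coincidence_pipeline(make_trace(rep(0L, 100))),
               "no events", class = "smc_param_error")
})

test_that("associated-fraction recovery holds across the truth grid", {
  for (f_true in seq(0.1, 0.9, by = 0.2)) {
    sim <- simulate_mixture(f_true, 2000,
                            acquisition_model(seed = round(100 * f_true)))
    res <- coincidence_pipeline(sim$trace)
    n_gfp <- res$class_counts[["gfp_only"]] + res$class_counts[["coincident"]]
    tol <- 3 * sqrt(f_true * (1 - f_true) / n_gfp) + 0.03
    expect_lt(abs(res$f_assoc_window - f_true), tol,
              label = sprintf("recovery at f_true = %.1f (got %.3f)", f_true,
                              res$f_assoc_window))
  }
})
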
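test_that("background-free, event-free acquisitions give an all-zero trace", {
  acq <- acquisition_model(duration = 1, background_green = 0,
                           background_red = 0, seed = 1)
  sim <- simulate_trace(species_model("idle", 1, 0, 0), acq)
  expect_equal(sum(sim$trace$green) + sum(sim$trace$red), 0)
  expect_equal(nrow(sim$truth$events), 0)
})

test_that("simulation is bit-identical under a fixed seed", {
  a <- simulate_trace(species_model("gfp", 1, 0, 10),
                      acquisition_model(duration = 5, seed = 7))
  b <- simulate_trace(species_model("gfp", 1, 0, 10),
                      acquisition_model(duration = 5, seed = 7))
  expect_identical(a$trace, b$trace)
  expect_identical(a$truth$events, b$truth$events)

  m1 <- simulate_mixture(0.4, 200, acquisition_model(duration = 20, seed = 3))
  m2 <- simulate_mixture(0.4, 200, acquisition_model(duration = 20, seed = 3))
  expect_identical(m1$trace, m2$trace)

  p1 <- simulate_puncta_image(2, 6, seed = 5)
  p2 <- simulate_puncta_image(2, 6, seed = 5)
  expect_identical(p1$image, p2$image)

  t1 <- simulate_proteome(50, seed = 11)
  t2 <- simulate_proteome(50, seed = 11)
  expect_identical(intensity_matrix(t1$table), intensity_matrix(t2$table))
})

test_that("spectral crosstalk reroutes the expected share of GFP photons", {
  acq <- acquisition_model(duration = 50, crosstalk = 0.06,
                           background_green = 0, background_red = 0, seed = 2)
  sim <- simulate_trace(species_model("gfp", 1, 0, 100), acq)
  share <- sum(sim$trace$red) / (sum(sim$trace$green) + sum(sim$trace$red))
  # Bernoulli rerouting: share is binomial around the crosstalk parameter
  n_photons <- sum(sim$trace$green) + sum(sim$trace$red)
  se <- sqrt(0.06 * 0.94 / n_photons)
  expect_lt(abs(share - 0.06), 4 * se + 1e-6)
})

test_that("mixture composition follows the association fraction", {
  acq <- acquisition_model(duration = 30, seed = 4)
  all_assoc <- simulate_mixture(1, 300, acq)
  expect_true(all(all_assoc$truth$events$species == "complex"))

  none <- simulate_mixture(0, 300, acquisition_model(duration = 30, seed = 5))
  expect_false(any(none$truth$events$species == "complex"))
  # unbound partners of both colors are present in equal number
  expect_equal(sum(none$truth$events$species == "gfp_only"),
               sum(none$truth$events$species == "mcherry_only"))

  # complex count is Binomial(n_events, f_assoc); check within 4 sigma
  m <- simulate_mixture(0.6, 2000, acquisition_model(duration = 180, seed = 6))
  n_complex <- m$truth$class_counts[["complex"]]
  expect_lt(abs(n_complex - 2000 * 0.6), 4 * sqrt(2000 * 0.6 * 0.4))
})

test_that("photon counts are conserved in expectation", {
  acq <- acquisition_model(duration = 30, background_green = 1,
                           background_red = 1, crosstalk = 0.06, seed = 8)
  sim <- simulate_trace(species_model("dimer", 2, 1, 10), acq)
  n_bins <- sim$trace$n_bins
  expected <- sum(sim$truth$events$expected_green) +
    sum(sim$truth$events$expected_red) + 2 * n_bins
  total <- sum(sim$trace$green) + sum(sim$trace$red)
  expect_lt(abs(total - expected), 4 * sqrt(expected))
})

test_that("generated artifacts parse back through the readers", {
  dir <- withr::local_tempdir()
  sim <- simulate_mixture(0.5, 100, acquisition_model(duration = 10, seed = 1))
  write_trace(sim$trace, file.path(dir, "t.tsv"))
  expect_identical(read_trace(file.path(dir, "t.tsv"))$green, sim$trace$green)

  prot <- simulate_proteome(40, n_flagged = 3, n_low_peptide = 2, seed = 2)
  write_protein_groups(prot$table, file.path(dir, "pg.txt"))
  back <- read_protein_groups(file.path(dir, "pg.txt"),
                              attr(prot$table, "samples"))
  expect_equal(intensity_matrix(back), intensity_matrix(prot$table),
               tolerance = 1e-6)

  img <- simulate_puncta_image(1, 5, seed = 3)
  write_image(img$image, file.path(dir, "img.tif"))
  expect_identical(read_image(file.path(dir, "img.tif")), img$image)
})

test_that("comet and proteome generators honor their ground-truth contracts", {
  cm <- simulate_comet_image(0, seed = 10)
  expect_equal(cm$truth$tail_intensity, 0)
  expect_gt(cm$truth$head_intensity, 0)

  cm3 <- simulate_comet_image(0.3, seed = 11)
  expect_equal(cm3$truth$tail_intensity /
                 (cm3$truth$head_intensity + cm3$truth$tail_intensity), 0.3,
               tolerance = 1e-9)

  prot <- simulate_proteome(30, effects = numeric(0), seed = 12)
  expect_true(all(prot$truth$effects$true_log2fc == 0))

  expect_error(simulate_mixture(1.2, 10), class = "smc_param_error")
  expect_error(simulate_comet_image(-0.1), class = "smc_param_error")
  expect_error(acquisition_model(crosstalk = 1), class = "smc_param_error")
  expect_error(acquisition_model(bin_width = 0), class = "smc_param_error")
})
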
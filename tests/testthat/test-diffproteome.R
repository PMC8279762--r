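groups33 <- list(WT = paste0("WT_", 1:3), KO = paste0("KO_", 1:3))

make_table <- function(intens, peptides = NULL, flags = NULL) {
  n <- nrow(intens)
  colnames(intens) <- unlist(groups33)
  protein_groups(
    ids = sprintf("P%d", seq_len(n)), gene_names = sprintf("G%d", seq_len(n)),
    unique_peptides = peptides %||% rep(5L, n),
    flags = flags %||% data.frame(only_identified_by_site = rep(FALSE, n),
                                  reverse = rep(FALSE, n),
                                  potential_contaminant = rep(FALSE, n)),
    intensities = intens)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("filtering drops flagged, low-evidence and sparse rows", {
  intens <- matrix(2^rnorm(5 * 6, 25), 5, 6)
  intens[2, 4:6] <- c(100, NA, NA)       # only 1 of 3 valid in KO
  flags <- data.frame(only_identified_by_site = c(FALSE, FALSE, TRUE, FALSE, FALSE),
                      reverse = c(FALSE, FALSE, FALSE, TRUE, FALSE),
                      potential_contaminant = rep(FALSE, 5))
  peptides <- c(5L, 5L, 5L, 5L, 1L)
  tab <- make_table(intens, peptides, flags)
  kept <- filter_table(tab, groups33)
  expect_equal(kept$ids, "P1")           # 2 sparse, 3+4 flagged, 5 low-peptide

  # boundary inclusion: exactly 2 peptides and 2 valid per group retained
  intens2 <- matrix(2^rnorm(6), 1, 6)
  intens2[1, c(3, 6)] <- NA
  tab2 <- make_table(intens2, peptides = 2L)
  expect_equal(nrow(filter_table(tab2, groups33)), 1)

  # idempotence
  once <- filter_table(tab, groups33)
  twice <- filter_table(once, groups33)
  expect_equal(as.data.frame(once), as.data.frame(twice))

  expect_error(filter_table(tab, list(WT = "WT_1", KO = groups33$KO)),
               class = "smc_param_error")
})

test_that("log2 transform and z-scores preserve missingness", {
  m <- matrix(c(8, 2, NA, 16), 2, 2)
  lt <- log2_transform(m)
  expect_equal(lt[1, 1], 3)
  expect_true(is.na(lt[1, 2]))

  m_bad <- m; m_bad[2, 1] <- -1
  expect_error(log2_transform(m_bad), "row 2", class = "smc_param_error")

  set.seed(47)
  x <- matrix(rnorm(60, 25), 6, 10)
  x[1, 3] <- NA
  x[4, ] <- 7                             # constant row
  z <- zscore(x)
  for (i in c(1:3, 5:6)) {
    expect_equal(mean(z[i, ], na.rm = TRUE), 0, tolerance = 1e-12)
    expect_equal(sd(z[i, ], na.rm = TRUE), 1, tolerance = 1e-12)
  }
  expect_true(all(z[4, ] == 0))
  expect_true(attr(z, "degenerate")[4])
  expect_true(is.na(z[1, 3]))
})

test_that("the d statistic matches hand evaluation and limits", {
  expect_equal(d_statistic(c(1, 2, 3), c(1, 2, 3), s0 = 1), 0)
  # zero pooled variance: d = diff / s0
  expect_equal(d_statistic(c(0, 0, 0), c(1, 1, 1), s0 = 1), 1)
  expect_error(d_statistic(c(0, 0), c(1, 1), s0 = 0),
               class = "smc_param_error")
  # s0 -> large drives d to zero
  expect_lt(abs(d_statistic(c(0, 1, 0), c(5, 6, 7), s0 = 1e6)), 1e-4)
  expect_error(d_statistic(c(1), c(1, 2)), class = "smc_param_error")
})

test_that("pooled t-test p-values agree with stats::t.test", {
  set.seed(57)
  x <- matrix(rnorm(10 * 6, 25), 10, 6)
  colnames(x) <- unlist(groups33)
  st <- smctools:::row_stats(x, 1:3, 4:6, s0 = 0)
  for (i in 1:10) {
    ref <- t.test(x[i, 4:6], x[i, 1:3], var.equal = TRUE)
    expect_equal(st$p[i], ref$p.value, tolerance = 1e-12)
    expect_equal(st$log2fc[i], unname(ref$estimate[1] - ref$estimate[2]),
                 tolerance = 1e-12)
  }
})

test_that("observed d is invariant to sample order within groups", {
  sim <- simulate_proteome(50, effects = c(2, -1), seed = 67)
  x <- log2_transform(intensity_matrix(filter_table(sim$table,
                                                    sim$truth$groups)))
  d1 <- smctools:::row_stats(x, 1:3, 4:6, 1)$d
  d2 <- smctools:::row_stats(x, c(3, 1, 2), c(5, 6, 4), 1)$d
  expect_equal(d1, d2)
})

test_that("permutation FDR recovers spiked effects and controls the null", {
  # strong spike, low noise: nearly all spiked proteins are called
  sim <- simulate_proteome(1000, effects = rep(c(2, -2), 25),
                           residual_sd = 0.3, missing_rate = 0, seed = 77)
  res <- diff_proteome(sim$table, sim$truth$groups)
  spiked <- sim$truth$effects$ids[sim$truth$effects$true_log2fc != 0]
  called <- res$proteins$ids[res$proteins$significant]
  expect_gte(sum(spiked %in% called) / length(spiked), 0.9)
  # false positives among the null background stay rare
  expect_lte(sum(!(called %in% spiked)), 0.02 * 950)

  # global null: false-positive proportion stays near the target FDR
  fpp <- sapply(1:5, function(s) {
    simn <- simulate_proteome(400, seed = 200 + s)
    resn <- diff_proteome(simn$table, simn$truth$groups)
    mean(resn$proteins$significant)
  })
  expect_lte(mean(fpp), 0.07)

  expect_equal(res$n_permutations, 18)   # 3v3: 20 relabelings minus 2 trivial
})

test_that("effect estimates are accurate and the pipeline never imputes", {
  sim <- simulate_proteome(500, effects = rep(c(1.5, -1.5), 50),
                           residual_sd = 0.3, seed = 87)
  res <- diff_proteome(sim$table, sim$truth$groups)
  merged <- merge(res$proteins, sim$truth$effects, by = "ids")
  err <- abs(merged$log2fc - merged$true_log2fc)
  expect_lte(median(err), 0.2)

  # missing cells stay missing: group means use observed values only
  x <- intensity_matrix(filter_table(sim$table, sim$truth$groups))
  i <- which(rowSums(is.na(x)) == 1)[1]
  row <- log2_transform(x[i, ])
  prot <- res$proteins[res$proteins$ids ==
                         filter_table(sim$table, sim$truth$groups)$ids[i], ]
  expect_equal(prot$mean_WT, mean(row[1:3], na.rm = TRUE))
  expect_equal(prot$mean_KO, mean(row[4:6], na.rm = TRUE))
})

test_that("the volcano table mirrors the differential result", {
  sim <- simulate_proteome(200, effects = c(-1), residual_sd = 0.1,
                           missing_rate = 0, seed = 97)
  res <- diff_proteome(sim$table, sim$truth$groups)
  v <- volcano_table(res)
  expect_equal(v$neg_log10_p, -log10(res$proteins$p))
  expect_equal(v$neg_log10_p[res$proteins$p == 0.01],
               rep(2, sum(res$proteins$p == 0.01)))
  # the spiked 2-fold-down protein lands near log2FC -1
  expect_equal(v$log2fc[v$ids == "P00001"], -1, tolerance = 0.35)
})
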
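test_that("Wilcoxon screen matches hand-derived and enumerated p-values", {
  pm <- tibble::tibble(
    patient_id = sprintf("S%d", 1:6),
    pep_0001 = c(1, 2, 3, 4, 5, 6),   # extreme separation, exact p = 0.1
    pep_0002 = c(10, 10, 12, 5, 5, 7) # arbitrary
  )
  labels <- tibble::tibble(patient_id = pm$patient_id,
                           label = rep(c("UNCONTROLLED", "CONTROLLED"), each = 3))
  out <- wilcoxon_screen(pm, labels)
  expect_equal(out$p_value[out$peptide_id == "pep_0001"], 0.1)
  expect_equal(out$p_value[out$peptide_id == "pep_0001"],
               bf_wilcox_p(1:3, 4:6))
  expect_equal(out$direction[out$peptide_id == "pep_0001"], "DOWN")
  expect_equal(out$fold_change[out$peptide_id == "pep_0001"], 2 / 5)
})

test_that("fold change and direction follow the group means", {
  pm <- tibble::tibble(patient_id = sprintf("S%d", 1:4),
                       pep_0001 = c(10, 10, 5, 5),
                       pep_0002 = c(3, 3, 3, 3))
  labels <- tibble::tibble(patient_id = pm$patient_id,
                           label = rep(c("UNCONTROLLED", "CONTROLLED"), each = 2))
  out <- wilcoxon_screen(pm, labels)
  expect_equal(out$fold_change, c(2, 1))
  expect_equal(out$direction, c("UP", NA))
  # identical vectors: no signal
  expect_gte(out$p_value[2], 0.99)
})

test_that("a zero controlled mean flags the peptide instead of dropping it", {
  pm <- tibble::tibble(patient_id = sprintf("S%d", 1:8),
                       pep_0001 = c(5, 6, 7, 8, 0, 0, 0, 0))
  labels <- tibble::tibble(patient_id = pm$patient_id,
                           label = rep(c("UNCONTROLLED", "CONTROLLED"), each = 4))
  out <- wilcoxon_screen(pm, labels)
  expect_true(out$flagged)
  expect_true(is.na(out$fold_change))
  expect_equal(out$direction, "UP") # from the rank statistic
  expect_equal(out$freq_controlled, 0)
})

test_that("exact rank-sum p equals brute-force enumeration for random small groups", {
  set.seed(101)
  for (k in 1:20) {
    n1 <- sample(3:5, 1); n2 <- sample(3:5, 1)
    x <- round(rnorm(n1, 10, 3), 2); y <- round(rnorm(n2, 11, 3), 2)
    # distinct values ensure the exact branch of wilcox.test
    if (anyDuplicated(c(x, y))) next
    pm <- tibble::tibble(patient_id = sprintf("S%d", seq_len(n1 + n2)),
                         pep_0001 = c(x, y))
    labels <- tibble::tibble(
      patient_id = pm$patient_id,
      label = rep(c("UNCONTROLLED", "CONTROLLED"), c(n1, n2)))
    out <- wilcoxon_screen(pm, labels)
    expect_equal(out$p_value, bf_wilcox_p(x, y), tolerance = 1e-12)
  }
})

test_that("Spearman slope correlation handles monotone, tied and constant input", {
  pm <- tibble::tibble(patient_id = sprintf("S%d", 1:5),
                       pep_0001 = c(-12, -8, -3, 0, 4),
                       pep_0002 = c(12, 8, 3, 0, -4),
                       pep_0003 = c(1, 2.5, 2.5, 4, 5),
                       pep_0004 = rep(7, 5))
  slopes <- tibble::tibble(patient_id = pm$patient_id,
                           pct_slope = c(-12, -8, -3, 0, 4))
  out <- spearman_slope_correlation(pm, slopes)
  expect_equal(out$rho[1], 1)
  expect_equal(out$rho[2], -1)
  # hand-computed with average ranks: ranks x = (1, 2.5, 2.5, 4, 5) vs
  # slope ranks (1..5); rho = 9.5 / sqrt(9.5 * 10)
  expect_equal(out$rho[3], 9.5 / sqrt(95), tolerance = 1e-12)
  expect_true(is.na(out$rho[4]))
  expect_error(spearman_slope_correlation(pm[1:2, ], slopes[1:2, ]), ">= 3")
})

test_that("between-method regression r2 behaves analytically", {
  set.seed(7)
  n <- 200
  rho_a <- rnorm(n, 0, 0.3)
  corr_a <- tibble::tibble(peptide_id = sprintf("p%03d", 1:n), rho = rho_a,
                           rho_p = 0.01)
  # identical lists: r2 = 1
  out <- method_agreement_regression(corr_a, corr_a)
  expect_equal(out$r_squared, 1)
  expect_equal(out$n_peptides, n)
  # attenuated copy with known noise: population r2 = 0.64*var_a / total
  rho_b <- 0.8 * rho_a + rnorm(n, 0, 0.1)
  corr_b <- dplyr::mutate(corr_a, rho = rho_b)
  out <- method_agreement_regression(corr_a, corr_b)
  r2_pop <- (0.64 * 0.09) / (0.64 * 0.09 + 0.01)
  expect_lt(abs(out$r_squared - r2_pop), 0.06)
  # permuted copy on null data: r2 near zero
  corr_p <- dplyr::mutate(corr_a, rho = sample(rho_a))
  out <- method_agreement_regression(corr_a, corr_p)
  expect_lt(out$r_squared, 0.1)
  expect_error(method_agreement_regression(corr_a[1:2, ], corr_b[1:2, ]),
               "fewer than 3")
})

test_that("per-method screen applies each method's own groups and filter", {
  co <- simulate_cohort(sim_config(n_patients = 40, n_peptides = 30,
                                   n_differential = 5, seed = 21))
  ve <- add_egfr(co$visits)
  lab <- label_patients(ve)
  out <- screen_all_methods(co$peptides, lab)
  expect_setequal(unique(out$method), egfr_methods())
  expect_true(all(c("p_value", "fold_change", "direction", "rho", "rho_p")
                  %in% names(out)))
  # every reported peptide passes the frequency filter for its method
  m1 <- dplyr::filter(out, method == "CKD_EPI_CR")
  kept <- frequency_filter(co$peptides,
                           dplyr::filter(lab, method == "CKD_EPI_CR"))
  expect_setequal(m1$peptide_id, kept)
})
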
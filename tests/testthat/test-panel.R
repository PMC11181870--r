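stats_row <- function(pep, method, p, dir) {
  tibble::tibble(peptide_id = pep, method = method, p_value = p,
                 direction = dir)
}

test_that("concordance selection needs >= 3 significant methods sharing a direction", {
  st <- dplyr::bind_rows(
    stats_row("pepA", c("M1", "M2", "M3"), 0.01, "DOWN"),
    stats_row("pepA", "M4", 0.2, "UP"),
    stats_row("pepB", c("M1", "M2"), 0.01, "UP"),
    stats_row("pepC", c("M1", "M2"), 0.01, "DOWN"),
    stats_row("pepC", "M3", 0.01, "UP")
  )
  expect_equal(select_concordant_panel(st), "pepA")
  # direction consistency can be switched off
  expect_setequal(select_concordant_panel(st,
                                          require_consistent_direction = FALSE),
                  c("pepA", "pepC"))
  # empty selection is a valid result
  expect_identical(select_concordant_panel(st, p_threshold = 0.001),
                   character())
})

test_that("selection is monotone in p_threshold and min_methods", {
  set.seed(33)
  peps <- sprintf("pep%03d", 1:60)
  st <- purrr::map_dfr(c("M1", "M2", "M3", "M4"), function(m) {
    stats_row(peps, m, runif(60)^2, sample(c("UP", "DOWN"), 60, TRUE,
                                           prob = c(0.3, 0.7)))
  })
  prev <- character()
  for (p_thr in c(0.01, 0.05, 0.2, 0.5)) {
    cur <- select_concordant_panel(st, p_threshold = p_thr)
    expect_true(all(prev %in% cur))
    prev <- cur
  }
  prev <- select_concordant_panel(st, min_methods = 4)
  for (mm in 3:1) {
    cur <- select_concordant_panel(st, min_methods = mm)
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("consistency filter keeps only direction-stable peptides seen everywhere", {
  d <- dplyr::bind_rows(
    tibble::tibble(peptide_id = "pepA", cohort = c("c1", "c2", "c3"),
                   direction = "DOWN"),
    tibble::tibble(peptide_id = "pepB", cohort = c("c1", "c2", "c3"),
                   direction = c("DOWN", "DOWN", "UP")),
    tibble::tibble(peptide_id = "pepC", cohort = c("c1", "c2"),
                   direction = "UP")
  )
  expect_equal(consistency_filter(c("pepA", "pepB", "pepC"), d), "pepA")
  # ground-truth containment on a synthetic multi-cohort screen with a
  # shared peptide biology across the three cohorts
  mk <- function(s) sim_config(n_patients = 60, n_peptides = 80,
                               n_differential = 15, effect_size = 1.5,
                               seed = 100 + s)
  truth <- simulate_cohort(mk(1))$truth$peptides
  runs <- purrr::map_dfr(1:3, function(s) {
    co <- simulate_cohort(mk(s), peptide_truth = truth)
    lab <- label_patients(add_egfr(co$visits, "EKFC_CYS"), "EKFC_CYS")
    dplyr::mutate(wilcoxon_screen(co$peptides, lab), cohort = paste0("c", s))
  })
  planted <- truth$peptide_id[truth$differential]
  kept <- consistency_filter(planted, runs)
  expect_true(all(kept %in% planted))
  expect_gt(length(kept), length(planted) / 2)
})

test_that("the SVM separates linearly separated clusters perfectly", {
  d <- make_two_group_peptides(n_per_group = 15, n_pep = 5, shift = 4)
  model <- train_svm_panel(d$peptides, d$labels, sprintf("pep_%04d", 1:5))
  sc <- predict(model, d$peptides)
  r <- roc_auc(sc$score, d$labels$label)
  expect_equal(r$auc, 1.0)
  pred <- predict(model, d$peptides, type = "label")
  expect_equal(pred$label, d$labels$label)
})

test_that("training validates labels, panel and class sizes", {
  d <- make_two_group_peptides(8, 4)
  expect_error(train_svm_panel(d$peptides, d$labels, character()), "empty")
  expect_error(train_svm_panel(d$peptides, d$labels, "nope"), "column")
  one <- dplyr::mutate(d$labels, label = "UNCONTROLLED")
  expect_error(train_svm_panel(d$peptides, one, "pep_0001"), "single class|non-empty")
  expect_error(train_svm_panel(d$peptides, d$labels, "pep_0001", C = -1), "> 0")
  few <- dplyr::slice(d$labels, c(1:3, 9:16))
  expect_error(train_svm_panel(d$peptides[c(1:3, 9:16), ], few, "pep_0001"),
               ">= 5")
})

test_that("fast leave-one-out equals the naive per-fold refit", {
  d <- make_two_group_peptides(n_per_group = 12, n_pep = 6, shift = 0.8,
                               seed = 5)
  panel <- sprintf("pep_%04d", 1:6)
  cv <- loo_auc(d$peptides, d$labels, panel)
  tr <- nephropep:::.prep_training(d$peptides, d$labels, sort(panel),
                                   "patient_id")
  st <- nephropep:::.panel_stats(tr$x)
  z <- nephropep:::.panel_transform(tr$x, st$center, st$scale)
  naive <- bf_loo_scores(z, tr$y, 256, 2e-5)
  expect_equal(cv$scores$score, naive, tolerance = 1e-7)
  expect_equal(cv$auc, bf_auc(naive, tr$y == "UNCONTROLLED"),
               tolerance = 1e-9)
})

test_that("tidy and glance summarize a fitted panel", {
  d <- make_two_group_peptides(10, 4, shift = 1)
  model <- train_svm_panel(d$peptides, d$labels, sprintf("pep_%04d", 1:4))
  td <- tidy(model)
  expect_equal(td$peptide_id, sprintf("pep_%04d", 1:4))
  expect_true(all(td$scale > 0))
  gl <- glance(model)
  expect_equal(gl$n_panel, 4)
  expect_equal(gl$C, 256)
  expect_equal(gl$n_train, 20)
})

test_that("take-one-out removes noise, never lowers LOO AUC, and counts evals", {
  d <- make_two_group_peptides(n_per_group = 12, n_pep = 8, shift = 1.2,
                               seed = 8)
  # dilute with pure-noise peptides
  set.seed(9)
  noise <- matrix(exp(rnorm(24 * 4, 10, 1)), 24, 4)
  colnames(noise) <- sprintf("noise_%02d", 1:4)
  pm <- dplyr::bind_cols(d$peptides, tibble::as_tibble(noise))
  panel <- c(sprintf("pep_%04d", 1:8), colnames(noise))
  base <- loo_auc(pm, d$labels, panel)
  opt <- take_one_out_optimize(pm, d$labels, panel)
  expect_gte(attr(opt, "loo_auc"), base$auc)
  tr <- attr(opt, "trace")
  # each candidate scan costs |current panel| LOO evaluations, plus the
  # initial evaluation and (when the search stops by itself) one final
  # unproductive scan
  p0 <- length(panel); R <- nrow(tr)
  scans_productive <- if (R) sum(p0 - seq_len(R) + 1) else 0
  expect_gte(attr(opt, "n_loo_evals"), 1L + scans_productive)
  expect_lte(attr(opt, "n_loo_evals"), 1L + scans_productive + (p0 - R))
  # the reported final AUC is reproducible from the returned panel
  again <- loo_auc(pm, d$labels, opt$panel)
  expect_equal(again$auc, attr(opt, "loo_auc"), tolerance = 1e-12)
})

test_that("an exact duplicate column is never protective and the search terminates", {
  d <- make_two_group_peptides(n_per_group = 10, n_pep = 5, shift = 2,
                               seed = 10)
  pm <- dplyr::mutate(d$peptides, pep_dup = .data$pep_0001)
  panel <- c(sprintf("pep_%04d", 1:5), "pep_dup")
  opt <- take_one_out_optimize(pm, d$labels, panel, max_rounds = 10)
  expect_s3_class(opt, "svm_panel")
  base <- loo_auc(pm, d$labels, panel)$auc
  expect_gte(attr(opt, "loo_auc"), base)
  expect_lte(nrow(attr(opt, "trace")), 10)
})
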
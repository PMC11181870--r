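test_that("AUC matches pair enumeration on fixed and random fixtures", {
  # hand case: pos {3, 2}, neg {1, 2} -> (1 + 1 + 1 + 0.5)/4
  r <- roc_auc(c(3, 2, 1, 2), c("UNCONTROLLED", "UNCONTROLLED",
                                "CONTROLLED", "CONTROLLED"))
  expect_equal(r$auc, 0.875)
  expect_equal(r$n_pos, 2); expect_equal(r$n_neg, 2)
  # all-tied scores
  r <- roc_auc(rep(1, 10), rep(c("UNCONTROLLED", "CONTROLLED"), 5))
  expect_equal(r$auc, 0.5)
  # perfect ordering
  r <- roc_auc(c(5, 4, 2, 1), c("UNCONTROLLED", "UNCONTROLLED",
                                "CONTROLLED", "CONTROLLED"))
  expect_equal(r$auc, 1.0)
  expect_equal(r$ci_low, r$auc) # degenerate DeLong variance
  set.seed(55)
  for (k in 1:25) {
    n <- sample(8:30, 1)
    sc <- round(rnorm(n), 1) # forces some ties
    lb <- sample(c("UNCONTROLLED", "CONTROLLED"), n, replace = TRUE)
    if (length(unique(lb)) < 2) next
    r <- roc_auc(sc, lb)
    expect_equal(r$auc, bf_auc(sc, lb == "UNCONTROLLED"), tolerance = 1e-12)
    expect_true(r$ci_low <= r$auc && r$auc <= r$ci_high)
  }
  expect_error(roc_auc(1:4, rep("CONTROLLED", 4)), "both classes")
})

test_that("DeLong CI and p agree with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(77)
  for (k in 1:10) {
    sc <- c(rnorm(30, 1), rnorm(35))
    lb <- rep(c("UNCONTROLLED", "CONTROLLED"), c(30, 35))
    mine <- roc_auc(sc, lb)
    ref <- suppressMessages(pROC::roc(response = lb, predictor = sc,
                                      levels = c("CONTROLLED", "UNCONTROLLED"),
                                      direction = "<"))
    ci <- suppressWarnings(as.numeric(pROC::ci.auc(ref, method = "delong")))
    expect_equal(mine$auc, as.numeric(ref$auc), tolerance = 1e-12)
    expect_equal(c(mine$ci_low, mine$ci_high), ci[c(1, 3)], tolerance = 1e-9)
  }
})

test_that("label overlap counts agree with hand tallies and are order-invariant", {
  lt <- tibble::tibble(
    patient_id = rep(sprintf("P%d", 1:4), 2),
    method = rep(c("A", "B"), each = 4),
    label = c("UNCONTROLLED", "UNCONTROLLED", "CONTROLLED", "CONTROLLED",
              "UNCONTROLLED", "CONTROLLED", "CONTROLLED", "CONTROLLED")
  )
  ov <- label_overlap(lt)
  expect_equal(ov$n_common, 4)
  expect_equal(ov$prop_identical, 3 / 4)
  # permuting methods and patients changes nothing
  lt2 <- lt[sample(nrow(lt)), ]
  lt2$method <- factor(lt2$method, levels = c("B", "A"))
  ov2 <- label_overlap(dplyr::mutate(lt2, method = as.character(method)))
  expect_equal(ov2$prop_identical, ov$prop_identical)
  expect_equal(ov2$n_identical, ov$n_identical)
  # pattern counts partition the shared patients
  expect_equal(sum(ov$pattern_counts$n), ov$n_common)
  # identical labels across all methods -> proportion 1
  all_same <- dplyr::mutate(lt, label = "CONTROLLED")
  expect_equal(label_overlap(all_same)$prop_identical, 1)
})

test_that("Venn cells and the informative denominator behave", {
  lt <- tibble::tibble(
    patient_id = rep(sprintf("P%d", 1:3), 2),
    method = rep(c("A", "B"), each = 3),
    label = c("UNCONTROLLED", "EXCLUDED", "CONTROLLED",
              "UNCONTROLLED", "EXCLUDED", "UNCONTROLLED")
  )
  ov <- label_overlap(lt)
  expect_equal(ov$n_informative, 2) # P1 and P3 never excluded
  expect_equal(ov$prop_identical_informative, 1 / 2) # only P1 agrees
  v <- ov$venn
  expect_equal(v$n[v$label == "UNCONTROLLED" & v$methods == "A+B"], 1)
  expect_equal(v$n[v$label == "UNCONTROLLED" & v$methods == "B"], 1)
  # per-label venn cells partition the assignments of that label
  u_total <- sum(v$n[v$label == "UNCONTROLLED"])
  expect_equal(u_total, 2) # P1 (both) and P3 (B only)
})

test_that("paired Pearson correlation handles trivial and degenerate input", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4)
  expect_equal(baseline_slope_correlation(x, x)$r, 1)
  expect_equal(baseline_slope_correlation(x, -x)$r, -1)
  # hand-computed five-point example
  y <- c(2, 3, 1, 6, 5)
  ct <- baseline_slope_correlation(x, y)
  num <- sum((x - mean(x)) * (y - mean(y)))
  den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(ct$r, num / den, tolerance = 1e-12)
  expect_true(is.na(baseline_slope_correlation(rep(1, 4), c(1, 2, 3, 4))$r))
  expect_error(baseline_slope_correlation(1:2, 1:2), ">= 3")
})

test_that("verification rates follow the mode definition", {
  disc <- tibble::tibble(peptide_id = sprintf("p%02d", 1:12),
                         p_value = c(rep(0.01, 10), 0.5, 0.9),
                         direction = rep(c("UP", "DOWN"), 6))
  # validation: 7 of the 10 significant share direction, 3 of those also p<.05
  val <- disc
  val$direction[c(1, 3, 5)] <- c("DOWN", "UP", "DOWN") # flip three
  val$p_value <- 0.2
  same <- sum(disc$direction[1:10] == val$direction[1:10])
  val$p_value[which(disc$direction[1:10] == val$direction[1:10])[1:3]] <- 0.01
  out_dir <- verification_rate(disc, val, "direction_only")
  expect_equal(out_dir$n_discovery_significant, 10)
  expect_equal(out_dir$rate, same / 10)
  out_p <- verification_rate(disc, val, "direction_and_p")
  expect_equal(out_p$rate, 3 / 10)
  # identical tables verify fully under both modes
  expect_equal(verification_rate(disc, disc, "direction_only")$rate, 1)
  expect_equal(verification_rate(disc, disc, "direction_and_p")$rate, 1)
  # no significant discovery peptides -> undefined rate
  none <- dplyr::mutate(disc, p_value = 0.99)
  expect_true(is.na(verification_rate(none, val)$rate))
})
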
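#' ROC AUC with DeLong inference
#'
#' AUC by the Mann-Whitney identity (ties count one half) with a DeLong
#' variance estimate giving a Wald confidence interval and a two-sided
#' p-value against AUC = 0.5. With perfectly separated scores the DeLong
#' variance is zero; the CI then collapses to the point estimate and the
#' p-value to 0 (or 1 at AUC exactly 0.5).
#'
#' @param scores Continuous classifier scores, larger = more likely
#'   positive.
#' @param labels Class labels, same length as `scores`.
#' @param positive The positive-class label, default `"UNCONTROLLED"`.
#' @param conf_level Confidence level, default 0.95.
#' @return An object of class `"roc_result"`: a list with `auc`, `ci_low`,
#'   `ci_high`, `p_vs_half`, `n_pos`, `n_neg`, and the `scores`/`labels`
#'   used (for plotting).
#' @export
roc_auc <- function(scores, labels, positive = "UNCONTROLLED",
                    conf_level = 0.95) {
  if (length(scores) != length(labels)) abort("length mismatch")
  ok <- is.finite(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  is_pos <- labels == positive
  m <- sum(is_pos); n <- sum(!is_pos)
  if (m == 0 || n == 0) abort("both classes must be present")
  x <- scores[is_pos]; y <- scores[!is_pos]

  # DeLong placements: V10_i = P-hat(X_i beats a random Y), and vice versa
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  v10 <- rowMeans(psi)
  v01 <- 1 - colMeans(psi) # placements of the negatives for AUC(Y over X)
  auc <- mean(v10)
  s10 <- if (m > 1) var(v10) else 0
  s01 <- if (n > 1) var(1 - v01) else 0
  se <- sqrt(s10 / m + s01 / n)
  zq <- qnorm(1 - (1 - conf_level) / 2)
  ci <- c(max(0, auc - zq * se), min(1, auc + zq * se))
  p <- if (se > 0) {
    2 * pnorm(-abs(auc - 0.5) / se)
  } else if (auc == 0.5) 1 else 0

  structure(list(auc = auc, ci_low = ci[1], ci_high = ci[2], p_vs_half = p,
                 n_pos = m, n_neg = n, conf_level = conf_level,
                 scores = scores, labels = labels, positive = positive),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC = %.3f (%d%% CI %.3f-%.3f), p vs 0.5 = %.3g; n+ = %d, n- = %d\n",
              x$auc, round(100 * x$conf_level), x$ci_low, x$ci_high,
              x$p_vs_half, x$n_pos, x$n_neg))
  invisible(x)
}

#' @rdname roc_auc
#' @param x A `"roc_result"`.
#' @param ... Unused.
#' @method tidy roc_result
#' @export
tidy.roc_result <- function(x, ...) {
  tibble(auc = x$auc, ci_low = x$ci_low, ci_high = x$ci_high,
         p_vs_half = x$p_vs_half, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Label concordance across eGFR equations
#'
#' Cross-tabulates the kidney function labels assigned by several eGFR
#' equations over their shared patients. "Overall overlap" is the fraction
#' labeled identically by *all* methods; because the right denominator is
#' debatable, it is reported both over all shared patients
#' (`prop_identical`) and over the patients whom no method excluded
#' (`prop_identical_informative`). Per-label method-subset (Venn cell)
#' counts are also returned: for each label, the number of patients
#' assigned that label by exactly each subset of methods. The result is
#' invariant to method and patient order.
#'
#' @param labels_tbl Tibble with `patient_id`, `method`, `label`.
#' @param methods Methods to compare (default: all present).
#' @return An object of class `"label_concordance"`: list with `methods`,
#'   `n_common`, `n_identical`, `prop_identical`, `n_informative`,
#'   `n_identical_informative`, `prop_identical_informative`,
#'   `pattern_counts` (tibble of label patterns), and `venn` (tibble:
#'   `label`, `methods` (collapsed subset), `n`).
#' @export
label_overlap <- function(labels_tbl, methods = NULL) {
  d <- as_tibble(labels_tbl)
  if (is.null(methods)) methods <- sort(unique(d$method))
  d <- filter(d, .data$method %in% methods)
  wide <- tidyr::pivot_wider(d[, c("patient_id", "method", "label")],
                             names_from = "method", values_from = "label")
  wide <- wide[stats::complete.cases(wide), , drop = FALSE]
  if (!nrow(wide)) abort("no patients shared by all requested methods")
  lab_m <- as.matrix(wide[, sort(methods), drop = FALSE])

  identical_all <- apply(lab_m, 1, function(r) length(unique(r)) == 1)
  informative <- apply(lab_m, 1, function(r) !any(r == "EXCLUDED"))

  pattern_counts <- as_tibble(lab_m) %>%
    count(dplyr::across(dplyr::everything()), name = "n") %>%
    arrange(dplyr::desc(.data$n))

  venn <- purrr::map_dfr(sort(unique(as.vector(lab_m))), function(L) {
    subset_key <- apply(lab_m == L, 1, function(r) {
      paste(sort(methods)[r], collapse = "+")
    })
    keep <- subset_key != ""
    if (!any(keep)) return(tibble())
    tibble(label = L, methods = subset_key[keep]) %>%
      count(.data$label, .data$methods, name = "n")
  })

  structure(list(
    methods = sort(methods),
    n_common = nrow(lab_m),
    n_identical = sum(identical_all),
    prop_identical = mean(identical_all),
    n_informative = sum(informative),
    n_identical_informative = sum(identical_all & informative),
    prop_identical_informative =
      if (sum(informative)) sum(identical_all & informative) / sum(informative)
      else NA_real_,
    pattern_counts = pattern_counts,
    venn = venn
  ), class = "label_concordance")
}

#' @export
print.label_concordance <- function(x, ...) {
  cat(sprintf("Label concordance across %d methods (%s)\n",
              length(x$methods), paste(x$methods, collapse = ", ")))
  cat(sprintf("  %d shared patients; identical in all: %d (%.1f%%)\n",
              x$n_common, x$n_identical, 100 * x$prop_identical))
  cat(sprintf("  among %d never-excluded patients: %d identical (%.1f%%)\n",
              x$n_informative, x$n_identical_informative,
              100 * x$prop_identical_informative))
  invisible(x)
}

#' Pearson correlation of paired per-patient quantities
#'
#' Convenience wrapper used to compare baseline eGFR values or percentage
#' slopes between two estimating equations.
#'
#' @param values_a,values_b Paired numeric vectors (>= 3 finite pairs).
#' @return Tibble with `r`, `p_value`, `n`; `r` is `NA` when either vector
#'   is constant.
#' @export
baseline_slope_correlation <- function(values_a, values_b) {
  ok <- is.finite(values_a) & is.finite(values_b)
  a <- values_a[ok]; b <- values_b[ok]
  if (length(a) < 3) abort("need >= 3 paired finite values")
  if (sd(a) == 0 || sd(b) == 0) {
    return(tibble(r = NA_real_, p_value = NA_real_, n = length(a)))
  }
  ct <- cor.test(a, b)
  tibble(r = unname(ct$estimate), p_value = unname(ct$p.value),
         n = length(a))
}

#' Cross-cohort verification rate of discovery-significant peptides
#'
#' Among the peptides nominally significant in the discovery screen
#' (p < `p_threshold`), the fraction verified in a validation screen:
#' either by showing the same fold-change direction (`"direction_only"`)
#' or by the same direction plus nominal significance in the validation
#' cohort (`"direction_and_p"`).
#'
#' @param discovery,validation Screen tibbles with `peptide_id`,
#'   `p_value`, `direction` (shared peptide ids are matched by id).
#' @param mode `"direction_only"` or `"direction_and_p"`.
#' @param p_threshold Significance threshold, default 0.05.
#' @return Tibble with `mode`, `n_discovery_significant`, `n_verified`,
#'   `rate` (`NA` when no discovery peptide is significant).
#' @export
verification_rate <- function(discovery, validation,
                              mode = c("direction_only", "direction_and_p"),
                              p_threshold = 0.05) {
  mode <- match.arg(mode)
  d <- dplyr::inner_join(
    dplyr::select(as_tibble(discovery), "peptide_id", p_d = "p_value",
                  dir_d = "direction"),
    dplyr::select(as_tibble(validation), "peptide_id", p_v = "p_value",
                  dir_v = "direction"),
    by = "peptide_id"
  )
  sig <- filter(d, !is.na(.data$p_d), .data$p_d < p_threshold)
  n_sig <- nrow(sig)
  verified <- !is.na(sig$dir_d) & !is.na(sig$dir_v) & sig$dir_d == sig$dir_v
  if (mode == "direction_and_p") {
    verified <- verified & !is.na(sig$p_v) & sig$p_v < p_threshold
  }
  tibble(mode = mode, n_discovery_significant = n_sig,
         n_verified = sum(verified),
         rate = if (n_sig) sum(verified) / n_sig else NA_real_)
}
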
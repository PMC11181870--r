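#' Per-peptide Wilcoxon screen between uncontrolled and controlled groups
#'
#' Two-sided Wilcoxon rank-sum test per peptide on raw intensities (zeros
#' included as genuine non-detections), with the fold change defined as the
#' mean of the uncontrolled group divided by the mean of the controlled
#' group, also zero-inclusive. P-values are exact when both groups have
#' fewer than 50 samples and there are no ties, and use the normal
#' approximation with tie and continuity correction otherwise (the
#' `stats::wilcox.test` contract). No multiple-testing correction is applied
#' to the selection statistic; a Benjamini-Hochberg `q_value` is reported as
#' metadata only.
#'
#' @param peptides Intensity tibble (sample id column + peptide columns).
#' @param labels Labels as in [frequency_filter()]; only `UNCONTROLLED` and
#'   `CONTROLLED` samples enter the test.
#' @param id_col Sample id column name.
#' @return Tibble with one row per peptide: `peptide_id`, `p_value`,
#'   `q_value`, `fold_change` (`NA` and `flagged = TRUE` when the controlled
#'   mean is zero), `direction` (`"UP"` iff fold change > 1; from the rank
#'   statistic when the fold change is undefined; `NA` at exactly 1),
#'   `freq_uncontrolled`, `freq_controlled`, `flagged`.
#' @export
wilcoxon_screen <- function(peptides, labels, id_col = "patient_id") {
  peptides <- as_tibble(peptides)
  lab <- .labels_as_vector(labels, id_col)
  ids_u <- intersect(peptides[[id_col]], names(lab)[lab == "UNCONTROLLED"])
  ids_c <- intersect(peptides[[id_col]], names(lab)[lab == "CONTROLLED"])
  if (length(ids_u) < 2 || length(ids_c) < 2) {
    abort("need >= 2 samples per group")
  }
  pep_cols <- setdiff(names(peptides), id_col)
  mu_rows <- match(ids_u, peptides[[id_col]])
  mc_rows <- match(ids_c, peptides[[id_col]])

  res <- purrr::map_dfr(pep_cols, function(pc) {
    x <- peptides[[pc]][mu_rows]
    y <- peptides[[pc]][mc_rows]
    wt <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))
    # a completely constant peptide carries no evidence; the tie-corrected
    # normal approximation degenerates to 0/0 there
    if (is.nan(wt$p.value)) wt$p.value <- 1
    mu <- mean(x); mc <- mean(y)
    flagged <- mc == 0
    fc <- if (flagged) NA_real_ else mu / mc
    dir <- if (flagged) {
      # direction from the rank-sum statistic: W above its null mean means
      # the uncontrolled group tends larger
      if (wt$statistic > length(x) * length(y) / 2) "UP" else "DOWN"
    } else if (fc > 1) "UP" else if (fc < 1) "DOWN" else NA_character_
    tibble(peptide_id = pc, p_value = unname(wt$p.value),
           fold_change = fc, direction = dir,
           freq_uncontrolled = mean(x > 0), freq_controlled = mean(y > 0),
           flagged = flagged)
  })
  res$q_value <- p.adjust(res$p_value, method = "BH")
  res[, c("peptide_id", "p_value", "q_value", "fold_change", "direction",
          "freq_uncontrolled", "freq_controlled", "flagged")]
}

#' Spearman correlation of peptide intensity with eGFR percentage slope
#'
#' Spearman rank correlation (average ranks for ties) between each peptide's
#' intensity and the per-patient percentage slope, with the p-value from the
#' t approximation. Constant peptide vectors yield `NA` (undefined rank
#' correlation), recorded rather than dropped.
#'
#' @param peptides Intensity tibble.
#' @param slopes Tibble with `patient_id` and `pct_slope` columns.
#' @param id_col Sample id column name.
#' @return Tibble: `peptide_id`, `rho`, `rho_p`, `n`.
#' @export
spearman_slope_correlation <- function(peptides, slopes,
                                       id_col = "patient_id") {
  peptides <- as_tibble(peptides)
  slopes <- as_tibble(slopes)
  s <- setNames(slopes$pct_slope, slopes[[id_col]])
  ids <- intersect(peptides[[id_col]], names(s)[is.finite(s)])
  if (length(ids) < 3) abort("need >= 3 samples with a finite slope")
  rows <- match(ids, peptides[[id_col]])
  sv <- s[ids]
  pep_cols <- setdiff(names(peptides), id_col)
  purrr::map_dfr(pep_cols, function(pc) {
    x <- peptides[[pc]][rows]
    if (length(unique(x)) < 2) {
      return(tibble(peptide_id = pc, rho = NA_real_, rho_p = NA_real_,
                    n = length(x)))
    }
    ct <- suppressWarnings(cor.test(x, sv, method = "spearman",
                                    exact = FALSE))
    tibble(peptide_id = pc, rho = unname(ct$estimate),
           rho_p = unname(ct$p.value), n = length(x))
  })
}

#' Between-method agreement of peptide-slope correlations
#'
#' Restricts two per-peptide Spearman correlation tables (one per eGFR
#' equation) to peptides whose correlation p-value is below `p_cut` in both,
#' regresses the rho values of method B on those of method A by OLS, and
#' returns the coefficient of determination.
#'
#' @param corr_a,corr_b Tibbles from [spearman_slope_correlation()],
#'   indexed by shared `peptide_id`s.
#' @param p_cut Correlation p-value cut applied to both tables, default 0.1.
#' @return List with `r_squared`, `n_peptides`, `slope`, `intercept`.
#' @export
method_agreement_regression <- function(corr_a, corr_b, p_cut = 0.1) {
  d <- dplyr::inner_join(
    dplyr::select(as_tibble(corr_a), "peptide_id", rho_a = "rho",
                  p_a = "rho_p"),
    dplyr::select(as_tibble(corr_b), "peptide_id", rho_b = "rho",
                  p_b = "rho_p"),
    by = "peptide_id"
  ) %>%
    filter(is.finite(.data$rho_a), is.finite(.data$rho_b),
           .data$p_a < p_cut, .data$p_b < p_cut)
  if (nrow(d) < 3) abort("fewer than 3 shared peptides pass the p-value cut")
  fit <- lm(rho_b ~ rho_a, data = d)
  # identical correlation lists give an exact fit; the perfect-fit warning
  # from summary.lm is expected there
  list(r_squared = suppressWarnings(summary(fit))$r.squared,
       n_peptides = nrow(d),
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]))
}

#' Run the differential screen under every eGFR-equation labeling
#'
#' For each method: applies the detection-frequency filter with that
#' method's own uncontrolled/controlled groups, runs the Wilcoxon screen,
#' and (when slopes are supplied) the peptide-slope Spearman correlation.
#'
#' @param peptides Intensity tibble.
#' @param labels_tbl Tibble from [label_patients()] (columns `patient_id`,
#'   `method`, `label`, optionally `pct_slope`).
#' @param threshold Detection-frequency threshold, default 0.30.
#' @param id_col Sample id column name.
#' @return Tibble of per-peptide statistics with a `method` column; rows
#'   exist only for peptides passing that method's frequency filter.
#' @export
screen_all_methods <- function(peptides, labels_tbl, threshold = 0.30,
                               id_col = "patient_id") {
  labels_tbl <- as_tibble(labels_tbl)
  purrr::map_dfr(unique(labels_tbl$method), function(m) {
    lt <- filter(labels_tbl, .data$method == m)
    kept <- frequency_filter(peptides, lt, threshold = threshold,
                             id_col = id_col)
    sub <- peptides[, c(id_col, kept), drop = FALSE]
    stats <- wilcoxon_screen(sub, lt, id_col = id_col)
    if ("pct_slope" %in% names(lt) && any(is.finite(lt$pct_slope))) {
      rho <- spearman_slope_correlation(sub, lt, id_col = id_col)
      stats <- left_join(stats, rho[, c("peptide_id", "rho", "rho_p")],
                         by = "peptide_id")
    }
    mutate(stats, method = m, .before = 1)
  })
}
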
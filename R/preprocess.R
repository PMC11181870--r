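#' Normalize peptide intensities to internal-standard peptides
#'
#' Per-sample multiplicative normalization against a set of internal-standard
#' peptides: for each sample, the log-intensities of its detected standards
#' are regressed on the reference log-intensities with the slope fixed at 1
#' (an intercept-only regression in log space, i.e. a single multiplicative
#' factor), and every intensity in the sample is divided by the fitted
#' factor. Zeros encode non-detection, are excluded from the fit and stay
#' exactly zero after scaling.
#'
#' @param peptides Tibble: sample id column plus one non-negative intensity
#'   column per peptide (0 = not detected).
#' @param standards Character vector of internal-standard peptide ids; all
#'   must be columns of `peptides`.
#' @param reference Optional named numeric vector of target log-intensities
#'   (natural log), one per standard. Defaults to the per-standard median of
#'   the detected log-intensities across samples, making the operation
#'   self-contained.
#' @param id_col Name of the sample id column, default `"patient_id"`.
#' @return List with `peptides` (the rescaled tibble) and `model` (a tibble
#'   with one row per sample: `scale_factor`, `n_standards_detected`,
#'   `flagged`). Samples with fewer than two detected standards are flagged
#'   and passed through unscaled, with a warning.
#' @export
normalize_peptides <- function(peptides, standards, reference = NULL,
                               id_col = "patient_id") {
  peptides <- as_tibble(peptides)
  if (!id_col %in% names(peptides)) abort(sprintf("no `%s` column", id_col))
  pep_cols <- setdiff(names(peptides), id_col)
  if (!all(standards %in% pep_cols)) {
    abort("every internal-standard id must be a column of `peptides`")
  }
  std <- as.matrix(peptides[, standards, drop = FALSE])
  if (any(as.matrix(peptides[, pep_cols]) < 0)) {
    abort("peptide intensities must be non-negative")
  }

  if (is.null(reference)) {
    reference <- apply(std, 2, function(x) median(log(x[x > 0])))
  } else {
    if (is.null(names(reference)) || !all(standards %in% names(reference))) {
      abort("`reference` must be named by standard peptide id")
    }
    reference <- reference[standards]
  }

  n_det <- rowSums(std > 0)
  # intercept-only log-space fit: factor = exp(mean(log(x_s) - ref_s))
  logratio <- log(std) - matrix(reference, nrow(std), ncol(std), byrow = TRUE)
  logratio[std == 0] <- NA
  fac <- exp(rowMeans(logratio, na.rm = TRUE))
  flagged <- n_det < 2
  fac[flagged] <- 1
  if (any(flagged)) {
    warn(sprintf("%d sample(s) had < 2 detected standards; passed through unscaled",
                 sum(flagged)))
  }

  scaled <- peptides
  scaled[pep_cols] <- as_tibble(as.matrix(peptides[, pep_cols]) / fac)
  model <- tibble(!!id_col := peptides[[id_col]],
                  scale_factor = unname(fac),
                  n_standards_detected = unname(n_det),
                  flagged = unname(flagged))
  list(peptides = scaled, model = model, standards = standards,
       reference = reference)
}

#' Detection-frequency filter
#'
#' Keeps a peptide iff its detection frequency (fraction of samples with a
#' nonzero intensity) reaches the threshold in at least one of the two
#' label groups. The threshold is inclusive (a frequency of exactly 30%
#' passes the default filter). Raising the threshold never adds peptides.
#'
#' @param peptides Intensity tibble as in [normalize_peptides()].
#' @param labels Tibble with `patient_id` and `label` columns, labels
#'   `"UNCONTROLLED"` / `"CONTROLLED"` (other labels are dropped), or a
#'   named character vector.
#' @param threshold Minimum detection frequency, default 0.30.
#' @param id_col Sample id column name.
#' @return Character vector of retained peptide ids.
#' @export
frequency_filter <- function(peptides, labels, threshold = 0.30,
                             id_col = "patient_id") {
  peptides <- as_tibble(peptides)
  lab <- .labels_as_vector(labels, id_col)
  lab <- lab[lab %in% c("UNCONTROLLED", "CONTROLLED")]
  ids <- intersect(peptides[[id_col]], names(lab))
  grp <- split(ids, lab[ids])
  if (length(grp) < 2 || any(lengths(grp) == 0)) {
    abort("both label groups must be non-empty")
  }
  pep_cols <- setdiff(names(peptides), id_col)
  m <- as.matrix(peptides[match(ids, peptides[[id_col]]), pep_cols,
                          drop = FALSE])
  keep <- rep(FALSE, length(pep_cols))
  for (g in grp) {
    freq <- colMeans(m[match(g, ids), , drop = FALSE] > 0)
    keep <- keep | freq >= threshold
  }
  pep_cols[keep]
}

# Accepts a tibble (patient_id, label) or a named vector; returns named vector.
.labels_as_vector <- function(labels, id_col = "patient_id") {
  if (is.data.frame(labels)) {
    if (!all(c(id_col, "label") %in% names(labels))) {
      abort(sprintf("`labels` needs `%s` and `label` columns", id_col))
    }
    setNames(as.character(labels$label), labels[[id_col]])
  } else {
    if (is.null(names(labels))) abort("`labels` vector must be named by sample id")
    as.character(labels) |> setNames(names(labels))
  }
}
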
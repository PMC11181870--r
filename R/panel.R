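#' Select a cross-equation concordant biomarker panel
#'
#' A peptide enters the panel iff it is nominally significant (Wilcoxon
#' p-value below `p_threshold`) under at least `min_methods` of the
#' eGFR-equation labelings *and* those significant methods agree on the
#' direction of regulation. Missing method-peptide pairs are treated as
#' non-significant. Relaxing `p_threshold` or `min_methods` never removes a
#' selected peptide.
#'
#' @param stats Tibble of per-method screen statistics (columns `method`,
#'   `peptide_id`, `p_value`, `direction`), e.g. from [screen_all_methods()].
#' @param min_methods Minimum number of concordant significant methods,
#'   default 3 (of 4).
#' @param p_threshold Nominal significance threshold, default 0.05.
#' @param require_consistent_direction Require one shared direction among
#'   the significant methods (default `TRUE`).
#' @return Character vector of selected peptide ids, lexicographically
#'   sorted. An empty selection is a valid result.
#' @export
select_concordant_panel <- function(stats, min_methods = 3,
                                    p_threshold = 0.05,
                                    require_consistent_direction = TRUE) {
  if (min_methods < 1 || min_methods > 4) abort("`min_methods` must be in 1..4")
  sig <- as_tibble(stats) %>%
    filter(!is.na(.data$p_value), .data$p_value < p_threshold)
  if (!nrow(sig)) return(character())
  sel <- sig %>%
    group_by(.data$peptide_id) %>%
    summarise(n_sig = dplyr::n_distinct(.data$method),
              n_dir = dplyr::n_distinct(.data$direction),
              any_na_dir = anyNA(.data$direction),
              .groups = "drop") %>%
    filter(.data$n_sig >= min_methods)
  if (require_consistent_direction) {
    sel <- filter(sel, .data$n_dir == 1, !.data$any_na_dir)
  }
  sort(sel$peptide_id)
}

#' Cross-cohort / cross-method consistency filter
#'
#' Keeps the panel peptides whose direction of regulation is identical in
#' every supplied cohort-method combination. A peptide absent from any
#' combination (or with an undefined direction there) cannot be confirmed
#' and is excluded.
#'
#' @param panel Character vector of candidate peptide ids.
#' @param directions Tibble with columns `peptide_id`, `direction`, and one
#'   or both of `cohort` and `method` identifying each evaluation unit.
#' @return Character vector of confirmed peptide ids, sorted.
#' @export
consistency_filter <- function(panel, directions) {
  d <- as_tibble(directions)
  unit_cols <- intersect(c("cohort", "method"), names(d))
  if (!length(unit_cols)) abort("`directions` needs a `cohort` and/or `method` column")
  d$.unit <- do.call(paste, c(d[unit_cols], sep = "\r"))
  n_units <- dplyr::n_distinct(d$.unit)
  ok <- d %>%
    filter(.data$peptide_id %in% panel, !is.na(.data$direction)) %>%
    group_by(.data$peptide_id) %>%
    summarise(n_units_seen = dplyr::n_distinct(.data$.unit),
              n_dir = dplyr::n_distinct(.data$direction), .groups = "drop") %>%
    filter(.data$n_units_seen == n_units, .data$n_dir == 1)
  sort(ok$peptide_id)
}

# ---- internal SVM plumbing ------------------------------------------------

# log(1 + intensity), then per-feature z-score with the supplied statistics.
.panel_transform <- function(m, center, scale) {
  lm_ <- log1p(m)
  sweep(sweep(lm_, 2, center, "-"), 2, scale, "/")
}

.panel_stats <- function(m) {
  lm_ <- log1p(m)
  center <- colMeans(lm_)
  scale <- apply(lm_, 2, sd)
  scale[!is.finite(scale) | scale == 0] <- 1 # constant feature: center only
  list(center = center, scale = scale)
}

.fit_svm <- function(z, y, C, gamma) {
  e1071::svm(z, y, type = "C-classification", kernel = "radial",
             cost = C, gamma = gamma, scale = FALSE, fitted = FALSE)
}

.decision_scores <- function(fit, z, positive) {
  dv <- attr(stats::predict(fit, z, decision.values = TRUE),
             "decision.values")
  sgn <- if (startsWith(colnames(dv)[1], positive)) 1 else -1
  sgn * dv[, 1]
}

# Decision values computed directly from the fitted support-vector state
# (equivalent to predict(..., decision.values = TRUE) but without its
# per-call overhead; the hot path of leave-one-out evaluation).
.decision_scores_direct <- function(fit, z, gamma, positive) {
  sv <- fit$SV
  d2 <- outer(rowSums(z^2), rowSums(sv^2), "+") - 2 * tcrossprod(z, sv)
  dec <- exp(-gamma * pmax(d2, 0)) %*% fit$coefs - fit$rho
  sgn <- if (fit$levels[fit$labels[1]] == positive) 1 else -1
  as.numeric(sgn * dec)
}

# Leave-one-out decision scores with the exact support-vector shortcut: a
# training point with alpha = 0 leaves the dual solution unchanged when
# removed, so its LOO score equals its full-model score. Standardization is
# computed once on the full training set (see the methods vignette).
.loo_scores <- function(z, y, C, gamma, positive) {
  fit <- .fit_svm(z, y, C, gamma)
  scores <- .decision_scores_direct(fit, z, gamma, positive)
  for (i in fit$index) {
    f_i <- .fit_svm(z[-i, , drop = FALSE], y[-i], C, gamma)
    scores[i] <- .decision_scores_direct(f_i, z[i, , drop = FALSE], gamma,
                                         positive)
  }
  scores
}

.mw_auc <- function(scores, is_pos) {
  r <- rank(scores)
  n1 <- sum(is_pos); n0 <- sum(!is_pos)
  (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.prep_training <- function(peptides, labels, panel, id_col) {
  peptides <- as_tibble(peptides)
  lab <- .labels_as_vector(labels, id_col)
  lab <- lab[lab %in% c("UNCONTROLLED", "CONTROLLED")]
  ids <- intersect(peptides[[id_col]], names(lab))
  if (!length(panel)) abort("empty peptide panel")
  if (!all(panel %in% names(peptides))) {
    abort("every panel peptide must be a column of the training matrix")
  }
  y <- factor(lab[ids], levels = c("CONTROLLED", "UNCONTROLLED"))
  if (nlevels(droplevels(y)) < 2) abort("training labels contain a single class")
  x <- as.matrix(peptides[match(ids, peptides[[id_col]]), panel,
                          drop = FALSE])
  list(ids = ids, x = x, y = y)
}

#' Train the RBF-SVM peptide panel classifier
#'
#' Fits a C-classification support vector machine with a radial basis
#' kernel on log-transformed (`log(1 + intensity)`, zeros mapped to 0) and
#' per-feature standardized intensities of the panel peptides. The
#' hyperparameters default to the fixed values C = 256, gamma = 2e-5; no
#' hyperparameter search is performed. The continuous classifier score is
#' the signed distance to the separating hyperplane, oriented so that
#' larger scores indicate `UNCONTROLLED`. The fit is deterministic given
#' the data.
#'
#' @param peptides Intensity tibble (sample id column + peptide columns).
#' @param labels Labels as in [frequency_filter()]; samples labeled
#'   `EXCLUDED` are dropped.
#' @param panel Character vector of panel peptide ids (columns of
#'   `peptides`).
#' @param C,gamma RBF-SVM hyperparameters.
#' @param id_col Sample id column name.
#' @return An object of class `"svm_panel"`.
#' @export
train_svm_panel <- function(peptides, labels, panel, C = 256, gamma = 2e-5,
                            id_col = "patient_id") {
  if (C <= 0 || gamma <= 0) abort("`C` and `gamma` must be > 0")
  panel <- sort(unique(panel))
  tr <- .prep_training(peptides, labels, panel, id_col)
  if (min(table(tr$y)) < 5) abort("need >= 5 samples per class")
  st <- .panel_stats(tr$x)
  z <- .panel_transform(tr$x, st$center, st$scale)
  fit <- .fit_svm(z, tr$y, C, gamma)
  structure(
    list(panel = panel, C = C, gamma = gamma, fit = fit,
         center = st$center, scale = st$scale, positive = "UNCONTROLLED",
         id_col = id_col, n_train = length(tr$ids),
         class_counts = table(tr$y)),
    class = "svm_panel"
  )
}

#' Predict panel classifier scores or labels
#'
#' @param object An `"svm_panel"` from [train_svm_panel()].
#' @param peptides Intensity tibble containing all panel peptides.
#' @param type `"score"` for the signed hyperplane distance (larger =
#'   more likely uncontrolled) or `"label"`.
#' @param ... Unused.
#' @return Tibble with the sample id column and `score` or `label`.
#' @export
predict.svm_panel <- function(object, peptides, type = c("score", "label"),
                              ...) {
  type <- match.arg(type)
  peptides <- as_tibble(peptides)
  if (!all(object$panel %in% names(peptides))) {
    abort("`peptides` lacks some panel peptides")
  }
  x <- as.matrix(peptides[, object$panel, drop = FALSE])
  z <- .panel_transform(x, object$center, object$scale)
  score <- .decision_scores(object$fit, z, object$positive)
  out <- tibble(!!object$id_col := peptides[[object$id_col]],
                score = unname(score))
  if (type == "label") {
    out$label <- ifelse(out$score > 0, "UNCONTROLLED", "CONTROLLED")
    out$score <- NULL
  }
  out
}

#' Leave-one-out cross-validated panel AUC
#'
#' Computes the leave-one-out decision score for every training sample
#' (refitting the SVM without that sample) and the AUC of those scores for
#' discriminating uncontrolled from controlled. Samples whose dual
#' coefficient is zero in the full fit are scored by the full model -- an
#' exact shortcut, since removing such a point leaves the solution
#' unchanged.
#'
#' @inheritParams train_svm_panel
#' @return List with `auc` and `scores` (tibble: sample id, `score`,
#'   `label`).
#' @export
loo_auc <- function(peptides, labels, panel, C = 256, gamma = 2e-5,
                    id_col = "patient_id") {
  panel <- sort(unique(panel))
  tr <- .prep_training(peptides, labels, panel, id_col)
  st <- .panel_stats(tr$x)
  z <- .panel_transform(tr$x, st$center, st$scale)
  scores <- .loo_scores(z, tr$y, C, gamma, "UNCONTROLLED")
  list(
    auc = .mw_auc(scores, tr$y == "UNCONTROLLED"),
    scores = tibble(!!id_col := tr$ids, score = unname(scores),
                    label = as.character(tr$y))
  )
}

#' Take-one-out panel refinement
#'
#' Greedy backward elimination of panel peptides scored by leave-one-out
#' cross-validated AUC: in each round the single peptide whose removal
#' maximally increases the LOO AUC is dropped; the procedure stops when no
#' removal strictly increases the AUC (or after `max_rounds`). Ties are
#' broken by lexicographic peptide id. The returned panel never has a lower
#' LOO AUC than the input panel.
#'
#' @inheritParams train_svm_panel
#' @param max_rounds Optional cap on the number of elimination rounds.
#' @return An `"svm_panel"` trained on the refined panel, with attributes
#'   `trace` (tibble: `round`, `removed`, `auc_before`, `auc_after`),
#'   `loo_auc` (final LOO AUC) and `n_loo_evals` (number of LOO AUC
#'   evaluations performed, `|panel|` per round plus the initial one).
#' @export
take_one_out_optimize <- function(peptides, labels, panel, C = 256,
                                  gamma = 2e-5, max_rounds = Inf,
                                  id_col = "patient_id") {
  panel <- sort(unique(panel))
  if (length(panel) < 2) abort("take-one-out needs a panel of >= 2 peptides")
  tr <- .prep_training(peptides, labels, panel, id_col)
  if (min(table(tr$y)) < 5) abort("need >= 5 samples per class")
  st <- .panel_stats(tr$x)
  z_full <- .panel_transform(tr$x, st$center, st$scale)
  is_pos <- tr$y == "UNCONTROLLED"
  n_evals <- 0L
  loo_eval <- function(cols) {
    n_evals <<- n_evals + 1L
    s <- .loo_scores(z_full[, cols, drop = FALSE], tr$y, C, gamma,
                     "UNCONTROLLED")
    .mw_auc(s, is_pos)
  }

  current <- panel
  auc_now <- loo_eval(current)
  trace <- list()
  round <- 0L
  while (length(current) > 1 && round < max_rounds) {
    cand_auc <- vapply(current,
                       function(pid) loo_eval(setdiff(current, pid)),
                       numeric(1))
    best <- max(cand_auc)
    if (best <= auc_now) break
    drop_id <- names(cand_auc)[cand_auc == best][1] # lexicographic tie-break
    round <- round + 1L
    trace[[round]] <- tibble(round = round, removed = drop_id,
                             auc_before = auc_now, auc_after = best)
    current <- setdiff(current, drop_id)
    auc_now <- best
  }

  model <- train_svm_panel(peptides, labels, current, C = C, gamma = gamma,
                           id_col = id_col)
  attr(model, "trace") <- if (length(trace)) bind_rows(trace) else
    tibble(round = integer(), removed = character(),
           auc_before = numeric(), auc_after = numeric())
  attr(model, "loo_auc") <- auc_now
  attr(model, "n_loo_evals") <- n_evals
  model
}

#' @export
print.svm_panel <- function(x, ...) {
  cat("RBF-SVM peptide panel classifier\n")
  cat(sprintf("  peptides: %d   C = %g, gamma = %g\n",
              length(x$panel), x$C, x$gamma))
  cat(sprintf("  training samples: %d (%s)\n", x$n_train,
              paste(names(x$class_counts), x$class_counts,
                    sep = " = ", collapse = ", ")))
  la <- attr(x, "loo_auc")
  if (!is.null(la)) cat(sprintf("  leave-one-out AUC: %.3f\n", la))
  invisible(x)
}

#' Tidy a fitted peptide panel model
#'
#' @param x An `"svm_panel"`.
#' @param ... Unused.
#' @return One row per panel peptide with its feature transform statistics.
#' @method tidy svm_panel
#' @export
tidy.svm_panel <- function(x, ...) {
  tibble(peptide_id = x$panel, center = unname(x$center),
         scale = unname(x$scale))
}

#' One-row model summary of a peptide panel model
#'
#' @param x An `"svm_panel"`.
#' @param ... Unused.
#' @return Tibble with panel size, hyperparameters, training size, number
#'   of support vectors and (if the model came out of
#'   [take_one_out_optimize()]) the leave-one-out AUC.
#' @method glance svm_panel
#' @export
glance.svm_panel <- function(x, ...) {
  tibble(n_panel = length(x$panel), C = x$C, gamma = x$gamma,
         n_train = x$n_train, n_support = x$fit$tot.nSV,
         loo_auc = attr(x, "loo_auc") %||% NA_real_)
}

#' Serialize a panel model to JSON
#'
#' Writes the peptide list, feature transform and kernel hyperparameters
#' (not the fitted support-vector state, which is rebuilt by retraining).
#'
#' @param model An `"svm_panel"`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_panel_json <- function(model, path) {
  stopifnot(inherits(model, "svm_panel"))
  jsonlite::write_json(
    list(panel = model$panel,
         transform = list(type = "log1p_zscore",
                          center = as.list(model$center),
                          scale = as.list(model$scale)),
         kernel = list(type = "radial", C = model$C, gamma = model$gamma),
         n_train = model$n_train,
         loo_auc = attr(model, "loo_auc")),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
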
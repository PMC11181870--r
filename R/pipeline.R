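#' Pipeline run configuration
#'
#' Assembles and validates the configuration of [run_pipeline()]. The
#' analysis defaults are the study constants the package is built around:
#' detection-frequency threshold 0.30, nominal significance 0.05,
#' concordance in at least 3 of 4 equations, correlation p-value cut 0.1
#' for the between-method regression, SVM C = 256 and gamma = 2e-5, and
#' model development under the `EKFC_CYS` labeling.
#'
#' @param sim A [sim_config()] describing the synthetic cohort to generate,
#'   or `NULL` when `visits` / `peptides` are supplied directly to
#'   [run_pipeline()].
#' @param methods eGFR equations to label with.
#' @param label_window Slope window used for the screen labels.
#' @param train_method Labeling used to train the panel classifier.
#' @param freq_threshold,p_threshold,min_methods,rho_p_cut Analysis
#'   thresholds (see Details).
#' @param svm_c,svm_gamma SVM hyperparameters.
#' @param n_standards Number of highest-detection peptides used as
#'   internal standards for normalization.
#' @param optimize Run [take_one_out_optimize()] after training.
#' @param max_rounds Cap on elimination rounds (default unlimited).
#' @param seed Seed controlling all randomness (forwarded to `sim` if that
#'   was left at its default seed).
#' @param out_dir Output directory for artifacts and the run manifest, or
#'   `NULL` to skip writing.
#' @return A validated list of class `"run_config"`.
#' @export
run_config <- function(sim = sim_config(seed = seed),
                       methods = egfr_methods(),
                       label_window = c("full_period", "between_visits"),
                       train_method = "EKFC_CYS",
                       freq_threshold = 0.30, p_threshold = 0.05,
                       min_methods = 3, rho_p_cut = 0.1,
                       svm_c = 256, svm_gamma = 2e-5,
                       n_standards = 10, optimize = TRUE, max_rounds = Inf,
                       seed = 1L, out_dir = NULL) {
  label_window <- match.arg(label_window)
  if (!all(methods %in% egfr_methods())) {
    abort(sprintf("unknown eGFR method(s): %s",
                  paste(setdiff(methods, egfr_methods()), collapse = ", ")))
  }
  if (!train_method %in% methods) abort("`train_method` must be in `methods`")
  if (freq_threshold < 0 || freq_threshold > 1) abort("`freq_threshold` in [0,1]")
  if (p_threshold <= 0 || p_threshold > 1) abort("`p_threshold` in (0,1]")
  if (min_methods < 1 || min_methods > length(methods)) {
    abort("`min_methods` must be in 1..length(methods)")
  }
  if (svm_c <= 0 || svm_gamma <= 0) abort("SVM hyperparameters must be > 0")
  structure(list(
    sim = sim, methods = methods, label_window = label_window,
    train_method = train_method, freq_threshold = freq_threshold,
    p_threshold = p_threshold, min_methods = min_methods,
    rho_p_cut = rho_p_cut, svm_c = svm_c, svm_gamma = svm_gamma,
    n_standards = n_standards, optimize = optimize, max_rounds = max_rounds,
    seed = as.integer(seed), out_dir = out_dir
  ), class = "run_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name,
                  conditionMessage(e)),
          class = "nephropep_stage_error")
  })
}

#' Run the full biomarker discovery pipeline
#'
#' Executes the chain simulate -> eGFR -> label -> normalize -> screen ->
#' select -> train -> evaluate -> concordance on a synthetic cohort (or on
#' supplied tables), and optionally writes every intermediate artifact plus
#' a run manifest with file checksums and the resolved configuration.
#' Reruns with an identical configuration and seed reproduce all artifacts
#' bit-identically.
#'
#' @param config A [run_config()].
#' @param visits,peptides Optional externally supplied visit table and
#'   peptide matrix (both required together); otherwise the cohort is
#'   simulated from `config$sim`.
#' @return Invisibly, a list of class `"nephropep_run"` with elements
#'   `cohort`, `labels`, `screen`, `panel`, `model`, `evaluation`,
#'   `report` and `manifest`.
#' @export
run_pipeline <- function(config = run_config(), visits = NULL,
                         peptides = NULL) {
  stopifnot(inherits(config, "run_config"))
  truth <- NULL

  cohort <- .stage("simulate", {
    if (is.null(visits) != is.null(peptides)) {
      abort("supply both `visits` and `peptides`, or neither")
    }
    if (is.null(visits)) {
      co <- simulate_cohort(config$sim)
      truth <- co$truth
      co
    } else {
      list(visits = as_tibble(visits), peptides = as_tibble(peptides),
           truth = NULL, config = config$sim)
    }
  })

  visits_egfr <- .stage("egfr", add_egfr(cohort$visits, config$methods))

  labels <- .stage("label", {
    bind_rows(
      label_patients(visits_egfr, config$methods, window = "full_period"),
      label_patients(visits_egfr, config$methods, window = "between_visits")
    )
  })
  labels_screen <- filter(labels, .data$window == config$label_window)

  norm <- .stage("preprocess", {
    pep_cols <- setdiff(names(cohort$peptides), "patient_id")
    det <- colMeans(as.matrix(cohort$peptides[, pep_cols]) > 0)
    standards <- names(sort(det, decreasing = TRUE))[
      seq_len(min(config$n_standards, length(pep_cols)))]
    normalize_peptides(cohort$peptides, sort(standards))
  })

  screen <- .stage("screen", {
    screen_all_methods(norm$peptides, labels_screen,
                       threshold = config$freq_threshold)
  })

  panel <- .stage("select", {
    select_concordant_panel(screen, min_methods = config$min_methods,
                            p_threshold = config$p_threshold)
  })
  if (!length(panel)) {
    abort("pipeline stage 'select' failed: empty concordant panel")
  }

  train_labels <- filter(labels_screen, .data$method == config$train_method)
  model <- .stage("train", {
    if (config$optimize && length(panel) >= 2) {
      take_one_out_optimize(norm$peptides, train_labels, panel,
                            C = config$svm_c, gamma = config$svm_gamma,
                            max_rounds = config$max_rounds)
    } else {
      train_svm_panel(norm$peptides, train_labels, panel,
                      C = config$svm_c, gamma = config$svm_gamma)
    }
  })

  evaluation <- .stage("evaluate", {
    cv <- loo_auc(norm$peptides, train_labels, model$panel,
                  C = config$svm_c, gamma = config$svm_gamma)
    roc <- roc_auc(cv$scores$score, cv$scores$label)
    overlap <- lapply(c(full_period = "full_period",
                        between_visits = "between_visits"), function(w) {
      label_overlap(filter(labels, .data$window == w), config$methods)
    })
    pair <- c("CKD_EPI_CR", "EKFC_CYS")
    corr <- NULL
    if (all(pair %in% config$methods)) {
      ve <- visits_egfr %>% group_by(.data$patient_id) %>%
        arrange(.data$time_years, .by_group = TRUE) %>%
        summarise(dplyr::across(dplyr::all_of(paste0("egfr_", pair)),
                                dplyr::first), .groups = "drop")
      sl <- labels %>%
        filter(.data$window == "full_period", .data$method %in% pair) %>%
        tidyr::pivot_wider(id_cols = "patient_id", names_from = "method",
                           values_from = "pct_slope")
      corr <- list(
        baseline = baseline_slope_correlation(ve[[paste0("egfr_", pair[1])]],
                                              ve[[paste0("egfr_", pair[2])]]),
        pct_slope = baseline_slope_correlation(sl[[pair[1]]], sl[[pair[2]]])
      )
    }
    agreement <- NULL
    if ("rho" %in% names(screen)) {
      others <- setdiff(config$methods, config$train_method)
      ref <- filter(screen, .data$method == config$train_method)
      agreement <- purrr::map_dfr(others, function(m) {
        res <- tryCatch(
          method_agreement_regression(ref,
                                      filter(screen, .data$method == m),
                                      p_cut = config$rho_p_cut),
          error = function(e) list(r_squared = NA_real_, n_peptides = 0L)
        )
        tibble(method_a = config$train_method, method_b = m,
               r_squared = res$r_squared, n_peptides = res$n_peptides)
      })
    }
    list(loo = cv, roc = roc, overlap = overlap, correlations = corr,
         agreement = agreement)
  })

  concordant <- .stage("concord", {
    dirs <- screen[, c("peptide_id", "method", "direction")]
    consistency_filter(model$panel, dirs)
  })

  report <- list(
    n_patients = dplyr::n_distinct(cohort$visits$patient_id),
    n_peptides = ncol(cohort$peptides) - 1L,
    n_frequency_filtered = dplyr::n_distinct(screen$peptide_id),
    n_concordant_selected = length(panel),
    n_panel_final = length(model$panel),
    n_direction_consistent = length(concordant),
    loo_auc = evaluation$roc$auc,
    loo_auc_ci = c(evaluation$roc$ci_low, evaluation$roc$ci_high),
    overlap_prop_full_period = evaluation$overlap$full_period$prop_identical,
    overlap_prop_between_visits =
      evaluation$overlap$between_visits$prop_identical,
    baseline_corr_r =
      if (!is.null(evaluation$correlations)) evaluation$correlations$baseline$r
      else NA_real_,
    pct_slope_corr_r =
      if (!is.null(evaluation$correlations))
        evaluation$correlations$pct_slope$r else NA_real_
  )

  run <- structure(list(cohort = cohort, truth = truth, labels = labels,
                        screen = screen, panel = panel, model = model,
                        evaluation = evaluation, concordant = concordant,
                        report = report, config = config),
                   class = "nephropep_run")

  if (!is.null(config$out_dir)) {
    run$manifest <- .write_run(run, config$out_dir)
  }
  invisible(run)
}

# Write all artifacts and a deterministic manifest (no timestamps, relative
# paths, md5 checksums) so that identical config + seed give bit-identical
# output.
.write_run <- function(run, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cfg <- run$config
  files <- character()

  wr <- function(name, writer) {
    path <- file.path(dir, name)
    writer(path)
    files[[name]] <<- unname(tools::md5sum(path))
    name
  }
  wr("visits.csv", function(p) readr::write_csv(run$cohort$visits, p))
  wr("peptides.tsv", function(p) readr::write_tsv(run$cohort$peptides, p))
  if (!is.null(run$truth)) {
    wr("ground_truth.json", function(p) {
      jsonlite::write_json(run$truth, p, dataframe = "columns", digits = NA)
    })
  }
  wr("labels.csv", function(p) readr::write_csv(run$labels, p))
  wr("screen.tsv", function(p) readr::write_tsv(run$screen, p))
  wr("panel.json", function(p) {
    jsonlite::write_json(list(concordant = run$panel,
                              final = run$model$panel,
                              direction_consistent = run$concordant),
                         p, digits = NA)
  })
  wr("model.json", function(p) write_panel_json(run$model, p))
  wr("evaluation.json", function(p) {
    ev <- run$evaluation
    jsonlite::write_json(list(
      roc = tidy(ev$roc), loo_scores = ev$loo$scores,
      overlap = lapply(ev$overlap, function(o) {
        o[c("n_common", "n_identical", "prop_identical", "n_informative",
            "n_identical_informative", "prop_identical_informative",
            "venn")]
      }),
      correlations = ev$correlations, agreement = ev$agreement
    ), p, dataframe = "columns", auto_unbox = TRUE, digits = NA)
  })
  wr("report.json", function(p) {
    jsonlite::write_json(run$report, p, auto_unbox = TRUE, digits = NA)
  })

  resolved <- unclass(cfg)
  resolved$sim <- unclass(resolved$sim)
  resolved$out_dir <- NULL # location-independent manifest
  resolved$max_rounds <- if (is.finite(resolved$max_rounds)) {
    resolved$max_rounds
  } else {
    "unlimited"
  }
  manifest <- list(tool = "nephropep",
                   version = as.character(utils::packageVersion("nephropep")),
                   config = resolved,
                   stages = c("simulate", "egfr", "label", "preprocess",
                              "screen", "select", "train", "evaluate",
                              "concord"),
                   files = as.list(files))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}

#' @export
print.nephropep_run <- function(x, ...) {
  r <- x$report
  cat("nephropep pipeline run\n")
  cat(sprintf("  patients: %d   peptides: %d (%d pass frequency filter)\n",
              r$n_patients, r$n_peptides, r$n_frequency_filtered))
  cat(sprintf("  concordant panel: %d -> final panel: %d (direction-consistent: %d)\n",
              r$n_concordant_selected, r$n_panel_final,
              r$n_direction_consistent))
  cat(sprintf("  leave-one-out AUC (%s labels): %.3f (95%% CI %.3f-%.3f)\n",
              x$config$train_method, r$loo_auc, r$loo_auc_ci[1],
              r$loo_auc_ci[2]))
  cat(sprintf("  label overlap across equations: %.1f%% (full period), %.1f%% (between visits)\n",
              100 * r$overlap_prop_full_period,
              100 * r$overlap_prop_between_visits))
  invisible(x)
}
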
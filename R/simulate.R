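#' Simulation configuration for a synthetic longitudinal cohort
#'
#' Bundles and validates the parameters of [simulate_cohort()]. The defaults
#' describe the cohort structure the package is designed around: ~200
#' patients under RAS-inhibitor treatment with 4 roughly annual visits,
#' a latent per-patient GFR trajectory that is either stable (0 %/yr) or
#' declining (-15 %/yr), serum markers back-calculated from the latent GFR
#' with ~5% assay noise, and a zero-inflated log-normal peptide matrix in
#' which a subset of peptides is shifted in decliners (majority
#' down-regulated, collagen-fragment-like; minority up-regulated,
#' antitrypsin-fragment-like).
#'
#' @param n_patients Number of patients.
#' @param n_visits Visits per patient (one baseline + `n_visits - 1`
#'   follow-ups).
#' @param visit_interval_mean,visit_interval_sd Mean and SD (years) of the
#'   gaps between consecutive visits.
#' @param n_peptides Number of peptides in the intensity matrix.
#' @param n_differential Number of peptides truly associated with decline.
#' @param effect_size Standardized mean difference on the log-intensity scale
#'   between decliners and stable patients, for differential peptides.
#' @param frac_down Proportion of differential peptides down-regulated in
#'   decliners.
#' @param decline_frac Proportion of patients with truly declining GFR.
#' @param true_decline_rate,true_stable_rate True annualized percentage
#'   change in GFR (%/yr) for decliners and stable patients.
#' @param measurement_cv_creatinine,measurement_cv_cystatin Multiplicative
#'   assay coefficient of variation for the two serum markers (fraction;
#'   0 disables noise).
#' @param detection_base_freq Target mean detection frequency of
#'   non-differential peptides.
#' @param trajectory Shape of the latent GFR curve. `"linear_pct"` (default)
#'   is linear in time with an annual change equal to the configured percent
#'   of the time-0 value, so the configured rate is exactly the OLS
#'   percentage slope in the noise-free case; `"log_linear"` applies a
#'   constant multiplicative decline per year.
#' @param seed Integer seed; all randomness in [simulate_cohort()] derives
#'   from it.
#'
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_patients = 200, n_visits = 4,
                       visit_interval_mean = 1.0, visit_interval_sd = 0.2,
                       n_peptides = 500, n_differential = 50,
                       effect_size = 1.0, frac_down = 0.8,
                       decline_frac = 0.5,
                       true_decline_rate = -15, true_stable_rate = 0,
                       measurement_cv_creatinine = 0.05,
                       measurement_cv_cystatin = 0.05,
                       detection_base_freq = 0.7,
                       trajectory = c("linear_pct", "log_linear"),
                       seed = 1L) {
  trajectory <- match.arg(trajectory)
  cfg <- list(
    n_patients = n_patients, n_visits = n_visits,
    visit_interval_mean = visit_interval_mean,
    visit_interval_sd = visit_interval_sd,
    n_peptides = n_peptides, n_differential = n_differential,
    effect_size = effect_size, frac_down = frac_down,
    decline_frac = decline_frac,
    true_decline_rate = true_decline_rate,
    true_stable_rate = true_stable_rate,
    measurement_cv_creatinine = measurement_cv_creatinine,
    measurement_cv_cystatin = measurement_cv_cystatin,
    detection_base_freq = detection_base_freq,
    trajectory = trajectory, seed = as.integer(seed)
  )
  counts <- c("n_patients", "n_visits", "n_peptides")
  for (f in counts) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] < 1) {
      abort(sprintf("`%s` must be a count >= 1", f))
    }
  }
  if (cfg$n_differential < 0 || cfg$n_differential > cfg$n_peptides) {
    abort("`n_differential` must lie in [0, n_peptides]")
  }
  for (f in c("frac_down", "decline_frac", "detection_base_freq")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) abort(sprintf("`%s` must lie in [0, 1]", f))
  }
  for (f in c("visit_interval_mean", "measurement_cv_creatinine",
              "measurement_cv_cystatin")) {
    if (cfg[[f]] < 0) abort(sprintf("`%s` must be >= 0", f))
  }
  if (cfg$visit_interval_mean <= 0) abort("`visit_interval_mean` must be > 0")
  structure(cfg, class = "sim_config")
}

# Truncated normal by rejection; vectorized, deterministic under set.seed.
.rnorm_trunc <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  x
}

# Log-normal multiplicative noise with unit median and coefficient of
# variation cv (cv = 0 returns exactly 1).
.lognorm_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  exp(rnorm(n, 0, sqrt(log(1 + cv^2))))
}

#' Simulate a synthetic cohort with known ground truth
#'
#' Generates a clinical visit table, a peptide intensity matrix and the
#' ground truth that produced them. The latent per-patient GFR trajectory
#' drives both: serum creatinine and cystatin C are obtained by analytically
#' inverting the CKD-EPI 2009 creatinine and CKD-EPI 2012 cystatin equations
#' at the true GFR (then perturbed by multiplicative log-normal assay noise),
#' so the combined and EKFC equations disagree with truth only through noise
#' and their own functional form -- deliberately reproducing the
#' between-equation discordance seen in real cohorts. Peptide intensities are
#' zero-inflated log-normal: each peptide is detected with a probability
#' logistic in its mean log-intensity (calibrated so the average detection
#' frequency equals `detection_base_freq`), and differential peptides are
#' shifted by `effect_size` standard deviations in decliners, with sign per
#' their planted direction.
#'
#' @param config A [sim_config()].
#' @param peptide_truth Optional peptide ground truth from a previously
#'   simulated cohort (`cohort$truth$peptides`): reuses its per-peptide
#'   mean/SD, differential flags and directions so that a second cohort
#'   shares the same peptide biology (as validation cohorts do in a real
#'   multi-cohort study) while patients and noise are drawn afresh.
#' @return A list of class `"nephro_cohort"` with elements
#'   \describe{
#'     \item{visits}{tibble: `patient_id`, `visit_index`, `time_years`,
#'       `age_baseline`, `sex`, `scr_mg_dl`, `scys_mg_l`.}
#'     \item{peptides}{tibble: `patient_id` plus one non-negative intensity
#'       column per peptide (0 = not detected); one baseline urine sample
#'       per patient.}
#'     \item{truth}{list with `patients` (true status and baseline GFR),
#'       `gfr` (true GFR at each visit) and `peptides` (differential flag
#'       and direction).}
#'     \item{config}{the input configuration.}
#'   }
#' @export
simulate_cohort <- function(config = sim_config(), peptide_truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_patients

  patient_id <- sprintf("P%04d", seq_len(n))
  age <- .rnorm_trunc(n, 67.5, 8, 30, 90)
  sex <- ifelse(runif(n) < 0.53, "F", "M")
  gfr0 <- .rnorm_trunc(n, 63.3, 16.8, 20, 120)
  n_decl <- round(config$decline_frac * n)
  status <- rep("stable", n)
  status[sample.int(n, n_decl)] <- "decliner"
  rate <- ifelse(status == "decliner", config$true_decline_rate,
                 config$true_stable_rate)

  # visit times: baseline at 0, positive increments ~ N(mean, sd), floored
  gaps <- matrix(pmax(0.2, rnorm((config$n_visits - 1) * n,
                                 config$visit_interval_mean,
                                 config$visit_interval_sd)),
                 nrow = n)
  times <- cbind(0, t(apply(gaps, 1, cumsum)))
  if (config$n_visits == 1) times <- matrix(0, n, 1)

  visits <- tibble(
    patient_id = rep(patient_id, each = config$n_visits),
    visit_index = rep(seq_len(config$n_visits), n),
    time_years = as.vector(t(times)),
    age_baseline = rep(age, each = config$n_visits),
    sex = rep(sex, each = config$n_visits),
    rate = rep(rate, each = config$n_visits),
    gfr0 = rep(gfr0, each = config$n_visits)
  )
  visits$gfr_true <- if (config$trajectory == "linear_pct") {
    visits$gfr0 * (1 + visits$rate * visits$time_years / 100)
  } else {
    visits$gfr0 * (1 + visits$rate / 100)^visits$time_years
  }
  if (any(visits$gfr_true <= 0)) {
    abort("configuration drives true GFR to <= 0; equation inversion undefined")
  }

  scr_true <- invert_egfr(visits$gfr_true, visits$age_baseline, visits$sex,
                          method = "CKD_EPI_CR")
  scys_true <- invert_egfr(visits$gfr_true, visits$age_baseline, visits$sex,
                           method = "CKD_EPI_CYS")
  visits$scr_mg_dl <- scr_true *
    .lognorm_noise(nrow(visits), config$measurement_cv_creatinine)
  visits$scys_mg_l <- scys_true *
    .lognorm_noise(nrow(visits), config$measurement_cv_cystatin)

  # ---- peptide matrix (one baseline urine sample per patient) ----
  p <- config$n_peptides
  if (is.null(peptide_truth)) {
    peptide_id <- sprintf("pep_%04d", seq_len(p))
    mu <- rnorm(p, 12, 1.5)        # mean log-intensity (natural log, a.u.)
    sigma <- runif(p, 0.7, 1.3)    # per-peptide log-scale SD

    differential <- rep(FALSE, p)
    differential[sample.int(p, config$n_differential)] <- TRUE
    direction <- rep(NA_character_, p)
    idx_diff <- which(differential)
    n_down <- round(config$frac_down * length(idx_diff))
    if (length(idx_diff)) {
      down <- sample(idx_diff, n_down)
      direction[down] <- "DOWN"
      direction[setdiff(idx_diff, down)] <- "UP"
    }
  } else {
    pt <- as_tibble(peptide_truth)
    need <- c("peptide_id", "differential", "direction", "mu", "sigma")
    if (!all(need %in% names(pt)) || nrow(pt) != p) {
      abort("`peptide_truth` must carry mu/sigma/flags for exactly n_peptides peptides")
    }
    peptide_id <- pt$peptide_id
    mu <- pt$mu; sigma <- pt$sigma
    differential <- pt$differential; direction <- pt$direction
  }

  # detection probability logistic in centred mean log-intensity, with the
  # intercept calibrated so mean(p_det) hits detection_base_freq exactly
  if (config$detection_base_freq >= 1) {
    p_det <- rep(1, p)
  } else if (config$detection_base_freq <= 0) {
    p_det <- rep(0, p)
  } else {
    z <- mu - mean(mu)
    a <- uniroot(function(a) mean(plogis(a + z)) - config$detection_base_freq,
                 c(-30, 30), tol = 1e-12)$root
    p_det <- plogis(a + z)
  }

  decl <- status == "decliner"
  shift <- ifelse(differential,
                  ifelse(direction == "DOWN", -1, 1) * config$effect_size * sigma,
                  0)
  # detection follows the (group-shifted) mean log-intensity, so a
  # down-regulated peptide is also detected less often in decliners
  if (config$detection_base_freq >= 1 || config$detection_base_freq <= 0) {
    p_det_mat <- matrix(rep(p_det, each = n), n, p)
  } else {
    z <- mu - mean(mu)
    p_det_mat <- plogis(matrix(rep(a + z, each = n), n, p) +
                          outer(decl, shift))
  }
  det <- matrix(rbinom(n * p, 1, p_det_mat), n, p)
  logint <- matrix(rnorm(n * p,
                         mean = rep(mu, each = n) + outer(decl, shift),
                         sd = rep(sigma, each = n)),
                   n, p)
  intensity <- det * exp(logint)
  colnames(intensity) <- peptide_id
  peptides <- dplyr::bind_cols(tibble(patient_id = patient_id),
                               as_tibble(intensity))

  truth <- list(
    patients = tibble(patient_id = patient_id, status = status,
                      true_rate = rate, baseline_gfr = gfr0),
    gfr = visits[, c("patient_id", "visit_index", "time_years", "gfr_true")],
    peptides = tibble(peptide_id = peptide_id, differential = differential,
                      direction = direction, mu = mu, sigma = sigma)
  )
  visits <- visits[, c("patient_id", "visit_index", "time_years",
                       "age_baseline", "sex", "scr_mg_dl", "scys_mg_l")]
  structure(list(visits = visits, peptides = peptides, truth = truth,
                 config = config),
            class = "nephro_cohort")
}

#' Write a simulated cohort to disk
#'
#' Writes the visit table as CSV, the peptide matrix as TSV (samples in
#' rows, header row of peptide ids) and the ground truth as JSON.
#'
#' @param cohort A `"nephro_cohort"` from [simulate_cohort()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, a named character vector of the three file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "nephro_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    visits = file.path(dir, "visits.csv"),
    peptides = file.path(dir, "peptides.tsv"),
    truth = file.path(dir, "ground_truth.json")
  )
  readr::write_csv(cohort$visits, paths["visits"])
  readr::write_tsv(cohort$peptides, paths["peptides"])
  jsonlite::write_json(cohort$truth, paths["truth"], dataframe = "columns",
                       digits = NA)
  invisible(paths)
}
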
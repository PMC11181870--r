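#' The four eGFR estimating equations
#'
#' Returns the identifiers of the glomerular filtration rate estimating
#' equations supported by the package: the CKD-EPI 2009 creatinine equation
#' (`CKD_EPI_CR`), the CKD-EPI 2012 cystatin C equation (`CKD_EPI_CYS`), the
#' CKD-EPI 2012 combined creatinine-cystatin equation (`CKD_EPI_CR_CYS`), and
#' the EKFC cystatin C equation (`EKFC_CYS`). The 2021 race-free CKD-EPI
#' refits are deliberately not included.
#'
#' @return Character vector of the four method identifiers.
#' @export
egfr_methods <- function() {
  c("CKD_EPI_CR", "CKD_EPI_CYS", "CKD_EPI_CR_CYS", "EKFC_CYS")
}

# Sex-specific constants of the CKD-EPI equations. kappa / alpha are the
# creatinine knot and below-knot exponent; the cystatin knot is 0.8 mg/L for
# both sexes.
.ckd_epi_const <- list(
  CKD_EPI_CR = list(
    intercept = 141, age_base = 0.993, female = 1.018, black = 1.159,
    kappa = c(F = 0.7, M = 0.9), alpha = c(F = -0.329, M = -0.411),
    exp_hi = -1.209
  ),
  CKD_EPI_CYS = list(
    intercept = 133, age_base = 0.996, female = 0.932, black = 1,
    kappa_cys = 0.8, exp_lo_cys = -0.499, exp_hi_cys = -1.328
  ),
  CKD_EPI_CR_CYS = list(
    intercept = 135, age_base = 0.995, female = 0.969, black = 1.08,
    kappa = c(F = 0.7, M = 0.9), alpha = c(F = -0.248, M = -0.207),
    exp_hi = -0.601,
    kappa_cys = 0.8, exp_lo_cys = -0.375, exp_hi_cys = -0.711
  )
)

.check_sex <- function(sex) {
  if (!all(sex %in% c("F", "M"))) {
    abort("`sex` must be coded \"F\" or \"M\".")
  }
}

.check_analyte <- function(x, name, method) {
  if (is.null(x) || all(is.na(x))) {
    abort(sprintf("method %s requires `%s` (missing input)", method, name))
  }
  if (any(!is.finite(x) | x <= 0)) {
    abort(sprintf("`%s` must be finite and > 0 (got a non-positive value)", name))
  }
}

# Demographic multiplier (everything except the analyte power terms).
.egfr_demo_factor <- function(method, age, sex, race_black, ekfc_q) {
  if (method == "EKFC_CYS") {
    f <- rep(107.3, length(age))
    older <- age > 40
    f[older] <- f[older] * 0.990^(age[older] - 40)
    return(f)
  }
  k <- .ckd_epi_const[[method]]
  f <- k$intercept * k$age_base^age
  f[sex == "F"] <- f[sex == "F"] * k$female
  if (race_black) f <- f * k$black
  f
}

# Piecewise power term for one analyte: min(x/kappa,1)^lo * max(x/kappa,1)^hi
.knot_term <- function(x, kappa, exp_lo, exp_hi) {
  r <- x / kappa
  pmin(r, 1)^exp_lo * pmax(r, 1)^exp_hi
}

#' Compute estimated GFR
#'
#' Evaluates one of the four supported estimating equations. Units are fixed:
#' serum creatinine in mg/dL, serum cystatin C in mg/L, age in years; there is
#' no unit autodetection, and a missing required analyte raises an explicit
#' error rather than propagating `NA`.
#'
#' @param age Age in years (vectorized; must be > 0).
#' @param sex `"F"` or `"M"` (vectorized).
#' @param method One of [egfr_methods()].
#' @param scr Serum creatinine, mg/dL. Required for `CKD_EPI_CR` and
#'   `CKD_EPI_CR_CYS`.
#' @param scys Serum cystatin C, mg/L. Required for `CKD_EPI_CYS`,
#'   `CKD_EPI_CR_CYS` and `EKFC_CYS`.
#' @param race_black Apply the published Black race coefficient of the 2009
#'   creatinine (1.159) and 2012 combined (1.08) equations. Off by default;
#'   the 2012 cystatin and EKFC equations carry no race term.
#' @param ekfc_q Rescaling constant Q (mg/L) of the EKFC cystatin equation:
#'   the population median cystatin C of healthy adults. Either a single
#'   value (default 0.83, sex-independent) or a named vector `c(F = , M = )`
#'   for a sex-specific policy.
#'
#' @return Numeric vector of eGFR in mL/min/1.73 m^2.
#' @examples
#' compute_egfr(age = 65, sex = "F", method = "CKD_EPI_CR", scr = 1.1)
#' compute_egfr(age = 65, sex = "F", method = "EKFC_CYS", scys = 1.2)
#' @export
compute_egfr <- function(age, sex, method, scr = NULL, scys = NULL,
                         race_black = FALSE, ekfc_q = 0.83) {
  method <- match.arg(method, egfr_methods())
  .check_sex(sex)
  if (any(!is.finite(age) | age <= 0)) abort("`age` must be finite and > 0")
  n <- max(length(age), length(sex), length(scr), length(scys))
  age <- rep_len(age, n)
  sex <- rep_len(sex, n)

  if (method %in% c("CKD_EPI_CR", "CKD_EPI_CR_CYS")) {
    .check_analyte(scr, "scr", method)
    scr <- rep_len(scr, n)
  }
  if (method %in% c("CKD_EPI_CYS", "CKD_EPI_CR_CYS", "EKFC_CYS")) {
    .check_analyte(scys, "scys", method)
    scys <- rep_len(scys, n)
  }

  g <- .egfr_demo_factor(method, age, sex, race_black, ekfc_q)

  if (method == "EKFC_CYS") {
    q <- if (length(ekfc_q) > 1) unname(ekfc_q[sex]) else rep_len(ekfc_q, n)
    if (any(!is.finite(q) | q <= 0)) abort("`ekfc_q` must be positive")
    r <- scys / q
    return(g * ifelse(r < 1, r^(-0.322), r^(-1.132)))
  }

  k <- .ckd_epi_const[[method]]
  if (!is.null(k[["kappa"]])) {
    g <- g * .knot_term(scr, unname(k$kappa[sex]), unname(k$alpha[sex]), k$exp_hi)
  }
  if (!is.null(k[["kappa_cys"]])) {
    g <- g * .knot_term(scys, k$kappa_cys, k$exp_lo_cys, k$exp_hi_cys)
  }
  g
}

#' Invert an eGFR estimating equation
#'
#' Solves analytically for the analyte concentration that yields a target
#' eGFR, given age and sex. Each equation is a strictly decreasing piecewise
#' power function of its analyte, so the branch is selected by comparing the
#' target with the eGFR at the knot concentration and inverted in closed
#' form. For `CKD_EPI_CR_CYS` the equation is inverted for creatinine at a
#' supplied (fixed) cystatin value. Primarily simulator support:
#' `compute_egfr(invert_egfr(g)) == g` to within 1e-9 relative error.
#'
#' @inheritParams compute_egfr
#' @param target_gfr Desired eGFR, mL/min/1.73 m^2 (> 0).
#' @param scys For `CKD_EPI_CR_CYS` only: the cystatin C value (mg/L) held
#'   fixed while solving for creatinine.
#'
#' @return Analyte concentration: creatinine mg/dL for `CKD_EPI_CR` and
#'   `CKD_EPI_CR_CYS`, cystatin C mg/L for `CKD_EPI_CYS` and `EKFC_CYS`.
#' @export
invert_egfr <- function(target_gfr, age, sex, method, scys = NULL,
                        race_black = FALSE, ekfc_q = 0.83) {
  method <- match.arg(method, egfr_methods())
  .check_sex(sex)
  if (any(!is.finite(target_gfr) | target_gfr <= 0)) {
    abort("`target_gfr` must be finite and > 0")
  }
  n <- max(length(target_gfr), length(age), length(sex), length(scys))
  target_gfr <- rep_len(target_gfr, n)
  age <- rep_len(age, n)
  sex <- rep_len(sex, n)

  a <- .egfr_demo_factor(method, age, sex, race_black, ekfc_q)

  if (method == "EKFC_CYS") {
    q <- if (length(ekfc_q) > 1) unname(ekfc_q[sex]) else rep_len(ekfc_q, n)
    ratio <- target_gfr / a # = r^(-0.322) if r < 1 else r^(-1.132)
    r <- ifelse(ratio > 1, ratio^(1 / -0.322), ratio^(1 / -1.132))
    return(r * q)
  }

  k <- .ckd_epi_const[[method]]
  if (method == "CKD_EPI_CR_CYS") {
    .check_analyte(scys, "scys", method)
    scys <- rep_len(scys, n)
    a <- a * .knot_term(scys, k$kappa_cys, k$exp_lo_cys, k$exp_hi_cys)
  }
  if (method == "CKD_EPI_CYS") {
    kappa <- rep_len(k$kappa_cys, n)
    exp_lo <- rep_len(k$exp_lo_cys, n)
    exp_hi <- rep_len(k$exp_hi_cys, n)
  } else {
    kappa <- unname(k$kappa[sex])
    exp_lo <- unname(k$alpha[sex])
    exp_hi <- rep_len(k$exp_hi, n)
  }
  # target/a = min(x/kappa,1)^exp_lo * max(x/kappa,1)^exp_hi; at the knot the
  # ratio is 1, and both exponents are negative, so ratio > 1 selects the
  # below-knot branch.
  ratio <- target_gfr / a
  r <- ifelse(ratio > 1, ratio^(1 / exp_lo), ratio^(1 / exp_hi))
  r * kappa
}

#' Append eGFR columns to a visit table
#'
#' Tidy wrapper around [compute_egfr()]: takes a clinical visit table with
#' columns `age_baseline`, `sex`, `scr_mg_dl`, `scys_mg_l` and appends one
#' `egfr_<method>` column per requested method. Age is treated as fixed at
#' its baseline value over the follow-up.
#'
#' @param visits Data frame of clinical visits (one row per patient visit).
#' @param methods Character vector of methods, default all four.
#' @inheritParams compute_egfr
#' @return The input as a tibble with one additional eGFR column per method.
#' @export
add_egfr <- function(visits, methods = egfr_methods(), race_black = FALSE,
                     ekfc_q = 0.83) {
  methods <- match.arg(methods, egfr_methods(), several.ok = TRUE)
  visits <- as_tibble(visits)
  need <- c("age_baseline", "sex")
  if (any(methods %in% c("CKD_EPI_CR", "CKD_EPI_CR_CYS"))) need <- c(need, "scr_mg_dl")
  if (any(methods != "CKD_EPI_CR"))                        need <- c(need, "scys_mg_l")
  missing_cols <- setdiff(need, names(visits))
  if (length(missing_cols)) {
    abort(paste0("`visits` lacks required columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  for (m in methods) {
    visits[[paste0("egfr_", m)]] <- compute_egfr(
      age = visits$age_baseline, sex = visits$sex, method = m,
      scr = visits$scr_mg_dl %||% NULL, scys = visits$scys_mg_l %||% NULL,
      race_black = race_black, ekfc_q = ekfc_q
    )
  }
  visits
}

`%||%` <- function(a, b) if (is.null(a)) b else a
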
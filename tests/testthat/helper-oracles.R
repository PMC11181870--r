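# Brute-force oracles, independent of the package implementation.

# Exact two-sided rank-sum p by enumeration of all C(n1+n2, n1) group
# assignments of the pooled ranks (midranks for ties).
bf_wilcox_p <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  n1 <- length(x)
  idx <- utils::combn(length(pooled), n1)
  sums <- apply(idx, 2, function(ix) sum(r[ix]))
  obs <- sum(r[seq_len(n1)])
  centre <- n1 * (length(pooled) + 1) / 2
  # two-sided: mass at least as far from the null mean as observed
  mean(abs(sums - centre) >= abs(obs - centre) - 1e-9)
}

# AUC by direct enumeration of positive-negative pairs (ties count 1/2).
bf_auc <- function(scores, is_pos) {
  x <- scores[is_pos]
  y <- scores[!is_pos]
  cmp <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Naive leave-one-out decision scores: refit for every single sample,
# no support-vector shortcut (used to validate the fast path).
bf_loo_scores <- function(z, y, C, gamma, positive = "UNCONTROLLED") {
  vapply(seq_len(nrow(z)), function(i) {
    fit <- e1071::svm(z[-i, , drop = FALSE], y[-i], type = "C-classification",
                      kernel = "radial", cost = C, gamma = gamma,
                      scale = FALSE, fitted = FALSE)
    dv <- attr(predict(fit, z[i, , drop = FALSE], decision.values = TRUE),
               "decision.values")
    sgn <- if (startsWith(colnames(dv)[1], positive)) 1 else -1
    sgn * dv[1, 1]
  }, numeric(1))
}

# Small fully-detected peptide tibble with a known group split.
make_two_group_peptides <- function(n_per_group = 20, n_pep = 10,
                                    shift = 0, seed = 42) {
  set.seed(seed)
  n <- 2 * n_per_group
  ids <- sprintf("S%03d", seq_len(n))
  grp <- rep(c("UNCONTROLLED", "CONTROLLED"), each = n_per_group)
  m <- matrix(exp(rnorm(n * n_pep, 10, 1)), n, n_pep)
  m[grp == "UNCONTROLLED", ] <- m[grp == "UNCONTROLLED", ] * exp(shift)
  colnames(m) <- sprintf("pep_%04d", seq_len(n_pep))
  list(
    peptides = dplyr::bind_cols(tibble::tibble(patient_id = ids),
                                tibble::as_tibble(m)),
    labels = tibble::tibble(patient_id = ids, label = grp)
  )
}
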
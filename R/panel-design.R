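# Exhaustive tau^2-best subset of size k (enumeration; used for certifying
# constructed instances — independent of the branch-and-bound path).
enumerate_best_subset <- function(x, groups, k) {
  cols <- utils::combn(ncol(x), k)
  taus <- apply(cols, 2, function(cc)
    tau_squared(x[, cc, drop = FALSE], groups)$tau_squared)
  cols[, which.max(taus)]
}

#' Generate a certified train/test cohort for minimal-panel evaluation
#'
#' Builds a two-cohort design (a training set and an independently drawn
#' test set from the same distribution) in which `k_signal` probes jointly
#' carry the group separation. The planted minimal panel size is
#' certified, not assumed: candidate cohorts are drawn at successive
#' sub-seeds until exhaustive subset enumeration confirms that for every
#' size below `k_signal` the tau^2-best subset fails to linearly separate
#' the training groups, while the tau^2-best `k_signal`-subset separates
#' them — the same smallest-sufficient-panel rule that
#' [minimal_panel()] applies, evaluated by enumeration instead of branch
#' and bound.
#'
#' The signal probes share `k_signal - 1` latent noise factors (the
#' methylation analogue of cell-composition or technical confounders):
#' each signal probe alone is too noisy to separate the groups, and no
#' subset smaller than `k_signal` can cancel all factors, but the full
#' `k_signal`-probe discriminant combination cancels them and separates
#' cleanly — which is also why an independently drawn test cohort is
#' classified essentially without error.
#'
#' @param n_train_fp,n_train_sd Training cohort sizes (default 12 / 10).
#' @param n_test_fp,n_test_sd Test cohort sizes (default 4 / 7).
#' @param k_signal Number of signal probes = certified panel size.
#' @param n_candidates Total candidate probes (signal + noise).
#' @param delta_beta Group shift per signal probe.
#' @param factor_sd Loading scale of the shared latent noise factors.
#' @param noise_sd Residual per-probe beta noise after factor noise.
#' @param seed Base seed; sub-seeds `seed, seed + 1, ...` are tried until
#'   certification succeeds (bounded by `max_tries`).
#' @param max_tries Maximum sub-seeds to try.
#' @return List: `train`, `test` (beta matrices over the candidate
#'   probes), `groups_train`, `groups_test`, `signal_probes`, `k_signal`,
#'   `seed_used`.
#' @export
generate_panel_design_cohort <- function(n_train_fp = 12, n_train_sd = 10,
                                         n_test_fp = 4, n_test_sd = 7,
                                         k_signal = 4, n_candidates = 20,
                                         delta_beta = 0.15,
                                         factor_sd = 0.10, noise_sd = 0.02,
                                         seed = 1L, max_tries = 50L) {
  stopifnot(k_signal >= 1, n_candidates >= k_signal)
  n_factors <- k_signal - 1
  draw <- function(s) {
    set.seed(s)
    g_tr <- c(rep("FP", n_train_fp), rep("SD", n_train_sd))
    g_te <- c(rep("FP", n_test_fp), rep("SD", n_test_sd))
    base <- stats::runif(n_candidates, 0.3, 0.6)
    loadings <- if (n_factors > 0) {
      l <- matrix(stats::rnorm(k_signal * n_factors), k_signal, n_factors)
      # loadings orthogonal to the all-ones signal direction: the full
      # panel's equal-weight contrast is then factor-free, while any
      # probe subset keeps a factor-noise component
      ones <- rep(1, k_signal)
      l <- l - ones %*% crossprod(ones, l) / k_signal
      sweep(l, 2, sqrt(colSums(l^2)), "/") * factor_sd * sqrt(k_signal)
    } else NULL
    marg_sd <- sqrt(noise_sd^2 + n_factors * factor_sd^2)
    gen <- function(g) {
      n <- length(g)
      m <- matrix(rep(base, each = n), n, n_candidates)
      sig <- seq_len(k_signal)
      m[g == "FP", sig] <- m[g == "FP", sig] + delta_beta
      if (n_factors > 0) {
        f <- matrix(stats::rnorm(n * n_factors), n, n_factors)
        m[, sig] <- m[, sig] + f %*% t(loadings)
      }
      m[, sig] <- m[, sig] +
        matrix(stats::rnorm(n * k_signal, 0, noise_sd), n, k_signal)
      noise_cols <- setdiff(seq_len(n_candidates), sig)
      m[, noise_cols] <- m[, noise_cols] +
        matrix(stats::rnorm(n * length(noise_cols), 0, marg_sd),
               n, length(noise_cols))
      m <- pmin(pmax(m, 0), 1)
      dimnames(m) <- list(sprintf("%s%02d", ifelse(g == "FP", "F", "S"),
                                  seq_len(n)),
                          sprintf("cand%02d", seq_len(n_candidates)))
      m
    }
    list(train = gen(g_tr), test = gen(g_te),
         groups_train = g_tr, groups_test = g_te)
  }
  separates <- function(x, groups) {
    fit <- lda_fit(x, groups)
    all(lda_predict(fit, x)$class == groups)
  }
  for (s in seed + seq_len(max_tries) - 1L) {
    inst <- draw(s)
    ok <- TRUE
    for (k in seq_len(k_signal - 1)) {
      cc <- enumerate_best_subset(inst$train, inst$groups_train, k)
      if (separates(inst$train[, cc, drop = FALSE], inst$groups_train)) {
        ok <- FALSE
        break
      }
    }
    if (!ok) next
    cc <- enumerate_best_subset(inst$train, inst$groups_train, k_signal)
    # the tau^2-best k_signal subset must be the planted signal set itself
    # and must separate the training groups
    if (!identical(sort(cc), seq_len(k_signal))) next
    if (!separates(inst$train[, cc, drop = FALSE], inst$groups_train)) next
    inst$signal_probes <- colnames(inst$train)[seq_len(k_signal)]
    inst$k_signal <- as.integer(k_signal)
    inst$seed_used <- s
    return(inst)
  }
  stop("no certified instance found in ", max_tries, " tries; ",
       "adjust delta_beta/noise_sd")
}
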
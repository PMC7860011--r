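#' Count methylation extremes per cohort
#'
#' Counts beta observations above the hypermethylation threshold and below
#' the hypomethylation threshold in each group, either over all
#' sample-by-probe cells (`mode = "observation"`, the histogram-pooling
#' convention) or over per-probe cohort means (`mode = "probe_mean"`).
#' Reports the percent excess of the FP cohort over the SD cohort in both
#' tails: `(count_FP / count_SD - 1) * 100`.
#'
#' @param beta Samples x probes beta matrix.
#' @param groups Two-level per-sample labels (FP/SD order preferred).
#' @param hi Hypermethylation threshold, counted strictly above (default 0.8).
#' @param lo Hypomethylation threshold, counted strictly below (default 0.1).
#' @param mode `"observation"` or `"probe_mean"`.
#' @return List with `counts` (tibble: group, n_high, n_low, n_total) and
#'   `percent_diff` (named: high, low), FP relative to SD.
#' @export
count_methylation_extremes <- function(beta, groups, hi = 0.8, lo = 0.1,
                                       mode = c("observation", "probe_mean")) {
  mode <- match.arg(mode)
  stopifnot(hi > lo)
  groups <- factor(groups)
  if (nlevels(groups) != 2 || any(table(groups) == 0)) {
    stop("need two non-empty cohorts")
  }
  lv <- if (all(c("FP", "SD") %in% levels(groups))) c("FP", "SD") else levels(groups)
  count_one <- function(g) {
    x <- beta[groups == g, , drop = FALSE]
    if (mode == "probe_mean") x <- colMeans(x)
    c(n_high = sum(x > hi), n_low = sum(x < lo), n_total = length(x))
  }
  c1 <- count_one(lv[1])
  c2 <- count_one(lv[2])
  counts <- tibble::tibble(group = lv,
                           n_high = unname(c(c1["n_high"], c2["n_high"])),
                           n_low = unname(c(c1["n_low"], c2["n_low"])),
                           n_total = unname(c(c1["n_total"], c2["n_total"])))
  list(counts = counts,
       percent_diff = c(high = extremes_percent_diff(c1["n_high"], c2["n_high"]),
                        low = extremes_percent_diff(c1["n_low"], c2["n_low"])))
}

#' Percent excess of one extreme count over another
#'
#' `(count_fp / count_sd - 1) * 100`, the scale on which cohort-level
#' hyper/hypomethylation excess is reported.
#'
#' @param count_fp,count_sd Nonnegative counts (`count_sd > 0`).
#' @return Percent difference (e.g. `20.2` for a 20.2% excess).
#' @export
extremes_percent_diff <- function(count_fp, count_sd) {
  stopifnot(count_sd > 0)
  unname((count_fp / count_sd - 1) * 100)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test: exact when `min(n) <= 8` and there are no
#' ties, otherwise the normal approximation with tie correction (no
#' continuity correction). The U statistic counts pairs where an `x`
#' observation exceeds a `y` observation (ties count half).
#'
#' @param x,y Nonempty numeric vectors.
#' @return List: `U`, `p`.
#' @export
mann_whitney_u <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  r <- rank(c(x, y))
  u <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  has_ties <- anyDuplicated(c(x, y)) > 0
  exact <- min(length(x), length(y)) <= 8 && !has_ties
  p <- stats::wilcox.test(x, y, exact = exact, correct = FALSE,
                          alternative = "two.sided")$p.value
  list(U = unname(u), p = p)
}

#' Pearson chi-square test for a 2x2 table
#'
#' The uncorrected Pearson statistic
#' `chi2 = n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` with p from the
#' chi-square distribution on one degree of freedom. No Yates continuity
#' correction is applied.
#'
#' @param table 2x2 matrix of nonnegative integer counts with positive
#'   margins.
#' @return List: `chi2`, `p`.
#' @examples
#' chi_square_2x2(rbind(c(9, 7), c(3, 14)))$p # ~0.021
#' @export
chi_square_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero margin in 2x2 table")
  }
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  n <- a + b + c + d
  chi2 <- n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  list(chi2 = unname(chi2), p = unname(stats::pchisq(chi2, df = 1,
                                                     lower.tail = FALSE)))
}

# Negative log posterior and gradient for logistic regression with
# independent Cauchy priors on standardized coefficients.
neglogpost <- function(b, X, y, scales) {
  eta <- drop(X %*% b)
  nll <- sum(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta)
  nlp <- sum(log1p((b / scales)^2)) # Cauchy log density up to constants
  nll + nlp
}
neglogpost_grad <- function(b, X, y, scales) {
  mu <- stats::plogis(drop(X %*% b))
  g_ll <- drop(crossprod(X, mu - y))
  g_pr <- 2 * b / (scales^2 + b^2)
  g_ll + g_pr
}

#' Bayesian logistic regression by Cauchy-prior MAP
#'
#' Penalized maximum a-posteriori logistic regression with independent
#' Student-t priors with one degree of freedom (Cauchy) on the
#' coefficients — the weakly informative default that keeps estimates
#' finite under the complete separation that small two-group cohorts
#' produce by chance. Continuous covariates are standardized to mean 0 and
#' sd 0.5, binary covariates shifted to mean 0; the prior scale is
#' `prior_scale` for covariates and 10 for the intercept. Wald standard
#' errors come from the Hessian of the negative log posterior at the mode,
#' and coefficients are reported back on the original covariate scale.
#'
#' @param design Data frame of covariates (numeric or two-valued).
#' @param outcome Two-class vector (factor, character or 0/1).
#' @param prior_scale Cauchy scale for standardized coefficients
#'   (default 2.5).
#' @param max_iter Optimizer iteration cap.
#' @return Tibble: `term`, `estimate`, `std_error`, `z`, `p`,
#'   `significant` (p < 0.05), plus attribute `prior_scale`.
#' @export
bayes_logistic <- function(design, outcome, prior_scale = 2.5,
                           max_iter = 500) {
  design <- as.data.frame(design)
  stopifnot(ncol(design) >= 1)
  y <- if (is.numeric(outcome)) outcome else
    as.integer(factor(outcome)) - 1L
  if (length(unique(y)) != 2) stop("outcome must have both classes")
  cc <- stats::complete.cases(design, y)
  design <- design[cc, , drop = FALSE]
  y <- y[cc]
  X0 <- stats::model.matrix(~., data = design)
  # standardize non-intercept columns: binary -> center; continuous ->
  # center and scale to sd 0.5 (so prior_scale means the same across types)
  ctr <- rep(0, ncol(X0)); scl <- rep(1, ncol(X0))
  for (j in 2:ncol(X0)) {
    v <- X0[, j]
    ctr[j] <- mean(v)
    if (length(unique(v)) > 2) scl[j] <- stats::sd(v) / 0.5
    X0[, j] <- (v - ctr[j]) / scl[j]
  }
  scales <- c(10, rep(prior_scale, ncol(X0) - 1))
  opt <- stats::optim(rep(0, ncol(X0)), fn = neglogpost,
                      gr = neglogpost_grad,
                      X = X0, y = y, scales = scales,
                      method = "BFGS", hessian = TRUE,
                      control = list(maxit = max_iter, reltol = 1e-12))
  if (opt$convergence != 0) {
    stop("MAP optimization did not converge (code ", opt$convergence,
         "): ", opt$message)
  }
  se_std <- sqrt(diag(solve(opt$hessian)))
  b_std <- opt$par
  # back to original covariate scale; intercept absorbs the centering
  b <- b_std / scl
  b[1] <- b_std[1] - sum(b_std[-1] * ctr[-1] / scl[-1])
  se <- se_std / scl
  se[1] <- sqrt(drop(t(c(1, -ctr[-1] / scl[-1])) %*%
                       solve(opt$hessian) %*% c(1, -ctr[-1] / scl[-1])))
  z <- b / se
  p <- 2 * stats::pnorm(-abs(z))
  out <- tibble::tibble(term = colnames(X0), estimate = b, std_error = se,
                        z = z, p = p, significant = p < 0.05)
  attr(out, "prior_scale") <- prior_scale
  out
}
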
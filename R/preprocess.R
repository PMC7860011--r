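#' Exclude failed samples and probes by detection p-value
#'
#' Applies the standard two-stage array QC: first samples whose fraction of
#' probes with detection p above `p_thresh` exceeds `sample_fail_frac` are
#' dropped, then probes failing in more than `probe_fail_frac` of the
#' remaining samples are dropped. Surviving beta values are untouched.
#'
#' @param beta Samples x probes beta matrix with dimnames.
#' @param detp Detection p-value matrix, conformal with `beta`.
#' @param p_thresh Detection p-value above which a measurement counts as
#'   failed (default 0.1).
#' @param probe_fail_frac Maximum tolerated fraction of failed samples per
#'   probe (default 0.05).
#' @param sample_fail_frac Maximum tolerated fraction of failed probes per
#'   sample (default 0.1).
#' @return A list with the filtered `beta` matrix and `report`, a list with
#'   tibbles `excluded_samples` (id, fraction failed) and `excluded_probes`
#'   (id, reason) plus `n_evaluable`, the count of surviving probes.
#' @export
filter_by_detection <- function(beta, detp, p_thresh = 0.1,
                                probe_fail_frac = 0.05,
                                sample_fail_frac = 0.1) {
  stopifnot(all(dim(beta) == dim(detp)),
            p_thresh > 0, p_thresh < 1)
  failed <- detp > p_thresh
  samp_frac <- rowMeans(failed)
  drop_samp <- samp_frac > sample_fail_frac
  if (all(drop_samp)) stop("empty cohort: all samples exceed sample_fail_frac")
  keep_s <- !drop_samp
  probe_frac <- colMeans(failed[keep_s, , drop = FALSE])
  drop_probe <- probe_frac > probe_fail_frac
  report <- list(
    excluded_samples = tibble::tibble(
      sample_id = rownames(beta)[drop_samp],
      fraction_failed = unname(samp_frac[drop_samp])),
    excluded_probes = tibble::tibble(
      probe_id = colnames(beta)[drop_probe],
      reason = sprintf("detection p > %g in %.1f%% of samples",
                       p_thresh, 100 * probe_frac[drop_probe])),
    n_evaluable = sum(!drop_probe)
  )
  list(beta = beta[keep_s, !drop_probe, drop = FALSE], report = report)
}

# 3-state beta-mixture EM with k-means initialization and method-of-moments
# M-step. States are kept ordered by mean (unmethylated < hemi < methylated).
# Convergence: relative log-likelihood change below tol.
fit_beta_mixture <- function(x, tol = 1e-5, max_iter = 1000) {
  x <- pmin(pmax(x, 1e-4), 1 - 1e-4)
  km <- stats::kmeans(x, centers = sort(c(0.1, 0.5, 0.9)), iter.max = 50)
  ord <- order(km$centers)
  z <- matrix(0, length(x), 3)
  z[cbind(seq_along(x), match(km$cluster, ord))] <- 1
  a <- b <- w <- numeric(3)
  ll_old <- -Inf
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    for (k in 1:3) {
      wk <- z[, k]
      sw <- sum(wk)
      w[k] <- sw / length(x)
      m <- sum(wk * x) / sw
      v <- sum(wk * (x - m)^2) / sw
      v <- max(v, 1e-6)
      # method-of-moments for Beta(a, b)
      common <- m * (1 - m) / v - 1
      common <- max(common, 1e-3)
      a[k] <- max(m * common, 1e-2)
      b[k] <- max((1 - m) * common, 1e-2)
    }
    dens <- vapply(1:3, function(k) w[k] * stats::dbeta(x, a[k], b[k]),
                   numeric(length(x)))
    tot <- rowSums(dens)
    tot[tot < 1e-300] <- 1e-300
    z <- dens / tot
    ll <- sum(log(tot))
    trace <- c(trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (1 + abs(ll))) {
      # ties in state assignment resolved toward the lower-mean state
      st <- max.col(z, ties.method = "first")
      return(list(a = a, b = b, w = w, state = st, loglik = ll, iter = it))
    }
    ll_old <- ll
  }
  stop("beta-mixture EM did not converge after ", max_iter,
       " iterations; log-likelihood trace tail: ",
       paste(signif(utils::tail(trace, 5), 8), collapse = ", "))
}

#' BMIQ intra-sample normalization of type II probes
#'
#' Beta-mixture quantile normalization for a single sample: fits a 3-state
#' beta mixture (unmethylated / hemimethylated / methylated) separately to
#' the type I and type II probes, then quantile-maps the type II
#' unmethylated and methylated states onto the corresponding type I state
#' distributions; the middle (hemimethylated) state is carried over by a
#' monotone linear interpolation between the two mapped boundary states.
#' Type I probes are returned unchanged.
#'
#' @param beta_row Numeric beta vector for one sample.
#' @param design_type Character vector of "I"/"II" probe design labels,
#'   aligned with `beta_row`.
#' @param min_probes Minimum probes required per design type (default 100).
#' @return Normalized beta vector, same length and order; values in `[0, 1]`
#'   and monotone non-decreasing within the type II probe set.
#' @export
bmiq_normalize <- function(beta_row, design_type, min_probes = 100) {
  stopifnot(length(beta_row) == length(design_type),
            all(design_type %in% c("I", "II")))
  i1 <- design_type == "I"
  i2 <- design_type == "II"
  if (sum(i1) < min_probes || sum(i2) < min_probes) {
    stop("need at least ", min_probes, " probes of each design type")
  }
  fit1 <- fit_beta_mixture(beta_row[i1])
  fit2 <- fit_beta_mixture(beta_row[i2])
  x2 <- pmin(pmax(beta_row[i2], 1e-4), 1 - 1e-4)
  st2 <- fit2$state
  out2 <- x2

  # U state: map via type II CDF -> type I quantile function
  u <- st2 == 1
  if (any(u)) {
    p <- stats::pbeta(x2[u], fit2$a[1], fit2$b[1])
    out2[u] <- stats::qbeta(p, fit1$a[1], fit1$b[1])
  }
  # M state likewise
  m <- st2 == 3
  if (any(m)) {
    p <- stats::pbeta(x2[m], fit2$a[3], fit2$b[3])
    out2[m] <- stats::qbeta(p, fit1$a[3], fit1$b[3])
  }
  # H state: linear interpolation between mapped state boundaries
  h <- st2 == 2
  if (any(h)) {
    lo_src <- if (any(u)) max(x2[u]) else min(x2[h])
    hi_src <- if (any(m)) min(x2[m]) else max(x2[h])
    lo_dst <- if (any(u)) max(out2[u]) else lo_src
    hi_dst <- if (any(m)) min(out2[m]) else hi_src
    if (hi_src <= lo_src) {
      out2[h] <- x2[h]
    } else {
      sc <- (hi_dst - lo_dst) / (hi_src - lo_src)
      out2[h] <- lo_dst + (x2[h] - lo_src) * sc
    }
  }
  out <- beta_row
  out[i2] <- pmin(pmax(out2, 0), 1)
  out
}

#' Apply BMIQ normalization to every sample of a beta matrix
#'
#' @param beta Samples x probes beta matrix.
#' @param annotation Probe manifest tibble with `probe_id` and `design_type`.
#' @param min_probes Passed to [bmiq_normalize()].
#' @return Normalized beta matrix of the same shape.
#' @export
bmiq_normalize_matrix <- function(beta, annotation, min_probes = 100) {
  dt <- annotation$design_type[match(colnames(beta), annotation$probe_id)]
  if (anyNA(dt)) stop("probes missing from annotation: ",
                      paste(utils::head(colnames(beta)[is.na(dt)], 5),
                            collapse = ", "))
  out <- t(apply(beta, 1, bmiq_normalize, design_type = dt,
                 min_probes = min_probes))
  dimnames(out) <- dimnames(beta)
  out
}

logit_clamp <- function(beta, eps = 1e-3) {
  stats::qlogis(pmin(pmax(beta, eps), 1 - eps))
}

#' Remove batch effects from a beta matrix with ComBat
#'
#' Maps beta values to M-values (logit with clamping at `1e-3`), removes
#' per-probe batch location/scale effects with the parametric
#' empirical-Bayes scheme of ComBat while protecting the group effect, and
#' maps back to the beta scale. With a single batch the input is returned
#' unchanged.
#'
#' @param beta Samples x probes beta matrix.
#' @param batch Per-sample batch (plate) labels.
#' @param covariates Optional per-sample data frame of covariates to protect
#'   (typically the FP/SD group); categorical columns are expanded via
#'   `model.matrix`.
#' @return Batch-corrected beta matrix, same shape and dimnames.
#' @export
combat_correct <- function(beta, batch, covariates = NULL) {
  stopifnot(length(batch) == nrow(beta))
  batch <- factor(batch)
  if (any(table(batch) < 2)) stop("every batch needs at least 2 samples")
  if (nlevels(batch) == 1) return(beta)
  mod <- NULL
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    mod <- stats::model.matrix(~., data = covariates)
    # a batch perfectly aliased with a protected covariate is inestimable
    full <- cbind(mod, stats::model.matrix(~batch)[, -1, drop = FALSE])
    if (qr(full)$rank < ncol(full)) {
      stop("batch is confounded with a protected covariate; ",
           "batch effects are inestimable")
    }
  }
  m <- logit_clamp(beta)
  corrected <- sva::ComBat(dat = t(m), batch = batch, mod = mod,
                           par.prior = TRUE, prior.plots = FALSE)
  out <- stats::plogis(t(corrected))
  dimnames(out) <- dimnames(beta)
  out
}

#' Screen covariates for confounding via SVD components
#'
#' Computes the top `min(n_components, n_samples - 1)` left singular vectors
#' of the column-centered beta matrix and tests each component against each
#' sample covariate: Kruskal-Wallis for categorical variables, Spearman rank
#' correlation for numeric ones. Raw p-values are reported per component;
#' a variable is flagged as a potential confounder when any of its
#' associations survives at BH-adjusted q below `alpha`, which keeps the
#' screen-wide false-flag rate near `alpha` despite the many component
#' tests.
#'
#' @param beta Samples x probes beta matrix.
#' @param covariates Data frame of per-sample variables (categorical or
#'   numeric); constant columns are skipped with a warning.
#' @param n_components Maximum number of components (default 20).
#' @param alpha Flagging cutoff on the raw p-value (default 0.05).
#' @return Tibble with `component`, `variable`, `p`, `q` (BH within the full
#'   screen) and `flagged`.
#' @export
svd_confounder_screen <- function(beta, covariates, n_components = 20,
                                  alpha = 0.05) {
  stopifnot(nrow(beta) >= 3, nrow(beta) == nrow(covariates))
  x <- scale(beta, center = TRUE, scale = FALSE)
  k <- min(n_components, nrow(beta) - 1)
  sv <- svd(x, nu = k, nv = 0)
  comps <- sv$u[, seq_len(k), drop = FALSE]
  res <- list()
  for (v in names(covariates)) {
    col <- covariates[[v]]
    if (length(unique(col[!is.na(col)])) < 2) {
      warning("covariate '", v, "' is constant; skipped")
      next
    }
    numeric_v <- is.numeric(col)
    p <- vapply(seq_len(k), function(j) {
      ok <- !is.na(col)
      if (numeric_v) {
        stats::cor.test(comps[ok, j], col[ok], method = "spearman",
                        exact = FALSE)$p.value
      } else {
        stats::kruskal.test(comps[ok, j], factor(col[ok]))$p.value
      }
    }, numeric(1))
    res[[v]] <- tibble::tibble(component = seq_len(k), variable = v, p = p)
  }
  out <- dplyr::bind_rows(res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$flagged <- out$q < alpha
  out
}
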
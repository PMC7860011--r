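# Within-group (E) and total (T) scatter matrices for a two-group design,
# with a small ridge when near-singular. Returns log-determinants.
scatter_matrices <- function(x, g1) {
  x <- as.matrix(x)
  k <- ncol(x)
  mu <- colMeans(x)
  mu1 <- colMeans(x[g1, , drop = FALSE])
  mu2 <- colMeans(x[!g1, , drop = FALSE])
  E <- crossprod(sweep(x[g1, , drop = FALSE], 2, mu1)) +
    crossprod(sweep(x[!g1, , drop = FALSE], 2, mu2))
  Tm <- crossprod(sweep(x, 2, mu))
  ridge <- 1e-6 * sum(diag(Tm)) / k
  list(E = E, T = Tm, ridge = ridge)
}

log_det <- function(m) {
  d <- determinant(m, logarithm = TRUE)
  if (d$sign <= 0) return(-Inf)
  as.numeric(d$modulus)
}

#' Tau-squared separation of a CpG subset
#'
#' Computes Wilks' Lambda = det(E)/det(T) from the within-group scatter E
#' and total scatter T of the given probe subset, and the two-group
#' separation criterion tau^2 = 1 - Lambda (the general
#' `1 - Lambda^(1/l)` with `l = min(groups - 1, k) = 1` for two groups).
#' Larger tau^2 means better separation. A small ridge
#' (`1e-6 * trace/k`) is added to both scatters when T is near-singular.
#'
#' @param x Samples x k matrix of beta values for the candidate subset.
#' @param groups Two-level per-sample labels.
#' @return A `subset_score` list: `probe_ids`, `tau_squared`,
#'   `wilks_lambda`.
#' @examples
#' x <- matrix(c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9), ncol = 1)
#' tau_squared(x, rep(c("a", "b"), each = 3))$tau_squared # 0.9
#' @export
tau_squared <- function(x, groups) {
  x <- as.matrix(x)
  groups <- factor(groups)
  stopifnot(nlevels(groups) == 2, all(table(groups) >= 2), ncol(x) >= 1)
  g1 <- groups == levels(groups)[1]
  sc <- scatter_matrices(x, g1)
  ldT <- log_det(sc$T)
  ldE <- log_det(sc$E)
  if (!is.finite(ldT) || !is.finite(ldE)) {
    k <- ncol(x)
    sc$E <- sc$E + diag(sc$ridge, k)
    sc$T <- sc$T + diag(sc$ridge, k)
    ldT <- log_det(sc$T)
    ldE <- log_det(sc$E)
    if (!is.finite(ldT)) stop("degenerate subset: total scatter is singular")
  }
  lambda <- exp(ldE - ldT)
  lambda <- min(max(lambda, 0), 1)
  structure(list(probe_ids = colnames(x), tau_squared = 1 - lambda,
                 wilks_lambda = lambda), class = "subset_score")
}

#' Exact best CpG subset by branch and bound on tau-squared
#'
#' Finds, among `m` candidate probes, the subset of size `k` with globally
#' maximal tau^2 separation, by depth-first branch and bound. Pruning uses
#' the monotonicity of tau^2 under inclusion
#' (`tau^2(S) <= tau^2(S union R)` for any superset): a partial subset S
#' with remaining pool R is abandoned when the tau^2 of S union R — an
#' upper bound on every completion — cannot beat the incumbent. The result
#' is the exact optimum, identical to exhaustive enumeration.
#'
#' @param x Samples x m matrix of candidate-probe beta values.
#' @param groups Two-level per-sample labels.
#' @param k Subset size to select (`1 <= k <= m`).
#' @return A `subset_score` for the optimal subset, with probes in
#'   candidate order; ties between equal-tau^2 subsets are broken
#'   lexicographically by probe id.
#' @export
leaps_and_bounds_select <- function(x, groups, k) {
  x <- as.matrix(x)
  m <- ncol(x)
  if (k > m) stop("k (", k, ") exceeds the number of candidates (", m, ")")
  groups <- factor(groups)
  g1 <- groups == levels(groups)[1]
  if (is.null(colnames(x))) colnames(x) <- paste0("v", seq_len(m))

  # full-pool scatter matrices computed once; every subset and bound is a
  # pair of submatrix log-determinants from here on
  sc <- scatter_matrices(x, g1)
  Ef <- sc$E
  Tf <- sc$T
  tau_cols <- function(cols) {
    ldE <- log_det(Ef[cols, cols, drop = FALSE])
    ldT <- log_det(Tf[cols, cols, drop = FALSE])
    if (!is.finite(ldT) || !is.finite(ldE)) {
      r <- 1e-6 * sum(diag(Tf[cols, cols, drop = FALSE])) / length(cols)
      ldE <- log_det(Ef[cols, cols, drop = FALSE] + diag(r, length(cols)))
      ldT <- log_det(Tf[cols, cols, drop = FALSE] + diag(r, length(cols)))
      if (!is.finite(ldT)) stop("degenerate subset: total scatter is singular")
    }
    1 - min(max(exp(ldE - ldT), 0), 1)
  }

  # order candidates by individual tau^2 (descending) so good subsets are
  # found early and the monotone bound prunes aggressively
  singles <- vapply(seq_len(m), function(j) tau_cols(j), numeric(1))
  ord <- order(-singles, colnames(x))
  name_o <- colnames(x)[ord]

  best_tau <- -Inf
  best_cols <- integer(0)
  key_of <- function(cols) paste(sort(name_o[cols]), collapse = ",")
  best_key <- ""
  consider <- function(cols) {
    tv <- tau_cols(ord[cols])
    if (tv > best_tau + 1e-12 ||
        (abs(tv - best_tau) <= 1e-12 && key_of(cols) < best_key)) {
      best_tau <<- tv
      best_cols <<- cols
      best_key <<- key_of(cols)
    }
  }
  recurse <- function(chosen, pool) {
    need <- k - length(chosen)
    if (need == 0) {
      consider(chosen)
      return(invisible())
    }
    if (length(pool) < need) return(invisible())
    # monotone bound: tau^2 of any completion <= tau^2(chosen union pool)
    if (length(best_cols) &&
        tau_cols(ord[c(chosen, pool)]) < best_tau - 1e-12) {
      return(invisible())
    }
    for (i in seq_along(pool)) {
      recurse(c(chosen, pool[i]), pool[-seq_len(i)])
    }
  }
  recurse(integer(0), seq_len(m))
  sel <- sort(name_o[best_cols])
  tau_squared(x[, sel, drop = FALSE], groups)
}

#' Fit a two-class linear discriminant on a CpG panel
#'
#' Classic LDA with pooled within-class covariance: the discriminant
#' direction is `w = Sigma_pooled^{-1} (mu_FP - mu_SD)`, rescaled so the
#' projected pooled within-group variance is 1 and sign-fixed so the FP
#' centroid projects negative. The decision threshold on LD1 is the
#' midpoint of the projected class means shifted by the log prior ratio.
#'
#' @param x Samples x k beta matrix restricted to the panel probes.
#' @param groups Two-level labels; level "FP" (if present) is the positive
#'   class of the contrast.
#' @param priors Named class priors (default: observed frequencies).
#' @return A `panel_model` list: `probe_ids`, `weights`, `center` (grand
#'   mean), projected class means `proj_means`, `priors`, `threshold`,
#'   `log_det_pooled`.
#' @export
lda_fit <- function(x, groups, priors = NULL) {
  x <- as.matrix(x)
  groups <- factor(groups)
  if (nlevels(groups) != 2 || any(table(groups) == 0)) {
    stop("need two non-empty classes")
  }
  lv <- if (all(c("FP", "SD") %in% levels(groups))) c("FP", "SD") else levels(groups)
  g1 <- groups == lv[1]
  k <- ncol(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("v", seq_len(k))
  n1 <- sum(g1); n2 <- sum(!g1)
  mu1 <- colMeans(x[g1, , drop = FALSE])
  mu2 <- colMeans(x[!g1, , drop = FALSE])
  S <- (crossprod(sweep(x[g1, , drop = FALSE], 2, mu1)) +
          crossprod(sweep(x[!g1, , drop = FALSE], 2, mu2))) / (n1 + n2 - 2)
  if (!is.finite(log_det(S)) || rcond_safe(S) < 1e-10) {
    S <- S + diag(1e-6 * sum(diag(S)) / k, k)
  }
  w <- solve(S, mu1 - mu2)
  # unit projected within-class variance; identical class means leave a
  # null direction (w = 0), under which posteriors fall back to the priors
  wSw <- drop(t(w) %*% S %*% w)
  if (wSw > 1e-12) w <- w / sqrt(wSw) else w <- w * 0
  center <- (mu1 + mu2) / 2
  m1 <- drop(crossprod(w, mu1 - center))
  m2 <- drop(crossprod(w, mu2 - center))
  if (m1 > m2) { # FP centroid on the negative side
    w <- -w; m1 <- -m1; m2 <- -m2
  }
  if (is.null(priors)) {
    priors <- c(n1, n2) / (n1 + n2)
  } else {
    priors <- priors[lv] / sum(priors[lv])
  }
  names(priors) <- lv
  thr <- if (m1 == m2) 0 else
    (m1 + m2) / 2 - log(priors[1] / priors[2]) / (m1 - m2)
  structure(list(
    probe_ids = colnames(x), weights = stats::setNames(w, colnames(x)),
    center = center, proj_means = stats::setNames(c(m1, m2), lv),
    priors = priors, threshold = unname(thr),
    log_det_pooled = log_det(S), classes = lv
  ), class = "panel_model")
}

rcond_safe <- function(m) {
  tryCatch(1 / kappa(m, exact = FALSE), error = function(e) 0)
}

#' Classify samples with a fitted CpG panel model
#'
#' Projects beta values onto LD1 and converts to class probabilities via
#' the two-class Gaussian discriminant on the projected scale (unit
#' within-class variance). Predictions carry a confidence band: `"high"`
#' when the winning class probability is at least 0.95, `"low"` when it is
#' only above 0.5.
#'
#' @param model A `panel_model` from [lda_fit()].
#' @param x Samples x probes beta matrix containing the panel probes
#'   (matched by column name when present).
#' @return Tibble: `sample_id`, `ld1`, one probability column per class
#'   (`prob_fp`, `prob_sd` for FP/SD labels), `class`, `band`.
#' @export
lda_predict <- function(model, x) {
  x <- as.matrix(x)
  if (!is.null(colnames(x))) {
    missing <- setdiff(model$probe_ids, colnames(x))
    if (length(missing)) {
      stop("panel probes missing from input: ",
           paste(missing, collapse = ", "))
    }
    x <- x[, model$probe_ids, drop = FALSE]
  } else if (ncol(x) != length(model$probe_ids)) {
    stop("input has ", ncol(x), " columns but the panel has ",
         length(model$probe_ids), " probes")
  }
  z <- drop(sweep(x, 2, model$center) %*% model$weights)
  m <- model$proj_means
  pri <- model$priors
  d1 <- log(pri[1]) - (z - m[1])^2 / 2
  d2 <- log(pri[2]) - (z - m[2])^2 / 2
  p1 <- 1 / (1 + exp(d2 - d1))
  cls <- ifelse(p1 >= 0.5, model$classes[1], model$classes[2])
  pmax_ <- pmax(p1, 1 - p1)
  band <- ifelse(pmax_ >= 0.95, "high", "low")
  out <- tibble::tibble(
    sample_id = if (is.null(rownames(x))) paste0("sample", seq_along(z))
                else rownames(x),
    ld1 = unname(z))
  out[[paste0("prob_", tolower(model$classes[1]))]] <- unname(p1)
  out[[paste0("prob_", tolower(model$classes[2]))]] <- unname(1 - p1)
  out$class <- unname(cls)
  out$band <- unname(band)
  out
}

#' Select the minimal CpG panel that separates the training groups
#'
#' For `k = 1 ... k_max`, finds the exact best size-k subset by
#' [leaps_and_bounds_select()], fits an LDA, and returns the model of the
#' smallest k with zero training misclassifications — preferring models
#' that require fewer input features. If no k separates the training set,
#' the `k_max` model is returned flagged `separating = FALSE`.
#'
#' @param x Samples x m candidate beta matrix (typically the top DMPs).
#' @param groups Two-level labels.
#' @param k_max Largest panel size to try.
#' @param priors Optional class priors, passed to [lda_fit()].
#' @return A `panel_model` with extra fields `tau_squared`, `k` and
#'   `separating`.
#' @export
minimal_panel <- function(x, groups, k_max = 10, priors = NULL) {
  x <- as.matrix(x)
  stopifnot(k_max <= ncol(x))
  groups <- factor(groups)
  last <- NULL
  for (k in seq_len(k_max)) {
    sc <- leaps_and_bounds_select(x, groups, k)
    fit <- lda_fit(x[, sc$probe_ids, drop = FALSE], groups, priors = priors)
    pred <- lda_predict(fit, x[, sc$probe_ids, drop = FALSE])
    acc <- mean(pred$class == as.character(groups))
    fit$tau_squared <- sc$tau_squared
    fit$k <- k
    fit$separating <- acc == 1
    if (acc == 1) return(fit)
    last <- fit
  }
  last
}

#' Repeated stratified cross-validation of minimal-panel classification
#'
#' Runs the full selection-plus-fit procedure inside every training fold
#' (no information leakage): within each of `repeats` repetitions, samples
#' are split into `folds` stratified folds; for each fold a minimal panel
#' is selected and fitted on the remaining samples and evaluated on the
#' held-out fold.
#'
#' @param x Samples x m candidate beta matrix.
#' @param groups Two-level labels.
#' @param folds Number of folds (default 5).
#' @param repeats Number of repetitions (default 3).
#' @param k_max Passed to [minimal_panel()].
#' @param seed Seed controlling fold assignment.
#' @return Tibble with `repeat_id`, `fold`, `n_test`, `accuracy`; mean
#'   accuracy is `mean(out$accuracy)` weighted naturally by equal folds.
#' @export
repeated_cv <- function(x, groups, folds = 5, repeats = 3, k_max = 6,
                        seed = 1L) {
  x <- as.matrix(x)
  groups <- factor(groups)
  if (any(table(groups) < folds)) {
    stop("stratification impossible: a class has fewer samples than folds")
  }
  set.seed(seed)
  out <- list()
  for (r in seq_len(repeats)) {
    fold_id <- integer(nrow(x))
    for (lv in levels(groups)) {
      idx <- which(groups == lv)
      fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    for (f in seq_len(folds)) {
      test <- fold_id == f
      fit <- minimal_panel(x[!test, , drop = FALSE], groups[!test],
                           k_max = k_max)
      pred <- lda_predict(fit, x[test, fit$probe_ids, drop = FALSE])
      out[[length(out) + 1L]] <- tibble::tibble(
        repeat_id = r, fold = f, n_test = sum(test),
        accuracy = mean(pred$class == as.character(groups[test])))
    }
  }
  dplyr::bind_rows(out)
}

#' @export
print.panel_model <- function(x, ...) {
  cat("<panel_model> ", length(x$probe_ids), "-CpG linear discriminant\n",
      sep = "")
  cat("  probes:", paste(x$probe_ids, collapse = ", "), "\n")
  cat("  projected means:", paste(x$classes, signif(x$proj_means, 4),
                                  collapse = "; "),
      " threshold:", signif(x$threshold, 4), "\n")
  if (!is.null(x$separating)) {
    cat("  training separation:", if (x$separating) "complete" else
      "incomplete (non-separating)", "\n")
  }
  invisible(x)
}

#' Tidy a fitted CpG panel model
#'
#' @param x A `panel_model`.
#' @param ... Unused.
#' @return Tibble with one row per panel probe: `probe_id`, `weight`,
#'   `center` (the per-probe grand mean subtracted before projection).
#' @export
tidy.panel_model <- function(x, ...) {
  tibble::tibble(probe_id = x$probe_ids,
                 weight = unname(x$weights),
                 center = unname(x$center))
}

#' One-row summary of a fitted CpG panel model
#'
#' @param x A `panel_model`.
#' @param ... Unused.
#' @return Tibble with `k`, `tau_squared` (when selection produced it),
#'   `threshold`, projected class means and `separating`.
#' @export
glance.panel_model <- function(x, ...) {
  tibble::tibble(
    k = length(x$probe_ids),
    tau_squared = if (is.null(x$tau_squared)) NA_real_ else x$tau_squared,
    threshold = x$threshold,
    proj_mean_fp = unname(x$proj_means[1]),
    proj_mean_sd = unname(x$proj_means[2]),
    separating = if (is.null(x$separating)) NA else x$separating
  )
}

#' Serialize a panel model to JSON
#'
#' @param model A `panel_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel_model <- function(model, path) {
  obj <- list(probe_ids = model$probe_ids,
              weights = unname(model$weights),
              center = unname(model$center),
              proj_means = unname(model$proj_means),
              classes = model$classes,
              priors = unname(model$priors),
              threshold = model$threshold)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a panel model from JSON
#'
#' @param path Path written by [write_panel_model()].
#' @return A `panel_model`.
#' @export
read_panel_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    probe_ids = obj$probe_ids,
    weights = stats::setNames(obj$weights, obj$probe_ids),
    center = stats::setNames(obj$center, obj$probe_ids),
    proj_means = stats::setNames(obj$proj_means, obj$classes),
    priors = stats::setNames(obj$priors, obj$classes),
    threshold = obj$threshold, classes = obj$classes
  ), class = "panel_model")
}
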
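# exhaustive-search oracle, independent of the branch-and-bound path
exhaustive_best <- function(x, groups, k) {
  cols <- utils::combn(ncol(x), k)
  taus <- apply(cols, 2, function(cc)
    tau_squared(x[, cc, drop = FALSE], groups)$tau_squared)
  best <- max(taus)
  # lexicographic tie-break on sorted probe-id sets
  cand <- which(taus >= best - 1e-12)
  keys <- vapply(cand, function(i)
    paste(sort(colnames(x)[cols[, i]]), collapse = ","), character(1))
  list(ids = sort(colnames(x)[cols[, cand[order(keys)[1]]]]), tau = best)
}

test_that("tau^2 matches hand-computed scatters for a single probe", {
  x <- matrix(c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9), ncol = 1,
              dimnames = list(NULL, "p1"))
  g <- rep(c("a", "b"), each = 3)
  # SSE_within = 0.02 + 0.02 = 0.04, SST = 0.58 -> tau^2 = 1 - 0.04/0.58
  sc <- tau_squared(x, g)
  expect_equal(sc$tau_squared, 1 - 0.04 / 0.58, tolerance = 1e-10)
  expect_equal(sc$wilks_lambda, 0.04 / 0.58, tolerance = 1e-10)

  # identical group means: no separation
  x0 <- matrix(c(0.1, 0.2, 0.3, 0.3, 0.2, 0.1), ncol = 1)
  expect_lt(tau_squared(x0, g)$tau_squared, 1e-10)

  # near-degenerate within-group variance: tau^2 -> 1
  x1 <- matrix(c(0.1, 0.1 + 1e-9, 0.1 - 1e-9, 0.9, 0.9 + 1e-9, 0.9 - 1e-9),
               ncol = 1)
  expect_gt(tau_squared(x1, g)$tau_squared, 0.999)
})

test_that("tau^2 is invariant to affine rescaling of single probes", {
  d <- random_candidates(81, n = 16, m = 5)
  t0 <- tau_squared(d$x, d$groups)$tau_squared
  x2 <- d$x
  x2[, 3] <- 5 * x2[, 3] - 2
  expect_equal(tau_squared(x2, d$groups)$tau_squared, t0, tolerance = 1e-9)
})

test_that("branch and bound equals exhaustive search over random instances", {
  for (s in 1:25) {
    set.seed(s)
    m <- sample(6:12, 1)
    k <- sample(1:4, 1)
    k <- min(k, m)
    d <- random_candidates(1000 + s, n = 14, m = m,
                           sep = runif(1, 0, 1.5))
    got <- leaps_and_bounds_select(d$x, d$groups, k)
    want <- exhaustive_best(d$x, d$groups, k)
    expect_identical(sort(got$probe_ids), want$ids)
    expect_equal(got$tau_squared, want$tau, tolerance = 1e-9)
  }
})

test_that("optimal tau^2 is non-decreasing in panel size", {
  d <- random_candidates(83, n = 18, m = 10, sep = 0.8)
  taus <- vapply(1:6, function(k)
    leaps_and_bounds_select(d$x, d$groups, k)$tau_squared, numeric(1))
  expect_true(all(diff(taus) >= -1e-9))
  # k = m: tau^2 of the full candidate set, no choice left
  full <- leaps_and_bounds_select(d$x, d$groups, 10)
  expect_equal(full$tau_squared, tau_squared(d$x, d$groups)$tau_squared,
               tolerance = 1e-12)
  expect_error(leaps_and_bounds_select(d$x, d$groups, 11), "exceeds")
})

test_that("the probes carrying all separation are selected", {
  set.seed(85)
  g <- toy_groups()
  x <- matrix(rnorm(20 * 10, 0, 1), 20, 10,
              dimnames = list(NULL, sprintf("p%02d", 1:10)))
  x[g == "FP", 1] <- x[g == "FP", 1] + 2.5
  x[g == "FP", 2] <- x[g == "FP", 2] - 2.5
  got <- leaps_and_bounds_select(x, g, 2)
  expect_setequal(got$probe_ids, c("p01", "p02"))
})

test_that("LDA recovers the closed-form direction and degenerate limits", {
  skip_if_not_installed("MASS")
  set.seed(87)
  g <- toy_groups(15, 15)
  mu <- c(0.2, 0.5, 0.7)
  x <- matrix(rnorm(30 * 3, 0, 0.05), 30, 3,
              dimnames = list(sprintf("s%02d", 1:30), c("a", "b", "c")))
  x <- sweep(x, 2, mu, "+")
  x[g == "FP", ] <- sweep(x[g == "FP", ], 2, c(0.1, 0.05, -0.08), "+")
  fit <- lda_fit(x, g)
  ml <- MASS::lda(x, grouping = g)
  cosine <- abs(sum(fit$weights * ml$scaling) /
                  sqrt(sum(fit$weights^2) * sum(ml$scaling^2)))
  expect_gt(cosine, 0.999)
  # spherical covariance: direction parallel to the mean difference
  xs <- matrix(rnorm(4000, 0, 1), 1000, 4)
  gs <- toy_groups(500, 500)
  xs[gs == "FP", ] <- sweep(xs[gs == "FP", ], 2, c(1, 2, -1, 0.5), "+")
  fs <- lda_fit(xs, gs)
  dmu <- colMeans(xs[gs == "FP", ]) - colMeans(xs[gs == "SD", ])
  cos2 <- abs(sum(fs$weights * dmu) / sqrt(sum(fs$weights^2) * sum(dmu^2)))
  expect_gt(cos2, 0.99)
  # exactly equal class means: posterior falls back to the priors
  half <- matrix(rnorm(20, 0, 1), 10, 2)
  x0 <- rbind(half, half)
  f0 <- lda_fit(x0, toy_groups())
  p0 <- lda_predict(f0, matrix(c(50, -50), 1, 2))
  expect_equal(p0$prob_fp, unname(f0$priors["FP"]), tolerance = 1e-9)
  expect_error(lda_fit(x0, rep("FP", 20)), "two non-empty classes")
})

test_that("projection geometry: FP negative, unit pooled variance, midpoint", {
  set.seed(89)
  g <- toy_groups(12, 10)
  x <- matrix(rnorm(22 * 3, 0.5, 0.05), 22, 3)
  x[g == "FP", ] <- x[g == "FP", ] + 0.15
  fit <- lda_fit(x, g)
  expect_lt(fit$proj_means["FP"], fit$proj_means["SD"])
  z <- drop(sweep(x, 2, fit$center) %*% fit$weights)
  s2_pooled <- (sum((z[g == "FP"] - mean(z[g == "FP"]))^2) +
                  sum((z[g == "SD"] - mean(z[g == "SD"]))^2)) / (22 - 2)
  expect_equal(s2_pooled, 1, tolerance = 1e-9)
  expect_equal(fit$threshold,
               mean(fit$proj_means) -
                 log(fit$priors[1] / fit$priors[2]) / diff(rev(fit$proj_means)),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("predictions are coherent probabilities with confidence bands", {
  set.seed(91)
  g <- toy_groups(12, 10)
  x <- matrix(rnorm(22 * 4, 0.5, 0.04), 22, 4,
              dimnames = list(sprintf("s%02d", 1:22),
                              sprintf("cg%02d", 1:4)))
  x[g == "FP", ] <- x[g == "FP", ] + 0.2
  fit <- lda_fit(x, g, priors = c(FP = 0.5, SD = 0.5))
  pred <- lda_predict(fit, x)
  expect_equal(pred$prob_fp + pred$prob_sd, rep(1, 22))
  expect_true(all(pred$band %in% c("high", "low")))
  expect_identical(pred$class, g)
  # a sample exactly at the threshold splits 50/50 under equal priors
  xt <- fit$center + fit$threshold * fit$weights / sum(fit$weights^2)
  pt <- lda_predict(fit, matrix(xt, 1, dimnames = list("t", names(xt))))
  expect_equal(pt$prob_fp, 0.5, tolerance = 1e-9)
  # LD1 is affine: doubling the offset from center doubles LD1
  p1 <- lda_predict(fit, matrix(fit$center + 0.01, 1,
                                dimnames = list("a", names(fit$center))))
  p2 <- lda_predict(fit, matrix(fit$center + 0.02, 1,
                                dimnames = list("b", names(fit$center))))
  expect_equal(p2$ld1, 2 * p1$ld1, tolerance = 1e-9)
  expect_error(lda_predict(fit, x[, 1:3]), "missing")
})

test_that("minimal panel finds a single separating probe immediately", {
  set.seed(93)
  g <- toy_groups(8, 8)
  x <- matrix(runif(16 * 5, 0.4, 0.6), 16, 5,
              dimnames = list(NULL, sprintf("cg%02d", 1:5)))
  x[g == "FP", 3] <- runif(8, 0.8, 0.95) # disjoint support on probe 3
  pm <- minimal_panel(x, g, k_max = 5)
  expect_identical(pm$k, 1L)
  expect_identical(pm$probe_ids, "cg03")
  expect_true(pm$separating)
})

test_that("pure-noise candidates are flagged non-separating", {
  flags <- vapply(1:10, function(s) {
    d <- random_candidates(2000 + s, n = 30, m = 8)
    pm <- minimal_panel(d$x, d$groups, k_max = 3)
    isFALSE(pm$separating)
  }, logical(1))
  expect_gte(mean(flags), 0.9)
})

test_that("the certified train/test design yields the planted panel size", {
  skip_if_not_installed("MASS")
  inst <- generate_panel_design_cohort(seed = 5)
  # independent certification cross-check with MASS::lda on the signal set
  ml <- MASS::lda(inst$train[, inst$signal_probes], inst$groups_train)
  acc_mass <- mean(predict(ml)$class == inst$groups_train)
  expect_equal(acc_mass, 1)
  pm <- minimal_panel(inst$train, inst$groups_train, k_max = 8)
  expect_identical(pm$k, inst$k_signal)
  pred <- lda_predict(pm, inst$test[, pm$probe_ids, drop = FALSE])
  expect_equal(mean(pred$class == inst$groups_test), 1)
})

test_that("repeated cross-validation is stratified, leak-free and seeded", {
  # strongly separable cohort: three probes carry a large additive shift
  set.seed(97)
  g <- toy_groups(15, 15)
  x <- matrix(runif(30 * 10, 0.3, 0.7), 30, 10,
              dimnames = list(NULL, sprintf("cg%02d", 1:10)))
  x[g == "FP", 1:3] <- pmin(x[g == "FP", 1:3] + 0.3, 1)
  cv <- repeated_cv(x, g, folds = 5, repeats = 2, k_max = 5, seed = 3)
  expect_identical(nrow(cv), 10L)
  expect_gte(mean(cv$accuracy), 0.9)
  cv2 <- repeated_cv(x, g, folds = 5, repeats = 2, k_max = 5, seed = 3)
  expect_identical(cv, cv2)
  # permuted labels: chance-level accuracy
  set.seed(11)
  accs <- vapply(1:4, function(s) {
    gp <- sample(g)
    mean(repeated_cv(x, gp, folds = 5, repeats = 1, k_max = 3,
                     seed = s)$accuracy)
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.2)
  expect_error(repeated_cv(x[c(1:4, 16:19), ], g[c(1:4, 16:19)],
                           folds = 5), "stratification")
})

test_that("panel models round-trip through JSON and tidy/glance work", {
  set.seed(95)
  g <- toy_groups(8, 8)
  x <- matrix(runif(16 * 3, 0.3, 0.7), 16, 3,
              dimnames = list(NULL, c("cg1", "cg2", "cg3")))
  x[g == "FP", ] <- x[g == "FP", ] + 0.2
  fit <- lda_fit(x, g)
  path <- withr::local_tempfile(fileext = ".json")
  write_panel_model(fit, path)
  back <- read_panel_model(path)
  expect_equal(back$weights, fit$weights)
  expect_equal(back$threshold, fit$threshold)
  expect_equal(lda_predict(back, x), lda_predict(fit, x))
  td <- tidy(fit)
  expect_identical(td$probe_id, c("cg1", "cg2", "cg3"))
  expect_identical(names(glance(fit)),
                   c("k", "tau_squared", "threshold", "proj_mean_fp",
                     "proj_mean_sd", "separating"))
})

test_that("the shipped published reference panel loads intact", {
  path <- system.file("extdata", "pmf_6cpg_panel.json",
                      package = "methylpanel")
  ref <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_identical(nrow(ref$probes), 6L)
  expect_equal(ref$probes$ld_coefficient[ref$probes$probe_id == "cg03983220"],
               -7.431161)
  expect_true(all(ref$probes$island_relation %in%
                    c("Island", "N_Shore", "OpenSea")))
})
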
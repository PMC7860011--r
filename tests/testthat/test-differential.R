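# brute-force oracle: enumerate candidate bumps (same-sign runs above the
# cutoff within gap clusters) by direct looping over probes
oracle_bumps <- function(chr, pos, coef, max_gap, cutoff) {
  ord <- order(chr, pos)
  chr <- chr[ord]; pos <- pos[ord]; coef <- coef[ord]
  runs <- list()
  cur <- integer(0)
  flush <- function(cur) {
    if (length(cur)) runs[[length(runs) + 1L]] <<- cur
    integer(0)
  }
  for (i in seq_along(coef)) {
    new_cluster <- i > 1 && (chr[i] != chr[i - 1] ||
                               pos[i] - pos[i - 1] > max_gap)
    sign_flip <- length(cur) > 0 && sign(coef[i]) != sign(coef[cur[1]])
    if (abs(coef[i]) > cutoff && !new_cluster && !sign_flip) {
      cur <- c(cur, i)
    } else {
      cur <- flush(cur)
      if (abs(coef[i]) > cutoff) cur <- i
    }
  }
  flush(cur)
  lapply(runs, function(r) list(start = pos[r[1]], end = pos[r[length(r)]],
                                n = length(r), area = sum(abs(coef[r]))))
}

test_that("BH adjustment reproduces hand-computed q-values", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjamini_hochberg(0.37), 0.37)
  expect_equal(benjamini_hochberg(rep(1, 5)), rep(1, 5))
  expect_identical(benjamini_hochberg(numeric(0)), numeric(0))
  # order-preservation and monotonicity in p
  set.seed(1)
  p <- runif(30)
  q <- benjamini_hochberg(p)
  expect_equal(q[order(p)], sort(q))
  expect_equal(benjamini_hochberg(p[c(5:30, 1:4)]), q[c(5:30, 1:4)])
})

test_that("moderated t reduces to the ordinary t-test when the prior is off", {
  co <- small_cohort(seed = 51, n_probes = 300, dmp = FALSE)
  dmp <- fit_dmp(co$beta, co$samples$group, prior_df = 0)
  m <- qlogis(pmin(pmax(co$beta, 1e-3), 1 - 1e-3))
  fp <- co$samples$group == "FP"
  ref <- vapply(seq_len(ncol(m)), function(j)
    stats::t.test(m[fp, j], m[!fp, j], var.equal = TRUE)$statistic,
    numeric(1))
  got <- dmp$moderated_t[match(colnames(co$beta), dmp$probe_id)]
  expect_equal(unname(got), unname(ref), tolerance = 1e-6)
})

test_that("moderated statistics agree with the limma implementation", {
  skip_if_not_installed("limma")
  co <- small_cohort(seed = 53, n_probes = 800)
  m <- qlogis(pmin(pmax(co$beta, 1e-3), 1 - 1e-3))
  design <- model.matrix(~ factor(co$samples$group, levels = c("SD", "FP")))
  lf <- limma::eBayes(limma::lmFit(t(m), design))
  dmp <- fit_dmp(co$beta, co$samples$group, prior_df_cap = Inf)
  ord <- match(colnames(co$beta), dmp$probe_id)
  expect_gt(cor(dmp$moderated_t[ord], lf$t[, 2]), 0.9999)
  expect_equal(unname(dmp$moderated_t[ord]), unname(lf$t[, 2]),
               tolerance = 0.02)
})

test_that("DMP p-values are calibrated under label permutation", {
  co <- small_cohort(seed = 55, n_probes = 2000, dmp = FALSE)
  fracs <- vapply(1:5, function(s) {
    set.seed(s)
    g <- sample(co$samples$group)
    mean(fit_dmp(co$beta, g)$p < 0.05)
  }, numeric(1))
  mc_sd <- sqrt(0.05 * 0.95 / 2000)
  expect_lt(abs(mean(fracs) - 0.05), 3 * mc_sd)
})

test_that("planted DMPs are recovered with controlled empirical FDR", {
  fdrs <- vapply(1:10, function(s) {
    co <- generate_cohort(sim_config(
      n_fp = 12, n_sd = 10, n_probes = 3000,
      dmp_spec = list(list(probes = 1:25, delta_beta = 0.12)),
      batch_effect_sd = 0, seed = 60 + s))
    dmp <- fit_dmp(co$beta, co$samples$group)
    calls <- dmp$probe_id[dmp$significant]
    if (length(calls) == 0) return(0)
    mean(!(calls %in% co$truth$dmp$probe_ids))
  }, numeric(1))
  expect_lte(mean(fdrs), 0.2)
})

test_that("moderated t sign matches the direction of the beta difference", {
  co <- small_cohort(seed = 57, n_probes = 500)
  dmp <- fit_dmp(co$beta, co$samples$group)
  big <- abs(dmp$delta_beta) > 0.02
  expect_true(all(sign(dmp$moderated_t[big]) == sign(dmp$delta_beta[big])))
})

test_that("bump enumeration equals the brute-force oracle on small instances", {
  for (s in 1:20) {
    set.seed(s)
    n <- sample(10:50, 1)
    chr <- paste0("chr", sort(sample(1:3, n, TRUE)))
    pos <- unlist(tapply(seq_len(n), chr, function(ix)
      cumsum(sample(c(50, 100, 300, 500), length(ix), TRUE))))[order(order(chr))]
    # regenerate positions sorted within chromosome
    pos <- ave(seq_len(n), chr, FUN = function(ix)
      cumsum(sample(c(50, 100, 300, 500), length(ix), TRUE)))
    coef <- rnorm(n, 0, 0.1)
    cutoff <- quantile(abs(coef), 0.7, names = FALSE)
    got <- methylpanel:::find_bumps(chr, pos, coef, 250, cutoff)
    want <- oracle_bumps(chr, pos, coef, 250, cutoff)
    expect_identical(length(got), length(want))
    key <- function(b) paste(b$start, b$end, round(b$area, 10))
    expect_setequal(vapply(got, key, character(1)),
                    vapply(want, key, character(1)))
  }
})

test_that("probes further apart than max_gap never share a DMR", {
  co <- generate_cohort(sim_config(
    n_fp = 8, n_sd = 8, n_probes = 800,
    dmp_spec = list(list(probes = 1:2, delta_beta = 0.3)),
    batch_effect_sd = 0, seed = 61))
  # planted probes 1 and 2 sit 50 kb apart on chr1 (uniform manifest)
  dmr <- find_dmrs(co$beta, co$samples$group, co$annotation,
                   n_perm = 25, fdr = 1.01)
  two_probe <- dmr$n_probes[vapply(dmr$probe_ids, function(pp)
    all(c("cg00000001", "cg00000002") %in% pp), logical(1))]
  expect_length(two_probe, 0)
})

test_that("a planted DMR is recovered with high probe overlap", {
  co <- generate_cohort(sim_config(
    n_fp = 12, n_sd = 10, n_probes = 2000,
    dmr_spec = list(list(chr = 3, start = 1e6, n = 8, spacing = 100,
                         delta_beta = 0.15)),
    batch_effect_sd = 0, seed = 63))
  dmr <- find_dmrs(co$beta, co$samples$group, co$annotation, n_perm = 100,
                   seed = 63)
  expect_gt(nrow(dmr), 0)
  truth <- co$truth$dmr[[1]]$probe_ids
  jac <- max(vapply(dmr$probe_ids, function(pp)
    length(intersect(pp, truth)) / length(union(pp, truth)), numeric(1)))
  expect_gte(jac, 0.75)
})

test_that("null data rarely yields significant DMRs", {
  hits <- vapply(1:10, function(s) {
    co <- generate_cohort(sim_config(n_fp = 8, n_sd = 8, n_probes = 800,
                                     batch_effect_sd = 0, seed = 70 + s))
    nrow(find_dmrs(co$beta, co$samples$group, co$annotation, n_perm = 50,
                   seed = s))
  }, numeric(1))
  expect_gte(mean(hits == 0), 0.9)
})

test_that("enrichment reduces to hypergeometric for equal probe counts", {
  ann <- tibble::tibble(probe_id = sprintf("cg%03d", 1:200),
                        gene = rep(sprintf("G%02d", 1:50), each = 4))
  sets <- list(t1 = sprintf("G%02d", 1:10), t2 = sprintf("G%02d", 25:40))
  hits <- sprintf("G%02d", c(1:5, 30))
  en <- gene_set_enrichment(hits, ann, sets)
  p_hyper <- phyper(5 - 1, 10, 40, 6, lower.tail = FALSE)
  expect_equal(en$p[en$term_id == "t1"], p_hyper, tolerance = 1e-3)
})

test_that("a strongly enriched term ranks first and empty hits rank nothing", {
  set.seed(71)
  ann <- tibble::tibble(probe_id = sprintf("cg%03d", 1:260),
                        gene = rep(sprintf("G%02d", 1:50),
                                   times = sample(3:8, 50, TRUE))[1:260])
  sets <- list(hit_term = sprintf("G%02d", 1:9),
               decoy1 = sprintf("G%02d", 20:34),
               decoy2 = sprintf("G%02d", 35:50))
  en <- gene_set_enrichment(sprintf("G%02d", 1:8), ann, sets)
  expect_identical(en$term_id[1], "hit_term")
  en0 <- gene_set_enrichment(character(0), ann, sets)
  expect_false(any(en0$significant))
})

test_that("hit genes outside the universe are dropped with a warning", {
  ann <- tibble::tibble(probe_id = sprintf("cg%03d", 1:40),
                        gene = rep(sprintf("G%02d", 1:10), each = 4))
  expect_warning(gene_set_enrichment(c("G01", "NOT_A_GENE"), ann,
                                     list(t = c("G01", "G02"))),
                 "dropped")
})

test_that("heatmap clustering separates well-separated planted groups", {
  co <- generate_cohort(sim_config(
    n_fp = 10, n_sd = 10, n_probes = 600,
    dmp_spec = list(list(probes = 1:25, delta_beta = 0.25)),
    batch_effect_sd = 0, seed = 73))
  dmp <- fit_dmp(co$beta, co$samples$group)
  hm <- cluster_heatmap_order(co$beta, dmp, top_n = 25)
  cl <- cutree(hm$sample_tree, k = 2)
  grp <- co$samples$group[match(rownames(co$beta), co$samples$sample_id)]
  tab <- table(cl, grp)
  expect_true(min(rowSums(tab)) > 0 &&
                (sum(diag(tab)) == 20 || sum(diag(tab[2:1, ])) == 20))
})

test_that("heatmap ordering handles degenerate inputs", {
  co <- small_cohort(seed = 75, n_probes = 300)
  dmp <- fit_dmp(co$beta, co$samples$group)
  beta_dup <- co$beta
  beta_dup[2, ] <- beta_dup[1, ] # duplicate sample rows merge first
  hm <- cluster_heatmap_order(beta_dup, dmp, top_n = 20)
  first_merge <- hm$sample_tree$merge[1, ]
  expect_setequal(-first_merge, c(1, 2))
  expect_equal(hm$sample_tree$height[1], 0)
  hm2 <- cluster_heatmap_order(co$beta, dmp, top_n = 2)
  expect_length(hm2$probe_order, 2)
  expect_error(cluster_heatmap_order(co$beta, dmp, top_n = 1), "top_n")
})
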
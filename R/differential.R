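#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up BH q-values with enforced monotonicity, order-preserving.
#' Thin wrapper over [stats::p.adjust()] so the FDR procedure used across
#' the package is named in one place.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same length and order.
#' @export
benjamini_hochberg <- function(p) {
  if (length(p) == 0) return(numeric(0))
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

# Smyth-style empirical-Bayes hyperparameters from per-probe sample
# variances: prior df d0 and prior scale s0^2 by moments matching on
# log variances. d0 is capped (default 100) for stability.
estimate_var_prior <- function(s2, df, cap = 100) {
  s2 <- pmax(s2, 1e-12)
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  ebar <- mean(e)
  v <- mean((e - ebar)^2 * length(e) / (length(e) - 1))
  target <- v - trigamma(df / 2)
  if (!is.finite(target) || target <= trigamma(cap / 2)) {
    d0 <- cap
  } else {
    d0 <- 2 * stats::uniroot(function(x) trigamma(x) - target,
                             lower = 1e-4, upper = 1e8,
                             tol = 1e-10)$root
    d0 <- min(d0, cap)
  }
  s0_2 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_2 = s0_2)
}

#' Probe-level differential methylation with moderated t-statistics
#'
#' Per probe, tests the FP vs SD group contrast on M-values (logit-beta)
#' with empirical-Bayes variance moderation: residual variances are shrunk
#' toward a common prior whose degrees of freedom and scale are estimated
#' by moments matching on the log variances; the moderated t uses
#' `df = residual df + prior df`. Effects are reported as `delta_beta`
#' (mean beta FP minus mean beta SD) for interpretability while testing is
#' done on the variance-stabilized M scale. Significance is purely FDR
#' based: a probe is called differentially methylated when `q <= fdr`,
#' with no delta-beta cutoff.
#'
#' @param beta Samples x probes beta matrix.
#' @param groups Per-sample two-level labels; the first level in
#'   `c("FP", "SD")` order (or factor order) is the contrast's positive side.
#' @param prior_df_cap Cap on the estimated prior degrees of freedom.
#' @param prior_df Optional fixed prior df overriding estimation (0 gives
#'   the ordinary two-sample t on M-values).
#' @param fdr FDR threshold used for the `significant` flag (default 0.1).
#' @return Tibble with one row per probe: `probe_id`, `mean_fp`, `mean_sd`,
#'   `delta_beta`, `moderated_t`, `df`, `p`, `q`, `significant`; sorted by
#'   ascending `p` with stable ties.
#' @export
fit_dmp <- function(beta, groups, prior_df_cap = 100, prior_df = NULL,
                    fdr = 0.1) {
  groups <- factor(groups)
  stopifnot(nlevels(groups) == 2, all(table(groups) >= 2))
  lv <- if (all(c("FP", "SD") %in% levels(groups))) c("FP", "SD") else levels(groups)
  g1 <- groups == lv[1]
  g2 <- groups == lv[2]
  n1 <- sum(g1); n2 <- sum(g2)
  m <- logit_clamp(beta)
  mu1 <- colMeans(m[g1, , drop = FALSE])
  mu2 <- colMeans(m[g2, , drop = FALSE])
  rss <- colSums(sweep(m[g1, , drop = FALSE], 2, mu1)^2) +
    colSums(sweep(m[g2, , drop = FALSE], 2, mu2)^2)
  df_res <- n1 + n2 - 2
  s2 <- rss / df_res
  flagged_zero <- s2 < 1e-10
  s2 <- pmax(s2, 1e-10) # variance floor for degenerate probes
  if (is.null(prior_df)) {
    pr <- estimate_var_prior(s2, df_res, cap = prior_df_cap)
  } else if (prior_df <= 0) {
    pr <- list(d0 = 0, s0_2 = 0)
  } else {
    pr <- list(d0 = prior_df,
               s0_2 = estimate_var_prior(s2, df_res, cap = prior_df_cap)$s0_2)
  }
  s2_mod <- (pr$d0 * pr$s0_2 + df_res * s2) / (pr$d0 + df_res)
  se <- sqrt(s2_mod * (1 / n1 + 1 / n2))
  tstat <- (mu1 - mu2) / se
  df_tot <- df_res + pr$d0
  p <- 2 * stats::pt(-abs(tstat), df = df_tot)
  q <- benjamini_hochberg(p)
  out <- tibble::tibble(
    probe_id = colnames(beta),
    mean_fp = colMeans(beta[g1, , drop = FALSE]),
    mean_sd = colMeans(beta[g2, , drop = FALSE]),
    delta_beta = colMeans(beta[g1, , drop = FALSE]) -
      colMeans(beta[g2, , drop = FALSE]),
    moderated_t = unname(tstat),
    df = df_tot,
    p = unname(p),
    q = unname(q),
    significant = unname(q <= fdr),
    zero_variance = unname(flagged_zero)
  )
  dplyr::arrange(out, .data$p, dplyr::desc(abs(.data$moderated_t)),
                 .data$probe_id)
}

# Partition probe indices (sorted by position within one chromosome) into
# clusters with consecutive gaps <= max_gap.
cluster_by_gap <- function(pos, max_gap) {
  if (length(pos) == 0) return(integer(0))
  cumsum(c(1L, as.integer(diff(pos) > max_gap)))
}

# Enumerate maximal runs of probes whose |coef| exceeds the cutoff, within
# gap clusters, and score each run by its area (sum of |coef|). Runs mixing
# signs are split so a bump is consistently hyper- or hypomethylated.
find_bumps <- function(chr, pos, coef, max_gap, cutoff) {
  ord <- order(chr, pos)
  chr <- chr[ord]; pos <- pos[ord]; coef <- coef[ord]; idx <- ord
  bumps <- list()
  for (ch in unique(chr)) {
    sel <- chr == ch
    cl <- cluster_by_gap(pos[sel], max_gap)
    p_ch <- pos[sel]; c_ch <- coef[sel]; i_ch <- idx[sel]
    for (g in unique(cl)) {
      in_g <- cl == g
      exceed <- abs(c_ch[in_g]) > cutoff
      sgn <- sign(c_ch[in_g])
      run_id <- cumsum(c(1L, as.integer(diff(exceed) != 0 |
                                          diff(sgn) != 0)[])) # split on sign flips
      for (r in unique(run_id[exceed])) {
        take <- run_id == r & exceed
        if (!any(take)) next
        bumps[[length(bumps) + 1L]] <- list(
          chr = ch,
          start = min(p_ch[in_g][take]), end = max(p_ch[in_g][take]),
          probe_idx = i_ch[in_g][take],
          area = sum(abs(c_ch[in_g][take])),
          n_probes = sum(take)
        )
      }
    }
  }
  bumps
}

#' Bump-hunting differentially methylated regions
#'
#' Detects DMRs from per-probe group-difference coefficients: probes are
#' clustered so consecutive within-chromosome gaps are at most `max_gap`;
#' candidate bumps are maximal same-sign runs whose absolute coefficient
#' exceeds the `cutoff_quantile` of all absolute coefficients; each bump is
#' scored by its area (sum of absolute coefficients). The null distribution
#' of areas is built by recomputing coefficients under `n_perm` group-label
#' permutations; a bump's p-value is the (add-one smoothed) fraction of
#' pooled permutation areas at least as large, and BH-adjusted q-values are
#' thresholded at `fdr`.
#'
#' @param beta Samples x probes beta matrix.
#' @param groups Two-level per-sample labels.
#' @param annotation Probe manifest with `probe_id`, `chr`, `pos`.
#' @param max_gap Maximum within-region probe gap in bp (default 250).
#' @param cutoff_quantile Quantile of `|coefficient|` defining the bump
#'   inclusion cutoff (default 0.99).
#' @param n_perm Number of label permutations for the null (default 250).
#' @param fdr FDR threshold on q (default 0.05).
#' @param seed Seed for the permutation null.
#' @return Tibble of regions: `chr`, `start`, `end` (1-based inclusive),
#'   `n_probes`, `probe_ids` (list column), `area`, `p`, `q`, filtered to
#'   `q <= fdr` and sorted by `p`.
#' @export
find_dmrs <- function(beta, groups, annotation, max_gap = 250,
                      cutoff_quantile = 0.99, n_perm = 250, fdr = 0.05,
                      seed = 1L) {
  if (n_perm < 10) stop("n_perm < 10 gives an unstable permutation null")
  groups <- factor(groups)
  stopifnot(nlevels(groups) == 2)
  ann <- annotation[match(colnames(beta), annotation$probe_id), ]
  g1 <- groups == levels(groups)[1]
  coef_fun <- function(lab1) {
    colMeans(beta[lab1, , drop = FALSE]) - colMeans(beta[!lab1, , drop = FALSE])
  }
  coef <- coef_fun(g1)
  cutoff <- stats::quantile(abs(coef), cutoff_quantile, names = FALSE)
  obs <- find_bumps(ann$chr, ann$pos, coef, max_gap, cutoff)
  if (length(obs) == 0) {
    return(tibble::tibble(chr = character(), start = integer(),
                          end = integer(), n_probes = integer(),
                          probe_ids = list(), area = numeric(),
                          p = numeric(), q = numeric()))
  }
  set.seed(seed)
  null_areas <- numeric(0)
  n_samp <- nrow(beta)
  for (b in seq_len(n_perm)) {
    perm <- sample(n_samp)
    coef_p <- coef_fun(g1[perm])
    cut_p <- stats::quantile(abs(coef_p), cutoff_quantile, names = FALSE)
    bp <- find_bumps(ann$chr, ann$pos, coef_p, max_gap, cut_p)
    null_areas <- c(null_areas,
                    if (length(bp)) vapply(bp, `[[`, numeric(1), "area") else numeric(0))
  }
  areas <- vapply(obs, `[[`, numeric(1), "area")
  p <- vapply(areas, function(a) (1 + sum(null_areas >= a)) /
                (1 + length(null_areas)), numeric(1))
  q <- benjamini_hochberg(p)
  out <- tibble::tibble(
    chr = vapply(obs, `[[`, character(1), "chr"),
    start = vapply(obs, function(b) as.integer(b$start), integer(1)),
    end = vapply(obs, function(b) as.integer(b$end), integer(1)),
    n_probes = vapply(obs, function(b) as.integer(b$n_probes), integer(1)),
    probe_ids = lapply(obs, function(b) colnames(beta)[b$probe_idx]),
    area = areas, p = p, q = q
  )
  out <- dplyr::arrange(out, .data$p, dplyr::desc(.data$area))
  out[out$q <= fdr, , drop = FALSE]
}

# Wallenius noncentral hypergeometric upper tail P(X >= x) with a single
# odds parameter w for the "in term" genes, by numerical integration of
# the pmf.
wallenius_upper_tail <- function(x, m1, m2, n, w) {
  if (x <= 0) return(1)
  pmf <- function(k) {
    if (k < max(0, n - m2) || k > min(n, m1)) return(0)
    d <- w * (m1 - k) + (m2 - (n - k))
    if (d <= 0) return(as.numeric(k == min(n, m1)))
    f <- function(t) {
      exp(lchoose(m1, k) + lchoose(m2, n - k) +
            log1p(-t^(w / d)) * k + log1p(-t^(1 / d)) * (n - k))
    }
    stats::integrate(f, 0, 1, rel.tol = 1e-8, stop.on.error = FALSE)$value
  }
  tail_p <- sum(vapply(x:min(n, m1), pmf, numeric(1)))
  min(max(tail_p, 0), 1)
}

#' Gene-set enrichment with probe-count bias correction
#'
#' Tests each gene set for over-representation of hit genes while
#' correcting for the selection bias induced by unequal probe counts per
#' gene (genes with many probes are more likely to contain a significant
#' CpG). Following the gometh approach, the bias enters as the odds
#' parameter of a Wallenius noncentral hypergeometric distribution: the
#' odds for a term is the mean probe count of its genes relative to the
#' mean probe count of the remaining universe.
#'
#' @param hit_genes Character vector of differentially methylated genes.
#' @param annotation Probe manifest with `probe_id` and `gene` columns; the
#'   gene universe and per-gene probe counts derive from it.
#' @param gene_sets Named list of character vectors (e.g. read from GMT via
#'   [read_gmt()]).
#' @param fdr FDR threshold for the `significant` flag (default 0.1).
#' @return Tibble: `term_id`, `n_genes_in_term`, `n_hit`, `odds`, `p`, `q`,
#'   `significant`, sorted by `p`.
#' @export
gene_set_enrichment <- function(hit_genes, annotation, gene_sets, fdr = 0.1) {
  stopifnot(length(gene_sets) > 0)
  counts <- table(annotation$gene[annotation$gene != ""])
  universe <- names(counts)
  missing <- setdiff(hit_genes, universe)
  if (length(missing)) {
    warning("hit genes absent from the probe universe dropped: ",
            paste(utils::head(missing, 5), collapse = ", "))
  }
  hits <- intersect(unique(hit_genes), universe)
  res <- purrr::map_dfr(names(gene_sets), function(tid) {
    term <- intersect(gene_sets[[tid]], universe)
    m1 <- length(term)
    if (m1 == 0) return(NULL)
    m2 <- length(universe) - m1
    x <- length(intersect(hits, term))
    w_in <- mean(counts[term])
    w_out <- if (m2 > 0) mean(counts[setdiff(universe, term)]) else w_in
    w <- w_in / w_out
    tibble::tibble(term_id = tid, n_genes_in_term = m1, n_hit = x,
                   odds = w,
                   p = wallenius_upper_tail(x, m1, m2, length(hits), w))
  })
  res$q <- benjamini_hochberg(res$p)
  res$significant <- res$q <= fdr
  dplyr::arrange(res, .data$p)
}

#' Read gene sets from a GMT file
#'
#' @param path Path to a tab-delimited GMT file (term, description, genes...).
#' @return Named list of character gene vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  sets
}

#' Order samples and probes for a differential-methylation heatmap
#'
#' Selects the `top_n` most differentially methylated probes (smallest p,
#' ties by larger |t| then probe id) and clusters samples and probes
#' separately by agglomerative clustering with centroid linkage on squared
#' Euclidean distance of beta values, the convention under which centroid
#' linkage is well defined (merge heights may invert, which is accepted).
#'
#' @param beta Samples x probes beta matrix.
#' @param records DMP tibble from [fit_dmp()].
#' @param top_n Number of probes to keep (>= 2).
#' @return List with `probe_order`, `sample_order` (leaf orders),
#'   `probe_tree`, `sample_tree` (hclust objects) and `probe_ids`.
#' @export
cluster_heatmap_order <- function(beta, records, top_n = 1000) {
  if (top_n < 2) stop("top_n must be at least 2")
  stopifnot(top_n <= nrow(records))
  rec <- dplyr::arrange(records, .data$p, dplyr::desc(abs(.data$moderated_t)),
                        .data$probe_id)
  ids <- rec$probe_id[seq_len(top_n)]
  x <- beta[, ids, drop = FALSE]
  sample_tree <- stats::hclust(stats::dist(x)^2, method = "centroid")
  probe_tree <- stats::hclust(stats::dist(t(x))^2, method = "centroid")
  list(probe_ids = ids,
       probe_order = ids[probe_tree$order],
       sample_order = rownames(x)[sample_tree$order],
       probe_tree = probe_tree, sample_tree = sample_tree)
}
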
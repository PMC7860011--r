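#' Define a linear epigenetic clock
#'
#' A clock is an intercept (years) plus per-probe weights (years per beta
#' unit), the form shared by the Horvath, Hannum and PhenoAge predictors.
#' Coefficients are data, not code: published coefficient sets can be read
#' from CSV with [read_clock()].
#'
#' @param intercept Intercept in years.
#' @param weights Named numeric vector, names are probe ids.
#' @param name Label for the clock.
#' @return A `clock_model` list.
#' @export
clock_model <- function(intercept, weights, name = "custom") {
  stopifnot(length(weights) >= 1, !is.null(names(weights)),
            !anyDuplicated(names(weights)), all(is.finite(weights)),
            is.finite(intercept))
  structure(list(intercept = intercept, weights = weights, name = name),
            class = "clock_model")
}

#' Read clock coefficients from CSV
#'
#' Expects two columns `probe_id, weight`; the first data row holds the
#' intercept (probe_id `"(Intercept)"` or `"Intercept"`).
#'
#' @param path CSV path.
#' @param name Clock label (default: file name).
#' @return A `clock_model`.
#' @export
read_clock <- function(path, name = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(ncol(d) >= 2)
  is_int <- d[[1]] %in% c("(Intercept)", "Intercept", "intercept")
  if (!any(is_int)) stop("no intercept row found in ", path)
  clock_model(intercept = d[[2]][which(is_int)[1]],
              weights = stats::setNames(d[[2]][!is_int], d[[1]][!is_int]),
              name = if (is.null(name)) basename(path) else name)
}

#' Compute epigenetic age per sample
#'
#' Scores each sample with a linear clock:
#' `EA = intercept + sum(weight_i * beta_i)` over the clock probes. Probes
#' absent from the matrix are either imputed by the cohort mean of the
#' available clock probes' policy (`"mean"`: per-probe cohort mean beta,
#' which for a fully missing probe is unavailable and excluded with its
#' weight) or raise an error (`"strict"`). A sample must cover at least
#' `min_coverage` of the clock probes.
#'
#' @param beta Samples x probes beta matrix.
#' @param clock A `clock_model`.
#' @param samples Optional sample sheet tibble with `sample_id` and `age`
#'   (chronological age, years); when supplied, `ca` and `delta = ea - ca`
#'   are filled in.
#' @param missing_policy `"mean"` or `"strict"`.
#' @param min_coverage Minimum fraction of clock probes that must be
#'   measured per sample (default 0.8).
#' @return Tibble: `sample_id`, `ea`, `ca`, `delta`.
#' @export
compute_epigenetic_age <- function(beta, clock, samples = NULL,
                                   missing_policy = c("mean", "strict"),
                                   min_coverage = 0.8) {
  missing_policy <- match.arg(missing_policy)
  probes <- names(clock$weights)
  present <- intersect(probes, colnames(beta))
  absent <- setdiff(probes, colnames(beta))
  if (length(absent)) {
    if (missing_policy == "strict") {
      stop("clock probes missing from matrix: ",
           paste(utils::head(absent, 10), collapse = ", "))
    }
  }
  b <- beta[, present, drop = FALSE]
  na_frac_per_sample <- rowMeans(is.na(b))
  coverage <- (length(present) / length(probes)) * (1 - na_frac_per_sample)
  if (any(coverage < min_coverage)) {
    bad <- rownames(beta)[coverage < min_coverage]
    stop("clock coverage below ", min_coverage, " for sample(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         if (length(absent)) paste0("; missing probes include ",
                                    paste(utils::head(absent, 5),
                                          collapse = ", ")) else "")
  }
  if (anyNA(b)) {
    if (missing_policy == "strict") {
      stop("missing clock beta values under strict policy")
    }
    cm <- colMeans(b, na.rm = TRUE)
    for (j in seq_len(ncol(b))) b[is.na(b[, j]), j] <- cm[j]
  }
  ea <- clock$intercept + drop(b %*% clock$weights[present])
  out <- tibble::tibble(
    sample_id = if (is.null(rownames(beta))) paste0("sample", seq_along(ea))
                else rownames(beta),
    ea = unname(ea))
  if (!is.null(samples)) {
    out$ca <- samples$age[match(out$sample_id, samples$sample_id)]
  } else {
    out$ca <- NA_real_
  }
  out$delta <- out$ea - out$ca
  out
}

#' Contingency test of epigenetic-age excess between groups
#'
#' Counts, per group, the samples whose epigenetic age strictly exceeds
#' their chronological age (`delta > 0`; ties count as "not larger") and
#' tests the 2x2 table with Pearson's chi-square (df 1, no continuity
#' correction) via [chi_square_2x2()].
#'
#' @param results Age tibble from [compute_epigenetic_age()] with `delta`.
#' @param groups Per-sample two-level labels aligned with `results`.
#' @return List: `table` (2x2, rows = groups, cols = EA>CA yes/no),
#'   `chi2`, `p`.
#' @export
ea_ca_contingency <- function(results, groups) {
  groups <- factor(groups)
  stopifnot(nlevels(groups) == 2, length(groups) == nrow(results))
  if (any(table(groups) == 0)) stop("a group has zero samples")
  older <- results$delta > 0
  tab <- rbind(
    c(sum(older & groups == levels(groups)[1]),
      sum(!older & groups == levels(groups)[1])),
    c(sum(older & groups == levels(groups)[2]),
      sum(!older & groups == levels(groups)[2])))
  dimnames(tab) <- list(levels(groups), c("ea_gt_ca", "ea_le_ca"))
  ct <- chi_square_2x2(tab)
  list(table = tab, chi2 = ct$chi2, p = ct$p)
}

#' Group comparison of epigenetic-age discrepancy
#'
#' Per-group mean epigenetic age, chronological age and their difference,
#' with a two-sided Mann-Whitney U test on `delta = ea - ca` between the
#' two groups.
#'
#' @inheritParams ea_ca_contingency
#' @return List: `summary` tibble (group, n, mean_ea, mean_ca, mean_delta)
#'   and `p` (Mann-Whitney, two-sided).
#' @export
group_age_difference <- function(results, groups) {
  groups <- factor(groups)
  stopifnot(nlevels(groups) == 2, all(table(groups) >= 2))
  d <- dplyr::mutate(results, group = groups)
  summ <- dplyr::summarise(
    dplyr::group_by(d, .data$group),
    n = dplyr::n(),
    mean_ea = mean(.data$ea),
    mean_ca = mean(.data$ca),
    mean_delta = mean(.data$delta),
    .groups = "drop")
  lv <- levels(groups)
  mw <- mann_whitney_u(d$delta[d$group == lv[1]], d$delta[d$group == lv[2]])
  list(summary = summ, p = mw$p, U = mw$U)
}
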
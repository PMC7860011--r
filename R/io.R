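#' Read a beta-value matrix from delimited text
#'
#' Expects a tab-delimited samples x probes layout: header row of probe
#' ids, first column of sample ids. Values are validated to lie in
#' `[0, 1]`; violations are reported with their cell coordinates.
#'
#' @param path TSV path.
#' @return Numeric matrix with sample row names and probe column names.
#' @export
read_beta_matrix <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, row.names = 1)
  m <- as.matrix(d)
  bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("beta values outside [0,1] at (",
         paste(apply(utils::head(bad, 5), 1, function(rc)
           paste0(rownames(m)[rc[1]], ", ", colnames(m)[rc[2]])),
           collapse = "; "), ")")
  }
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m))) {
    stop("duplicate sample or probe ids")
  }
  m
}

#' Read an intensity or detection-p matrix
#'
#' Same layout as [read_beta_matrix()] without the `[0, 1]` constraint.
#'
#' @param path TSV path.
#' @return Numeric matrix.
#' @export
read_matrix <- function(path) {
  as.matrix(utils::read.delim(path, check.names = FALSE, row.names = 1))
}

island_vocab <- c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf",
                  "OpenSea")

#' Read a probe manifest
#'
#' CSV with columns `probe_id, chr, pos, design_type, island_relation,
#' gene`. Island relations are normalized case-insensitively to the fixed
#' vocabulary (Island, N_Shore, S_Shore, N_Shelf, S_Shelf, OpenSea) with a
#' warning on mismatched case; unknown values are an error.
#'
#' @param path CSV path.
#' @return Annotation tibble.
#' @export
read_manifest <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  req <- c("probe_id", "chr", "pos", "design_type", "island_relation", "gene")
  if (!all(req %in% names(d))) {
    stop("manifest missing columns: ",
         paste(setdiff(req, names(d)), collapse = ", "))
  }
  idx <- match(tolower(d$island_relation), tolower(island_vocab))
  if (anyNA(idx)) {
    stop("unknown island_relation values: ",
         paste(unique(d$island_relation[is.na(idx)]), collapse = ", "))
  }
  fixed <- island_vocab[idx]
  if (any(fixed != d$island_relation)) {
    warning(sum(fixed != d$island_relation),
            " island_relation value(s) normalized to canonical case")
  }
  d$island_relation <- fixed
  if (!all(d$design_type %in% c("I", "II"))) stop("design_type must be I/II")
  if (anyDuplicated(d$probe_id)) stop("duplicate probe ids in manifest")
  d$gene[is.na(d$gene)] <- ""
  d
}

#' Read a sample sheet
#'
#' CSV with at least `sample_id, group`; `group` must be FP/SD. Optional
#' clinical columns (plate, age, sex, leukocytes, platelets, hemoglobin,
#' hmr) pass through.
#'
#' @param path CSV path.
#' @return Sample tibble.
#' @export
read_sample_sheet <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("sample_id", "group") %in% names(d))) {
    stop("sample sheet needs sample_id and group columns")
  }
  if (anyDuplicated(d$sample_id)) stop("duplicate sample ids")
  if (!all(d$group %in% c("FP", "SD"))) {
    stop("group must be FP or SD; got: ",
         paste(setdiff(unique(d$group), c("FP", "SD")), collapse = ", "))
  }
  d
}

write_matrix_tsv <- function(m, path) {
  d <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic cohort to a directory of plain-text files
#'
#' Emits `beta.tsv`, `meth.tsv`, `unmeth.tsv`, `detp.tsv` (samples x
#' probes), `manifest.csv`, `samples.csv` and `truth.json`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_tsv(cohort$beta, file.path(dir, "beta.tsv"))
  write_matrix_tsv(cohort$meth, file.path(dir, "meth.tsv"))
  write_matrix_tsv(cohort$unmeth, file.path(dir, "unmeth.tsv"))
  write_matrix_tsv(cohort$detp, file.path(dir, "detp.tsv"))
  readr::write_csv(cohort$annotation, file.path(dir, "manifest.csv"))
  readr::write_csv(cohort$samples, file.path(dir, "samples.csv"))
  tr <- cohort$truth
  tr$failed_cells <- as.data.frame(tr$failed_cells)
  jsonlite::write_json(tr, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory path.
#' @return List with `beta`, `meth`, `unmeth`, `detp`, `annotation`,
#'   `samples` (no truth record: it is ground-truth metadata, reread only
#'   when needed via jsonlite).
#' @export
read_cohort <- function(dir) {
  beta <- read_beta_matrix(file.path(dir, "beta.tsv"))
  ann <- read_manifest(file.path(dir, "manifest.csv"))
  samples <- read_sample_sheet(file.path(dir, "samples.csv"))
  mism <- c(setdiff(colnames(beta), ann$probe_id),
            setdiff(ann$probe_id, colnames(beta)))
  if (length(mism)) {
    stop("probe ids disagree between beta matrix and manifest: ",
         paste(utils::head(mism, 5), collapse = ", "))
  }
  mism <- c(setdiff(rownames(beta), samples$sample_id),
            setdiff(samples$sample_id, rownames(beta)))
  if (length(mism)) {
    stop("sample ids disagree between beta matrix and sample sheet: ",
         paste(utils::head(mism, 5), collapse = ", "))
  }
  list(beta = beta,
       meth = read_matrix(file.path(dir, "meth.tsv")),
       unmeth = read_matrix(file.path(dir, "unmeth.tsv")),
       detp = read_matrix(file.path(dir, "detp.tsv")),
       annotation = ann, samples = samples)
}

#' Write DMRs as BED
#'
#' Converts the internal 1-based inclusive coordinates to BED's 0-based
#' half-open convention.
#'
#' @param dmrs DMR tibble from [find_dmrs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dmr_bed <- function(dmrs, path) {
  bed <- data.frame(chrom = dmrs$chr, chromStart = dmrs$start - 1L,
                    chromEnd = dmrs$end,
                    name = sprintf("dmr_%d", seq_len(nrow(dmrs))),
                    score = round(pmin(1000, -10 * log10(pmax(dmrs$p, 1e-100)))))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Default pipeline configuration
#'
#' All stage parameters in one validated list: detection thresholds,
#' normalization and batch handling, differential-methylation and DMR
#' settings, panel-selection pool size and CV design, clock and CNA
#' parameters. Unknown names are rejected.
#'
#' @param ... Name-value overrides of the defaults.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    p_thresh = 0.1, probe_fail_frac = 0.05, sample_fail_frac = 0.1,
    bmiq = TRUE, bmiq_min_probes = 100,
    combat = TRUE,
    dmp_fdr = 0.1,
    dmr_max_gap = 250, dmr_cutoff_quantile = 0.99, dmr_n_perm = 250,
    dmr_fdr = 0.05,
    heatmap_top_n = 1000,
    candidate_pool = 40, k_max = 10,
    cv_folds = 5, cv_repeats = 3,
    cna_min_probes = 10, cna_alpha = 0.01, cna_threshold = 0.5,
    extremes_hi = 0.8, extremes_lo = 0.1,
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, over)
  stopifnot(cfg$cv_folds >= 2, cfg$dmr_n_perm >= 10,
            cfg$p_thresh > 0, cfg$p_thresh < 1)
  structure(cfg, class = "pipeline_config")
}

#' Run the full methylation analysis pipeline
#'
#' Executes filter -> BMIQ -> SVD confounder screen -> ComBat (statistics
#' branch only) -> DMPs -> DMRs -> heatmap clustering -> minimal-panel
#' selection and LDA (on the non-batch-corrected branch) -> cross-validated
#' accuracy -> epigenetic age (when a clock is supplied) -> CNA profile ->
#' cohort extremes report. Classification deliberately uses the
#' non-batch-corrected matrix; statistics use the corrected one.
#'
#' @param cohort List with `beta`, `detp`, `meth`, `unmeth`, `annotation`,
#'   `samples` (a `synthetic_cohort` or [read_cohort()] output).
#' @param config A [pipeline_config()].
#' @param clock Optional `clock_model` for the epigenetic-age stage.
#' @param out_dir Optional directory: when given, tables are written there
#'   (DMP TSV, DMR BED+TSV, SEG, predictions TSV, report JSON).
#' @return List of stage results: `filter_report`, `svd_screen`,
#'   `dmp`, `dmr`, `heatmap`, `panel`, `cv`, `age`, `cna`, `extremes`,
#'   `config`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(), clock = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  samples <- cohort$samples
  if (config$cv_folds > min(table(samples$group))) {
    stop("stratification impossible: cv_folds exceeds the smaller class")
  }
  flt <- filter_by_detection(cohort$beta, cohort$detp,
                             p_thresh = config$p_thresh,
                             probe_fail_frac = config$probe_fail_frac,
                             sample_fail_frac = config$sample_fail_frac)
  beta <- flt$beta
  samples <- samples[match(rownames(beta), samples$sample_id), ]
  groups <- samples$group
  log_stage("filter", beta)
  if (config$bmiq) {
    beta <- bmiq_normalize_matrix(beta, cohort$annotation,
                                  min_probes = config$bmiq_min_probes)
    log_stage("bmiq", beta)
  }
  covars <- samples[, intersect(c("plate", "age", "sex"), names(samples))]
  svd_screen <- svd_confounder_screen(beta, as.data.frame(covars))
  # statistics branch: batch-corrected; classification branch: untouched
  beta_stats <- beta
  if (config$combat && "plate" %in% names(samples) &&
      length(unique(samples$plate)) > 1) {
    beta_stats <- combat_correct(beta, samples$plate,
                                 covariates = data.frame(group = groups))
    log_stage("combat", beta_stats)
  }
  dmp <- fit_dmp(beta_stats, groups, fdr = config$dmp_fdr)
  dmr <- find_dmrs(beta_stats, groups, cohort$annotation,
                   max_gap = config$dmr_max_gap,
                   cutoff_quantile = config$dmr_cutoff_quantile,
                   n_perm = config$dmr_n_perm, fdr = config$dmr_fdr,
                   seed = config$seed)
  hm <- cluster_heatmap_order(beta_stats, dmp,
                              top_n = min(config$heatmap_top_n, nrow(dmp)))
  pool <- dmp$probe_id[seq_len(min(config$candidate_pool, nrow(dmp)))]
  panel <- minimal_panel(beta[, pool, drop = FALSE], groups,
                         k_max = min(config$k_max, length(pool)))
  cv <- repeated_cv(beta[, pool, drop = FALSE], groups,
                    folds = config$cv_folds, repeats = config$cv_repeats,
                    k_max = panel$k %||% config$k_max, seed = config$seed)
  age <- NULL
  if (!is.null(clock)) {
    age <- compute_epigenetic_age(cohort$beta, clock, samples = samples)
    age <- age[match(rownames(beta), age$sample_id), ]
  }
  cna <- cna_profile(cohort$meth[rownames(beta), colnames(beta)],
                     cohort$unmeth[rownames(beta), colnames(beta)],
                     groups, annotation = cohort$annotation,
                     min_probes = config$cna_min_probes,
                     alpha = config$cna_alpha,
                     threshold = config$cna_threshold)
  extremes <- count_methylation_extremes(beta_stats, groups,
                                         hi = config$extremes_hi,
                                         lo = config$extremes_lo)
  res <- list(filter_report = flt$report, svd_screen = svd_screen,
              dmp = dmp, dmr = dmr, heatmap = hm, panel = panel, cv = cv,
              age = age, cna = cna, extremes = extremes, config = config)
  if (!is.null(out_dir)) write_pipeline_outputs(res, beta, out_dir)
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

log_stage <- function(stage, m) {
  message(sprintf("[%s] %d samples x %d probes", stage, nrow(m), ncol(m)))
}

write_pipeline_outputs <- function(res, beta, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(res$dmp, file.path(out_dir, "dmp.tsv"))
  if (nrow(res$dmr)) {
    write_dmr_bed(res$dmr, file.path(out_dir, "dmr.bed"))
    readr::write_tsv(dplyr::select(res$dmr, -"probe_ids"),
                     file.path(out_dir, "dmr.tsv"))
  }
  write_seg(res$cna$segments, "FP_vs_SD", file.path(out_dir, "cna.seg"))
  pred <- lda_predict(res$panel, beta[, res$panel$probe_ids, drop = FALSE])
  readr::write_tsv(pred, file.path(out_dir, "predictions.tsv"))
  write_panel_model(res$panel, file.path(out_dir, "panel.json"))
  report <- list(
    n_evaluable = res$filter_report$n_evaluable,
    excluded_samples = res$filter_report$excluded_samples$sample_id,
    extremes = list(counts = res$extremes$counts,
                    percent_diff = as.list(res$extremes$percent_diff)),
    cv_mean_accuracy = mean(res$cv$accuracy),
    panel_size = length(res$panel$probe_ids))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
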
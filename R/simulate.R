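#' Configure a synthetic methylation cohort
#'
#' Builds a validated configuration for [generate_cohort()]. The defaults
#' emulate a two-group bone-marrow cohort measured on an EPIC-style array:
#' 16 fibrotic-progression (FP) and 17 stable-disease (SD) samples on two
#' amplification plates, with bimodal baseline methylation, a compressed
#' dynamic range for type II probes, plate batch effects on the logit scale,
#' sporadic probe failures, and an age-linear epigenetic-clock signal.
#'
#' @param n_fp,n_sd Number of FP and SD samples (>= 1).
#' @param n_probes Number of array probes.
#' @param n_plates Number of amplification plates (batches).
#' @param dmp_spec List of planted differentially methylated positions; each
#'   element is `list(probes = <integer probe indices>, delta_beta = <shift>)`.
#'   The `delta_beta` (in `[-1, 1]`) is added to FP samples on the beta scale.
#' @param dmr_spec List of planted differentially methylated regions; each
#'   element is `list(chr = <chromosome index>, start = <bp>, n = <probe
#'   count>, spacing = <bp between probes>, delta_beta = <shift>)`. Region
#'   probes are carved out of the probe pool and placed at the configured
#'   spacing so that region detection sees realistic gaps.
#' @param cna_spec List of planted copy-number segments; each element is
#'   `list(samples = <sample indices>, chr = <chromosome index>, start = <bp>,
#'   end = <bp>, log2_shift = <shift>)`. Both intensity channels are scaled by
#'   `2^log2_shift` inside the segment for the listed samples.
#' @param clock_spec Planted epigenetic clock: `list(probes = <indices>,
#'   weight = <years per beta unit>, intercept = <years>, noise_sd = <years>)`.
#'   Clock probes get beta values linear in chronological age so that the
#'   matching [clock_model()] recovers age up to `noise_sd`.
#' @param batch_effect_sd Standard deviation of per-plate, per-probe location
#'   shifts applied on the logit(beta) scale.
#' @param probe_fail_rate Fraction of sample-probe cells whose detection
#'   p-value is inflated to simulate failed probes.
#' @param age_range Chronological-age range (years) sampled uniformly.
#' @param type2_frac Fraction of probes with Infinium type II design.
#' @param type2_compression Multiplicative compression of type II beta values
#'   around 0.5, emulating the reduced dynamic range that motivates BMIQ.
#' @param seed Integer seed; identical config + seed gives identical cohorts.
#'
#' @return An object of class `sim_config`.
#' @seealso [generate_cohort()]
#' @export
sim_config <- function(n_fp = 16, n_sd = 17, n_probes = 10000, n_plates = 2,
                       dmp_spec = list(), dmr_spec = list(), cna_spec = list(),
                       clock_spec = NULL,
                       batch_effect_sd = 0.25, probe_fail_rate = 0.005,
                       age_range = c(45, 80),
                       type2_frac = 0.84, type2_compression = 0.75,
                       seed = 1L) {
  stopifnot(n_fp >= 1, n_sd >= 1, n_probes >= 1, n_plates >= 1,
            probe_fail_rate >= 0, probe_fail_rate <= 1,
            batch_effect_sd >= 0,
            type2_frac >= 0, type2_frac <= 1,
            type2_compression > 0, type2_compression <= 1,
            length(age_range) == 2, age_range[1] <= age_range[2])
  dmp_probes <- unlist(lapply(dmp_spec, function(d) {
    stopifnot(is.numeric(d$probes), abs(d$delta_beta) <= 1)
    d$probes
  }))
  clock_probes <- if (!is.null(clock_spec)) {
    stopifnot(is.numeric(clock_spec$probes), length(clock_spec$probes) >= 1,
              is.numeric(clock_spec$weight), is.numeric(clock_spec$intercept),
              clock_spec$noise_sd >= 0)
    clock_spec$probes
  } else integer()
  for (d in dmr_spec) {
    stopifnot(d$n >= 2, d$spacing >= 1, abs(d$delta_beta) <= 1)
  }
  if (anyDuplicated(dmp_probes)) {
    stop("overlapping planted DMP probe sets: probe index ",
         dmp_probes[duplicated(dmp_probes)][1])
  }
  coll <- intersect(dmp_probes, clock_probes)
  if (length(coll)) {
    stop("planted DMP probes collide with clock probes: ",
         paste(utils::head(coll, 5), collapse = ", "))
  }
  if (max(c(0, dmp_probes, clock_probes)) > n_probes) {
    stop("planted probe index exceeds n_probes")
  }
  structure(list(
    n_fp = as.integer(n_fp), n_sd = as.integer(n_sd),
    n_probes = as.integer(n_probes), n_plates = as.integer(n_plates),
    dmp_spec = dmp_spec, dmr_spec = dmr_spec, cna_spec = cna_spec,
    clock_spec = clock_spec,
    batch_effect_sd = batch_effect_sd, probe_fail_rate = probe_fail_rate,
    age_range = age_range, type2_frac = type2_frac,
    type2_compression = type2_compression, seed = as.integer(seed)
  ), class = "sim_config")
}

# Place probes on 22 autosomes: uniform spacing, with DMR clusters carved
# out of the tail of the probe pool and laid down at their own spacing.
build_manifest <- function(config) {
  n <- config$n_probes
  n_dmr_probes <- sum(vapply(config$dmr_spec, function(d) d$n, numeric(1)))
  n_bg <- n - n_dmr_probes
  if (n_bg < 22) stop("too few probes to cover 22 autosomes")
  chr_sizes <- round(seq(240, 50, length.out = 22)) # Mb, roughly hg-like taper
  chr_bg <- rep(1:22, times = round(n_bg * chr_sizes / sum(chr_sizes)))
  chr_bg <- chr_bg[seq_len(min(n_bg, length(chr_bg)))]
  if (length(chr_bg) < n_bg) chr_bg <- c(chr_bg, rep(22L, n_bg - length(chr_bg)))
  pos <- integer(n)
  chr <- integer(n)
  idx <- 1L
  for (c22 in 1:22) {
    k <- sum(chr_bg == c22)
    if (k == 0) next
    # uniform spacing across the chromosome, > typical maxGap so background
    # probes never chain into spurious region clusters
    pos[idx:(idx + k - 1)] <- seq(5000L, by = 50000L, length.out = k)
    chr[idx:(idx + k - 1)] <- c22
    idx <- idx + k
  }
  for (d in config$dmr_spec) {
    k <- d$n
    pos[idx:(idx + k - 1)] <- seq(d$start, by = d$spacing, length.out = k)
    chr[idx:(idx + k - 1)] <- d$chr
    idx <- idx + k
  }
  probe_id <- sprintf("cg%08d", seq_len(n))
  islands <- c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf", "OpenSea")
  tibble::tibble(
    probe_id = probe_id,
    chr = paste0("chr", chr),
    pos = as.integer(pos),
    design_type = sample(c("I", "II"), n, replace = TRUE,
                         prob = c(1 - config$type2_frac, config$type2_frac)),
    island_relation = sample(islands, n, replace = TRUE,
                             prob = c(0.2, 0.1, 0.1, 0.05, 0.05, 0.5)),
    gene = ifelse(stats::runif(n) < 0.6,
                  paste0("GENE", 1 + (seq_len(n) - 1L) %/% 4L), "")
  )
}

#' Generate a synthetic methylation cohort with known ground truth
#'
#' Simulates a complete two-group EPIC-style cohort: a beta-value matrix,
#' methylated/unmethylated intensity channels, detection p-values, a probe
#' manifest, a sample sheet and a `truth` record of everything planted.
#' Baseline beta values follow a three-component mixture (unmethylated,
#' hemimethylated, methylated probes); type II probes are compressed toward
#' 0.5; group effects, plate batch effects (logit scale), copy-number
#' intensity shifts and an age-linear clock signal are planted per `config`.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `synthetic_cohort`: a list with matrices
#'   `beta`, `meth`, `unmeth`, `detp` (samples x probes, dimnames set),
#'   tibbles `annotation` and `samples`, and a `truth` list naming the
#'   planted DMP/DMR/CNA/clock probes and failed cells.
#' @examples
#' cohort <- generate_cohort(sim_config(n_fp = 4, n_sd = 4, n_probes = 500))
#' dim(cohort$beta)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_samp <- config$n_fp + config$n_sd
  n <- config$n_probes

  annotation <- build_manifest(config)
  # DMR probes occupy the tail of the probe pool, in spec order
  n_dmr_probes <- sum(vapply(config$dmr_spec, function(d) d$n, numeric(1)))
  dmr_idx_pool <- if (n_dmr_probes) (n - n_dmr_probes + 1L):n else integer()

  group <- c(rep("FP", config$n_fp), rep("SD", config$n_sd))
  samples <- tibble::tibble(
    sample_id = sprintf("S%02d", seq_len(n_samp)),
    group = group,
    plate = paste0("plate", 1 + (seq_len(n_samp) - 1L) %% config$n_plates),
    age = round(stats::runif(n_samp, config$age_range[1], config$age_range[2]), 1),
    sex = sample(c("F", "M"), n_samp, replace = TRUE),
    leukocytes = round(stats::rlnorm(n_samp, log(9), 0.4), 1),
    platelets = round(stats::rlnorm(n_samp, log(600), 0.35)),
    hemoglobin = round(stats::rnorm(n_samp, 13, 1.5), 1),
    hmr = stats::rbinom(n_samp, 1, ifelse(group == "FP", 0.45, 0.08))
  )

  # baseline: per-probe 3-state mixture mean, then per-sample Beta noise
  state <- sample(1:3, n, replace = TRUE, prob = c(0.35, 0.15, 0.5))
  probe_mean <- numeric(n)
  probe_mean[state == 1] <- stats::rbeta(sum(state == 1), 2, 18)  # unmethylated
  probe_mean[state == 2] <- stats::rbeta(sum(state == 2), 12, 12) # hemimethylated
  probe_mean[state == 3] <- stats::rbeta(sum(state == 3), 18, 2)  # methylated
  conc <- 80 # per-probe precision of sample-level Beta noise
  beta <- matrix(stats::rbeta(n_samp * n,
                              rep(probe_mean, each = n_samp) * conc,
                              rep(1 - probe_mean, each = n_samp) * conc),
                 nrow = n_samp, ncol = n)

  # planted group effects (beta scale, FP samples)
  truth_dmp <- integer(); truth_delta <- numeric()
  for (d in config$dmp_spec) {
    beta[group == "FP", d$probes] <- beta[group == "FP", d$probes] + d$delta_beta
    truth_dmp <- c(truth_dmp, d$probes)
    truth_delta <- c(truth_delta, rep(d$delta_beta, length(d$probes)))
  }
  truth_dmr <- list()
  off <- 0L
  for (i in seq_along(config$dmr_spec)) {
    d <- config$dmr_spec[[i]]
    idx <- dmr_idx_pool[(off + 1L):(off + d$n)]
    off <- off + d$n
    beta[group == "FP", idx] <- beta[group == "FP", idx] + d$delta_beta
    truth_dmr[[i]] <- list(chr = paste0("chr", d$chr), probes = idx,
                           probe_ids = annotation$probe_id[idx],
                           delta_beta = d$delta_beta)
  }

  # clock signal: beta linear in chronological age, inverse of the planted clock
  truth_clock <- NULL
  if (!is.null(config$clock_spec)) {
    cs <- config$clock_spec
    k <- length(cs$probes)
    span <- k * cs$weight
    b_age <- (samples$age - cs$intercept) / span
    if (any(b_age < 0 | b_age > 1)) {
      stop("clock_spec maps some ages outside [0,1] on the beta scale; ",
           "adjust weight/intercept")
    }
    sd_b <- cs$noise_sd / (cs$weight * sqrt(k))
    beta[, cs$probes] <- b_age +
      matrix(stats::rnorm(n_samp * k, 0, sd_b), n_samp, k)
    truth_clock <- list(probes = cs$probes,
                        probe_ids = annotation$probe_id[cs$probes],
                        weight = cs$weight, intercept = cs$intercept)
  }

  # plate batch effects on the logit scale keep beta inside (0,1)
  if (config$batch_effect_sd > 0 && config$n_plates > 1) {
    plate_f <- factor(samples$plate)
    gamma <- matrix(stats::rnorm(nlevels(plate_f) * n, 0, config$batch_effect_sd),
                    nlevels(plate_f), n)
    m <- stats::qlogis(pmin(pmax(beta, 1e-6), 1 - 1e-6))
    beta <- stats::plogis(m + gamma[as.integer(plate_f), , drop = FALSE])
  }

  # type II compression toward 0.5 (reduced dynamic range)
  type2 <- annotation$design_type == "II"
  beta[, type2] <- 0.5 + config$type2_compression * (beta[, type2] - 0.5)
  beta <- pmin(pmax(beta, 0), 1)

  # intensities: beta = meth / (meth + unmeth + offset), offset 100
  offset <- 100
  total <- matrix(stats::rlnorm(n_samp * n, log(4000), 0.2), n_samp, n)
  meth <- beta * (total + offset)
  unmeth <- pmax(total - meth, 1)

  truth_cna <- list()
  for (i in seq_along(config$cna_spec)) {
    cv <- config$cna_spec[[i]]
    in_seg <- which(annotation$chr == paste0("chr", cv$chr) &
                      annotation$pos >= cv$start & annotation$pos <= cv$end)
    fac <- 2^cv$log2_shift
    meth[cv$samples, in_seg] <- meth[cv$samples, in_seg] * fac
    unmeth[cv$samples, in_seg] <- unmeth[cv$samples, in_seg] * fac
    truth_cna[[i]] <- list(samples = cv$samples, chr = paste0("chr", cv$chr),
                           start = cv$start, end = cv$end,
                           probes = in_seg, log2_shift = cv$log2_shift)
  }
  # channel measurement noise
  meth <- meth * stats::rlnorm(n_samp * n, 0, 0.03)
  unmeth <- unmeth * stats::rlnorm(n_samp * n, 0, 0.03)

  detp <- matrix(stats::runif(n_samp * n, 0, 0.01), n_samp, n)
  failed <- matrix(stats::runif(n_samp * n) < config$probe_fail_rate, n_samp, n)
  detp[failed] <- stats::runif(sum(failed), 0.2, 1)

  dn <- list(samples$sample_id, annotation$probe_id)
  dimnames(beta) <- dimnames(meth) <- dimnames(unmeth) <- dimnames(detp) <- dn

  structure(list(
    beta = beta, meth = meth, unmeth = unmeth, detp = detp,
    annotation = annotation, samples = samples,
    truth = list(
      dmp = list(probes = truth_dmp, probe_ids = annotation$probe_id[truth_dmp],
                 delta_beta = truth_delta),
      dmr = truth_dmr, cna = truth_cna, clock = truth_clock,
      failed_cells = which(failed, arr.ind = TRUE)
    ),
    config = config
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", nrow(x$beta), " samples x ", ncol(x$beta),
      " probes (", sum(x$samples$group == "FP"), " FP / ",
      sum(x$samples$group == "SD"), " SD)\n", sep = "")
  cat("  planted: ", length(x$truth$dmp$probes), " DMPs, ",
      length(x$truth$dmr), " DMRs, ", length(x$truth$cna), " CNA segments, ",
      if (is.null(x$truth$clock)) "no clock" else
        paste0(length(x$truth$clock$probes), "-probe clock"), "\n", sep = "")
  invisible(x)
}
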
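#' Combined methylation-array intensity
#'
#' Per probe and sample, the total signal `meth + unmeth` used for
#' copy-number work (combined-intensity convention of methylation-array
#' CNA tools).
#'
#' @param meth,unmeth Nonnegative samples x probes intensity matrices.
#' @return Total-intensity matrix of the same shape.
#' @export
combined_intensity <- function(meth, unmeth) {
  stopifnot(all(dim(meth) == dim(unmeth)))
  if (any(meth < 0) || any(unmeth < 0)) stop("negative intensity")
  meth + unmeth
}

#' Per-probe log2 copy ratios against a reference cohort
#'
#' Each probe's ratio is `log2(sample / median(reference))`, then the
#' sample's median autosomal log2 ratio is recentered to 0 so that array
#' scale differences (and whole-genome ploidy, which a relative assay
#' cannot see) are removed. Probes whose reference median is zero are
#' dropped with a message.
#'
#' @param sample_total Named total-intensity vector for the query sample
#'   (or a median profile across query samples).
#' @param reference_totals Samples x probes total-intensity matrix of the
#'   reference cohort (>= 3 samples).
#' @return Named vector of per-probe log2 ratios (dropped probes absent).
#' @export
log2_ratio <- function(sample_total, reference_totals) {
  stopifnot(nrow(reference_totals) >= 3,
            length(sample_total) == ncol(reference_totals))
  ref_med <- apply(reference_totals, 2, stats::median)
  ok <- ref_med > 0 & sample_total > 0
  if (!all(ok)) {
    message(sum(!ok), " probe(s) dropped: zero reference median or signal")
  }
  r <- log2(sample_total[ok] / ref_med[ok])
  r - stats::median(r)
}

# Best single split of a ratio stretch by two-sample t-statistic; returns
# the split index (last probe of the left part) and its p-value.
best_split <- function(x, min_probes) {
  n <- length(x)
  if (n < 2 * min_probes) return(NULL)
  cand <- min_probes:(n - min_probes)
  stat <- vapply(cand, function(i) {
    a <- x[1:i]; b <- x[(i + 1):n]
    sp <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
      (length(a) + length(b) - 2)
    if (sp <= 1e-30) {
      # zero pooled variance: an exact level shift is an infinitely strong
      # split, a constant stretch offers no split at all
      return(if (abs(mean(a) - mean(b)) < 1e-12) 0 else Inf)
    }
    abs(mean(a) - mean(b)) / sqrt(sp * (1 / length(a) + 1 / length(b)))
  }, numeric(1))
  i <- cand[which.max(stat)]
  tmax <- max(stat)
  p <- if (is.infinite(tmax)) 0 else 2 * stats::pt(-tmax, df = n - 2)
  list(split = i, p = p)
}

segment_one_chr <- function(x, pos, min_probes, alpha) {
  n <- length(x)
  if (n < 2 * min_probes) {
    return(tibble::tibble(start = pos[1], end = pos[n], n_probes = n,
                          seg_log2 = mean(x),
                          first = 1L, last = n))
  }
  bs <- best_split(x, min_probes)
  if (is.null(bs) || bs$p >= alpha) {
    return(tibble::tibble(start = pos[1], end = pos[n], n_probes = n,
                          seg_log2 = mean(x),
                          first = 1L, last = n))
  }
  left <- segment_one_chr(x[1:bs$split], pos[1:bs$split], min_probes, alpha)
  right <- segment_one_chr(x[(bs$split + 1):n], pos[(bs$split + 1):n],
                           min_probes, alpha)
  right$first <- right$first + bs$split
  right$last <- right$last + bs$split
  dplyr::bind_rows(left, right)
}

#' Segment a log2 copy-ratio profile
#'
#' Recursive binary segmentation per chromosome: each stretch is split at
#' the position maximizing the two-sample t-statistic between its flanks;
#' a split is accepted when its p-value is below `alpha` and both sides
#' retain at least `min_probes` probes. Segment values are the means of
#' their probes, so the per-segment probe mean is conserved exactly.
#'
#' @param ratios Named per-probe log2 ratio vector.
#' @param annotation Probe manifest with `probe_id`, `chr`, `pos`.
#' @param min_probes Minimum probes per segment (default 10).
#' @param alpha Split acceptance p-value (default 0.01).
#' @return Tibble of segments: `chr`, `start`, `end` (1-based inclusive
#'   probe positions), `n_probes`, `seg_log2`; contiguous, non-overlapping
#'   and covering all retained probes per chromosome.
#' @export
segment_profile <- function(ratios, annotation, min_probes = 10,
                            alpha = 0.01) {
  ann <- annotation[match(names(ratios), annotation$probe_id), ]
  stopifnot(!anyNA(ann$chr))
  out <- list()
  for (ch in unique(ann$chr)) {
    sel <- which(ann$chr == ch)
    sel <- sel[order(ann$pos[sel])]
    seg <- segment_one_chr(ratios[sel], ann$pos[sel], min_probes, alpha)
    seg$chr <- ch
    out[[ch]] <- seg[, c("chr", "start", "end", "n_probes", "seg_log2")]
  }
  dplyr::bind_rows(out)
}

#' Call copy-number gains and losses from segments
#'
#' A segment is a gain when its mean log2 ratio is at least `threshold`, a
#' loss when at most `-threshold` (boundary inclusive), otherwise neutral.
#'
#' @param segments Segment tibble from [segment_profile()].
#' @param threshold Absolute log2 call threshold (> 0; default 0.5).
#' @return The segment tibble with a `call` column in
#'   `{"gain", "loss", "neutral"}`.
#' @export
call_cna <- function(segments, threshold = 0.5) {
  stopifnot(threshold > 0)
  segments$call <- ifelse(segments$seg_log2 >= threshold, "gain",
                          ifelse(segments$seg_log2 <= -threshold, "loss",
                                 "neutral"))
  segments
}

#' Full copy-number profile of one group against a reference group
#'
#' Convenience pipeline for the median-vs-reference design: computes
#' combined intensities, takes the per-probe median of the query group,
#' forms log2 ratios against the reference group, segments and calls.
#'
#' @param meth,unmeth Intensity matrices for all samples.
#' @param groups Per-sample labels.
#' @param query,reference Group labels for the query and reference cohorts.
#' @param annotation Probe manifest.
#' @param min_probes,alpha,threshold Passed through to
#'   [segment_profile()] and [call_cna()].
#' @return List with `ratios` (per-probe tibble: probe_id, chr, pos,
#'   log2_ratio) and `segments` (called segment tibble).
#' @export
cna_profile <- function(meth, unmeth, groups, query = "FP",
                        reference = "SD", annotation,
                        min_probes = 10, alpha = 0.01, threshold = 0.5) {
  total <- combined_intensity(meth, unmeth)
  qmed <- apply(total[groups == query, , drop = FALSE], 2, stats::median)
  ratios <- log2_ratio(qmed, total[groups == reference, , drop = FALSE])
  seg <- call_cna(segment_profile(ratios, annotation,
                                  min_probes = min_probes, alpha = alpha),
                  threshold = threshold)
  ann <- annotation[match(names(ratios), annotation$probe_id), ]
  list(ratios = tibble::tibble(probe_id = names(ratios), chr = ann$chr,
                               pos = ann$pos, log2_ratio = unname(ratios)),
       segments = seg)
}

#' Write segments in SEG format
#'
#' Tab-delimited SEG (sample, chrom, loc.start, loc.end, num.mark,
#' seg.mean), 1-based coordinates.
#'
#' @param segments Called or uncalled segment tibble.
#' @param sample_id Sample (or group) identifier for the first column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_seg <- function(segments, sample_id, path) {
  out <- data.frame(ID = sample_id, chrom = segments$chr,
                    loc.start = segments$start, loc.end = segments$end,
                    num.mark = segments$n_probes,
                    seg.mean = segments$seg_log2)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
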
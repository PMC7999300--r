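#' Per-bin log2 depth ratios of tumour vs matched normal
#'
#' Library-size-normalises both samples, then computes
#' `log2((t_i / T) / (n_i / N))` per bin. Bins whose raw normal count falls
#' below `min_count` are masked (NA ratio) — the normal provides no reliable
#' baseline there.
#'
#' @param tumour,normal Depth-bin data.frames (chrom, start, end, count)
#'   with identical binning.
#' @param min_count Minimum normal read count per usable bin (default 10).
#' @return data.frame chrom, start, end, log2_ratio (NA where masked).
#' @export
log2_ratios <- function(tumour, normal, min_count = 10) {
  if (nrow(tumour) != nrow(normal) ||
      !all(tumour$chrom == normal$chrom & tumour$start == normal$start &
             tumour$end == normal$end))
    stop("tumour and normal bins must share identical binning")
  Tt <- sum(tumour$count); Nn <- sum(normal$count)
  r <- log2((tumour$count / Tt) / (normal$count / Nn))
  r[normal$count < min_count | tumour$count == 0] <- NA
  data.frame(chrom = tumour$chrom, start = tumour$start, end = tumour$end,
             log2_ratio = r, stringsAsFactors = FALSE)
}

#' Segment log2 ratios by recursive binary change-point splitting
#'
#' A documented simplification of circular binary segmentation (no
#' permutation p-values, no circular wrap): at each recursion step the
#' candidate sub-segment maximising the two-sample t statistic against the
#' rest of the current segment is found by a joint scan over both
#' boundaries; the split is accepted when `|t| >= t_threshold` and every
#' resulting piece keeps at least `min_bins` bins, and recursion continues
#' on the pieces. The noise scale in the t statistic is estimated robustly
#' from successive bin differences. Final segments are called loss/gain/neutral by
#' mean ratio against `loss_cut`/`gain_cut`, and flagged `large_scale` when
#' longer than `large_scale_bp` (10 Mb scaled by the miniaturisation factor).
#'
#' @param ratios Output of [log2_ratios()].
#' @param min_bins Minimum bins per segment (default 5).
#' @param t_threshold t statistic needed to accept a split (default 5).
#' @param loss_cut,gain_cut Mean-ratio call thresholds (defaults -0.3/+0.3).
#' @param large_scale_bp Length threshold for the large-scale flag
#'   (default 10 Mb * 0.02 miniaturisation = 200 kb).
#' @return data.frame of class `cna_segments`: chrom, start, end, n_bins,
#'   mean_log2_ratio, call, large_scale.
#' @export
segment_ratios <- function(ratios, min_bins = 5L, t_threshold = 5.0,
                           loss_cut = -0.3, gain_cut = 0.3,
                           large_scale_bp = 10e6 * 0.02) {
  out <- lapply(split(ratios, ratios$chrom), function(rc) {
    rc <- rc[order(rc$start), , drop = FALSE]
    keep <- !is.na(rc$log2_ratio)
    rc <- rc[keep, , drop = FALSE]
    if (nrow(rc) < min_bins) return(NULL)
    # noise scale estimated once per chromosome: successive-difference MAD
    # is robust to level shifts and stable, unlike per-segment estimates
    s2 <- (stats::median(abs(diff(rc$log2_ratio))) /
             (sqrt(2) * stats::qnorm(0.75)))^2
    if (s2 == 0) s2 <- stats::var(rc$log2_ratio)
    segs <- split_recursive(rc$log2_ratio, min_bins, t_threshold, s2)
    data.frame(chrom = rc$chrom[1],
               start = rc$start[segs$start],
               end = rc$end[segs$end],
               n_bins = segs$end - segs$start + 1L,
               mean_log2_ratio = segs$mean,
               stringsAsFactors = FALSE)
  })
  seg <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(seg))
    seg <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n_bins = integer(),
                      mean_log2_ratio = numeric())
  rownames(seg) <- NULL
  seg$call <- ifelse(seg$mean_log2_ratio <= loss_cut, "loss",
                     ifelse(seg$mean_log2_ratio >= gain_cut, "gain",
                            "neutral"))
  seg$large_scale <- (seg$end - seg$start) > large_scale_bp
  class(seg) <- c("cna_segments", "data.frame")
  seg
}

# returns data.frame of (start index, end index, mean) over x.
# Each recursion step scans all candidate segments [i..j] jointly against
# their complement (the circular-binary-segmentation move), which localises
# both boundaries of an interior event; a single-point split would smear
# them. The noise scale is estimated robustly from successive differences
# (MAD-based), so an unsplit level shift cannot inflate the denominator and
# mask its own change-point.
split_recursive <- function(x, min_bins, t_threshold, s2) {
  n <- length(x)
  best <- best_segment(x, min_bins, s2)
  if (is.null(best) || abs(best$t) < t_threshold)
    return(data.frame(start = 1L, end = n, mean = mean(x)))
  parts <- list()
  if (best$i > 1L)
    parts <- c(parts, list(cbind(1L, best$i - 1L)))
  parts <- c(parts, list(cbind(best$i, best$j)))
  if (best$j < n)
    parts <- c(parts, list(cbind(best$j + 1L, n)))
  out <- lapply(parts, function(p) {
    sub <- split_recursive(x[p[1]:p[2]], min_bins, t_threshold, s2)
    sub$start <- sub$start + p[1] - 1L
    sub$end <- sub$end + p[1] - 1L
    sub
  })
  do.call(rbind, out)
}

best_segment <- function(x, min_bins, s2) {
  n <- length(x)
  if (n < 2L * min_bins) return(NULL)
  if (is.na(s2) || s2 == 0) return(NULL)     # constant data: nothing to split
  cs <- c(0, cumsum(x))
  tot <- cs[n + 1]
  best <- list(t = 0, i = NA_integer_, j = NA_integer_)
  for (i in seq_len(n - min_bins + 1L)) {
    if (i - 1L != 0L && i - 1L < min_bins) next   # left remainder too short
    j <- seq.int(i + min_bins - 1L, n)
    j <- j[n - j == 0L | n - j >= min_bins]       # right remainder too short
    if (i == 1L) j <- j[j != n]                   # segment must be proper
    if (!length(j)) next
    nin <- j - i + 1L
    nout <- n - nin
    m_in <- (cs[j + 1L] - cs[i]) / nin
    m_out <- (tot - (cs[j + 1L] - cs[i])) / nout
    tstat <- (m_in - m_out) / sqrt(s2 * (1 / nin + 1 / nout))
    k <- which.max(abs(tstat))
    if (abs(tstat[k]) > abs(best$t))
      best <- list(t = tstat[k], i = i, j = j[k])
  }
  if (is.na(best$i)) NULL else best
}

#' Filter tumour segments against a panel of normals
#'
#' Removes a tumour segment when any normal sample contains a segment with
#' the same call overlapping it by at least `min_reciprocal` reciprocal
#' overlap — CNAs also seen in normal tissues are recurrent artefacts, not
#' somatic events. Idempotent. Neutral tumour segments are never removed.
#'
#' @param segments Tumour `cna_segments`.
#' @param normals List of `cna_segments` from normal tissues.
#' @param min_reciprocal Reciprocal-overlap fraction (default 0.5).
#' @return Filtered `cna_segments`; removed rows are reported in the
#'   `removed` attribute together with the matching normal index.
#' @export
filter_panel <- function(segments, normals, min_reciprocal = 0.5) {
  if (!length(normals)) stop("need at least one normal sample's segments")
  drop <- logical(nrow(segments))
  why <- rep(NA_integer_, nrow(segments))
  for (i in seq_len(nrow(segments))) {
    if (segments$call[i] == "neutral") next
    for (k in seq_along(normals)) {
      nm <- normals[[k]]
      same <- nm$call == segments$call[i] & nm$chrom == segments$chrom[i]
      if (!any(same)) next
      nm <- nm[same, , drop = FALSE]
      ov <- pmin(nm$end, segments$end[i]) - pmax(nm$start, segments$start[i])
      lenT <- segments$end[i] - segments$start[i]
      lenN <- nm$end - nm$start
      hit <- ov > 0 & ov / lenT >= min_reciprocal &
        ov / lenN >= min_reciprocal
      if (any(hit)) { drop[i] <- TRUE; why[i] <- k; break }
    }
  }
  out <- segments[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- cbind(segments[drop, , drop = FALSE],
                                matched_normal = why[drop])
  class(out) <- c("cna_segments", "data.frame")
  out
}

#' Recombination status of an engineered locus from read depth
#'
#' Compares normalised tumour-over-normal depth across a target interval
#' (e.g. the floxed exon cassette of a conditional allele): biallelic
#' excision removes nearly all reads, monoallelic excision about half.
#'
#' @param tumour,normal Depth-bin data.frames with identical binning.
#' @param interval List or data.frame row with chrom, start, end.
#' @param hom_cut,het_cut Ratio thresholds: below `hom_cut` (0.25) ->
#'   `homozygous_recombined`; below `het_cut` (0.75) -> `heterozygous`;
#'   otherwise `not_recombined`.
#' @return Character status, or `"undetermined"` if the normal has no
#'   coverage on the interval.
#' @export
recombination_status <- function(tumour, normal, interval,
                                 hom_cut = 0.25, het_cut = 0.75) {
  sel <- tumour$chrom == interval$chrom &
    tumour$start < interval$end & tumour$end > interval$start
  tn <- sum(tumour$count[sel]); nn <- sum(normal$count[sel])
  if (nn == 0) return("undetermined")
  r <- (tn / sum(tumour$count)) / (nn / sum(normal$count))
  if (r < hom_cut) "homozygous_recombined"
  else if (r < het_cut) "heterozygous"
  else "not_recombined"
}

#' Association between Tp53 status and large-scale CNAs
#'
#' Two-sided Fisher exact test on the 2x2 table of per-sample Tp53
#' inactivation vs presence of at least one large-scale CNA.
#'
#' @param tp53_mut Logical vector per sample.
#' @param has_large_cna Logical vector per sample.
#' @return List with `table` (2x2) and `p_value` (1, with a note, when a
#'   margin is degenerate).
#' @export
associate_cna_genotype <- function(tp53_mut, has_large_cna) {
  stopifnot(length(tp53_mut) == length(has_large_cna))
  tab <- table(factor(tp53_mut, levels = c(FALSE, TRUE)),
               factor(has_large_cna, levels = c(FALSE, TRUE)),
               dnn = c("tp53_mut", "large_cna"))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(table = tab, p_value = 1,
                note = "degenerate margin; no test possible"))
  list(table = tab, p_value = fisher.test(tab)$p.value, note = NULL)
}

#' Write CNA segments as BED5+ (chrom, start, end, call, mean_log2, flag)
#' @param segments `cna_segments`.
#' @param path Output file.
#' @export
write_segments_bed <- function(segments, path) {
  df <- data.frame(chrom = segments$chrom, start = segments$start,
                   end = segments$end, name = segments$call,
                   score = round(segments$mean_log2_ratio, 4),
                   large_scale = as.integer(segments$large_scale))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
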
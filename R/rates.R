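#' Regression of SNS burden on tumour age
#'
#' Ordinary least squares of per-organoid coding+splice SNS counts on the
#' weeks elapsed between driver induction and sacrifice. The slope estimates
#' the SNS accrual rate per week.
#'
#' @param weeks Numeric vector of tumour ages (weeks).
#' @param sns_counts Matching SNS counts.
#' @return List of class `regression_result`: slope, intercept, r_squared,
#'   p_value (two-sided, on the slope), n, degenerate flag (TRUE when n = 2,
#'   where R^2 = 1 is forced).
#' @export
fit_rate_regression <- function(weeks, sns_counts) {
  stopifnot(length(weeks) == length(sns_counts))
  if (length(unique(weeks)) < 2) stop("need >= 2 distinct x values")
  fit <- lm(sns_counts ~ weeks)
  sm <- suppressWarnings(summary(fit))   # perfect fits warn harmlessly
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p_value = if (nrow(sm$coefficients) > 1 &&
                               ncol(sm$coefficients) >= 4)
                   sm$coefficients[2, 4] else NA_real_,
                 n = length(weeks),
                 degenerate = length(weeks) == 2),
            class = "regression_result")
}

#' Cell doubling time from seeding and harvest counts
#'
#' `duration * log(2) / (log(N_harvest) - log(N_seed))`; the ratio of
#' logarithms makes the result invariant to the logarithm base.
#'
#' @param cells_at_seeding,cells_at_harvest Positive cell counts, harvest
#'   strictly greater than seeding.
#' @param duration_hours Elapsed culture time in hours.
#' @return Doubling time in hours.
#' @export
doubling_time <- function(cells_at_seeding, cells_at_harvest,
                          duration_hours) {
  if (any(cells_at_seeding <= 0) || any(cells_at_harvest <= 0))
    stop("cell counts must be > 0")
  if (any(cells_at_harvest <= cells_at_seeding))
    stop("no doubling: harvest count must exceed seeding count")
  if (any(duration_hours <= 0)) stop("duration must be > 0")
  duration_hours * log(2) / (log(cells_at_harvest) - log(cells_at_seeding))
}

#' Stratify SNS density by replication timing and genomic territory
#'
#' Assigns each variant a (timing stratum, territory) pair and reports
#' counts and per-Mb densities. Raw per-Mb densities are reported;
#' triplet-matched comparisons can be built by combining these counts with
#' [triplet_census()] run per stratum.
#'
#' @param variants Variant data.frame (chrom, pos, and context when
#'   triplet matching is requested).
#' @param genome A `genome_model` (provides timing domains and territory
#'   masks).
#' @return data.frame of class `stratum_density`: timing, territory,
#'   sns_count, territory_bp, density_per_mb. Variants outside any timing
#'   domain land in stratum "undefined".
#' @export
timing_strata <- function(variants, genome) {
  masks <- territory_masks(genome)
  td <- genome$timing
  n <- nrow(variants)
  timing <- rep("undefined", n)
  terr <- rep("intergenic", n)
  if (n) {
    vg <- GenomicRanges::GRanges(variants$chrom,
                                 IRanges::IRanges(variants$pos + 1L,
                                                  variants$pos + 1L))
    tg <- GenomicRanges::GRanges(td$chrom,
                                 IRanges::IRanges(td$start + 1L, td$end))
    hit <- GenomicRanges::findOverlaps(vg, tg, select = "first")
    timing[!is.na(hit)] <- td$stratum[hit[!is.na(hit)]]
    for (m in c("coding", "intronic")) {
      inm <- !is.na(GenomicRanges::findOverlaps(vg, masks[[m]],
                                                select = "first"))
      terr[inm] <- m
    }
  }
  # territory bp per (timing, territory) cell
  tg <- GenomicRanges::GRanges(td$chrom,
                               IRanges::IRanges(td$start + 1L, td$end))
  strata <- unique(td$stratum)
  rows <- list()
  for (st in strata) for (m in names(masks)) {
    cell_bp <- sum(as.numeric(GenomicRanges::width(
      GenomicRanges::intersect(masks[[m]], tg[td$stratum == st]))))
    cnt <- sum(timing == st & terr == m)
    rows[[paste(st, m)]] <- data.frame(
      timing = st, territory = m, sns_count = cnt, territory_bp = cell_bp,
      density_per_mb = if (cell_bp > 0) cnt / (cell_bp / 1e6) else NA,
      stringsAsFactors = FALSE)
  }
  undef <- sum(timing == "undefined")
  if (undef)
    rows[["undefined"]] <- data.frame(timing = "undefined", territory = "any",
                                      sns_count = undef, territory_bp = 0,
                                      density_per_mb = NA)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("stratum_density", "data.frame")
  out
}

#' Pairwise burden comparison across organoid groups
#'
#' Two-sided t tests between every pair of groups (classic Student's pooled
#' test by default, Welch optional), with Benjamini-Hochberg adjustment
#' across all reported pairs. Identical zero-variance groups get p = 1.
#'
#' @param groups Named list of numeric vectors (per-organoid SNS counts),
#'   each of length >= 2.
#' @param var_equal Use the pooled-variance Student's test (default TRUE).
#' @return data.frame: group1, group2, t, p_raw, p_adjusted.
#' @export
compare_burden <- function(groups, var_equal = TRUE) {
  stopifnot(length(groups) >= 2, all(lengths(groups) >= 2))
  nm <- names(groups)
  pairs <- utils::combn(length(groups), 2)
  res <- apply(pairs, 2, function(ij) {
    x <- groups[[ij[1]]]; y <- groups[[ij[2]]]
    if (stats::var(x) == 0 && stats::var(y) == 0 && mean(x) == mean(y))
      return(c(t = 0, p = 1))
    tt <- t.test(x, y, var.equal = var_equal)
    c(t = unname(tt$statistic), p = tt$p.value)
  })
  out <- data.frame(group1 = nm[pairs[1, ]], group2 = nm[pairs[2, ]],
                    t = res["t", ], p_raw = res["p", ],
                    stringsAsFactors = FALSE)
  out$p_adjusted <- p.adjust(out$p_raw, method = "BH")
  out
}
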
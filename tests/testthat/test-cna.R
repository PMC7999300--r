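flat_bins <- function(n = 300, count = 100L, chrom = "c1", bin = 1000L) {
  data.frame(chrom = chrom, start = seq(0L, by = bin, length.out = n),
             end = seq(bin, by = bin, length.out = n),
             count = rep(count, n), stringsAsFactors = FALSE)
}

test_that("log2 ratios are 0 for self-comparison and -1 for half depth", {
  b <- flat_bins()
  r <- log2_ratios(b, b)
  expect_true(all(r$log2_ratio == 0))
  t2 <- b; t2$count[101:120] <- 50L
  r2 <- log2_ratios(t2, b)
  # library-size normalisation shifts everything slightly; compare deltas
  expect_equal(mean(r2$log2_ratio[101:120]) - mean(r2$log2_ratio[-(101:120)]),
               -1, tolerance = 1e-9)
  bad <- b[-1, ]
  expect_error(log2_ratios(bad, b), "binning")
  # low-coverage normal bins are masked
  nm <- b; nm$count[5] <- 3L
  expect_true(is.na(log2_ratios(b, nm)$log2_ratio[5]))
})

test_that("flat ratios yield one neutral segment per chromosome", {
  b <- flat_bins()
  r <- log2_ratios(b, b)
  seg <- segment_ratios(r)
  expect_identical(nrow(seg), 1L)
  expect_identical(seg$call, "neutral")
  expect_identical(seg$n_bins, 300L)
})

test_that("planted change-points are recovered within +-2 bins", {
  set.seed(61)
  hits <- 0L
  for (k in 1:100) {
    x <- rnorm(200, 0, 0.1)
    x[91:110] <- x[91:110] - 1          # 20-bin one-copy loss
    r <- data.frame(chrom = "c1", start = (0:199) * 1000L,
                    end = (1:200) * 1000L, log2_ratio = x)
    seg <- segment_ratios(r)
    losses <- seg[seg$call == "loss", ]
    ok <- nrow(losses) == 1 &&
      abs(losses$start / 1000 - 90) <= 2 &&
      abs(losses$end / 1000 - 110) <= 2
    hits <- hits + ok
  }
  expect_identical(hits, 100L)
})

test_that("pure noise yields <0.1 false segments per genome", {
  set.seed(62)
  extra <- 0L
  for (k in 1:100) {
    r <- data.frame(chrom = "c1", start = (0:299) * 1000L,
                    end = (1:300) * 1000L, log2_ratio = rnorm(300, 0, 0.1))
    seg <- segment_ratios(r)
    extra <- extra + (nrow(seg) - 1L) + sum(seg$call != "neutral")
  }
  expect_lt(extra / 100, 0.1)
})

test_that("segment means reproduce bin means and segments tile the extent", {
  set.seed(63)
  x <- rnorm(150, 0, 0.1); x[41:80] <- x[41:80] + 0.8
  r <- data.frame(chrom = "c1", start = (0:149) * 1000L,
                  end = (1:150) * 1000L, log2_ratio = x)
  seg <- segment_ratios(r)
  expect_identical(seg$start[1], 0L)
  expect_identical(seg$end[nrow(seg)], 150000L)
  expect_true(all(seg$start[-1] == seg$end[-nrow(seg)]))
  for (i in seq_len(nrow(seg))) {
    sel <- r$start >= seg$start[i] & r$end <= seg$end[i]
    expect_equal(seg$mean_log2_ratio[i], mean(x[sel]), tolerance = 1e-9)
  }
  # large-scale flag is exactly length > threshold
  expect_identical(seg$large_scale, (seg$end - seg$start) > 10e6 * 0.02)
})

test_that("panel-of-normals filtering matches a brute-force oracle", {
  mkseg <- function(start, end, call) {
    s <- data.frame(chrom = "c1", start = start, end = end,
                    n_bins = 10L, mean_log2_ratio = ifelse(call == "loss",
                                                           -1, 1),
                    call = call, stringsAsFactors = FALSE)
    s$large_scale <- FALSE
    class(s) <- c("cna_segments", "data.frame")
    s
  }
  tum <- mkseg(c(0L, 5000L, 20000L), c(3000L, 8000L, 30000L),
               c("loss", "gain", "loss"))
  norm <- list(mkseg(0L, 3000L, "loss"),      # exact match: removed
               mkseg(21000L, 29000L, "gain")) # wrong call: retained
  out <- filter_panel(tum, norm)
  expect_identical(out$start, c(5000L, 20000L))
  # idempotent
  expect_identical(filter_panel(out, norm)$start, out$start)
  # randomized sets vs O(n^2) oracle
  set.seed(64)
  for (k in 1:20) {
    ts <- sort(sample(seq(0L, 90000L, 1000L), 6))
    tum <- mkseg(ts, ts + sample(2:9, 6, TRUE) * 1000L,
                 sample(c("loss", "gain"), 6, TRUE))
    ns <- sort(sample(seq(0L, 90000L, 1000L), 6))
    nrm <- mkseg(ns, ns + sample(2:9, 6, TRUE) * 1000L,
                 sample(c("loss", "gain"), 6, TRUE))
    got <- filter_panel(tum, list(nrm))
    keep_oracle <- vapply(seq_len(nrow(tum)), function(i) {
      !any(vapply(seq_len(nrow(nrm)), function(j) {
        if (nrm$call[j] != tum$call[i]) return(FALSE)
        ov <- min(nrm$end[j], tum$end[i]) - max(nrm$start[j], tum$start[i])
        lt <- tum$end[i] - tum$start[i]; ln <- nrm$end[j] - nrm$start[j]
        ov > 0 && ov / lt >= 0.5 && ov / ln >= 0.5
      }, logical(1)))
    }, logical(1))
    expect_identical(got$start, tum$start[keep_oracle])
  }
})

test_that("recombination status calls match depth ratios", {
  b <- flat_bins(100)
  iv <- list(chrom = "c1", start = 40000L, end = 50000L)
  expect_identical(recombination_status(b, b, iv), "not_recombined")
  t_het <- b; t_het$count[41:50] <- 50L
  expect_identical(recombination_status(t_het, b, iv), "heterozygous")
  t_hom <- b; t_hom$count[41:50] <- 2L
  expect_identical(recombination_status(t_hom, b, iv),
                   "homozygous_recombined")
  n0 <- b; n0$count[41:50] <- 0L
  expect_identical(recombination_status(b, n0, iv), "undetermined")
  # simulated biallelic excision at depth 100: called in >=99/100 seeds
  set.seed(65)
  ok <- 0L
  for (k in 1:100) {
    tt <- b; tt$count <- rpois(100, 100)
    tt$count[41:50] <- rpois(10, 2)
    nn <- b; nn$count <- rpois(100, 100)
    ok <- ok + (recombination_status(tt, nn, iv) == "homozygous_recombined")
  }
  expect_gte(ok, 99L)
})

test_that("Tp53 association uses the Fisher exact test", {
  # perfect association in 10 + 10 samples
  res <- associate_cna_genotype(rep(c(FALSE, TRUE), each = 10),
                                rep(c(FALSE, TRUE), each = 10))
  # two-sided exact p: both perfectly-separated tables, 2 / C(20,10)
  expect_equal(res$p_value, 2 / choose(20, 10), tolerance = 1e-9)
  ident <- associate_cna_genotype(c(TRUE, TRUE, FALSE, FALSE),
                                  c(TRUE, FALSE, TRUE, FALSE))
  expect_identical(ident$p_value, 1)
  degen <- associate_cna_genotype(c(TRUE, TRUE), c(TRUE, FALSE))
  expect_identical(degen$p_value, 1)
  expect_match(degen$note, "degenerate")
})

test_that("simulated Tp53-gated cohorts show the association", {
  g <- build_genome(genome_config(chrom_lengths = c(c1 = 1e6, c2 = 1e6),
                                  n_genes = 0), seed = 66)
  tp53 <- rep(c(FALSE, TRUE), each = 10)
  large <- logical(20)
  for (i in 1:20) {
    cfg <- sim_config(driver_schedule = list(apc = 0, kras = 0,
                                             tp53 = if (tp53[i]) 0 else NA),
                      duration_weeks = 25, sns_rate_per_week = 0.01,
                      cna_rate_per_week_tp53null = 0.15,
                      cna_length_range_bp = c(1e5, 5e5))
    tr <- simulate_lineage(g, cfg, seed = 600 + i)
    cc <- clone_cnas(tr, "N1")
    large[i] <- nrow(cc) > 0 && any((cc$end - cc$start) > 10e6 * 0.02)
  }
  res <- associate_cna_genotype(tp53, large)
  expect_lt(res$p_value, 0.01)
})
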
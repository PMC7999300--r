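test_that("CNA gating on Tp53 is exact and rates are genotype-independent", {
  g <- fast_genome()
  # tp53 never mutated -> zero CNA events anywhere, for any replicate
  cfg <- sim_config(driver_schedule = list(apc = 0, kras = 0, tp53 = NA),
                    branching_times = c(3, 6), duration_weeks = 12)
  for (s in 1:5) {
    tr <- simulate_lineage(g, cfg, seed = s)
    expect_identical(sum(vapply(tr$state, function(st) nrow(st$cnas),
                                integer(1))), 0L)
  }
  # tp53 lost mid-way: CNAs only on edges overlapping the Tp53-null era
  cfg2 <- sim_config(driver_schedule = list(apc = 0, kras = 0, tp53 = 6),
                     branching_times = c(3), duration_weeks = 12,
                     cna_rate_per_week_tp53null = 1)
  tr <- simulate_lineage(g, cfg2, seed = 4)
  for (id in tr$nodes$id) {
    pc <- tr$private[[id]]
    if (!is.null(pc$cna) && nrow(pc$cna))
      expect_gt(tr$nodes$end[tr$nodes$id == id], 6)
  }
})

test_that("SNS counts are Poisson in elapsed time, independent of drivers", {
  g <- fast_genome()
  frac <- clonetrace:::coding_splice_fraction(g)
  rate <- 0.8 / frac
  n <- 40
  count_total <- function(tp53) {
    cfg <- sim_config(driver_schedule = list(apc = 0, kras = 0, tp53 = tp53),
                      duration_weeks = 2, cna_rate_per_week_tp53null = 0)
    vapply(seq_len(n), function(s) nrow(clone_mutations(
      simulate_lineage(g, cfg, seed = 1000 + s + if (is.na(tp53)) 0 else n),
      "N1")), integer(1))
  }
  a <- count_total(NA); b <- count_total(0)
  se <- sqrt(stats::var(a) / n + stats::var(b) / n)
  expect_lt(abs(mean(a) - mean(b)), 3 * se)
  expect_lt(abs(mean(c(a, b)) - rate * 2), 3 * sqrt(rate * 2 / (2 * n)))
})

test_that("realized contexts follow signature weights; infinite sites holds", {
  g <- fast_genome()
  cfg <- sim_config(signature_weights = c(sig1_like = 1, sig17_like = 0,
                                          uniform = 0),
                    sns_rate_per_week = 5, duration_weeks = 10,
                    driver_schedule = list(apc = 0, kras = 0, tp53 = NA))
  tr <- simulate_lineage(g, cfg, seed = 9)
  m <- clone_mutations(tr, "N1")
  expect_gt(nrow(m), 200)
  expect_gte(mean(grepl("C>T]G", m$context, fixed = TRUE)), 0.85)
  expect_false(anyDuplicated(paste(m$chrom, m$pos)) > 0)
  # ref matches the genome and context matches the sequence
  v <- variant_table(m$chrom, m$pos, m$ref, m$alt, genome = g)
  expect_identical(v$context, m$context)
})

test_that("missing context class fails with a clear message", {
  # genome with no CpG at all: sig1-like placement must fail loudly
  g <- genome_from_sequences(c(m = paste(rep("AT", 500), collapse = "")))
  cfg <- sim_config(signature_weights = c(sig1_like = 1, sig17_like = 0,
                                          uniform = 0),
                    sns_rate_per_week = 2, duration_weeks = 10)
  expect_error(simulate_lineage(g, cfg, seed = 1), "context class")
})

test_that("organoid sampling reflects local copy number", {
  g <- fast_genome()
  cfg <- sim_config(driver_schedule = list(apc = 0, kras = 0, tp53 = NA),
                    sns_rate_per_week = 2, duration_weeks = 10)
  tr <- simulate_lineage(g, cfg, seed = 21)
  o <- sample_organoid(tr, "N1", depth_mean = 100, seed = 3)
  m <- clone_mutations(tr, "N1")
  expect_identical(nrow(o$calls), nrow(m))        # every mutation emitted
  expect_identical(anyDuplicated(o$calls[c("chrom", "pos", "alt")]), 0L)
  expect_true(all(o$calls$sample_id == "N1"))
  expect_error(sample_organoid(tr, "N1", depth_mean = 0.5), "depth_mean")
  # loss with mutated copy retained -> VAF 1; lost -> absent: engineer states
  st <- tr$state$N1
  st$variants$tot_copies[1] <- 1L; st$variants$mut_copies[1] <- 1L
  st$variants$mut_copies[2] <- 0L
  tr$state$N1 <- st
  o2 <- sample_organoid(tr, "N1", depth_mean = 200, seed = 4)
  kept <- paste(o2$calls$chrom, o2$calls$pos)
  expect_false(paste(st$variants$chrom[2], st$variants$pos[2]) %in% kept)
  v1 <- o2$calls$vaf[kept == paste(st$variants$chrom[1], st$variants$pos[1])]
  expect_equal(v1, 1.0)
})

test_that("bulk sampling dilutes VAF by purity and clone fraction", {
  g <- fast_genome()
  cfg <- sim_config(driver_schedule = list(apc = 0, kras = 0, tp53 = NA),
                    sns_rate_per_week = 4, duration_weeks = 10,
                    branching_times = 5)
  tr <- simulate_lineage(g, cfg, seed = 33)
  leaves <- clone_leaves(tr)
  # purity 0.6, clone fraction 0.5: expected het VAF = 0.6 * 0.5 / 2 = 0.15
  b <- sample_bulk(tr, setNames(c(0.5, 0.5), leaves), purity = 0.6,
                   depth_mean = 2000, seed = 5)
  trunk <- clone_mutations(tr, "N1")
  key <- paste(b$calls$chrom, b$calls$pos)
  priv1 <- clone_mutations(tr, leaves[1])
  only1 <- setdiff(paste(priv1$chrom, priv1$pos), paste(trunk$chrom, trunk$pos))
  expect_equal(mean(b$calls$vaf[key %in% only1]), 0.15, tolerance = 0.01)
  # truncal VAF strictly above subclone-private VAF
  expect_gt(mean(b$calls$vaf[key %in% paste(trunk$chrom, trunk$pos)]),
            mean(b$calls$vaf[key %in% only1]))
  # purity 1, single clone: expectations match the organoid sampler
  b2 <- sample_bulk(tr, setNames(1, leaves[1]), purity = 1,
                    depth_mean = 2000, seed = 6)
  m1 <- clone_mutations(tr, leaves[1])
  expect_identical(nrow(b2$calls), nrow(m1))
  expect_equal(mean(b2$calls$vaf[b2$calls$total_depth > 0]), 0.5,
               tolerance = 0.02)
  expect_error(sample_bulk(tr, numeric(0)), "mixture")
  expect_error(sample_bulk(tr, setNames(1, leaves[1]), purity = 0), "purity")
})

test_that("duration near zero leaves only founder-era mutations", {
  g <- fast_genome()
  cfg <- sim_config(duration_weeks = 1e-6)
  tr <- simulate_lineage(g, cfg, seed = 2)
  expect_lte(nrow(clone_mutations(tr, "N1")), 1L)
})
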
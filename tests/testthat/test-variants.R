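test_that("known codon changes annotate as expected", {
  g <- toy_gene_genome()
  # exon1 covers [100,130); put a TGG codon at CDS positions 0-2
  g <- set_genome_seq(g, "chr", 100L, "TGGCTT")
  # TGG -> TGA at codon position 3: stop gained
  v <- data.frame(chrom = "chr", pos = 102L, ref = "G", alt = "A")
  expect_identical(as.character(annotate_consequence(v, g)), "nonsense")
  # CTT -> CTC at codon position 3 (Leu): synonymous
  v <- data.frame(chrom = "chr", pos = 105L, ref = "T", alt = "C")
  expect_identical(as.character(annotate_consequence(v, g)), "synonymous")
  # TGG -> TCG (Trp -> Ser): missense
  v <- data.frame(chrom = "chr", pos = 101L, ref = "G", alt = "C")
  expect_identical(as.character(annotate_consequence(v, g)), "missense")
  # intronic base just past exon1 end: splice site; 3 bp in: noncoding
  base_at <- function(p) substr(as.character(g$chromosomes[["chr"]]),
                                p + 1, p + 1)
  for (p in c(130L, 131L)) {
    v <- data.frame(chrom = "chr", pos = p, ref = base_at(p),
                    alt = setdiff(c("A", "C", "G", "T"), base_at(p))[1])
    expect_identical(as.character(annotate_consequence(v, g)), "splice_site")
  }
  v <- data.frame(chrom = "chr", pos = 135L, ref = base_at(135L),
                  alt = setdiff(c("A", "C", "G", "T"), base_at(135L))[1])
  expect_identical(as.character(annotate_consequence(v, g)), "noncoding")
  # ref mismatch is rejected with the position named
  v <- data.frame(chrom = "chr", pos = 102L,
                  ref = setdiff(c("A", "C", "G", "T"), base_at(102L))[1],
                  alt = base_at(102L))
  expect_error(annotate_consequence(v, g), "chr:102")
})

test_that("CDS annotation agrees with a full-translation oracle", {
  # oracle: rebuild and translate the entire CDS for ref and alt
  oracle <- function(v, g) {
    gene <- g$genes[1, ]
    es <- gene$exon_starts[[1]]; ee <- gene$exon_ends[[1]]
    s <- as.character(g$chromosomes[[gene$chrom]])
    cds <- paste(vapply(seq_along(es), function(j)
      substr(s, es[j] + 1, ee[j]), character(1)), collapse = "")
    idx <- sum(pmax(0, pmin(ee, v$pos) - es))   # 0-based within plus CDS
    mut <- cds
    substr(mut, idx + 1, idx + 1) <- v$alt
    tx <- function(x) {
      if (gene$strand == "-")
        x <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(x)))
      as.character(Biostrings::translate(Biostrings::DNAString(x),
                                         no.init.codon = TRUE))
    }
    a <- tx(cds); b <- tx(mut)
    d <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    if (!length(d)) "synonymous"
    else if (substr(b, d[1], d[1]) == "*") "nonsense"
    else "missense"
  }
  for (strand in c("+", "-")) {
    g <- toy_gene_genome(seed = if (strand == "+") 7 else 8)
    g$genes$strand <- strand
    set.seed(17)
    exonic <- c(100:129, 150:179)
    pos <- sample(exonic, 200, replace = TRUE)
    s <- as.character(g$chromosomes[["chr"]])
    for (p in pos) {
      ref <- substr(s, p + 1, p + 1)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      v <- data.frame(chrom = "chr", pos = p, ref = ref, alt = alt)
      expect_identical(as.character(annotate_consequence(v, g)),
                       oracle(v, g),
                       label = paste("strand", strand, "pos", p, "alt", alt))
    }
  }
})

test_that("presence tiers follow the thresholds and recall is high", {
  expect_identical(as.character(call_presence(0L, 100L)), "absent")
  expect_identical(as.character(call_presence(30L, 100L)), "high")
  expect_identical(as.character(call_presence(15L, 100L)), "mid")
  expect_identical(as.character(call_presence(5L, 100L)), "low")
  expect_identical(as.character(call_presence(2L, 100L)), "absent")
  expect_identical(as.character(call_presence(0L, 0L)), "absent")
  expect_error(call_presence(1L, 10L, t_low = 0.3, t_mid = 0.2))
  # truly-present het variants at depth 100: recall >= 0.99
  set.seed(31)
  n <- 10000
  ad <- rbinom(n, 100, 0.5)
  tier <- call_presence(ad, rep(100L, n))
  expect_gte(mean(tier != "absent"), 0.99)
})

test_that("vaf_summary aggregates by role", {
  calls <- data.frame(sample_id = c("a", "a", "b"),
                      alt_depth = c(5L, 2L, 30L),
                      total_depth = c(10L, 10L, 100L),
                      role = c("organoid", "organoid", "primary_biopsy"))
  vs <- vaf_summary(calls)
  expect_equal(vs$mean_vaf[vs$role == "organoid"], 0.35)
  expect_equal(vs$mean_vaf[vs$role == "primary_biopsy"], 0.3)
  expect_identical(nrow(vaf_summary(calls[0, ])), 0L)
})

test_that("VCF round-trip is exact", {
  calls <- data.frame(chrom = c("chr2", "chr1", "chr1"),
                      pos = c(5L, 99L, 3L),
                      ref = c("A", "C", "G"), alt = c("T", "T", "A"),
                      alt_depth = c(10L, 0L, 55L),
                      total_depth = c(30L, 80L, 100L),
                      stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(calls, "orgX", path)
  back <- read_vcf(path)
  expect_identical(back$sample_id, "orgX")
  o <- order(calls$chrom, calls$pos, calls$alt)
  expect_identical(back$calls,
                   `rownames<-`(calls[o, ], NULL))
  # empty call set round-trips too
  write_vcf(calls[0, ], "empty", path)
  expect_identical(nrow(read_vcf(path)$calls), 0L)
})
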
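# Shared small fixtures, built once per test run.

# 400 kb single-chromosome genome with a dozen small genes: fast to index,
# used wherever gene-size classes don't matter.
fast_genome <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- build_genome(genome_config(
        chrom_lengths = c(chrA = 4e5), n_genes = 12,
        gene_span_range = c(3e3, 5e4), timing_block_bp = 5e4),
        seed = 42)
    cache
  }
})

# hand-built single-gene genome for consequence oracle tests:
# plus-strand gene, 2 exons of 30 bp each with a 20 bp intron
toy_gene_genome <- function(seed = 7) {
  set.seed(seed)
  seq <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
               collapse = "")
  genes <- data.frame(gene_id = "g1", chrom = "chr", strand = "+",
                      span_start = 100L, span_end = 180L,
                      genomic_span_bp = 80L, coding_length_bp = 60L,
                      stringsAsFactors = FALSE)
  genes$exon_starts <- list(c(100L, 150L))
  genes$exon_ends <- list(c(130L, 180L))
  genome_from_sequences(c(chr = seq), genes = genes)
}

# replace a subsequence of a genome chromosome (for codon construction)
set_genome_seq <- function(genome, chrom, start0, replacement) {
  s <- as.character(genome$chromosomes[[chrom]])
  substr(s, start0 + 1L, start0 + nchar(replacement)) <- replacement
  seqs <- as.character(genome$chromosomes)
  seqs[[chrom]] <- s
  genome_from_sequences(seqs, genes = genome$genes, timing = genome$timing)
}

# carrier sets of every variant column, as sorted comma-joined strings
carrier_sets <- function(mat) {
  bin <- mat > 0
  unique(vapply(seq_len(ncol(bin)), function(j)
    paste(sort(rownames(bin)[bin[, j]]), collapse = ","), character(1)))
}
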
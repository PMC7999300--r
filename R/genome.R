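#' Configuration for the toy genome builder
#'
#' @param chrom_lengths Named integer vector of chromosome lengths in bp.
#'   Coordinates are 0-based half-open throughout the package.
#' @param n_genes Number of gene models to place.
#' @param gene_span_range Two-element numeric, min/max genomic span (bp).
#'   Spans are drawn log-uniformly, which populates both the small
#'   (<= 150 kb) and large (> 150 kb) size classes at the default range.
#' @param cpg_depletion Factor in (0, 1] by which NpCpG triplets are depleted
#'   relative to a uniform-composition genome (mammalian genomes are strongly
#'   CpG-depleted; 0.2 is a realistic default).
#' @param coding_fraction Fraction of a gene's span occupied by coding exons.
#' @param exon_range Two-element integer, min/max exon count per gene.
#' @param timing_block_bp Approximate size of replication-timing domains; each
#'   chromosome is partitioned exactly into early/mid/late S-phase blocks.
#' @return A list of class `genome_config`.
#' @export
genome_config <- function(chrom_lengths = c(chr1 = 2e6, chr2 = 2e6, chr3 = 2e6),
                          n_genes = 60,
                          gene_span_range = c(5e3, 4e5),
                          cpg_depletion = 0.2,
                          coding_fraction = 0.05,
                          exon_range = c(3L, 12L),
                          timing_block_bp = 2e5) {
  if (is.null(names(chrom_lengths)) || anyDuplicated(names(chrom_lengths)))
    stop("chrom_lengths must be uniquely named")
  if (cpg_depletion <= 0 || cpg_depletion > 1)
    stop("cpg_depletion must be in (0, 1]")
  if (n_genes > 0 && max(gene_span_range) > max(chrom_lengths))
    stop("gene span range exceeds the longest chromosome: ",
         max(gene_span_range), " > ", max(chrom_lengths))
  structure(list(chrom_lengths = chrom_lengths, n_genes = n_genes,
                 gene_span_range = gene_span_range,
                 cpg_depletion = cpg_depletion,
                 coding_fraction = coding_fraction,
                 exon_range = as.integer(exon_range),
                 timing_block_bp = timing_block_bp),
            class = "genome_config")
}

#' Build a toy reference genome
#'
#' Generates chromosome sequences with a controllable NpCpG depletion, places
#' non-overlapping multi-exon gene models with log-uniform genomic spans, and
#' partitions every chromosome into early/mid/late replication-timing domains.
#' Deterministic for a fixed seed.
#'
#' CpG depletion is realised by first drawing an i.i.d. uniform sequence and
#' then, scanning 5' to 3', replacing the G of each CpG dinucleotide with an
#' A or T with probability `1 - cpg_depletion`; the replacement bases cannot
#' create new CpG sites, so the realised NpCpG triplet count is the uniform
#' expectation scaled by the depletion factor (up to sampling noise).
#'
#' @param config A [genome_config()].
#' @param seed Integer seed.
#' @return An object of class `genome_model` with elements `chromosomes`
#'   (a [Biostrings::DNAStringSet]), `genes` (data.frame with list-columns
#'   `exon_starts`, `exon_ends`), and `timing` (data.frame of domains with
#'   stratum early/mid/late).
#' @export
build_genome <- function(config = genome_config(), seed = 1L) {
  stopifnot(inherits(config, "genome_config"))
  set.seed(seed)
  lens <- as.integer(config$chrom_lengths)
  names(lens) <- names(config$chrom_lengths)

  seqs <- lapply(lens, function(L) {
    x <- sample(BASES, L, replace = TRUE)
    if (config$cpg_depletion < 1) {
      cg <- which(x[-L] == "C" & x[-1] == "G")
      kill <- cg[runif(length(cg)) > config$cpg_depletion]
      if (length(kill))
        x[kill + 1L] <- sample(c("A", "T"), length(kill), replace = TRUE)
    }
    paste(x, collapse = "")
  })
  chromosomes <- Biostrings::DNAStringSet(unlist(seqs))
  names(chromosomes) <- names(lens)

  genes <- place_genes(lens, config)
  timing <- make_timing_domains(lens, config$timing_block_bp)

  structure(list(chromosomes = chromosomes, genes = genes, timing = timing,
                 config = config, seed = seed,
                 cache = new.env(parent = emptyenv())),
            class = "genome_model")
}

# non-overlapping placement; spans log-uniform in gene_span_range
place_genes <- function(lens, config) {
  n <- config$n_genes
  empty <- data.frame(gene_id = character(), chrom = character(),
                      strand = character(), span_start = integer(),
                      span_end = integer(), genomic_span_bp = integer(),
                      coding_length_bp = integer(),
                      stringsAsFactors = FALSE)
  empty$exon_starts <- list(); empty$exon_ends <- list()
  if (n == 0) return(empty)
  rng <- log(config$gene_span_range)
  spans <- as.integer(round(exp(runif(n, rng[1], rng[2]))))
  # greedy placement into per-chromosome free space, longest first
  ord <- order(spans, decreasing = TRUE)
  occupied <- lapply(lens, function(L) IRanges::IRanges())
  rows <- vector("list", n)
  for (k in ord) {
    span <- spans[k]
    placed <- FALSE
    for (attempt in seq_len(200)) {
      ci <- sample(length(lens), 1)
      L <- lens[ci]
      if (span >= L) next
      start <- sample.int(L - span, 1) - 1L   # 0-based
      cand <- IRanges::IRanges(start + 1L, start + span)   # 1-based internal
      if (length(IRanges::findOverlaps(cand, occupied[[ci]])) == 0) {
        occupied[[ci]] <- c(occupied[[ci]], cand)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      # deterministic fallback: first free gap large enough, any chromosome
      for (ci in sample(length(lens))) {
        gaps <- IRanges::setdiff(IRanges::IRanges(1L, lens[ci]),
                                 occupied[[ci]])
        fit <- which(IRanges::width(gaps) > span)
        if (length(fit)) {
          start <- IRanges::start(gaps)[fit[1]] - 1L
          occupied[[ci]] <- c(occupied[[ci]],
                              IRanges::IRanges(start + 1L, start + span))
          placed <- TRUE
          break
        }
      }
    }
    if (!placed) stop("could not place gene of span ", span,
                      " without overlap; reduce n_genes or spans")
    ex <- make_exons(start, span, config)
    rows[[k]] <- list(chrom = names(lens)[ci],
                      strand = sample(c("+", "-"), 1),
                      span_start = ex$starts[1],
                      span_end = ex$ends[length(ex$ends)],
                      exon_starts = ex$starts, exon_ends = ex$ends)
  }
  genes <- data.frame(
    gene_id = sprintf("gene%03d", seq_len(n)),
    chrom = vapply(rows, `[[`, character(1), "chrom"),
    strand = vapply(rows, `[[`, character(1), "strand"),
    span_start = vapply(rows, `[[`, integer(1), "span_start"),
    span_end = vapply(rows, `[[`, integer(1), "span_end"),
    stringsAsFactors = FALSE)
  genes$exon_starts <- lapply(rows, `[[`, "exon_starts")
  genes$exon_ends <- lapply(rows, `[[`, "exon_ends")
  genes$genomic_span_bp <- genes$span_end - genes$span_start
  genes$coding_length_bp <- vapply(seq_len(n), function(i)
    sum(genes$exon_ends[[i]] - genes$exon_starts[[i]]), integer(1))
  genes[order(genes$chrom, genes$span_start), , drop = FALSE]
}

# exons: first starts at span start, last ends at span end, total CDS % 3 == 0,
# exon sizes + intron gaps tile the span exactly
make_exons <- function(start, span, config) {
  cds <- as.integer(round(span * config$coding_fraction))
  cds <- max(3L, cds - (cds %% 3L))
  n_max <- min(config$exon_range[2], cds %/% 3L, span - cds + 1L)
  n_min <- min(config$exon_range[1], n_max)
  n_ex <- if (n_max <= n_min) n_min else
    sample(seq.int(n_min, n_max), 1)
  if (n_ex <= 1L) {   # degenerate short gene: one exon filling the span
    cds <- span - (span %% 3L)
    return(list(starts = start, ends = start + cds))
  }
  sizes <- rep(cds %/% n_ex, n_ex)
  sizes[1] <- sizes[1] + cds %% n_ex
  gaps <- integer(0)
  if (n_ex > 1L) {
    intron_total <- span - cds
    gaps <- rep(1L, n_ex - 1L)
    extra <- intron_total - (n_ex - 1L)
    if (extra > 0)
      gaps <- gaps + as.integer(stats::rmultinom(
        1, extra, rep(1, n_ex - 1L)))
  }
  starts <- integer(n_ex); ends <- integer(n_ex)
  pos <- start
  for (i in seq_len(n_ex)) {
    starts[i] <- pos
    ends[i] <- pos + sizes[i]
    pos <- ends[i] + if (i < n_ex) gaps[i] else 0L
  }
  list(starts = starts, ends = ends)
}

make_timing_domains <- function(lens, block_bp) {
  strata <- c("early", "mid", "late")
  out <- lapply(names(lens), function(cn) {
    L <- lens[[cn]]
    n_blocks <- max(3L, as.integer(round(L / block_bp)))
    edges <- unique(as.integer(round(seq(0, L, length.out = n_blocks + 1L))))
    data.frame(chrom = cn, start = edges[-length(edges)], end = edges[-1],
               stratum = sample(rep(strata, length.out = length(edges) - 1L)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Build a genome model from explicit sequences
#'
#' Wraps given chromosome strings (and optional gene/timing tables) in a
#' `genome_model`, for small deterministic fixtures and oracle tests.
#'
#' @param sequences Named character vector of A/C/G/T strings.
#' @param genes Optional gene data.frame in the [build_genome()] layout.
#' @param timing Optional timing-domain data.frame (chrom, start, end,
#'   stratum); defaults to one "early" domain spanning each chromosome.
#' @return A `genome_model`.
#' @export
genome_from_sequences <- function(sequences, genes = NULL, timing = NULL) {
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("sequences must be uniquely named")
  chromosomes <- Biostrings::DNAStringSet(sequences)
  if (is.null(genes)) {
    genes <- data.frame(gene_id = character(), chrom = character(),
                        strand = character(), span_start = integer(),
                        span_end = integer(), genomic_span_bp = integer(),
                        coding_length_bp = integer(),
                        stringsAsFactors = FALSE)
    genes$exon_starts <- list(); genes$exon_ends <- list()
  }
  if (is.null(timing))
    timing <- data.frame(chrom = names(sequences), start = 0L,
                         end = nchar(sequences), stratum = "early",
                         stringsAsFactors = FALSE)
  structure(list(chromosomes = chromosomes, genes = genes, timing = timing,
                 config = NULL, seed = NA_integer_,
                 cache = new.env(parent = emptyenv())),
            class = "genome_model")
}

#' Genomic territory masks (coding / intronic / intergenic)
#'
#' The three territories partition the genome exactly: coding is the union of
#' exons, intronic is gene spans minus exons, intergenic is everything else.
#'
#' @param genome A `genome_model`.
#' @return Named list of [GenomicRanges::GRanges] objects (1-based internal
#'   representation as is conventional for GRanges).
#' @export
territory_masks <- function(genome) {
  stopifnot(inherits(genome, "genome_model"))
  lens <- Biostrings::width(genome$chromosomes)
  names(lens) <- names(genome$chromosomes)
  si <- GenomicRanges::GRanges(names(lens), IRanges::IRanges(1, lens))
  g <- genome$genes
  if (nrow(g) == 0) {
    empty <- GenomicRanges::GRanges()
    return(list(coding = empty, intronic = empty, intergenic = si))
  }
  exon_gr <- GenomicRanges::GRanges(
    rep(g$chrom, lengths(g$exon_starts)),
    IRanges::IRanges(unlist(g$exon_starts) + 1L, unlist(g$exon_ends)))
  span_gr <- GenomicRanges::GRanges(
    g$chrom, IRanges::IRanges(g$span_start + 1L, g$span_end))
  coding <- GenomicRanges::reduce(exon_gr)
  intronic <- GenomicRanges::setdiff(GenomicRanges::reduce(span_gr), coding)
  intergenic <- GenomicRanges::setdiff(si, GenomicRanges::reduce(span_gr))
  list(coding = coding, intronic = intronic, intergenic = intergenic)
}

#' Pyrimidine-collapsed triplet census of a genome territory
#'
#' Counts, over the 32 pyrimidine-centred trinucleotides, every genomic
#' position whose centre base lies in the territory and whose two flanking
#' bases are defined on the chromosome. Purine-centred positions are counted
#' via their reverse complement, the same collapse convention used by
#' [spectrum96()], so spectrum numerator and census denominator share one
#' convention.
#'
#' @param genome A `genome_model`.
#' @param territory `NULL` for whole chromosomes, or a
#'   [GenomicRanges::GRanges] of intervals (1-based, as returned by
#'   [territory_masks()]).
#' @return Named integer vector of length 32 in [pyrimidine_triplets()] order.
#' @export
triplet_census <- function(genome, territory = NULL) {
  stopifnot(inherits(genome, "genome_model"))
  counts64 <- integer(64)
  tri64 <- Biostrings::mkAllStrings(BASES, 3)
  names(counts64) <- tri64
  if (is.null(territory)) {
    tf <- Biostrings::trinucleotideFrequency(genome$chromosomes, step = 1)
    counts64[colnames(tf)] <- counts64[colnames(tf)] + colSums(tf)
  } else {
    if (length(territory) > 0) {
      lens <- setNames(Biostrings::width(genome$chromosomes),
                       names(genome$chromosomes))
      red <- GenomicRanges::reduce(territory)
      for (i in seq_along(red)) {
        cn <- as.character(GenomicRanges::seqnames(red)[i])
        s <- max(1L, GenomicRanges::start(red)[i] - 1L)
        e <- min(lens[[cn]], GenomicRanges::end(red)[i] + 1L)
        if (e - s + 1L < 3L) next
        sub <- Biostrings::subseq(genome$chromosomes[[cn]], s, e)
        tf <- Biostrings::trinucleotideFrequency(sub, step = 1)
        counts64[names(tf)] <- counts64[names(tf)] + tf
      }
    }
  }
  collapse_census(counts64)
}

collapse_census <- function(counts64) {
  out <- setNames(numeric(32), pyrimidine_triplets())
  for (tri in names(counts64)) {
    ctr <- substr(tri, 2, 2)
    key <- if (ctr %in% c("C", "T")) tri else revcomp(tri)
    out[key] <- out[key] + counts64[[tri]]
  }
  setNames(as.integer(out), names(out))
}
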
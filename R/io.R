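#' Write / read a toy genome as FASTA + BED
#'
#' The genome is serialised as `genome.fasta` (sequences), `genes.bed`
#' (BED12; exon blocks carry the CDS structure), `timing.bed` (BED with the
#' stratum in the name column) and `genome.json` (builder config and seed).
#' All BED coordinates are 0-based half-open, matching the package's
#' internal convention.
#'
#' @param genome A `genome_model`.
#' @param dir Output directory (created if needed).
#' @export
write_genome <- function(genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(genome$chromosomes,
                              file.path(dir, "genome.fasta"))
  g <- genome$genes
  if (nrow(g)) {
    sizes <- vapply(seq_len(nrow(g)), function(i) paste(
      g$exon_ends[[i]] - g$exon_starts[[i]], collapse = ","), character(1))
    rel <- vapply(seq_len(nrow(g)), function(i) paste(
      g$exon_starts[[i]] - g$span_start[i], collapse = ","), character(1))
    bed <- data.frame(g$chrom, g$span_start, g$span_end, g$gene_id, 0,
                      g$strand, g$span_start, g$span_end, "0,0,0",
                      lengths(g$exon_starts), sizes, rel)
  } else bed <- data.frame()
  write.table(bed, file.path(dir, "genes.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(genome$timing[c("chrom", "start", "end", "stratum")],
              file.path(dir, "timing.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  cfg <- genome$config
  jsonlite::write_json(list(seed = genome$seed,
                            chrom_lengths = as.list(cfg$chrom_lengths),
                            cpg_depletion = cfg$cpg_depletion),
                       file.path(dir, "genome.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_genome
#' @return `read_genome`: a `genome_model` reconstructed from the files.
#' @export
read_genome <- function(dir) {
  chromosomes <- Biostrings::readDNAStringSet(file.path(dir, "genome.fasta"))
  names(chromosomes) <- sub("\\s.*", "", names(chromosomes))
  bed_path <- file.path(dir, "genes.bed")
  info <- file.info(bed_path)
  if (!is.na(info$size) && info$size > 0) {
    bed <- read.table(bed_path, sep = "\t", stringsAsFactors = FALSE)
    genes <- data.frame(gene_id = bed$V4, chrom = bed$V1, strand = bed$V6,
                        span_start = bed$V2, span_end = bed$V3,
                        stringsAsFactors = FALSE)
    genes$exon_starts <- lapply(seq_len(nrow(bed)), function(i)
      as.integer(strsplit(bed$V12[i], ",")[[1]]) + bed$V2[i])
    genes$exon_ends <- lapply(seq_len(nrow(bed)), function(i)
      genes$exon_starts[[i]] + as.integer(strsplit(bed$V11[i], ",")[[1]]))
    genes$genomic_span_bp <- genes$span_end - genes$span_start
    genes$coding_length_bp <- vapply(seq_len(nrow(genes)), function(i)
      sum(genes$exon_ends[[i]] - genes$exon_starts[[i]]), integer(1))
  } else {
    genes <- data.frame(gene_id = character(), chrom = character(),
                        strand = character(), span_start = integer(),
                        span_end = integer(), genomic_span_bp = integer(),
                        coding_length_bp = integer(),
                        stringsAsFactors = FALSE)
    genes$exon_starts <- list(); genes$exon_ends <- list()
  }
  timing <- read.table(file.path(dir, "timing.bed"), sep = "\t",
                       col.names = c("chrom", "start", "end", "stratum"),
                       stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "genome.json"),
                              simplifyVector = TRUE)
  structure(list(chromosomes = chromosomes, genes = genes, timing = timing,
                 config = NULL, seed = meta$seed,
                 cache = new.env(parent = emptyenv())),
            class = "genome_model")
}

#' Write depth bins as TSV (chrom, start, end, count)
#' @param bins Depth-bin data.frame.
#' @param path Output file.
#' @export
write_depth_bins <- function(bins, path) {
  write.table(bins, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_depth_bins
#' @export
read_depth_bins <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
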
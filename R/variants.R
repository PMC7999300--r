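#' Construct a variant table
#'
#' Variants are plain data.frames with columns `chrom`, `pos` (0-based),
#' `ref`, `alt`, and `context` (the pyrimidine-collapsed 3-mer class,
#' computed from the genome when one is supplied). `ref` must match the
#' genome at `pos`.
#'
#' @param chrom,pos,ref,alt Vectors of equal length.
#' @param genome Optional `genome_model`, used to validate `ref` and fill in
#'   `context`.
#' @return data.frame of class `variant_table`.
#' @export
variant_table <- function(chrom, pos, ref, alt, genome = NULL) {
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   ref = as.character(ref), alt = as.character(alt),
                   stringsAsFactors = FALSE)
  if (any(df$ref == df$alt)) stop("ref and alt must differ")
  if (!is.null(genome)) {
    ctx <- variant_context(df, genome)
    gref <- substr(ctx$triplet, 2, 2)
    bad <- which(!is.na(ctx$triplet) & gref != df$ref)
    if (length(bad))
      stop("ref mismatch with genome at ", df$chrom[bad[1]], ":",
           df$pos[bad[1]], " (genome has ", gref[bad[1]],
           ", variant claims ", df$ref[bad[1]], ")")
    df$context <- collapse_context(ctx$triplet, df$alt)
  } else if (is.null(df$context)) {
    df$context <- NA_character_
  }
  class(df) <- c("variant_table", "data.frame")
  df
}

# 3-mer centred on each variant; NA at chromosome ends
variant_context <- function(df, genome) {
  lens <- setNames(Biostrings::width(genome$chromosomes),
                   names(genome$chromosomes))
  triplet <- rep(NA_character_, nrow(df))
  for (i in seq_len(nrow(df))) {
    L <- lens[[df$chrom[i]]]
    p <- df$pos[i]                     # 0-based
    if (is.null(L) || p < 0 || p >= L) stop("position out of bounds: ",
                                            df$chrom[i], ":", p)
    if (p >= 1 && p <= L - 2)
      triplet[i] <- as.character(
        Biostrings::subseq(genome$chromosomes[[df$chrom[i]]], p, p + 2))
  }
  list(triplet = triplet)
}

#' Annotate coding consequence of single nucleotide substitutions
#'
#' Positions within the 2 intronic bp flanking an internal exon boundary are
#' `splice_site` (canonical donor/acceptor; the window is configurable).
#' Positions inside a coding exon are translated on the coding strand with
#' the standard genetic code: unchanged amino acid is `synonymous`, a gained
#' stop is `nonsense`, anything else `missense`. All remaining positions are
#' `noncoding`. CDS positions are never splice_site.
#'
#' @param variants A `variant_table` (or data.frame with the same columns).
#' @param genome A `genome_model` providing gene models and sequence.
#' @param splice_window Intronic bp flanking internal exon boundaries
#'   treated as splice site (default 2).
#' @return Factor vector with levels missense, nonsense, synonymous,
#'   splice_site, noncoding; attribute `gene_id` gives the assigned gene
#'   (NA outside genes).
#' @export
annotate_consequence <- function(variants, genome, splice_window = 2L) {
  stopifnot(inherits(genome, "genome_model"))
  lv <- c("missense", "nonsense", "synonymous", "splice_site", "noncoding")
  n <- nrow(variants)
  out <- rep("noncoding", n)
  gene_hit <- rep(NA_character_, n)
  genes <- genome$genes
  ctx <- variant_context(variants, genome)
  gref <- ifelse(is.na(ctx$triplet), NA, substr(ctx$triplet, 2, 2))
  # genome ref at chromosome ends (no triplet) still needs checking
  for (i in seq_len(n)) {
    base <- as.character(Biostrings::subseq(
      genome$chromosomes[[variants$chrom[i]]],
      variants$pos[i] + 1L, variants$pos[i] + 1L))
    if (base != variants$ref[i])
      stop("ref mismatch with genome at ", variants$chrom[i], ":",
           variants$pos[i])
  }
  if (nrow(genes) == 0)
    return(structure(factor(out, levels = lv), gene_id = gene_hit))
  for (i in seq_len(n)) {
    p <- variants$pos[i]; cn <- variants$chrom[i]
    gi <- which(genes$chrom == cn & genes$span_start <= p & p < genes$span_end)
    if (!length(gi)) next
    g <- genes[gi[1], ]
    gene_hit[i] <- g$gene_id
    es <- g$exon_starts[[1]]; ee <- g$exon_ends[[1]]
    in_exon <- any(es <= p & p < ee)
    if (in_exon) {
      out[i] <- classify_cds(p, variants$alt[i], g, genome)
    } else {
      # intronic: splice site if within window of an internal boundary
      n_ex <- length(es)
      donors <- ee[-n_ex]      # intron starts (exon ends), 0-based
      acceptors <- es[-1]      # intron ends (next exon starts)
      near <- any(p >= donors & p < donors + splice_window) ||
        any(p >= acceptors - splice_window & p < acceptors)
      out[i] <- if (isTRUE(near)) "splice_site" else "noncoding"
    }
  }
  structure(factor(out, levels = lv), gene_id = gene_hit)
}

classify_cds <- function(p, alt, g, genome) {
  es <- g$exon_starts[[1]]; ee <- g$exon_ends[[1]]
  seqs <- vapply(seq_along(es), function(j) as.character(
    Biostrings::subseq(genome$chromosomes[[g$chrom]], es[j] + 1L, ee[j])),
    character(1))
  cds <- paste(seqs, collapse = "")
  # index of p within the concatenated plus-strand CDS
  prior <- sum(pmax(0L, pmin(ee, p) - es))
  idx_plus <- prior            # 0-based index into plus-strand CDS
  L <- nchar(cds)
  if (g$strand == "+") {
    cds_c <- cds; idx <- idx_plus; alt_c <- alt
  } else {
    cds_c <- revcomp(cds); idx <- L - 1L - idx_plus; alt_c <- COMPLEMENT[[alt]]
  }
  codon_i <- idx %/% 3L
  within <- idx %% 3L
  codon <- substr(cds_c, codon_i * 3L + 1L, codon_i * 3L + 3L)
  if (nchar(codon) < 3L) return("noncoding")   # trailing partial (shouldn't occur)
  mut <- codon
  substr(mut, within + 1L, within + 1L) <- alt_c
  aa_ref <- as.character(Biostrings::translate(
    Biostrings::DNAString(codon), no.init.codon = TRUE))
  aa_alt <- as.character(Biostrings::translate(
    Biostrings::DNAString(mut), no.init.codon = TRUE))
  if (aa_ref == aa_alt) "synonymous"
  else if (aa_alt == "*") "nonsense"
  else "missense"
}

#' Tiered presence call for one or more variant calls
#'
#' Mirrors heat-map rendering tiers commonly used for bulk biopsies: calls
#' below `min_alt_reads` supporting reads are absent; otherwise the VAF is
#' binned at `t_low` and `t_mid` into low / mid / high. Any non-absent tier
#' counts as "present" when building presence matrices. Zero total depth
#' yields absent.
#'
#' @param alt_depth,total_depth Integer vectors.
#' @param t_low,t_mid VAF thresholds, `0 < t_low < t_mid <= 1`
#'   (defaults 0.10 and 0.20).
#' @param min_alt_reads Minimum supporting reads (default 3).
#' @return Ordered factor absent < low < mid < high.
#' @export
call_presence <- function(alt_depth, total_depth,
                          t_low = 0.10, t_mid = 0.20, min_alt_reads = 3L) {
  if (!(t_low > 0 && t_low < t_mid && t_mid <= 1))
    stop("need 0 < t_low < t_mid <= 1")
  stopifnot(all(alt_depth >= 0), all(alt_depth <= total_depth))
  vaf <- ifelse(total_depth > 0, alt_depth / total_depth, 0)
  tier <- ifelse(alt_depth < min_alt_reads | total_depth == 0, "absent",
                 ifelse(vaf >= t_mid, "high",
                        ifelse(vaf >= t_low, "mid", "low")))
  factor(tier, levels = c("absent", "low", "mid", "high"), ordered = TRUE)
}

#' Summarise VAF by sample role
#'
#' @param calls data.frame with columns `sample_id`, `alt_depth`,
#'   `total_depth` and `role` (e.g. organoid / primary_biopsy / metastasis).
#' @return data.frame with per-role mean, median and n.
#' @export
vaf_summary <- function(calls) {
  if (nrow(calls) == 0)
    return(data.frame(role = character(), mean_vaf = numeric(),
                      median_vaf = numeric(), n = integer()))
  vaf <- calls$alt_depth / calls$total_depth
  agg <- lapply(split(vaf, calls$role), function(v)
    c(mean = mean(v), median = median(v), n = length(v)))
  data.frame(role = names(agg),
             mean_vaf = vapply(agg, `[[`, numeric(1), "mean"),
             median_vaf = vapply(agg, `[[`, numeric(1), "median"),
             n = vapply(agg, `[[`, numeric(1), "n"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write / read one sample's variant calls as minimal VCF 4.2
#'
#' One sample per file; POS is 1-based in the file (internal coordinates are
#' 0-based); FORMAT is `AD:DP` with AD holding ref,alt depths.
#'
#' @param calls data.frame with columns chrom, pos, ref, alt, alt_depth,
#'   total_depth.
#' @param sample_id Sample name for the header column.
#' @param path Output file.
#' @export
write_vcf <- function(calls, sample_id, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           sample_id)), con)
  if (nrow(calls)) {
    o <- order(calls$chrom, calls$pos, calls$alt)
    calls <- calls[o, ]
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tAD:DP\t%d,%d:%d",
                       calls$chrom, calls$pos + 1L, calls$ref, calls$alt,
                       calls$total_depth - calls$alt_depth, calls$alt_depth,
                       calls$total_depth), con)
  }
  invisible(path)
}

#' @rdname write_vcf
#' @return `read_vcf` returns a list with `sample_id` and `calls` (0-based
#'   positions).
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) stop("no #CHROM header in ", path)
  sample_id <- strsplit(lines[hdr], "\t")[[1]][10]
  body <- lines[-seq_len(hdr)]
  if (!length(body)) {
    calls <- data.frame(chrom = character(), pos = integer(),
                        ref = character(), alt = character(),
                        alt_depth = integer(), total_depth = integer())
    return(list(sample_id = sample_id, calls = calls))
  }
  f <- strsplit(body, "\t")
  gt <- vapply(f, `[[`, character(1), 10)
  ad <- strsplit(sub(":.*", "", gt), ",")
  calls <- data.frame(
    chrom = vapply(f, `[[`, character(1), 1),
    pos = as.integer(vapply(f, `[[`, character(1), 2)) - 1L,
    ref = vapply(f, `[[`, character(1), 4),
    alt = vapply(f, `[[`, character(1), 5),
    alt_depth = as.integer(vapply(ad, `[[`, character(1), 2)),
    total_depth = as.integer(sub(".*:", "", gt)),
    stringsAsFactors = FALSE)
  list(sample_id = sample_id, calls = calls)
}
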
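#' Sequence a single-cell-derived organoid from one clone
#'
#' Every mutation carried by the clone is emitted as a variant call with
#' binomial read sampling: total depth is Poisson around
#' `depth_mean * local_copies / 2` and alt reads are
#' `Binomial(DP, mutated_copies / total_copies)` — 0.5 in copy-neutral
#' diploid regions, as expected for heterozygous mutations in a single-cell
#' culture. Depth bins reflect local copy number relative to diploid.
#'
#' @param tree A `clone_tree`.
#' @param node Clone (node id) the organoid derives from.
#' @param depth_mean Mean sequencing depth (must be >= 1; >= 20 recommended).
#' @param sample_id Sample name (defaults to the node id).
#' @param seed Integer seed.
#' @return List with `calls` (data.frame: sample_id, chrom, pos, ref, alt,
#'   context, alt_depth, total_depth, vaf), `depth_bins` (chrom, start, end,
#'   count) and `role = "organoid"`.
#' @export
sample_organoid <- function(tree, node, depth_mean = 100, sample_id = node,
                            seed = 1L) {
  if (depth_mean < 1) stop("depth_mean must be >= 1")
  stopifnot(inherits(tree, "clone_tree"))
  set.seed(seed)
  vars <- clone_mutations(tree, node)
  n <- nrow(vars)
  dp <- pmax(1L, rpois(n, depth_mean * vars$tot_copies / 2))
  ad <- rbinom(n, dp, vars$mut_copies / vars$tot_copies)
  calls <- data.frame(sample_id = sample_id, chrom = vars$chrom,
                      pos = vars$pos, ref = vars$ref, alt = vars$alt,
                      context = vars$context, alt_depth = ad,
                      total_depth = dp, stringsAsFactors = FALSE)
  calls$vaf <- calls$alt_depth / calls$total_depth
  calls <- calls[order(calls$chrom, calls$pos, calls$alt), , drop = FALSE]
  rownames(calls) <- NULL
  bins <- depth_bins_for(tree$genome, clone_cnas(tree, node),
                         purity = 1, fractions = 1, depth_mean = depth_mean,
                         bin_bp = tree$config$bin_bp)
  list(sample_id = sample_id, role = "organoid", calls = calls,
       depth_bins = bins)
}

#' Sequence a bulk biopsy as a purity-diluted clone mixture
#'
#' The expected VAF of a variant is
#' `purity * sum(f * mut) / (purity * sum(f * tot) + (1 - purity) * 2)`
#' over the carrying clones — `purity * f / 2` for a heterozygous
#' copy-neutral variant carried by clone fraction `f`. Depth-bin expectation
#' is `2 + purity * sum(f * copy_delta)` relative to diploid.
#'
#' @param tree A `clone_tree`.
#' @param mixture Named numeric vector: clone node id -> cell fraction
#'   (fractions must sum to 1).
#' @param purity Tumour-cell fraction of the biopsy, in (0, 1].
#' @param depth_mean Mean sequencing depth.
#' @param sample_id Sample name.
#' @param role Sample role, `"primary_biopsy"` or `"metastasis"`.
#' @param seed Integer seed.
#' @return Same shape as [sample_organoid()].
#' @export
sample_bulk <- function(tree, mixture, purity = 0.6, depth_mean = 100,
                        sample_id = "bulk", role = "primary_biopsy",
                        seed = 1L) {
  if (!length(mixture)) stop("mixture must contain at least one clone")
  if (abs(sum(mixture) - 1) > 1e-9) stop("mixture fractions must sum to 1")
  if (purity <= 0 || purity > 1) stop("purity must be in (0, 1]")
  stopifnot(inherits(tree, "clone_tree"))
  set.seed(seed)
  clones <- names(mixture)
  # variant universe over the mixture, with per-clone copy state
  per <- lapply(clones, function(nd) tree$state[[nd]]$variants)
  univ <- unique(do.call(rbind, per)[c("id", "chrom", "pos", "ref", "alt",
                                       "context")])
  rownames(univ) <- NULL
  if (is.null(univ) || nrow(univ) == 0) {
    calls <- data.frame(sample_id = character(), chrom = character(),
                        pos = integer(), ref = character(), alt = character(),
                        context = character(), alt_depth = integer(),
                        total_depth = integer(), vaf = numeric())
  } else {
    mut_w <- numeric(nrow(univ)); tot_w <- numeric(nrow(univ))
    for (k in seq_along(clones)) {
      st <- per[[k]]
      m <- match(univ$id, st$id)
      mut_k <- ifelse(is.na(m), 0L, st$mut_copies[m])
      tot_k <- ifelse(is.na(m), 2L, st$tot_copies[m])  # non-carriers diploid
      mut_w <- mut_w + mixture[k] * mut_k
      tot_w <- tot_w + mixture[k] * tot_k
    }
    denom <- purity * tot_w + (1 - purity) * 2
    evaf <- purity * mut_w / denom
    dp <- pmax(1L, rpois(nrow(univ), depth_mean * denom / 2))
    ad <- rbinom(nrow(univ), dp, pmin(1, evaf))
    calls <- data.frame(sample_id = sample_id, chrom = univ$chrom,
                        pos = univ$pos, ref = univ$ref, alt = univ$alt,
                        context = univ$context, alt_depth = ad,
                        total_depth = dp, stringsAsFactors = FALSE)
    calls$vaf <- calls$alt_depth / calls$total_depth
    calls <- calls[order(calls$chrom, calls$pos, calls$alt), , drop = FALSE]
    rownames(calls) <- NULL
  }
  cna_list <- do.call(rbind, lapply(seq_along(clones), function(k) {
    cc <- clone_cnas(tree, clones[k])
    if (nrow(cc)) cbind(cc, fraction = unname(mixture[k])) else NULL
  }))
  bins <- depth_bins_for(tree$genome, cna_list, purity = purity,
                         fractions = NULL, depth_mean = depth_mean,
                         bin_bp = tree$config$bin_bp)
  list(sample_id = sample_id, role = role, calls = calls, depth_bins = bins)
}

#' Sequence a matched normal tissue (diploid, no somatic variants)
#'
#' @param genome A `genome_model`.
#' @param depth_mean Mean depth.
#' @param bin_bp Bin width.
#' @param sample_id Sample name.
#' @param seed Integer seed.
#' @return List with empty `calls` and diploid `depth_bins`.
#' @export
sample_normal <- function(genome, depth_mean = 100, bin_bp = 2e4,
                          sample_id = "normal", seed = 1L) {
  set.seed(seed)
  bins <- depth_bins_for(genome, NULL, purity = 1, fractions = 1,
                         depth_mean = depth_mean, bin_bp = bin_bp)
  list(sample_id = sample_id, role = "normal",
       calls = data.frame(sample_id = character(), chrom = character(),
                          pos = integer(), ref = character(),
                          alt = character(), context = character(),
                          alt_depth = integer(), total_depth = integer(),
                          vaf = numeric()),
       depth_bins = bins)
}

# expected per-bin copies: 2 + purity * sum(fraction * delta) over CNAs whose
# interval covers the bin midpoint (fraction column used when present)
depth_bins_for <- function(genome, cnas, purity, fractions, depth_mean,
                           bin_bp) {
  lens <- setNames(Biostrings::width(genome$chromosomes),
                   names(genome$chromosomes))
  out <- lapply(names(lens), function(cn) {
    starts <- seq(0L, lens[[cn]] - 1L, by = as.integer(bin_bp))
    ends <- pmin(starts + as.integer(bin_bp), lens[[cn]])
    mid <- (starts + ends) / 2
    delta <- numeric(length(starts))
    if (!is.null(cnas) && nrow(cnas)) {
      cc <- cnas[cnas$chrom == cn, , drop = FALSE]
      fr <- if ("fraction" %in% names(cc)) cc$fraction else
        rep(1, nrow(cc))
      for (j in seq_len(nrow(cc)))
        delta <- delta + ifelse(mid >= cc$start[j] & mid < cc$end[j],
                                fr[j] * cc$copy_delta[j], 0)
    }
    copies <- pmax(0, 2 + purity * delta)
    data.frame(chrom = cn, start = starts, end = ends,
               count = rpois(length(starts), depth_mean * copies / 2),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
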
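#' Monte-Carlo test for SNS enrichment in large genes
#'
#' Genes are split at `size_threshold_bp` of *genomic span*; each SNS is
#' randomly reassigned to the small or large group with probability equal to
#' the group's share of *total coding length* (the two notions deliberately
#' differ: grouping is by span, weighting by coding sequence). The p-value
#' is the fraction of replicates in which the number of SNSs landing in
#' large genes exceeds (`strict_greater`, the default reading of "more than
#' observed") or reaches (`greater_or_equal`) the observed count.
#'
#' @param sns_gene_ids Character vector: the gene each observed SNS maps to.
#' @param genes Gene model data.frame (needs `gene_id`, `genomic_span_bp`,
#'   `coding_length_bp`).
#' @param size_threshold_bp Span threshold separating small from large
#'   (default 150 kb).
#' @param n_reps Number of Monte-Carlo replicates (default one million).
#' @param seed Integer seed.
#' @param rule `"strict_greater"` or `"greater_or_equal"`.
#' @return List of class `permutation_result`: observed/expected large-gene
#'   counts, `p_value`, `p_large`, `n_reps`, `rule`, `seed`.
#' @export
permutation_test <- function(sns_gene_ids, genes,
                             size_threshold_bp = 150000,
                             n_reps = 1000000L, seed = 1L,
                             rule = c("strict_greater", "greater_or_equal")) {
  rule <- match.arg(rule)
  if (!length(sns_gene_ids)) stop("empty SNS list")
  miss <- setdiff(sns_gene_ids, genes$gene_id)
  if (length(miss)) stop("SNSs map to unknown genes: ",
                         paste(utils::head(miss, 3), collapse = ", "))
  large <- genes$genomic_span_bp > size_threshold_bp
  cl_large <- sum(as.numeric(genes$coding_length_bp[large]))
  cl_small <- sum(as.numeric(genes$coding_length_bp[!large]))
  n <- length(sns_gene_ids)
  observed <- sum(sns_gene_ids %in% genes$gene_id[large])
  if (cl_large == 0 || cl_small == 0) {
    warning("all genes in one size group; p forced to 1")
    return(structure(list(observed_large_count = observed,
                          expected_large_count = n * (cl_large > 0),
                          p_large = as.numeric(cl_large > 0),
                          p_value = 1, n_reps = n_reps, rule = rule,
                          seed = seed), class = "permutation_result"))
  }
  p_large <- cl_large / (cl_large + cl_small)
  set.seed(seed)
  draws <- rbinom(n_reps, n, p_large)
  hits <- if (rule == "strict_greater") sum(draws > observed) else
    sum(draws >= observed)
  structure(list(observed_large_count = observed,
                 expected_large_count = n * p_large,
                 p_large = p_large, p_value = hits / n_reps,
                 n_reps = n_reps, rule = rule, seed = seed),
            class = "permutation_result")
}

#' Exact binomial tail matching the permutation scheme
#'
#' Because the Monte-Carlo scheme assigns SNSs independently, its p-value
#' converges to a binomial tail; this closed form serves as the independent
#' oracle for [permutation_test()].
#'
#' @param n_sns Number of SNSs.
#' @param p_large Probability of landing in the large-gene group.
#' @param observed Observed large-gene SNS count.
#' @param rule As in [permutation_test()].
#' @return Exact tail probability.
#' @export
exact_tail <- function(n_sns, p_large, observed,
                       rule = c("strict_greater", "greater_or_equal")) {
  rule <- match.arg(rule)
  stopifnot(p_large >= 0, p_large <= 1, observed >= 0, observed <= n_sns)
  if (rule == "strict_greater")
    pbinom(observed, n_sns, p_large, lower.tail = FALSE)
  else
    pbinom(observed - 1, n_sns, p_large, lower.tail = FALSE)
}

#' Observed / expected SNS counts per gene-size bin
#'
#' Expected counts distribute the total SNS count over bins in proportion to
#' each bin's share of total coding length; observed and expected both sum
#' to the number of SNSs. Ratio is NA where the expected count is 0.
#'
#' @param sns_gene_ids Gene assignment per SNS.
#' @param genes Gene model data.frame.
#' @param bin_edges_bp Increasing numeric vector of bin edges over genomic
#'   span; must cover all gene sizes (default 0/50k/100k/150k/Inf).
#' @return data.frame with bin, observed, expected, ratio.
#' @export
obs_exp_ratios <- function(sns_gene_ids, genes,
                           bin_edges_bp = c(0, 5e4, 1e5, 1.5e5, Inf)) {
  if (is.unsorted(bin_edges_bp, strictly = TRUE))
    stop("bin edges must be strictly increasing (no overlap)")
  if (min(genes$genomic_span_bp) < bin_edges_bp[1] ||
      max(genes$genomic_span_bp) >= max(bin_edges_bp) &&
      is.finite(max(bin_edges_bp)))
    stop("bins do not cover all gene sizes")
  bin_of_gene <- cut(genes$genomic_span_bp, bin_edges_bp, right = FALSE,
                     include.lowest = FALSE)
  n <- length(sns_gene_ids)
  cl <- tapply(as.numeric(genes$coding_length_bp), bin_of_gene, sum,
               default = 0)
  expected <- n * cl / sum(as.numeric(genes$coding_length_bp))
  sns_bin <- bin_of_gene[match(sns_gene_ids, genes$gene_id)]
  observed <- as.numeric(table(sns_bin))
  data.frame(bin = levels(bin_of_gene), observed = observed,
             expected = as.numeric(expected),
             ratio = ifelse(expected > 0, observed / expected, NA),
             stringsAsFactors = FALSE)
}
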
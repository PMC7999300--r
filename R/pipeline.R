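#' Default four-tumour cohort design
#'
#' Mirrors the induction-to-sacrifice design the simulator emulates: two
#' early tumours (2 and 10 weeks, Tp53 intact, organoids from independent
#' transformation events) and two late tumours (20 and 25 weeks, Tp53 lost
#' at induction, organoids clonally related within each tumour). The
#' 25-week tumour also yields two primary biopsies and four metastases, two
#' of which are seeded by the same clone.
#'
#' @return data.frame with one row per tumour: id, duration_weeks,
#'   tp53_week (NA = never), n_organoids, related (single tree vs
#'   independent lineages), n_biopsies, n_metastases.
#' @export
default_cohort_design <- function() {
  data.frame(
    id = c("T1", "T2", "T3", "T4"),
    duration_weeks = c(2, 10, 20, 25),
    tp53_week = c(NA, NA, 0, 0),
    n_organoids = c(3L, 3L, 2L, 7L),
    related = c(FALSE, FALSE, TRUE, TRUE),
    n_biopsies = c(0L, 0L, 0L, 2L),
    n_metastases = c(0L, 0L, 0L, 4L),
    stringsAsFactors = FALSE)
}

#' Simulate a full organoid-sequencing cohort
#'
#' Builds (or reuses) a toy genome, simulates each tumour of the design,
#' derives single-cell organoids, bulk biopsies and metastasis samples with
#' read sampling, and three normal tissues for the panel of normals.
#' Deterministic for a fixed seed. When `out_dir` is given the dataset is
#' also written to disk (FASTA/BED genome, one VCF and depth-bin TSV per
#' sample, truth JSON).
#'
#' @param design See [default_cohort_design()].
#' @param genome Optional pre-built `genome_model`.
#' @param depth_mean Mean sequencing depth for every sample.
#' @param purity Bulk biopsy purity.
#' @param seed Integer seed.
#' @param out_dir Optional output directory.
#' @return List of class `cohort`: `genome`, `tumours` (per tumour: `trees`,
#'   `samples`, `organoid_nodes`), `normals` (list of 3 normal tissues),
#'   `design`, `seed`.
#' @export
simulate_cohort <- function(design = default_cohort_design(), genome = NULL,
                            depth_mean = 100, purity = 0.6, seed = 1L,
                            out_dir = NULL) {
  if (any(design$n_organoids < 1)) stop("each tumour needs >= 1 organoid")
  set.seed(seed)
  if (is.null(genome)) genome <- build_genome(genome_config(), seed = seed)
  tumours <- list()
  for (i in seq_len(nrow(design))) {
    d <- design[i, ]
    tseed <- seed * 1000L + i
    sched <- list(apc = 0, kras = 0,
                  tp53 = if (is.na(d$tp53_week)) NA else d$tp53_week)
    if (d$related) {
      bt <- if (d$n_organoids > 1)
        sort(runif(d$n_organoids - 1L, 0.2 * d$duration_weeks,
                   0.9 * d$duration_weeks)) else numeric(0)
      cfg <- sim_config(driver_schedule = sched, branching_times = bt,
                        duration_weeks = d$duration_weeks)
      tree <- simulate_lineage(genome, cfg, seed = tseed)
      leaves <- clone_leaves(tree)
      org_nodes <- leaves[seq_len(d$n_organoids)]
      trees <- list(tree)
      tree_of <- setNames(rep(1L, d$n_organoids), org_nodes)
    } else {
      cfg <- sim_config(driver_schedule = sched,
                        duration_weeks = d$duration_weeks)
      trees <- lapply(seq_len(d$n_organoids), function(k)
        simulate_lineage(genome, cfg, seed = tseed + k))
      org_nodes <- vapply(trees, function(tr) clone_leaves(tr)[1],
                          character(1))
      tree_of <- setNames(seq_len(d$n_organoids), org_nodes)
    }
    samples <- list()
    for (k in seq_along(org_nodes)) {
      sid <- sprintf("%s_O%d", d$id, k)
      samples[[sid]] <- sample_organoid(trees[[tree_of[k]]], org_nodes[k],
                                        depth_mean = depth_mean,
                                        sample_id = sid,
                                        seed = tseed + 100L + k)
    }
    if (d$related && d$n_biopsies > 0) {
      tree <- trees[[1]]
      split_at <- ceiling(length(org_nodes) / 2)
      parts <- list(org_nodes[seq_len(split_at)],
                    org_nodes[-seq_len(split_at)])
      for (b in seq_len(min(d$n_biopsies, 2L))) {
        mix <- setNames(rep(1 / length(parts[[b]]), length(parts[[b]])),
                        parts[[b]])
        sid <- sprintf("%s_PT%d", d$id, b)
        samples[[sid]] <- sample_bulk(tree, mix, purity = purity,
                                      depth_mean = depth_mean,
                                      sample_id = sid,
                                      role = "primary_biopsy",
                                      seed = tseed + 200L + b)
      }
    }
    if (d$related && d$n_metastases > 0) {
      tree <- trees[[1]]
      internals <- tree$nodes$id[!tree$nodes$is_leaf]
      seeds_pool <- unique(c(internals[1], org_nodes))
      picks <- seeds_pool[1 + (seq_len(d$n_metastases - 1L) %%
                                 length(seeds_pool))]
      picks <- c(picks, picks[length(picks)])   # last two share a clone
      picks <- picks[seq_len(d$n_metastases)]
      for (m in seq_len(d$n_metastases)) {
        sid <- sprintf("%s_MT%d", d$id, m)
        samples[[sid]] <- sample_bulk(tree, setNames(1, picks[m]),
                                      purity = 0.8,
                                      depth_mean = depth_mean,
                                      sample_id = sid, role = "metastasis",
                                      seed = tseed + 300L + m)
      }
    }
    tumours[[d$id]] <- list(trees = trees, samples = samples,
                            organoid_nodes = org_nodes, tree_of = tree_of,
                            design = d)
  }
  normals <- lapply(seq_len(3), function(k)
    sample_normal(genome, depth_mean = depth_mean,
                  sample_id = c("liver", "kidney", "spleen")[k],
                  seed = seed * 7L + k))
  names(normals) <- c("liver", "kidney", "spleen")
  cohort <- structure(list(genome = genome, tumours = tumours,
                           normals = normals, design = design, seed = seed),
                      class = "cohort")
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

#' Write a simulated cohort to disk
#' @param cohort A `cohort`.
#' @param dir Output directory.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genome(cohort$genome, file.path(dir, "genome"))
  truth <- list(seed = cohort$seed)
  for (tid in names(cohort$tumours)) {
    tu <- cohort$tumours[[tid]]
    tdir <- file.path(dir, tid)
    dir.create(tdir, showWarnings = FALSE)
    for (sid in names(tu$samples)) {
      s <- tu$samples[[sid]]
      write_vcf(s$calls, sid, file.path(tdir, paste0(sid, ".vcf")))
      write_depth_bins(s$depth_bins,
                       file.path(tdir, paste0(sid, ".bins.tsv")))
    }
    truth[[tid]] <- list(
      organoid_nodes = as.list(tu$organoid_nodes),
      nodes = lapply(tu$trees, `[[`, "nodes"))
  }
  for (nid in names(cohort$normals))
    write_depth_bins(cohort$normals[[nid]]$depth_bins,
                     file.path(dir, paste0(nid, ".bins.tsv")))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}

#' Analyse a simulated (or assembled) cohort end to end
#'
#' Runs every analysis stage on a `cohort`: presence matrices and sharing
#' classes per tumour, VAF summaries by role, pooled 96-context spectrum
#' (raw and triplet-normalised over the coding territory) with signature
#' decomposition, consequence counts, gene-size enrichment test, per-sample
#' CNA segmentation with panel-of-normals filtering and the Tp53/large-CNA
#' association, clonal phylogeny (and metastasis seeding count) for related
#' tumours, SNS-burden regression on tumour age, replication-timing strata,
#' and pairwise burden comparisons.
#'
#' @param cohort A `cohort` from [simulate_cohort()].
#' @param n_reps Permutation-test replicates (default 1e5 here; the
#'   canonical figure-level default of 1e6 is available via
#'   [permutation_test()]).
#' @param seed Seed for the permutation test.
#' @param out_dir Optional directory for the JSON/TSV/Newick report.
#' @return List of class `cohort_report`.
#' @export
run_analyze <- function(cohort, n_reps = 100000L, seed = 1L,
                        out_dir = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  genome <- cohort$genome
  report <- list()

  all_org_calls <- list(); burden <- list(); ages <- list()
  tumour_reports <- list()
  for (tid in names(cohort$tumours)) {
    tu <- cohort$tumours[[tid]]
    tr <- list()
    mat <- build_presence_matrix(unname(tu$samples))
    tr$matrix <- mat
    roles <- mat_roles(mat)
    orgs <- names(roles)[roles == "organoid"]
    if (tu$design$related && length(orgs) >= 2) {
      sh <- classify_sharing(mat, orgs)
      tr$sharing <- sh$counts
      comp <- check_compatibility(mat)
      tree <- build_tree(comp, rownames(mat))
      tr$tree_newick <- write_newick(tree)
      tr$root_out_degree <- root_out_degree(tree)
      tr$n_conflicts <- length(comp$conflicts)
      tr$seeding_events <- count_seeding_events(mat)
    }
    counts <- integer(0)
    for (sid in orgs) {
      calls <- tu$samples[[sid]]$calls
      cons <- annotate_consequence(calls, genome)
      keep <- cons != "noncoding"
      counts[sid] <- sum(keep)
      calls$consequence <- as.character(cons)
      calls$gene_id <- attr(cons, "gene_id")
      calls$role <- "organoid"
      all_org_calls[[sid]] <- calls
    }
    burden[[tid]] <- counts
    ages[[tid]] <- rep(tu$design$duration_weeks, length(counts))
    tumour_reports[[tid]] <- tr
  }
  report$tumours <- tumour_reports

  org_calls <- do.call(rbind, all_org_calls)
  coding_calls <- org_calls[org_calls$consequence != "noncoding", ,
                            drop = FALSE]

  # VAF summary over organoid + bulk calls
  keep_cols <- c("sample_id", "alt_depth", "total_depth", "role")
  bulk_calls <- do.call(rbind, lapply(cohort$tumours, function(tu)
    do.call(rbind, lapply(tu$samples, function(s)
      if (s$role != "organoid" && nrow(s$calls))
        cbind(s$calls, role = s$role)[keep_cols] else NULL))))
  report$vaf <- vaf_summary(rbind(org_calls[keep_cols], bulk_calls))

  # spectra over coding territory
  masks <- territory_masks(genome)
  census <- triplet_census(genome, masks$coding)
  uniq <- unique(org_calls[c("chrom", "pos", "ref", "alt")])
  spec <- spectrum96(uniq, genome)
  nspec <- normalize_spectrum(spec, census)
  fit <- fit_signatures(spec)
  report$spectrum <- list(raw = as.numeric(spec),
                          normalized = as.numeric(nspec),
                          weights = fit$weights, residual = fit$residual)

  report$consequences <- table(coding_calls$consequence)

  # gene-size enrichment over coding/splice SNSs
  with_gene <- coding_calls[!is.na(coding_calls$gene_id), , drop = FALSE]
  if (nrow(with_gene) > 0) {
    pt <- permutation_test(with_gene$gene_id, genome$genes,
                           n_reps = n_reps, seed = seed)
    report$gene_size <- list(p_value = pt$p_value,
                             observed = pt$observed_large_count,
                             expected = pt$expected_large_count,
                             exact = exact_tail(nrow(with_gene), pt$p_large,
                                                pt$observed_large_count))
    report$obs_exp <- obs_exp_ratios(with_gene$gene_id, genome$genes)
  }

  # CNA pipeline with panel of normals
  normal_bins <- cohort$normals[[1]]$depth_bins
  panel <- lapply(cohort$normals, function(nb)
    segment_ratios(log2_ratios(nb$depth_bins, normal_bins)))
  tp53 <- logical(0); large <- logical(0)
  seg_report <- list()
  for (tid in names(cohort$tumours)) {
    tu <- cohort$tumours[[tid]]
    roles <- vapply(tu$samples, `[[`, character(1), "role")
    for (sid in names(tu$samples)[roles == "organoid"]) {
      segs <- segment_ratios(log2_ratios(tu$samples[[sid]]$depth_bins,
                                         normal_bins))
      segs <- filter_panel(segs, panel)
      seg_report[[sid]] <- segs
      k <- match(sid, names(tu$samples))
      node <- tu$organoid_nodes[[k]]
      tree <- tu$trees[[tu$tree_of[[k]]]]
      tp53[sid] <- tree$nodes$tp53_mut[tree$nodes$id == node]
      large[sid] <- any(segs$call != "neutral" & segs$large_scale)
    }
  }
  report$cna <- list(segments = seg_report,
                     association = associate_cna_genotype(tp53, large))

  # burden regression and group comparison
  report$regression <- fit_rate_regression(unlist(ages), unlist(burden))
  multi <- burden[lengths(burden) >= 2]
  if (length(multi) >= 2) report$burden_comparison <- compare_burden(multi)

  report$strata <- timing_strata(uniq, genome)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (tid in names(report$tumours)) {
      nwk <- report$tumours[[tid]]$tree_newick
      if (!is.null(nwk))
        writeLines(nwk, file.path(out_dir, paste0(tid, ".nwk")))
    }
    slim <- report
    slim$tumours <- lapply(report$tumours, function(tr)
      tr[setdiff(names(tr), "matrix")])
    slim$cna$segments <- NULL
    jsonlite::write_json(slim, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  class(report) <- "cohort_report"
  report
}

#' Worked-example presence matrices shipped with the package
#'
#' Two small fixtures encode published-style sharing structures for direct
#' reconstruction: `example_two_organoid_matrix()` is a tumour with two
#' organoids sharing 14 variants, with 2 and 6 private to each; and
#' `example_metastasis_matrix()` is a seven-organoid, four-metastasis tumour
#' whose variant groups form a clonal tree with three branches off the
#' trunk, four truncal SNSs, two conflicting characters, and three distinct
#' metastasis profiles.
#'
#' @return A `presence_matrix`.
#' @export
example_two_organoid_matrix <- function() {
  read_presence_matrix(system.file("extdata", "example_two_organoid.tsv",
                                   package = "clonetrace", mustWork = TRUE))
}

#' @rdname example_two_organoid_matrix
#' @export
example_metastasis_matrix <- function() {
  read_presence_matrix(system.file("extdata", "example_metastasis.tsv",
                                   package = "clonetrace", mustWork = TRUE))
}

#' Run the in-package worked examples
#'
#' Loads the two fixture matrices and reports sharing classes, the clonal
#' tree, conflicts and seeding events.
#' @return Named list of results.
#' @export
run_examples <- function() {
  m3 <- example_two_organoid_matrix()
  m4 <- example_metastasis_matrix()
  sh3 <- classify_sharing(m3)
  sh4 <- classify_sharing(m4)
  comp <- check_compatibility(m4)
  tree <- build_tree(comp, rownames(m4))
  list(two_organoid = list(sharing = sh3$counts, note = sh3$note),
       metastasis = list(sharing = sh4$counts,
                         root_out_degree = root_out_degree(tree),
                         newick = write_newick(tree),
                         n_conflict_characters = sum(lengths(lapply(
                           comp$conflicts, `[[`, "characters"))),
                         seeding_events = count_seeding_events(m4)))
}
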
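#' Configuration for the clonal-evolution simulator
#'
#' The simulated dynamics encode the study design this package targets:
#' single nucleotide substitutions (SNSs) accrue as a Poisson process at a
#' time-constant rate that does not depend on how many driver genes are
#' inactivated, while copy number alterations (CNAs) arise only on lineages
#' that have lost Tp53 (unless `cna_rate_per_week_tp53wt` is raised above
#' its default of 0).
#'
#' @param sns_rate_per_week Expected number of coding + splice-site SNSs per
#'   lineage per week (default 0.8, so a 25-week lineage accrues ~20 coding
#'   SNSs). SNSs are placed genome-wide; the genome-wide intensity is the
#'   coding rate divided by the genome's coding+splice fraction, so the
#'   coding+splice count has exactly this mean by Poisson thinning.
#' @param normal_sns_rate_per_week SNS rate for non-transformed lineages
#'   (default one tenth of the tumour rate, a configurable ratio motivated
#'   by reported order-of-magnitude differences between precancerous and
#'   normal intestinal organoids).
#' @param signature_weights Named weights over `sig1_like`, `sig17_like`,
#'   `uniform`; must sum to 1. Class draws follow the reference profiles of
#'   [reference_profiles()].
#' @param cna_rate_per_week_tp53null,cna_rate_per_week_tp53wt CNA event
#'   rates per lineage per week after/without Tp53 loss.
#' @param cna_length_range_bp Two-element numeric; CNA lengths are drawn
#'   log-uniformly from this range. The default is 5-80 Mb scaled by
#'   `genome_scale`, so both sub-threshold and large-scale events occur.
#' @param genome_scale Miniaturisation factor mapping real-genome lengths
#'   onto the toy genome (toy chromosome length / 100 Mb nominal;
#'   default 0.02). The 10 Mb large-scale threshold scales by the same
#'   factor, preserving its semantics.
#' @param driver_schedule Named list of times (weeks) at which Apc, Kras and
#'   Tp53 are hit; `NA` means never. All extant lineages switch genotype at
#'   the scheduled time (recombinase induction acts tumour-wide), so
#'   genotype flags are monotone along every root-to-leaf path.
#' @param branching_times Times (weeks) at which a uniformly chosen extant
#'   lineage splits in two.
#' @param duration_weeks Total simulated time.
#' @param transformed Logical; if FALSE the lineage is a normal-tissue
#'   lineage and `normal_sns_rate_per_week` applies.
#' @param late_enrichment,large_gene_enrichment Optional placement biases
#'   (acceptance-weight multipliers) for late-S replicating domains and for
#'   genes with genomic span > 150 kb; both default to 1 (uniform placement).
#' @param bin_bp Depth-bin width for read-count emission (default 20 kb).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(sns_rate_per_week = 0.8,
                       normal_sns_rate_per_week = 0.08,
                       signature_weights = c(sig1_like = 0.55,
                                             sig17_like = 0.15,
                                             uniform = 0.30),
                       cna_rate_per_week_tp53null = 0.15,
                       cna_rate_per_week_tp53wt = 0,
                       genome_scale = 0.02,
                       cna_length_range_bp = c(5e6, 8e7) * genome_scale,
                       driver_schedule = list(apc = 0, kras = 0, tp53 = NA),
                       branching_times = numeric(0),
                       duration_weeks = 25,
                       transformed = TRUE,
                       late_enrichment = 1,
                       large_gene_enrichment = 1,
                       bin_bp = 2e4) {
  if (sns_rate_per_week < 0 || normal_sns_rate_per_week < 0 ||
      cna_rate_per_week_tp53null < 0 || cna_rate_per_week_tp53wt < 0)
    stop("rates must be >= 0")
  if (abs(sum(signature_weights) - 1) > 1e-9)
    stop("signature_weights must sum to 1")
  if (duration_weeks <= 0) stop("duration_weeks must be > 0")
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate one clonal lineage tree
#'
#' Grows a rooted clone tree over `duration_weeks`: SNSs arrive as a Poisson
#' process along each branch at a genotype-independent rate, with
#' trinucleotide contexts drawn from the configured signature mixture and
#' placed by rejection sampling (so the realised class frequencies follow
#' the mixture exactly, regardless of genome composition). CNAs arrive only
#' during branch time where Tp53 is lost (at the Tp53-wild-type rate
#' otherwise, default 0), with log-uniform lengths; overlapping CNAs on one
#' lineage are redrawn so copy-number arithmetic stays unambiguous. SNS
#' placement obeys infinite sites (no position hit twice per tree).
#'
#' @param genome A `genome_model`.
#' @param config A [sim_config()].
#' @param seed Integer seed; the simulation is deterministic given
#'   (genome, config, seed).
#' @return Object of class `clone_tree`: `nodes` data.frame (id, parent,
#'   birth/end times, genotype flags, leaf flag), `private` per-node event
#'   lists, `state` per-node full mutation state (variants with
#'   mutated/total copy counts, CNAs), plus genome and config references.
#' @export
simulate_lineage <- function(genome, config = sim_config(), seed = 1L) {
  stopifnot(inherits(genome, "genome_model"), inherits(config, "sim_config"))
  set.seed(seed)
  dur <- config$duration_weeks

  # --- topology -------------------------------------------------------------
  bt <- sort(config$branching_times)
  bt <- bt[bt > 0 & bt < dur]
  nodes <- data.frame(id = "N1", parent = NA_character_, birth = 0,
                      end = dur, stringsAsFactors = FALSE)
  extant <- "N1"
  for (tb in bt) {
    leaf <- if (length(extant) == 1) extant else sample(extant, 1)
    nodes$end[nodes$id == leaf] <- tb
    kids <- paste0("N", nrow(nodes) + seq_len(2))
    nodes <- rbind(nodes, data.frame(id = kids, parent = leaf, birth = tb,
                                     end = dur, stringsAsFactors = FALSE))
    extant <- c(setdiff(extant, leaf), kids)
  }
  nodes$is_leaf <- !(nodes$id %in% nodes$parent)
  sched <- config$driver_schedule
  flag_at <- function(t, when) !is.na(when) && t >= when
  nodes$apc_mut <- vapply(nodes$end, flag_at, logical(1), sched$apc)
  nodes$kras_mut <- vapply(nodes$end, flag_at, logical(1), sched$kras)
  nodes$tp53_mut <- vapply(nodes$end, flag_at, logical(1), sched$tp53)

  # --- rates ----------------------------------------------------------------
  cache <- genome_seq_cache(genome)
  frac <- coding_splice_fraction(genome)
  base_rate <- if (config$transformed) config$sns_rate_per_week else
    config$normal_sns_rate_per_week
  genome_rate <- if (frac > 0) base_rate / frac else base_rate
  profiles <- reference_profiles()
  mix <- profiles$sig1_like * config$signature_weights[["sig1_like"]] +
    profiles$sig17_like * config$signature_weights[["sig17_like"]] +
    profiles$uniform * config$signature_weights[["uniform"]]

  used <- new.env(parent = emptyenv())   # infinite-sites registry
  counter <- new.env(parent = emptyenv())
  counter$sns <- 0L; counter$cna <- 0L

  private <- list(); state <- list()
  # DFS in order of creation (parents precede children by construction)
  for (i in seq_len(nrow(nodes))) {
    nd <- nodes[i, ]
    pstate <- if (is.na(nd$parent)) empty_state() else state[[nd$parent]]
    res <- evolve_edge(nd, pstate, genome, config, cache, genome_rate, mix,
                       used, counter)
    private[[nd$id]] <- res$private
    state[[nd$id]] <- res$state
  }

  structure(list(nodes = nodes, private = private, state = state,
                 genome = genome, config = config, seed = seed),
            class = "clone_tree")
}

empty_state <- function() {
  list(variants = data.frame(
    id = character(), chrom = character(), pos = integer(),
    ref = character(), alt = character(), context = character(),
    mut_copies = integer(), tot_copies = integer(),
    origin = character(), stringsAsFactors = FALSE),
    cnas = data.frame(id = character(), chrom = character(),
                      start = integer(), end = integer(), kind = character(),
                      copy_delta = integer(), origin = character(),
                      stringsAsFactors = FALSE))
}

# simulate private events on one edge and propagate state
evolve_edge <- function(nd, pstate, genome, config, cache, genome_rate, mix,
                        used, counter) {
  t0 <- nd$birth; t1 <- nd$end
  elapsed <- t1 - t0
  n_sns <- if (elapsed > 0) rpois(1, genome_rate * elapsed) else 0L
  # CNA-eligible time on this edge
  tp53_t <- config$driver_schedule$tp53
  null_time <- if (is.na(tp53_t)) 0 else max(0, t1 - max(t0, tp53_t))
  wt_time <- elapsed - null_time
  n_cna <- rpois(1, config$cna_rate_per_week_tp53null * null_time +
                   config$cna_rate_per_week_tp53wt * wt_time)

  ev <- data.frame(type = rep(c("sns", "cna"), c(n_sns, n_cna)))
  ev$time <- runif(n_sns + n_cna, t0, t1)
  ev <- ev[order(ev$time), , drop = FALSE]

  st <- pstate
  sns_rows <- list(); cna_rows <- list()
  for (k in seq_len(nrow(ev))) {
    if (ev$type[k] == "sns") {
      counter$sns <- counter$sns + 1L
      v <- place_sns(genome, config, cache, mix, used)
      v$id <- sprintf("s%05d", counter$sns)
      v$origin <- nd$id
      # local copy number at the new site
      ov <- st$cnas$chrom == v$chrom & st$cnas$start <= v$pos &
        v$pos < st$cnas$end
      tot <- 2L + sum(st$cnas$copy_delta[ov])
      if (tot < 1L) next                       # fully deleted region
      v$mut_copies <- 1L; v$tot_copies <- tot
      sns_rows[[length(sns_rows) + 1L]] <- v
      st$variants <- rbind(st$variants, as.data.frame(v)[names(st$variants)])
    } else {
      counter$cna <- counter$cna + 1L
      cn <- place_cna(genome, config, st$cnas)
      if (is.null(cn)) next
      cn$id <- sprintf("c%03d", counter$cna)
      cn$origin <- nd$id
      cna_rows[[length(cna_rows) + 1L]] <- cn
      st$cnas <- rbind(st$cnas, as.data.frame(cn)[names(st$cnas)])
      # update copy counts of variants inside the event
      hit <- which(st$variants$chrom == cn$chrom &
                     st$variants$pos >= cn$start & st$variants$pos < cn$end)
      for (h in hit) {
        m <- st$variants$mut_copies[h]; tt <- st$variants$tot_copies[h]
        if (cn$copy_delta > 0) {
          st$variants$mut_copies[h] <- m + rbinom(1, 1, m / tt)
          st$variants$tot_copies[h] <- tt + 1L
        } else {
          st$variants$mut_copies[h] <- m - rbinom(1, 1, m / tt)
          st$variants$tot_copies[h] <- tt - 1L
        }
      }
    }
  }
  list(state = st,
       private = list(sns = do.call(rbind, lapply(sns_rows, as.data.frame)),
                      cna = do.call(rbind, lapply(cna_rows, as.data.frame))))
}

# draw one SNS: signature class from the mixture, then a uniform draw over
# the genome positions whose pyrimidine-collapsed triplet matches the class
# (precomputed index; equivalent in distribution to rejection sampling but
# without the per-event genome scan). Placement biases are applied by
# thinning; infinite sites via the `used` registry.
place_sns <- function(genome, config, cache, mix, used) {
  cl <- sample(names(mix), 1, prob = mix)
  target_tri <- class_triplet(cl)
  pyr_alt <- substr(cl, 5, 5)
  idx <- context_index(genome)
  slot <- idx[[target_tri]]
  if (is.null(slot) || nrow(slot) == 0)
    stop("no genomic position matching context class ", cl,
         " (triplet ", target_tri, ") exists in this genome")
  w_late <- config$late_enrichment
  w_large <- config$large_gene_enrichment
  w_max <- max(1, w_late) * max(1, w_large)
  ctr <- substr(target_tri, 2, 2)
  for (try in seq_len(10000L)) {
    r <- slot[sample.int(nrow(slot), 1L), ]
    cn <- cache$names[r[["chrom_i"]]]
    pos <- r[["pos"]]
    key <- paste0(cn, ":", pos)
    if (!is.null(used[[key]])) next
    if (w_max > 1) {
      w <- pos_weight(genome, cn, pos, w_late, w_large)
      if (runif(1) > w / w_max) next
    }
    used[[key]] <- TRUE
    fwd_pyr <- r[["flipped"]] == 0L
    ref <- if (fwd_pyr) ctr else COMPLEMENT[[ctr]]
    alt <- if (fwd_pyr) pyr_alt else COMPLEMENT[[pyr_alt]]
    return(list(chrom = cn, pos = pos, ref = ref, alt = alt, context = cl))
  }
  stop("could not place an SNS of class ", cl,
       " without violating infinite sites; genome too saturated")
}

# memoised per-genome index: for each pyrimidine-collapsed triplet, the
# 0-based centre positions carrying it (flipped = centre is a purine on the
# forward strand)
context_index <- function(genome) {
  env <- genome$cache
  if (!is.null(env$ctx_index)) return(env$ctx_index)
  base_code <- c(A = 0L, C = 1L, G = 2L, T = 3L)
  tri64 <- Biostrings::mkAllStrings(BASES, 3)     # code order 0..63
  coll <- vapply(tri64, function(t) {
    if (substr(t, 2, 2) %in% c("C", "T")) t else revcomp(t)
  }, character(1), USE.NAMES = FALSE)
  flip64 <- !(substr(tri64, 2, 2) %in% c("C", "T"))
  map64 <- match(coll, pyrimidine_triplets())
  ascii_code <- rep(NA_integer_, 128)
  ascii_code[utf8ToInt("A")] <- 0L; ascii_code[utf8ToInt("C")] <- 1L
  ascii_code[utf8ToInt("G")] <- 2L; ascii_code[utf8ToInt("T")] <- 3L
  per_chrom <- lapply(seq_along(genome$chromosomes), function(ci) {
    x <- ascii_code[utf8ToInt(as.character(genome$chromosomes[[ci]]))]
    L <- length(x)
    if (L < 3) return(NULL)
    codes <- 16L * x[1:(L - 2L)] + 4L * x[2:(L - 1L)] + x[3:L]
    cls <- map64[codes + 1L]
    flp <- flip64[codes + 1L]
    list(ci = ci, sp = split(seq_len(L - 2L), cls), flp = flp)
  })
  out <- setNames(vector("list", 32), pyrimidine_triplets())
  for (k in seq_len(32)) {
    key <- as.character(k)
    parts <- lapply(per_chrom, function(pc) {
      if (is.null(pc) || is.null(pc$sp[[key]])) return(NULL)
      pos <- pc$sp[[key]]              # 0-based centre == index
      cbind(chrom_i = pc$ci, pos = pos, flipped = as.integer(pc$flp[pos]))
    })
    parts <- parts[!vapply(parts, is.null, logical(1))]
    out[[k]] <- if (length(parts)) do.call(rbind, parts) else
      matrix(integer(0), ncol = 3,
             dimnames = list(NULL, c("chrom_i", "pos", "flipped")))
  }
  if (!is.null(env)) env$ctx_index <- out
  out
}

pos_weight <- function(genome, chrom, pos, w_late, w_large) {
  w <- 1
  if (w_late != 1) {
    td <- genome$timing
    row <- td[td$chrom == chrom & td$start <= pos & pos < td$end, , drop = FALSE]
    if (nrow(row) && row$stratum[1] == "late") w <- w * w_late
  }
  if (w_large != 1) {
    g <- genome$genes
    hit <- g$chrom == chrom & g$span_start <= pos & pos < g$span_end &
      g$genomic_span_bp > 150000
    if (any(hit)) w <- w * w_large
  }
  w
}

# one CNA; redrawn (up to 100x) to avoid overlapping lineage CNAs
place_cna <- function(genome, config, existing) {
  lens <- setNames(Biostrings::width(genome$chromosomes),
                   names(genome$chromosomes))
  rng <- log(config$cna_length_range_bp)
  for (try in seq_len(100L)) {
    len <- as.integer(round(exp(runif(1, rng[1], rng[2]))))
    ok_chr <- which(lens > len)
    if (!length(ok_chr)) next
    ci <- if (length(ok_chr) == 1) ok_chr else
      sample(ok_chr, 1, prob = lens[ok_chr])
    start <- sample.int(lens[ci] - len, 1) - 1L
    end <- start + len
    cn <- names(lens)[ci]
    if (nrow(existing)) {
      ov <- existing$chrom == cn & existing$start < end & start < existing$end
      if (any(ov)) next
    }
    kind <- sample(c("loss", "gain"), 1)
    return(list(chrom = cn, start = start, end = end, kind = kind,
                copy_delta = if (kind == "loss") -1L else 1L))
  }
  NULL   # could not place without overlap; event dropped
}

genome_seq_cache <- function(genome) {
  seqs <- as.character(genome$chromosomes)
  list(seq = unname(seqs), names = names(seqs),
       lens = unname(Biostrings::width(genome$chromosomes)))
}

#' Fraction of the genome that is coding sequence or splice site
#'
#' Used by the simulator to thin the genome-wide SNS intensity so the
#' coding+splice count has exactly the configured per-week mean.
#' @param genome A `genome_model`.
#' @return Numeric fraction in [0, 1].
#' @export
coding_splice_fraction <- function(genome) {
  masks <- territory_masks(genome)
  coding <- sum(as.numeric(GenomicRanges::width(masks$coding)))
  splice <- 0
  g <- genome$genes
  if (nrow(g)) {
    n_internal <- vapply(g$exon_starts, function(s)
      max(0L, 2L * (length(s) - 1L)), integer(1))
    splice <- sum(n_internal) * 2      # 2 bp on each intronic side
  }
  total <- sum(as.numeric(Biostrings::width(genome$chromosomes)))
  (coding + splice) / total
}

#' Full mutation set of a clone
#'
#' @param tree A `clone_tree`.
#' @param node Node id.
#' @return data.frame of variants carried by the clone (mutated copies > 0).
#' @export
clone_mutations <- function(tree, node) {
  st <- tree$state[[node]]
  if (is.null(st)) stop("unknown node: ", node)
  st$variants[st$variants$mut_copies > 0L, , drop = FALSE]
}

#' @rdname clone_mutations
#' @return `clone_cnas`: data.frame of CNA events carried by the clone.
#' @export
clone_cnas <- function(tree, node) {
  st <- tree$state[[node]]
  if (is.null(st)) stop("unknown node: ", node)
  st$cnas
}

#' Leaf node ids of a clone tree
#' @param tree A `clone_tree`.
#' @export
clone_leaves <- function(tree) tree$nodes$id[tree$nodes$is_leaf]
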
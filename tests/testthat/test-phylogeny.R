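tier_matrix <- function(sets, samples) {
  m <- matrix(0L, length(samples), length(sets),
              dimnames = list(samples, names(sets)))
  for (nm in names(sets)) m[sets[[nm]], nm] <- 3L
  presence_matrix(m, rep("organoid", length(samples)))
}

test_that("laminar families pass; overlapping non-nested sets conflict", {
  samples <- c("A", "B", "C")
  ok <- tier_matrix(list(v1 = c("A", "B", "C"), v2 = c("A", "B"),
                         v3 = "C"), samples)
  comp <- check_compatibility(ok)
  expect_length(comp$conflicts, 0)
  bad <- tier_matrix(list(v1 = c("A", "B"), v2 = c("A", "B"),
                          v3 = c("B", "C")), samples)
  comp2 <- check_compatibility(bad)
  # larger group (2 characters on {A,B}) kept, {B,C} excluded
  expect_length(comp2$conflicts, 1)
  expect_identical(comp2$conflicts[[1]]$characters, "v3")
  expect_error(check_compatibility(ok, samples = "A"), ">= 2")
})

test_that("metastasis example: conflicting pair excluded, shape recovered", {
  m4 <- example_metastasis_matrix()
  comp <- check_compatibility(m4)
  excluded <- unlist(lapply(comp$conflicts, `[[`, "characters"))
  expect_setequal(excluded, c("SNS_X1", "SNS_X2"))
  tree <- build_tree(comp, rownames(m4))
  expect_identical(root_out_degree(tree), 3L)
  # MT3 and MT4 are sibling leaves under one node
  p3 <- tree$nodes$parent[tree$nodes$label %in% c("MT3", "MT4")]
  expect_identical(p3[1], p3[2])
  nwk <- write_newick(tree)
  expect_identical(sum(read_newick(nwk)$nodes$is_leaf), 11L)
})

test_that("trunk-only matrix gives a single internal node", {
  m <- tier_matrix(list(v1 = c("A", "B", "C"), v2 = c("A", "B", "C")),
                   c("A", "B", "C"))
  tree <- build_tree(check_compatibility(m), rownames(m))
  internal <- tree$nodes[!tree$nodes$is_leaf, ]
  expect_identical(nrow(internal), 1L)
  expect_identical(root_out_degree(tree), 3L)   # three sample leaves
  expect_setequal(tree$edge_characters[[internal$id]], c("v1", "v2"))
})

test_that("edges carry exactly the characters of the leaves below them", {
  m4 <- example_metastasis_matrix()
  comp <- check_compatibility(m4)
  tree <- build_tree(comp, rownames(m4))
  bin <- m4 > 0
  for (id in tree$nodes$id) {
    ch <- tree$edge_characters[[id]]
    below <- tree$sets[[id]]
    for (v in ch)
      expect_setequal(rownames(bin)[bin[, v]], below)
  }
})

test_that("reconstruction is invariant to sample/character permutation", {
  m4 <- example_metastasis_matrix()
  set.seed(8)
  perm <- unclass(m4)[sample(nrow(m4)), sample(ncol(m4))]
  pm <- presence_matrix(perm, attr(m4, "roles")[rownames(perm)])
  t1 <- build_tree(check_compatibility(m4), rownames(m4))
  t2 <- build_tree(check_compatibility(pm), rownames(pm))
  expect_identical(tree_clades(t1), tree_clades(t2))
})

test_that("simulated lineages are reconstructed exactly from perfect calls", {
  g <- fast_genome()
  for (s in 1:8) {
    n_leaves <- 2 + (s %% 4)
    cfg <- sim_config(driver_schedule = list(apc = 0, kras = 0, tp53 = NA),
                      sns_rate_per_week = 4, duration_weeks = 10,
                      branching_times = sort(runif(n_leaves - 1, 1, 9)))
    tr <- simulate_lineage(g, cfg, seed = 700 + s)
    leaves <- clone_leaves(tr)
    samples <- lapply(leaves, function(l) {
      m <- clone_mutations(tr, l)
      list(sample_id = l, role = "organoid",
           calls = data.frame(chrom = m$chrom, pos = m$pos, ref = m$ref,
                              alt = m$alt, alt_depth = 50L,
                              total_depth = 100L, stringsAsFactors = FALSE))
    })
    mat <- build_presence_matrix(samples)
    # truth oracle: each variant's carrier set = leaves below its origin
    below <- function(id) {
      kids <- tr$nodes$id[!is.na(tr$nodes$parent) & tr$nodes$parent == id]
      if (!length(kids)) return(intersect(id, leaves))
      unlist(lapply(kids, below))
    }
    for (nd in tr$nodes$id) {
      p <- tr$private[[nd]]$sns
      if (is.null(p) || !nrow(p)) next
      keys <- paste(p$chrom, p$pos, p$alt, sep = ":")
      keys <- intersect(keys, colnames(mat))     # CNA-free: all retained
      for (key in keys)
        expect_setequal(rownames(mat)[mat[, key] > 0], below(nd))
    }
    comp <- check_compatibility(mat)
    expect_length(comp$conflicts, 0)             # truth is conflict-free
    tree <- build_tree(comp, rownames(mat))
    got <- tree_clades(tree)
    want <- sort(unique(c(carrier_sets(mat), rownames(mat),
                          paste(sort(rownames(mat)), collapse = ","))))
    expect_identical(got, want)
  }
})

test_that("newick writer/parser round-trips random trees", {
  set.seed(90)
  rand_sets <- function(samples) {
    # random laminar family by recursive splitting
    out <- list()
    rec <- function(s) {
      out[[length(out) + 1L]] <<- s
      if (length(s) >= 2 && runif(1) < 0.8) {
        k <- sample(seq_len(length(s) - 1), 1)
        rec(s[1:k]); rec(s[-(1:k)])
      }
    }
    rec(samples)
    setNames(out, sprintf("grp%02d", seq_along(out)))
  }
  for (k in 1:100) {
    samples <- paste0("S", seq_len(sample(2:8, 1)))
    sets <- rand_sets(sample(samples))
    m <- tier_matrix(sets, samples)
    tree <- build_tree(check_compatibility(m), samples)
    nwk <- write_newick(tree)
    back <- read_newick(nwk)
    expect_identical(write_newick(back), nwk)
    expect_identical(tree_clades(back), tree_clades(tree))
    expect_setequal(unname(unlist(back$edge_characters)),
                    unname(unlist(tree$edge_characters)))
  }
  # single leaf form and malformed input
  m1 <- tier_matrix(list(v = "A"), c("A", "B"))
  t1 <- build_tree(check_compatibility(m1), c("A", "B"))
  expect_match(write_newick(t1), "^\\(.*\\).*;$")
  expect_error(read_newick("(A,B)"), "';'")
  expect_error(read_newick("(A,[x);"), "position")
  # newick topology agrees with the ape parser on a comment-free tree
  plain <- "((A,B),C);"
  tr_ape <- ape::read.tree(text = plain)
  tr_own <- read_newick(plain)
  expect_setequal(tr_own$nodes$label[tr_own$nodes$is_leaf], tr_ape$tip.label)
  expect_identical(sum(!tr_own$nodes$is_leaf), tr_ape$Nnode)
})
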
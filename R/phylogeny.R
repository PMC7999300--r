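#' Group binary characters and find a maximal compatible (laminar) set
#'
#' Characters (variant or CNA presence columns) are first merged into groups
#' by identical carrier sample-set. Two groups are compatible exactly when
#' their carrier sets are nested or disjoint; a family that is pairwise
#' compatible is laminar and supports a perfect phylogeny in which every
#' character changes state once. Conflicts are resolved greedily: groups are
#' kept in order of descending size (number of characters, i.e. mutation
#' support), ties broken by lexicographically smallest sample set, and a
#' group conflicting with an already-kept group is excluded and reported
#' with its conflicting partners.
#'
#' @param matrix A `presence_matrix` (tiers are collapsed to binary
#'   presence).
#' @param samples Samples to use (default: all rows).
#' @return List with `groups` (kept, each a list with `set`, `characters`)
#'   and `conflicts` (excluded groups, each with `set`, `characters`,
#'   `conflicts_with` indices into `groups`).
#' @export
check_compatibility <- function(matrix, samples = rownames(matrix)) {
  if (length(samples) < 2) stop("need >= 2 samples")
  bin <- matrix[samples, , drop = FALSE] > 0
  carried <- colSums(bin) > 0
  sets <- apply(bin[, carried, drop = FALSE], 2, function(col)
    paste(sort(samples[col]), collapse = "\r"))
  by_set <- split(colnames(bin)[carried], sets)
  groups <- lapply(names(by_set), function(key) list(
    set = strsplit(key, "\r", fixed = TRUE)[[1]],
    characters = by_set[[key]]))
  sizes <- vapply(groups, function(g) length(g$characters), integer(1))
  keys <- vapply(groups, function(g) paste(g$set, collapse = ","),
                 character(1))
  ord <- order(-sizes, keys)
  groups <- groups[ord]
  kept <- list(); conflicts <- list()
  for (g in groups) {
    bad <- which(vapply(kept, function(k) !sets_compatible(g$set, k$set),
                        logical(1)))
    if (length(bad)) {
      g$conflicts_with <- bad
      conflicts[[length(conflicts) + 1L]] <- g
    } else {
      kept[[length(kept) + 1L]] <- g
    }
  }
  list(groups = kept, conflicts = conflicts)
}

sets_compatible <- function(a, b) {
  i <- length(intersect(a, b))
  i == 0 || i == length(a) || i == length(b)
}

#' Build the clonal tree of a laminar character family
#'
#' The tree is the Hasse diagram of the carrier sets ordered by inclusion,
#' rooted at the all-samples set (added if absent); each group's characters
#' attach to the edge entering its node, so truncal characters sit on the
#' root's edge. Samples attach as leaves under their minimal containing
#' set; samples with identical profiles become sibling leaves and are never
#' merged. CNA characters are handled identically to SNS characters.
#'
#' @param compat Output of [check_compatibility()] (or a list with a
#'   `groups` element forming a laminar family).
#' @param samples Character vector of all sample ids.
#' @return Object of class `phylo_tree`: `nodes` data.frame (id, parent,
#'   label, is_leaf), `sets` and `edge_characters` lists indexed by node id.
#' @export
build_tree <- function(compat, samples) {
  groups <- compat$groups
  for (i in seq_along(groups)) for (j in seq_len(i - 1L))
    if (!sets_compatible(groups[[i]]$set, groups[[j]]$set))
      stop("groups are not laminar; run check_compatibility first")
  sets <- lapply(groups, `[[`, "set")
  chars <- lapply(groups, `[[`, "characters")
  all_set <- sort(samples)
  keyof <- function(s) paste(sort(s), collapse = "\r")
  keys <- vapply(sets, keyof, character(1))
  if (!(keyof(all_set) %in% keys)) {
    sets <- c(list(all_set), sets)
    chars <- c(list(character(0)), chars)
    keys <- c(keyof(all_set), keys)
  } else {          # put root set first
    ri <- match(keyof(all_set), keys)
    ordr <- c(ri, setdiff(seq_along(sets), ri))
    sets <- sets[ordr]; chars <- chars[ordr]; keys <- keys[ordr]
  }
  n <- length(sets)
  sizes <- lengths(sets)
  parent <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    sup <- which(vapply(seq_len(n), function(j)
      j != i && all(sets[[i]] %in% sets[[j]]) &&
        (sizes[j] > sizes[i] ||
           (sizes[j] == sizes[i] && j < i)), logical(1)))
    if (length(sup)) parent[i] <- sup[which.min(sizes[sup])]
  }
  ids <- paste0("C", seq_len(n))
  nodes <- data.frame(id = ids,
                      parent = ifelse(is.na(parent), NA, ids[parent]),
                      label = NA_character_, is_leaf = FALSE,
                      stringsAsFactors = FALSE)
  edge_characters <- setNames(chars, ids)
  node_sets <- setNames(sets, ids)
  # attach each sample under its minimal containing set
  for (s in samples) {
    containing <- which(vapply(sets, function(x) s %in% x, logical(1)))
    mi <- containing[which.min(sizes[containing])]
    lid <- paste0("L_", s)
    nodes <- rbind(nodes, data.frame(id = lid, parent = ids[mi],
                                     label = s, is_leaf = TRUE,
                                     stringsAsFactors = FALSE))
    edge_characters[[lid]] <- character(0)
    node_sets[[lid]] <- s
  }
  structure(list(nodes = nodes, sets = node_sets,
                 edge_characters = edge_characters,
                 conflicts = compat$conflicts),
            class = "phylo_tree")
}

#' Children of each node / root helpers
#' @noRd
tree_children <- function(tree, id)
  tree$nodes$id[!is.na(tree$nodes$parent) & tree$nodes$parent == id]

tree_root <- function(tree) tree$nodes$id[is.na(tree$nodes$parent)]

#' Out-degree of the tree root (number of branches projecting from the trunk)
#' @param tree A `phylo_tree`.
#' @export
root_out_degree <- function(tree) length(tree_children(tree, tree_root(tree)))

#' Serialise / parse a clonal tree as Newick with edge character comments
#'
#' Character groups carried by the edge entering a node are written as a
#' bracketed `[id|id|...]` suffix on that node. Round-trips preserve
#' topology, leaf names, and edge characters.
#'
#' @param tree A `phylo_tree`.
#' @return `write_newick`: a single Newick string terminated by `;`.
#' @export
write_newick <- function(tree) {
  # children ordered by the smallest leaf label in their subtree, so the
  # serialisation is canonical and survives node-id relabelling on re-read
  min_leaf <- function(id) min(tree$sets[[id]])
  fmt <- function(id) {
    kids <- tree_children(tree, id)
    base <- if (!length(kids)) {
      lbl <- tree$nodes$label[tree$nodes$id == id]
      if (is.na(lbl)) "" else lbl
    } else {
      kids <- kids[order(vapply(kids, min_leaf, character(1)))]
      paste0("(", paste(vapply(kids, fmt, character(1)),
                        collapse = ","), ")")
    }
    ch <- tree$edge_characters[[id]]
    if (length(ch)) paste0(base, "[", paste(ch, collapse = "|"), "]")
    else base
  }
  paste0(fmt(tree_root(tree)), ";")
}

#' @rdname write_newick
#' @param text Newick string as produced by [write_newick()].
#' @return `read_newick`: a `phylo_tree` (sets are recomputed from leaf
#'   labels).
#' @export
read_newick <- function(text) {
  text <- trimws(text)
  if (!nchar(text) || substr(text, nchar(text), nchar(text)) != ";")
    stop("malformed newick: missing terminal ';'")
  s <- substr(text, 1, nchar(text) - 1L)
  pos <- 1L
  nodes <- data.frame(id = character(), parent = character(),
                      label = character(), is_leaf = logical(),
                      stringsAsFactors = FALSE)
  chars <- list()
  counter <- new.env(); counter$n <- 0L
  peek <- function() if (pos <= nchar(s)) substr(s, pos, pos) else ""
  parse_node <- function(parent) {
    counter$n <- counter$n + 1L
    id <- paste0("C", counter$n)
    label <- NA_character_; leaf <- TRUE
    if (peek() == "(") {
      leaf <- FALSE
      pos <<- pos + 1L
      repeat {
        parse_node(id)
        if (peek() == ",") { pos <<- pos + 1L; next }
        if (peek() == ")") { pos <<- pos + 1L; break }
        stop("malformed newick at position ", pos)
      }
    }
    # label (leaf name)
    start <- pos
    while (pos <= nchar(s) && !(peek() %in% c(",", ")", "[", "(")))
      pos <<- pos + 1L
    if (pos > start) label <- substr(s, start, pos - 1L)
    if (leaf && (is.na(label) || !nchar(label)))
      stop("malformed newick: unnamed leaf at position ", start)
    ch <- character(0)
    if (peek() == "[") {
      close <- regexpr("]", substr(s, pos, nchar(s)), fixed = TRUE)
      if (close < 0) stop("malformed newick: unclosed '[' at position ", pos)
      inner <- substr(s, pos + 1L, pos + close - 2L)
      if (nchar(inner)) ch <- strsplit(inner, "|", fixed = TRUE)[[1]]
      pos <<- pos + close
    }
    nodes <<- rbind(nodes, data.frame(
      id = id, parent = if (is.null(parent)) NA_character_ else parent,
      label = label, is_leaf = leaf, stringsAsFactors = FALSE))
    chars[[id]] <<- ch
    id
  }
  parse_node(NULL)
  if (pos <= nchar(s)) stop("malformed newick: trailing text at position ",
                            pos)
  tr <- structure(list(nodes = nodes, sets = NULL,
                       edge_characters = chars, conflicts = list()),
                  class = "phylo_tree")
  # recompute sets from leaf labels
  leafset <- function(id) {
    kids <- tree_children(tr, id)
    if (!length(kids)) tr$nodes$label[tr$nodes$id == id]
    else sort(unlist(lapply(kids, leafset)))
  }
  tr$sets <- setNames(lapply(tr$nodes$id, leafset), tr$nodes$id)
  tr
}

#' Clades (leaf label sets below each edge) of a tree
#'
#' Utility for topology comparison: returns the set of leaf-label subsets
#' subtended by each node, as sorted comma-joined strings.
#' @param tree A `phylo_tree`.
#' @export
tree_clades <- function(tree) {
  sets <- lapply(tree$nodes$id, function(id) {
    sub <- tree$sets[[id]]
    paste(sort(sub), collapse = ",")
  })
  sort(unique(unlist(sets)))
}
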
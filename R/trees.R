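# Internal unrooted-tree representation used by the parsimony engine.
#
# A "ut" tree is a list(ntip, edge) where `edge` is an m x 2 integer matrix
# of undirected edges; tips are nodes 1..ntip (indices into a canonical
# taxon vector), internal nodes have larger ids (not necessarily
# contiguous).  A binary unrooted tree over n tips has 2n - 3 edges.
# User-facing functions exchange ape "phylo" objects; the ut form exists
# because branch swapping mutates edge matrices millions of times.

ut_new3 <- function(tips3, internal_id) {
  list(ntip = NA_integer_,
       edge = cbind(tips3, rep(internal_id, 3L)))
}

ut_adjacency <- function(edge) {
  maxn <- max(edge)
  adj <- vector("list", maxn)
  for (k in seq_len(nrow(edge))) {
    a <- edge[k, 1L]; b <- edge[k, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# Postorder traversal rooted on the edge incident to `start` (a tip).
# Returns list(order = internal nodes in postorder, children = list keyed by
# node id, root = the internal node adjacent to `start`).
ut_rooted <- function(edge, start = 1L) {
  adj <- ut_adjacency(edge)
  root <- adj[[start]]
  if (length(root) != 1L) stop2("start node must be a tip")
  children <- vector("list", length(adj))
  order <- integer(0)
  # iterative DFS
  stack <- list(c(root, start))  # (node, parent)
  post <- integer(0)
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    v <- top[1L]; p <- top[2L]
    kids <- setdiff(adj[[v]], p)
    children[[v]] <- kids
    post <- c(post, v)
    for (k in kids) if (length(adj[[k]]) > 1L)
      stack[[length(stack) + 1L]] <- c(k, v)
  }
  # post currently preorder of internal nodes; reverse for postorder
  list(order = rev(post), children = children, root = root)
}

# Tip clusters below every internal edge, rooted away from tip `start`.
# Returns a list: keys (character split keys) and sets (integer vectors),
# one entry per nontrivial bipartition.
ut_splits <- function(edge, ntip, start = 1L) {
  ro <- ut_rooted(edge, start)
  maxn <- max(edge)
  clus <- vector("list", maxn)
  for (i in seq_len(ntip)) clus[[i]] <- i
  for (v in ro$order) {
    clus[[v]] <- sort(unlist(clus[ro$children[[v]]], use.names = FALSE))
  }
  sets <- list()
  for (v in ro$order) {
    for (k in ro$children[[v]]) {
      s <- clus[[k]]
      if (length(s) >= 2L && length(s) <= ntip - 2L)
        sets[[length(sets) + 1L]] <- s
    }
  }
  keys <- vapply(sets, paste, character(1), collapse = ",")
  list(keys = keys, sets = sets)
}

ut_signature <- function(edge, ntip) {
  paste(sort(ut_splits(edge, ntip)$keys), collapse = "|")
}

# Remove a tip's pendant edge leaving a valid smaller tree (used in tests).
ut_validate <- function(edge, ntip) {
  deg <- tabulate(edge, nbins = max(edge))
  if (any(deg[seq_len(ntip)] != 1L)) stop2("every tip must have degree 1")
  internal <- which(deg > 0)
  internal <- internal[internal > ntip]
  if (any(deg[internal] != 3L)) stop2("internal nodes must have degree 3")
  if (nrow(edge) != 2L * ntip - 3L) stop2("binary tree must have 2n-3 edges")
  invisible(TRUE)
}

# --- conversions -----------------------------------------------------------

ut_newick <- function(edge, ntip, labels, node_labels = NULL) {
  adj <- ut_adjacency(edge)
  lab <- function(v, p) {
    if (v <= ntip) return(labels[v])
    kids <- setdiff(adj[[v]], p)
    paste0("(", paste(vapply(kids, lab, character(1), p = v),
                      collapse = ","), ")")
  }
  root <- adj[[1L]]
  kids <- setdiff(adj[[root]], 1L)
  paste0("(", labels[1L], ",",
         paste(vapply(kids, lab, character(1), p = root), collapse = ","),
         ");")
}

ut_to_phylo <- function(tree, labels) {
  ape::read.tree(text = ut_newick(tree$edge, tree$ntip, labels))
}

phylo_to_ut <- function(phy, taxa) {
  if (!inherits(phy, "phylo")) stop2("expected a 'phylo' tree")
  if (!setequal(phy$tip.label, taxa))
    stop2("tree leaves do not match the taxon set; difference: ",
          paste(c(setdiff(phy$tip.label, taxa),
                  setdiff(taxa, phy$tip.label)), collapse = ", "))
  phy <- ape::unroot(phy)
  n <- length(taxa)
  map <- integer(max(phy$edge))
  map[seq_len(n)] <- match(phy$tip.label, taxa)
  internals <- sort(unique(phy$edge[phy$edge > n]))
  map[internals] <- n + seq_along(internals)
  edge <- cbind(map[phy$edge[, 1L]], map[phy$edge[, 2L]])
  list(ntip = n, edge = edge)
}

#' Nontrivial bipartitions of a tree
#'
#' Each internal edge of an unrooted tree splits the leaves in two; the
#' nontrivial splits (both sides of size >= 2) identify the topology.  The
#' splits are returned as a character vector of canonical keys (sorted
#' indices of the side not containing the first taxon in `taxa`, comma
#' separated), invariant under re-rooting.
#'
#' @param phy a `phylo` tree.
#' @param taxa canonical taxon ordering (default: sorted tip labels).
#' @return character vector of split keys.
#' @export
tree_bipartitions <- function(phy, taxa = sort(phy$tip.label)) {
  ut <- phylo_to_ut(phy, taxa)
  sort(ut_splits(ut$edge, ut$ntip)$keys)
}

#' Read and write Newick tree files
#'
#' Thin wrappers over the ape readers/writers that always return a list of
#' trees and preserve internal-node labels (used for support values).
#'
#' @param path file path.
#' @return `read_newick()`: a list of `phylo` trees.
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (inherits(tr, "phylo")) list(tr) else unclass(tr)
}

#' @rdname read_newick
#' @param trees a `phylo` or list of `phylo` trees.
#' @return `write_newick()`: `path`, invisibly.
#' @export
write_newick <- function(trees, path) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  writeLines(vapply(trees, ape::write.tree, character(1)), path)
  invisible(path)
}

# Build a (possibly multifurcating) phylo from compatible clusters.
# `clusters`: list of integer tip sets, none containing tip 1; optional
# `node_labels` (same length) annotate the corresponding internal nodes.
clusters_to_phylo <- function(clusters, ntip, labels, node_labels = NULL) {
  if (length(clusters)) {
    o <- order(-lengths(clusters))
    clusters <- clusters[o]
    if (!is.null(node_labels)) node_labels <- node_labels[o]
  }
  nc <- length(clusters)
  parent_of <- function(i) {
    s <- clusters[[i]]
    for (j in rev(seq_len(nc))) {  # smallest containing cluster
      if (j == i) next
      if (length(clusters[[j]]) > length(s) && all(s %in% clusters[[j]]))
        return(j)
    }
    0L
  }
  cl_parent <- if (nc) vapply(seq_len(nc), parent_of, integer(1)) else integer(0)
  tip_parent <- vapply(seq_len(ntip), function(t) {
    best <- 0L
    for (j in rev(seq_len(nc)))
      if (t %in% clusters[[j]]) { best <- j; break }
    best
  }, integer(1))
  build <- function(j) {  # newick of cluster node j (0 = root)
    tips <- which(tip_parent == j)
    subs <- which(cl_parent == j)
    if (j != 0L) subs <- setdiff(subs, j)
    parts <- c(labels[tips], vapply(subs, build, character(1)))
    lab <- if (j != 0L && !is.null(node_labels)) node_labels[j] else ""
    paste0("(", paste(parts, collapse = ","), ")", lab)
  }
  nwk <- paste0(build(0L), ";")
  ape::read.tree(text = nwk)
}

#' Generate a uniformly random unrooted binary tree
#'
#' Sequential addition: taxa are attached one at a time on a uniformly
#' chosen edge, which makes every labeled topology equally likely.
#'
#' @param n_taxa number of leaves (>= 3).
#' @param seed integer seed (optional; RNG state is restored).
#' @param labels tip labels (default `t1`, `t2`, ...).
#' @return a `phylo` tree.
#' @export
gen_random_tree <- function(n_taxa, seed = NULL,
                            labels = paste0("t", seq_len(n_taxa))) {
  if (!is_count(n_taxa) || n_taxa < 3L) stop2("need n_taxa >= 3")
  n_taxa <- as.integer(n_taxa)
  with_seed(seed, {
    edge <- cbind(1:3, rep(n_taxa + 1L, 3L))
    next_int <- n_taxa + 2L
    for (t in seq_len(n_taxa)[-(1:3)]) {
      e <- sample.int(nrow(edge), 1L)
      edge <- ut_insert_tip(edge, e, t, next_int)
      next_int <- next_int + 1L
    }
    ape::read.tree(text = ut_newick(edge, n_taxa, labels))
  })
}

# Subdivide edge `e` with new internal node `w` and attach tip/node `t`.
ut_insert_tip <- function(edge, e, t, w) {
  u <- edge[e, 1L]; v <- edge[e, 2L]
  rbind(edge[-e, , drop = FALSE],
        c(u, w), c(w, v), c(w, t))
}
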
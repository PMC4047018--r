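# Consensus trees, bootstrap proportions, Bremer decay, and
# unambiguous-synapomorphy mapping.

as_tree_list <- function(trees) {
  if (inherits(trees, "parsimony_search")) return(trees$trees)
  if (inherits(trees, "phylo")) return(list(trees))
  trees
}

# split keys and sets for every tree over a common taxon ordering
collect_splits <- function(trees, taxa) {
  lapply(trees, function(tr) {
    ut <- phylo_to_ut(tr, taxa)
    ut_splits(ut$edge, ut$ntip)
  })
}

common_taxa <- function(trees) {
  taxa <- sort(trees[[1L]]$tip.label)
  for (tr in trees[-1L])
    if (!setequal(tr$tip.label, taxa))
      stop2("trees are not over the same leaf set; difference: ",
            paste(c(setdiff(tr$tip.label, taxa),
                    setdiff(taxa, tr$tip.label)), collapse = ", "))
  taxa
}

#' Strict consensus tree
#'
#' The tree whose bipartitions are exactly those present in every input
#' tree; conflicts collapse into polytomies.
#'
#' @param trees a list of `phylo` trees (or a `"parsimony_search"`), all
#'   over the same leaf set.
#' @return a `phylo` tree (possibly multifurcating).
#' @export
strict_consensus <- function(trees) {
  trees <- as_tree_list(trees)
  if (!length(trees)) stop2("need at least one tree")
  taxa <- common_taxa(trees)
  sp <- collect_splits(trees, taxa)
  keys <- Reduce(intersect, lapply(sp, `[[`, "keys"))
  sets <- sp[[1L]]$sets[match(keys, sp[[1L]]$keys)]
  clusters_to_phylo(sets, length(taxa), taxa)
}

#' Majority-rule consensus tree
#'
#' Retains the bipartitions occurring in strictly more than
#' `threshold` of the trees (default 50%); the retained set is always
#' pairwise compatible for thresholds >= 0.5.  Internal nodes are labeled
#' with the percentage of trees containing their bipartition.
#'
#' @param trees list of `phylo` trees (or a `"parsimony_search"`).
#' @param threshold retention threshold in `[0.5, 1)`; a split is kept
#'   when its frequency is strictly greater.
#' @return a `phylo` tree with `node.label` frequencies (percent).
#' @export
majority_consensus <- function(trees, threshold = 0.5) {
  trees <- as_tree_list(trees)
  if (!length(trees)) stop2("need at least one tree")
  if (threshold < 0.5 || threshold >= 1)
    stop2("'threshold' must be in [0.5, 1)")
  taxa <- common_taxa(trees)
  sp <- collect_splits(trees, taxa)
  allkeys <- unlist(lapply(sp, `[[`, "keys"))
  counts <- table(allkeys)
  freq <- as.numeric(counts) / length(trees)
  keep <- freq > threshold
  keys <- names(counts)[keep]
  setmap <- list()
  for (s in sp)
    for (i in seq_along(s$keys))
      if (is.null(setmap[[s$keys[i]]])) setmap[[s$keys[i]]] <- s$sets[[i]]
  clusters_to_phylo(setmap[keys], length(taxa), taxa,
                    node_labels = sprintf("%.1f", 100 * freq[keep]))
}

#' Bootstrap support for bipartitions
#'
#' Each replicate resamples characters with replacement to the original
#' character count, runs a (reduced) heuristic search on the resampled
#' matrix, and contributes the bipartitions of the strict consensus of its
#' best trees.  Support is the plain percentage of replicates containing a
#' bipartition ("absolute frequencies").  Deterministic given `seed`.
#'
#' @param matrix a `"character_matrix"`.
#' @param replicates bootstrap replicates (>= 1).
#' @param seed integer seed.
#' @param config per-replicate search configuration (default: 5
#'   random-addition replicates, modest holds, strict MPT search).
#' @param min_support only report splits at or above this percentage
#'   (default 0: all observed splits).
#' @return an object of class `"support_annotations"`: data.frame with
#'   columns `split`, `clade`, `support`, plus provenance attributes.
#' @export
bootstrap_support <- function(matrix, replicates = 100L, seed = 1L,
                              config = search_config(replicates = 5L,
                                                     hold_per_replicate = 20L,
                                                     max_trees = 200L),
                              min_support = 0) {
  stopifnot(is_count(replicates))
  taxa <- sort(matrix$taxa)
  idx <- with_seed(seed, lapply(seq_len(replicates), function(i)
    sample.int(matrix$nchar, matrix$nchar, replace = TRUE)))
  counts <- new.env(parent = emptyenv())
  setmap <- list()
  failed <- 0L
  for (r in seq_len(replicates)) {
    cells <- matrix$cells[, idx[[r]], drop = FALSE]
    bm <- character_matrix(cells)
    res <- tryCatch({
      cfg <- config
      cfg$seed <- config$seed + r
      heuristic_search(bm, cfg)
    }, error = function(e) NULL)
    if (is.null(res) || !length(res$trees)) {
      failed <- failed + 1L
      warning("bootstrap replicate ", r, " failed; excluded", call. = FALSE)
      next
    }
    sp <- collect_splits(res$trees, taxa)
    keys <- Reduce(intersect, lapply(sp, `[[`, "keys"))
    for (k in keys) {
      counts[[k]] <- (counts[[k]] %||% 0L) + 1L
      if (is.null(setmap[[k]]))
        setmap[[k]] <- sp[[1L]]$sets[[match(k, sp[[1L]]$keys)]]
    }
  }
  denom <- replicates - failed
  if (denom < 1L) stop2("all bootstrap replicates failed")
  keys <- ls(counts)
  support <- vapply(keys, function(k) 100 * counts[[k]] / denom, numeric(1))
  keep <- support >= min_support
  out <- data.frame(
    split = keys[keep],
    clade = vapply(setmap[keys[keep]], function(s)
      paste(taxa[s], collapse = " "), character(1)),
    support = support[keep],
    stringsAsFactors = FALSE)
  out <- out[order(-out$support, out$split), ]
  rownames(out) <- NULL
  structure(out, class = c("support_annotations", "data.frame"),
            kind = "bootstrap", taxa = taxa,
            provenance = list(replicates = replicates, failed = failed,
                              seed = seed, config = config))
}

#' Bremer decay indices
#'
#' Sweeps TBR from the most-parsimonious trees accepting topologies up to
#' `k_max` steps beyond the best length, then reports for each bipartition
#' of the strict consensus of the MPTs the smallest extra-step bound at
#' which a collected tree lacking it exists.  Bipartitions still present
#' in every collected tree at `k_max` are reported as `> k_max` (coded
#' `Inf`).  Because the sweep may not enumerate every suboptimal tree, a
#' reported decay can only overestimate the true value; raise
#' `config$hold_per_replicate` to tighten it.
#'
#' @param matrix a `"character_matrix"`.
#' @param best a `"parsimony_search"` holding the MPT set.
#' @param k_max largest extra-step bound swept (>= 1).
#' @param config search configuration for the sweep (the suboptimal bound
#'   is set to `k_max` internally).
#' @return a `"support_annotations"` data.frame with columns `split`,
#'   `clade`, `decay`.
#' @export
bremer_decay <- function(matrix, best, k_max = 3L,
                         config = search_config(hold_per_replicate = 2000L,
                                                max_trees = 5000L)) {
  stopifnot(is_count(k_max), inherits(best, "parsimony_search"))
  enc <- encode_matrix(matrix)
  taxa <- sort(matrix$taxa)
  starts <- lapply(best$trees, function(tr) phylo_to_ut(tr, enc$taxa)$edge)
  sw <- tbr_sweep(starts, enc, hold = config$hold_per_replicate,
                  bound = k_max)
  L <- sw$best
  if (L < best$length)
    warning("suboptimal sweep found shorter trees than the supplied MPT set",
            call. = FALSE)
  # re-key splits against the sorted taxon ordering used for reporting
  canon <- function(ed) {
    sp <- ut_splits(ed, length(enc$taxa))
    vapply(sp$sets, function(s) {
      idx <- sort(match(enc$taxa[s], taxa))
      if (1L %in% idx) idx <- setdiff(seq_along(taxa), idx)
      paste(idx, collapse = ",")
    }, character(1))
  }
  # bipartitions of the strict consensus of the best trees in the sweep
  best_idx <- which(sw$lengths == L)
  spbest <- lapply(best_idx, function(i) canon(sw$edges[[i]]))
  keys <- Reduce(intersect, spbest)
  sets <- lapply(strsplit(keys, ","), as.integer)
  spall <- lapply(sw$edges, canon)
  decay <- vapply(keys, function(k) {
    lacking <- vapply(spall, function(kk) !(k %in% kk), logical(1))
    if (!any(lacking)) return(Inf)
    min(sw$lengths[lacking]) - L
  }, numeric(1))
  ord <- order(decay, keys, decreasing = c(TRUE, FALSE), method = "radix")
  out <- data.frame(
    split = keys,
    clade = vapply(sets, function(s) paste(taxa[s], collapse = " "),
                   character(1)),
    decay = decay, stringsAsFactors = FALSE)[ord, ]
  rownames(out) <- NULL
  structure(out, class = c("support_annotations", "data.frame"),
            kind = "bremer", taxa = taxa,
            provenance = list(k_max = k_max, config = config,
                              pooled_trees = length(sw$edges),
                              truncated = sw$truncated))
}

#' @export
print.support_annotations <- function(x, ...) {
  cat(attr(x, "kind") %||% "support", "annotations for",
      nrow(x), "bipartition(s)\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Annotate a consensus tree with per-bipartition support values
#'
#' Rebuilds the tree with internal-node labels taken from a
#' `"support_annotations"` table (bipartitions absent from the table get
#' empty labels), so supports survive a Newick round trip attached to the
#' same bipartitions.
#'
#' @param phy a `phylo` tree.
#' @param ann a `"support_annotations"` data.frame.
#' @param column which column to write (default the third: support/decay).
#' @return a `phylo` with `node.label`.
#' @export
annotate_support <- function(phy, ann, column = 3L) {
  taxa <- attr(ann, "taxa") %||% sort(phy$tip.label)
  ut <- phylo_to_ut(phy, taxa)
  sp <- ut_splits(ut$edge, ut$ntip)
  val <- ann[[column]][match(sp$keys, ann$split)]
  lab <- ifelse(is.na(val), "",
                ifelse(is.infinite(val), "Inf", format(val, trim = TRUE)))
  clusters_to_phylo(sp$sets, ut$ntip, taxa, node_labels = lab)
}

# --- unambiguous synapomorphies -------------------------------------------

#' Map unambiguous character changes onto a tree
#'
#' Roots the tree on the outgroup, computes for every character the
#' minimum-cost state reconstructions by dynamic programming (uniform
#' change cost, unordered states, set-valued tips), and reports the
#' branches on which the character changes in *every* most-parsimonious
#' reconstruction: a branch change is unambiguous precisely when forcing
#' the two ends of the branch to share a state costs extra steps.  Both
#' accelerated and delayed optimizations are special cases of that
#' criterion, so the reported changes are those present under both.
#'
#' @param tree a binary `phylo` over the matrix taxa.
#' @param matrix a `"character_matrix"`.
#' @param outgroup taxon name used to root the tree.
#' @return an object of class `"synapomorphy_map"`: data.frame with
#'   columns `clade` (tips below the branch), `character` (1-based index),
#'   `from`, `to` (state sets as strings).
#' @export
map_synapomorphies <- function(tree, matrix, outgroup) {
  enc <- encode_matrix(matrix)
  taxa <- enc$taxa
  og <- match(normalize_taxon(outgroup), taxa)
  if (is.na(og)) stop2("outgroup '", outgroup, "' not in the matrix")
  ut <- phylo_to_ut(tree, taxa)
  ut_validate(ut$edge, ut$ntip)
  ro <- ut_rooted(ut$edge, start = og)
  maxn <- max(ut$edge)
  ntip <- ut$ntip
  # tip clusters for branch naming
  clus <- vector("list", maxn)
  for (i in seq_len(ntip)) clus[[i]] <- i
  for (v in ro$order)
    clus[[v]] <- sort(unlist(clus[ro$children[[v]]], use.names = FALSE))
  # parent map (rooted away from outgroup)
  parent <- integer(maxn)
  parent[ro$root] <- og
  for (v in ro$order) for (k in ro$children[[v]]) parent[k] <- v
  preorder <- rev(ro$order)

  rows <- list()
  for (j in seq_len(matrix$nchar)) {
    syms <- matrix$universe[[j]]
    k <- length(syms)
    if (k < 2L) next
    bits <- enc$bit[syms]
    tipok <- function(node) bitwAnd(enc$masks[node, j], bits) != 0L
    down <- matrix(Inf, maxn, k)
    for (i in seq_len(ntip)) down[i, ] <- ifelse(tipok(i), 0, Inf)
    contrib <- function(v) pmin(down[v, ], min(down[v, ]) + 1)
    for (v in ro$order) {
      kids <- ro$children[[v]]
      down[v, ] <- contrib(kids[1L]) + contrib(kids[2L])
    }
    Lj <- min(down[ro$root, ] + contrib(og))
    up <- matrix(Inf, maxn, k)
    up[ro$root, ] <- down[og, ]          # outgroup tip is the root's parent
    for (v in preorder) {
      kids <- ro$children[[v]]
      upv <- pmin(up[v, ], min(up[v, ]) + 1)
      up[kids[1L], ] <- upv + contrib(kids[2L])
      up[kids[2L], ] <- upv + contrib(kids[1L])
    }
    # every branch (parent[v], v), v != root-of-outgroup-edge
    nodes <- c(seq_len(ntip)[-og], ro$order)
    for (v in nodes) {
      forced <- min(up[v, ] + down[v, ])
      if (forced <= Lj) next  # some MPR keeps the branch constant
      mpr <- function(node) syms[down[node, ] +
        pmin(up[node, ], min(up[node, ]) + 1) == Lj]
      par_mpr <- if (parent[v] == og)
        syms[down[og, ] +
               pmin(down[ro$root, ], min(down[ro$root, ]) + 1) == Lj]
      else mpr(parent[v])
      rows[[length(rows) + 1L]] <- data.frame(
        clade = paste(taxa[clus[[v]]], collapse = " "),
        character = j,
        from = paste(par_mpr, collapse = "/"),
        to = paste(mpr(v), collapse = "/"),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
    else data.frame(clade = character(0), character = integer(0),
                    from = character(0), to = character(0))
  out <- out[order(out$clade, out$character), ]
  rownames(out) <- NULL
  structure(out, class = c("synapomorphy_map", "data.frame"),
            outgroup = outgroup)
}

#' @export
print.synapomorphy_map <- function(x, ...) {
  cat("Unambiguous changes on", length(unique(x$clade)), "branch(es)\n")
  print.data.frame(x, ...)
  invisible(x)
}
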
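# Random-addition Wagner construction, TBR branch swapping, and the
# pooled heuristic search.

#' Search configuration
#'
#' Bundles the knobs of a heuristic parsimony search: the number of
#' random-addition replicates, the per-replicate cap on equally good trees
#' held during swapping, the global tree-memory cap, the RNG seed, and the
#' suboptimal bound (extra steps beyond the best length that a retained
#' tree may have; 0 for a strict MPT search).
#'
#' @param replicates random-addition sequences (>= 1).
#' @param hold_per_replicate trees held per replicate during TBR (>= 1).
#' @param max_trees global cap on pooled trees (>= 1).
#' @param seed integer seed recorded in every result.
#' @param suboptimal_bound accepted extra steps (>= 0).
#' @return a list of class `"search_config"`.
#' @export
search_config <- function(replicates = 10L, hold_per_replicate = 1000L,
                          max_trees = 10000L, seed = 1L,
                          suboptimal_bound = 0L) {
  stopifnot(is_count(replicates), is_count(hold_per_replicate),
            is_count(max_trees), length(seed) == 1L,
            is.numeric(suboptimal_bound), suboptimal_bound >= 0)
  structure(list(replicates = as.integer(replicates),
                 hold_per_replicate = as.integer(hold_per_replicate),
                 max_trees = as.integer(max_trees),
                 seed = as.integer(seed),
                 suboptimal_bound = as.numeric(suboptimal_bound)),
            class = "search_config")
}

fitch_total <- function(edge, enc) {
  sum(enc$weights * fitch_engine(edge, length(enc$taxa), enc$masks))
}

# Stepwise Wagner addition on the encoded matrix.  `order` is a
# permutation of tip indices; ties among equally good insertion edges are
# broken by a uniform draw from the current RNG stream.
wagner_ut <- function(enc, order) {
  ntip <- length(enc$taxa)
  stopifnot(length(order) == ntip, ntip >= 3L)
  edge <- cbind(order[1:3], rep(ntip + 1L, 3L))
  next_id <- ntip + 2L
  start <- order[1L]
  for (t in order[-(1:3)]) {
    lens <- vapply(seq_len(nrow(edge)), function(e) {
      cand <- ut_insert_tip(edge, e, t, next_id)
      sum(enc$weights * fitch_engine_from(cand, enc$masks, start))
    }, numeric(1))
    bestE <- which(lens == min(lens))
    e <- if (length(bestE) == 1L) bestE else
      bestE[sample.int(length(bestE), 1L)]
    edge <- ut_insert_tip(edge, e, t, next_id)
    next_id <- next_id + 1L
  }
  edge
}

# fitch_engine rooted at an arbitrary tip (partial trees during addition
# need not contain tip 1).
fitch_engine_from <- function(edge, masks, start) {
  ro <- ut_rooted(edge, start = start)
  maxn <- max(edge)
  nchr <- ncol(masks)
  M <- matrix(0L, maxn, nchr)
  tips <- unique(as.integer(edge))
  tips <- tips[tips <= nrow(masks)]
  M[tips, ] <- masks[tips, , drop = FALSE]
  steps <- integer(nchr)
  for (v in ro$order) {
    kids <- ro$children[[v]]
    a <- M[kids[1L], ]; b <- M[kids[2L], ]
    inter <- bitwAnd(a, b)
    zero <- inter == 0L
    steps <- steps + zero
    M[v, ] <- ifelse(zero, bitwOr(a, b), inter)
  }
  steps + (bitwAnd(M[ro$root, ], masks[start, ]) == 0L)
}

#' Random-addition Wagner tree
#'
#' Builds a binary tree by stepwise addition: taxa are inserted in a
#' random (seeded) order, each on the edge minimizing total Fitch length,
#' ties broken uniformly at random.
#'
#' @param matrix a `"character_matrix"` (>= 3 taxa).
#' @param seed integer seed (optional).
#' @param order optional explicit addition order (taxon indices).
#' @return list with `tree` (phylo) and `length`.
#' @export
wagner_addition <- function(matrix, seed = NULL, order = NULL) {
  enc <- encode_matrix(matrix)
  ntip <- length(enc$taxa)
  if (ntip < 3L) stop2("need at least 3 taxa")
  edge <- with_seed(seed, {
    o <- order %||% sample.int(ntip)
    wagner_ut(enc, o)
  })
  list(tree = ape::read.tree(text = ut_newick(edge, ntip, enc$taxa)),
       length = fitch_total(edge, enc))
}

# --- TBR moves -------------------------------------------------------------

# All tree-bisection-reconnection neighbors of a binary tree.  Every edge
# (internal and pendant) is bisected; pendant bisections yield the SPR
# moves of single leaves.
tbr_neighbors <- function(edge, ntip) {
  res <- list()
  m <- nrow(edge)
  for (e in seq_len(m)) {
    u <- edge[e, 1L]; v <- edge[e, 2L]
    rem <- edge[-e, , drop = FALSE]
    compU <- reach(rem, u)
    inU <- matrix(c(rem[, 1L] %in% compU, rem[, 2L] %in% compU), ncol = 2)
    rowsU <- inU[, 1L] & inU[, 2L]
    fragU <- rem[rowsU, , drop = FALSE]
    fragV <- rem[!rowsU, , drop = FALSE]
    su <- suppress_node(fragU, u)
    sv <- suppress_node(fragV, v)
    resU <- su$edges; resV <- sv$edges
    single_u <- nrow(resU) == 0L  # fragment is the lone node u
    single_v <- nrow(resV) == 0L
    if (single_u && single_v) next  # n = 2 fragment pair, cannot occur
    if (single_u || single_v) {
      tipnode <- if (single_u) u else v
      host <- if (single_u) resV else resU
      w <- if (single_u) sv$freed else su$freed
      for (b in seq_len(nrow(host))) {
        nb <- rbind(host[-b, , drop = FALSE],
                    c(host[b, 1L], w), c(w, host[b, 2L]), c(w, tipnode))
        res[[length(res) + 1L]] <- nb
      }
    } else {
      for (a in seq_len(nrow(resU))) {
        pa <- resU[a, ]
        baseU <- resU[-a, , drop = FALSE]
        for (b in seq_len(nrow(resV))) {
          pb <- resV[b, ]
          nb <- rbind(baseU,
                      c(pa[1L], u), c(u, pa[2L]),
                      resV[-b, , drop = FALSE],
                      c(pb[1L], v), c(v, pb[2L]),
                      c(u, v))
          res[[length(res) + 1L]] <- nb
        }
      }
    }
  }
  res
}

# nodes reachable from `s` over edge rows `rem`
reach <- function(rem, s) {
  comp <- s
  added <- s
  while (length(added)) {
    hit <- rem[, 1L] %in% added | rem[, 2L] %in% added
    nodes <- unique(as.integer(rem[hit, ]))
    added <- setdiff(nodes, comp)
    comp <- c(comp, added)
  }
  comp
}

# remove a now degree-2 node from a fragment, merging its incident edges
suppress_node <- function(frag, node) {
  hit <- which(frag[, 1L] == node | frag[, 2L] == node)
  if (length(hit) == 0L) return(list(edges = frag, freed = node))
  if (length(hit) != 2L) stop2("internal error: node degree ", length(hit))
  nbrs <- setdiff(as.integer(frag[hit, ]), node)
  list(edges = rbind(frag[-hit, , drop = FALSE], nbrs), freed = node)
}

# --- TBR hill-climbing with bounded tree holding ---------------------------

tbr_sweep <- function(start_edges, enc, hold, bound) {
  ntip <- length(enc$taxa)
  kept <- new.env(parent = emptyenv())
  lens <- new.env(parent = emptyenv())
  best <- Inf
  truncated <- FALSE
  queue <- character(0)
  add_tree <- function(edge, len) {
    sig <- ut_signature(edge, ntip)
    if (!is.null(kept[[sig]])) return(invisible(NULL))
    if (length(ls(kept)) >= hold) { truncated <<- TRUE; return(invisible(NULL)) }
    kept[[sig]] <- edge
    lens[[sig]] <- len
    queue <<- c(queue, sig)
    invisible(NULL)
  }
  prune <- function() {
    for (sig in ls(kept)) {
      if (lens[[sig]] > best + bound) { rm(list = sig, envir = kept); rm(list = sig, envir = lens) }
    }
  }
  for (st in start_edges) {
    len <- fitch_total(st, enc)
    if (len < best) { best <- len; prune() }
    if (len <= best + bound) add_tree(st, len)
  }
  while (length(queue)) {
    sig <- queue[1L]
    queue <- queue[-1L]
    cur <- kept[[sig]]
    if (is.null(cur)) next  # pruned meanwhile
    for (nb in tbr_neighbors(cur, ntip)) {
      len <- fitch_total(nb, enc)
      if (len > best + bound) next
      if (len < best) { best <- len; prune() }
      add_tree(nb, len)
    }
  }
  sigs <- ls(kept)
  keep <- sigs[vapply(sigs, function(s) lens[[s]] <= best + bound, logical(1))]
  list(edges = lapply(keep, function(s) kept[[s]]),
       lengths = vapply(keep, function(s) lens[[s]], numeric(1)),
       signatures = keep, best = best, truncated = truncated)
}

#' TBR branch swapping from a set of starting trees
#'
#' Repeatedly bisects every held tree on each edge and reconnects every
#' pair of branches of the two fragments, accepting topologies whose
#' length is within `suboptimal_bound` of the best length seen, until no
#' held tree yields a new acceptable topology.  Deterministic: the move
#' enumeration involves no randomness.
#'
#' @param start a `phylo`, a list of `phylo`, or a `"parsimony_search"`.
#' @param matrix a `"character_matrix"`.
#' @param config a [search_config()]; `hold_per_replicate` caps the trees
#'   held during the sweep.
#' @return a `"parsimony_search"` object.
#' @export
tbr_search <- function(start, matrix, config = search_config()) {
  enc <- encode_matrix(matrix)
  trees <- if (inherits(start, "parsimony_search")) start$trees
           else if (inherits(start, "phylo")) list(start) else start
  starts <- lapply(trees, function(tr) {
    ut <- phylo_to_ut(tr, enc$taxa)
    ut_validate(ut$edge, ut$ntip)
    ut$edge
  })
  sw <- tbr_sweep(starts, enc, hold = config$hold_per_replicate,
                  bound = config$suboptimal_bound)
  make_search_result(sw$edges, sw$lengths, sw$signatures, sw$best, enc,
                     config, truncated = sw$truncated, replicates_run = 0L)
}

make_search_result <- function(edges, lengths, signatures, best, enc,
                               config, truncated, replicates_run) {
  ntip <- length(enc$taxa)
  phylos <- lapply(edges, function(ed)
    ape::read.tree(text = ut_newick(ed, ntip, enc$taxa)))
  per_char <- if (length(edges))
    as.integer(fitch_engine(edges[[1L]], ntip, enc$masks)) else integer(0)
  structure(list(trees = phylos, lengths = lengths,
                 signatures = signatures, length = best,
                 per_char_steps = per_char, taxa = enc$taxa,
                 config = config, truncated = truncated,
                 replicates_run = replicates_run),
            class = "parsimony_search")
}

#' Heuristic maximum-parsimony search
#'
#' Runs `replicates` random-addition Wagner builds, each followed by TBR
#' branch swapping, and pools the distinct best topologies across
#' replicates (up to `max_trees`).  Fully deterministic given the seed:
#' replicate `r` uses RNG stream `seed + r`.
#'
#' @param matrix a `"character_matrix"`.
#' @param config a [search_config()].
#' @return an object of class `"parsimony_search"`: list with `trees`
#'   (phylo list), `length` (best steps), `per_char_steps`, `signatures`,
#'   `config`, `truncated`, `replicates_run`.
#' @export
heuristic_search <- function(matrix, config = search_config()) {
  enc <- encode_matrix(matrix)
  ntip <- length(enc$taxa)
  if (ntip < 3L) stop2("need at least 3 taxa")
  bound <- config$suboptimal_bound
  pool <- new.env(parent = emptyenv())
  pool_len <- new.env(parent = emptyenv())
  best <- Inf
  truncated <- FALSE
  for (r in seq_len(config$replicates)) {
    start <- with_seed(config$seed + r, wagner_ut(enc, sample.int(ntip)))
    sw <- tbr_sweep(list(start), enc, hold = config$hold_per_replicate,
                    bound = bound)
    truncated <- truncated || sw$truncated
    if (sw$best < best) {
      best <- sw$best
      for (s in ls(pool)) if (pool_len[[s]] > best + bound) {
        rm(list = s, envir = pool); rm(list = s, envir = pool_len)
      }
    }
    for (i in seq_along(sw$signatures)) {
      if (sw$lengths[i] > best + bound) next
      s <- sw$signatures[i]
      if (!is.null(pool[[s]])) next
      if (length(ls(pool)) >= config$max_trees) {
        truncated <- TRUE
        warning("max_trees = ", config$max_trees,
                " reached; tree set truncated", call. = FALSE)
        break
      }
      pool[[s]] <- sw$edges[[i]]
      pool_len[[s]] <- sw$lengths[i]
    }
  }
  sigs <- ls(pool)
  make_search_result(lapply(sigs, function(s) pool[[s]]),
                     vapply(sigs, function(s) pool_len[[s]], numeric(1)),
                     sigs, best, enc, config,
                     truncated = truncated,
                     replicates_run = config$replicates)
}

#' @export
print.parsimony_search <- function(x, ...) {
  cat(sprintf("Parsimony search: %d tree(s) of length %g (%d taxa)\n",
              length(x$trees), x$length, length(x$taxa)))
  cat(sprintf("  replicates %d, hold %d, max_trees %d, bound %g, seed %d%s\n",
              x$replicates_run, x$config$hold_per_replicate,
              x$config$max_trees, x$config$suboptimal_bound,
              x$config$seed,
              if (isTRUE(x$truncated)) " [truncated]" else ""))
  invisible(x)
}

#' @export
summary.parsimony_search <- function(object, ...) {
  cat(sprintf("best length %g; %d distinct topologies\n",
              object$length, length(object$trees)))
  cat("per-character steps: total", sum(object$per_char_steps), "\n")
  invisible(object)
}
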
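# Independent oracles used across the suite.  These deliberately take
# different algorithmic routes than the package internals: uniform-cost
# Sankoff dynamic programming for tree length, exhaustive topology
# enumeration for optima and step bounds, and brute-force enumeration of
# minimum-cost reconstructions for synapomorphy checks.

# --- exhaustive topology enumeration --------------------------------------

.topo_cache <- new.env(parent = emptyenv())

# all unrooted binary topologies over tips 1..n as edge matrices
# (internal ids n+1 .. 2n-2)
all_topologies <- function(n) {
  key <- as.character(n)
  if (!is.null(.topo_cache[[key]])) return(.topo_cache[[key]])
  trees <- list(cbind(1:3, rep(n + 1L, 3L)))
  for (t in seq_len(n)[-(1:3)]) {
    w <- n + t - 2L
    trees <- unlist(lapply(trees, function(ed)
      lapply(seq_len(nrow(ed)), function(e)
        rbind(ed[-e, , drop = FALSE],
              c(ed[e, 1L], w), c(w, ed[e, 2L]), c(w, t)))),
      recursive = FALSE)
  }
  .topo_cache[[key]] <- trees
  trees
}

# rooted traversal schedules for every topology of size n (computed once)
.ro_cache <- new.env(parent = emptyenv())
all_topology_schedules <- function(n) {
  key <- as.character(n)
  if (!is.null(.ro_cache[[key]])) return(.ro_cache[[key]])
  out <- lapply(all_topologies(n), topo_schedule, n = n)
  .ro_cache[[key]] <- out
  out
}

# postorder schedule rooted at tip 1 (independent re-derivation)
topo_schedule <- function(edge, n) {
  maxn <- max(edge)
  adj <- vector("list", maxn)
  for (k in seq_len(nrow(edge))) {
    a <- edge[k, 1L]; b <- edge[k, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  root <- adj[[1L]]
  ord <- integer(0)
  kids <- vector("list", maxn)
  walk <- function(v, p) {
    ch <- setdiff(adj[[v]], p)
    kids[[v]] <<- ch
    for (k in ch) if (k > n) walk(k, v)
    ord <<- c(ord, v)
  }
  walk(root, 1L)
  list(order = ord, children = kids, root = root)
}

# --- uniform-cost Sankoff oracle ------------------------------------------

# cells: character matrix of state strings ('?' missing), rows = taxa in
# tip order 1..n.  Returns total length (and per-character steps) on the
# topology given by a schedule.
sankoff_steps <- function(sched, cells, n) {
  nchr <- ncol(cells)
  steps <- numeric(nchr)
  for (j in seq_len(nchr)) {
    obs <- sort(unique(unlist(strsplit(cells[cells[, j] != "?", j], ""))))
    if (length(obs) < 2L) next
    k <- length(obs)
    tipcost <- function(i) {
      s <- cells[i, j]
      if (s == "?") rep(0, k)
      else ifelse(obs %in% strsplit(s, "")[[1L]], 0, Inf)
    }
    down <- matrix(Inf, max(sched$order), k)
    for (i in seq_len(n)) down[i, ] <- tipcost(i)
    for (v in sched$order) {
      acc <- rep(0, k)
      for (c in sched$children[[v]]) {
        dc <- down[c, ]
        acc <- acc + pmin(dc, min(dc) + 1)
      }
      down[v, ] <- acc
    }
    t1 <- tipcost(1L)
    steps[j] <- min(down[sched$root, ] + pmin(t1, min(t1) + 1))
  }
  steps
}

sankoff_length <- function(cm, edge = NULL, sched = NULL) {
  n <- length(cm$taxa)
  if (is.null(sched)) sched <- topo_schedule(edge, n)
  sum(sankoff_steps(sched, cm$cells, n))
}

# exhaustive minimum/maximum length over every topology
exhaustive_lengths <- function(cm) {
  n <- length(cm$taxa)
  scheds <- all_topology_schedules(n)
  vapply(scheds, function(s) sum(sankoff_steps(s, cm$cells, n)), numeric(1))
}

# --- random matrix generator for oracle suites ----------------------------

random_cells <- function(ntaxa, nchar, k = 2L, p_missing = 0,
                         p_poly = 0) {
  cells <- matrix("", ntaxa, nchar)
  for (j in seq_len(nchar)) {
    for (i in seq_len(ntaxa)) {
      r <- runif(1)
      cells[i, j] <- if (r < p_missing) "?"
        else if (r < p_missing + p_poly)
          paste(sort(sample(0:(k - 1L), 2L)), collapse = "")
        else as.character(sample(0:(k - 1L), 1L))
    }
  }
  rownames(cells) <- sprintf("t%02d", seq_len(ntaxa))
  cells
}

# --- brute-force minimum reconstructions (for synapomorphy checks) --------

# enumerate every minimum-cost assignment of states to internal nodes of a
# schedule; returns list(assignments = matrix(nodes x reconstructions),
# cost).  Small instances only.
all_min_reconstructions <- function(sched, cells, j, n) {
  obs <- sort(unique(unlist(strsplit(cells[cells[, j] != "?", j], ""))))
  if (length(obs) < 2L) return(NULL)
  internal <- sched$order
  k <- length(obs)
  tipstate <- function(i) {
    s <- cells[i, j]
    if (s == "?") obs else intersect(strsplit(s, "")[[1L]], obs)
  }
  grids <- rep(list(obs), length(internal))
  combos <- expand.grid(grids, stringsAsFactors = FALSE)
  # cost of a full assignment: sum over edges of mismatch, minimized over
  # tip-set resolutions
  edge_cost <- function(assign_named) {
    cost <- 0
    for (v in internal) {
      for (c in sched$children[[v]]) {
        sv <- assign_named[[as.character(v)]]
        if (c <= n) {
          ts <- tipstate(c)
          cost <- cost + (!(sv %in% ts))
        } else {
          cost <- cost + (sv != assign_named[[as.character(c)]])
        }
      }
    }
    # root edge to tip 1
    ts <- tipstate(1L)
    cost + (!(assign_named[[as.character(sched$root)]] %in% ts))
  }
  costs <- apply(combos, 1L, function(row) {
    edge_cost(as.list(stats::setNames(row, as.character(internal))))
  })
  best <- min(costs)
  list(assignments = combos[costs == best, , drop = FALSE],
       nodes = internal, cost = best, states = obs)
}

# --- misc ------------------------------------------------------------------

make_cm <- function(cells) character_matrix(cells)

tiny_tree <- function(nwk) ape::read.tree(text = nwk)

expect_same_splits <- function(a, b) {
  taxa <- sort(a$tip.label)
  expect_setequal(tree_bipartitions(a, taxa), tree_bipartitions(b, taxa))
}

# --- fast mask-based scoring used only to make exhaustive enumeration
#     affordable (independent re-implementation of the pass; the scoring
#     rule itself is separately validated against Sankoff) ---------------

encode_cells_masks <- function(cells) {
  syms <- sort(unique(unlist(strsplit(cells[cells != "?"], ""))))
  bit <- stats::setNames(bitwShiftL(1L, seq_along(syms) - 1L), syms)
  full <- sum(bit)
  m <- matrix(0L, nrow(cells), ncol(cells))
  for (i in seq_len(nrow(cells))) for (j in seq_len(ncol(cells))) {
    s <- cells[i, j]
    m[i, j] <- if (s == "?") as.integer(full)
      else sum(bit[strsplit(s, "")[[1]]])
  }
  m
}

fast_pass_length <- function(sched, masks) {
  maxn <- max(sched$order)
  nchr <- ncol(masks)
  M <- matrix(0L, maxn, nchr)
  M[seq_len(nrow(masks)), ] <- masks
  steps <- 0L
  for (v in sched$order) {
    kids <- sched$children[[v]]
    a <- M[kids[1], ]; b <- M[kids[2], ]
    inter <- bitwAnd(a, b)
    z <- inter == 0L
    steps <- steps + sum(z)
    M[v, ] <- ifelse(z, bitwOr(a, b), inter)
  }
  steps + sum(bitwAnd(M[sched$root, ], masks[1, ]) == 0L)
}

exhaustive_best_fast <- function(cells, n) {
  masks <- encode_cells_masks(cells)
  scheds <- all_topology_schedules(n)
  best <- Inf
  for (s in scheds) {
    L <- fast_pass_length(s, masks)
    if (L < best) best <- L
  }
  best
}
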
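# Fitch scoring, per-character step bounds, and homoplasy indices.

# Core Fitch pass on the internal tree form: state sets are integer
# bitmasks, vectorized across characters.  The tree is rooted on the
# pendant edge of tip 1; the score of unordered characters is invariant
# under that choice.
fitch_engine <- function(edge, ntip, masks) {
  ro <- ut_rooted(edge, start = 1L)
  maxn <- max(edge)
  nchr <- ncol(masks)
  M <- matrix(0L, maxn, nchr)
  M[seq_len(ntip), ] <- masks
  steps <- integer(nchr)
  for (v in ro$order) {
    kids <- ro$children[[v]]
    if (length(kids) != 2L)
      stop2("tree must be binary for Fitch scoring")
    a <- M[kids[1L], ]
    b <- M[kids[2L], ]
    inter <- bitwAnd(a, b)
    zero <- inter == 0L
    steps <- steps + zero
    M[v, ] <- ifelse(zero, bitwOr(a, b), inter)
  }
  final <- bitwAnd(M[ro$root, ], masks[1L, ])
  steps + (final == 0L)
}

#' Fitch parsimony length of a tree
#'
#' Counts the minimum number of state changes each unordered character
#' requires on a binary tree, treating missing cells as "any state" and
#' polymorphic cells as their state set, and sums them (weighted).  The
#' length is invariant under re-rooting and leaf-order permutation.
#'
#' @param tree a `phylo` tree whose tip labels equal the matrix taxa.
#' @param matrix a `"character_matrix"`.
#' @return list with `length` (total weighted steps) and `steps`
#'   (per-character integer vector).
#' @export
fitch_length <- function(tree, matrix) {
  enc <- encode_matrix(matrix)
  ut <- phylo_to_ut(tree, enc$taxa)
  ut_validate(ut$edge, ut$ntip)
  steps <- fitch_engine(ut$edge, ut$ntip, enc$masks)
  list(length = sum(enc$weights * steps), steps = as.integer(steps))
}

# --- per-character step bounds --------------------------------------------

# min steps over all trees for one character: (size of the smallest state
# set intersecting every non-missing cell) - 1.  Cells are bitmasks; the
# missing mask (full universe) intersects everything and is ignored.
min_steps_mask <- function(cellmasks, full) {
  cells <- unique(cellmasks[cellmasks != full])
  if (!length(cells)) return(0L)
  states <- which(bitwAnd(full, bitwShiftL(1L, 0:30)) != 0L) - 1L
  if (length(states) < 2L) return(0L)
  for (size in seq_along(states)) {
    combs <- utils::combn(states, size)
    for (j in seq_len(ncol(combs))) {
      cover <- sum(bitwShiftL(1L, combs[, j]))
      if (all(bitwAnd(cells, cover) != 0L)) return(size - 1L)
    }
  }
  length(states) - 1L
}

# max steps over all trees: n_eff - the largest number of cells that can
# share one state (set-valued cells adopt the globally best state).
max_steps_mask <- function(cellmasks, full) {
  cells <- cellmasks[cellmasks != full]
  if (!length(cells)) return(0L)
  best <- 0L
  for (s in 0:30) {
    b <- bitwShiftL(1L, s)
    if (bitwAnd(full, b) == 0L) next
    best <- max(best, sum(bitwAnd(cells, b) != 0L))
  }
  length(cells) - best
}

#' Minimum and maximum possible steps per character
#'
#' `min_steps()` is the smallest number of changes any tree can achieve
#' for each character (the denominator structure of the consistency
#' index); `max_steps()` is the largest number any tree can force (the
#' structure behind the retention index).  Both treat missing cells as
#' unconstrained and polymorphic cells as free to adopt any of their
#' states.
#'
#' @param matrix a `"character_matrix"`.
#' @return integer vector, one entry per character.
#' @export
min_steps <- function(matrix) {
  enc <- encode_matrix(matrix)
  vapply(seq_len(ncol(enc$masks)), function(j) {
    full <- full_mask(matrix, enc, j)
    min_steps_mask(enc$masks[, j], full)
  }, integer(1))
}

#' @rdname min_steps
#' @export
max_steps <- function(matrix) {
  enc <- encode_matrix(matrix)
  vapply(seq_len(ncol(enc$masks)), function(j) {
    full <- full_mask(matrix, enc, j)
    max_steps_mask(enc$masks[, j], full)
  }, integer(1))
}

full_mask <- function(matrix, enc, j) {
  as.integer(sum(enc$bit[matrix$universe[[j]]]))
}

#' Ensemble consistency and retention indices
#'
#' `CI = sum(m_i) / L` and `RI = (sum(g_i) - L) / (sum(g_i) - sum(m_i))`,
#' where `m_i`/`g_i` are the per-character minimum and maximum steps and
#' `L` the realized tree length.  All characters are included by default;
#' `exclude_uninformative` drops characters that cannot show homoplasy on
#' any tree (`g_i == m_i`) from both indices.
#'
#' @param matrix a `"character_matrix"`.
#' @param L realized (best) tree length for this matrix.
#' @param exclude_uninformative drop characters with `g_i == m_i`.
#' @return list with `CI`, `RI` (NA when undefined), `sum_min`, `sum_max`.
#' @export
ci_ri <- function(matrix, L, exclude_uninformative = FALSE) {
  m <- min_steps(matrix)
  g <- max_steps(matrix)
  if (exclude_uninformative) {
    keep <- g > m
    L <- L - sum(m[!keep])  # uninformative characters realize m_i steps
    m <- m[keep]; g <- g[keep]
  }
  sm <- sum(m); sg <- sum(g)
  if (L < sm) stop2("L = ", L, " below the minimum possible ", sm)
  CI <- if (L == 0) NA_real_ else sm / L
  RI <- if (sg == sm) NA_real_ else (sg - L) / (sg - sm)
  list(CI = CI, RI = RI, sum_min = sm, sum_max = sg)
}
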
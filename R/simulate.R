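# Seeded generators emulating the two kinds of input the pipeline
# consumes: two-group continuous measurement attributes, and discrete
# characters evolved on a known tree with fossil-like missingness.

#' Simulation settings for two-group measurement attributes
#'
#' Defaults emulate a well-behaved ratio attribute of the scapular-neck
#' kind: about twenty measured species per side of the
#' basal-hadrosauroid/hadrosaurid split, species means five pooled
#' standard deviations apart (cleanly detached intervals), and one to
#' three measured specimens per species with small within-species
#' measurement scatter.
#'
#' @param attributes character vector of attribute ids.
#' @param mean_basal,mean_hadrosaurid per-attribute side means (recycled).
#' @param sd per-attribute between-taxon standard deviation (recycled).
#' @param n_basal,n_hadrosaurid taxa per side (>= 2).
#' @param specimens_min,specimens_max per-taxon specimen count range.
#' @param specimen_sd within-taxon (between-specimen) measurement sd.
#' @param seed integer seed.
#' @return a list of class `"measurement_sim_spec"`.
#' @export
measurement_sim_spec <- function(attributes = "MA1",
                                 mean_basal = 0.48, mean_hadrosaurid = 0.68,
                                 sd = 0.04,
                                 n_basal = 20L, n_hadrosaurid = 20L,
                                 specimens_min = 1L, specimens_max = 3L,
                                 specimen_sd = 0.01, seed = 1L) {
  stopifnot(n_basal >= 2L, n_hadrosaurid >= 2L, all(sd > 0),
            specimens_min >= 1L, specimens_max >= specimens_min)
  structure(list(attributes = attributes,
                 mean_basal = rep_len(mean_basal, length(attributes)),
                 mean_hadrosaurid = rep_len(mean_hadrosaurid,
                                            length(attributes)),
                 sd = rep_len(sd, length(attributes)),
                 n_basal = as.integer(n_basal),
                 n_hadrosaurid = as.integer(n_hadrosaurid),
                 specimens_min = as.integer(specimens_min),
                 specimens_max = as.integer(specimens_max),
                 specimen_sd = specimen_sd, seed = as.integer(seed)),
            class = "measurement_sim_spec")
}

#' Generate two-group Gaussian measurement data
#'
#' Draws a true per-taxon value from its side's Gaussian for each
#' attribute, then per-specimen observations around the true value, and
#' returns the long-form table together with group labels and the
#' generating truth (side and true value per taxon).
#'
#' @param spec a [measurement_sim_spec()].
#' @return list with `table` (a `"measurement_table"`), `labels` (named
#'   group vector: a few basal iguanodontians, the rest basal
#'   hadrosauroids on the basal side; hadrosaurines/lambeosaurines split
#'   the other side), and `truth` (data.frame).
#' @export
gen_two_group_measurements <- function(spec = measurement_sim_spec()) {
  stopifnot(inherits(spec, "measurement_sim_spec"))
  if (spec$specimens_min < 1L) stop2("at least one specimen per taxon")
  nb <- spec$n_basal; nh <- spec$n_hadrosaurid
  taxa <- c(sprintf("basal_%02d", seq_len(nb)),
            sprintf("derived_%02d", seq_len(nh)))
  side <- rep(c("basal", "hadrosaurid"), c(nb, nh))
  group <- c(rep(c("basal_iguanodontian", "basal_hadrosauroid"),
                 c(min(3L, nb - 1L), nb - min(3L, nb - 1L))),
             rep(c("hadrosaurine", "lambeosaurine"),
                 c(ceiling(nh / 2), floor(nh / 2))))
  with_seed(spec$seed, {
    rows <- list()
    truth <- list()
    for (a in seq_along(spec$attributes)) {
      mu <- ifelse(side == "basal", spec$mean_basal[a],
                   spec$mean_hadrosaurid[a])
      true_val <- stats::rnorm(length(taxa), mu, spec$sd[a])
      nspec <- sample(spec$specimens_min:spec$specimens_max,
                      length(taxa), replace = TRUE)
      for (i in seq_along(taxa)) {
        obs <- stats::rnorm(nspec[i], true_val[i], spec$specimen_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          taxon = taxa[i], attribute = spec$attributes[a],
          specimen = sprintf("S%02d", seq_len(nspec[i])),
          value = obs, stringsAsFactors = FALSE)
      }
      truth[[a]] <- data.frame(taxon = taxa, attribute = spec$attributes[a],
                               side = side, true_value = true_val,
                               stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, rows)
    list(table = measurement_table(df$taxon, df$attribute, df$specimen,
                                   df$value),
         labels = stats::setNames(group, taxa),
         truth = do.call(rbind, truth))
  })
}

#' Simulation settings for discrete character matrices
#'
#' Defaults loosely follow the shape of a morphological hadrosauroid
#' matrix scaled to test size: 16 taxa, 100 unordered characters with 2-4
#' states, a low per-edge change probability, and 30% missing cells
#' (fossil taxa are incomplete).
#'
#' @param n_taxa,n_char matrix dimensions.
#' @param states_min,states_max per-character state-count range (2-6).
#' @param p_change per-edge probability of a state change in `[0, 1)`.
#' @param missing_frac fraction of cells masked as missing in `[0, 1)`.
#' @param block_missing if TRUE, missingness is applied in per-taxon
#'   character blocks (whole anatomical regions absent, as in incomplete
#'   specimens) instead of independently per cell.
#' @param seed integer seed.
#' @return list of class `"character_sim_spec"`.
#' @export
character_sim_spec <- function(n_taxa = 16L, n_char = 100L,
                               states_min = 2L, states_max = 4L,
                               p_change = 0.1, missing_frac = 0.3,
                               block_missing = FALSE, seed = 1L) {
  stopifnot(n_taxa >= 4L, n_char >= 1L, states_min >= 2L,
            states_max <= 6L, states_max >= states_min,
            p_change >= 0, p_change < 1,
            missing_frac >= 0, missing_frac < 1)
  structure(list(n_taxa = as.integer(n_taxa), n_char = as.integer(n_char),
                 states_min = as.integer(states_min),
                 states_max = as.integer(states_max),
                 p_change = p_change, missing_frac = missing_frac,
                 block_missing = isTRUE(block_missing),
                 seed = as.integer(seed)),
            class = "character_sim_spec")
}

#' Evolve discrete characters on a tree
#'
#' Roots the tree arbitrarily, draws a uniform root state per character,
#' and changes state along each edge with the specified probability (to a
#' uniformly chosen different state).  A missingness mask is then applied.
#' The generating tree and per-character change counts are attached as
#' attribute `"truth"`.
#'
#' @param tree a `phylo` tree whose tips become the taxa.
#' @param spec a [character_sim_spec()] (its `n_taxa` is ignored in favor
#'   of the tree).
#' @return a `"character_matrix"`.
#' @export
evolve_characters <- function(tree, spec = character_sim_spec()) {
  stopifnot(inherits(spec, "character_sim_spec"))
  taxa <- tree$tip.label
  ntip <- length(taxa)
  ut <- phylo_to_ut(tree, taxa)
  ro <- ut_rooted(ut$edge, start = 1L)
  with_seed(spec$seed, {
    nstates <- sample(spec$states_min:spec$states_max, spec$n_char,
                      replace = TRUE)
    maxn <- max(ut$edge)
    state <- matrix(0L, maxn, spec$n_char)
    changes <- integer(spec$n_char)
    root_state <- vapply(nstates, function(k) sample.int(k, 1L) - 1L,
                         integer(1))
    state[ro$root, ] <- root_state
    evolve_edge <- function(from_states) {
      flip <- stats::runif(spec$n_char) < spec$p_change
      new <- from_states
      if (any(flip)) {
        for (j in which(flip)) {
          others <- setdiff(0:(nstates[j] - 1L), from_states[j])
          new[j] <- if (length(others) == 1L) others else sample(others, 1L)
        }
        changes <<- changes + flip
      }
      new
    }
    # preorder walk from the root (tip 1 hangs off the root edge)
    for (v in rev(ro$order)) {
      for (k in ro$children[[v]]) state[k, ] <- evolve_edge(state[v, ])
    }
    state[1L, ] <- evolve_edge(state[ro$root, ])
    cells <- matrix(as.character(state[seq_len(ntip), , drop = FALSE]),
                    ntip, spec$n_char)
    if (spec$missing_frac > 0) {
      if (spec$block_missing) {
        nblocks <- 5L
        bounds <- floor(seq(0L, spec$n_char, length.out = nblocks + 1L))
        for (i in seq_len(ntip)) for (b in seq_len(nblocks)) {
          if (stats::runif(1) < spec$missing_frac && bounds[b + 1L] > bounds[b])
            cells[i, (bounds[b] + 1L):bounds[b + 1L]] <- "?"
        }
      } else {
        mask <- matrix(stats::runif(ntip * spec$n_char) < spec$missing_frac,
                       ntip, spec$n_char)
        cells[mask] <- "?"
      }
    }
    rownames(cells) <- taxa
    out <- character_matrix(cells)
    attr(out, "truth") <- list(tree = tree, changes = changes,
                               n_states = nstates, spec = spec)
    out
  })
}

#' Printed interval standards and focal values for the six diagnostic
#' measurement attributes
#'
#' Returns the published decision standards for the six measurement
#' attributes used to evaluate the focal taxon *Zhanghenglong
#' yangchengensis*, exactly as printed: per-side component intervals, the
#' printed boundary value, and the focal taxon's measured values
#' (ratios dimensionless, angles in degrees).  MA1's hadrosaurid side is
#' the merged pair of adjacent components; MA3 and MA5 have reversed
#' polarity (the basal side holds the high values).
#'
#' @return list with `standards` (named list of
#'   [`attribute_standard`] objects) and `values` (named numeric vector of
#'   the focal taxon's measurements).
#' @export
published_standards <- function() {
  std <- list(
    MA1 = attribute_standard("MA1", basal_intervals = c(0.26, 0.33),
                             hadrosaurid_intervals = c(0.36, 0.57),
                             boundary = 0.35),
    MA2 = attribute_standard("MA2", basal_intervals = c(0.20, 0.33),
                             hadrosaurid_intervals = c(0.38, 0.49),
                             boundary = 0.35),
    MA3 = attribute_standard("MA3", basal_intervals = c(13, 31),
                             hadrosaurid_intervals = c(0, 9),
                             boundary = 10),
    MA4 = attribute_standard("MA4", basal_intervals = c(0.10, 0.18),
                             hadrosaurid_intervals = c(0.21, 0.60),
                             boundary = 0.20),
    MA5 = attribute_standard("MA5", basal_intervals = c(18, 28),
                             hadrosaurid_intervals = c(8, 13),
                             boundary = 15),
    MA6 = attribute_standard("MA6", basal_intervals = c(0.38, 0.58),
                             hadrosaurid_intervals = c(0.60, 0.76),
                             boundary = 0.59))
  values <- c(MA1 = 0.37, MA2 = 0.37, MA3 = 16, MA4 = 0.17,
              MA5 = 13, MA6 = 0.50)
  list(standards = std, values = values)
}
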
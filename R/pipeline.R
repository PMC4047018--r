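# End-to-end pipeline runs: each writes its outputs plus a manifest
# (config, seed, package version) into a run directory, so every number
# in a report traces back to a recorded configuration.

write_manifest <- function(out_dir, stage, params, files) {
  lines <- c(sprintf("stage: %s", stage),
             sprintf("package: hadromosaic %s",
                     as.character(utils::packageVersion("hadromosaic"))),
             sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
             "params:",
             sprintf("  %s: %s", names(params),
                     vapply(params, function(p)
                       paste(format(p, trim = TRUE), collapse = " "),
                       character(1))),
             "outputs:",
             sprintf("  - %s", files))
  writeLines(lines, file.path(out_dir, "manifest.txt"))
  invisible(NULL)
}

ensure_dir <- function(d) {
  if (!dir.exists(d)) dir.create(d, recursive = TRUE)
  d
}

#' Discretize measurement attributes into interval standards
#'
#' End-to-end clustering stage: per attribute, collapse specimens to
#' taxon means (excluding the focal taxon), select a mixture model by
#' BIC, convert the fitted partition into ordered component intervals,
#' map components onto the basal/hadrosaurid split, and keep the
#' diagnostic attributes.  Writes `standards.tsv`, `bic_tables.tsv` and a
#' manifest into `out_dir`.
#'
#' @param measurements a `"measurement_table"` or path to one.
#' @param labels named group vector or path to a labels file.
#' @param focal focal taxon name excluded from clustering.
#' @param out_dir output directory (created if needed).
#' @param G_max largest component count tried.
#' @param min_alignment diagnostic threshold on the alignment score.
#' @return (invisibly) list with `standards`, `selected`, `bic_tables`.
#' @export
run_discretize <- function(measurements, labels, focal = NULL,
                           out_dir = "discretize_run", G_max = 9L,
                           min_alignment = 0.9) {
  if (is.character(measurements)) measurements <- read_measurements(measurements)
  if (is.character(labels)) labels <- read_group_labels(labels)
  ensure_dir(out_dir)
  attrs <- sort(unique(measurements$attribute))
  standards <- list()
  bic_rows <- list()
  for (a in attrs) {
    vals <- build_attribute_dataset(measurements, a, exclude = focal)
    sel <- select_gmm(vals, G_range = seq_len(min(G_max, length(vals))))
    part <- partition_to_intervals(sel$best, vals, attribute = a)
    standards[[a]] <- components_to_sides(part, labels)
    bic_rows[[a]] <- cbind(attribute = a, sel$table)
  }
  selected <- select_diagnostic_attributes(standards, min_alignment)
  f_std <- file.path(out_dir, "standards.tsv")
  write_standards(standards, f_std)
  f_bic <- file.path(out_dir, "bic_tables.tsv")
  utils::write.table(do.call(rbind, bic_rows), f_bic, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  f_sel <- file.path(out_dir, "diagnostic_attributes.txt")
  writeLines(selected, f_sel)
  write_manifest(out_dir, "discretize",
                 list(focal = focal %||% "none", G_max = G_max,
                      min_alignment = min_alignment,
                      n_attributes = length(attrs)),
                 basename(c(f_std, f_bic, f_sel)))
  invisible(list(standards = standards, selected = selected,
                 bic_tables = do.call(rbind, bic_rows)))
}

#' Classify a focal taxon against interval standards
#'
#' Reads standards (as written by [run_discretize()] or built from
#' printed intervals) and a named vector of focal values, classifies each
#' attribute, and writes the mosaic report.  Values for attributes with
#' no standard are skipped with a warning; a duplicated attribute keeps
#' the last value (with a warning).
#'
#' @param standards list of `"attribute_standard"` or path to a
#'   standards file.
#' @param values named numeric vector, or path to a two-column
#'   (attribute, value) delimited file.
#' @param taxon focal taxon name for the report.
#' @param out_dir output directory.
#' @return (invisibly) a `"mosaic_summary"` (NULL for empty input).
#' @export
run_classify <- function(standards, values, taxon = "focal",
                         out_dir = "classify_run") {
  if (is.character(standards)) standards <- read_standards(standards)
  if (is.character(values) && length(values) == 1L && file.exists(values)) {
    header <- readLines(values, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
    df <- utils::read.table(values, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE)
    values <- stats::setNames(as.numeric(df$value), df$attribute)
  }
  ensure_dir(out_dir)
  if (anyDuplicated(names(values))) {
    warning("duplicate attribute value(s); last wins", call. = FALSE)
    values <- values[!duplicated(names(values), fromLast = TRUE)]
  }
  known <- names(values) %in% vapply(standards, `[[`, character(1),
                                     "attribute")
  if (any(!known)) {
    warning("skipping value(s) for unknown attribute(s): ",
            paste(names(values)[!known], collapse = ", "), call. = FALSE)
    values <- values[known]
  }
  f_rep <- file.path(out_dir, "mosaic_report.tsv")
  if (!length(values)) {
    utils::write.table(
      data.frame(attribute = character(0), value = numeric(0),
                 side = character(0)),
      f_rep, sep = "\t", row.names = FALSE, quote = FALSE)
    write_manifest(out_dir, "classify",
                   list(taxon = taxon, n_values = 0L), basename(f_rep))
    return(invisible(NULL))
  }
  std_by <- stats::setNames(standards,
                            vapply(standards, `[[`, character(1), "attribute"))
  sides <- vapply(names(values), function(a)
    classify_value(values[[a]], std_by[[a]]), character(1))
  ms <- mosaic_summary(sides, taxon = taxon)
  utils::write.table(
    data.frame(attribute = names(values), value = unname(values),
               side = unname(sides)),
    f_rep, sep = "\t", row.names = FALSE, quote = FALSE)
  f_sum <- file.path(out_dir, "mosaic_summary.txt")
  writeLines(c(sprintf("taxon: %s", taxon),
               sprintf("basal: %d", ms$counts[["basal"]]),
               sprintf("hadrosaurid: %d", ms$counts[["hadrosaurid"]]),
               sprintf("straddle: %s", ms$straddle)), f_sum)
  write_manifest(out_dir, "classify",
                 list(taxon = taxon, n_values = length(values)),
                 basename(c(f_rep, f_sum)))
  invisible(ms)
}

#' Heuristic parsimony search on a character matrix
#'
#' Runs [heuristic_search()] and [ci_ri()], then writes the MPT list
#' (Newick), a run report (length, tree count, CI, RI, seed), and the
#' per-character step vector.
#'
#' @param matrix a `"character_matrix"` or path to a NEXUS/TNT file.
#' @param out_dir output directory.
#' @param config a [search_config()].
#' @param dialect matrix file dialect when `matrix` is a path.
#' @return (invisibly) list with `search` and `indices`.
#' @export
run_search <- function(matrix, out_dir = "search_run",
                       config = search_config(), dialect = "guess") {
  if (is.character(matrix)) matrix <- read_character_matrix(matrix, dialect)
  ensure_dir(out_dir)
  res <- heuristic_search(matrix, config)
  idx <- ci_ri(matrix, res$length)
  f_trees <- file.path(out_dir, "mpts.nwk")
  write_newick(res$trees, f_trees)
  f_rep <- file.path(out_dir, "search_report.tsv")
  utils::write.table(
    data.frame(length = res$length, n_trees = length(res$trees),
               CI = round(idx$CI, 3), RI = round(idx$RI, 3),
               sum_min_steps = idx$sum_min, sum_max_steps = idx$sum_max,
               replicates = config$replicates, seed = config$seed,
               truncated = res$truncated),
    f_rep, sep = "\t", row.names = FALSE, quote = FALSE)
  f_steps <- file.path(out_dir, "per_character_steps.tsv")
  utils::write.table(
    data.frame(character = seq_along(res$per_char_steps),
               steps = res$per_char_steps),
    f_steps, sep = "\t", row.names = FALSE, quote = FALSE)
  write_manifest(out_dir, "search",
                 list(replicates = config$replicates,
                      hold = config$hold_per_replicate,
                      max_trees = config$max_trees, seed = config$seed,
                      suboptimal_bound = config$suboptimal_bound),
                 basename(c(f_trees, f_rep, f_steps)))
  invisible(list(search = res, indices = idx))
}

#' Consensus and clade support for a set of most-parsimonious trees
#'
#' Computes strict and majority-rule consensus trees, bootstrap
#' proportions, Bremer decay indices and the unambiguous synapomorphies
#' on the strict consensus (when it is binary) or on the first MPT, and
#' writes annotated Newick plus delimited support tables.
#'
#' @param matrix a `"character_matrix"` or path.
#' @param trees a `"parsimony_search"`, list of `phylo`, or Newick path.
#' @param out_dir output directory.
#' @param bootstrap_replicates bootstrap replicates (0 skips bootstrap).
#' @param bremer_kmax Bremer sweep bound (0 skips Bremer).
#' @param seed integer seed for the bootstrap.
#' @param outgroup taxon used to root the synapomorphy mapping (default:
#'   first taxon of the matrix).
#' @param dialect matrix dialect when `matrix` is a path.
#' @return (invisibly) list with `strict`, `majority`, `bootstrap`,
#'   `bremer`, `synapomorphies`.
#' @export
run_support <- function(matrix, trees, out_dir = "support_run",
                        bootstrap_replicates = 100L, bremer_kmax = 3L,
                        seed = 1L, outgroup = NULL, dialect = "guess") {
  if (is.character(matrix)) matrix <- read_character_matrix(matrix, dialect)
  if (is.character(trees)) trees <- read_newick(trees)
  tree_list <- as_tree_list(trees)
  ensure_dir(out_dir)
  strict <- strict_consensus(tree_list)
  maj <- majority_consensus(tree_list)
  files <- character(0)
  f <- file.path(out_dir, "strict_consensus.nwk")
  write_newick(strict, f); files <- c(files, f)
  f <- file.path(out_dir, "majority_consensus.nwk")
  write_newick(maj, f); files <- c(files, f)
  boot <- NULL
  if (bootstrap_replicates > 0) {
    boot <- bootstrap_support(matrix, replicates = bootstrap_replicates,
                              seed = seed)
    f <- file.path(out_dir, "bootstrap_support.tsv")
    utils::write.table(as.data.frame(boot), f, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    files <- c(files, f)
    f <- file.path(out_dir, "strict_consensus_bootstrap.nwk")
    write_newick(annotate_support(strict, boot), f)
    files <- c(files, f)
  }
  brem <- NULL
  if (bremer_kmax > 0 && inherits(trees, "parsimony_search")) {
    brem <- bremer_decay(matrix, trees, k_max = bremer_kmax)
    f <- file.path(out_dir, "bremer_decay.tsv")
    utils::write.table(as.data.frame(brem), f, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    files <- c(files, f)
  }
  og <- outgroup %||% matrix$taxa[1L]
  syn_tree <- if (ape::is.binary(strict)) strict else tree_list[[1L]]
  syn <- map_synapomorphies(syn_tree, matrix, og)
  f <- file.path(out_dir, "synapomorphies.tsv")
  utils::write.table(as.data.frame(syn), f, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  files <- c(files, f)
  write_manifest(out_dir, "support",
                 list(bootstrap_replicates = bootstrap_replicates,
                      bremer_kmax = bremer_kmax, seed = seed,
                      outgroup = og, n_trees = length(tree_list)),
                 basename(files))
  invisible(list(strict = strict, majority = maj, bootstrap = boot,
                 bremer = brem, synapomorphies = syn))
}

#' Generate synthetic inputs on disk
#'
#' Writes either a two-group measurement dataset (table + labels) or a
#' character matrix evolved on a random tree (matrix + true tree), in the
#' same formats the readers consume.
#'
#' @param kind `"measurements"` or `"characters"`.
#' @param out_dir output directory.
#' @param spec a [measurement_sim_spec()] or [character_sim_spec()].
#' @return (invisibly) the generated objects.
#' @export
run_simulate <- function(kind = c("measurements", "characters"),
                         out_dir = "simulate_run", spec = NULL) {
  kind <- match.arg(kind)
  ensure_dir(out_dir)
  if (kind == "measurements") {
    spec <- spec %||% measurement_sim_spec()
    sim <- gen_two_group_measurements(spec)
    f1 <- file.path(out_dir, "measurements.tsv")
    write_measurements(sim$table, f1)
    f2 <- file.path(out_dir, "labels.tsv")
    utils::write.table(
      data.frame(taxon = names(sim$labels), group = unname(sim$labels)),
      f2, sep = "\t", row.names = FALSE, quote = FALSE)
    f3 <- file.path(out_dir, "truth.tsv")
    utils::write.table(sim$truth, f3, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    write_manifest(out_dir, "simulate",
                   list(kind = kind, seed = spec$seed),
                   basename(c(f1, f2, f3)))
    invisible(sim)
  } else {
    spec <- spec %||% character_sim_spec()
    tree <- gen_random_tree(spec$n_taxa, seed = spec$seed)
    mat <- evolve_characters(tree, spec)
    f1 <- file.path(out_dir, "matrix.nex")
    write_character_matrix(mat, f1, dialect = "nexus")
    f2 <- file.path(out_dir, "true_tree.nwk")
    write_newick(tree, f2)
    write_manifest(out_dir, "simulate",
                   list(kind = kind, seed = spec$seed,
                        n_taxa = spec$n_taxa, n_char = spec$n_char),
                   basename(c(f1, f2)))
    invisible(list(matrix = mat, tree = tree))
  }
}
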
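#' Convert a fitted mixture into an ordered component partition
#'
#' Assigns every taxon to its maximum-a-posteriori mixture component,
#' relabels the components `C01`, `C02`, ... in increasing value order
#' (by interval lower bound, which coincides with increasing mean
#' whenever the MAP regions are contiguous), and records each
#' component's closed value interval (the minimum and maximum of its
#' assigned values).  Components left empty by the MAP assignment are
#' dropped with a warning and the remainder renumbered.
#'
#' @param model a `"gmm1d"` fit over `values`.
#' @param values numeric vector the model was fitted to.
#' @param taxa taxon names, same length as `values` (defaults to
#'   `names(values)`).
#' @param attribute attribute identifier carried through to reports.
#' @return an object of class `"component_partition"`: list with
#'   `attribute`, `assignments` (data.frame taxon/value/component) and
#'   `components` (data.frame component/mean/lower/upper/n).
#' @export
partition_to_intervals <- function(model, values, taxa = names(values),
                                   attribute = "attr") {
  force(taxa)
  values <- as.numeric(values)
  if (is.null(taxa)) taxa <- paste0("t", seq_along(values))
  if (length(taxa) != length(values)) stop2("taxa/values length mismatch")
  map <- predict.gmm1d(model, values, type = "class")
  used <- sort(unique(map))
  if (length(used) < model$G)
    warning("dropping ", model$G - length(used),
            " empty component(s) after MAP assignment", call. = FALSE)
  # order primarily by the interval's lower bound (equals mean order for
  # contiguous MAP regions, and keeps interval order well defined when a
  # broad component catches both tails), ties by component mean
  lo <- vapply(used, function(g) min(values[map == g]), numeric(1))
  ord <- used[order(lo, model$means[used])]
  relab <- match(map, ord)
  lab <- sprintf("C%02d", relab)
  comps <- data.frame(
    component = sprintf("C%02d", seq_along(ord)),
    mean = model$means[ord],
    lower = as.numeric(tapply(values, relab, min)),
    upper = as.numeric(tapply(values, relab, max)),
    n = as.integer(table(relab)),
    stringsAsFactors = FALSE)
  structure(list(attribute = attribute,
                 assignments = data.frame(taxon = taxa, value = values,
                                          component = lab,
                                          stringsAsFactors = FALSE),
                 components = comps),
            class = "component_partition")
}

#' @export
print.component_partition <- function(x, ...) {
  cat("Component partition of attribute", x$attribute, "\n")
  print(x$components, digits = 4)
  invisible(x)
}

#' Boundary value between two adjacent component intervals
#'
#' The boundary between a lower and an upper value interval is the mean of
#' the greatest value of the lower interval and the least value of the
#' upper interval.  The result is exact (unrounded); rounding to printed
#' precision is a presentation concern.
#'
#' @param lower,upper numeric length-2 intervals `c(min, max)` with
#'   `max(lower) < min(upper)`.
#' @return a single number.
#' @examples
#' boundary_between(c(0.38, 0.58), c(0.60, 0.76))  # 0.59
#' @export
boundary_between <- function(lower, upper) {
  if (length(lower) != 2L || length(upper) != 2L)
    stop2("intervals must be numeric length-2 vectors")
  if (max(lower) >= min(upper))
    stop2("intervals overlap or touch: max(lower) = ", max(lower),
          " >= min(upper) = ", min(upper))
  (max(lower) + min(upper)) / 2
}

#' Construct an attribute standard
#'
#' An attribute standard is the decision rule distilled from one clustered
#' measurement attribute: the value interval(s) occupied by basal
#' hadrosauroids (plus basal iguanodontians), the interval(s) occupied by
#' hadrosaurids, a boundary value between the two sides, and the polarity
#' (which side holds the low values).  If `boundary` is omitted it is
#' computed by the interval-midpoint rule from the adjacent extremes of the
#' two sides.
#'
#' @param attribute attribute identifier.
#' @param basal_intervals,hadrosaurid_intervals matrix with columns
#'   `lower`, `upper` (or a length-2 vector for a single interval).
#' @param boundary optional boundary value.
#' @param alignment fraction of taxa whose component side matched their
#'   taxonomic side (NA when constructed from printed intervals).
#' @param diagnostic logical; FALSE when the component/side arrangement is
#'   unusable (single component, non-contiguous sides).
#' @return an object of class `"attribute_standard"`.
#' @export
attribute_standard <- function(attribute, basal_intervals,
                               hadrosaurid_intervals, boundary = NULL,
                               alignment = NA_real_, diagnostic = TRUE) {
  as_im <- function(x) {
    if (is.null(x)) return(matrix(numeric(0), 0, 2,
                                  dimnames = list(NULL, c("lower", "upper"))))
    m <- if (is.matrix(x)) x else matrix(x, ncol = 2, byrow = TRUE)
    colnames(m) <- c("lower", "upper")
    m[order(m[, 1L]), , drop = FALSE]
  }
  b <- as_im(basal_intervals)
  h <- as_im(hadrosaurid_intervals)
  polarity <- NA_character_
  if (nrow(b) && nrow(h)) {
    if (max(b[, 2L]) < min(h[, 1L])) polarity <- "basal"
    else if (max(h[, 2L]) < min(b[, 1L])) polarity <- "hadrosaurid"
    else if (isTRUE(diagnostic))
      stop2("basal and hadrosaurid intervals overlap for ", attribute)
    if (is.null(boundary) && !is.na(polarity)) {
      lo <- if (polarity == "basal") b else h
      hi <- if (polarity == "basal") h else b
      boundary <- boundary_between(c(min(lo[, 1L]), max(lo[, 2L])),
                                   c(min(hi[, 1L]), max(hi[, 2L])))
    }
  }
  structure(list(attribute = attribute, basal = b, hadrosaurid = h,
                 boundary = boundary %||% NA_real_, polarity = polarity,
                 alignment = alignment, diagnostic = diagnostic),
            class = "attribute_standard")
}

#' @export
print.attribute_standard <- function(x, ...) {
  fmt <- function(m) if (!nrow(m)) "-" else
    paste(sprintf("[%g, %g]", m[, 1L], m[, 2L]), collapse = " + ")
  cat(sprintf("%s: basal %s | hadrosaurid %s | boundary %g (low side: %s)",
              x$attribute, fmt(x$basal), fmt(x$hadrosaurid),
              x$boundary, x$polarity))
  if (!is.na(x$alignment)) cat(sprintf(" | alignment %.3f", x$alignment))
  if (!x$diagnostic) cat(" [non-diagnostic]")
  cat("\n")
  invisible(x)
}

#' Map partition components onto the basal/hadrosaurid split
#'
#' Each component is assigned to the binary side (basal vs hadrosaurid)
#' holding the majority of its taxa; contiguous components of the same side
#' are merged into one interval per run.  When the resulting arrangement is
#' exactly one basal run and one hadrosaurid run along the value axis, the
#' boundary between the adjacent opposite-side intervals is computed and
#' the standard is diagnostic; otherwise (a single side, or an interleaved
#' arrangement such as basal / hadrosaurid / basal) it is flagged
#' non-diagnostic.  The alignment score is the fraction of taxa whose
#' component side matches their own label side.
#'
#' @param partition a `"component_partition"`.
#' @param labels named character vector taxon -> group (see
#'   [read_group_labels()]); every partitioned taxon must be labeled.
#' @return an `"attribute_standard"`.
#' @export
components_to_sides <- function(partition, labels) {
  asg <- partition$assignments
  missing <- setdiff(asg$taxon, names(labels))
  if (length(missing))
    stop2("unlabeled taxa: ", paste(missing, collapse = ", "))
  side <- group_side(labels[asg$taxon])
  comps <- partition$components
  comp_side <- vapply(comps$component, function(cc) {
    s <- side[asg$component == cc]
    if (sum(s == "basal") >= sum(s == "hadrosaurid")) "basal" else "hadrosaurid"
  }, character(1))
  alignment <- mean(side == comp_side[match(asg$component, comps$component)])

  runs <- rle(comp_side)
  merged <- do.call(rbind, lapply(seq_along(runs$lengths), function(i) {
    idx <- seq(sum(runs$lengths[seq_len(i - 1L)]) + 1L,
               sum(runs$lengths[seq_len(i)]))
    c(lower = min(comps$lower[idx]), upper = max(comps$upper[idx]))
  }))

  diagnostic <- length(runs$values) == 2L
  if (!diagnostic && length(runs$values) > 2L)
    warning("non-contiguous side arrangement (",
            paste(runs$values, collapse = ", "), ") for attribute ",
            partition$attribute, "; standard flagged non-diagnostic",
            call. = FALSE)

  bi <- merged[runs$values == "basal", , drop = FALSE]
  hi <- merged[runs$values == "hadrosaurid", , drop = FALSE]
  boundary <- NULL
  if (diagnostic) {
    boundary <- tryCatch(
      boundary_between(merged[1L, ], merged[2L, ]),
      error = function(e) {
        diagnostic <<- FALSE
        warning("adjacent opposite-side intervals overlap for attribute ",
                partition$attribute, "; standard flagged non-diagnostic",
                call. = FALSE)
        NULL
      })
  }
  # collapse possibly interleaved runs per side into row sets
  std <- attribute_standard(partition$attribute,
                            basal_intervals = bi, hadrosaurid_intervals = hi,
                            boundary = boundary, alignment = alignment,
                            diagnostic = diagnostic && partition_has_2plus(partition))
  std
}

partition_has_2plus <- function(partition) nrow(partition$components) >= 2L

#' Keep the attributes usable as quantitative standards
#'
#' Retains attributes whose standard has at least two components arranged
#' contiguously by side and an alignment score at or above
#' `min_alignment`.  Output order is deterministic (sorted attribute id).
#'
#' @param standards list of `"attribute_standard"` objects.
#' @param min_alignment minimum fraction of taxa on the matching side
#'   (default 0.9).
#' @return character vector of attribute ids (possibly empty).
#' @export
select_diagnostic_attributes <- function(standards, min_alignment = 0.9) {
  keep <- vapply(standards, function(s)
    isTRUE(s$diagnostic) && !is.na(s$alignment) &&
      s$alignment >= min_alignment, logical(1))
  sort(vapply(standards[keep], `[[`, character(1), "attribute"))
}

#' Classify a focal value against an attribute standard
#'
#' A value lying inside a side's interval classifies to that side.  A value
#' falling in the gap between intervals is split at the boundary with the
#' "up to b" convention: values less than or equal to the boundary belong
#' to the low-value side, values greater than it to the high-value side.
#'
#' @param value a single number.
#' @param standard an `"attribute_standard"` with a boundary.
#' @return `"basal"` or `"hadrosaurid"`.
#' @export
classify_value <- function(value, standard) {
  stopifnot(length(value) == 1L, is.finite(value))
  inside <- function(m) nrow(m) > 0 &&
    any(value >= m[, 1L] & value <= m[, 2L])
  if (inside(standard$basal)) return("basal")
  if (inside(standard$hadrosaurid)) return("hadrosaurid")
  if (is.na(standard$boundary))
    stop2("standard for ", standard$attribute, " has no boundary")
  low <- standard$polarity
  high <- setdiff(c("basal", "hadrosaurid"), low)
  if (value <= standard$boundary) low else high
}

#' Summarize per-attribute classifications of a focal taxon
#'
#' @param sides named character vector attribute -> side (from
#'   [classify_value()]).
#' @param taxon focal taxon id (for display).
#' @return an object of class `"mosaic_summary"` with per-side counts and a
#'   straddle flag (TRUE when both sides are represented).
#' @export
mosaic_summary <- function(sides, taxon = "focal") {
  if (!length(sides)) stop2("no classified attributes")
  counts <- c(basal = sum(sides == "basal"),
              hadrosaurid = sum(sides == "hadrosaurid"))
  structure(list(taxon = taxon, sides = sides, counts = counts,
                 straddle = all(counts > 0)),
            class = "mosaic_summary")
}

#' @export
print.mosaic_summary <- function(x, ...) {
  cat("Mosaic classification of", x$taxon, "\n")
  for (a in names(x$sides)) cat(" ", a, "->", x$sides[[a]], "\n")
  cat(sprintf("basal %d / hadrosaurid %d; straddle: %s\n",
              x$counts["basal"], x$counts["hadrosaurid"], x$straddle))
  invisible(x)
}

#' Write attribute standards as delimited text
#'
#' One row per interval with the standard-level fields repeated, so the
#' file round-trips through [read_standards()].
#'
#' @param standards list of `"attribute_standard"` objects.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_standards <- function(standards, path) {
  rows <- do.call(rbind, lapply(standards, function(s) {
    one <- function(side) {
      m <- s[[side]]
      if (!nrow(m)) return(NULL)
      data.frame(attribute = s$attribute, side = side,
                 lower = m[, 1L], upper = m[, 2L],
                 boundary = s$boundary, polarity = s$polarity,
                 alignment = s$alignment, diagnostic = s$diagnostic,
                 stringsAsFactors = FALSE)
    }
    rbind(one("basal"), one("hadrosaurid"))
  }))
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read attribute standards written by [write_standards()]
#'
#' @param path file path.
#' @return named list of `"attribute_standard"` objects.
#' @export
read_standards <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  out <- lapply(split(df, df$attribute), function(d) {
    attribute_standard(
      d$attribute[1L],
      basal_intervals = as.matrix(d[d$side == "basal", c("lower", "upper")]),
      hadrosaurid_intervals =
        as.matrix(d[d$side == "hadrosaurid", c("lower", "upper")]),
      boundary = d$boundary[1L], alignment = d$alignment[1L],
      diagnostic = as.logical(d$diagnostic[1L]))
  })
  out[order(names(out))]
}
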
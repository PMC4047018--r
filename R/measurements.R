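#' Construct a measurement table
#'
#' A measurement table holds long-form continuous osteological observations:
#' one row per (taxon, attribute, specimen) with a numeric value.  Values
#' are dimensionless ratios (non-negative) or angles in degrees (0 to 180).
#'
#' @param taxon,attribute,specimen,value vectors of equal length.
#' @return a data.frame of class `"measurement_table"`.
#' @export
measurement_table <- function(taxon, attribute, specimen, value) {
  df <- data.frame(taxon = as.character(taxon),
                   attribute = as.character(attribute),
                   specimen = as.character(specimen),
                   value = as.numeric(value),
                   stringsAsFactors = FALSE)
  bad <- which(!is.finite(df$value))
  if (length(bad))
    stop2("non-numeric or non-finite value in row(s) ",
          paste(bad, collapse = ", "))
  if (any(df$value < 0))
    stop2("negative measurement values are not allowed (ratios are >= 0, ",
          "angles are in [0, 180] degrees)")
  key <- paste(df$taxon, df$attribute, df$specimen, sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1L]
    stop2("duplicate (taxon, attribute, specimen) observation in row ", d,
          ": ", df$taxon[d], ", ", df$attribute[d], ", ", df$specimen[d])
  }
  class(df) <- c("measurement_table", "data.frame")
  df
}

#' Read a measurement table from delimited text
#'
#' Expects columns `taxon`, `attribute`, `specimen`, `value`; the field
#' separator (comma or tab) is detected from the header line.  Taxon names
#' have internal whitespace normalized to underscores.
#'
#' @param path file path.
#' @return a `"measurement_table"`.
#' @export
read_measurements <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("taxon", "attribute", "specimen", "value")
  if (!all(need %in% names(df)))
    stop2("measurement file must have columns: ", paste(need, collapse = ", "))
  if (nrow(df) == 0L)
    return(measurement_table(character(0), character(0), character(0),
                             numeric(0)))
  val <- suppressWarnings(as.numeric(df$value))
  if (anyNA(val))
    stop2("non-numeric value in row ", which(is.na(val))[1L], " of ", path)
  measurement_table(normalize_taxon(df$taxon), df$attribute, df$specimen, val)
}

#' Write a measurement table as delimited text
#'
#' @param table a `"measurement_table"`.
#' @param path file path.
#' @param sep field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_measurements <- function(table, path, sep = "\t") {
  utils::write.table(as.data.frame(table), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

normalize_taxon <- function(x) gsub("[[:space:]]+", "_", trimws(x))

#' Per-taxon attribute dataset for clustering
#'
#' Collapses the observations of one measurement attribute to a single value
#' per taxon (the arithmetic mean over specimens), optionally excluding a
#' focal taxon whose data must not participate in the clustering.
#'
#' @param table a `"measurement_table"`.
#' @param attribute attribute identifier, e.g. `"MA6"`.
#' @param exclude taxa to drop (typically the focal taxon under evaluation).
#' @return a named numeric vector (names are taxa).
#' @export
build_attribute_dataset <- function(table, attribute, exclude = NULL) {
  sub <- table[table$attribute == attribute, , drop = FALSE]
  if (!is.null(exclude))
    sub <- sub[!(sub$taxon %in% normalize_taxon(exclude)), , drop = FALSE]
  if (nrow(sub) == 0L)
    stop2("no observations for attribute '", attribute, "'")
  means <- tapply(sub$value, sub$taxon, mean)
  out <- as.numeric(means)
  names(out) <- names(means)
  out
}

#' Read per-taxon group labels
#'
#' A two-column delimited file (`taxon`, `group`) assigning each measured
#' taxon to one of `basal_iguanodontian`, `basal_hadrosauroid`,
#' `hadrosaurine`, `lambeosaurine`.
#'
#' @param path file path.
#' @return named character vector taxon -> group.
#' @export
read_group_labels <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!all(c("taxon", "group") %in% names(df)))
    stop2("labels file must have columns: taxon, group")
  ok <- c("basal_iguanodontian", "basal_hadrosauroid",
          "hadrosaurine", "lambeosaurine")
  bad <- setdiff(unique(df$group), ok)
  if (length(bad))
    stop2("unknown group(s): ", paste(bad, collapse = ", "))
  stats::setNames(df$group, normalize_taxon(df$taxon))
}

#' Binary side of a taxonomic group label
#'
#' Projects the four-way group labels onto the binary split the interval
#' standards target: basal iguanodontians and basal hadrosauroids map to
#' `"basal"`, hadrosaurines and lambeosaurines to `"hadrosaurid"`.
#'
#' @param group character vector of group labels.
#' @return character vector of `"basal"` / `"hadrosaurid"`.
#' @export
group_side <- function(group) {
  out <- ifelse(group %in% c("basal_iguanodontian", "basal_hadrosauroid"),
                "basal",
         ifelse(group %in% c("hadrosaurine", "lambeosaurine"),
                "hadrosaurid", NA_character_))
  if (anyNA(out))
    stop2("unknown group label(s): ",
          paste(unique(group[is.na(out)]), collapse = ", "))
  out
}
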
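#' Construct a character-taxon matrix
#'
#' Cells are stored as strings of state symbols: `"0"` for a fixed state,
#' `"02"` for a polymorphic cell (the set {0, 2}), and `"?"` for missing
#' ("any state").  Characters are indexed 1-based throughout, matching the
#' field's "character 7" citation style.  All characters are unordered
#' (nonadditive) and, by default, equally weighted.
#'
#' @param cells character matrix (taxa in rows, characters in columns) of
#'   state strings; row names are taxon identifiers.
#' @param weights per-character positive weights (default all 1).
#' @param partition_tag optional per-character tag
#'   (`"cranial"`/`"postcranial"`/`"unknown"`).
#' @param symbols optional declared state universe common to all
#'   characters; defaults to the union of observed symbols per character.
#' @return an object of class `"character_matrix"` with elements `taxa`,
#'   `nchar`, `cells`, `universe` (list of per-character symbol sets),
#'   `weights`, `ordering`, `partition_tag`.
#' @export
character_matrix <- function(cells, weights = NULL, partition_tag = NULL,
                             symbols = NULL) {
  if (!is.matrix(cells) || !is.character(cells))
    stop2("'cells' must be a character matrix")
  taxa <- rownames(cells)
  if (is.null(taxa) || anyDuplicated(taxa))
    stop2("cells must have unique taxon row names")
  nc <- ncol(cells)
  if (any(cells == "" | is.na(cells)))
    stop2("empty cell(s): every cell must be a non-empty state set or '?'")
  universe <- lapply(seq_len(nc), function(j) {
    obs <- sort(unique(unlist(strsplit(cells[cells[, j] != "?", j], ""))))
    if (!is.null(symbols)) {
      bad <- setdiff(obs, symbols)
      if (length(bad))
        stop2("symbol(s) ", paste(bad, collapse = ""),
              " in character ", j, " outside declared symbol set")
    }
    if (length(obs)) obs else "0"
  })
  weights <- weights %||% rep(1, nc)
  if (length(weights) != nc || any(weights <= 0))
    stop2("'weights' must be ", nc, " positive numbers")
  structure(list(taxa = taxa, nchar = nc, cells = cells,
                 universe = universe, weights = weights,
                 ordering = rep("unordered", nc),
                 partition_tag = partition_tag %||% rep("unknown", nc)),
            class = "character_matrix")
}

#' @export
print.character_matrix <- function(x, ...) {
  np <- sum(nchar(x$cells) > 1L & x$cells != "?")
  cat(sprintf(paste0("Character matrix: %d taxa x %d unordered characters ",
                     "(%d missing cells, %d polymorphic cells)\n"),
              length(x$taxa), x$nchar, sum(x$cells == "?"), np))
  invisible(x)
}

#' @export
dim.character_matrix <- function(x) c(length(x$taxa), x$nchar)

#' Read a character-taxon matrix (NEXUS or TNT dialect)
#'
#' The NEXUS reader handles a `DATA` or `CHARACTERS` block with
#' `DIMENSIONS`, optional `FORMAT` (`SYMBOLS`, `MISSING`, `GAP`), and a
#' `MATRIX` body; the TNT reader handles an `xread` block (`nchar` then
#' `ntax`).  Polymorphic cells may be written as `{01}`, `(01)` or `[01]`;
#' `?` (and the gap symbol `-`) map to missing.  Taxon names may be quoted;
#' internal whitespace is normalized to underscores.  Declared dimensions
#' are enforced: any mismatch is a hard parse error naming the offender.
#'
#' @param path file path.
#' @param dialect `"nexus"` or `"tnt"`; default guesses from content.
#' @return a `"character_matrix"`.
#' @export
read_character_matrix <- function(path, dialect = c("guess", "nexus", "tnt")) {
  dialect <- match.arg(dialect)
  txt <- readLines(path, warn = FALSE)
  if (dialect == "guess")
    dialect <- if (any(grepl("#NEXUS", txt, ignore.case = TRUE))) "nexus"
               else "tnt"
  if (dialect == "nexus") parse_nexus_matrix(txt) else parse_tnt_matrix(txt)
}

# split a matrix row body into cell tokens; bracket groups become sorted
# multi-symbol strings, '?' and the gap symbol become '?'
tokenize_cells <- function(body, gap = "-", missing_sym = "?") {
  chars <- strsplit(body, "")[[1L]]
  out <- character(0)
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch %in% c(" ", "\t")) { i <- i + 1L; next }
    if (ch %in% c("{", "(", "[")) {
      close <- c("{" = "}", "(" = ")", "[" = "]")[[ch]]
      j <- i + 1L
      grp <- character(0)
      while (j <= length(chars) && chars[j] != close) {
        if (!chars[j] %in% c(" ", "\t")) grp <- c(grp, chars[j])
        j <- j + 1L
      }
      if (j > length(chars)) stop2("unclosed state group in matrix body")
      if (!length(grp)) stop2("empty state group in matrix body")
      out <- c(out, paste(sort(unique(grp)), collapse = ""))
      i <- j + 1L
    } else {
      out <- c(out, if (ch %in% c(missing_sym, gap)) "?" else ch)
      i <- i + 1L
    }
  }
  out
}

parse_nexus_matrix <- function(txt) {
  txt <- gsub("\\[[^][]*\\]", "", txt)  # strip [comments] (not state groups:
  # NEXUS uses {} or () for polymorphism; [] is reserved for comments)
  one <- paste(txt, collapse = "\n")
  dims <- regmatches(one, regexpr(
    "DIMENSIONS[^;]*;", one, ignore.case = TRUE))
  if (!length(dims)) stop2("NEXUS: no DIMENSIONS statement")
  ntax <- as.integer(sub(".*NTAX\\s*=\\s*([0-9]+).*", "\\1", dims,
                         ignore.case = TRUE))
  nchr <- as.integer(sub(".*NCHAR\\s*=\\s*([0-9]+).*", "\\1", dims,
                         ignore.case = TRUE))
  if (is.na(ntax) || is.na(nchr)) stop2("NEXUS: cannot parse dimensions")
  fmt <- regmatches(one, regexpr("FORMAT[^;]*;", one, ignore.case = TRUE))
  missing_sym <- "?"; gap <- "-"; symbols <- NULL
  if (length(fmt)) {
    m <- regmatches(fmt, regexpr("MISSING\\s*=\\s*\\S", fmt,
                                 ignore.case = TRUE))
    if (length(m)) missing_sym <- substr(m, nchar(m), nchar(m))
    g <- regmatches(fmt, regexpr("GAP\\s*=\\s*\\S", fmt, ignore.case = TRUE))
    if (length(g)) gap <- substr(g, nchar(g), nchar(g))
    s <- regmatches(fmt, regexpr('SYMBOLS\\s*=\\s*"[^"]*"', fmt,
                                 ignore.case = TRUE))
    if (length(s)) {
      s <- sub('^[^"]*"', "", sub('"$', "", s))
      symbols <- setdiff(strsplit(s, "")[[1L]], " ")
    }
  }
  mat <- regmatches(one, regexpr("MATRIX[^;]*;", one, ignore.case = TRUE))
  if (!length(mat)) stop2("NEXUS: no MATRIX statement")
  body <- sub(";$", "", sub("^MATRIX", "", mat, ignore.case = TRUE))
  parse_matrix_rows(strsplit(body, "\n")[[1L]], ntax, nchr,
                    gap = gap, missing_sym = missing_sym, symbols = symbols)
}

parse_tnt_matrix <- function(txt) {
  one <- paste(txt, collapse = "\n")
  m <- regexpr("xread[^;]*;", one, ignore.case = TRUE)
  if (m == -1L) stop2("TNT: no xread block")
  body <- sub(";$", "", sub("^xread", "", regmatches(one, m),
                            ignore.case = TRUE))
  body <- sub("^\\s*'[^']*'", "", body)  # optional quoted title
  lines <- strsplit(body, "\n")[[1L]]
  lines <- lines[nzchar(trimws(lines))]
  head <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  if (length(head) < 2L) stop2("TNT: expected 'nchar ntax' after xread")
  nchr <- as.integer(head[1L]); ntax <- as.integer(head[2L])
  if (is.na(nchr) || is.na(ntax)) stop2("TNT: cannot parse dimensions")
  rest <- c(paste(head[-(1:2)], collapse = " "), lines[-1L])
  parse_matrix_rows(rest, ntax, nchr, gap = "-", missing_sym = "?")
}

parse_matrix_rows <- function(lines, ntax, nchr, gap, missing_sym,
                              symbols = NULL) {
  lines <- lines[nzchar(trimws(lines))]
  taxa <- character(0)
  rows <- list()
  for (ln in lines) {
    ln <- trimws(ln)
    if (startsWith(ln, "'")) {
      nm <- sub("^'([^']*)'.*", "\\1", ln)
      body <- sub("^'[^']*'", "", ln)
    } else if (startsWith(ln, '"')) {
      nm <- sub('^"([^"]*)".*', "\\1", ln)
      body <- sub('^"[^"]*"', "", ln)
    } else {
      nm <- sub("\\s.*", "", ln)
      body <- sub("^\\S+", "", ln)
    }
    nm <- normalize_taxon(nm)
    cellv <- tokenize_cells(body, gap = gap, missing_sym = missing_sym)
    if (nm %in% taxa) {  # interleaved continuation
      rows[[nm]] <- c(rows[[nm]], cellv)
    } else {
      taxa <- c(taxa, nm)
      rows[[nm]] <- cellv
    }
  }
  if (length(taxa) != ntax)
    stop2("declared NTAX = ", ntax, " but matrix has ", length(taxa),
          " taxon rows")
  for (nm in taxa)
    if (length(rows[[nm]]) != nchr)
      stop2("taxon '", nm, "' has ", length(rows[[nm]]),
            " characters, declared NCHAR = ", nchr)
  cells <- do.call(rbind, rows[taxa])
  rownames(cells) <- taxa
  character_matrix(cells, symbols = symbols)
}

#' Write a character-taxon matrix (NEXUS or TNT dialect)
#'
#' Round-trips through [read_character_matrix()]: polymorphic cells are
#' serialized as `{01}` (NEXUS) or `[01]` (TNT) groups and missing cells
#' as `?`.
#'
#' @param matrix a `"character_matrix"`.
#' @param path file path.
#' @param dialect `"nexus"` or `"tnt"`.
#' @return `path`, invisibly.
#' @export
write_character_matrix <- function(matrix, path,
                                   dialect = c("nexus", "tnt")) {
  dialect <- match.arg(dialect)
  x <- matrix
  open <- if (dialect == "nexus") "{" else "["
  close <- if (dialect == "nexus") "}" else "]"
  fmt_cell <- function(s) {
    if (s == "?" || nchar(s) == 1L) s else paste0(open, s, close)
  }
  rows <- vapply(seq_along(x$taxa), function(i)
    paste0(x$taxa[i], "  ",
           paste(vapply(x$cells[i, ], fmt_cell, character(1)),
                 collapse = "")),
    character(1))
  syms <- sort(unique(unlist(x$universe)))
  out <- if (dialect == "nexus") {
    c("#NEXUS", "BEGIN DATA;",
      sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", length(x$taxa), x$nchar),
      sprintf('  FORMAT SYMBOLS="%s" MISSING=? GAP=-;',
              paste(syms, collapse = " ")),
      "  MATRIX", paste0("    ", rows), "  ;", "END;")
  } else {
    c(sprintf("xread %d %d", x$nchar, length(x$taxa)), rows, ";")
  }
  writeLines(out, path)
  invisible(path)
}

# --- internal bitmask encoding used by the parsimony engine -----------------

# Encode cells as integer bitmasks over a per-matrix symbol table.
# '?' maps to the full per-character universe.
encode_matrix <- function(x) {
  stopifnot(inherits(x, "character_matrix"))
  syms <- sort(unique(unlist(x$universe)))
  if (length(syms) > 30L) stop2("more than 30 distinct states unsupported")
  bit <- stats::setNames(bitwShiftL(1L, seq_along(syms) - 1L), syms)
  nt <- length(x$taxa)
  masks <- matrix(0L, nt, x$nchar)
  for (j in seq_len(x$nchar)) {
    full <- sum(bit[x$universe[[j]]])
    for (i in seq_len(nt)) {
      s <- x$cells[i, j]
      masks[i, j] <- if (s == "?") as.integer(full)
        else sum(bit[strsplit(s, "")[[1L]]])
    }
  }
  list(masks = masks, symbols = syms, bit = bit,
       taxa = x$taxa, weights = x$weights)
}

# Decode a state-set bitmask back to symbols.
decode_mask <- function(mask, symbols) {
  symbols[bitwAnd(bitwShiftL(1L, seq_along(symbols) - 1L), mask) != 0L]
}
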
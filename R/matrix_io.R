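#' Character-taxon matrix for discrete morphological data
#'
#' Builds a validated character-taxon matrix from a character matrix of cell
#' tokens. Each cell token is either a string of state digits (`"0"` for a
#' fixed scoring, `"02"` for a polymorphic cell containing states 0 and 2),
#' `"?"` for missing, or `"-"` for inapplicable. Missing and inapplicable
#' cells are stored distinctly but both behave as "any observed state" during
#' parsimony optimization.
#'
#' @param cells character matrix (taxa in rows, characters in columns) of
#'   cell tokens.
#' @param taxa character vector of taxon labels (defaults to the rownames of
#'   `cells`). Labels are normalized by collapsing runs of whitespace and
#'   underscores; duplicates after normalization are an error.
#' @param char_labels optional character vector of character labels.
#' @param weights positive character weights (default all 1).
#' @param ordered logical flags, one per character; only unordered characters
#'   are supported by the optimization engine, so any `TRUE` triggers a
#'   warning and the flag is kept for reporting only.
#' @return an object of class `char_matrix` with fields `taxa`, `masks`
#'   (state-set bit masks), `special` (0 scored / 1 missing / 2 inapplicable),
#'   `char_labels`, `weights`, `ordered`, `active_chars`, `active_taxa`.
#' @export
char_matrix <- function(cells, taxa = rownames(cells), char_labels = NULL,
                        weights = NULL, ordered = NULL) {
  if (!is.matrix(cells) || !is.character(cells))
    stopf("`cells` must be a character matrix of cell tokens")
  n_taxa <- nrow(cells)
  n_char <- ncol(cells)
  if (is.null(taxa)) taxa <- paste0("t", seq_len(n_taxa))
  if (length(taxa) != n_taxa) stopf("length of `taxa` != nrow(cells)")
  taxa <- normalize_label(as.character(taxa))
  if (anyDuplicated(taxa))
    stopf("duplicate taxon label after normalization: %s",
          taxa[duplicated(taxa)][1])
  weights <- weights %||% rep(1, n_char)
  if (length(weights) != n_char || any(weights <= 0))
    stopf("`weights` must be %d positive numbers", n_char)
  ordered <- ordered %||% rep(FALSE, n_char)
  if (any(ordered))
    warning("ordered characters are not supported by the engine; ",
            "flags kept for reporting only", call. = FALSE)

  masks <- matrix(0L, n_taxa, n_char)
  special <- matrix(0L, n_taxa, n_char)
  for (j in seq_len(n_char)) {
    col <- cells[, j]
    for (i in seq_len(n_taxa)) {
      tok <- col[i]
      if (tok == "?") {
        special[i, j] <- 1L
      } else if (tok == "-") {
        special[i, j] <- 2L
      } else {
        if (!grepl("^[0-9]+$", tok))
          stopf("invalid cell token '%s' (taxon %s, character %d)",
                tok, taxa[i], j)
        st <- unique(as.integer(strsplit(tok, "")[[1]]))
        masks[i, j] <- states_to_mask(st)
      }
    }
    # missing/inapplicable carry the full observed state set of the character
    alph <- Reduce(bitwOr, masks[, j], 0L)
    if (alph == 0L) alph <- 1L  # completely unscored character: inert
    masks[special[, j] > 0L, j] <- alph
  }

  structure(
    list(taxa = taxa, masks = masks, special = special,
         char_labels = char_labels, weights = as.numeric(weights),
         ordered = as.logical(ordered),
         active_chars = rep(TRUE, n_char), active_taxa = rep(TRUE, n_taxa)),
    class = "char_matrix")
}

#' @export
print.char_matrix <- function(x, ...) {
  cat(sprintf("char_matrix: %d taxa x %d characters\n",
              length(x$taxa), ncol(x$masks)))
  n_missing <- sum(x$special == 1L)
  n_inapp <- sum(x$special == 2L)
  pc <- matrix(vapply(as.integer(x$masks), mask_popcount, 0L), nrow(x$masks))
  n_poly <- sum(x$special == 0L & pc > 1L)
  cat(sprintf("  missing: %d  inapplicable: %d  polymorphic: %d cells\n",
              n_missing, n_inapp, n_poly))
  cat(sprintf("  active: %d taxa, %d characters\n",
              sum(x$active_taxa), sum(x$active_chars)))
  invisible(x)
}

#' Dimensions of a character matrix
#' @param x a `char_matrix`.
#' @export
dim.char_matrix <- function(x) c(length(x$taxa), ncol(x$masks))

# tokens back from masks/special (inverse of the constructor)
cells_of <- function(m) {
  tok <- matrix("", nrow(m$masks), ncol(m$masks))
  for (j in seq_len(ncol(m$masks)))
    for (i in seq_len(nrow(m$masks))) {
      sp <- m$special[i, j]
      tok[i, j] <- if (sp == 1L) "?" else if (sp == 2L) "-" else
        paste(mask_to_states(m$masks[i, j]), collapse = "")
    }
  rownames(tok) <- m$taxa
  tok
}

#' Read a character-taxon matrix in TNT or NEXUS format
#'
#' Parses the `xread` block of a TNT file or the DATA/CHARACTERS block of a
#' NEXUS file. `?` maps to missing, `-` to inapplicable, and bracketed
#' (`[01]`, TNT) or parenthesized/braced (`(01)`, `{01}`, NEXUS) groups to
#' polymorphic state sets. Parsed dimensions must match the declared ones.
#'
#' @param file path to the input file (or `NULL` when `text` is given).
#' @param text the file contents as a single string or character vector.
#' @param format `"auto"`, `"tnt"` or `"nexus"`.
#' @return a [char_matrix].
#' @export
read_char_matrix <- function(file = NULL, text = NULL,
                             format = c("auto", "tnt", "nexus")) {
  format <- match.arg(format)
  if (is.null(text)) text <- readLines(file, warn = FALSE)
  text <- paste(text, collapse = "\n")
  if (format == "auto") {
    format <- if (grepl("#NEXUS", text, ignore.case = TRUE)) "nexus"
              else if (grepl("\\bxread\\b", text, ignore.case = TRUE)) "tnt"
              else stopf("cannot auto-detect format (no #NEXUS and no xread)")
  }
  if (format == "tnt") parse_tnt(text) else parse_nexus(text)
}

# split a symbol string into cell tokens, honoring [..], (..), {..}
split_symbols <- function(s, what) {
  chars <- strsplit(s, "")[[1]]
  toks <- character(0)
  i <- 1
  closers <- c("[" = "]", "(" = ")", "{" = "}")
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch %in% names(closers)) {
      j <- i + 1
      while (j <= length(chars) && chars[j] != closers[ch]) j <- j + 1
      if (j > length(chars)) stopf("unterminated '%s' group in %s", ch, what)
      grp <- chars[(i + 1):(j - 1)]
      grp <- grp[grp != " "]
      if (length(grp) < 2 || !all(grepl("^[0-9]$", grp)))
        stopf("polymorphic group must contain >= 2 state digits in %s", what)
      toks <- c(toks, paste(grp, collapse = ""))
      i <- j + 1
    } else if (grepl("^[0-9?\\-]$", ch)) {
      toks <- c(toks, ch)
      i <- i + 1
    } else if (ch %in% c(" ", "\t")) {
      i <- i + 1
    } else {
      stopf("undeclared state symbol '%s' in %s", ch, what)
    }
  }
  toks
}

parse_tnt <- function(text) {
  # strip comments ('...' titles are handled below)
  body <- sub(".*\\bxread\\b", "", text, ignore.case = TRUE)
  # optional quoted title
  body <- sub("^\\s*'[^']*'", "", body)
  body <- sub("^\\s*\"[^\"]*\"", "", body)
  m <- regmatches(body, regexec("^\\s*(\\d+)\\s+(\\d+)", body))[[1]]
  if (length(m) != 3) stopf("TNT: expected 'nchar ntax' after xread")
  n_char <- as.integer(m[2]); n_taxa <- as.integer(m[3])
  body <- sub("^\\s*\\d+\\s+\\d+", "", body)
  body <- sub("(?s);.*$", "", body, perl = TRUE)
  lines <- strsplit(body, "\n")[[1]]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (any(grepl("^&", lines)))
    stopf("TNT: interleaved (&) matrices are not supported")
  taxa <- character(0)
  rows <- list()
  for (ln in lines) {
    sp <- regmatches(ln, regexec("^(\\S+)\\s*(.*)$", ln))[[1]]
    if (length(sp) != 3) stopf("TNT: malformed row '%s'", ln)
    lab <- normalize_label(sp[2])
    toks <- split_symbols(sp[3], sprintf("row '%s'", lab))
    if (lab %in% taxa) stopf("duplicate taxon label '%s'", lab)
    if (length(toks) != n_char)
      stopf("dimension mismatch: taxon '%s' has %d characters, declared %d",
            lab, length(toks), n_char)
    taxa <- c(taxa, lab)
    rows[[lab]] <- toks
  }
  if (length(taxa) != n_taxa)
    stopf("dimension mismatch: %d taxa parsed, %d declared",
          length(taxa), n_taxa)
  cells <- do.call(rbind, rows)
  if (is.null(cells)) cells <- matrix(character(0), 0, n_char)
  char_matrix(cells, taxa = taxa)
}

parse_nexus <- function(text) {
  if (!grepl("#NEXUS", text, ignore.case = TRUE))
    stopf("NEXUS: missing #NEXUS header")
  # remove [...] comments outside the matrix? NEXUS comments conflict with
  # TNT-style polymorphism; NEXUS polymorphism uses () or {}, so [..] here
  # is always a comment.
  text <- gsub("\\[[^]]*\\]", "", text)
  blk <- regmatches(text, regexec(
    "(?is)begin\\s+(data|characters)\\s*;(.*?)end\\s*;", text, perl = TRUE))[[1]]
  if (length(blk) < 3) stopf("NEXUS: no DATA or CHARACTERS block found")
  blk <- blk[3]
  dims <- regmatches(blk, regexec(
    "(?is)dimensions[^;]*ntax\\s*=\\s*(\\d+)[^;]*nchar\\s*=\\s*(\\d+)",
    blk, perl = TRUE))[[1]]
  if (length(dims) < 3) {
    dims <- regmatches(blk, regexec(
      "(?is)dimensions[^;]*nchar\\s*=\\s*(\\d+)[^;]*ntax\\s*=\\s*(\\d+)",
      blk, perl = TRUE))[[1]]
    if (length(dims) < 3) stopf("NEXUS: DIMENSIONS with NTAX and NCHAR required")
    n_char <- as.integer(dims[2]); n_taxa <- as.integer(dims[3])
  } else {
    n_taxa <- as.integer(dims[2]); n_char <- as.integer(dims[3])
  }
  mat <- regmatches(blk, regexec("(?is)matrix(.*?);", blk, perl = TRUE))[[1]]
  if (length(mat) < 2) stopf("NEXUS: MATRIX command not found")
  lines <- strsplit(mat[2], "\n")[[1]]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  taxa <- character(0)
  rows <- list()
  for (ln in lines) {
    if (grepl("^'", ln)) {
      sp <- regmatches(ln, regexec("^'([^']*)'\\s+(.*)$", ln))[[1]]
    } else {
      sp <- regmatches(ln, regexec("^(\\S+)\\s*(.*)$", ln))[[1]]
    }
    if (length(sp) != 3) stopf("NEXUS: malformed matrix row '%s'", ln)
    lab <- normalize_label(sp[2])
    toks <- split_symbols(sp[3], sprintf("row '%s'", lab))
    if (lab %in% taxa) stopf("duplicate taxon label '%s'", lab)
    if (length(toks) != n_char)
      stopf("dimension mismatch: taxon '%s' has %d characters, declared %d",
            lab, length(toks), n_char)
    taxa <- c(taxa, lab)
    rows[[lab]] <- toks
  }
  if (length(taxa) != n_taxa)
    stopf("dimension mismatch: %d taxa parsed, %d declared",
          length(taxa), n_taxa)
  cells <- do.call(rbind, rows)
  if (is.null(cells)) cells <- matrix(character(0), 0, n_char)
  char_matrix(cells, taxa = taxa)
}

#' Write a character-taxon matrix in TNT or NEXUS format
#'
#' The emitted text re-parses to a cell-identical matrix (round-trip law) and
#' is byte-reproducible for identical input.
#'
#' @param m a [char_matrix].
#' @param file optional path; when `NULL` the text is returned.
#' @param format `"tnt"` or `"nexus"`.
#' @return the file text, invisibly when `file` is given.
#' @export
write_char_matrix <- function(m, file = NULL, format = c("tnt", "nexus")) {
  format <- match.arg(format)
  stopifnot(inherits(m, "char_matrix"))
  cells <- cells_of(m)
  alph <- sort(unique(unlist(lapply(seq_len(ncol(m$masks)), function(j)
    mask_to_states(Reduce(bitwOr, m$masks[, j], 0L))))))
  if (length(alph) > 0 && max(alph) > 9)
    stopf("state alphabet exceeds the dialect's symbol set (0-9)")
  fmt_row <- function(i, poly_open, poly_close) {
    toks <- vapply(cells[i, ], function(tok) {
      if (nchar(tok) > 1 && !tok %in% c("?", "-"))
        paste0(poly_open, tok, poly_close)
      else tok
    }, "")
    paste0(m$taxa[i], "  ", paste(toks, collapse = ""))
  }
  if (format == "tnt") {
    rows <- vapply(seq_along(m$taxa), fmt_row, "",
                   poly_open = "[", poly_close = "]")
    out <- c("xread", "'written by fitchsearch'",
             sprintf("%d %d", ncol(m$masks), length(m$taxa)),
             rows, ";")
  } else {
    rows <- vapply(seq_along(m$taxa), fmt_row, "",
                   poly_open = "(", poly_close = ")")
    out <- c("#NEXUS", "BEGIN DATA;",
             sprintf("DIMENSIONS NTAX=%d NCHAR=%d;",
                     length(m$taxa), ncol(m$masks)),
             sprintf("FORMAT SYMBOLS=\"%s\" MISSING=? GAP=-;",
                     paste(alph, collapse = " ")),
             "MATRIX", rows, ";", "END;")
  }
  txt <- paste(out, collapse = "\n")
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}
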
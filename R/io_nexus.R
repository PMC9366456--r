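## NEXUS reading/writing for discrete morphological matrices.
##
## A purpose-built reader is used (rather than ape::read.nexus.data) because
## the data model requires polymorphic cells as state sets, a preserved
## distinction between "?" (missing) and the gap symbol (inapplicable), and
## hard errors on dimension mismatches.

## strip [...] comments (possibly spanning lines); NEXUS comments do not nest
## inside quoted tokens in the matrices handled here
strip_nexus_comments <- function(text) gsub("\\[[^]]*\\]", "", text)

#' Read a NEXUS discrete character matrix
#'
#' Parses the CHARACTERS or DATA block of a NEXUS file with digit state
#' symbols.  Polymorphisms written `{01}` or `(01)` become state sets; the
#' missing symbol (default `?`) becomes `NA`; the gap symbol (default `-`)
#' becomes the inapplicable token `"-"`.  Interleaved matrices are supported.
#'
#' @param path path to a NEXUS file.
#' @param ordered optional integer vector of character indices to flag as
#'   ordered (additive).  Default: all unordered.
#' @param partitions optional named list of partition label -> character
#'   indices, attached to the returned matrix.
#' @return a [character_matrix()].
#' @export
read_nexus_matrix <- function(path, ordered = NULL, partitions = list()) {
  raw <- readLines(path, warn = FALSE)
  text <- strip_nexus_comments(paste(raw, collapse = "\n"))
  if (!grepl("^\\s*#NEXUS", text, ignore.case = TRUE))
    stop("not a NEXUS file (missing #NEXUS header): ", path)

  dim_m <- regmatches(text, regexpr("DIMENSIONS[^;]*;", text, ignore.case = TRUE))
  if (!length(dim_m)) stop("parse error: no DIMENSIONS statement in ", path)
  ntax <- as.integer(sub(".*NTAX\\s*=\\s*([0-9]+).*", "\\1", dim_m,
                         ignore.case = TRUE))
  nchar_ <- as.integer(sub(".*NCHAR\\s*=\\s*([0-9]+).*", "\\1", dim_m,
                           ignore.case = TRUE))
  if (is.na(ntax) || is.na(nchar_))
    stop("parse error: DIMENSIONS must declare NTAX and NCHAR")

  missing_sym <- "?"; gap_sym <- "-"; interleave <- FALSE
  fmt <- regmatches(text, regexpr("FORMAT[^;]*;", text, ignore.case = TRUE))
  if (length(fmt)) {
    gm <- regmatches(fmt, regexpr("MISSING\\s*=\\s*\\S", fmt, ignore.case = TRUE))
    if (length(gm)) missing_sym <- substr(gm, nchar(gm), nchar(gm))
    gg <- regmatches(fmt, regexpr("GAP\\s*=\\s*\\S", fmt, ignore.case = TRUE))
    if (length(gg)) gap_sym <- substr(gg, nchar(gg), nchar(gg))
    interleave <- grepl("INTERLEAVE", fmt, ignore.case = TRUE)
  }

  mat_start <- regexpr("\\bMATRIX\\b", text, ignore.case = TRUE)
  if (mat_start < 0) stop("parse error: no MATRIX statement in ", path)
  rest <- substr(text, mat_start + attr(mat_start, "match.length"), nchar(text))
  mat_end <- regexpr(";", rest, fixed = TRUE)
  if (mat_end < 0) stop("parse error: MATRIX not terminated by ';'")
  body <- substr(rest, 1L, mat_end - 1L)

  lines <- strsplit(body, "\n", fixed = TRUE)[[1]]
  rows <- list()
  for (li in seq_along(lines)) {
    ln <- trimws(lines[[li]])
    if (!nzchar(ln)) next
    ## taxon name: quoted or up to first whitespace
    if (startsWith(ln, "'")) {
      m <- regexpr("^'([^']*)'", ln)
      name <- sub("^'([^']*)'.*", "\\1", ln)
      seq_part <- trimws(substr(ln, attr(m, "match.length") + 1L, nchar(ln)))
    } else {
      name <- sub("\\s.*$", "", ln)
      seq_part <- trimws(sub("^\\S+", "", ln))
    }
    name <- gsub(" ", "_", name)
    if (!nzchar(seq_part))
      stop("parse error at matrix line ", li, ": taxon '", name,
           "' has no character data")
    toks <- tokenize_states(seq_part, li)
    if (!is.null(rows[[name]])) {
      if (!interleave)
        stop("duplicate taxon '", name, "' in non-interleaved matrix")
      rows[[name]] <- c(rows[[name]], toks)
    } else rows[[name]] <- toks
  }
  if (length(rows) != ntax)
    stop("parse error: matrix has ", length(rows),
         " taxa but DIMENSIONS declares NTAX=", ntax)
  lens <- lengths(rows)
  if (any(lens != nchar_))
    stop("parse error: taxon '", names(rows)[which(lens != nchar_)[1]],
         "' has ", lens[which(lens != nchar_)[1]],
         " characters but DIMENSIONS declares NCHAR=", nchar_)

  cells <- do.call(rbind, rows)
  cells[cells == missing_sym] <- NA_character_
  cells[!is.na(cells) & cells == gap_sym] <- "-"
  ord <- rep(FALSE, nchar_)
  if (!is.null(ordered)) ord[ordered] <- TRUE
  character_matrix(cells, ordered = ord, partitions = partitions)
}

## split a NEXUS state row into single-character tokens, with {..}/(..)
## polymorphism groups collapsed to digit strings
tokenize_states <- function(s, line_no) {
  chars <- strsplit(gsub("\\s", "", s), "")[[1]]
  out <- character(0); i <- 1L; n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "{" || ch == "(") {
      close <- if (ch == "{") "}" else ")"
      j <- i + 1L
      while (j <= n && chars[j] != close) j <- j + 1L
      if (j > n) stop("parse error at matrix line ", line_no,
                      ": unterminated polymorphism group")
      grp <- chars[(i + 1L):(j - 1L)]
      grp <- grp[grp != ","]
      if (!length(grp) || !all(grepl("[0-9]", grp)))
        stop("parse error at matrix line ", line_no,
             ": bad polymorphism group")
      out <- c(out, paste(grp, collapse = ""))
      i <- j + 1L
    } else {
      out <- c(out, ch)
      i <- i + 1L
    }
  }
  out
}

#' Write a character matrix as NEXUS
#'
#' Emits a CHARACTERS block that [read_nexus_matrix()] reparses to an
#' identical object; output is byte-stable for a fixed input.
#'
#' @param x a `character_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_nexus_matrix <- function(x, path) {
  stopifnot(inherits(x, "character_matrix"))
  cells <- x$cells
  enc <- function(v) {
    v <- ifelse(is.na(v), "?", v)
    v <- ifelse(nchar(v) > 1L & v != "-", paste0("{", v, "}"), v)
    paste(v, collapse = "")
  }
  symbols <- sort(unique(unlist(strsplit(cells[!is.na(cells) & cells != "-"], ""))))
  if (!length(symbols)) symbols <- "0"
  name_w <- max(nchar(x$taxa)) + 2L
  lines <- c("#NEXUS", "", "BEGIN CHARACTERS;",
             sprintf("\tDIMENSIONS NTAX=%d NCHAR=%d;", length(x$taxa), x$n_chars),
             sprintf("\tFORMAT DATATYPE=STANDARD SYMBOLS=\"%s\" MISSING=? GAP=-;",
                     paste(symbols, collapse = " ")),
             "\tMATRIX")
  for (i in seq_along(x$taxa)) {
    lines <- c(lines, sprintf("\t%-*s%s", name_w, x$taxa[i], enc(cells[i, ])))
  }
  lines <- c(lines, "\t;", "END;")
  writeLines(lines, path)
  invisible(path)
}
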
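## Per-taxon metadata: clade assignment and body-size category.

#' Read a per-taxon metadata table
#'
#' Reads a delimited table (comma or tab, chosen by file extension) with a
#' header containing at least `taxon` and `clade` columns and optionally
#' `size_category`.  Taxon names are matched against the matrix after
#' normalising spaces to underscores (case-sensitive otherwise).  Matrix
#' taxa without a metadata row are retained with `clade = NA` and flagged
#' `unassigned`; metadata rows naming taxa absent from the matrix are
#' dropped with a warning.
#'
#' @param path CSV/TSV file.
#' @param matrix a [character_matrix()] defining the taxon universe, or a
#'   character vector of taxon names.
#' @return a data.frame of class `taxon_metadata` with one row per matrix
#'   taxon: `taxon`, `clade`, `size_category`, `unassigned`; unmatched
#'   metadata rows are attached as attribute `"unmatched"`.
#' @export
read_metadata <- function(path, matrix) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, strip.white = TRUE)
  names(df) <- tolower(names(df))
  if (!"taxon" %in% names(df))
    stop("metadata table must have a 'taxon' column")
  taxon_metadata(df, matrix)
}

#' Build a validated taxon metadata table
#'
#' @param df data.frame with columns `taxon`, `clade` and optionally
#'   `size_category` (one of small, medium, large, very_large).
#' @param matrix a [character_matrix()] or character vector of taxon names.
#' @return a `taxon_metadata` data.frame (see [read_metadata()]).
#' @export
taxon_metadata <- function(df, matrix) {
  taxa <- if (inherits(matrix, "character_matrix")) matrix$taxa
          else as.character(matrix)
  df$taxon <- gsub(" ", "_", df$taxon)
  if (!"size_category" %in% names(df)) df$size_category <- NA_character_
  bad <- !is.na(df$size_category) & !(df$size_category %in% SIZE_CATEGORIES)
  if (any(bad))
    stop("invalid size_category value(s): ",
         paste(unique(df$size_category[bad]), collapse = ", "),
         " (must be one of ", paste(SIZE_CATEGORIES, collapse = ", "), ")")
  if (anyDuplicated(df$taxon))
    stop("duplicate taxon in metadata: ",
         paste(unique(df$taxon[duplicated(df$taxon)]), collapse = ", "))
  unmatched <- setdiff(df$taxon, taxa)
  if (length(unmatched))
    warning(length(unmatched), " metadata row(s) name taxa absent from the ",
            "matrix and were dropped: ",
            paste(utils::head(unmatched, 5), collapse = ", "),
            if (length(unmatched) > 5) ", ..." else "")
  idx <- match(taxa, df$taxon)
  out <- data.frame(taxon = taxa,
                    clade = df$clade[idx],
                    size_category = df$size_category[idx],
                    unassigned = is.na(idx),
                    stringsAsFactors = FALSE)
  if ("notes" %in% names(df)) out$notes <- df$notes[idx]
  attr(out, "unmatched") <- unmatched
  class(out) <- c("taxon_metadata", "data.frame")
  out
}

#' Write a taxon metadata table as CSV
#' @param meta a `taxon_metadata` data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  utils::write.csv(as.data.frame(meta)[, c("taxon", "clade", "size_category")],
                   path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

## named list clade -> tip labels, excluding NA/outgroup-style labels
clade_tip_lists <- function(metadata, exclude = c(NA, "outgroup")) {
  keep <- !(metadata$clade %in% exclude) & !is.na(metadata$clade)
  split(metadata$taxon[keep], metadata$clade[keep])
}
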
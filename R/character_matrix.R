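#' Discrete morphological character matrix
#'
#' The central data container: taxa in rows, characters in columns.  Each
#' cell is a set of small non-negative integer states encoded as a string of
#' digits ("0", "02" for the polymorphism \{0,2\}), `NA` for missing ("?") or
#' `"-"` for inapplicable.  Missing and inapplicable are kept distinct in the
#' container, but all dissimilarity computations treat both as "not scored"
#' (see the methods vignette for the rationale).
#'
#' @param cells character matrix with unique rownames (taxa); entries are
#'   digit strings, `NA` (missing) or `"-"` (inapplicable).
#' @param ordered logical vector, one per character: is the character treated
#'   as ordered (additive)?  Default all unordered.
#' @param partitions named list mapping partition labels to character indices
#'   (or column names).  Labels must come from `partition_vocabulary`.
#' @param partition_vocabulary controlled vocabulary of admissible partition
#'   labels.
#' @return an object of class `character_matrix` with fields `cells`,
#'   `taxa`, `n_chars`, `char_meta` (data frame with `n_observed_states`,
#'   `ordered`), `partitions`.
#' @export
character_matrix <- function(cells, ordered = NULL, partitions = list(),
                             partition_vocabulary = c("skull", "postcranium",
                                                      "snout", "temporal",
                                                      "dentition")) {
  if (!is.matrix(cells) || !is.character(cells))
    stop("`cells` must be a character matrix")
  taxa <- rownames(cells)
  if (is.null(taxa) || anyNA(taxa)) stop("`cells` must have taxon rownames")
  if (anyDuplicated(taxa)) {
    stop("duplicate taxon name(s): ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  }
  nc <- ncol(cells)
  ok <- is.na(cells) | cells == "-" | grepl("^[0-9]+$", cells)
  if (!all(ok)) {
    bad <- which(!ok)[1L]
    stop("invalid cell value '", cells[bad], "' at (",
         taxa[(bad - 1L) %% nrow(cells) + 1L], ", char ",
         (bad - 1L) %/% nrow(cells) + 1L, ")")
  }
  ## normalise polymorphisms: sorted unique digits
  poly <- which(!is.na(cells) & cells != "-" & nchar(cells) > 1L)
  if (length(poly)) {
    cells[poly] <- vapply(strsplit(cells[poly], ""), function(s)
      paste(sort(unique(s)), collapse = ""), character(1))
  }
  if (is.null(colnames(cells))) colnames(cells) <- paste0("c", seq_len(nc))

  n_obs <- integer(nc)
  for (j in seq_len(nc)) {
    v <- cells[, j]
    v <- v[!is.na(v) & v != "-"]
    n_obs[j] <- length(unique(unlist(strsplit(v, ""))))
  }
  if (is.null(ordered)) ordered <- rep(FALSE, nc)
  stopifnot(is.logical(ordered), length(ordered) == nc)

  vocab <- unique(c(partition_vocabulary, names(partitions)))
  parts <- lapply(partitions, function(idx) {
    if (is.character(idx)) idx <- match(idx, colnames(cells))
    idx <- as.integer(idx)
    if (anyNA(idx) || any(idx < 1L | idx > nc))
      stop("partition refers to unknown characters")
    sort(unique(idx))
  })
  if (length(parts) && !all(names(parts) %in% vocab))
    stop("partition label(s) outside the controlled vocabulary: ",
         paste(setdiff(names(parts), vocab), collapse = ", "))

  structure(list(cells = cells, taxa = taxa, n_chars = nc,
                 char_meta = data.frame(character = colnames(cells),
                                        n_observed_states = n_obs,
                                        ordered = ordered,
                                        stringsAsFactors = FALSE),
                 partitions = parts,
                 partition_vocabulary = vocab),
            class = "character_matrix")
}

#' @export
print.character_matrix <- function(x, ...) {
  n_missing <- sum(is.na(x$cells))
  n_inap <- sum(x$cells == "-", na.rm = TRUE)
  cat("character_matrix:", length(x$taxa), "taxa x", x$n_chars, "characters\n")
  cat("  missing cells:", n_missing, " inapplicable:", n_inap,
      " ordered characters:", sum(x$char_meta$ordered), "\n")
  if (length(x$partitions))
    cat("  partitions:", paste(sprintf("%s(%d)", names(x$partitions),
                                       lengths(x$partitions)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.character_matrix <- function(x) c(length(x$taxa), x$n_chars)

#' Subset a character matrix by taxa and/or characters
#'
#' @param x a `character_matrix`.
#' @param taxa taxon names to keep (default all).
#' @param chars character indices or names to keep (default all).
#' @return a `character_matrix`.
#' @export
subset_matrix <- function(x, taxa = NULL, chars = NULL) {
  stopifnot(inherits(x, "character_matrix"))
  ti <- if (is.null(taxa)) seq_along(x$taxa) else match(taxa, x$taxa)
  if (anyNA(ti)) stop("unknown taxa: ", paste(taxa[is.na(ti)], collapse = ", "))
  cj <- if (is.null(chars)) seq_len(x$n_chars)
        else if (is.character(chars)) match(chars, colnames(x$cells))
        else as.integer(chars)
  if (anyNA(cj) || any(cj < 1L | cj > x$n_chars)) stop("unknown characters")
  parts <- lapply(x$partitions, function(idx) match(intersect(idx, cj), cj))
  parts <- parts[lengths(parts) > 0L]
  character_matrix(x$cells[ti, cj, drop = FALSE],
                   ordered = x$char_meta$ordered[cj],
                   partitions = parts,
                   partition_vocabulary = x$partition_vocabulary)
}

## Integer bitmask representation: bit s set iff state s in the cell's set;
## 0 = not scored (missing or inapplicable).  Used by all distance code.
state_masks <- function(x) {
  stopifnot(inherits(x, "character_matrix"))
  m <- matrix(0L, nrow = length(x$taxa), ncol = x$n_chars,
              dimnames = list(x$taxa, colnames(x$cells)))
  cells <- x$cells
  scored <- !is.na(cells) & cells != "-"
  idx <- which(scored)
  if (length(idx)) {
    masks <- vapply(strsplit(cells[idx], ""), function(s)
      sum(bitwShiftL(1L, as.integer(s))), integer(1))
    m[idx] <- masks
  }
  m
}

## decode a bitmask into its integer states
mask_states <- function(mask) which(bitwAnd(mask, bitwShiftL(1L, 0:9)) > 0L) - 1L
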
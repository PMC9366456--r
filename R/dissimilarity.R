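## Pairwise morphological dissimilarity (MORD) and patristic morphological
## distances, plus the pair table joining them for saturation analyses.

#' MORD pairwise dissimilarity between taxa
#'
#' For each pair of taxa the dissimilarity is the mean per-character
#' difference over characters scored in both (the maximum observable
#' rescaled distance).  Unordered characters contribute 0 when the state
#' sets intersect and 1 otherwise; ordered characters contribute the
#' minimum absolute state difference between the sets, rescaled by that
#' character's observed state range.  Missing and inapplicable cells are
#' both "not scored".  Pairs with no comparable character are UNDEFINED
#' (`NA`).
#'
#' @param x a [character_matrix()].
#' @param partition optional partition label; restricts the computation to
#'   characters carrying that label.
#' @param chars optional explicit character indices (overrides `partition`).
#' @return a `distance_matrix` object (fields `taxa`, `value`, `kind`,
#'   `n_comparable`) with `kind = "dissimilarity"`.
#' @export
mord_dissimilarity <- function(x, partition = NULL, chars = NULL) {
  stopifnot(inherits(x, "character_matrix"))
  if (length(x$taxa) < 2L) stop("matrix must contain at least 2 taxa")
  if (is.null(chars)) {
    if (!is.null(partition)) {
      chars <- x$partitions[[partition]]
      if (is.null(chars) || !length(chars))
        stop("partition '", partition, "' is empty or undeclared")
    } else chars <- seq_len(x$n_chars)
  }
  masks <- state_masks(x)[, chars, drop = FALSE]
  ordered <- x$char_meta$ordered[chars]
  res <- mord_from_masks(masks, ordered)
  structure(list(taxa = x$taxa, value = res$D, kind = "dissimilarity",
                 n_comparable = res$n_comp),
            class = "distance_matrix")
}

## core MORD on a bitmask matrix (taxa x chars); ordered = logical per char
mord_from_masks <- function(masks, ordered = rep(FALSE, ncol(masks))) {
  n <- nrow(masks)
  taxa <- rownames(masks)
  ## fast path: unordered characters, no polymorphisms (every mask a power
  ## of two or zero) -> matches/comparable via crossproducts
  if (!any(ordered) && all(bitwAnd(masks, pmax(masks - 1L, 0L)) == 0L)) {
    S <- (masks > 0L) * 1
    comp <- tcrossprod(S)
    match_ct <- matrix(0, n, n)
    for (s in unique(masks[masks > 0L]))
      match_ct <- match_ct + tcrossprod((masks == s) * 1)
    D <- 1 - match_ct / comp
    D[comp == 0] <- NA_real_
    diag(D) <- 0
    dimnames(D) <- list(taxa, taxa)
    storage.mode(comp) <- "integer"
    diag(comp) <- 0L
    dimnames(comp) <- list(taxa, taxa)
    return(list(D = D, n_comp = comp))
  }
  D <- matrix(0, n, n, dimnames = list(taxa, taxa))
  n_comp <- matrix(0L, n, n, dimnames = list(taxa, taxa))
  has_ord <- any(ordered)
  if (has_ord) {
    ord_idx <- which(ordered)
    ## per ordered character: observed range and decoded state lists
    ranges <- numeric(length(ord_idx))
    sets <- vector("list", length(ord_idx))
    for (u in seq_along(ord_idx)) {
      col <- masks[, ord_idx[u]]
      states <- sort(unique(unlist(lapply(col[col > 0L], mask_states))))
      ranges[u] <- if (length(states) > 1L) diff(range(states)) else 0
      sets[[u]] <- lapply(col, function(m) if (m > 0L) mask_states(m) else integer(0))
    }
  }
  unord <- which(!ordered)
  for (i in seq_len(n - 1L)) {
    js <- (i + 1L):n
    A <- masks[i, , drop = TRUE]
    B <- masks[js, , drop = FALSE]
    scoredA <- A > 0L
    comp <- B > 0L & rep(scoredA, each = length(js))
    ## unordered: difference 1 where state sets do not intersect
    diffsum <- numeric(length(js))
    if (length(unord)) {
      Au <- matrix(A[unord], nrow = length(js), ncol = length(unord), byrow = TRUE)
      Bu <- B[, unord, drop = FALSE]
      inter <- bitwAnd(Bu, Au) > 0L
      diffsum <- rowSums(comp[, unord, drop = FALSE] & !inter)
    }
    if (has_ord) {
      for (u in seq_along(ord_idx)) {
        c0 <- ord_idx[u]
        if (!scoredA[c0] || ranges[u] == 0) next
        sa <- sets[[u]][[i]]
        for (jj in seq_along(js)) {
          sb <- sets[[u]][[js[jj]]]
          if (!length(sb)) next
          d <- min(abs(outer(sa, sb, "-"))) / ranges[u]
          diffsum[jj] <- diffsum[jj] + d
        }
      }
    }
    ncmp <- rowSums(comp)
    D[i, js] <- D[js, i] <- ifelse(ncmp > 0L, diffsum / ncmp, NA_real_)
    n_comp[i, js] <- n_comp[js, i] <- as.integer(ncmp)
  }
  diag(D) <- 0
  list(D = D, n_comp = n_comp)
}

#' Patristic morphological distances on a changes tree
#'
#' The distance between two taxa is the sum of branch lengths (expected
#' character-state changes) on the unique path connecting them.
#'
#' @param tree a [changes_tree()] (or a `time_tree`, giving distances in
#'   Myr).
#' @return a `distance_matrix` with `kind = "patristic"`.
#' @export
patristic_distances <- function(tree) {
  phy <- if (inherits(tree, "changes_tree") || inherits(tree, "time_tree"))
    tree$phylo else tree
  stopifnot(inherits(phy, "phylo"))
  if (any(phy$edge.length < 0)) stop("negative branch length")
  dd <- ape::dist.nodes(phy)[seq_len(ape::Ntip(phy)), seq_len(ape::Ntip(phy))]
  dimnames(dd) <- list(phy$tip.label, phy$tip.label)
  structure(list(taxa = phy$tip.label, value = dd, kind = "patristic"),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat("distance_matrix (", x$kind, "): ", length(x$taxa), " taxa, ",
      sum(is.na(x$value[upper.tri(x$value)])), " undefined pair(s)\n", sep = "")
  invisible(x)
}

#' Assemble the taxon-pair table used by saturation analyses
#'
#' One row per unordered pair of taxa in `scope`, joining dissimilarity,
#' patristic distance, the age of the pair's most recent common ancestor on
#' the time tree, and (when metadata are supplied) clade and size labels.
#' Pairs with undefined dissimilarity are dropped with a message.
#'
#' @param D dissimilarity `distance_matrix`.
#' @param P patristic `distance_matrix`.
#' @param time_tree a [time_tree()] supplying MRCA ages.
#' @param metadata optional [taxon_metadata()].
#' @param scope optional character vector of taxa to restrict to.
#' @return a data.frame of class `pair_table` with columns `taxon_a`,
#'   `taxon_b`, `D`, `P`, `mrca_age` and group labels.
#' @export
build_pair_table <- function(D, P, time_tree, metadata = NULL, scope = NULL) {
  stopifnot(inherits(D, "distance_matrix"), inherits(P, "distance_matrix"),
            inherits(time_tree, "time_tree"))
  taxa <- Reduce(intersect, list(D$taxa, P$taxa, time_tree$phylo$tip.label))
  if (!is.null(scope)) taxa <- intersect(taxa, scope)
  if (length(taxa) < 2L)
    stop("fewer than 2 taxa shared by the distance matrices and tree",
         if (!is.null(scope)) " within scope" else "")
  phy <- time_tree$phylo
  mrca <- ape::mrca(phy)
  tipno <- match(taxa, phy$tip.label)
  pairs <- utils::combn(seq_along(taxa), 2L)
  a <- taxa[pairs[1L, ]]; b <- taxa[pairs[2L, ]]
  out <- data.frame(taxon_a = a, taxon_b = b,
                    D = D$value[cbind(a, b)],
                    P = P$value[cbind(a, b)],
                    mrca_age = time_tree$node_age[
                      mrca[cbind(tipno[pairs[1L, ]], tipno[pairs[2L, ]])]],
                    stringsAsFactors = FALSE)
  if (!is.null(metadata)) {
    ia <- match(a, metadata$taxon); ib <- match(b, metadata$taxon)
    out$clade_a <- metadata$clade[ia]; out$clade_b <- metadata$clade[ib]
    out$size_a <- metadata$size_category[ia]
    out$size_b <- metadata$size_category[ib]
  }
  dropped <- sum(is.na(out$D))
  if (dropped) {
    message(dropped, " pair(s) with undefined dissimilarity dropped")
    out <- out[!is.na(out$D), , drop = FALSE]
  }
  if (!nrow(out)) warning("all pairs have undefined dissimilarity")
  rownames(out) <- NULL
  class(out) <- c("pair_table", "data.frame")
  out
}

#' Restrict a pair table to pairs diverging within a time window
#'
#' @param pairs a `pair_table`.
#' @param window numeric length-2, `c(old, young)` in Ma with old > young
#'   (e.g. `c(320, 272)` for the Carboniferous-early Permian).
#' @return the filtered `pair_table` (rows with
#'   `young <= mrca_age <= old`).
#' @export
filter_pairs_by_divergence <- function(pairs, window) {
  stopifnot(inherits(pairs, "data.frame"), length(window) == 2L)
  if (!(window[1] > window[2]))
    stop("window must be c(old, young) with old > young, got (",
         window[1], ", ", window[2], ")")
  out <- pairs[pairs$mrca_age >= window[2] & pairs$mrca_age <= window[1], ,
               drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pair_table", "data.frame")
  out
}

#' Write / read a pair table as TSV (fixed column order)
#' @param pairs a `pair_table`.
#' @param path file path.
#' @return `path` (writer) or the `pair_table` (reader).
#' @export
write_pair_table <- function(pairs, path) {
  lead <- intersect(c("taxon_a", "taxon_b", "D", "P", "mrca_age"), names(pairs))
  cols <- c(lead, setdiff(names(pairs), lead))
  utils::write.table(as.data.frame(pairs)[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pair_table
#' @export
read_pair_table <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  class(out) <- c("pair_table", "data.frame")
  out
}

#' Write a distance matrix as square CSV
#' @param d a `distance_matrix`.
#' @param path file path.
#' @export
write_distance_matrix <- function(d, path) {
  utils::write.csv(d$value, path, row.names = TRUE, quote = FALSE)
  invisible(path)
}
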
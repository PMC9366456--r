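## Time-calibrated trees and change-unit trees.
##
## Both containers wrap an ape "phylo" topology.  A time_tree carries node
## ages in Ma (root oldest, increasing into the past) and optional per-branch
## relative evolutionary rates; a changes_tree carries branch lengths in
## expected character-state changes.

#' Build a time-calibrated tree
#'
#' Node ages are computed from the phylo branch lengths and a root-age
#' anchor.  If no anchor is given the youngest tip is placed at 0 Ma.
#'
#' @param phylo a rooted `ape::phylo` with non-negative branch lengths in Myr.
#' @param root_age age of the root in Ma; default places the youngest tip at
#'   0 Ma.
#' @param branch_rate optional numeric vector of per-branch relative rates,
#'   one per row of `phylo$edge` (NA where unknown).
#' @param tip_age_range optional 2-column matrix (min, max Ma) of
#'   first-appearance ranges, rownames = tip labels.
#' @return an object of class `time_tree`: list with `phylo`, `root_age`,
#'   `node_age` (length Ntip+Nnode), `branch_rate`, `tip_age_range`.
#' @export
time_tree <- function(phylo, root_age = NULL, branch_rate = NULL,
                      tip_age_range = NULL) {
  stopifnot(inherits(phylo, "phylo"))
  if (is.null(phylo$edge.length)) stop("tree has no branch lengths")
  if (any(phylo$edge.length < 0)) stop("negative branch length in tree")
  if (!ape::is.rooted(phylo)) stop("tree must be rooted")
  depth <- ape::node.depth.edgelength(phylo)
  if (is.null(root_age)) root_age <- max(depth)
  node_age <- root_age - depth
  if (min(node_age) < -1e-6)
    stop("root_age anchor places ", sum(node_age < -1e-6),
         " node(s) at negative age")
  node_age[node_age < 0] <- 0
  if (!is.null(branch_rate)) {
    stopifnot(length(branch_rate) == nrow(phylo$edge))
    if (any(branch_rate < 0, na.rm = TRUE)) stop("negative branch rate")
  }
  if (!is.null(tip_age_range)) {
    stopifnot(is.matrix(tip_age_range), ncol(tip_age_range) == 2L,
              !is.null(rownames(tip_age_range)))
  }
  structure(list(phylo = phylo, root_age = root_age, node_age = node_age,
                 branch_rate = branch_rate, tip_age_range = tip_age_range),
            class = "time_tree")
}

#' @export
print.time_tree <- function(x, ...) {
  cat("time_tree:", ape::Ntip(x$phylo), "tips, root age",
      format(x$root_age, digits = 6), "Ma")
  if (!is.null(x$branch_rate))
    cat(";", sum(!is.na(x$branch_rate)), "branches with rates")
  cat("\n")
  invisible(x)
}

## tip sets (sorted labels) below every internal node
clade_tip_sets <- function(phylo) {
  pp <- ape::prop.part(phylo)
  lab <- attr(pp, "labels")
  lapply(pp, function(i) sort(lab[i]))
}

#' Build a tree with branch lengths in expected character changes
#'
#' @param phylo a rooted `ape::phylo`; branch lengths are expected
#'   character-state changes (per character).
#' @param reference optional [time_tree()] whose topology this tree must
#'   match; congruence (identical clade sets) is enforced on construction.
#' @return an object of class `changes_tree`.
#' @export
changes_tree <- function(phylo, reference = NULL) {
  stopifnot(inherits(phylo, "phylo"))
  if (is.null(phylo$edge.length)) stop("tree has no branch lengths")
  if (any(phylo$edge.length < 0)) stop("negative branch length in tree")
  if (!ape::is.rooted(phylo)) stop("tree must be rooted")
  if (!is.null(reference)) {
    stopifnot(inherits(reference, "time_tree"))
    if (!setequal(phylo$tip.label, reference$phylo$tip.label))
      stop("changes tree and reference time tree have different tip sets")
    a <- clade_tip_sets(phylo)
    b <- clade_tip_sets(reference$phylo)
    key <- function(s) vapply(s, paste, character(1), collapse = "\r")
    if (!setequal(key(a), key(b)))
      stop("changes tree topology is not congruent with the reference tree")
  }
  structure(list(phylo = phylo), class = "changes_tree")
}

#' @export
print.changes_tree <- function(x, ...) {
  cat("changes_tree:", ape::Ntip(x$phylo), "tips, total length",
      format(sum(x$phylo$edge.length), digits = 6), "expected changes\n")
  invisible(x)
}

## ---------------------------------------------------------------------------
## Annotated-Newick parsing.  ape drops [&...] comment metadata, so trees
## carrying MrBayes-style per-branch annotations are parsed here and handed
## back as a phylo plus a per-edge annotation table.

## parse "key=value,key={a,b}" into a named character vector
parse_annotation <- function(s) {
  if (!nzchar(s)) return(character(0))
  s <- sub("^&", "", s)
  out <- character(0); keys <- character(0)
  i <- 1L; n <- nchar(s); buf <- ""
  depth <- 0L
  flush <- function(buf) {
    eq <- regexpr("=", buf, fixed = TRUE)
    if (eq > 0) {
      keys <<- c(keys, substr(buf, 1L, eq - 1L))
      out <<- c(out, substr(buf, eq + 1L, nchar(buf)))
    }
  }
  while (i <= n) {
    ch <- substr(s, i, i)
    if (ch == "{") depth <- depth + 1L
    if (ch == "}") depth <- depth - 1L
    if (ch == "," && depth == 0L) { flush(buf); buf <- "" } else buf <- paste0(buf, ch)
    i <- i + 1L
  }
  flush(buf)
  names(out) <- keys
  out
}

## Recursive-descent parser for Newick with [&...] comments after node
## labels and/or after the colon (MrBayes places branch annotations in
## either position).  Returns list(phylo, annotations) where annotations is
## a list (one per edge, in phylo$edge row order) of named character vectors.
parse_annotated_newick <- function(string) {
  s <- gsub("\\s", "", string)
  pos <- 1L; n <- nchar(s)
  peek <- function() if (pos <= n) substr(s, pos, pos) else ""
  take_comment <- function() {
    ann <- character(0)
    while (peek() == "[") {
      close <- regexpr("]", substr(s, pos, n), fixed = TRUE)
      if (close < 0) stop("parse error: unterminated [ comment")
      ann <- c(ann, parse_annotation(substr(s, pos + 1L, pos + close - 2L)))
      pos <<- pos + close
    }
    ann
  }
  take_label <- function() {
    if (peek() == "'") {
      close <- regexpr("'", substr(s, pos + 1L, n), fixed = TRUE)
      if (close < 0) stop("parse error: unterminated quoted label")
      lab <- substr(s, pos + 1L, pos + close - 1L)
      pos <<- pos + close + 1L
      return(lab)
    }
    m <- regexpr("^[^][(),:;]+", substr(s, pos, n))
    if (m < 0) return("")
    lab <- substr(s, pos, pos + attr(m, "match.length") - 1L)
    pos <<- pos + attr(m, "match.length")
    lab
  }
  ## node store
  nodes <- new.env()
  nodes$children <- list(); nodes$label <- character(0)
  nodes$len <- numeric(0); nodes$ann <- list()
  new_node <- function() {
    id <- length(nodes$label) + 1L
    nodes$children[[id]] <- integer(0)
    nodes$label[id] <- ""
    nodes$len[id] <- NA_real_
    nodes$ann[[id]] <- character(0)
    id
  }
  parse_clade <- function() {
    id <- new_node()
    if (peek() == "(") {
      pos <<- pos + 1L
      repeat {
        child <- parse_clade()
        nodes$children[[id]] <- c(nodes$children[[id]], child)
        if (peek() == ",") { pos <<- pos + 1L; next }
        if (peek() == ")") { pos <<- pos + 1L; break }
        stop("parse error: expected ',' or ')' at position ", pos)
      }
      nodes$label[id] <- take_label()
    } else {
      lab <- take_label()
      if (!nzchar(lab)) stop("parse error: empty tip label at position ", pos)
      nodes$label[id] <- lab
    }
    ann <- take_comment()
    if (peek() == ":") {
      pos <<- pos + 1L
      ann <- c(ann, take_comment())
      m <- regexpr("^[+-]?[0-9.]+([eE][+-]?[0-9]+)?", substr(s, pos, n))
      if (m < 0) stop("parse error: missing branch length after ':'")
      nodes$len[id] <- as.numeric(substr(s, pos, pos + attr(m, "match.length") - 1L))
      pos <<- pos + attr(m, "match.length")
      ann <- c(ann, take_comment())
    }
    nodes$ann[[id]] <- ann
    id
  }
  root <- parse_clade()
  if (peek() != ";") stop("parse error: tree not terminated by ';'")

  ## convert to ape numbering: tips 1..Ntip (order of appearance),
  ## internals Ntip+1.. in preorder with the root first
  is_tip <- lengths(nodes$children) == 0L
  tip_ids <- which(is_tip); int_ids <- integer(0)
  preorder <- function(id) {
    if (!is_tip[id]) {
      int_ids <<- c(int_ids, id)
      for (ch in nodes$children[[id]]) preorder(ch)
    }
  }
  preorder(root)
  ntip <- length(tip_ids)
  newid <- integer(length(nodes$label))
  newid[tip_ids] <- seq_len(ntip)
  newid[int_ids] <- ntip + seq_along(int_ids)

  edges <- matrix(0L, 0L, 2L); elen <- numeric(0); eann <- list()
  for (id in c(int_ids)) {
    for (ch in nodes$children[[id]]) {
      edges <- rbind(edges, c(newid[id], newid[ch]))
      elen <- c(elen, nodes$len[ch])
      eann[[length(eann) + 1L]] <- nodes$ann[[ch]]
    }
  }
  node_lab <- nodes$label[int_ids]
  if (!any(nzchar(node_lab))) node_lab <- NULL
  phy <- structure(list(edge = edges,
                        edge.length = if (all(is.na(elen))) NULL else elen,
                        Nnode = length(int_ids),
                        tip.label = nodes$label[tip_ids],
                        node.label = node_lab),
                   class = "phylo", order = "cladewise")
  list(phylo = phy, annotations = eann, root_annotation = nodes$ann[[root]])
}

#' Read a (possibly annotated) NEXUS/Newick tree as a time tree
#'
#' Handles plain Newick files and NEXUS TREES blocks (with TRANSLATE
#' tables), including MrBayes-style `[&rate=...]` comment metadata on
#' branches.  Node ages are derived from branch lengths plus a root-age
#' anchor.
#'
#' @param path tree file.
#' @param rate_key name of the per-branch annotation field holding the
#'   relative evolutionary rate (default "rate").
#' @param root_age root-age anchor in Ma; default youngest tip at 0 Ma.
#' @return a [time_tree()]; `branch_rate` is populated where annotations
#'   exist and NA elsewhere (NULL when no branch carries the key).
#' @export
read_annotated_tree <- function(path, rate_key = "rate", root_age = NULL) {
  nwk <- extract_newick(path)
  p <- parse_annotated_newick(nwk$string)
  phy <- p$phylo
  if (!is.null(nwk$translate)) {
    idx <- match(phy$tip.label, names(nwk$translate))
    phy$tip.label[!is.na(idx)] <- unname(nwk$translate[idx[!is.na(idx)]])
  }
  if (is.null(phy$edge.length)) stop("tree has no branch lengths: ", path)
  if (any(phy$edge.length < 0)) stop("negative branch length in ", path)
  rates <- vapply(p$annotations, function(a) {
    v <- suppressWarnings(as.numeric(a[rate_key]))
    if (length(v)) v else NA_real_
  }, numeric(1))
  if (all(is.na(rates))) rates <- NULL
  time_tree(phy, root_age = root_age, branch_rate = rates)
}

#' Read a tree whose branch lengths are expected character changes
#'
#' @param path tree file (Newick or NEXUS).
#' @param reference optional [time_tree()] for a topology congruence check.
#' @return a [changes_tree()].
#' @export
read_changes_tree <- function(path, reference = NULL) {
  nwk <- extract_newick(path)
  p <- parse_annotated_newick(nwk$string)
  phy <- p$phylo
  if (!is.null(nwk$translate)) {
    idx <- match(phy$tip.label, names(nwk$translate))
    phy$tip.label[!is.na(idx)] <- unname(nwk$translate[idx[!is.na(idx)]])
  }
  changes_tree(phy, reference = reference)
}

## pull the first tree statement (and TRANSLATE table) out of a NEXUS or
## plain-Newick file, preserving [&...] comments
extract_newick <- function(path) {
  text <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (!grepl("^\\s*#NEXUS", text, ignore.case = TRUE)) {
    m <- regexpr("\\([^;]*;", text)
    if (m < 0) stop("no Newick tree found in ", path)
    return(list(string = regmatches(text, m), translate = NULL))
  }
  translate <- NULL
  tm <- regexpr("TRANSLATE[^;]*;", text, ignore.case = TRUE)
  if (tm > 0) {
    tt <- substr(text, tm + 9L, tm + attr(tm, "match.length") - 2L)
    entries <- strsplit(trimws(tt), ",")[[1]]
    entries <- trimws(entries)
    keys <- sub("\\s.*$", "", entries)
    vals <- gsub("'", "", sub("^\\S+\\s+", "", entries))
    translate <- stats::setNames(gsub(" ", "_", vals), keys)
  }
  m <- regexpr("\\bTREE\\b[^=]*=", text, ignore.case = TRUE)
  if (m < 0) stop("no TREE statement in NEXUS file ", path)
  rest <- substr(text, m + attr(m, "match.length"), nchar(text))
  ## drop a leading rooting comment like [&R]
  rest <- sub("^\\s*(\\[&[RU]\\])?\\s*", "", rest)
  e <- regexpr(";", rest, fixed = TRUE)
  if (e < 0) stop("TREE statement not terminated by ';' in ", path)
  list(string = substr(rest, 1L, e), translate = translate)
}

#' Write a time tree as annotated NEXUS
#'
#' Branch rates (when present) are emitted as MrBayes-style `[&rate=...]`
#' comments that [read_annotated_tree()] reparses; output is byte-stable.
#'
#' @param tree a [time_tree()].
#' @param path output file.
#' @param rate_key annotation key used for branch rates.
#' @return `path`, invisibly.
#' @export
write_annotated_tree <- function(tree, path, rate_key = "rate") {
  stopifnot(inherits(tree, "time_tree"))
  phy <- tree$phylo
  rates <- tree$branch_rate
  ntip <- ape::Ntip(phy)
  kids <- split(seq_len(nrow(phy$edge)), phy$edge[, 1])
  build <- function(node) {
    rows <- kids[[as.character(node)]]
    parts <- vapply(rows, function(r) {
      child <- phy$edge[r, 2]
      sub <- if (child <= ntip) phy$tip.label[child] else build(child)
      ann <- if (!is.null(rates) && !is.na(rates[r]))
        sprintf("[&%s=%.10g]", rate_key, rates[r]) else ""
      sprintf("%s%s:%.10g", sub, ann, phy$edge.length[r])
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  root <- ntip + 1L
  writeLines(c("#NEXUS", "BEGIN TREES;",
               paste0("\tTREE tree1 = [&R] ", build(root), ";"),
               "END;"), path)
  invisible(path)
}

## ages of all nodes (tips first, then internals), named helper
node_ages <- function(tree) {
  stopifnot(inherits(tree, "time_tree"))
  tree$node_age
}

## per-edge durations in Myr (parent age - child age)
edge_durations <- function(tree) {
  stopifnot(inherits(tree, "time_tree"))
  tree$node_age[tree$phylo$edge[, 1]] - tree$node_age[tree$phylo$edge[, 2]]
}
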
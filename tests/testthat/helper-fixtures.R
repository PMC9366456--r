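# Shared fixtures, all built in code.

# write a small NEXUS matrix file and return its path
write_tiny_nexus <- function(lines, file = tempfile(fileext = ".nex")) {
  writeLines(lines, file)
  file
}

tiny_nexus_lines <- function(matrix_rows, ntax, nchar,
                             symbols = "0 1 2", extra_format = "") {
  c("#NEXUS", "BEGIN DATA;",
    sprintf("DIMENSIONS NTAX=%d NCHAR=%d;", ntax, nchar),
    sprintf("FORMAT DATATYPE=STANDARD SYMBOLS=\"%s\" MISSING=? GAP=-%s;",
            symbols, extra_format),
    "MATRIX", matrix_rows, ";", "END;")
}

# character matrix straight from a list of row strings like "01?{12}-"
cm_from_strings <- function(rows, ordered = NULL) {
  cells <- do.call(rbind, lapply(rows, function(r)
    charsat:::tokenize_states(r, 0L)))
  rownames(cells) <- names(rows)
  cells[cells == "?"] <- NA_character_
  character_matrix(cells, ordered = ordered)
}

# small fixed time tree: ((A:10,B:10):10,C:20); root age settable
tiny_time_tree <- function(root_age = 320) {
  time_tree(ape::read.tree(text = "((A:10,B:10):10,C:20);"),
            root_age = root_age)
}

# exhaustive-enumeration Mk likelihood oracle (sums over all internal-node
# state assignments); independent of the pruning implementation
enum_mk_loglik <- function(phy, trait, n_states, rates, spec) {
  qs <- charsat:::mk_q_matrices(spec, rates)
  reg <- spec$regimes
  if (is.null(reg)) reg <- rep(spec$regime_levels[1], nrow(phy$edge))
  Pm <- lapply(seq_len(nrow(phy$edge)), function(e) {
    Q <- qs[[reg[e]]]
    charsat:::expm_ss(Q * phy$edge.length[e])
  })
  ntip <- ape::Ntip(phy)
  ints <- (ntip + 1L):(ntip + phy$Nnode)
  tipidx <- match(trait[phy$tip.label], spec$state_order)
  grid <- do.call(expand.grid, rep(list(seq_len(n_states)), length(ints)))
  tot <- 0
  for (g in seq_len(nrow(grid))) {
    st <- integer(ntip + phy$Nnode)
    st[ints] <- as.integer(grid[g, ])
    st[seq_len(ntip)] <- tipidx
    p <- 1 / n_states
    for (e in seq_len(nrow(phy$edge)))
      p <- p * Pm[[e]][st[phy$edge[e, 1]], st[phy$edge[e, 2]]]
    tot <- tot + p
  }
  log(tot)
}

# independent shortest-path patristic oracle built on igraph
igraph_patristic <- function(phy) {
  g <- igraph::graph_from_edgelist(apply(phy$edge, 2, as.character),
                                   directed = FALSE)
  igraph::E(g)$weight <- phy$edge.length
  d <- igraph::distances(g)
  tipv <- as.character(seq_len(ape::Ntip(phy)))
  out <- d[tipv, tipv]
  dimnames(out) <- list(phy$tip.label, phy$tip.label)
  out
}
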
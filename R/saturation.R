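## Character-state saturation: Michaelis-Menten asymptote estimation,
## equal-rates null simulation, the 84% confidence-interval decision rule,
## and the node-wise constraint scan.

Z84 <- stats::qnorm(0.92)  # ~1.4051; half-width multiplier of an 84% CI

## core Michaelis-Menten least squares: D ~ vmax * P / (km + P), fitted by
## Levenberg-Marquardt with analytic Jacobian and both parameters bounded
## below at 0 (log-scale restarts guard against bad starts)
fit_mm_core <- function(P, D) {
  n <- length(P)
  if (stats::sd(D) == 0) {
    ## flat data: asymptote is the common value, km degenerate at 0
    return(list(vmax = D[1], km = 0, vmax_se = 0, residual_ss = 0,
                converged = TRUE))
  }
  v0 <- max(D); if (v0 <= 0) v0 <- 1e-6
  k0 <- stats::median(P); if (k0 <= 0) k0 <- 1e-6
  starts <- list(c(v0, k0), c(2 * v0, 5 * k0), c(v0, k0 / 5))
  resid_fn <- function(par) D - par[1] * P / (par[2] + P)
  jac_fn <- function(par) {
    f <- P / (par[2] + P)
    cbind(-f, par[1] * P / (par[2] + P)^2)
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = resid_fn, jac = jac_fn,
                         lower = c(0, 1e-12),
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || deviance(fit) < deviance(best)) best <- fit
  }
  if (is.null(best)) return(list(converged = FALSE))
  par <- coef(best)
  rss <- deviance(best)
  J <- jac_fn(par)
  se <- tryCatch({
    sigma2 <- rss / max(n - 2L, 1L)
    v <- sigma2 * solve(crossprod(J))[1, 1]
    if (is.finite(v) && v >= 0) sqrt(v) else NA_real_
  }, error = function(e) NA_real_)
  list(vmax = par[1], km = par[2], vmax_se = se, residual_ss = rss,
       converged = is.finite(se))
}

#' Fit a Michaelis-Menten saturation curve to a pair table
#'
#' Estimates the asymptote (vmax, the dissimilarity at character-state
#' saturation) and half-saturation constant km of
#' `D = vmax * P / (km + P)` by nonlinear least squares, with an 84%
#' asymptotic-normal confidence interval on vmax
#' (`vmax +/- 1.4051 * SE`).  Underdetermined input (fewer than
#' `min_pairs` rows, or fewer than 3 distinct patristic distances) yields
#' an untestable result rather than an error.
#'
#' @param pairs a `pair_table` (or any data.frame with columns `D`, `P`).
#' @param min_pairs minimum usable pair count for a testable fit
#'   (default 6; a 2-parameter fit with a meaningful CI needs at least
#'   this much).
#' @return an object of class `mm_fit`: `vmax`, `km`, `vmax_se`,
#'   `vmax_ci84`, `n_pairs`, `residual_ss`, `converged`, `untestable`.
#' @export
fit_michaelis_menten <- function(pairs, min_pairs = 6L) {
  stopifnot(is.data.frame(pairs), all(c("D", "P") %in% names(pairs)))
  keep <- is.finite(pairs$D) & is.finite(pairs$P)
  D <- pairs$D[keep]; P <- pairs$P[keep]
  out <- list(vmax = NA_real_, km = NA_real_, vmax_se = NA_real_,
              vmax_ci84 = c(NA_real_, NA_real_), n_pairs = length(D),
              residual_ss = NA_real_, converged = FALSE, untestable = TRUE)
  class(out) <- "mm_fit"
  if (length(D) < min_pairs || length(unique(P)) < 3L) return(out)
  core <- fit_mm_core(P, D)
  if (!isTRUE(core$converged)) return(out)
  out$vmax <- core$vmax; out$km <- core$km
  out$vmax_se <- core$vmax_se
  out$vmax_ci84 <- core$vmax + c(-1, 1) * Z84 * core$vmax_se
  out$residual_ss <- core$residual_ss
  out$converged <- TRUE; out$untestable <- FALSE
  out
}

#' @export
print.mm_fit <- function(x, ...) {
  if (x$untestable) {
    cat("mm_fit: untestable (n_pairs =", x$n_pairs, ")\n")
  } else {
    cat(sprintf("mm_fit: vmax = %.4f (84%% CI %.4f-%.4f), km = %.4f, n = %d\n",
                x$vmax, x$vmax_ci84[1], x$vmax_ci84[2], x$km, x$n_pairs))
  }
  invisible(x)
}

## ---------------------------------------------------------------------------
## Equal-rates null simulation

## forward-simulate every character under a k-state equal-rates Markov chain
## whose expected number of state changes on each branch equals the branch
## length; returns an integer state matrix (taxa x chars, states 0..k-1)
simulate_null_states <- function(phylo, k_per_char) {
  nch <- length(k_per_char)
  ntip <- ape::Ntip(phylo)
  nnode <- ntip + phylo$Nnode
  edge <- phylo$edge; blen <- phylo$edge.length
  states <- matrix(0L, nnode, nch)
  groups <- split(seq_len(nch), k_per_char)
  root <- ntip + 1L
  for (g in groups) {
    k <- k_per_char[g[1]]
    states[root, g] <- sample.int(k, length(g), replace = TRUE) - 1L
  }
  ## preorder: cladewise edge order visits parents before children
  ord <- reorder(phylo, "cladewise")$edge
  oblen <- reorder(phylo, "cladewise")$edge.length
  for (e in seq_len(nrow(ord))) {
    p <- ord[e, 1]; ch <- ord[e, 2]; b <- oblen[e]
    for (g in groups) {
      k <- k_per_char[g[1]]
      s <- states[p, g]
      if (b <= 0) { states[ch, g] <- s; next }
      ## P(state unchanged) under k-state ER with expected changes b
      p_same <- 1 / k + (k - 1) / k * exp(-k * b / (k - 1))
      change <- stats::runif(length(g)) >= p_same
      if (any(change)) {
        shift <- sample.int(k - 1L, sum(change), replace = TRUE)
        s[change] <- (s[change] + shift) %% k
      }
      states[ch, g] <- s
    }
  }
  out <- states[seq_len(ntip), , drop = FALSE]
  rownames(out) <- phylo$tip.label
  out
}

#' Simulate one null character matrix under an equal-rates model
#'
#' Each character evolves independently along the changes tree under a
#' k-state equal-rates Markov process, where k is the character's observed
#' state count in the template (invariant characters use k = 2) and the
#' expected number of changes per branch equals the branch length.  The
#' root state is uniform.  Missing and inapplicable scores are then written
#' into exactly the template's cells.
#'
#' @param changes_tree a [changes_tree()].
#' @param template the empirical [character_matrix()] supplying state
#'   counts and the missing-data mask.
#' @param seed integer seed.
#' @return a [character_matrix()] with the template's dimensions and mask.
#' @export
simulate_null_matrix <- function(changes_tree, template, seed) {
  stopifnot(inherits(changes_tree, "changes_tree"),
            inherits(template, "character_matrix"))
  phy <- changes_tree$phylo
  if (!setequal(phy$tip.label, template$taxa))
    stop("tree and template have different taxon sets")
  k <- pmax(template$char_meta$n_observed_states, 2L)
  states <- with_seed(seed, simulate_null_states(phy, k))
  states <- states[template$taxa, , drop = FALSE]
  cells <- matrix(as.character(states), nrow = nrow(states),
                  dimnames = list(template$taxa, colnames(template$cells)))
  cells[is.na(template$cells)] <- NA_character_
  cells[!is.na(template$cells) & template$cells == "-"] <- "-"
  character_matrix(cells, ordered = template$char_meta$ordered,
                   partitions = template$partitions,
                   partition_vocabulary = template$partition_vocabulary)
}

## internal: one null replicate -> full dissimilarity matrix (fast path,
## masks derived directly from simulated states + template mask)
null_dissimilarity <- function(phy, template_masks, k_per_char, ordered, seed) {
  states <- with_seed(seed, simulate_null_states(phy, k_per_char))
  states <- states[rownames(template_masks), , drop = FALSE]
  masks <- matrix(bitwShiftL(1L, states), nrow(states), ncol(states),
                  dimnames = dimnames(states))
  masks[template_masks == 0L] <- 0L
  mord_from_masks(masks, ordered)$D
}

#' Null distribution of the saturation asymptote
#'
#' Repeats [simulate_null_matrix()], recomputes the dissimilarity for each
#' replicate, pairs it with the *same* empirical patristic distances, fits
#' the Michaelis-Menten curve and collects the converged vmax estimates.
#'
#' @param changes_tree a [changes_tree()].
#' @param template the empirical [character_matrix()].
#' @param scope optional taxon subset; default all template taxa.
#' @param n_sims number of simulations (>= 100; the reference analysis used
#'   1000).
#' @param seed master seed; per-simulation seeds derived by [split_seed()].
#' @param pairs optional observed `pair_table` defining exactly which taxon
#'   pairs (and patristic distances) enter each null fit, e.g. after
#'   [filter_pairs_by_divergence()]; default all scope pairs.
#' @param min_pairs passed to [fit_michaelis_menten()].
#' @return an object of class `null_vmax`: `values` (converged vmax),
#'   `n_sims`, `central84` (8th and 92nd percentiles), `median`,
#'   `n_attempted`, `n_failed`.
#' @export
null_vmax_distribution <- function(changes_tree, template, scope = NULL,
                                   n_sims = 1000L, seed = 1L, pairs = NULL,
                                   min_pairs = 6L) {
  stopifnot(n_sims >= 100L)
  new_null_vmax(changes_tree, template, scope, n_sims, seed, pairs, min_pairs)
}

## same computation without the n_sims floor (used by scan_all_nodes and
## small-scale tests)
new_null_vmax <- function(changes_tree, template, scope, n_sims, seed,
                          pairs, min_pairs) {
  phy <- changes_tree$phylo
  if (!setequal(phy$tip.label, template$taxa))
    stop("tree and template have different taxon sets")
  scope <- scope %||% template$taxa
  tmasks <- state_masks(template)
  k <- pmax(template$char_meta$n_observed_states, 2L)
  ordered <- template$char_meta$ordered
  P <- patristic_distances(changes_tree)
  if (is.null(pairs)) {
    cmb <- utils::combn(scope, 2L)
    pair_a <- cmb[1L, ]; pair_b <- cmb[2L, ]
  } else {
    pair_a <- pairs$taxon_a; pair_b <- pairs$taxon_b
  }
  Pvec <- P$value[cbind(pair_a, pair_b)]
  seeds <- split_seed(seed, n_sims)
  values <- numeric(0); failed <- 0L
  for (s in seq_len(n_sims)) {
    Dm <- null_dissimilarity(phy, tmasks, k, ordered, seeds[s])
    fit <- fit_michaelis_menten(
      data.frame(D = Dm[cbind(pair_a, pair_b)], P = Pvec),
      min_pairs = min_pairs)
    if (fit$converged) values <- c(values, fit$vmax) else failed <- failed + 1L
  }
  if (failed > 0.2 * n_sims)
    warning(failed, " of ", n_sims, " null fits failed to converge")
  structure(list(values = values, n_sims = length(values),
                 central84 = unname(stats::quantile(values, c(0.08, 0.92))),
                 median = stats::median(values),
                 n_attempted = n_sims, n_failed = failed,
                 seed = seed),
            class = "null_vmax")
}

#' @export
print.null_vmax <- function(x, ...) {
  cat(sprintf("null_vmax: median %.4f, central 84%% band %.4f-%.4f (%d sims, %d failed)\n",
              x$median, x$central84[1], x$central84[2], x$n_attempted, x$n_failed))
  invisible(x)
}

#' Classify constraint from an observed fit and a null distribution
#'
#' Applies the 84% decision rule: constraint is *relaxed* when the observed
#' vmax 84% confidence interval lies entirely above the null band, and
#' *strengthened* when it lies entirely below; otherwise *none*.  With
#' `null_band = "central"` (default) the band is the central 84% interval
#' of the null vmax values (8th-92nd percentiles); `"onesided"` uses the
#' 84th percentile for the relaxed test and the 16th for the strengthened
#' test.
#'
#' @param observed an [fit_michaelis_menten()] result.
#' @param null a [null_vmax_distribution()] result.
#' @param null_band `"central"` or `"onesided"`.
#' @return an object of class `constraint_call` with fields `call`
#'   (`relaxed`, `strengthened`, `none` or `untestable`), `observed`,
#'   `null`.
#' @export
classify_constraint <- function(observed, null,
                                null_band = c("central", "onesided")) {
  null_band <- match.arg(null_band)
  stopifnot(inherits(observed, "mm_fit"), inherits(null, "null_vmax"))
  if (observed$untestable || !observed$converged || !length(null$values)) {
    call <- "untestable"
  } else {
    band <- if (null_band == "central") null$central84
            else unname(stats::quantile(null$values, c(0.16, 0.84)))
    call <- if (observed$vmax_ci84[1] > band[2]) "relaxed"
            else if (observed$vmax_ci84[2] < band[1]) "strengthened"
            else "none"
  }
  structure(list(call = call, observed = observed, null = null),
            class = "constraint_call")
}

#' @export
print.constraint_call <- function(x, ...) {
  cat("constraint_call:", x$call, "\n")
  invisible(x)
}

#' Scan every node of the tree for shifts in constraint
#'
#' For each internal node, the observed Michaelis-Menten asymptote is
#' fitted to the dissimilarity/patristic-distance pairs among the tips
#' descending from that node and compared against the same node-restricted
#' pairs in equal-rates null simulations (a single set of `n_sims`
#' simulated matrices is shared across nodes).  Nodes with fewer than
#' `min_pairs` usable pairs are untestable.
#'
#' @param time_tree a [time_tree()] (MRCA ages for the divergence window).
#' @param changes_tree the congruent [changes_tree()].
#' @param matrix the empirical [character_matrix()].
#' @param n_sims number of null simulations shared across nodes.
#' @param seed master seed.
#' @param pair_window optional `c(old, young)` Ma divergence window applied
#'   to pair MRCA ages, as in [filter_pairs_by_divergence()].
#' @param min_pairs minimum usable pairs per node.
#' @param clade_labels optional named list clade -> tip labels; a node whose
#'   tip set equals a named clade is labelled with it.
#' @param null_band passed to [classify_constraint()].
#' @param partition optional partition label restricting the dissimilarity.
#' @return a data.frame of class `constraint_scan`, one row per internal
#'   node: `node`, `clade_label`, `n_tips`, `n_pairs`, `vmax`, `ci_lo`,
#'   `ci_hi`, `null_lo`, `null_med`, `null_hi`, `call`.
#' @export
scan_all_nodes <- function(time_tree, changes_tree, matrix, n_sims = 100L,
                           seed = 1L, pair_window = NULL, min_pairs = 6L,
                           clade_labels = NULL,
                           null_band = c("central", "onesided"),
                           partition = NULL) {
  null_band <- match.arg(null_band)
  stopifnot(inherits(time_tree, "time_tree"),
            inherits(changes_tree, "changes_tree"),
            inherits(matrix, "character_matrix"))
  phy_t <- time_tree$phylo
  phy_c <- changes_tree$phylo
  if (!setequal(phy_t$tip.label, matrix$taxa) ||
      !setequal(phy_c$tip.label, matrix$taxa))
    stop("tree and matrix taxon sets differ")

  chars <- if (!is.null(partition)) {
    idx <- matrix$partitions[[partition]]
    if (is.null(idx) || !length(idx))
      stop("partition '", partition, "' is empty or undeclared")
    idx
  } else seq_len(matrix$n_chars)

  tmasks <- state_masks(matrix)[, chars, drop = FALSE]
  k <- pmax(matrix$char_meta$n_observed_states[chars], 2L)
  ordered <- matrix$char_meta$ordered[chars]

  Dobs <- mord_from_masks(tmasks, ordered)$D
  P <- patristic_distances(changes_tree)$value
  mrca <- ape::mrca(phy_t)

  ## shared null replicates (full dissimilarity matrices)
  seeds <- split_seed(seed, n_sims)
  ## null simulation runs on the scan's character subset only
  sub_template_masks <- tmasks
  Dnull <- lapply(seq_len(n_sims), function(s)
    null_dissimilarity(phy_c, sub_template_masks, k, ordered, seeds[s]))

  ntip <- ape::Ntip(phy_t)
  tipsets <- clade_node_tips(phy_t)
  ages <- time_tree$node_age
  label_key <- if (!is.null(clade_labels))
    stats::setNames(names(clade_labels),
                    vapply(clade_labels, function(t) paste(sort(t), collapse = "\r"),
                           character(1)))
  rows <- vector("list", phy_t$Nnode)
  for (i in seq_len(phy_t$Nnode)) {
    node <- ntip + i
    tips <- tipsets[[i]]
    lab <- NA_character_
    if (!is.null(clade_labels)) {
      kk <- paste(sort(tips), collapse = "\r")
      if (!is.na(label_key[kk])) lab <- unname(label_key[kk])
    }
    row <- data.frame(node = node, clade_label = lab, n_tips = length(tips),
                      n_pairs = 0L, vmax = NA_real_, ci_lo = NA_real_,
                      ci_hi = NA_real_, null_lo = NA_real_,
                      null_med = NA_real_, null_hi = NA_real_,
                      call = "untestable", stringsAsFactors = FALSE)
    if (length(tips) >= 2L) {
      cmb <- utils::combn(tips, 2L)
      a <- cmb[1L, ]; b <- cmb[2L, ]
      if (!is.null(pair_window)) {
        ma <- ages[mrca[cbind(match(a, phy_t$tip.label),
                             match(b, phy_t$tip.label))]]
        keep <- ma >= pair_window[2] & ma <= pair_window[1]
        a <- a[keep]; b <- b[keep]
      }
      dv <- Dobs[cbind(a, b)]
      ok <- is.finite(dv)
      a <- a[ok]; b <- b[ok]
      row$n_pairs <- length(a)
      if (length(a) >= min_pairs) {
        obs <- fit_michaelis_menten(
          data.frame(D = Dobs[cbind(a, b)], P = P[cbind(a, b)]),
          min_pairs = min_pairs)
        nulls <- vapply(Dnull, function(Dm) {
          f <- fit_michaelis_menten(
            data.frame(D = Dm[cbind(a, b)], P = P[cbind(a, b)]),
            min_pairs = min_pairs)
          if (f$converged) f$vmax else NA_real_
        }, numeric(1))
        nulls <- nulls[is.finite(nulls)]
        if (obs$converged && length(nulls) >= max(10L, 0.5 * n_sims)) {
          nd <- structure(list(values = nulls, n_sims = length(nulls),
                               central84 = unname(stats::quantile(nulls, c(0.08, 0.92))),
                               median = stats::median(nulls),
                               n_attempted = n_sims,
                               n_failed = n_sims - length(nulls)),
                          class = "null_vmax")
          cc <- classify_constraint(obs, nd, null_band = null_band)
          row$vmax <- obs$vmax
          row$ci_lo <- obs$vmax_ci84[1]; row$ci_hi <- obs$vmax_ci84[2]
          row$null_lo <- nd$central84[1]; row$null_med <- nd$median
          row$null_hi <- nd$central84[2]
          row$call <- cc$call
        }
      }
    }
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("constraint_scan", "data.frame")
  out
}

## tip labels below each internal node, indexed 1..Nnode
clade_node_tips <- function(phylo) {
  ntip <- ape::Ntip(phylo)
  nnode <- phylo$Nnode
  sets <- vector("list", ntip + nnode)
  for (t in seq_len(ntip)) sets[[t]] <- phylo$tip.label[t]
  edge <- reorder(phylo, "postorder")$edge
  for (e in seq_len(nrow(edge)))
    sets[[edge[e, 1]]] <- c(sets[[edge[e, 1]]], sets[[edge[e, 2]]])
  sets[(ntip + 1L):(ntip + nnode)]
}

#' Export a constraint scan as TSV and an annotated tree
#'
#' @param scan a `constraint_scan`.
#' @param path TSV output path.
#' @param tree optional [time_tree()]; when given, a Newick tree with the
#'   per-node call as node labels is written alongside (`<path>.nwk`).
#' @return `path`, invisibly.
#' @export
write_constraint_scan <- function(scan, path, tree = NULL) {
  utils::write.table(as.data.frame(scan), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(tree)) {
    phy <- tree$phylo
    phy$node.label <- scan$call[order(scan$node)]
    ape::write.tree(phy, paste0(path, ".nwk"))
  }
  invisible(path)
}

#' Monte-Carlo calibration of the CI-overlap rule
#'
#' Simulates pairs of independent, statistically identical normal mean
#' estimators (equal true means, equal standard errors), builds level-%
#' confidence intervals around each and returns the fraction of pairs
#' whose intervals overlap.  Two 84% intervals overlap about 95% of the
#' time, two 95% intervals about 99% of the time, which is why the
#' constraint test uses 84% intervals for a ~0.05 error rate.
#'
#' @param level CI level in percent, in (0, 100).
#' @param n_reps number of simulated pairs (>= 10000 recommended).
#' @param seed integer seed.
#' @return the overlap frequency (a number in `[0, 1]`).
#' @export
ci_overlap_calibration <- function(level = 84, n_reps = 10000L, seed = 1L) {
  stopifnot(level > 0, level < 100, n_reps >= 1)
  z <- stats::qnorm(0.5 + level / 200)
  with_seed(seed, {
    x1 <- stats::rnorm(n_reps)
    x2 <- stats::rnorm(n_reps)
    mean(abs(x1 - x2) <= 2 * z)
  })
}
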
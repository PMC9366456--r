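## Mk models of a discrete trait on a time tree: likelihood by Felsenstein
## pruning, single- and multi-regime fitting, Akaike-weight comparison,
## marginal ancestral-state reconstruction and forward simulation.

#' Specify an Mk model
#'
#' @param n_states number of trait states (e.g. 4 body-size categories).
#' @param rate_model `"ER"` (one shared transition rate) or `"ARD"` (a free
#'   rate for every ordered state pair, `n_states*(n_states-1)` per regime).
#' @param regimes optional per-branch regime labels (one per row of the
#'   tree's `edge` matrix); `NULL` means a single regime.
#' @param state_order ordered character vector of state labels; default
#'   `"s1".."sn"`.
#' @return an object of class `mk_spec`.
#' @export
mk_spec <- function(n_states, rate_model = c("ER", "ARD"), regimes = NULL,
                    state_order = NULL) {
  rate_model <- match.arg(rate_model)
  stopifnot(n_states >= 2L)
  if (is.null(state_order)) state_order <- paste0("s", seq_len(n_states))
  stopifnot(length(state_order) == n_states)
  regime_levels <- if (is.null(regimes)) "all" else unique(as.character(regimes))
  per_regime <- if (rate_model == "ER") 1L else n_states * (n_states - 1L)
  structure(list(n_states = as.integer(n_states), rate_model = rate_model,
                 regimes = regimes, regime_levels = regime_levels,
                 state_order = state_order,
                 n_params = per_regime * length(regime_levels),
                 per_regime = per_regime),
            class = "mk_spec")
}

#' Paint branch regimes by clade membership
#'
#' Each branch all of whose descendant tips belong to a named clade takes
#' that clade's regime (so the clade's stem branch is included); remaining
#' branches take `background`.
#'
#' @param tree a [time_tree()].
#' @param clades named list clade -> tip labels.
#' @param background regime label for unassigned branches; set it to one of
#'   the clade names to merge the backbone with that group.
#' @return character vector of regime labels, one per edge.
#' @export
paint_regimes <- function(tree, clades, background = "background") {
  phy <- tree$phylo
  tips <- clade_node_tips_all(phy)
  vapply(seq_len(nrow(phy$edge)), function(e) {
    below <- tips[[phy$edge[e, 2]]]
    for (g in names(clades)) if (all(below %in% clades[[g]])) return(g)
    background
  }, character(1))
}

## rate vector -> per-regime Q matrices (rows sum to zero)
mk_q_matrices <- function(spec, rates) {
  n <- spec$n_states
  qs <- vector("list", length(spec$regime_levels))
  names(qs) <- spec$regime_levels
  for (r in seq_along(qs)) {
    block <- rates[((r - 1L) * spec$per_regime + 1L):(r * spec$per_regime)]
    Q <- matrix(0, n, n)
    if (spec$rate_model == "ER") {
      Q[] <- block[1]
    } else {
      Q[row(Q) != col(Q)] <- 0  # fill row-major below
      idx <- 1L
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i != j) { Q[i, j] <- block[idx]; idx <- idx + 1L }
      }
    }
    diag(Q) <- 0
    diag(Q) <- -rowSums(Q)
    qs[[r]] <- Q
  }
  qs
}

## matrix exponential by scaling and squaring with a Taylor core;
## adequate for the small (<= 10 x 10) generator matrices used here
expm_ss <- function(A) {
  nrm <- max(abs(A))
  s <- max(0L, ceiling(log2(max(nrm, 1e-300))) + 1L)
  As <- A / 2^s
  P <- diag(nrow(A)); term <- diag(nrow(A))
  for (k in 1:16) {
    term <- term %*% As / k
    P <- P + term
  }
  for (i in seq_len(s)) P <- P %*% P
  P
}

## durations + regime labels per edge for a time_tree or phylo
edge_setup <- function(tree, spec) {
  if (inherits(tree, "time_tree")) {
    phy <- tree$phylo
    dur <- edge_durations(tree)
  } else {
    phy <- tree
    dur <- phy$edge.length
  }
  reg <- spec$regimes %||% rep(spec$regime_levels[1], nrow(phy$edge))
  if (length(reg) != nrow(phy$edge))
    stop("regime painting length does not match the edge count")
  list(phy = phy, dur = dur, reg = as.character(reg))
}

## tip likelihood matrix from a named trait vector
tip_likelihoods <- function(phy, trait, spec) {
  n <- spec$n_states
  ntip <- ape::Ntip(phy)
  miss <- setdiff(phy$tip.label, names(trait))
  if (length(miss))
    stop("trait missing for tip(s): ", paste(miss, collapse = ", "))
  st <- trait[phy$tip.label]
  if (is.character(st) || is.factor(st)) {
    idx <- match(as.character(st), spec$state_order)
    if (anyNA(idx))
      stop("trait state(s) outside state_order: ",
           paste(unique(st[is.na(idx)]), collapse = ", "))
  } else {
    idx <- as.integer(st)
    if (any(idx < 1L | idx > n)) stop("integer trait states must be in 1..n_states")
  }
  L <- matrix(0, ntip, n)
  L[cbind(seq_len(ntip), idx)] <- 1
  L
}

## per-edge transition matrices for given rates
edge_propagators <- function(setup, spec, rates) {
  qs <- mk_q_matrices(spec, rates)
  reg_idx <- split(seq_along(setup$reg), setup$reg)
  Pm <- vector("list", length(setup$dur))
  for (rg in names(reg_idx)) {
    idx <- reg_idx[[rg]]
    arr <- regime_propagators(qs[[rg]], setup$dur[idx])
    for (j in seq_along(idx)) Pm[[idx[j]]] <- arr[, , j]
  }
  Pm
}

## all transition matrices for one regime at once: with Q = V diag(l) V^-1,
## P(t) = sum_k exp(l_k t) * outer(V[,k], Vinv[k,]), so every edge's matrix
## is one column of a single (n^2 x k) %*% (k x n_edges) product
regime_propagators <- function(Q, times) {
  n <- nrow(Q)
  eg <- tryCatch(eigen(Q), error = function(e) NULL)
  ok <- FALSE
  if (!is.null(eg)) {
    Vi <- tryCatch(solve(eg$vectors), error = function(e) NULL)
    if (!is.null(Vi) && all(is.finite(abs(Vi))) &&
        max(abs(Vi)) * max(abs(eg$vectors)) < 1e8) ok <- TRUE
  }
  out <- array(0, c(n, n, length(times)))
  lam <- max(-diag(Q), 0)
  if (ok) {
    B <- vapply(seq_len(n), function(k)
      as.complex(as.vector(outer(eg$vectors[, k], Vi[k, ]))), complex(n * n))
    E <- exp(outer(as.complex(eg$values), times))  # k x n_times
    out[] <- Re(B %*% E)                           # n^2 x n_times
  } else if (lam * max(times) <= 500) {
    ## uniformisation: P(t) = sum_j Pois(j; lam*t) M^j with M = I + Q/lam;
    ## exact for defective (e.g. triangular) generators the eigen route
    ## cannot handle, and all-positive so numerically stable
    if (lam == 0) {
      out[] <- diag(n)
    } else {
      jmax <- ceiling(lam * max(times) + 8 * sqrt(lam * max(times)) + 25)
      M <- diag(n) + Q / lam
      Mstack <- matrix(0, n * n, jmax + 1L)
      Mp <- diag(n)
      Mstack[, 1L] <- as.vector(Mp)
      for (j in seq_len(jmax)) {
        Mp <- Mp %*% M
        Mstack[, j + 1L] <- as.vector(Mp)
      }
      W <- outer(0:jmax, times, function(j, t) stats::dpois(j, lam * t))
      out[] <- Mstack %*% W
    }
  } else {
    for (i in seq_along(times)) out[, , i] <- expm_ss(Q * times[i])
  }
  out[out < 0] <- 0
  ## renormalise rows to sum to 1
  for (i in seq_along(times)) {
    rs <- rowSums(out[, , i])
    out[, , i] <- out[, , i] / rs
  }
  out
}

## precomputed pruning engine: fixes the tree traversal, tip likelihoods and
## regime bookkeeping once so repeated likelihood evaluations (optimisation)
## only rebuild the per-edge propagators
mk_engine <- function(tree, trait, spec) {
  setup <- edge_setup(tree, spec)
  phy <- setup$phy
  n <- spec$n_states
  ntip <- ape::Ntip(phy)
  tipL <- tip_likelihoods(phy, trait, spec)
  po <- reorder(phy, "postorder")
  key <- paste(phy$edge[, 1], phy$edge[, 2])
  omap <- match(paste(po$edge[, 1], po$edge[, 2]), key)
  po_parent <- po$edge[, 1]; po_child <- po$edge[, 2]
  regimes <- setup$reg
  reg_idx <- split(seq_along(regimes), regimes)
  loglik <- function(rates) {
    qs <- mk_q_matrices(spec, rates)
    Pm <- array(0, c(n, n, length(setup$dur)))
    for (rg in names(reg_idx)) {
      idx <- reg_idx[[rg]]
      Pm[, , idx] <- regime_propagators(qs[[rg]], setup$dur[idx])
    }
    L <- matrix(1, ntip + phy$Nnode, n)
    L[seq_len(ntip), ] <- tipL
    logscale <- 0
    for (e in seq_along(po_parent)) {
      v <- Pm[, , omap[e]] %*% L[po_child[e], ]
      s <- max(v)
      if (s <= 0) return(-Inf)
      L[po_parent[e], ] <- L[po_parent[e], ] * (v / s)
      logscale <- logscale + log(s)
    }
    log(mean(L[ntip + 1L, ])) + logscale
  }
  list(loglik = loglik, setup = setup, tipL = tipL)
}

#' Mk log-likelihood of a discrete trait on a tree
#'
#' Felsenstein pruning with per-branch transition matrices
#' `exp(Q_regime * duration)` and a uniform root state distribution.
#'
#' @param tree a [time_tree()] (durations in Myr from node ages) or a
#'   `phylo` with branch lengths in time units.
#' @param trait named vector of tip states (labels from
#'   `spec$state_order`, or integers 1..n_states).
#' @param spec an [mk_spec()].
#' @param rates non-negative rate vector, length `spec$n_params`
#'   (regime blocks in `spec$regime_levels` order; within a block, ER has
#'   one rate and ARD has rates row-major over ordered pairs).
#' @return the log-likelihood.
#' @export
mk_loglik <- function(tree, trait, spec, rates) {
  stopifnot(inherits(spec, "mk_spec"))
  if (length(rates) != spec$n_params)
    stop("expected ", spec$n_params, " rates, got ", length(rates))
  if (any(rates < 0)) stop("rates must be non-negative")
  setup <- edge_setup(tree, spec)
  Pm <- edge_propagators(setup, spec, rates)
  mk_loglik_core(setup$phy, tip_likelihoods(setup$phy, trait, spec), Pm,
                 spec$n_states)
}

mk_loglik_core <- function(phy, tipL, Pm, n) {
  ntip <- ape::Ntip(phy)
  nnode <- ntip + phy$Nnode
  L <- matrix(1, nnode, n)
  L[seq_len(ntip), ] <- tipL
  po <- reorder(phy, "postorder")
  ## map postorder edges back to input edge order for the propagators
  key <- paste(phy$edge[, 1], phy$edge[, 2])
  omap <- match(paste(po$edge[, 1], po$edge[, 2]), key)
  logscale <- 0
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    v <- Pm[[omap[e]]] %*% L[ch, ]
    s <- max(v)
    if (s <= 0) return(-Inf)
    L[p, ] <- L[p, ] * (v / s)
    logscale <- logscale + log(s)
  }
  root <- ntip + 1L
  log(mean(L[root, ])) + logscale
}

#' Fit an Mk model by maximum likelihood
#'
#' Multi-start bounded optimisation on log-transformed rates
#' (L-BFGS-B, bounds `[1e-8, 1e3]` per Myr).  ARD likelihood surfaces are
#' multimodal, hence the restarts.
#'
#' @param tree,trait,spec as [mk_loglik()].
#' @param n_starts number of optimisation starts (>= 1).
#' @param seed seed for the randomised starting points.
#' @param maxit L-BFGS-B iteration cap per start.
#' @param init_rates optional rate vector used as an additional warm
#'   start (e.g. a fitted nested model's rates expanded to this spec).
#' @param factr L-BFGS-B convergence tolerance (relative likelihood
#'   change, in units of machine epsilon; optim's default 1e7).
#' @return an object of class `mk_fit`: `loglik`, `rates` (named),
#'   `k` (free-parameter count), `aic = 2k - 2*loglik`, `converged`,
#'   `at_boundary`, `spec`.
#' @export
fit_mk <- function(tree, trait, spec, n_starts = 5L, seed = 1L, maxit = 500L,
                   init_rates = NULL, factr = 1e7) {
  stopifnot(inherits(spec, "mk_spec"))
  engine <- mk_engine(tree, trait, spec)
  setup <- engine$setup
  lo <- log(1e-8); hi <- log(1e3)
  nll <- function(logr) -engine$loglik(exp(logr))
  ## heuristic base rate: about one expected change per lineage over the
  ## whole tree duration
  q0 <- 1 / max(sum(setup$dur) / ape::Ntip(setup$phy), 1e-6)
  starts <- with_seed(seed, {
    s <- list(rep(log(q0), spec$n_params))
    if (n_starts > 1L) {
      for (i in seq_len(n_starts - 1L)) {
        s[[i + 1L]] <- pmin(hi, pmax(lo, log(q0) +
          stats::rnorm(spec$n_params, 0, 1.5)))
      }
    }
    s
  })
  if (!is.null(init_rates)) {
    stopifnot(length(init_rates) == spec$n_params)
    starts <- c(list(pmin(hi, pmax(lo, log(pmax(init_rates, 1e-8))))), starts)
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      stats::optim(st, nll, method = "L-BFGS-B", lower = lo, upper = hi,
                   control = list(maxit = maxit, factr = factr)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("all optimisation starts failed")
  rates <- exp(best$par)
  names(rates) <- rate_names(spec)
  k <- spec$n_params
  loglik <- -best$value
  structure(list(loglik = loglik, rates = rates, k = k,
                 aic = 2 * k - 2 * loglik,
                 converged = best$convergence == 0,
                 at_boundary = any(best$par <= lo + 1e-6) ||
                   any(best$par >= hi - 1e-6),
                 spec = spec),
            class = "mk_fit")
}

rate_names <- function(spec) {
  n <- spec$n_states
  base <- if (spec$rate_model == "ER") "q" else {
    pairs <- expand.grid(to = seq_len(n), from = seq_len(n))
    pairs <- pairs[pairs$from != pairs$to, ]
    pairs <- pairs[order(pairs$from, pairs$to), ]
    paste0(spec$state_order[pairs$from], "->", spec$state_order[pairs$to])
  }
  unlist(lapply(spec$regime_levels, function(r) paste0(r, ":", base)))
}

#' @export
print.mk_fit <- function(x, ...) {
  cat(sprintf("mk_fit: logL = %.3f, k = %d, AIC = %.3f%s\n", x$loglik, x$k,
              x$aic, if (!x$converged) " (not converged)" else ""))
  invisible(x)
}

#' Fit the four-model set for a discrete trait
#'
#' Fits the candidate set used for body-size evolution: single-regime
#' equal-rates, single-regime all-rates-different, multi-regime
#' equal-rates and multi-regime all-rates-different.  Nested fits warm-
#' start the richer models (ER -> ARD, single -> multi), which keeps the
#' multi-regime likelihoods at or above their nested counterparts.
#'
#' @param tree a [time_tree()] or `phylo` in time units.
#' @param trait named vector of tip states.
#' @param regimes per-branch regime labels (see [paint_regimes()]).
#' @param state_order ordered state labels.
#' @param n_starts,seed,maxit,factr passed to [fit_mk()].
#' @return list with `fits` (named list of `mk_fit`) and `comparison`
#'   (a [model_comparison()] table).
#' @export
fit_mk_model_set <- function(tree, trait, regimes, state_order = NULL,
                             n_starts = 3L, seed = 1L, maxit = 500L,
                             factr = 1e7) {
  n <- length(unique(stats::na.omit(
    if (is.null(state_order)) as.character(trait) else state_order)))
  if (!is.null(state_order)) n <- length(state_order)
  nr <- length(unique(as.character(regimes)))
  sp_er1 <- mk_spec(n, "ER", state_order = state_order)
  sp_ard1 <- mk_spec(n, "ARD", state_order = state_order)
  sp_er2 <- mk_spec(n, "ER", regimes = regimes, state_order = state_order)
  sp_ard2 <- mk_spec(n, "ARD", regimes = regimes, state_order = state_order)
  f_er1 <- fit_mk(tree, trait, sp_er1, n_starts, seed, maxit, factr = factr)
  f_ard1 <- fit_mk(tree, trait, sp_ard1, n_starts, seed, maxit,
                   init_rates = rep(unname(f_er1$rates), sp_ard1$n_params),
                   factr = factr)
  f_er2 <- fit_mk(tree, trait, sp_er2, n_starts, seed, maxit,
                  init_rates = rep(unname(f_er1$rates), nr), factr = factr)
  f_ard2 <- fit_mk(tree, trait, sp_ard2, n_starts, seed, maxit,
                   init_rates = rep(unname(f_ard1$rates), nr), factr = factr)
  fits <- list(single_er = f_er1, single_ard = f_ard1,
               multi_er = f_er2, multi_ard = f_ard2)
  list(fits = fits, comparison = model_comparison(fits))
}

#' Akaike weights
#'
#' `w_i = exp(-(AIC_i - min AIC)/2)`, normalised to sum to 1.
#'
#' @param aics numeric vector of at least 2 finite AIC values.
#' @return numeric vector of weights summing to 1.
#' @export
akaike_weights <- function(aics) {
  if (length(aics) < 2L || any(!is.finite(aics)))
    stop("need at least 2 finite AIC values")
  d <- aics - min(aics)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Compare a set of fitted Mk models
#'
#' @param fits named list of [fit_mk()] results.
#' @return a data.frame of class `model_comparison` with columns `model`,
#'   `loglik`, `k`, `aic`, `weight`.
#' @export
model_comparison <- function(fits) {
  stopifnot(length(fits) >= 2L)
  out <- data.frame(model = names(fits),
                    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
                    k = vapply(fits, `[[`, numeric(1), "k"),
                    aic = vapply(fits, `[[`, numeric(1), "aic"),
                    stringsAsFactors = FALSE)
  out$weight <- akaike_weights(out$aic)
  rownames(out) <- NULL
  class(out) <- c("model_comparison", "data.frame")
  out
}

#' Marginal ancestral-state reconstruction
#'
#' Marginal posterior state probabilities at every internal node under a
#' fitted Mk model, computed by combined post-order (subtree) and pre-order
#' (rest-of-tree) passes with a uniform root prior.
#'
#' @param tree,trait,spec as [mk_loglik()].
#' @param rates fitted rate vector.
#' @return matrix of class `ancestral_recon` (internal nodes x states,
#'   rownames = node numbers); each row sums to 1.
#' @export
marginal_ancestral_states <- function(tree, trait, spec, rates) {
  setup <- edge_setup(tree, spec)
  phy <- setup$phy
  n <- spec$n_states
  ntip <- ape::Ntip(phy)
  nnode <- ntip + phy$Nnode
  Pm <- edge_propagators(setup, spec, rates)
  ## up pass: conditional likelihoods of each subtree (scaled)
  L <- matrix(1, nnode, n)
  L[seq_len(ntip), ] <- tip_likelihoods(phy, trait, spec)
  M <- vector("list", nrow(phy$edge))  # M[[e]] = P_e %*% L[child]
  po <- reorder(phy, "postorder")
  key <- paste(phy$edge[, 1], phy$edge[, 2])
  omap <- match(paste(po$edge[, 1], po$edge[, 2]), key)
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    v <- Pm[[omap[e]]] %*% L[ch, ]
    v <- v / max(v)
    M[[omap[e]]] <- as.vector(v)
    L[p, ] <- L[p, ] * v
  }
  ## down pass
  Down <- matrix(NA_real_, nnode, n)
  root <- ntip + 1L
  Down[root, ] <- rep(1 / n, n)
  pre <- po$edge[rev(seq_len(nrow(po$edge))), , drop = FALSE]
  pre_map <- rev(omap)
  kids_of <- split(seq_len(nrow(phy$edge)), phy$edge[, 1])
  for (e in seq_len(nrow(pre))) {
    p <- pre[e, 1]; ch <- pre[e, 2]; eid <- pre_map[e]
    sibs <- setdiff(kids_of[[as.character(p)]], eid)
    U <- Down[p, ]
    for (s in sibs) U <- U * M[[s]]
    v <- as.vector(t(Pm[[eid]]) %*% U)
    tot <- sum(v)
    Down[ch, ] <- if (tot > 0) v / tot else rep(1 / n, n)
  }
  marg <- Down * L
  marg <- marg / rowSums(marg)
  out <- marg[(ntip + 1L):nnode, , drop = FALSE]
  dimnames(out) <- list((ntip + 1L):nnode, spec$state_order)
  class(out) <- c("ancestral_recon", class(out))
  out
}

#' Forward-simulate a discrete trait under an Mk model
#'
#' @param tree a [time_tree()] or `phylo` with time branch lengths.
#' @param spec an [mk_spec()].
#' @param rates rate vector, as [mk_loglik()].
#' @param root_state `"uniform"` (default), `"stationary"`, or a state
#'   label/index fixing the root state.
#' @param seed integer seed.
#' @return an object of class `mk_sim`: `tip_states` (named character),
#'   `node_states` (all nodes, the full history for test oracles),
#'   `root_state`.
#' @export
simulate_mk <- function(tree, spec, rates, root_state = "uniform", seed = 1L) {
  setup <- edge_setup(tree, spec)
  phy <- setup$phy
  n <- spec$n_states
  ntip <- ape::Ntip(phy)
  Pm <- edge_propagators(setup, spec, rates)
  with_seed(seed, {
    root <- ntip + 1L
    nodes <- integer(ntip + phy$Nnode)
    nodes[root] <- if (identical(root_state, "uniform")) {
      sample.int(n, 1L)
    } else if (identical(root_state, "stationary")) {
      ## stationary distribution of the (first-regime) generator
      Q <- mk_q_matrices(spec, rates)[[1]]
      pi0 <- tryCatch({
        ns <- abs(Re(eigen(t(Q))$vectors[, which.min(abs(eigen(t(Q))$values))]))
        ns / sum(ns)
      }, error = function(e) rep(1 / n, n))
      sample.int(n, 1L, prob = pi0)
    } else if (is.character(root_state)) {
      match(root_state, spec$state_order)
    } else as.integer(root_state)
    if (is.na(nodes[root]) || nodes[root] < 1L || nodes[root] > n)
      stop("invalid root_state")
    co <- reorder(phy, "cladewise")
    key <- paste(phy$edge[, 1], phy$edge[, 2])
    cmap <- match(paste(co$edge[, 1], co$edge[, 2]), key)
    for (e in seq_len(nrow(co$edge))) {
      p <- co$edge[e, 1]; ch <- co$edge[e, 2]
      nodes[ch] <- sample.int(n, 1L, prob = Pm[[cmap[e]]][nodes[p], ])
    }
    tip_states <- stats::setNames(spec$state_order[nodes[seq_len(ntip)]],
                                  phy$tip.label)
    structure(list(tip_states = tip_states,
                   node_states = spec$state_order[nodes],
                   root_state = spec$state_order[nodes[root]]),
              class = "mk_sim")
  })
}

#' Write a trait table as CSV / a model comparison as TSV
#' @param trait named vector of tip states.
#' @param path output file.
#' @export
write_trait_table <- function(trait, path) {
  utils::write.csv(data.frame(taxon = names(trait), state = unname(trait)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @param cmp a [model_comparison()] table.
#' @rdname write_trait_table
#' @export
write_model_comparison <- function(cmp, path) {
  utils::write.table(as.data.frame(cmp), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export an ancestral-state reconstruction as an annotated NEXUS tree
#'
#' Each internal node carries a `[&p_<state>=...]` comment with its
#' marginal state probabilities.
#'
#' @param asr a [marginal_ancestral_states()] result.
#' @param tree the [time_tree()] (or `phylo`) the reconstruction was
#'   computed on.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ancestral_states <- function(asr, tree, path) {
  phy <- if (inherits(tree, "time_tree")) tree$phylo else tree
  ntip <- ape::Ntip(phy)
  states <- colnames(asr)
  kids <- split(seq_len(nrow(phy$edge)), phy$edge[, 1])
  node_comment <- function(node) {
    p <- asr[as.character(node), ]
    paste0("[&", paste(sprintf("p_%s=%.6f", states, p), collapse = ","), "]")
  }
  build <- function(node) {
    rows <- kids[[as.character(node)]]
    parts <- vapply(rows, function(r) {
      child <- phy$edge[r, 2]
      sub <- if (child <= ntip) phy$tip.label[child]
             else paste0(build(child), node_comment(child))
      sprintf("%s:%.10g", sub, phy$edge.length[r])
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  root <- ntip + 1L
  writeLines(c("#NEXUS", "BEGIN TREES;",
               paste0("\tTREE asr = [&R] ", build(root), node_comment(root),
                      ";"),
               "END;"), path)
  invisible(path)
}
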
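## Synthetic data with the statistical structure the analyses assume:
## birth-death trees with fossil tips, character matrices evolved under
## clade-specific accessible-state constraint and declining rates, and a
## 4-category size trait under regime-dependent transition rates.  Every
## generator records its ground truth.

#' Describe a synthetic study scenario
#'
#' Defaults emulate the structure of a Paleozoic amniote dataset: a
#' birth-death tree of ~80 fossil and extant tips rooted at 320 Ma, a few
#' hundred unordered characters evolving under an Mk process whose
#' accessible state space is restricted (k = 2) inside one constrained
#' clade and wider (k = 6) elsewhere, rates declining through time,
#' missing-at-random cells, and a 4-state body-size trait with an
#' upward-biased regime in one clade.
#'
#' @param seed master seed.
#' @param n_tips total tip count (fossil + extant) the tree is conditioned
#'   on.
#' @param birth,death per-lineage rates (per Myr).
#' @param root_age crown age in Ma.
#' @param n_chars number of characters.
#' @param k_constrained,k_background accessible state counts inside and
#'   outside the constrained clade (2..10).
#' @param base_rate expected character-state changes per character per Myr
#'   at the root age.
#' @param rate_profile `"constant"` or `"exponential"` decline through
#'   time.
#' @param half_life Myr for the rate to halve under the exponential
#'   profile.
#' @param rate_shape gamma shape for among-character rate variation
#'   (multipliers with mean 1); `Inf` disables the variation.
#' @param missing_fraction expected fraction of missing cells, in `[0, 1)`.
#' @param missing_mode `"mcar"` (completely at random) or `"taxon_biased"`
#'   (lognormal per-taxon sampling quality).
#' @param size_rate adjacent-step upward rate of the synapsid-style size
#'   regime, per Myr; the reptile-style regime uses `4 * size_rate`
#'   upward and `12 * size_rate` downward.
#' @param min_clade_frac minimum fraction of tips on each side of the root
#'   (both primary clades are diverse, as in the system being emulated).
#' @return a list of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(seed = 1L, n_tips = 80L, birth = 0.025,
                               death = 0.015, root_age = 320,
                               n_chars = 300L, k_constrained = 2L,
                               k_background = 6L, base_rate = 0.02,
                               rate_profile = c("exponential", "constant"),
                               half_life = 100, rate_shape = 2,
                               missing_fraction = 0.25,
                               missing_mode = c("mcar", "taxon_biased"),
                               size_rate = 0.015, min_clade_frac = 0.25) {
  rate_profile <- match.arg(rate_profile)
  missing_mode <- match.arg(missing_mode)
  stopifnot(birth >= 0, death >= 0, n_tips >= 2L,
            k_constrained >= 2L, k_constrained <= 10L,
            k_background >= 2L, k_background <= 10L,
            base_rate >= 0, missing_fraction >= 0, missing_fraction < 1)
  structure(list(seed = seed, n_tips = as.integer(n_tips), birth = birth,
                 death = death, root_age = root_age,
                 n_chars = as.integer(n_chars),
                 k_constrained = as.integer(k_constrained),
                 k_background = as.integer(k_background),
                 base_rate = base_rate, rate_profile = rate_profile,
                 half_life = half_life, rate_shape = rate_shape,
                 missing_fraction = missing_fraction,
                 missing_mode = missing_mode, size_rate = size_rate,
                 min_clade_frac = min_clade_frac),
            class = "synthetic_scenario")
}

#' Simulate a birth-death tree with fossil tips
#'
#' Forward crown-conditioned birth-death simulation from `root_age` to the
#' present; extinct lineages are retained as fossil (non-extant) tips.
#' Exactly `scenario$n_tips` tips are obtained by uniform taxon sampling
#' from a complete simulation with at least that many tips (mirroring the
#' incomplete sampling of real fossil datasets), always keeping both root
#' subclades so the crown age is preserved; complete simulations with too
#' few tips are rejected, erroring after `max_attempts`.
#'
#' @param scenario a [synthetic_scenario()].
#' @param max_attempts rejection-sampling cap.
#' @return a [time_tree()] rooted at `root_age`.
#' @export
simulate_tree <- function(scenario, max_attempts = 1000L) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  n <- scenario$n_tips
  seeds <- split_seed(scenario$seed, max_attempts)
  for (a in seq_len(max_attempts)) {
    phy <- with_seed(seeds[a], {
      full <- bd_forward(scenario$birth, scenario$death, scenario$root_age)
      if (is.null(full) || ape::Ntip(full) < n) NULL else {
        sampled <- NULL
        if (ape::Ntip(full) == n) sampled <- full else {
          ## root-side membership, to keep the crown intact under sampling
          ntip <- ape::Ntip(full)
          sides <- clade_node_tips_all(full)[
            full$edge[full$edge[, 1] == ntip + 1L, 2]]
          for (try in 1:20) {
            keep <- sample(full$tip.label, n)
            if (all(vapply(sides, function(s) any(s %in% keep), logical(1)))) {
              sampled <- ape::drop.tip(full, setdiff(full$tip.label, keep))
              break
            }
          }
        }
        sampled
      }
    })
    if (!is.null(phy)) {
      ## require both root subclades to be diverse
      ntip <- ape::Ntip(phy)
      kids <- phy$edge[phy$edge[, 1] == ntip + 1L, 2]
      side_n <- vapply(clade_node_tips_all(phy)[kids], length, integer(1))
      if (min(side_n) < scenario$min_clade_frac * n) next
      phy$tip.label <- paste0("t", seq_len(ntip))
      return(time_tree(phy, root_age = scenario$root_age))
    }
  }
  stop("could not obtain a tree with ", n, " tips in ",
       max_attempts, " attempts; adjust birth/death rates")
}

## forward birth-death simulation: crown root at age T with two lineages,
## run to the present; returns a phylo whose tips are extinct (fossil) and
## extant lineages, or NULL if fewer than 2 tips survive the bookkeeping
bd_forward <- function(birth, death, T) {
  parent <- c(NA_integer_, 1L, 1L)
  age <- c(T, NA_real_, NA_real_)       # filled when the node terminates
  is_tip <- c(FALSE, TRUE, TRUE)
  alive <- c(2L, 3L)
  t <- T
  while (length(alive) && t > 0) {
    rate_tot <- length(alive) * (birth + death)
    if (rate_tot <= 0) break
    t <- t - stats::rexp(1, rate_tot)
    if (t <= 0) break
    lin <- alive[sample.int(length(alive), 1L)]
    if (stats::runif(1) < birth / (birth + death)) {
      ## speciation: lin becomes an internal node with two daughters
      age[lin] <- t; is_tip[lin] <- FALSE
      id1 <- length(parent) + 1L; id2 <- id1 + 1L
      parent <- c(parent, lin, lin)
      age <- c(age, NA_real_, NA_real_)
      is_tip <- c(is_tip, TRUE, TRUE)
      alive <- c(setdiff(alive, lin), id1, id2)
    } else {
      ## extinction: lin becomes a fossil tip at age t
      age[lin] <- t
      alive <- setdiff(alive, lin)
    }
  }
  age[alive] <- 0                        # extant tips
  tips <- which(is_tip)
  if (length(tips) < 2L) return(NULL)
  ints <- which(!is_tip)
  newid <- integer(length(parent))
  newid[tips] <- seq_along(tips)
  ## internal nodes in preorder (parents before children by construction)
  newid[ints] <- length(tips) + seq_along(ints)
  edge <- cbind(newid[parent[-1L]], newid[-1L])
  storage.mode(edge) <- "integer"
  elen <- age[parent[-1L]] - age[-1L]
  phy <- list(edge = edge, edge.length = elen, Nnode = length(ints),
              tip.label = paste0("t", seq_along(tips)))
  class(phy) <- "phylo"
  phy <- ape::reorder.phylo(phy, "cladewise")
  phy
}

## integral of the rate profile over a branch (ages in Ma, old > young)
profile_integral <- function(scenario, old, young) {
  if (scenario$rate_profile == "constant") {
    scenario$base_rate * (old - young)
  } else {
    h <- scenario$half_life; A <- scenario$root_age
    ## rate(age a) = base * 2^{-(A - a)/h}; integrate over a in [young, old]
    scenario$base_rate * h / log(2) *
      (2^((old - A) / h) - 2^((young - A) / h))
  }
}

## rate profile evaluated at (a vector of) ages
profile_rate <- function(scenario, age) {
  if (scenario$rate_profile == "constant")
    rep(scenario$base_rate, length(age))
  else scenario$base_rate * 2^(-(scenario$root_age - age) / scenario$half_life)
}

#' Simulate a character matrix under clade-specific constraint
#'
#' Characters evolve independently under an equal-rates Mk process with a
#' restricted accessible state space inside the constrained clade
#' (`k_constrained` states; strong constraint means high homoplasy and a
#' low saturation asymptote) and a wider space elsewhere
#' (`k_background`).  Change events on a branch are Poisson with mean
#' equal to the branch's expected change count (rate profile integral
#' times a per-character gamma multiplier); each event moves to a uniform
#' other accessible state.  The per-branch expected change counts,
#' averaged over characters, become the branch lengths of the returned
#' changes tree (the true analogue of an inferred change-unit tree).
#' Missingness is applied last.
#'
#' @param tree a [time_tree()], typically from [simulate_tree()].
#' @param scenario a [synthetic_scenario()].
#' @param constrained_clade tip labels of the constrained clade; default
#'   picks the largest clade containing 1/4 to 1/2 of the tips.
#' @param changes_noise_sd optional lognormal sigma multiplying the changes
#'   tree branch lengths, emulating branch-length estimation error
#'   (default 0 = exact expected changes).
#' @return list with `matrix` (a [character_matrix()]), `changes_tree`
#'   (a [changes_tree()]), and `ground_truth` (constrained clade, per-edge
#'   accessible k, expected and realised change counts, rate multipliers,
#'   missing mask).
#' @export
simulate_constrained_matrix <- function(tree, scenario,
                                        constrained_clade = NULL,
                                        changes_noise_sd = 0) {
  stopifnot(inherits(tree, "time_tree"),
            inherits(scenario, "synthetic_scenario"))
  phy <- tree$phylo
  ntip <- ape::Ntip(phy)
  if (is.null(constrained_clade)) {
    sizes <- vapply(clade_node_tips(phy), length, integer(1))
    cand <- which(sizes >= ntip / 4 & sizes <= ntip / 2)
    if (!length(cand)) cand <- which.min(abs(sizes - ntip / 3))
    constrained_clade <- clade_node_tips(phy)[[cand[which.max(sizes[cand])]]]
  }
  tipsets <- clade_node_tips_all(phy)
  edge <- phy$edge
  in_clade <- vapply(edge[, 2], function(nd)
    all(tipsets[[nd]] %in% constrained_clade), logical(1))
  k_edge <- ifelse(in_clade, scenario$k_constrained, scenario$k_background)
  if (max(k_edge) > 10L) stop("accessible state count exceeds symbol capacity")

  p_age <- tree$node_age[edge[, 1]]
  c_age <- tree$node_age[edge[, 2]]
  m_edge <- profile_integral(scenario, p_age, c_age)  # expected changes/char

  seeds <- split_seed(scenario$seed, 4L)
  mult <- if (is.finite(scenario$rate_shape)) {
    with_seed(seeds[1], stats::rgamma(scenario$n_chars,
                                      shape = scenario$rate_shape,
                                      rate = scenario$rate_shape))
  } else rep(1, scenario$n_chars)

  nch <- scenario$n_chars
  nnode <- ntip + phy$Nnode
  states <- matrix(0L, nnode, nch)
  realized <- numeric(nrow(edge))
  with_seed(seeds[2], {
    root <- ntip + 1L
    k_root <- scenario$k_background
    states[root, ] <- sample.int(k_root, nch, replace = TRUE) - 1L
    co <- reorder(phy, "cladewise")
    key <- paste(edge[, 1], edge[, 2])
    cmap <- match(paste(co$edge[, 1], co$edge[, 2]), key)
    for (e in seq_len(nrow(co$edge))) {
      eid <- cmap[e]
      p <- co$edge[e, 1]; ch <- co$edge[e, 2]
      k <- k_edge[eid]
      s <- states[p, ]
      nev <- stats::rpois(nch, m_edge[eid] * mult)
      realized[eid] <- sum(nev)
      for (c0 in which(nev > 0L)) {
        cur <- s[c0]
        for (j in seq_len(nev[c0])) {
          if (cur < k) {
            cur <- (cur + sample.int(k - 1L, 1L)) %% k
          } else {
            cur <- sample.int(k, 1L) - 1L   # re-enter the accessible space
          }
        }
        s[c0] <- cur
      }
      states[ch, ] <- s
    }
  })

  cells <- matrix(as.character(states[seq_len(ntip), , drop = FALSE]),
                  nrow = ntip,
                  dimnames = list(phy$tip.label,
                                  paste0("c", seq_len(nch))))
  ## missingness
  mask <- with_seed(seeds[3], {
    if (scenario$missing_mode == "mcar") {
      matrix(stats::runif(ntip * nch) < scenario$missing_fraction,
             ntip, nch)
    } else {
      ptax <- pmin(0.9, scenario$missing_fraction *
                     stats::rlnorm(ntip, 0, 0.5))
      matrix(stats::runif(ntip * nch), ntip, nch) < ptax
    }
  })
  cells[mask] <- NA_character_

  chlen <- m_edge * mean(mult)
  if (changes_noise_sd > 0) {
    chlen <- chlen * with_seed(seeds[4],
      stats::rlnorm(length(chlen), -changes_noise_sd^2 / 2, changes_noise_sd))
  }
  cphy <- phy
  cphy$edge.length <- chlen
  list(matrix = character_matrix(cells),
       changes_tree = changes_tree(cphy, reference = tree),
       ground_truth = list(constrained_clade = sort(constrained_clade),
                           k_edge = k_edge,
                           expected_changes = m_edge * mean(mult),
                           realized_changes = realized,
                           rate_multipliers = mult,
                           missing_mask = mask))
}

#' Assign declining-through-time branch rates to a tree
#'
#' Deterministically sets each branch's relative rate to the profile
#' evaluated at the branch midpoint age, times an optional multiplicative
#' group effect (e.g. one clade evolving twice as fast).
#'
#' @param tree a [time_tree()].
#' @param scenario a [synthetic_scenario()] (profile, base rate,
#'   half-life).
#' @param group_multipliers optional named list clade-name -> multiplier;
#'   requires `groups`.
#' @param groups named list clade-name -> tip labels.
#' @return the `time_tree` with `branch_rate` populated.
#' @export
generate_rate_burst_tree <- function(tree, scenario, group_multipliers = NULL,
                                     groups = NULL) {
  stopifnot(inherits(tree, "time_tree"),
            inherits(scenario, "synthetic_scenario"))
  phy <- tree$phylo
  mid <- (tree$node_age[phy$edge[, 1]] + tree$node_age[phy$edge[, 2]]) / 2
  rate <- profile_rate(scenario, mid)
  if (!is.null(group_multipliers)) {
    if (is.null(groups)) stop("group_multipliers requires groups")
    tipsets <- clade_node_tips_all(phy)
    for (g in names(group_multipliers)) {
      in_g <- vapply(phy$edge[, 2], function(nd)
        all(tipsets[[nd]] %in% groups[[g]]), logical(1))
      rate[in_g] <- rate[in_g] * group_multipliers[[g]]
    }
  }
  time_tree(phy, root_age = tree$root_age, branch_rate = rate,
            tip_age_range = tree$tip_age_range)
}

#' Simulate a 4-category body-size trait under two regimes
#'
#' The trait evolves under a multi-regime all-rates-different Mk model:
#' the "synapsid-style" regime is an upper-triangular adjacent-step ladder
#' (slow transitions toward the next larger category; every
#' large-to-small rate is zero), while the "reptile-style" regime is
#' bidirectional and fast, with downward rates exceeding upward ones so
#' reversals are common.  The root state is the smallest category.  The
#' directional-ladder versus fast downward-biased-mixing contrast is what
#' keeps the generating model identifiable at realistic tip counts (see
#' the methods vignette).
#'
#' @param tree a [time_tree()].
#' @param scenario a [synthetic_scenario()] (`size_rate` sets the scale).
#' @param up_clade tip labels of the upward-biased (synapsid-style) clade;
#'   default one of the two root subclades.
#' @return list with `trait` (named tip states), `history` (the [mk_sim()]
#'   object, full node states), `spec`, `rates`, `regimes`, `up_clade`.
#' @export
simulate_size_dataset <- function(tree, scenario, up_clade = NULL) {
  stopifnot(inherits(tree, "time_tree"),
            inherits(scenario, "synthetic_scenario"))
  phy <- tree$phylo
  ntip <- ape::Ntip(phy)
  if (is.null(up_clade)) {
    root_kids <- phy$edge[phy$edge[, 1] == ntip + 1L, 2]
    tipsets <- clade_node_tips_all(phy)
    sides <- lapply(root_kids, function(nd) tipsets[[nd]])
    up_clade <- sides[[which.max(lengths(sides))]]
  }
  regimes <- paint_regimes(tree, list(up = up_clade), background = "bi")
  spec <- mk_spec(4L, "ARD", regimes = regimes,
                  state_order = SIZE_CATEGORIES)
  r <- scenario$size_rate
  ladder <- function(up_rate, down_rate) {
    Q <- matrix(0, 4, 4)
    for (i in 1:3) Q[i, i + 1] <- up_rate
    for (i in 2:4) Q[i, i - 1] <- down_rate
    Q
  }
  pack <- function(Q) {
    out <- numeric(0)
    for (i in 1:4) for (j in 1:4) if (i != j) out <- c(out, Q[i, j])
    out
  }
  blocks <- list(up = pack(ladder(r, 0)),
                 bi = pack(ladder(4 * r, 12 * r)))
  rates <- unlist(blocks[spec$regime_levels], use.names = FALSE)
  ## floor zero rates at the optimiser's lower bound so the generating
  ## model lies inside the fitted family
  sim_rates <- pmax(rates, 0)
  history <- simulate_mk(tree, spec, sim_rates, root_state = "small",
                         seed = scenario$seed)
  list(trait = history$tip_states, history = history, spec = spec,
       rates = rates, regimes = regimes, up_clade = sort(up_clade))
}

#' Write a full synthetic scenario to disk
#'
#' Writes the matrix (NEXUS), trees (annotated NEXUS / Newick), metadata
#' (CSV), trait table (CSV), ground truth (TSV) and a provenance file
#' recording the seed and parameters.  Everything round-trips through the
#' package's readers.
#'
#' @param scenario a [synthetic_scenario()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly; side effect: files
#'   `matrix.nex`, `time_tree.nex`, `changes_tree.nwk`, `metadata.csv`,
#'   `sizes.csv`, `ground_truth.tsv`, `provenance.txt`.
#' @export
write_synthetic_dataset <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tree <- simulate_tree(scenario)
  simmed <- simulate_constrained_matrix(tree, scenario)
  rated <- generate_rate_burst_tree(tree, scenario)
  sizes <- simulate_size_dataset(tree, scenario)
  write_nexus_matrix(simmed$matrix, file.path(dir, "matrix.nex"))
  write_annotated_tree(rated, file.path(dir, "time_tree.nex"))
  ape::write.tree(simmed$changes_tree$phylo, file.path(dir, "changes_tree.nwk"))
  clade <- ifelse(tree$phylo$tip.label %in% simmed$ground_truth$constrained_clade,
                  "constrained", "background")
  meta <- data.frame(taxon = tree$phylo$tip.label, clade = clade,
                     size_category = unname(sizes$trait[tree$phylo$tip.label]))
  utils::write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE,
                   quote = FALSE)
  write_trait_table(sizes$trait, file.path(dir, "sizes.csv"))
  gt <- data.frame(edge = seq_along(simmed$ground_truth$k_edge),
                   k = simmed$ground_truth$k_edge,
                   expected_changes = simmed$ground_truth$expected_changes,
                   realized_changes = simmed$ground_truth$realized_changes,
                   branch_rate = rated$branch_rate)
  utils::write.table(gt, file.path(dir, "ground_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(c(paste0("seed: ", scenario$seed),
               paste0("parameters: ",
                      paste(names(unclass(scenario)), unlist(scenario),
                            sep = "=", collapse = ", "))),
             file.path(dir, "provenance.txt"))
  invisible(dir)
}
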
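test_that("Mk likelihood matches closed forms on 2-tip trees", {
  # zero-length limit: identical tips carry no information beyond the root
  phy0 <- ape::read.tree(text = "(A:0,B:0);")
  sp3 <- mk_spec(3, "ER")
  expect_equal(mk_loglik(phy0, c(A = "s1", B = "s1"), sp3, 0.5), log(1 / 3))
  # 2-state ER closed form: P(same)=(1+exp(-2qt))/2
  phy <- ape::read.tree(text = "(A:2,B:2);")
  sp2 <- mk_spec(2, "ER")
  for (q in c(0.05, 0.3, 1.2)) {
    ps <- (1 + exp(-2 * q * 2)) / 2
    pd <- (1 - exp(-2 * q * 2)) / 2
    expect_equal(mk_loglik(phy, c(A = "s1", B = "s2"), sp2, q),
                 log(pd * ps), tolerance = 1e-10)
    expect_equal(mk_loglik(phy, c(A = "s1", B = "s1"), sp2, q),
                 log((ps^2 + pd^2) / 2 * 2 / 2) + log(1), tolerance = 1e-10)
  }
  expect_error(mk_loglik(phy, c(A = "s1", B = "s2"), sp2, -0.1), "non-negative")
})

test_that("pruning equals exhaustive enumeration across trees and models", {
  set.seed(17)
  for (ntip in 3:5) {
    for (n_states in 2:3) {
      phy <- ape::rtree(ntip)
      trait <- setNames(paste0("s", sample(n_states, ntip, TRUE)),
                        phy$tip.label)
      # ER
      spE <- mk_spec(n_states, "ER")
      qE <- runif(1, 0.05, 0.8)
      expect_equal(mk_loglik(phy, trait, spE, qE),
                   enum_mk_loglik(phy, trait, n_states, qE, spE),
                   tolerance = 1e-8)
      # ARD
      spA <- mk_spec(n_states, "ARD")
      rA <- runif(spA$n_params, 0.02, 0.9)
      expect_equal(mk_loglik(phy, trait, spA, rA),
                   enum_mk_loglik(phy, trait, n_states, rA, spA),
                   tolerance = 1e-8)
      # two-regime ARD with an arbitrary painting
      reg <- sample(c("x", "y"), nrow(phy$edge), TRUE)
      spM <- mk_spec(n_states, "ARD", regimes = reg)
      rM <- runif(spM$n_params, 0.02, 0.9)
      expect_equal(mk_loglik(phy, trait, spM, rM),
                   enum_mk_loglik(phy, trait, n_states, rM, spM),
                   tolerance = 1e-8)
    }
  }
})

test_that("Mk likelihood agrees with an independent implementation", {
  skip_if_not_installed("phytools")
  set.seed(9)
  phy <- ape::rtree(12)
  trait <- setNames(sample(c("a", "b", "c"), 12, TRUE), phy$tip.label)
  sp <- mk_spec(3, "ER", state_order = c("a", "b", "c"))
  q <- 0.4
  ours <- mk_loglik(phy, trait, sp, q)
  ref <- phytools::fitMk(phy, trait, model = "ER", fixedQ = {
    Q <- matrix(q, 3, 3); diag(Q) <- -2 * q; Q
  }, pi = "equal")
  expect_equal(ours, ref$logLik, tolerance = 1e-6)
})

test_that("ER rate recovery is unbiased: replicate median near the truth", {
  sc <- synthetic_scenario(seed = 27, n_tips = 300)
  tr <- simulate_tree(sc)
  sp <- mk_spec(3, "ER")
  q_true <- 0.02
  fits <- lapply(1:12, function(s) {
    sim <- simulate_mk(tr, sp, q_true, seed = 1000 + s)
    fit_mk(tr, sim$tip_states, sp, n_starts = 2, seed = 1)
  })
  expect_true(all(vapply(fits, `[[`, logical(1), "converged")))
  qhat <- vapply(fits, function(f) f$rates[[1]], numeric(1))
  expect_lt(abs(median(qhat) - q_true) / q_true, 0.25)
  expect_equal(fits[[1]]$aic, 2 * 1 - 2 * fits[[1]]$loglik)
})

test_that("regime degeneracy: identical paintings reproduce the unpainted fit", {
  sc <- synthetic_scenario(seed = 29, n_tips = 40)
  tr <- simulate_tree(sc)
  sp1 <- mk_spec(2, "ER")
  sim <- simulate_mk(tr, sp1, 0.01, seed = 2)
  f1 <- fit_mk(tr, sim$tip_states, sp1, n_starts = 2, seed = 1)
  same <- mk_spec(2, "ER", regimes = rep("only", nrow(tr$phylo$edge)))
  f2 <- fit_mk(tr, sim$tip_states, same, n_starts = 2, seed = 1)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
  # multi-regime with both regime blocks forced equal = single regime
  reg <- paint_regimes(tr, list(g = tr$phylo$tip.label[1:20]))
  spM <- mk_spec(2, "ER", regimes = reg)
  ll_multi <- mk_loglik(tr, sim$tip_states, spM, c(0.01, 0.01))
  ll_single <- mk_loglik(tr, sim$tip_states, sp1, 0.01)
  expect_equal(ll_multi, ll_single, tolerance = 1e-10)
})

test_that("constant traits drive the ER rate to the lower boundary", {
  sc <- synthetic_scenario(seed = 31, n_tips = 30)
  tr <- simulate_tree(sc)
  trait <- setNames(rep("s1", 30), tr$phylo$tip.label)
  fit <- fit_mk(tr, trait, mk_spec(2, "ER"), n_starts = 2, seed = 1)
  expect_true(fit$at_boundary)
  expect_lt(fit$rates[[1]], 1e-6)
})

test_that("Akaike weights follow the closed form and are shift-invariant", {
  expect_equal(akaike_weights(c(10, 10)), c(0.5, 0.5))
  expect_equal(akaike_weights(c(0, 20)),
               c(1 / (1 + exp(-10)), exp(-10) / (1 + exp(-10))))
  set.seed(1)
  a <- runif(5, 100, 140)
  w <- akaike_weights(a)
  expect_equal(sum(w), 1)
  expect_equal(akaike_weights(a + 57.3), w)
  expect_error(akaike_weights(c(1, NA)), "finite")
  expect_error(akaike_weights(3), "at least 2")
})

test_that("marginal ancestral states match direct Bayes computation and sum to 1", {
  # 2-tip tree: root posterior by hand from transition matrices
  phy <- ape::read.tree(text = "(A:1.5,B:0.7);")
  sp <- mk_spec(2, "ER")
  q <- 0.3
  asr <- marginal_ancestral_states(phy, c(A = "s1", B = "s2"), sp, q)
  Pt <- function(t) {
    ps <- (1 + exp(-2 * q * t)) / 2
    matrix(c(ps, 1 - ps, 1 - ps, ps), 2, 2)
  }
  lik <- c(Pt(1.5)[1, 1] * Pt(0.7)[1, 2], Pt(1.5)[2, 1] * Pt(0.7)[2, 2])
  expect_equal(unname(asr[1, ]), lik / sum(lik), tolerance = 1e-10)
  # uniform tips pull every node toward the shared state
  sc <- synthetic_scenario(seed = 33, n_tips = 25)
  tr <- simulate_tree(sc)
  trait <- setNames(rep(c("s1", "s2"), c(25, 0)), tr$phylo$tip.label)
  asr2 <- marginal_ancestral_states(tr, trait, mk_spec(2, "ER"), 0.005)
  expect_equal(unname(rowSums(asr2)), rep(1, nrow(asr2)), tolerance = 1e-9)
  expect_true(all(asr2[, "s1"] > 0.5))
  # annotated-NEXUS export carries per-node probability comments
  f <- tempfile(fileext = ".nex")
  write_ancestral_states(asr2, tr, f)
  txt <- paste(readLines(f), collapse = "")
  expect_true(grepl("p_s1=", txt) && grepl("#NEXUS", txt))
})

test_that("marginal reconstruction equals the enumeration oracle on small trees", {
  set.seed(23)
  phy <- ape::rtree(4)
  n <- 3
  sp <- mk_spec(n, "ARD")
  r <- runif(sp$n_params, 0.05, 0.6)
  trait <- setNames(c("s1", "s3", "s2", "s1"), phy$tip.label)
  asr <- marginal_ancestral_states(phy, trait, sp, r)
  # oracle: joint probability of each internal assignment, marginalised
  qs <- charsat:::mk_q_matrices(sp, r)
  Pm <- lapply(seq_len(nrow(phy$edge)), function(e)
    charsat:::expm_ss(qs[[1]] * phy$edge.length[e]))
  ints <- 5:7
  grid <- do.call(expand.grid, rep(list(1:n), 3))
  joint <- numeric(nrow(grid))
  tipidx <- match(trait[phy$tip.label], sp$state_order)
  for (g in seq_len(nrow(grid))) {
    st <- integer(7)
    st[ints] <- as.integer(grid[g, ]); st[1:4] <- tipidx
    p <- 1 / n
    for (e in seq_len(nrow(phy$edge)))
      p <- p * Pm[[e]][st[phy$edge[e, 1]], st[phy$edge[e, 2]]]
    joint[g] <- p
  }
  for (nd in 1:3) {
    marg <- vapply(1:n, function(s) sum(joint[grid[, nd] == s]), numeric(1))
    expect_equal(unname(asr[nd, ]), marg / sum(marg), tolerance = 1e-8)
  }
})

test_that("forward simulation honours zero rates, regimes and stationarity", {
  sc <- synthetic_scenario(seed = 37, n_tips = 50)
  tr <- simulate_tree(sc)
  sp <- mk_spec(4, "ER", state_order = SIZE_CATEGORIES)
  frozen <- simulate_mk(tr, sp, 0, root_state = "medium", seed = 3)
  expect_true(all(frozen$tip_states == "medium"))
  # high-rate ER approaches the uniform stationary distribution
  sp2 <- mk_spec(2, "ER")
  set.seed(77)
  freqs <- replicate(80, {
    s <- simulate_mk(tr, sp2, 0.5, seed = sample.int(1e6, 1))
    mean(s$tip_states == "s1")
  })
  # phylogenetic correlation inflates the per-replicate variance; 3-4 SE band
  expect_lt(abs(mean(freqs) - 0.5), 4 * sd(freqs) / sqrt(length(freqs)))
  # upward-only regime: size never decreases along any path in that clade
  sz <- simulate_size_dataset(tr, sc)
  ord <- match(sz$history$node_states, SIZE_CATEGORIES)
  phy <- tr$phylo
  up_edges <- which(sz$regimes == "up")
  for (e in up_edges) {
    expect_gte(ord[phy$edge[e, 2]], ord[phy$edge[e, 1]])
  }
})

test_that("the four-model comparison table is internally consistent", {
  sc <- synthetic_scenario(seed = 43, n_tips = 60)
  tr <- simulate_tree(sc)
  sz <- simulate_size_dataset(tr, sc)
  ms <- fit_mk_model_set(tr, sz$trait, sz$regimes, SIZE_CATEGORIES,
                         n_starts = 1, seed = 1, maxit = 200)
  cmp <- ms$comparison
  expect_equal(cmp$k, c(1, 12, 2, 24))
  expect_equal(cmp$aic, 2 * cmp$k - 2 * cmp$loglik)
  expect_equal(sum(cmp$weight), 1)
  # nested models never beat their supersets on raw likelihood
  expect_gte(ms$fits$single_ard$loglik, ms$fits$single_er$loglik - 1e-4)
  expect_gte(ms$fits$multi_er$loglik, ms$fits$single_er$loglik - 1e-4)
  expect_gte(ms$fits$multi_ard$loglik, ms$fits$single_ard$loglik - 1e-4)
})
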
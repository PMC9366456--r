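test_that("birth-death trees honour the scenario conditions and seeds", {
  sc <- synthetic_scenario(seed = 101, n_tips = 40)
  tr <- simulate_tree(sc)
  expect_equal(ape::Ntip(tr$phylo), 40L)
  expect_equal(tr$root_age, 320)
  # parent older than child everywhere; fossil tips above 0 Ma allowed
  edge <- tr$phylo$edge
  expect_true(all(tr$node_age[edge[, 1]] >= tr$node_age[edge[, 2]] - 1e-9))
  # both root subclades diverse
  kids <- edge[edge[, 1] == 41L, 2]
  sides <- charsat:::clade_node_tips_all(tr$phylo)[kids]
  expect_gte(min(lengths(sides)), 10L)
  # bit-reproducible under a fixed seed
  tr2 <- simulate_tree(sc)
  expect_identical(ape::write.tree(tr$phylo), ape::write.tree(tr2$phylo))
  # pure birth: all tips extant
  scp <- synthetic_scenario(seed = 102, n_tips = 30, death = 0)
  trp <- simulate_tree(scp)
  expect_true(all(abs(trp$node_age[1:30]) < 1e-6))
  # a death-dominated scenario has fossil tips
  scf <- synthetic_scenario(seed = 103, n_tips = 40)
  trf <- simulate_tree(scf)
  expect_gt(sum(trf$node_age[1:40] > 1), 0)
  # unattainable conditions error rather than loop forever
  sc_bad <- synthetic_scenario(seed = 1, n_tips = 500, birth = 0.003,
                               death = 0.003)
  expect_error(simulate_tree(sc_bad, max_attempts = 5L), "could not obtain")
})

test_that("constrained matrices carry coherent ground truth", {
  sc <- synthetic_scenario(seed = 107, n_tips = 30, n_chars = 100)
  tr <- simulate_tree(sc)
  out <- simulate_constrained_matrix(tr, sc)
  m <- out$matrix
  expect_equal(dim(m), c(30L, 100L))
  gt <- out$ground_truth
  # constrained clade is a real clade of intermediate size
  expect_true(length(gt$constrained_clade) >= 30 / 4 - 1)
  expect_true(all(gt$constrained_clade %in% tr$phylo$tip.label))
  # inside the clade only k_constrained states are accessible
  expect_setequal(unique(gt$k_edge), c(sc$k_constrained, sc$k_background))
  # missingness near the nominal fraction
  expect_equal(mean(is.na(m$cells)), sc$missing_fraction, tolerance = 0.05)
  # realised change counts track the Poisson expectation (per-edge totals)
  expect_equal(sum(gt$realized_changes),
               sum(gt$expected_changes) * sc$n_chars, tolerance = 0.15)
  # changes tree congruent with the time tree, branch lengths = expectations
  expect_equal(out$changes_tree$phylo$edge.length, gt$expected_changes)
  # deterministic regeneration
  out2 <- simulate_constrained_matrix(tr, sc)
  expect_identical(out$matrix$cells, out2$matrix$cells)
})

test_that("k=2 everywhere saturates dissimilarity near 1/2 on long trees", {
  sc <- synthetic_scenario(seed = 109, n_tips = 24, n_chars = 200,
                           k_background = 2, base_rate = 0.05,
                           rate_profile = "constant", missing_fraction = 0)
  tr <- simulate_tree(sc)
  out <- simulate_constrained_matrix(tr, sc, constrained_clade = character(0))
  D <- mord_dissimilarity(out$matrix)$value
  P <- patristic_distances(out$changes_tree)$value
  deep <- P[upper.tri(P)] > 5  # many expected changes per character
  expect_gt(sum(deep), 10)
  expect_equal(mean(D[upper.tri(D)][deep]), 0.5, tolerance = 0.05)
})

test_that("rate-burst trees follow the profile and group multipliers exactly", {
  sc <- synthetic_scenario(seed = 113, n_tips = 20, rate_profile = "constant",
                           base_rate = 0.03)
  tr0 <- simulate_tree(sc)
  tr <- generate_rate_burst_tree(tr0, sc)
  expect_equal(unname(tr$branch_rate), rep(0.03, nrow(tr0$phylo$edge)))
  sce <- synthetic_scenario(seed = 113, n_tips = 20,
                            rate_profile = "exponential", half_life = 10,
                            base_rate = 0.03)
  tre <- generate_rate_burst_tree(tr0, sce)
  mid <- (tr0$node_age[tr0$phylo$edge[, 1]] + tr0$node_age[tr0$phylo$edge[, 2]]) / 2
  expect_equal(unname(tre$branch_rate), 0.03 * 2^(-(320 - mid) / 10))
  g <- list(g1 = charsat:::clade_node_tips_all(tr0$phylo)[[
    tr0$phylo$edge[tr0$phylo$edge[, 1] == 21L, 2][1]]])
  trg <- generate_rate_burst_tree(tr0, sc, group_multipliers = list(g1 = 2),
                                  groups = g)
  in_g <- vapply(seq_len(nrow(tr0$phylo$edge)), function(e)
    all(charsat:::clade_node_tips_all(tr0$phylo)[[tr0$phylo$edge[e, 2]]] %in% g$g1),
    logical(1))
  expect_equal(unname(trg$branch_rate[in_g]), rep(0.06, sum(in_g)))
  expect_equal(unname(trg$branch_rate[!in_g]), rep(0.03, sum(!in_g)))
})

test_that("generated artifacts round-trip through the io layer unchanged", {
  sc <- synthetic_scenario(seed = 127, n_tips = 18, n_chars = 40)
  dir <- tempfile()
  write_synthetic_dataset(sc, dir)
  expect_true(all(file.exists(file.path(dir,
    c("matrix.nex", "time_tree.nex", "changes_tree.nwk", "metadata.csv",
      "sizes.csv", "ground_truth.tsv", "provenance.txt")))))
  tr <- simulate_tree(sc)
  simmed <- simulate_constrained_matrix(tr, sc)
  m2 <- read_nexus_matrix(file.path(dir, "matrix.nex"))
  expect_identical(unname(m2$cells), unname(simmed$matrix$cells))
  tt2 <- read_annotated_tree(file.path(dir, "time_tree.nex"), root_age = 320)
  expect_setequal(tt2$phylo$tip.label, tr$phylo$tip.label)
  ct2 <- read_changes_tree(file.path(dir, "changes_tree.nwk"), reference = tt2)
  expect_s3_class(ct2, "changes_tree")
  md <- read_metadata(file.path(dir, "metadata.csv"), m2)
  expect_false(any(md$unassigned))
  expect_setequal(unique(md$clade), c("constrained", "background"))
})
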
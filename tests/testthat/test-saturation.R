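test_that("Michaelis-Menten fitter recovers exact parameters from noiseless data", {
  P <- seq(0.1, 2, 0.1)
  fit <- fit_michaelis_menten(data.frame(D = 1.0 * P / (0.5 + P), P = P))
  expect_true(fit$converged)
  expect_equal(fit$vmax, 1.0, tolerance = 1e-6)
  expect_equal(fit$km, 0.5, tolerance = 1e-6)
  expect_true(fit$vmax_ci84[1] <= fit$vmax && fit$vmax <= fit$vmax_ci84[2])
})

test_that("degenerate and underdetermined inputs are handled honestly", {
  P <- seq(0.1, 2, 0.1)
  flat <- fit_michaelis_menten(data.frame(D = rep(0, 20), P = P))
  expect_equal(flat$vmax, 0)
  expect_true(flat$converged)
  # 2 pairs: below min_pairs -> untestable, not an error
  few <- fit_michaelis_menten(data.frame(D = c(.1, .2), P = c(1, 2)))
  expect_true(few$untestable)
  # <3 distinct P values -> untestable
  tied <- fit_michaelis_menten(data.frame(D = runif(10), P = rep(c(1, 2), 5)))
  expect_true(tied$untestable)
})

test_that("vmax is scale-equivariant in D and invariant to P scaling", {
  set.seed(2)
  P <- runif(40, 0.05, 3)
  D <- 0.8 * P / (0.4 + P) + rnorm(40, 0, 0.02)
  f0 <- fit_michaelis_menten(data.frame(D = D, P = P))
  fD <- fit_michaelis_menten(data.frame(D = 3 * D, P = P))
  fP <- fit_michaelis_menten(data.frame(D = D, P = 5 * P))
  expect_equal(fD$vmax, 3 * f0$vmax, tolerance = 1e-5)
  expect_equal(fP$vmax, f0$vmax, tolerance = 1e-5)
  expect_equal(fP$km, 5 * f0$km, tolerance = 1e-5)
})

test_that("vmax estimation is unbiased within Monte-Carlo error on noisy curves", {
  set.seed(31)
  est <- replicate(120, {
    P <- runif(50, 0.1, 4)
    D <- 0.9 * P / (0.6 + P) + rnorm(50, 0, 0.05)
    fit_michaelis_menten(data.frame(D = D, P = P))$vmax
  })
  mc_se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 0.9), 3 * mc_se + 0.005)
})

test_that("null matrices reproduce the template mask and the zero-length limit", {
  m <- cm_from_strings(c(A = "01?0", B = "0{12}-1", C = "1101"))
  phy0 <- ape::read.tree(text = "((A:0,B:0):0,C:0);")
  sim <- simulate_null_matrix(changes_tree(phy0), m, seed = 5)
  # zero branch lengths: every taxon inherits the root state
  expect_equal(dim(sim), dim(m))
  for (j in 1:4) {
    v <- sim$cells[, j]
    v <- v[!is.na(v) & v != "-"]
    expect_lte(length(unique(v)), 1L)
  }
  # mask written in exactly the template's cells
  expect_identical(is.na(sim$cells), is.na(m$cells))
  expect_identical(sim$cells == "-", m$cells == "-")
  # determinism under a fixed seed
  sim2 <- simulate_null_matrix(changes_tree(phy0), m, seed = 5)
  expect_identical(sim$cells, sim2$cells)
  phyX <- ape::read.tree(text = "((A:1,X:1):1,C:1);")
  expect_error(simulate_null_matrix(changes_tree(phyX), m, seed = 1),
               "taxon sets")
})

test_that("null simulation reaches the (k-1)/k stationary dissimilarity on long branches", {
  # taxa separated by very long paths; k=3 characters
  phy <- ape::read.tree(text = "((A:50,B:50):1,C:50);")
  cells <- rbind(A = rep("0", 300), B = rep("1", 300), C = rep("2", 300))
  m <- character_matrix(cells)
  expect_equal(m$char_meta$n_observed_states, rep(3L, 300))
  D <- mean(vapply(1:5, function(s)
    mord_dissimilarity(simulate_null_matrix(changes_tree(phy), m,
                                            seed = s))$value["A", "B"],
    numeric(1)))
  expect_equal(D, 2 / 3, tolerance = 0.04)
})

test_that("constraint classification applies the 84% CI-versus-band rule", {
  mk_fit_obj <- function(lo, hi) {
    structure(list(vmax = (lo + hi) / 2, km = 1, vmax_se = (hi - lo) / 2 / 1.4051,
                   vmax_ci84 = c(lo, hi), n_pairs = 50, residual_ss = 1,
                   converged = TRUE, untestable = FALSE), class = "mm_fit")
  }
  null_obj <- structure(list(values = seq(0.76, 0.87, length.out = 100),
                             n_sims = 100, central84 = c(0.76, 0.87),
                             median = 0.815, n_attempted = 100, n_failed = 0),
                        class = "null_vmax")
  expect_equal(classify_constraint(mk_fit_obj(0.90, 1.10), null_obj)$call, "relaxed")
  expect_equal(classify_constraint(mk_fit_obj(0.40, 0.50), null_obj)$call, "strengthened")
  expect_equal(classify_constraint(mk_fit_obj(0.70, 0.85), null_obj)$call, "none")
  bad <- structure(list(vmax = NA, vmax_ci84 = c(NA, NA), n_pairs = 2,
                        converged = FALSE, untestable = TRUE), class = "mm_fit")
  expect_equal(classify_constraint(bad, null_obj)$call, "untestable")
})

test_that("null vmax distributions are seed-reproducible with honest bookkeeping", {
  sc <- synthetic_scenario(seed = 3, n_tips = 25, n_chars = 80)
  tr <- simulate_tree(sc)
  sim <- simulate_constrained_matrix(tr, sc)
  nv1 <- null_vmax_distribution(sim$changes_tree, sim$matrix, n_sims = 100,
                                seed = 17)
  nv2 <- null_vmax_distribution(sim$changes_tree, sim$matrix, n_sims = 100,
                                seed = 17)
  expect_identical(nv1$values, nv2$values)
  expect_equal(nv1$n_attempted, 100L)
  expect_true(nv1$central84[1] <= nv1$median && nv1$median <= nv1$central84[2])
  expect_equal(nv1$n_sims + nv1$n_failed, 100L)
  expect_error(null_vmax_distribution(sim$changes_tree, sim$matrix,
                                      n_sims = 10, seed = 1), "n_sims")
})

test_that("stronger constraint (smaller k) yields smaller saturation asymptotes", {
  sc2 <- synthetic_scenario(seed = 8, n_tips = 30, n_chars = 150,
                            k_background = 2, missing_fraction = 0)
  sc6 <- synthetic_scenario(seed = 8, n_tips = 30, n_chars = 150,
                            k_background = 6, missing_fraction = 0)
  tr <- simulate_tree(sc2)
  m2 <- simulate_constrained_matrix(tr, sc2, constrained_clade = character(0))
  m6 <- simulate_constrained_matrix(tr, sc6, constrained_clade = character(0))
  f2 <- fit_michaelis_menten(build_pair_table(
    mord_dissimilarity(m2$matrix), patristic_distances(m2$changes_tree), tr))
  f6 <- fit_michaelis_menten(build_pair_table(
    mord_dissimilarity(m6$matrix), patristic_distances(m6$changes_tree), tr))
  expect_true(f2$converged && f6$converged)
  expect_lt(f2$vmax, f6$vmax)
})

test_that("84% and 95% CI overlap frequencies match theory", {
  # closed form: P(overlap) = 1 - 2*pnorm(-sqrt(2)*z)
  ov84 <- ci_overlap_calibration(84, 50000, seed = 2)
  ov95 <- ci_overlap_calibration(95, 50000, seed = 2)
  expect_equal(ov84, 1 - 2 * pnorm(-sqrt(2) * qnorm(0.92)), tolerance = 0.01)
  expect_equal(ov95, 1 - 2 * pnorm(-sqrt(2) * qnorm(0.975)), tolerance = 0.005)
  # widely separated estimators never overlap
  z <- qnorm(0.92)
  sep <- with(list(), {
    set.seed(4)
    x1 <- rnorm(1000); x2 <- rnorm(1000) + 1000
    mean(abs(x1 - x2) <= 2 * z)
  })
  expect_equal(sep, 0)
})
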
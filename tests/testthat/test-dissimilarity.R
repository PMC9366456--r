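test_that("MORD matches hand-enumerated examples", {
  # A=(0,1,0,?), B=(1,1,1,0): 3 comparable characters, 2 differ
  m <- cm_from_strings(c(A = "010?", B = "1110"))
  D <- mord_dissimilarity(m)
  expect_equal(D$value["A", "B"], 2 / 3)
  expect_equal(D$n_comparable["A", "B"], 3L)
  # identical complete rows
  m2 <- cm_from_strings(c(A = "0120", B = "0120"))
  expect_equal(mord_dissimilarity(m2)$value["A", "B"], 0)
  # no comparable characters -> undefined
  m3 <- cm_from_strings(c(A = "???", B = "012"))
  expect_true(is.na(mord_dissimilarity(m3)$value["A", "B"]))
  # polymorphism: intersecting state sets count as a match
  m4 <- cm_from_strings(c(A = "{01}2", B = "02"))
  expect_equal(mord_dissimilarity(m4)$value["A", "B"], 0)
  # inapplicable behaves like missing for the computation
  m5 <- cm_from_strings(c(A = "01-", B = "010"))
  expect_equal(mord_dissimilarity(m5)$value["A", "B"], 0)
  expect_error(mord_dissimilarity(cm_from_strings(c(A = "01"))), "2 taxa")
})

test_that("ordered characters use range-rescaled minimum state distance", {
  # char 1 ordered with observed states {0,1,2,4}: range 4
  cells <- rbind(A = c("0", "1"), B = c("4", "0"), C = c("12", "1"))
  m <- character_matrix(cells, ordered = c(TRUE, FALSE))
  D <- mord_dissimilarity(m)
  expect_equal(D$value["A", "B"], ((4 - 0) / 4 + 1) / 2)
  # minimum over the polymorphic set: |1-2|=1 rescaled by 4
  expect_equal(D$value["A", "C"], ((1 / 4) + 0) / 2)
  expect_equal(D$value["B", "C"], ((2 / 4) + 1) / 2)
})

test_that("MORD equals Hamming/n for complete unordered binary matrices", {
  set.seed(7)
  for (rep in 1:5) {
    cells <- matrix(sample(c("0", "1"), 6 * 30, TRUE), 6, 30,
                    dimnames = list(paste0("t", 1:6), NULL))
    m <- character_matrix(cells)
    D <- mord_dissimilarity(m)$value
    ham <- outer(seq_len(6), seq_len(6), Vectorize(function(i, j)
      mean(cells[i, ] != cells[j, ])))
    expect_equal(unname(D), unname(ham))
  }
})

test_that("MORD is invariant to taxon and character permutations, and to
           characters unscored in one member of a pair", {
  set.seed(11)
  pool <- c("0", "1", "2", "01", NA, "-")
  cells <- matrix(sample(pool, 8 * 25, TRUE, prob = c(.3, .3, .15, .05, .15, .05)),
                  8, 25, dimnames = list(paste0("t", 1:8), NULL))
  m <- character_matrix(cells)
  D <- mord_dissimilarity(m)$value
  for (rep in 1:3) {
    ti <- sample(8); cj <- sample(25)
    mp <- character_matrix(cells[ti, cj])
    Dp <- mord_dissimilarity(mp)$value
    expect_equal(Dp[rownames(D), colnames(D)], D)
  }
  # appending a character missing in taxon 1 never changes taxon 1's distances
  extra <- cells
  newcol <- sample(c("0", "1"), 8, TRUE)
  newcol[1] <- NA
  extra <- cbind(extra, newcol)
  D2 <- mord_dissimilarity(character_matrix(extra))$value
  expect_equal(D2[1, ], D[1, ])
})

test_that("patristic distances are path sums and satisfy tree metrics", {
  # single path
  p2 <- ape::read.tree(text = "(A:0.3,B:0.5);")
  expect_equal(patristic_distances(p2)$value["A", "B"], 0.8)
  # hand path sum on a 4-tip tree
  p4 <- ape::read.tree(text = "((A:1,B:2):3,(C:4,D:5):6);")
  P <- patristic_distances(p4)$value
  expect_equal(P["A", "C"], 1 + 3 + 6 + 4)
  expect_equal(unname(diag(P)), rep(0, 4))
  skip_if_not_installed("igraph")
  set.seed(3)
  for (rep in 1:5) {
    phy <- ape::rtree(8)
    P <- patristic_distances(phy)$value
    expect_equal(P, igraph_patristic(phy), tolerance = 1e-10)
    # four-point condition on random quartets
    q <- sample(8, 4)
    s <- c(P[q[1], q[2]] + P[q[3], q[4]],
           P[q[1], q[3]] + P[q[2], q[4]],
           P[q[1], q[4]] + P[q[2], q[3]])
    expect_lte(max(s) - sort(s, decreasing = TRUE)[2], 1e-10)
  }
})

test_that("pair tables join distances with MRCA ages and drop undefined pairs", {
  tt <- tiny_time_tree(320)
  m <- cm_from_strings(c(A = "0101", B = "1101", C = "???0"))
  D <- mord_dissimilarity(m)
  ct <- changes_tree(ape::read.tree(text = "((A:0.1,B:0.2):0.3,C:0.4);"),
                     reference = tt)
  P <- patristic_distances(ct)
  pt <- build_pair_table(D, P, tt)
  expect_equal(nrow(pt), 3L)  # C(3,2)
  ab <- pt[pt$taxon_a == "A" & pt$taxon_b == "B", ]
  expect_equal(ab$mrca_age, 310)
  expect_equal(ab$P, 0.3)
  # a pair whose MRCA is the root gets the root age
  expect_equal(pt$mrca_age[pt$taxon_b == "C" | pt$taxon_a == "C"], c(320, 320))
  # all-undefined scope warns and returns empty
  m2 <- cm_from_strings(c(A = "??", B = "01", C = "10"))
  D2 <- mord_dissimilarity(m2)
  expect_warning(
    pt2 <- suppressMessages(build_pair_table(D2, P, tt, scope = c("A", "B"))),
    "undefined")
  expect_equal(nrow(pt2), 0L)
  expect_error(build_pair_table(D, P, tt, scope = "Z"), "fewer than 2")
})

test_that("divergence-window filtering keeps mrca ages inside [young, old]", {
  pt <- structure(data.frame(taxon_a = "a", taxon_b = "b",
                             D = 0.5, P = 1,
                             mrca_age = c(300, 250, 320, 272, 271.9)),
                  class = c("pair_table", "data.frame"))
  kept <- filter_pairs_by_divergence(pt, c(320, 272))
  expect_equal(kept$mrca_age, c(300, 320, 272))
  expect_error(filter_pairs_by_divergence(pt, c(272, 320)), "old > young")
})

test_that("pair tables and distance matrices round-trip through disk", {
  tt <- tiny_time_tree()
  m <- cm_from_strings(c(A = "0101", B = "1101", C = "0110"))
  D <- mord_dissimilarity(m)
  P <- patristic_distances(changes_tree(
    ape::read.tree(text = "((A:0.1,B:0.2):0.3,C:0.4);")))
  pt <- build_pair_table(D, P, tt)
  f <- tempfile(fileext = ".tsv")
  write_pair_table(pt, f)
  pt2 <- read_pair_table(f)
  expect_equal(pt2$D, pt$D)
  expect_equal(pt2$taxon_a, pt$taxon_a)
  fd <- tempfile(fileext = ".csv")
  write_distance_matrix(D, fd)
  expect_true(file.exists(fd))
})
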
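test_that("Jukes-Cantor correction has the expected closed form", {
  s <- table2_sequences(total_length = 520)
  jc <- jc_distances(s)
  expect_equal(diag(jc), setNames(rep(0, 8), rownames(jc)))
  expect_true(isSymmetric(unclass(jc)))
  # closed form at p = 0.1
  p <- 0.1
  expect_equal(round(-0.75 * log(1 - 4 * p / 3), 5), 0.10733)
  # correction exceeds p and is increasing
  ps <- seq(0.01, 0.7, by = 0.01)
  d <- -0.75 * log(1 - 4 * ps / 3)
  expect_true(all(d >= ps))
  expect_true(all(diff(d) > 0))
  # undefined beyond saturation
  s_bad <- s
  s_bad$total_length <- 20  # forces p >= 0.75 for divergent pairs
  expect_error(jc_distances(s_bad), "0.75")
})

test_that("distances are metric (Hamming, chord) or near-metric (JC)", {
  s <- table2_sequences(total_length = 520)
  H <- hamming_matrix(s$states)$d
  n <- nrow(H)
  for (i in 1:n) for (j in 1:n) for (k in 1:n)
    expect_lte(H[i, j], H[i, k] + H[k, j])
  # the convex JC transform can overshoot the triangle inequality by
  # O(p^2); on this fixture the violation stays below 3e-4
  D <- jc_distances(s)
  viol <- 0
  for (i in 1:n) for (j in 1:n) for (k in 1:n)
    viol <- max(viol, D[i, j] - D[i, k] - D[k, j])
  expect_lt(viol, 3e-4)
  # chord distances over random frequency tables are metric
  set.seed(12)
  f <- list(matrix(0, 5, 6, dimnames = list(paste0("p", 1:5), NULL)))
  for (p in 1:5) f[[1]][p, ] <- {x <- rgamma(6, 1); x / sum(x)}
  C <- chord_distance(f)
  for (i in 1:5) for (j in 1:5) for (k in 1:5)
    expect_lte(C[i, j], C[i, k] + C[k, j] + 1e-12)
})

test_that("chord distance matches closed forms", {
  pops <- c("p1", "p2")
  f_id <- list(matrix(c(0.3, 0.7, 0.3, 0.7), 2, byrow = TRUE,
                      dimnames = list(pops, NULL)))
  expect_equal(chord_distance(f_id)["p1", "p2"], 0)
  f_dis <- list(matrix(c(1, 0, 0, 1), 2, byrow = TRUE,
                       dimnames = list(pops, NULL)))
  expect_equal(chord_distance(f_dis)["p1", "p2"], 2 * sqrt(2) / pi)
  f <- list(matrix(c(0.5, 0.5, 0.9, 0.1), 2, byrow = TRUE,
                   dimnames = list(pops, NULL)))
  hand <- 2 / pi * sqrt(2 * (1 - (sqrt(0.5 * 0.9) + sqrt(0.5 * 0.1))))
  expect_equal(chord_distance(f)["p1", "p2"], hand)
  # mismatched allele sets union with zeros: same answer as explicit zeros
  g <- build_genotype_table(list(
    a = list(rbind(c(1, 1), c(1, 1))),
    b = list(rbind(c(2, 2), c(2, 2)))), "L1")
  expect_equal(chord_distance(g)["a", "b"], 2 * sqrt(2) / pi)
})

test_that("neighbor joining solves the three-taxon closed form", {
  D <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(D)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl[c("A", "B", "C")]), c(0.5, 1.5, 2.5))
})

test_that("neighbor joining recovers additive trees exactly", {
  set.seed(5)
  for (n_taxa in c(5, 8)) {
    true_tree <- ape::rtree(n_taxa)
    D <- ape::cophenetic.phylo(true_tree)  # path-length oracle
    tr <- neighbor_joining(D)
    expect_equal(ape::dist.topo(ape::unroot(true_tree), tr), 0,
                 ignore_attr = TRUE)
    # recovered path lengths equal the input distances
    expect_equal(ape::cophenetic.phylo(tr)[rownames(D), colnames(D)], D,
                 tolerance = 1e-8)
  }
})

test_that("a star tree collapses internal branches to zero", {
  D <- matrix(2, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(D) <- 0
  tr <- neighbor_joining(D)
  internal <- tr$edge[, 2] > ape::Ntip(tr)
  expect_true(all(tr$edge.length[internal] < 1e-12))
  expect_error(neighbor_joining(D * NA), "non-finite")
})

test_that("bootstrap supports hit 100% for a single resampling unit", {
  g <- build_genotype_table(list(
    a = list(rbind(c(1, 1), c(1, 1))),
    b = list(rbind(c(2, 2), c(2, 2))),
    c = list(rbind(c(3, 3), c(3, 3))),
    d = list(rbind(c(3, 4), c(4, 4)))), "L1")
  # one locus: resampling falls back to genotypes, which are constant
  # within populations, so every replicate reproduces the same tree
  bt <- bootstrap_support(g, n_reps = 50, seed = 2)
  expect_true(all(bt$node.label == 100))
})

test_that("well-separated clusters earn high support", {
  g <- simulate_island_genotypes(
    c(a = 30, b = 30, c = 30, d = 30), c(12, 12, 12, 12),
    target_fst = 0.02, groups = c("g1", "g1", "g2", "g2"),
    group_fst = 0.5, seed = 21)
  bt <- bootstrap_support(g, n_reps = 50, seed = 4)
  # the (a,b) | (c,d) bipartition is the only internal edge of 4 tips
  expect_gte(max(bt$node.label, na.rm = TRUE), 95)
  # stochastic stability: two seeds agree within 5 points per node
  bt2 <- bootstrap_support(g, n_reps = 1000, seed = 5)
  bt3 <- bootstrap_support(g, n_reps = 1000, seed = 6)
  expect_true(all(abs(bt2$node.label - bt3$node.label) < 5))
})

test_that("sequence bootstrap resamples alignment columns", {
  s <- table2_sequences(total_length = 520)
  bt <- bootstrap_support(s, n_reps = 60, seed = 9)
  expect_s3_class(bt, "phylo")
  expect_setequal(bt$tip.label, rownames(table2_matrix()$states))
  tmp <- withr::local_tempfile(fileext = ".nwk")
  write_tree_newick(bt, tmp)
  expect_true(file.exists(tmp))
})
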
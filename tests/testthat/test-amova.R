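test_that("duplicated populations yield no among-group structure", {
  one <- rbind(c(1, 2), c(1, 1), c(2, 2), c(1, 2), c(2, 1), c(2, 2))
  g <- build_genotype_table(list(a = list(one), b = list(one),
                                 c = list(one), d = list(one)), "L1")
  am <- hierarchical_amova(g, groups = c(a = "g1", b = "g1",
                                         c = "g2", d = "g2"),
                           n_perm = 200, seed = 3)
  # identical tables give zero among-pop and among-group sums of squares;
  # the unbiased sigma_b estimate is then <= 0 (never positive structure)
  expect_lt(abs(am$fit$sigma["a"]), 1e-10)
  expect_lte(am$fit$sigma["b"], 0)
  expect_lt(abs(unname(am$fit$ss[1])), 1e-10)
  expect_lt(abs(unname(am$fit$ss[2])), 1e-10)
  expect_gt(am$p["Fct"], 0.2)
})

test_that("components equal a hand-computed nested ANOVA", {
  # 2 groups x 2 pops x 3 individuals, biallelic, one locus
  pops <- list(
    a1 = list(rbind(c(1, 1), c(1, 2), c(1, 1))),
    a2 = list(rbind(c(1, 1), c(1, 1), c(1, 2))),
    b1 = list(rbind(c(2, 2), c(1, 2), c(2, 2))),
    b2 = list(rbind(c(2, 2), c(2, 2), c(2, 1))))
  g <- build_genotype_table(pops, "L1")
  groups <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  am <- hierarchical_amova(g, groups = groups, n_perm = 0)

  # independent computation from pairwise identity distances over the 24
  # gene copies: SS(set) = (1/n) sum_{i<j} d_ij with d = 1 - identity
  copies <- unlist(lapply(pops, function(p) as.vector(t(p[[1]]))))
  popv <- rep(names(pops), each = 6)
  grpv <- groups[popv]
  ss_pairs <- function(x) {
    n <- length(x); tot <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      tot <- tot + (x[i] != x[j])
    tot / n
  }
  ss_tot <- ss_pairs(copies)
  ss_wp <- sum(tapply(copies, popv, ss_pairs))
  ss_wg <- sum(tapply(copies, grpv, ss_pairs))
  expect_equal(unname(am$fit$ss),
               unname(c(ss_tot - ss_wg, ss_wg - ss_wp, ss_wp)))
  # balanced design: n1 = n2 = copies per pop, n3 = copies per group
  msd <- c((ss_tot - ss_wg) / 1, (ss_wg - ss_wp) / 2, ss_wp / 20)
  sig_c <- msd[3]
  sig_b <- (msd[2] - sig_c) / 6
  sig_a <- (msd[1] - sig_c - 6 * sig_b) / 12
  expect_equal(unname(am$fit$sigma), unname(c(sig_a, sig_b, sig_c)))
  # identity F_ST = F_CT + (1 - F_CT) F_SC
  f <- am$fit
  expect_equal(f$Fst, f$Fct + (1 - f$Fct) * f$Fsc, tolerance = 1e-12)
})

test_that("percent variation sums to 100 and labels do not matter", {
  g <- simulate_island_genotypes(
    c(a = 20, b = 20, c = 20, d = 20), c(8, 10), 0.05,
    groups = c("g1", "g1", "g2", "g2"), group_fst = 0.15, seed = 5)
  gmap <- c(a = "g1", b = "g1", c = "g2", d = "g2")
  am <- hierarchical_amova(g, groups = gmap, n_perm = 0)
  expect_equal(sum(100 * am$fit$sigma / sum(am$fit$sigma)), 100,
               tolerance = 0.01)
  # relabel groups and populations
  g2 <- g
  ren <- c(a = "w", b = "x", c = "y", d = "z")
  g2$individuals$pop <- unname(ren[g$individuals$pop])
  am2 <- hierarchical_amova(
    g2, groups = setNames(c("G9", "G9", "G7", "G7"), c("w", "x", "y", "z")),
    n_perm = 0)
  expect_equal(am2$fit$sigma, am$fit$sigma)
})

test_that("a simulated 4-gene-pool design is recovered", {
  des <- fixture_dataset("table1_design")
  sizes <- setNames(des$n_mic, des$code)
  gmap <- setNames(c(rep("AtlN", 6), "Bra", "Oce", "Oce", "Saf"),
                   des$code)
  est <- vapply(1:20, function(i) {
    g <- simulate_island_genotypes(sizes, c(14, 18, 22, 25),
                                   target_fst = 0.002,
                                   groups = unname(gmap[names(sizes)]),
                                   group_fst = 0.24, seed = 900 + i)
    am <- hierarchical_amova(g, groups = gmap, n_perm = 0)
    c(fct = am$fit$Fct, fsc = am$fit$Fsc)
  }, c(fct = 0, fsc = 0))
  expect_lt(abs(mean(est["fct", ]) - 0.24), 0.05)
  expect_lt(abs(mean(est["fsc", ]) - 0.002), 0.01)
  # qualitative pattern: strong among-group, negligible within-group
  expect_gte(mean(est["fct", ] > 10 * abs(est["fsc", ])), 18 / 20)
})

test_that("permutation p-values are calibrated under no structure", {
  ps <- vapply(1:150, function(i) {
    g <- simulate_island_genotypes(c(a = 12, b = 12, c = 12, d = 12),
                                   c(6), 0, seed = 2000 + i)
    hierarchical_amova(g, n_perm = 39, seed = 3000 + i)$p["Fst"]
  }, numeric(1))
  # (hits+1)/(39+1) is discrete uniform on {1/40,...,1} up to the +1
  # conservatism: mean 0.5125, slightly thin lower tail
  expect_lt(abs(mean(ps) - 0.5125), 0.06)
  expect_lt(abs(mean(ps <= 0.1) - 0.1), 0.05)
  expect_gt(min(ps), 0)
})

test_that("a single-population group is flagged", {
  one <- rbind(c(1, 2), c(1, 1))
  g <- build_genotype_table(list(a = list(one), b = list(one),
                                 c = list(one)), "L1")
  am <- hierarchical_amova(g, groups = c(a = "g1", b = "g1", c = "g2"),
                           n_perm = 0)
  expect_true("g2" %in% am$flagged_groups)
})
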
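test_that("locus summaries match hand arithmetic on a 4-individual locus", {
  # genotypes 11/12, 12/12, 11/11, 12/14
  g <- build_genotype_table(list(
    p1 = list(rbind(c(11, 12), c(12, 12), c(11, 11), c(12, 14)))), "L1")
  sm <- locus_summaries(g, rarefaction_g = 2)
  expect_equal(sm$n, 4)
  expect_equal(sm$A, 3)
  expect_equal(sm$Ho, 0.5)
  # p = (3, 4, 1)/8; He = 2n/(2n-1) (1 - sum p^2)
  He <- 8 / 7 * (1 - (9 + 16 + 1) / 64)
  expect_equal(sm$He, He)
  expect_equal(sm$Fis, 1 - 0.5 / He)
})

test_that("monomorphic loci summarize to zero diversity, Fis undefined", {
  g <- build_genotype_table(list(
    p1 = list(rbind(c(7, 7), c(7, 7), c(7, 7)))), "L1")
  sm <- locus_summaries(g, rarefaction_g = 2)
  expect_equal(sm$A, 1)
  expect_equal(sm$He, 0)
  expect_equal(sm$Ho, 0)
  expect_true(is.na(sm$Fis))
})

test_that("rarefied richness hits its limits", {
  # all alleles distinct, rarefy to full sample: Rs = A
  expect_equal(allelic_richness(rep(1, 8), 8), 8)
  expect_equal(allelic_richness(c(5, 5), 1), 1)
  # monotone in g
  rs <- vapply(1:10, function(g) allelic_richness(c(6, 3, 1), g), 0)
  expect_true(all(diff(rs) > 0))
  expect_error(allelic_richness(c(2, 2), 10), "exceeds")
  g <- build_genotype_table(list(
    p1 = list(rbind(c(1, 2), c(3, 4), c(5, 6)))), "L1")
  expect_equal(locus_summaries(g, rarefaction_g = 6)$Rs, 6)
})

test_that("HWE exact enumeration reproduces the hand-computed case", {
  pairs <- rbind(c(1, 1), c(1, 1), c(2, 2), c(2, 2))
  expect_equal(hwe_exact_enumerate(pairs), 6 / 70, tolerance = 1e-10)
})

test_that("the HWE Markov chain agrees with full enumeration", {
  cases <- list(
    rbind(c(1, 1), c(1, 1), c(2, 2), c(2, 2)),            # hom excess
    rbind(c(1, 2), c(1, 2), c(1, 2), c(1, 2)),            # all het
    rbind(c(1, 2), c(1, 1), c(2, 2)),
    rbind(c(1, 1), c(1, 2), c(1, 2), c(2, 2), c(1, 2), c(1, 1)))
  for (i in seq_along(cases)) {
    exact <- hwe_exact_enumerate(cases[[i]])
    mc <- hwe_exact_mc(cases[[i]], seed = 50 + i)
    expect_lt(abs(mc$p - exact), 3 * max(mc$se, 1e-3))
  }
})

test_that("HWE chain p-values behave on random biallelic tables", {
  set.seed(7)
  for (i in 1:5) {
    n <- sample(3:6, 1)
    pairs <- cbind(sample(1:2, n, TRUE), sample(1:2, n, TRUE))
    if (length(unique(as.vector(pairs))) < 2) next
    exact <- hwe_exact_enumerate(pairs)
    mc <- hwe_exact_mc(pairs, seed = 60 + i)
    expect_lt(abs(mc$p - exact), 3 * max(mc$se, 1e-3))
  }
})

test_that("Weir-Cockerham theta vanishes for identical populations", {
  one <- rbind(c(1, 2), c(1, 1), c(2, 2), c(1, 2), c(2, 2))
  g <- build_genotype_table(list(p1 = list(one), p2 = list(one)), "L1")
  fs <- wc_fstats(g, n_perm = 99, seed = 1)
  expect_lte(fs$Fst, 0)
  expect_gt(fs$p_fst, 0.1)
})

test_that("variance components match brute-force ANOVA arithmetic", {
  # 2 pops x 4 individuals, biallelic; independent hand computation of
  # the Weir-Cockerham a, b, c from the definitional formulas
  p1 <- rbind(c(1, 1), c(1, 2), c(1, 1), c(1, 2))
  p2 <- rbind(c(2, 2), c(1, 2), c(2, 2), c(2, 2))
  g <- build_genotype_table(list(a = list(p1), b = list(p2)), "L1")
  fs <- wc_fstats(g)
  r <- 2; n1 <- 4; n2 <- 4; nbar <- 4
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  for (allele in 1:2) {
    pA <- c(sum(p1 == allele) / 8, sum(p2 == allele) / 8)
    hA <- c(mean(p1[, 1] != p1[, 2]), mean(p2[, 1] != p2[, 2]))
    pbar <- sum(c(n1, n2) * pA) / (r * nbar)
    s2 <- sum(c(n1, n2) * (pA - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(c(n1, n2) * hA) / (r * nbar)
    a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              hbar / 4) / (nbar - 1))
    b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    if (allele == 1) {
      tot_a <- a; tot_b <- b; tot_c <- cc
    } else {
      tot_a <- tot_a + a; tot_b <- tot_b + b; tot_c <- tot_c + cc
    }
  }
  expect_equal(fs$per_locus$a, tot_a)
  expect_equal(fs$per_locus$b, tot_b)
  expect_equal(fs$per_locus$c, tot_c)
  expect_equal(fs$Fst, tot_a / (tot_a + tot_b + tot_c))
})

test_that("estimators are invariant under allele relabeling", {
  g <- simulate_island_genotypes(c(a = 25, b = 25, c = 25), c(6, 8), 0.15,
                                 seed = 17)
  g2 <- g
  g2$alleles[] <- g$alleles * 3L + 11L  # monotone relabeling of sizes
  expect_equal(wc_fstats(g2)$Fst, wc_fstats(g)$Fst)
  expect_equal(jost_dest(g2, n_boot = 0)$D, jost_dest(g, n_boot = 0)$D)
})

test_that("Jost's D matches hand arithmetic on a three-population toy", {
  # one locus, two alleles, 4 individuals per pop, all homozygous
  p <- list(a = list(rbind(c(1, 1), c(1, 1), c(1, 1), c(2, 2))),
            b = list(rbind(c(1, 1), c(2, 2), c(2, 2), c(2, 2))),
            c = list(rbind(c(1, 1), c(1, 1), c(2, 2), c(2, 2))))
  g <- build_genotype_table(p, "L1")
  K <- 3; ntilde <- 4; Ho <- 0
  pm <- rbind(c(0.75, 0.25), c(0.25, 0.75), c(0.5, 0.5))
  Hs_obs <- 1 - mean(rowSums(pm^2))
  Hs <- ntilde / (ntilde - 1) * (Hs_obs - Ho / (2 * ntilde))
  pbar <- colMeans(pm)
  Ht <- 1 - sum(pbar^2) + Hs / (ntilde * K) - Ho / (2 * ntilde * K)
  D_hand <- (Ht - Hs) / (1 - Hs) * K / (K - 1)
  expect_equal(jost_dest(g, n_boot = 0)$D, D_hand)
})

test_that("Jost's D hits its extremes", {
  g0 <- simulate_island_genotypes(c(a = 150, b = 150), c(8), 0, seed = 5)
  expect_lt(abs(jost_dest(g0, n_boot = 0)$D), 0.05)
  al <- array(NA_integer_, c(40, 1, 2))
  al[1:20, 1, ] <- 101L; al[21:40, 1, ] <- 103L
  gd <- genotype_table(data.frame(id = sprintf("i%d", 1:40),
                                  pop = rep(c("a", "b"), each = 20)),
                       "L1", al)
  expect_equal(jost_dest(gd, n_boot = 0)$D, 1, tolerance = 1e-6)
})

test_that("Fst and Jost's D rank datasets concordantly", {
  fst_ladder <- seq(0.01, 0.4, length.out = 10)
  est <- vapply(seq_along(fst_ladder), function(i) {
    g <- simulate_island_genotypes(c(a = 40, b = 40, c = 40),
                                   c(10, 12), fst_ladder[i],
                                   seed = 700 + i)
    c(fst = wc_fstats(g)$Fst, d = jost_dest(g, n_boot = 0)$D)
  }, c(fst = 0, d = 0))
  expect_gt(cor(est["fst", ], est["d", ], method = "spearman"), 0)
})

test_that("the null-allele EM recovers truth and flags degeneracy", {
  # HWE data without nulls
  g0 <- simulate_island_genotypes(c(a = 400), c(8), 0, seed = 31)
  em0 <- null_allele_em(g0, locus = "locus01")
  expect_lt(em0$null_freq, 0.04)
  # injected null frequency 0.15, n = 500, 20 replicates
  est <- vapply(1:20, function(i) {
    gn <- simulate_island_genotypes(c(a = 500), c(10), 0,
                                    null_freq = 0.15, seed = 800 + i)
    null_allele_em(gn, locus = "locus01")$null_freq
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.15), 0.05)
  # all-homozygote two-allele data push the estimate to the boundary
  gh <- build_genotype_table(list(
    p1 = list(rbind(c(1, 1), c(1, 1), c(2, 2), c(2, 2)))), "L1")
  emh <- null_allele_em(gh, locus = "L1")
  expect_true(emh$boundary)
  expect_gt(emh$null_freq, 0.2)
})

test_that("BH adjustment follows the closed form", {
  expect_equal(fdr_adjust(0.037), 0.037)
  expect_equal(fdr_adjust(rep(0.02, 5)), rep(0.02, 5))
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  q <- fdr_adjust(c(0.001, 0.8, 0.04, 0.5))
  expect_true(all(q[order(c(0.001, 0.8, 0.04, 0.5))] ==
                    cummax(q[order(c(0.001, 0.8, 0.04, 0.5))])))
})

test_that("pairwise differentiation covers every pair symmetrically", {
  g <- simulate_island_genotypes(c(a = 20, b = 20, c = 20), c(6, 8), 0.2,
                                 seed = 13)
  pd <- pairwise_differentiation(g)
  expect_equal(nrow(pd), 3)
  expect_true(all(is.finite(pd$Fst)))
  expect_true(all(pd$Dest >= -0.05 & pd$Dest <= 1))
})
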
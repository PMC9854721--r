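# Microsatellite summaries, F-statistics, differentiation, HWE and null
# alleles.  Genotypes are handled by allele identity; sizes only matter for
# reporting.

# visible genotype pairs (2-col matrix) for one locus/pop, missing dropped
genotype_pairs <- function(g, locus, pops = NULL) {
  l <- match(locus, g$loci)
  keep <- if (is.null(pops)) rep(TRUE, nrow(g$individuals))
          else g$individuals$pop %in% pops
  a <- g$alleles[keep, l, , drop = FALSE]
  m <- cbind(a[, 1, 1], a[, 1, 2])
  m[!is.na(m[, 1]), , drop = FALSE]
}

#' Rarefied allelic richness
#'
#' Expected number of distinct alleles in a draw of `g` genes without
#' replacement from the observed allele counts.
#'
#' @param counts integer allele counts (one population, one locus).
#' @param g number of genes to rarefy to; must not exceed `sum(counts)`.
#' @return Expected allele count (`<= length(counts[counts > 0])`).
#' @export
allelic_richness <- function(counts, g) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (g > N) stop_wreckpop("rarefaction size exceeds available genes (",
                           N, ")")
  sum(1 - exp(lchoose(N - counts, g) - lchoose(N, g)))
}

#' Per-population, per-locus microsatellite summaries
#'
#' Number of alleles A, allelic richness rarefied to `rarefaction_g` genes,
#' observed heterozygosity Ho, unbiased expected heterozygosity He
#' (`2n/(2n-1) * (1 - sum p^2)`) and the within-population fixation index
#' `Fis = 1 - Ho/He` (undefined at monomorphic loci, reported `NA`).
#' Optionally adds the Hardy-Weinberg exact-test p-value
#' ([hwe_exact_mc()]) and the EM null-allele frequency
#' ([null_allele_em()]).
#'
#' @param g a [genotype_table()].
#' @param rarefaction_g genes to rarefy richness to; default twice the
#'   smallest per-locus sample; an explicit value exceeding some sample is
#'   an error.
#' @param hwe,null_alleles logical switches for the extra columns.
#' @param seed seed for the HWE Markov chain.
#' @return Data frame with one row per locus x population.
#' @export
locus_summaries <- function(g, rarefaction_g = NULL, hwe = FALSE,
                            null_alleles = FALSE, seed = 1) {
  stopifnot(inherits(g, "genotype_table"))
  pops <- unique(g$individuals$pop)
  rows <- list()
  for (loc in g$loci) {
    cts <- allele_counts_by_pop(g, loc)
    gmin <- min(vapply(cts, sum, 0L))
    rg <- if (is.null(rarefaction_g)) gmin else rarefaction_g
    for (p in pops) {
      pairs <- genotype_pairs(g, loc, p)
      n <- nrow(pairs)
      ct <- cts[[p]]
      A <- sum(ct > 0)
      if (n == 0) {
        rows[[length(rows) + 1]] <- data.frame(
          locus = loc, population = p, n = 0L, A = 0L, Rs = NA_real_,
          Ho = NA_real_, He = NA_real_, Fis = NA_real_)
        next
      }
      Rs <- if (rg <= sum(ct)) allelic_richness(ct, rg) else
        stop_wreckpop("rarefaction_g = ", rg, " exceeds sample of ",
                      sum(ct), " genes (", loc, " / ", p, ")")
      pfreq <- ct / sum(ct)
      Ho <- mean(pairs[, 1] != pairs[, 2])
      He <- if (A < 2) 0 else 2 * n / (2 * n - 1) * (1 - sum(pfreq^2))
      if (A < 2) Ho <- 0  # monomorphic convention
      Fis <- if (He > 0) 1 - Ho / He else NA_real_
      row <- data.frame(locus = loc, population = p, n = n, A = A, Rs = Rs,
                        Ho = Ho, He = He, Fis = Fis)
      if (hwe) {
        row$p_hwe <- if (A < 2 || n < 2) NA_real_ else
          hwe_exact_mc(pairs, seed = derive_seed(seed,
            match(loc, g$loci) * 1000L + match(p, pops)))$p
      }
      if (null_alleles) {
        row$null_freq <- if (A < 2) NA_real_ else
          null_allele_em(pairs)$null_freq
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  do.call(rbind, rows)
}

# log conditional probability of a genotype array given allele counts
# (Levene): log[ n! * prod a_i! * 2^H / ((2n)! * prod n_ij!) ]
hwe_log_prob <- function(tab) {
  n <- sum(tab[upper.tri(tab, diag = TRUE)])
  a <- rowSums(tab) + colSums(tab)  # gene counts per allele (diag twice)
  H <- sum(tab[upper.tri(tab)])
  lfactorial(n) + sum(lfactorial(a)) + H * log(2) -
    lfactorial(2 * n) - sum(lfactorial(tab[upper.tri(tab, diag = TRUE)]))
}

# genotype pairs -> upper-triangular count matrix over allele labels
pairs_to_table <- function(pairs) {
  al <- sort(unique(as.vector(pairs)))
  k <- length(al)
  tab <- matrix(0L, k, k, dimnames = list(al, al))
  i <- match(pmin(pairs[, 1], pairs[, 2]), al)
  j <- match(pmax(pairs[, 1], pairs[, 2]), al)
  for (r in seq_along(i)) tab[i[r], j[r]] <- tab[i[r], j[r]] + 1L
  tab
}

#' Hardy-Weinberg exact test by Markov chain
#'
#' Probability-ordering exact test: the p-value is the total conditional
#' probability (given the allele counts, Levene's distribution) of all
#' genotype arrays no more probable than the observed one. The sum is
#' estimated by a Metropolis Markov chain over genotype arrays using the
#' classical two-individual re-pairing proposal, run in batches whose
#' spread yields a Monte-Carlo standard error.
#'
#' @param pairs two-column matrix of allele pairs (one row per individual),
#'   or a [genotype_table()] together with `locus`/`pops`.
#' @param locus,pops locus name and optional population filter when `pairs`
#'   is a genotype table.
#' @param batches,iters_per_batch chain schedule (defaults 20 x 5000).
#' @param burn_in dememorization steps before sampling.
#' @param seed integer seed.
#' @return List with `p`, `se`, `batches` and the observed array's log
#'   probability.
#' @export
hwe_exact_mc <- function(pairs, locus = NULL, pops = NULL, batches = 20,
                         iters_per_batch = 5000, burn_in = 10000, seed = 1) {
  if (inherits(pairs, "genotype_table")) {
    if (is.null(locus)) stop_wreckpop("locus required with a genotype table")
    pairs <- genotype_pairs(pairs, locus, pops)
  }
  pairs <- matrix(as.integer(pairs), ncol = 2)
  if (nrow(pairs) < 2) stop_wreckpop("need at least 2 genotyped individuals")
  al <- sort(unique(as.vector(pairs)))
  if (length(al) < 2)
    return(list(p = NA_real_, se = NA_real_, skipped = "monomorphic"))
  lp_obs <- hwe_log_prob(pairs_to_table(pairs))
  set.seed(seed)
  cur <- cbind(match(pairs[, 1], al), match(pairs[, 2], al))
  k <- length(al)
  tab <- matrix(0L, k, k)
  for (r in seq_len(nrow(cur))) {
    i <- min(cur[r, ]); j <- max(cur[r, ])
    tab[i, j] <- tab[i, j] + 1L
  }
  lcur <- hwe_log_prob(tab)
  n <- nrow(cur)

  # the chain lives on ordered individual-labelled states; each genotype
  # array corresponds to n!/prod(n_ij!) * 2^H of them, which is already
  # proportional to the Levene probability, so the symmetric re-pairing
  # proposal is always accepted and the array's Levene log-probability
  # (the test statistic) is tracked incrementally.
  dec <- function(i, j) {
    ii <- min(i, j); jj <- max(i, j)
    r <- log(tab[ii, jj]) + if (ii != jj) -log(2) else 0
    tab[ii, jj] <<- tab[ii, jj] - 1L
    r
  }
  inc <- function(i, j) {
    ii <- min(i, j); jj <- max(i, j)
    tab[ii, jj] <<- tab[ii, jj] + 1L
    -log(tab[ii, jj]) + if (ii != jj) log(2) else 0
  }
  step <- function() {
    idx <- sample.int(n, 2)
    g1 <- cur[idx[1], ]; g2 <- cur[idx[2], ]
    if (runif(1) < 0.5) {
      new1 <- c(g1[1], g2[1]); new2 <- c(g1[2], g2[2])
    } else {
      new1 <- c(g1[1], g2[2]); new2 <- c(g1[2], g2[1])
    }
    dl <- dec(g1[1], g1[2]) + dec(g2[1], g2[2]) +
      inc(new1[1], new1[2]) + inc(new2[1], new2[2])
    cur[idx[1], ] <<- new1
    cur[idx[2], ] <<- new2
    lcur <<- lcur + dl
  }
  for (s in seq_len(burn_in)) step()
  batch_p <- numeric(batches)
  tol <- 1e-9
  for (b in seq_len(batches)) {
    hits <- 0L
    for (s in seq_len(iters_per_batch)) {
      step()
      if (lcur <= lp_obs + tol) hits <- hits + 1L
    }
    batch_p[b] <- hits / iters_per_batch
  }
  list(p = mean(batch_p), se = sd(batch_p) / sqrt(batches),
       batches = batch_p, log_prob_obs = lp_obs)
}

#' Exact Hardy-Weinberg p-value by full enumeration (two alleles)
#'
#' Enumerates every genotype array compatible with the observed allele
#' counts of a biallelic locus and sums the Levene probabilities of arrays
#' no more probable than the observed one. Serves as the exact reference
#' for the Markov-chain estimator.
#'
#' @param pairs two-column matrix of allele pairs (exactly two alleles).
#' @return Exact p-value.
#' @export
hwe_exact_enumerate <- function(pairs) {
  pairs <- matrix(as.integer(pairs), ncol = 2)
  al <- sort(unique(as.vector(pairs)))
  if (length(al) != 2) stop_wreckpop("enumeration supports 2 alleles")
  n <- nrow(pairs)
  nA <- sum(pairs == al[1])
  het_obs <- sum(pairs[, 1] != pairs[, 2])
  hets <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  logp <- vapply(hets, function(h) {
    naa <- (nA - h) / 2; nbb <- n - naa - h
    tab <- matrix(c(naa, 0, h, nbb), 2, 2)
    hwe_log_prob(tab)
  }, numeric(1))
  p <- exp(logp - logsumexp(logp))  # guards rounding; sums to 1 anyway
  sum(p[logp <= logp[match(het_obs, hets)] + 1e-9])
}

#' Weir-Cockerham F-statistics
#'
#' Per-locus and multilocus fixation indexes F_IS, F_ST and F_IT from the
#' Weir-Cockerham variance components a (among populations), b (among
#' individuals within populations) and c (within individuals), summed over
#' alleles and loci (ratio-of-sums estimators). Significance of
#' `F_ST > 0` by permuting genotypes among populations.
#'
#' @param g a [genotype_table()].
#' @param grouping optional population labels overriding
#'   `g$individuals$pop`.
#' @param n_perm permutations for the F_ST test (0 skips it).
#' @param seed permutation seed.
#' @return Object of class `"wc_fstats"` with `per_locus` (data frame of
#'   a, b, c, Fst, Fis, Fit) and multilocus `Fst`, `Fis`, `Fit`, `p_fst`.
#' @export
wc_fstats <- function(g, grouping = NULL, n_perm = 0, seed = 1) {
  stopifnot(inherits(g, "genotype_table"))
  pop <- if (is.null(grouping)) g$individuals$pop else as.character(grouping)
  if (length(unique(pop)) < 2)
    stop_wreckpop("F_ST undefined for a single population")
  comp <- wc_components(g, pop)
  per_locus <- comp$per_locus
  obs <- comp$multilocus
  p_fst <- NA_real_
  if (n_perm > 0) {
    set.seed(seed)
    hits <- 0L
    for (b in seq_len(n_perm)) {
      th <- wc_components(g, sample(pop))$multilocus["Fst"]
      if (!is.na(th) && th >= obs["Fst"]) hits <- hits + 1L
    }
    p_fst <- (hits + 1) / (n_perm + 1)
  }
  structure(list(per_locus = per_locus, Fst = unname(obs["Fst"]),
                 Fis = unname(obs["Fis"]), Fit = unname(obs["Fit"]),
                 p_fst = p_fst, n_perm = n_perm),
            class = "wc_fstats")
}

# variance components a, b, c per locus (summed over alleles)
wc_components <- function(g, pop) {
  loci <- g$loci
  out <- data.frame(locus = loci, a = NA_real_, b = NA_real_, c = NA_real_)
  for (li in seq_along(loci)) {
    l <- li
    a1 <- g$alleles[, l, 1]; a2 <- g$alleles[, l, 2]
    ok <- !is.na(a1)
    if (!sum(ok)) next
    p_lab <- pop[ok]; x1 <- a1[ok]; x2 <- a2[ok]
    pops <- unique(p_lab)
    r <- length(pops)
    if (r < 2) next
    ni <- as.numeric(table(factor(p_lab, levels = pops)))
    if (any(ni == 0)) { pops <- pops[ni > 0]; ni <- ni[ni > 0]; r <- length(pops) }
    if (r < 2) next
    nbar <- mean(ni)
    nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
    alleles <- sort(unique(c(x1, x2)))
    A <- B <- C <- 0
    for (al in alleles) {
      pi_ <- vapply(pops, function(pp) {
        sel <- p_lab == pp
        (sum(x1[sel] == al) + sum(x2[sel] == al)) / (2 * sum(sel))
      }, numeric(1))
      hi <- vapply(pops, function(pp) {
        sel <- p_lab == pp
        mean((x1[sel] == al) != (x2[sel] == al))
      }, numeric(1))
      pbar <- sum(ni * pi_) / (r * nbar)
      s2 <- if (r > 1) sum(ni * (pi_ - pbar)^2) / ((r - 1) * nbar) else 0
      hbar <- sum(ni * hi) / (r * nbar)
      if (nbar <= 1) next
      a <- nbar / nc *
        (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
      b <- nbar / (nbar - 1) *
        (pbar * (1 - pbar) - (r - 1) / r * s2 -
           (2 * nbar - 1) / (4 * nbar) * hbar)
      cc <- hbar / 2
      A <- A + a; B <- B + b; C <- C + cc
    }
    out$a[li] <- A; out$b[li] <- B; out$c[li] <- C
  }
  out$Fst <- out$a / (out$a + out$b + out$c)
  out$Fit <- 1 - out$c / (out$a + out$b + out$c)
  out$Fis <- 1 - out$c / (out$b + out$c)
  sa <- sum(out$a, na.rm = TRUE); sb <- sum(out$b, na.rm = TRUE)
  sc <- sum(out$c, na.rm = TRUE)
  multi <- c(Fst = sa / (sa + sb + sc), Fit = 1 - sc / (sa + sb + sc),
             Fis = 1 - sc / (sb + sc))
  list(per_locus = out, multilocus = multi)
}

#' @export
print.wc_fstats <- function(x, digits = 4, ...) {
  cat("Weir-Cockerham F-statistics (ratio-of-sums over",
      nrow(x$per_locus), "loci)\n")
  cat(sprintf("  multilocus: Fst = %.*f, Fis = %.*f, Fit = %.*f\n",
              digits, x$Fst, digits, x$Fis, digits, x$Fit))
  if (!is.na(x$p_fst))
    cat(sprintf("  P(Fst > 0): %.4g (%d permutations)\n", x$p_fst, x$n_perm))
  invisible(x)
}

# Nei-Chesser unbiased Hs/Ht and Jost D for one locus
jost_d_locus <- function(g, pop, locus) {
  l <- match(locus, g$loci)
  pairs_by <- lapply(unique(pop), function(pp) {
    m <- cbind(g$alleles[pop == pp, l, 1], g$alleles[pop == pp, l, 2])
    m[!is.na(m[, 1]), , drop = FALSE]
  })
  names(pairs_by) <- unique(pop)
  np <- vapply(pairs_by, nrow, 0L)
  use <- np > 0
  pairs_by <- pairs_by[use]; np <- np[use]
  K <- length(pairs_by)
  if (K < 2) return(NA_real_)
  ntilde <- K / sum(1 / np)
  alleles <- sort(unique(unlist(pairs_by)))
  pmat <- t(vapply(pairs_by, function(m) {
    v <- table(factor(as.vector(m), levels = alleles))
    as.numeric(v) / (2 * nrow(m))
  }, numeric(length(alleles))))
  Ho <- mean(vapply(pairs_by, function(m) mean(m[, 1] != m[, 2]), 0))
  Hs_obs <- 1 - mean(rowSums(pmat^2))
  Hs <- ntilde / (ntilde - 1) * (Hs_obs - Ho / (2 * ntilde))
  pbar <- colMeans(pmat)
  Ht_obs <- 1 - sum(pbar^2)
  Ht <- Ht_obs + Hs / (ntilde * K) - Ho / (2 * ntilde * K)
  if (Hs >= 1) return(NA_real_)
  (Ht - Hs) / (1 - Hs) * K / (K - 1)
}

#' Jost's differentiation index D
#'
#' Per-locus Jost D from Nei-Chesser unbiased gene-diversity estimators,
#' `D = (Ht - Hs)/(1 - Hs) * K/(K-1)`, with the multilocus value as the
#' arithmetic mean over loci. Significance and a percentile confidence
#' interval come from bootstrapping individuals within populations.
#'
#' @param g a [genotype_table()].
#' @param grouping optional population labels.
#' @param n_boot bootstrap replicates (default 1000; 0 skips).
#' @param seed bootstrap seed.
#' @return Object of class `"jost_d"`: `per_locus`, multilocus `D`,
#'   bootstrap `ci` (2.5/97.5 percentiles) and `p` (one-sided share of
#'   bootstrap replicates with `D <= 0`).
#' @export
jost_dest <- function(g, grouping = NULL, n_boot = 1000, seed = 1) {
  stopifnot(inherits(g, "genotype_table"))
  pop <- if (is.null(grouping)) g$individuals$pop else as.character(grouping)
  if (length(unique(pop)) < 2) stop_wreckpop("need at least 2 populations")
  per_locus <- vapply(g$loci, function(l) jost_d_locus(g, pop, l), 0)
  D <- mean(per_locus, na.rm = TRUE)
  ci <- c(NA_real_, NA_real_); pval <- NA_real_
  if (n_boot > 0) {
    set.seed(seed)
    boots <- numeric(n_boot)
    idx_by_pop <- split(seq_along(pop), pop)
    for (b in seq_len(n_boot)) {
      idx <- unlist(lapply(idx_by_pop, function(ii)
        ii[sample.int(length(ii), length(ii), replace = TRUE)]))
      gb <- genotype_table(g$individuals[idx, , drop = FALSE], g$loci,
                           g$alleles[idx, , , drop = FALSE])
      pl <- vapply(gb$loci, function(l) jost_d_locus(gb, pop[idx], l), 0)
      boots[b] <- mean(pl, na.rm = TRUE)
    }
    ci <- unname(quantile(boots, c(0.025, 0.975), na.rm = TRUE))
    pval <- mean(boots <= 0, na.rm = TRUE)
  }
  structure(list(per_locus = per_locus, D = D, ci = ci, p = pval,
                 n_boot = n_boot),
            class = "jost_d")
}

#' @export
print.jost_d <- function(x, digits = 4, ...) {
  cat(sprintf("Jost's D (multilocus arithmetic mean): %.*f\n", digits, x$D))
  print(round(x$per_locus, digits))
  if (x$n_boot > 0)
    cat(sprintf("  bootstrap 95%% CI [%.*f, %.*f], P(D <= 0) = %.3f (%d reps)\n",
                digits, x$ci[1], digits, x$ci[2], x$p, x$n_boot))
  invisible(x)
}

#' EM estimate of the null-allele frequency at a locus
#'
#' Expectation-maximization (Dempster-style) estimate of the frequency of a
#' non-amplifying (null) allele from apparent homozygote excess. A
#' null-carrying heterozygote is assumed to be scored as a homozygote for
#' its visible allele; null homozygotes produce no visible genotype and are
#' imputed from the current null frequency. Iterates until the change in
#' the null frequency drops below `tol`.
#'
#' @param pairs two-column matrix of visible allele pairs, or a
#'   [genotype_table()] with `locus`/`pops`.
#' @param locus,pops selection when `pairs` is a genotype table.
#' @param tol convergence tolerance (default 1e-8).
#' @param max_iter iteration cap; exceeding it is an error with a trace.
#' @return List with `null_freq`, visible `allele_freqs`, `iterations`,
#'   and `boundary` (TRUE when the estimate ran to its upper bound, e.g.
#'   for all-homozygote data).
#' @export
null_allele_em <- function(pairs, locus = NULL, pops = NULL, tol = 1e-8,
                           max_iter = 10000) {
  if (inherits(pairs, "genotype_table")) {
    if (is.null(locus)) stop_wreckpop("locus required with a genotype table")
    pairs <- genotype_pairs(pairs, locus, pops)
  }
  pairs <- matrix(as.integer(pairs), ncol = 2)
  n <- nrow(pairs)
  al <- sort(unique(as.vector(pairs)))
  if (length(al) < 2) stop_wreckpop("need at least 2 visible alleles")
  het <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  hom_counts <- table(factor(pairs[pairs[, 1] == pairs[, 2], 1], levels = al))
  het_copies <- table(factor(as.vector(het), levels = al))
  p <- as.numeric(table(factor(as.vector(pairs), levels = al))) / (2 * n)
  r <- 0.05
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    # E-step: split apparent homozygotes into true homs and null hets
    denom <- p^2 + 2 * p * r
    w_hom <- ifelse(denom > 0, p^2 / denom, 1)
    exp_true_hom <- as.numeric(hom_counts) * w_hom
    exp_null_het <- as.numeric(hom_counts) * (1 - w_hom)
    n_blank <- if (r < 1) n * r^2 / (1 - r^2) else 0  # imputed null homs
    N <- n + n_blank
    copies_vis <- as.numeric(het_copies) + 2 * exp_true_hom + exp_null_het
    copies_null <- sum(exp_null_het) + 2 * n_blank
    p_new <- copies_vis / (2 * N)
    r_new <- copies_null / (2 * N)
    delta <- abs(r_new - r)
    trace <- c(trace, r_new)
    p <- p_new; r <- r_new
    if (delta < tol) break
    if (r > 0.999) break  # boundary: heterozygote-free data drive r -> 1
    if (it == max_iter)
      stop_wreckpop("null-allele EM failed to converge in ", max_iter,
                    " iterations; trace tail: ",
                    paste(round(tail(trace, 5), 6), collapse = ", "))
  }
  boundary <- nrow(het) == 0 || r > 0.999
  list(null_freq = r, allele_freqs = setNames(p, al), iterations = it,
       boundary = boundary)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted q-values (monotone, capped at 1), as used to correct
#' families of per-locus and pairwise tests.
#'
#' @param p_values numeric vector in `[0, 1]` (`NA` passed through).
#' @return Adjusted q-values, same length and order.
#' @export
fdr_adjust <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    stop_wreckpop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Pairwise population differentiation (F_ST and Jost's D)
#'
#' Computes multilocus Weir-Cockerham F_ST and Jost's D for every
#' population pair, with permutation/bootstrap significance and BH-FDR
#' q-values across the pair family.
#'
#' @param g a [genotype_table()].
#' @param n_perm permutations per pair for F_ST (0 skips tests).
#' @param n_boot bootstrap replicates per pair for D (0 skips).
#' @param seed integer seed.
#' @return Data frame with one row per unordered pair: `Fst`, `Dest`,
#'   `p_fst`, `p_dest`, `q_fst`, `q_dest`.
#' @export
pairwise_differentiation <- function(g, n_perm = 0, n_boot = 0, seed = 1) {
  pops <- unique(g$individuals$pop)
  if (length(pops) < 2) stop_wreckpop("need at least 2 populations")
  prs <- combn(pops, 2)
  out <- data.frame(pop1 = prs[1, ], pop2 = prs[2, ], Fst = NA_real_,
                    Dest = NA_real_, p_fst = NA_real_, p_dest = NA_real_)
  for (i in seq_len(ncol(prs))) {
    gi <- filter_populations(g, prs[, i])
    fs <- wc_fstats(gi, n_perm = n_perm, seed = derive_seed(seed, i))
    jd <- jost_dest(gi, n_boot = n_boot, seed = derive_seed(seed, i + 5000L))
    out$Fst[i] <- fs$Fst; out$Dest[i] <- jd$D
    out$p_fst[i] <- fs$p_fst; out$p_dest[i] <- jd$p
  }
  out$q_fst <- fdr_adjust(out$p_fst)
  out$q_dest <- fdr_adjust(out$p_dest)
  out
}
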
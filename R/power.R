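# POWSIM-style simulation of the power to detect population structure.

# solve generations t (and possibly adjust Ne) so that
# 1 - (1 - 1/(2Ne))^t matches the target Fst within tol
solve_drift_schedule <- function(target_fst, Ne = NULL, tol = 1e-4) {
  if (target_fst == 0)
    return(list(Ne = if (is.null(Ne)) 1000 else Ne, t = 0, realized = 0,
                err = 0))
  best_for <- function(ne) {
    t <- round(log(1 - target_fst) / log(1 - 1 / (2 * ne)))
    t <- max(t, 1)
    realized <- 1 - (1 - 1 / (2 * ne))^t
    list(Ne = ne, t = t, realized = realized,
         err = abs(realized - target_fst))
  }
  if (!is.null(Ne)) {
    s <- best_for(Ne)
    if (s$err > tol)
      stop_wreckpop(sprintf(
        "target Fst %.4f unreachable with Ne = %d within %.1e (best t = %d gives %.5f); try Ne near %d",
        target_fst, Ne, tol, s$t, s$realized, s$Ne * 2))
    return(s)
  }
  # prefer the conventional Ne = 1000, then search outward
  for (ne in c(1000, seq(1010, 5000, by = 10), seq(990, 100, by = -10))) {
    s <- best_for(ne)
    if (s$err <= tol) return(s)
  }
  stop_wreckpop("no (Ne, t) schedule reaches target Fst ", target_fst,
                " within tolerance ", tol)
}

# drift one frequency vector: t generations of multinomial sampling of
# 2Ne genes
drift_freqs <- function(base, Ne, t) {
  f <- base
  if (t > 0) for (gen in seq_len(t)) {
    f <- as.numeric(rmultinom(1, 2 * Ne, f)) / (2 * Ne)
  }
  f
}

chi2_stat <- function(cnt) {
  e <- outer(rowSums(cnt), colSums(cnt)) / sum(cnt)
  sum((cnt - e)^2 / e, na.rm = TRUE)
}

#' Simulated power to detect population structure
#'
#' POWSIM-style assessment: in each replicate, `K` populations drift
#' independently from common base frequencies for `t` generations at
#' effective size `Ne` (with `Fst = 1 - (1 - 1/(2Ne))^t` matched to
#' `target_fst`; `t` is solved, and `Ne` adjusted if needed, to hit the
#' target within `1e-4`). Diploid genotypes are then sampled under
#' Hardy-Weinberg proportions at the given sample sizes, allele-frequency
#' homogeneity is tested per locus by a populations x alleles contingency
#' chi-square summed over loci, and power is the fraction of replicates
#' with combined `p < alpha`. Because microsatellite tables are sparse
#' (samples of a few individuals against 14-25 alleles), the summed
#' chi-square is referred to a Monte-Carlo reference distribution
#' (`mc_B` tables drawn with fixed margins per locus) rather than to its
#' asymptotic law, which keeps the test calibrated at `target_fst = 0`;
#' `mc_B = 0` falls back to the asymptotic p-value. Optionally Fisher
#' exact tests (Monte-Carlo p-values) per locus combined by Fisher's
#' method are added.
#'
#' @param base_freqs list of base allele-frequency vectors, one per locus.
#' @param sizes diploid sample sizes per population (length K).
#' @param target_fst target differentiation, in `[0, 0.5)`.
#' @param alpha nominal significance level (default 0.05).
#' @param reps simulation replicates (default 200).
#' @param Ne effective size per population (default: solved, preferring
#'   1000).
#' @param mc_B Monte-Carlo tables per locus for the chi-square reference
#'   distribution (default 199; 0 uses the asymptotic p-value).
#' @param fisher also run the Fisher-exact route (slower).
#' @param fisher_B Monte-Carlo replicates inside each Fisher test.
#' @param seed integer seed.
#' @return Object of class `"power_result"` with `power_chi2`, optionally
#'   `power_fisher`, the drift schedule and the realized mean chi-square
#'   p-value.
#' @export
structure_power <- function(base_freqs, sizes, target_fst, alpha = 0.05,
                            reps = 200, Ne = NULL, mc_B = 199,
                            fisher = FALSE, fisher_B = 1000, seed = 1) {
  if (target_fst < 0 || target_fst >= 0.5)
    stop_wreckpop("target_fst must lie in [0, 0.5)")
  if (any(sizes < 1)) stop_wreckpop("sizes must be >= 1")
  sched <- solve_drift_schedule(target_fst, Ne)
  K <- length(sizes)
  set.seed(seed)
  sig_chi2 <- logical(reps)
  sig_fisher <- if (fisher) logical(reps) else NULL
  pvals <- numeric(reps)
  for (r in seq_len(reps)) {
    chi2 <- 0; df <- 0
    sims <- numeric(mc_B)
    lfp <- 0  # Fisher's method accumulator: -2 sum log p
    for (l in seq_along(base_freqs)) {
      base <- base_freqs[[l]]
      counts <- matrix(0L, K, length(base))
      for (i in seq_len(K)) {
        f <- drift_freqs(base, sched$Ne, sched$t)
        counts[i, ] <- as.integer(rmultinom(1, 2 * sizes[i], f))
      }
      keep <- colSums(counts) > 0
      cnt <- counts[, keep, drop = FALSE]
      if (ncol(cnt) < 2) next  # monomorphic draw carries no signal
      chi2 <- chi2 + chi2_stat(cnt)
      df <- df + (nrow(cnt) - 1) * (ncol(cnt) - 1)
      if (mc_B > 0) {
        tabs <- stats::r2dtable(mc_B, rowSums(cnt), colSums(cnt))
        sims <- sims + vapply(tabs, chi2_stat, numeric(1))
      }
      if (fisher) {
        pf <- stats::fisher.test(cnt, simulate.p.value = TRUE,
                                 B = fisher_B)$p.value
        lfp <- lfp + -2 * log(max(pf, 1 / (fisher_B + 1)))
      }
    }
    p <- if (df == 0) 1
         else if (mc_B > 0) (1 + sum(sims >= chi2)) / (mc_B + 1)
         else pchisq(chi2, df, lower.tail = FALSE)
    pvals[r] <- p
    sig_chi2[r] <- p < alpha
    if (fisher) {
      pF <- pchisq(lfp, 2 * length(base_freqs), lower.tail = FALSE)
      sig_fisher[r] <- pF < alpha
    }
  }
  structure(list(power_chi2 = mean(sig_chi2),
                 power_fisher = if (fisher) mean(sig_fisher) else NA_real_,
                 target_fst = target_fst, realized_fst = sched$realized,
                 Ne = sched$Ne, t = sched$t, n_populations = K,
                 sizes = sizes, n_loci = length(base_freqs), reps = reps,
                 alpha = alpha, seed = seed, p_values = pvals),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf(
    "Structure-detection power: %.3f (chi-square route, %d replicates)\n",
    x$power_chi2, x$reps))
  if (!is.na(x$power_fisher))
    cat(sprintf("  Fisher-exact route: %.3f\n", x$power_fisher))
  cat(sprintf(
    "  design: K = %d populations (n = %s), %d loci, target Fst = %g\n",
    x$n_populations, paste(x$sizes, collapse = ","), x$n_loci,
    x$target_fst))
  cat(sprintf("  drift schedule: Ne = %d, t = %d (realized Fst = %.5f), alpha = %g\n",
              x$Ne, x$t, if (is.null(x$realized_fst)) x$target_fst
                         else x$realized_fst, x$alpha))
  invisible(x)
}

#' Base allele frequencies for a power analysis
#'
#' Draws uniform-Dirichlet base frequency vectors for loci whose allele
#' counts are sampled uniformly in `[min_alleles, max_alleles]`, the
#' polymorphism range of the wreckfish microsatellite panel.
#'
#' @param n_loci number of loci.
#' @param min_alleles,max_alleles allele-count range (defaults 14 and 25).
#' @param seed integer seed.
#' @return List of frequency vectors.
#' @export
draw_base_frequencies <- function(n_loci = 4, min_alleles = 14,
                                  max_alleles = 25, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n_loci), function(l) {
    k <- sample(seq(min_alleles, max_alleles), 1)
    x <- rgamma(k, 1)
    x / sum(x)
  })
}
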
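# Hierarchical analysis of molecular variance on microsatellite genotypes.
# Gene copies are the units; the distance between two copies is 0 for the
# same allele and 1 otherwise (F_ST-like AMOVA), or the squared size
# difference (R_ST-like) behind a switch.  Components are summed over loci.

# per-locus sums of squares at the three levels; within-set SS is
# (1/n) sum_{i<j} d_ij, which for the identity metric collapses to
# (n - sum(counts^2)/n)/2 and for the size metric to sum((x - mean)^2)
amova_locus_ss <- function(copies, pop, grp, metric) {
  ssw <- if (metric == "identity") {
    function(x) {
      n <- length(x)
      if (n == 0) return(0)
      tb <- table(x)
      (n - sum(tb^2) / n) / 2
    }
  } else {
    function(x) if (!length(x)) 0 else sum((x - mean(x))^2)
  }
  ss_total <- ssw(copies)
  ss_wp <- sum(tapply(copies, pop, ssw))
  ss_wg <- sum(tapply(copies, grp, ssw))
  list(total = ss_total, within_pop = ss_wp,
       among_pop_within_grp = ss_wg - ss_wp,
       among_grp = ss_total - ss_wg)
}

amova_fit <- function(g, pop, grp, metric) {
  loci <- g$loci
  ss <- c(among_grp = 0, among_pop_within_grp = 0, within_pop = 0)
  dfs <- c(0, 0, 0)
  sigma <- c(a = 0, b = 0, c = 0)
  nloci_used <- 0
  for (l in seq_along(loci)) {
    a1 <- g$alleles[, l, 1]; a2 <- g$alleles[, l, 2]
    ok <- !is.na(a1)
    if (sum(ok) < 2) next
    copies <- c(a1[ok], a2[ok])
    popc <- factor(rep(pop[ok], 2))
    grpc <- factor(rep(grp[ok], 2))
    s <- amova_locus_ss(copies, popc, grpc, metric)
    ssl <- c(s$among_grp, s$among_pop_within_grp, s$within_pop)
    # size coefficients for unequal samples (nested ANOVA on gene copies):
    # S1 = sum_p n_p^2 / N_g(p);  S2 = sum_p n_p^2 / N;  S3 = sum_g N_g^2 / N
    np <- table(droplevels(popc))
    ng <- table(droplevels(grpc))
    N <- length(copies)
    P <- length(np); G <- length(ng)
    if (P < 2) next
    pop2grp <- tapply(as.character(grpc), droplevels(popc),
                      function(z) z[1])
    S1 <- sum(as.numeric(np)^2 / as.numeric(ng[pop2grp[names(np)]]))
    S2 <- sum(as.numeric(np)^2) / N
    S3 <- sum(as.numeric(ng)^2) / N
    n1 <- if (P > G) (N - S1) / (P - G) else NA
    n2 <- if (G > 1) (S1 - S2) / (G - 1) else NA
    n3 <- if (G > 1) (N - S3) / (G - 1) else NA
    dfl <- c(G - 1, P - G, N - P)
    sig_c <- ssl[3] / dfl[3]
    sig_b <- if (dfl[2] > 0) (ssl[2] / dfl[2] - sig_c) / n1 else 0
    sig_a <- if (dfl[1] > 0) (ssl[1] / dfl[1] - sig_c - n2 * sig_b) / n3
             else 0
    sigma <- sigma + c(sig_a, sig_b, sig_c)
    ss <- ss + ssl
    dfs <- dfs + dfl
    nloci_used <- nloci_used + 1
  }
  if (nloci_used == 0) stop_wreckpop("no usable loci")
  tot <- sum(sigma)
  list(ss = ss, df = dfs, sigma = sigma, n_loci = nloci_used,
       Fct = unname(sigma["a"] / tot),
       Fsc = unname(sigma["b"] / (sigma["b"] + sigma["c"])),
       Fst = unname((sigma["a"] + sigma["b"]) / tot))
}

#' Hierarchical AMOVA with permutation tests
#'
#' Splits the total molecular variance of diploid multilocus genotypes into
#' among-group, among-population-within-group and within-population
#' components, with fixation indexes `F_CT = sigma_a / sigma_total`,
#' `F_SC = sigma_b / (sigma_b + sigma_c)` and
#' `F_ST = (sigma_a + sigma_b) / sigma_total` (so that
#' `F_ST = F_CT + (1 - F_CT) F_SC`). Sums of squares use gene copies as
#' units with the number-of-different-alleles distance (`metric =
#' "identity"`); `metric = "size"` switches to squared allele-size
#' differences. Components are summed over loci. Permutation schemes:
#' genotypes among populations within groups (F_SC), whole populations
#' among groups (F_CT), genotypes among all populations (F_ST).
#'
#' @param g a [genotype_table()].
#' @param groups named character vector or data frame mapping population
#'   code to group; `NULL` collapses to a one-level AMOVA (F_ST only).
#' @param n_perm permutations (default 1023); 0 skips the tests.
#' @param metric `"identity"` or `"size"`.
#' @param seed permutation seed.
#' @return Object of class `"amova_result"`.
#' @export
hierarchical_amova <- function(g, groups = NULL, n_perm = 1023,
                               metric = c("identity", "size"), seed = 1) {
  stopifnot(inherits(g, "genotype_table"))
  metric <- match.arg(metric)
  pop <- g$individuals$pop
  pops <- unique(pop)
  if (is.null(groups)) {
    grp_of <- setNames(rep("all", length(pops)), pops)
  } else {
    if (is.data.frame(groups))
      grp_of <- setNames(as.character(groups[[2]]), as.character(groups[[1]]))
    else grp_of <- groups
    if (!all(pops %in% names(grp_of)))
      stop_wreckpop("populations missing from group map: ",
                    paste(setdiff(pops, names(grp_of)), collapse = ", "))
  }
  grp <- unname(grp_of[pop])
  two_level <- length(unique(grp)) < 2
  single_pop_groups <- names(which(table(grp_of[pops]) == 1))
  fit <- amova_fit(g, pop, grp, metric)
  res <- list(fit = fit, n_perm = n_perm, metric = metric,
              two_level = two_level,
              flagged_groups = single_pop_groups)
  p <- c(Fct = NA_real_, Fsc = NA_real_, Fst = NA_real_)
  if (n_perm > 0) {
    set.seed(seed)
    hits <- c(Fct = 0L, Fsc = 0L, Fst = 0L)
    runs <- c(Fct = 0L, Fsc = 0L, Fst = 0L)
    for (b in seq_len(n_perm)) {
      # F_ST: genotypes among all populations
      f1 <- amova_fit(g, sample(pop), grp, metric)
      # guard degenerate permuted components
      if (is.finite(f1$Fst)) {
        runs["Fst"] <- runs["Fst"] + 1L
        if (f1$Fst >= fit$Fst) hits["Fst"] <- hits["Fst"] + 1L
      }
      if (!two_level) {
        # F_SC: genotypes among populations within their group
        permpop <- pop
        for (gg in unique(grp)) {
          sel <- grp == gg
          permpop[sel] <- sample(pop[sel])
        }
        f2 <- amova_fit(g, permpop, grp, metric)
        if (is.finite(f2$Fsc)) {
          runs["Fsc"] <- runs["Fsc"] + 1L
          if (f2$Fsc >= fit$Fsc) hits["Fsc"] <- hits["Fsc"] + 1L
        }
        # F_CT: whole populations among groups
        permmap <- setNames(sample(unname(grp_of[pops])), pops)
        f3 <- amova_fit(g, pop, unname(permmap[pop]), metric)
        if (is.finite(f3$Fct)) {
          runs["Fct"] <- runs["Fct"] + 1L
          if (f3$Fct >= fit$Fct) hits["Fct"] <- hits["Fct"] + 1L
        }
      }
    }
    p <- (hits + 1) / (runs + 1)
    if (two_level) p[c("Fct", "Fsc")] <- NA_real_
  }
  res$p <- p
  class(res) <- "amova_result"
  res
}

#' @export
print.amova_result <- function(x, digits = 4, ...) {
  f <- x$fit
  tot <- sum(f$sigma)
  pct <- 100 * f$sigma / tot
  cat("Hierarchical AMOVA (", x$metric, " distance, ",
      if (x$two_level) "one level" else "two levels", ")\n", sep = "")
  lev <- c("Among groups", "Among populations within groups",
           "Within populations")
  for (i in 1:3) {
    if (x$two_level && i == 1) next
    cat(sprintf("  %-33s SS = %9.3f  sigma = %8.5f  (%5.2f%%)\n",
                lev[i], f$ss[i], f$sigma[i], pct[i]))
  }
  cat(sprintf("  F_ST = %.*f", digits, f$Fst))
  if (!x$two_level)
    cat(sprintf(", F_CT = %.*f, F_SC = %.*f", digits, f$Fct, digits, f$Fsc))
  cat("\n")
  if (!all(is.na(x$p))) {
    cat("  permutation p-values (", x$n_perm, " permutations): ", sep = "")
    cat(paste(sprintf("%s = %.4g", names(x$p)[!is.na(x$p)],
                      x$p[!is.na(x$p)]), collapse = ", "), "\n")
  }
  if (length(x$flagged_groups))
    cat("  note: single-population group(s), F_CT low-powered:",
        paste(x$flagged_groups, collapse = ", "), "\n")
  invisible(x)
}
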
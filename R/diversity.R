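#' Haplotype (gene) diversity
#'
#' Unbiased haplotype diversity `Hd = n/(n-1) * (1 - sum(p_i^2))`, the
#' probability that two sequences drawn without replacement carry different
#' haplotypes.
#'
#' @param counts non-negative haplotype counts (zeros allowed).
#' @return `Hd` in `[0, 1]`.
#' @examples
#' haplotype_diversity(c(26, 4, 6, 4, 6, 4, 1, 1))  # 0.719
#' @export
haplotype_diversity <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) stop_wreckpop("haplotype diversity undefined for n < 2")
  p <- counts / n
  n / (n - 1) * (1 - sum(p^2))
}

#' Mean number of pairwise nucleotide differences (k)
#'
#' Average Hamming distance over all C(n,2) sequence pairs, computed from
#' haplotype frequencies rather than by materializing the pairs. Positions
#' where either haplotype carries an ambiguity code are skipped for that
#' pair (pairwise deletion).
#'
#' @param s a `sequence_set`.
#' @param lineage optional lineage filter (character vector of tags).
#' @return `k`, in units of nucleotide differences.
#' @export
mean_pairwise_differences <- function(s, lineage = NULL) {
  stopifnot(inherits(s, "sequence_set"))
  if (!is.null(lineage)) s <- filter_lineage(s, lineage)
  cnt <- table(s$records$haplotype)
  n <- sum(cnt)
  if (n < 2) stop_wreckpop("k undefined for fewer than 2 sequences")
  hap <- names(cnt)
  d <- hamming_matrix(s$states[hap, , drop = FALSE])$d
  f <- as.numeric(cnt)
  tot <- as.numeric(t(f) %*% d %*% f) / 2  # within-haplotype d = 0
  tot / choose(n, 2)
}

#' Number of segregating sites
#'
#' Counts positions with two or more distinct non-ambiguous states among
#' the included sequences.
#'
#' @inheritParams mean_pairwise_differences
#' @return Integer `S`.
#' @export
segregating_sites <- function(s, lineage = NULL) {
  stopifnot(inherits(s, "sequence_set"))
  if (!is.null(lineage)) s <- filter_lineage(s, lineage)
  if (nrow(s$records) < 2) stop_wreckpop("S undefined for fewer than 2 sequences")
  st <- s$states[unique(s$records$haplotype), , drop = FALSE]
  sum(apply(st, 2, function(col) {
    length(unique(col[!(col %in% AMBIGUOUS_CODES)])) >= 2
  }))
}

#' Log unsigned Stirling numbers of the first kind
#'
#' Returns `log |s(n, k)|` for `k = 1..n`, evaluated with the triangular
#' recurrence `|s(n+1,k)| = n |s(n,k)| + |s(n,k-1)|` carried in log space,
#' so that sample sizes in the hundreds remain numerically exact to double
#' precision.
#'
#' @param n positive integer.
#' @return Numeric vector of length `n`.
#' @export
log_stirling1 <- function(n) {
  n <- as.integer(n)
  stopifnot(n >= 1)
  ls <- 0  # |s(1,1)| = 1
  if (n == 1) return(ls)
  for (m in 2:n) {
    prev <- c(-Inf, ls, -Inf)  # pad k = 0 and k = m
    ls <- vapply(seq_len(m), function(k) {
      a <- log(m - 1) + prev[k + 1]  # (m-1) |s(m-1,k)|
      b <- prev[k]                   # |s(m-1,k-1)|
      mx <- max(a, b)
      if (!is.finite(mx)) -Inf else mx + log(exp(a - mx) + exp(b - mx))
    }, numeric(1))
  }
  ls
}

# Ewens sampling distribution of the number of haplotypes K:
# log P(K = j) for j = 1..n at scaled mutation rate theta
ewens_log_pmf <- function(n, theta) {
  ls <- log_stirling1(n)
  lrf <- sum(log(theta + 0:(n - 1)))
  ls + seq_len(n) * log(theta) - lrf
}

#' Fu's Fs neutrality statistic
#'
#' `Fs = ln(S'/(1-S'))` with `S' = P(K >= h_obs)` under the Ewens sampling
#' distribution at `theta` estimated from the mean pairwise difference
#' (pi-based theta). Large positive values indicate fewer haplotypes than
#' expected (e.g. across divergent lineages); large negative values an
#' excess (e.g. population expansion).
#'
#' @param n number of sequences (>= 2).
#' @param h_obs observed number of haplotypes, in `[1, n]`.
#' @param theta positive scaled mutation rate; conventionally the mean
#'   pairwise difference `k` of the same sequence set.
#' @return List with `Fs` (possibly `Inf`/`-Inf`, flagged via `boundary`)
#'   and `S_prime`.
#' @examples
#' fu_fs(52, 8, 7.402)$Fs   # ~6.67
#' fu_fs(2, 2, 1)$Fs        # 0: S' = theta/(theta+1) = 0.5
#' @export
fu_fs <- function(n, h_obs, theta) {
  n <- as.integer(n); h_obs <- as.integer(h_obs)
  if (n < 2) stop_wreckpop("Fs undefined for n < 2")
  if (h_obs < 1 || h_obs > n) stop_wreckpop("h_obs must lie in [1, n]")
  if (!is.finite(theta) || theta <= 0) stop_wreckpop("theta must be > 0")
  lp <- ewens_log_pmf(n, theta)
  lS <- logsumexp(lp[h_obs:n])
  l1mS <- if (h_obs == 1) -Inf else logsumexp(lp[seq_len(h_obs - 1)])
  Fs <- lS - l1mS
  boundary <- !is.finite(Fs)
  list(Fs = Fs, S_prime = exp(lS), boundary = boundary)
}

#' Monte-Carlo p-value for Fu's Fs
#'
#' Simulates the number of haplotypes K under the Ewens sampling
#' distribution at fixed `theta` (K is a sum of independent Bernoulli
#' variables with success probabilities `theta/(theta+i-1)`), and reports
#' the fraction of replicates with a haplotype number as low or lower than
#' observed, i.e. an Fs at least as large as the observed one.
#'
#' @inheritParams fu_fs
#' @param n_sim number of simulated samples.
#' @param seed integer seed.
#' @return List with `p`, `n_sim` and the observed `Fs`.
#' @export
fu_fs_pvalue <- function(n, h_obs, theta, n_sim = 10000, seed = 1) {
  if (!is.finite(theta) || theta <= 0) stop_wreckpop("theta must be > 0")
  obs <- fu_fs(n, h_obs, theta)
  set.seed(seed)
  p_i <- theta / (theta + 0:(n - 1))
  K <- colSums(matrix(runif(n * n_sim) < p_i, nrow = n))
  list(p = mean(K <= h_obs), n_sim = n_sim, Fs = obs$Fs)
}

#' Within-set sequence diversity summary
#'
#' Computes the standard intra-set diversity statistics (n, h, S, Hd, k,
#' and Fu's Fs with its Monte-Carlo p-value) for a sequence set or a
#' lineage subset of it. Per-site nucleotide diversity `Pi = k/L` is
#' reported only when the analyzed length L is known; it is never guessed.
#'
#' @param s a `sequence_set`.
#' @param lineage optional lineage filter.
#' @param fs_p logical: also simulate the Fs p-value.
#' @param n_sim,seed Monte-Carlo settings for the p-value.
#' @return Object of class `"diversity_stats"`.
#' @examples
#' tab <- read_variable_site_table(
#'   system.file("extdata", "table2_coi.tsv", package = "wreckpop"))
#' coi_diversity(expand_haplotypes(tab))
#' @export
coi_diversity <- function(s, lineage = NULL, fs_p = TRUE,
                          n_sim = 10000, seed = 1) {
  stopifnot(inherits(s, "sequence_set"))
  if (!is.null(lineage)) s <- filter_lineage(s, lineage)
  cnt <- table(s$records$haplotype)
  n <- sum(cnt); h <- length(cnt)
  if (n < 2) stop_wreckpop("diversity statistics undefined for n < 2")
  k <- mean_pairwise_differences(s)
  S <- segregating_sites(s)
  Hd <- haplotype_diversity(as.numeric(cnt))
  fs <- if (k > 0) fu_fs(n, h, k) else list(Fs = NA_real_, boundary = TRUE)
  p <- if (fs_p && k > 0) fu_fs_pvalue(n, h, k, n_sim, seed)$p else NA_real_
  structure(list(n = n, h = h, S = S, Hd = Hd, k = k,
                 Pi = if (!is.null(s$total_length)) k / s$total_length
                      else NA_real_,
                 L = s$total_length, Fs = fs$Fs, Fs_boundary = fs$boundary,
                 Fs_p = p, lineage = lineage),
            class = "diversity_stats")
}

#' @export
print.diversity_stats <- function(x, digits = 3, ...) {
  cat("Sequence diversity",
      if (!is.null(x$lineage)) paste0("(", paste(x$lineage, collapse = "+"),
                                      ")"), "\n")
  cat(sprintf("  n = %d sequences, h = %d haplotypes, S = %d segregating sites\n",
              x$n, x$h, x$S))
  cat(sprintf("  Hd = %.*f, k = %.*f differences", digits, x$Hd, digits, x$k))
  if (!is.na(x$Pi)) cat(sprintf(", Pi = %.4f (L = %d)", x$Pi, x$L))
  cat("\n")
  if (!is.na(x$Fs)) {
    cat(sprintf("  Fu's Fs = %.*f", digits, x$Fs))
    if (!is.na(x$Fs_p)) cat(sprintf(" (MC p = %.3f)", x$Fs_p))
    cat("\n")
  }
  invisible(x)
}

#' G+C content of full-length sequences
#'
#' Proportion of G and C among unambiguous bases in a FASTA alignment.
#' Requires full-length sequences; the variable-site table alone cannot
#' provide it.
#'
#' @param path FASTA file.
#' @return Fraction in `[0, 1]`.
#' @export
gc_content <- function(path) {
  aln <- ape::read.dna(path, format = "fasta", as.character = TRUE,
                       as.matrix = FALSE)
  b <- toupper(unlist(aln))
  b <- b[b %in% c("A", "C", "G", "T")]
  if (!length(b)) stop_wreckpop("no unambiguous bases found")
  mean(b %in% c("G", "C"))
}
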
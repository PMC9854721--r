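#' Between-lineage divergence (Dxy, Da) and within-lineage diversity
#'
#' `Dxy(i,j)` is the mean Hamming distance over all cross-lineage sequence
#' pairs divided by the analyzed length L (uncorrected p-distances, no
#' substitution-model correction). `Pi(i)` is the within-lineage mean
#' pairwise distance per site (0 for a single-sequence lineage, flagged).
#' `Da(i,j) = Dxy(i,j) - (Pi(i)+Pi(j))/2` is Nei's net divergence.
#'
#' @param s a `sequence_set`; its `lineage` column defines the partition.
#' @param L analyzed site count; defaults to the set's `total_length`.
#' @return Object of class `"lineage_divergence"` with `lineages`, `Pi`,
#'   `Dxy`, `Da`, plus `cross_mean_diff` (mean differences before division
#'   by L) and `single_sequence` flags.
#' @export
pairwise_dxy <- function(s, L = s$total_length) {
  stopifnot(inherits(s, "sequence_set"))
  if (is.null(L) || L <= 0)
    stop_wreckpop("analyzed length L is required for per-site divergence")
  lin <- unique(s$records$lineage)
  if (length(lin) < 1) stop_wreckpop("no lineages present")
  cnt_by <- lapply(lin, function(g) table(s$records$haplotype[
    s$records$lineage == g]))
  names(cnt_by) <- lin
  empty <- lin[vapply(cnt_by, sum, 0) == 0]
  if (length(empty)) stop_wreckpop("empty lineage: ", empty[1])
  d <- hamming_matrix(s$states)$d
  Pi <- setNames(numeric(length(lin)), lin)
  single <- setNames(logical(length(lin)), lin)
  for (g in lin) {
    f <- as.numeric(cnt_by[[g]]); hap <- names(cnt_by[[g]])
    n <- sum(f)
    single[g] <- n == 1
    Pi[g] <- if (n < 2) 0 else
      as.numeric(t(f) %*% d[hap, hap, drop = FALSE] %*% f) / 2 /
        choose(n, 2) / L
  }
  K <- length(lin)
  Dxy <- matrix(0, K, K, dimnames = list(lin, lin))
  cross <- Dxy
  if (K > 1) for (i in 1:(K - 1)) for (j in (i + 1):K) {
    fi <- as.numeric(cnt_by[[i]]); hi <- names(cnt_by[[i]])
    fj <- as.numeric(cnt_by[[j]]); hj <- names(cnt_by[[j]])
    tot <- as.numeric(t(fi) %*% d[hi, hj, drop = FALSE] %*% fj)
    m <- tot / (sum(fi) * sum(fj))
    cross[i, j] <- cross[j, i] <- m
    Dxy[i, j] <- Dxy[j, i] <- m / L
  }
  Da <- Dxy - outer(Pi, Pi, "+") / 2
  diag(Da) <- 0
  structure(list(lineages = lin, Pi = Pi, Dxy = Dxy, Da = Da,
                 cross_mean_diff = cross, single_sequence = single, L = L),
            class = "lineage_divergence")
}

#' @export
print.lineage_divergence <- function(x, digits = 5, ...) {
  cat("Lineage divergence (per site, L =", x$L, ")\n")
  m <- x$Dxy
  m[upper.tri(m)] <- x$Da[upper.tri(x$Da)]
  diag(m) <- x$Pi
  cat("  Dxy below diagonal, Da above, Pi on diagonal:\n")
  print(round(m, digits))
  if (any(x$single_sequence))
    cat("  note: single-sequence lineage(s), Pi set to 0:",
        paste(x$lineages[x$single_sequence], collapse = ", "), "\n")
  invisible(x)
}

#' Net nucleotide divergence between two lineages
#'
#' `Da = Dxy - (Pi_a + Pi_b)/2`: the between-lineage divergence net of
#' within-lineage polymorphism.
#'
#' @param dxy per-site divergence between the lineages.
#' @param pi_a,pi_b per-site diversity within each lineage.
#' @return `Da` (may be negative for weakly diverged lineages; a warning
#'   flags that case).
#' @examples
#' net_divergence(0.02838, 0.00196, 0.00269)  # 0.026055
#' @export
net_divergence <- function(dxy, pi_a, pi_b) {
  if (any(c(dxy, pi_a, pi_b) < 0)) stop_wreckpop("inputs must be >= 0")
  da <- dxy - (pi_a + pi_b) / 2
  if (da < 0) warning("negative net divergence (within-diversity exceeds ",
                      "between-divergence)", call. = FALSE)
  da
}

#' Net divergence between a hybrid lineage and its two parents
#'
#' Corrected average divergence between a putative hybrid lineage and the
#' pair of parental lineages: the mean of the two observed parent-hybrid
#' divergences minus half the parental net divergence,
#' `(d1h + d2h)/2 - d_net/2`. Setting `literal = TRUE` instead sums the two
#' observed divergences before subtracting half the parental net divergence
#' (`d1h + d2h - d_net/2`), exposing the uncorrected "sum" variant for
#' comparison.
#'
#' @param d_parent1_hyb,d_parent2_hyb observed per-site divergences between
#'   each parent and the hybrid lineage.
#' @param d_net_parents net per-site divergence between the parents (see
#'   [net_divergence()]).
#' @param literal use the sum form instead of the averaged (default) form.
#' @return Per-site corrected divergence.
#' @examples
#' hybrid_net_divergence(0.03799, 0.04330, 0.026055)  # 0.0276175
#' @export
hybrid_net_divergence <- function(d_parent1_hyb, d_parent2_hyb,
                                  d_net_parents, literal = FALSE) {
  if (any(c(d_parent1_hyb, d_parent2_hyb, d_net_parents) < 0))
    stop_wreckpop("inputs must be >= 0")
  base <- if (literal) d_parent1_hyb + d_parent2_hyb
          else (d_parent1_hyb + d_parent2_hyb) / 2
  base - d_net_parents / 2
}

#' Molecular-clock dating of a divergence
#'
#' Converts a per-site net divergence into a time estimate via a constant
#' clock rate, `T_years = d / rate * 1e6`, with optional bounds from a rate
#' interval (time bounds are evaluated at the interval endpoints; the upper
#' time bound comes from the slower rate).
#'
#' @param d per-site divergence.
#' @param rate substitutions/site/Myr between lineages (e.g. `0.02` for the
#'   conventional 2\% per Myr mitochondrial clock).
#' @param rate_bounds optional length-2 interval of rates.
#' @return Object of class `"clock_dating"` with `T_years` and, when
#'   bounds are given, `T_bounds_years` (low, high).
#' @examples
#' clock_date(0.0276175, 0.02)  # 1,380,875 years
#' @export
clock_date <- function(d, rate, rate_bounds = NULL) {
  if (rate <= 0) stop_wreckpop("clock rate must be > 0")
  if (d < 0) stop_wreckpop("divergence must be >= 0")
  T_years <- d / rate * 1e6
  T_bounds <- NULL
  if (!is.null(rate_bounds)) {
    if (length(rate_bounds) != 2 || any(rate_bounds <= 0))
      stop_wreckpop("rate_bounds must be two positive rates")
    T_bounds <- sort(d / rate_bounds * 1e6)
  }
  structure(list(d = d, rate = rate, rate_bounds = rate_bounds,
                 T_years = T_years, T_bounds_years = T_bounds),
            class = "clock_dating")
}

#' @export
print.clock_dating <- function(x, ...) {
  cat(sprintf("Molecular-clock dating: d = %g at %g subst/site/Myr\n",
              x$d, x$rate))
  cat(sprintf("  T = %s years bp\n", format(round(x$T_years), big.mark = ",")))
  if (!is.null(x$T_bounds_years))
    cat(sprintf("  rate interval [%g, %g] -> %.2f-%.2f Myr\n",
                min(x$rate_bounds), max(x$rate_bounds),
                x$T_bounds_years[1] / 1e6, x$T_bounds_years[2] / 1e6))
  invisible(x)
}
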
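# Genetic distances and neighbor-joining trees with bootstrap support.

#' Jukes-Cantor distances between sequences
#'
#' `d = -(3/4) ln(1 - 4p/3)` with `p` the per-site proportion of
#' differences (`Hamming / L`). Defined for `p < 0.75`.
#'
#' @param s a `sequence_set` (distances between its haplotypes).
#' @param L analyzed site count; defaults to the set's `total_length`.
#' @return A symmetric `"dist_matrix"` (labels, zero diagonal).
#' @export
jc_distances <- function(s, L = s$total_length) {
  stopifnot(inherits(s, "sequence_set"))
  if (is.null(L) || L <= 0) stop_wreckpop("analyzed length L is required")
  hap <- unique(s$records$haplotype)
  d <- hamming_matrix(s$states[hap, , drop = FALSE])$d
  p <- d / L
  if (any(p >= 0.75)) {
    bad <- which(p >= 0.75 & upper.tri(p), arr.ind = TRUE)[1, ]
    stop_wreckpop("JC distance undefined (p >= 0.75) for pair ",
                  hap[bad[1]], " / ", hap[bad[2]])
  }
  m <- -0.75 * log(1 - 4 * p / 3)
  structure(m, class = c("dist_matrix", class(m)))
}

#' Cavalli-Sforza chord distance between populations
#'
#' Per-locus chord distance `(2/pi) * sqrt(2 * (1 - sum_k sqrt(p_k q_k)))`
#' averaged over loci. Allele sets are unioned across populations with
#' zero frequencies for unobserved alleles.
#'
#' @param freqs either a [genotype_table()] or a list (one element per
#'   locus) of population x allele frequency matrices with population
#'   rownames; frequencies must sum to 1 per population.
#' @return A symmetric `"dist_matrix"` over populations.
#' @export
chord_distance <- function(freqs) {
  if (inherits(freqs, "genotype_table")) freqs <- allele_freqs(freqs)
  pops <- rownames(freqs[[1]])
  for (f in freqs) {
    if (!identical(rownames(f), pops))
      stop_wreckpop("all loci must cover the same populations")
    sums <- rowSums(f, na.rm = TRUE)
    if (any(abs(sums[!is.na(sums) & sums > 0] - 1) > 1e-6))
      stop_wreckpop("frequencies must sum to 1 per population")
  }
  K <- length(pops)
  d <- matrix(0, K, K, dimnames = list(pops, pops))
  for (i in seq_len(K - 1)) for (j in (i + 1):K) {
    per_locus <- vapply(freqs, function(f) {
      p <- f[i, ]; q <- f[j, ]
      if (anyNA(p) || anyNA(q)) return(NA_real_)
      cosf <- sum(sqrt(p * q))
      2 / pi * sqrt(2 * max(0, 1 - cosf))
    }, numeric(1))
    d[i, j] <- d[j, i] <- mean(per_locus, na.rm = TRUE)
  }
  structure(d, class = c("dist_matrix", class(d)))
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration on a symmetric distance matrix. Negative
#' branch lengths (a known NJ artifact) are clamped to zero by default and
#' flagged on the returned object.
#'
#' @param D symmetric distance matrix with labels (>= 3 taxa).
#' @param clamp_negative clamp negative branch lengths at 0 (default TRUE).
#' @return An [ape::phylo] object (unrooted), with attribute
#'   `"clamped_branches"` giving how many branches were clamped.
#' @export
neighbor_joining <- function(D, clamp_negative = TRUE) {
  D <- as.matrix(D)
  if (nrow(D) < 3) stop_wreckpop("neighbor-joining needs >= 3 taxa")
  if (any(!is.finite(D))) stop_wreckpop("non-finite distances")
  if (is.null(rownames(D))) rownames(D) <- colnames(D) <-
      paste0("t", seq_len(nrow(D)))
  tr <- ape::nj(as.dist(D))
  clamped <- 0L
  if (clamp_negative && any(tr$edge.length < 0)) {
    clamped <- sum(tr$edge.length < 0)
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  attr(tr, "clamped_branches") <- clamped
  tr
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Bootstraps the resampling units of the data (alignment columns for
#' sequences, loci for allele-frequency tables when two or more loci are
#' present, otherwise genotypes within populations), rebuilds the NJ tree
#' per replicate, and maps bipartition frequencies (percent) onto the
#' full-data tree's internal nodes.
#'
#' @param data a `sequence_set` (requires `total_length`; invariant sites
#'   are included as constant columns) or a [genotype_table()].
#' @param n_reps bootstrap replicates (default 10000).
#' @param seed integer seed.
#' @return The full-data NJ tree with `node.label` set to support
#'   percentages.
#' @export
bootstrap_support <- function(data, n_reps = 10000, seed = 1) {
  if (n_reps < 1) stop_wreckpop("n_reps must be >= 1")
  set.seed(seed)
  if (inherits(data, "sequence_set")) {
    if (is.null(data$total_length))
      stop_wreckpop("sequence bootstrap requires total_length")
    hap <- unique(data$records$haplotype)
    st <- data$states[hap, , drop = FALSE]
    L <- data$total_length
    n_var <- ncol(st)
    full <- neighbor_joining(jc_distances(data))
    make_rep <- function() {
      idx <- sample.int(L, L, replace = TRUE)
      var_idx <- idx[idx <= n_var]  # columns beyond n_var are invariant
      d <- if (length(var_idx))
        hamming_matrix(st[, var_idx, drop = FALSE])$d else
        matrix(0, length(hap), length(hap), dimnames = list(hap, hap))
      p <- d / L
      p[p >= 0.75] <- 0.7499
      m <- -0.75 * log(1 - 4 * p / 3)
      neighbor_joining(m)
    }
  } else if (inherits(data, "genotype_table")) {
    freqs <- allele_freqs(data)
    full <- neighbor_joining(chord_distance(freqs))
    n_loci <- length(freqs)
    if (n_loci >= 2) {
      make_rep <- function()
        neighbor_joining(chord_distance(
          freqs[sample.int(n_loci, n_loci, replace = TRUE)]))
    } else {
      pop <- data$individuals$pop
      idx_by_pop <- split(seq_along(pop), pop)
      make_rep <- function() {
        idx <- unlist(lapply(idx_by_pop, function(ii)
          ii[sample.int(length(ii), length(ii), replace = TRUE)]))
        gb <- genotype_table(data$individuals[idx, , drop = FALSE],
                             data$loci, data$alleles[idx, , , drop = FALSE])
        neighbor_joining(chord_distance(gb))
      }
    }
  } else stop_wreckpop("need a sequence_set or genotype_table")
  reps <- vector("list", n_reps)
  for (b in seq_len(n_reps)) reps[[b]] <- make_rep()
  counts <- ape::prop.clades(full, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  full$node.label <- round(100 * counts / n_reps, 1)
  attr(full, "n_reps") <- n_reps
  full
}

#' Write a tree with support values to Newick
#'
#' @param tree a `phylo` with optional `node.label` supports.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
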
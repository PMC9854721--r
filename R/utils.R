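# internal helpers shared across modules

IUPAC_CODES <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N", "-", "?")
# characters treated as ambiguous/missing for pairwise-deletion distances
AMBIGUOUS_CODES <- setdiff(IUPAC_CODES, c("A", "C", "G", "T", "U"))

logsumexp <- function(x) {
  x <- x[is.finite(x) | x > -Inf]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' @noRd
stop_wreckpop <- function(...) stop(..., call. = FALSE)

# Hamming distance between rows of a character matrix, pairwise deletion of
# ambiguous characters.  Returns list(d = integer distance matrix,
# sites = number of compared sites per pair).
hamming_matrix <- function(states) {
  n <- nrow(states)
  ok <- !matrix(states %in% AMBIGUOUS_CODES, nrow = n)
  d <- matrix(0L, n, n, dimnames = list(rownames(states), rownames(states)))
  sites <- matrix(ncol(states), n, n)
  if (n < 2) return(list(d = d, sites = sites))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    use <- ok[i, ] & ok[j, ]
    dij <- sum(states[i, use] != states[j, use])
    d[i, j] <- d[j, i] <- dij
    sites[i, j] <- sites[j, i] <- sum(use)
  }
  list(d = d, sites = sites)
}

# deterministic seed derivation for sub-tasks, kept below 2^31
derive_seed <- function(seed, k) {
  (as.integer(seed) + 1000003L * as.integer(k)) %% 2147483647L
}
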
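#' Four-gamete incompatible site pairs
#'
#' For every pair of variable positions, tests whether all four gametic
#' combinations occur among the sequences; such a pair cannot be explained
#' without recurrent mutation or recombination. Sites with more than two
#' states are decomposed into biallelic presence/absence of each state, and
#' the pair is flagged if any decomposition shows all four gametes.
#'
#' @param s a `sequence_set` with at least 4 sequences.
#' @return Two-column integer matrix of incompatible position pairs
#'   (left < right), ordered by left then right position.
#' @export
incompatible_pairs <- function(s) {
  stopifnot(inherits(s, "sequence_set"))
  if (nrow(s$records) < 4)
    stop_wreckpop("four-gamete test needs at least 4 sequences")
  st <- expanded_states(s)
  pos <- s$positions
  P <- ncol(st)
  out <- matrix(integer(0), ncol = 2)
  for (a in seq_len(P - 1)) {
    ca <- st[, a]
    oka <- !(ca %in% AMBIGUOUS_CODES)
    sa <- unique(ca[oka])
    if (length(sa) < 2) next
    for (b in (a + 1):P) {
      cb <- st[, b]
      okb <- !(cb %in% AMBIGUOUS_CODES)
      sb <- unique(cb[okb])
      if (length(sb) < 2) next
      use <- oka & okb
      # biallelic split: one indicator suffices for 2 states
      splits_a <- if (length(sa) == 2) sa[1] else sa
      splits_b <- if (length(sb) == 2) sb[1] else sb
      hit <- FALSE
      for (xa in splits_a) {
        ia <- ca[use] == xa
        for (xb in splits_b) {
          ib <- cb[use] == xb
          if (length(unique(paste(ia, ib))) == 4) { hit <- TRUE; break }
        }
        if (hit) break
      }
      if (hit) out <- rbind(out, c(pos[a], pos[b]))
    }
  }
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

#' Hudson-Kaplan minimum number of recombination events
#'
#' Lower bound Rm on the number of recombination events: reduce the
#' incompatible intervals to the minimal ones (delete every interval that
#' contains another incompatible interval), then scan by right endpoint,
#' accepting an interval whenever its left endpoint is at or beyond the
#' last accepted right endpoint (open-interval convention: adjacent
#' intervals may share an endpoint). The accepted set is a maximum
#' collection of disjoint incompatible intervals, each of which must host
#' at least one recombination event.
#'
#' @param pairs incompatible position pairs from [incompatible_pairs()],
#'   or a `sequence_set` (in which case the pairs are computed first).
#' @return Object of class `"recombination_report"` with
#'   `incompatible_pairs`, `Rm` and `intervals`.
#' @export
hudson_kaplan_rm <- function(pairs) {
  if (inherits(pairs, "sequence_set")) pairs <- incompatible_pairs(pairs)
  pairs <- matrix(as.integer(pairs), ncol = 2)
  if (nrow(pairs) == 0)
    return(structure(list(incompatible_pairs = pairs, Rm = 0L,
                          intervals = pairs),
                     class = "recombination_report"))
  if (any(pairs[, 1] >= pairs[, 2]))
    stop_wreckpop("pairs must satisfy left < right")
  # minimal intervals: drop any interval strictly containing another
  keep <- rep(TRUE, nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    contains_other <- pairs[, 1] >= pairs[i, 1] & pairs[, 2] <= pairs[i, 2] &
      !(pairs[, 1] == pairs[i, 1] & pairs[, 2] == pairs[i, 2])
    if (any(contains_other)) keep[i] <- FALSE
  }
  m <- pairs[keep, , drop = FALSE]
  m <- m[order(m[, 2], m[, 1]), , drop = FALSE]
  last <- -Inf
  iv <- matrix(integer(0), ncol = 2)
  for (r in seq_len(nrow(m))) {
    if (m[r, 1] >= last) {
      iv <- rbind(iv, m[r, ])
      last <- m[r, 2]
    }
  }
  structure(list(incompatible_pairs = pairs, Rm = nrow(iv), intervals = iv),
            class = "recombination_report")
}

#' @export
print.recombination_report <- function(x, ...) {
  cat(sprintf("Hudson-Kaplan recombination bound: Rm = %d (%d incompatible pairs)\n",
              x$Rm, nrow(x$incompatible_pairs)))
  if (x$Rm > 0) {
    cat("  localizing intervals:\n")
    apply(x$intervals, 1, function(r)
      cat(sprintf("    (%d, %d)\n", r[1], r[2])))
  }
  invisible(x)
}
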
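# shared fixture builders

table2_path <- function() {
  system.file("extdata", "table2_coi.tsv", package = "wreckpop")
}

table2_matrix <- function(total_length = NULL) {
  read_variable_site_table(table2_path(), total_length = total_length)
}

table2_sequences <- function(total_length = NULL) {
  expand_haplotypes(table2_matrix(total_length))
}

# tiny 2-population, 2-locus GENEPOP file content (3-digit coding)
write_mini_genepop <- function(path, digits = 3) {
  fmt <- function(a) sprintf(paste0("%0", digits, "d"), a)
  gt <- function(a, b) paste0(fmt(a), fmt(b))
  lines <- c(
    "mini example",
    "locA",
    "locB",
    "pop",
    paste0("north1 ,  ", gt(12, 14), " ", gt(7, 7)),
    paste0("north2 ,  ", gt(12, 12), " ", gt(7, 9)),
    "POP",
    paste0("south1 ,  ", gt(14, 14), " ", gt(9, 9)),
    paste0("south2 ,  ", gt(0, 0), " ", gt(7, 9)))
  writeLines(lines, path)
  path
}

# hand-built genotype table from a list of populations, each a list of
# per-locus 2-column matrices
build_genotype_table <- function(pop_list, loci) {
  ids <- character(0); pops <- character(0)
  n_tot <- sum(vapply(pop_list, function(p) nrow(p[[1]]), 0L))
  alleles <- array(NA_integer_, c(n_tot, length(loci), 2))
  row0 <- 0L
  for (pn in names(pop_list)) {
    n <- nrow(pop_list[[pn]][[1]])
    ids <- c(ids, sprintf("%s_%d", pn, seq_len(n)))
    pops <- c(pops, rep(pn, n))
    for (l in seq_along(loci)) {
      m <- pop_list[[pn]][[l]]
      alleles[row0 + seq_len(n), l, 1] <- pmin(m[, 1], m[, 2])
      alleles[row0 + seq_len(n), l, 2] <- pmax(m[, 1], m[, 2])
    }
    row0 <- row0 + n
  }
  genotype_table(data.frame(id = ids, pop = pops,
                            stringsAsFactors = FALSE), loci, alleles)
}

# brute-force mean pairwise Hamming distance over expanded sequences
brute_force_k <- function(s, lineage = NULL) {
  if (!is.null(lineage)) s <- filter_lineage(s, lineage)
  st <- s$states[s$records$haplotype, , drop = FALSE]
  n <- nrow(st)
  tot <- 0; np <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + sum(st[i, ] != st[j, ])
    np <- np + 1
  }
  list(sum = tot, pairs = np, k = tot / np)
}

# exact unsigned Stirling numbers of the first kind via integer
# polynomial expansion of x(x+1)...(x+n-1)
stirling_exact <- function(n) {
  coef <- c(0, 1)  # x
  if (n > 1) for (m in 1:(n - 1)) {
    coef <- c(0, coef) + m * c(coef, 0)  # multiply by (x + m)
  }
  coef[2:(n + 1)]  # |s(n, k)| for k = 1..n
}

# maximum set of pairwise-disjoint intervals by exhaustive subset search
# (open-interval convention: sharing an endpoint is allowed)
max_disjoint_exhaustive <- function(pairs) {
  n <- nrow(pairs)
  best <- 0
  for (mask in 0:(2^n - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(sel) <= best) next
    ok <- TRUE
    if (length(sel) > 1) {
      for (i in seq_along(sel)[-1]) for (j in seq_len(i - 1)) {
        a <- pairs[sel[i], ]; b <- pairs[sel[j], ]
        if (max(a[1], b[1]) < min(a[2], b[2])) { ok <- FALSE; break }
      }
    }
    if (ok) best <- length(sel)
  }
  best
}
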
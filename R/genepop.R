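#' Construct a diploid genotype table
#'
#' @param individuals data frame with columns `id`, `pop` and optionally
#'   `year`.
#' @param loci character vector of locus names.
#' @param alleles integer array of dim `c(n_individuals, n_loci, 2)`;
#'   `NA` encodes a missing genotype (both gene copies `NA`).
#' @return An object of class `"genotype_table"`.
#' @export
genotype_table <- function(individuals, loci, alleles) {
  individuals <- as.data.frame(individuals)
  if (!all(c("id", "pop") %in% names(individuals)))
    stop_wreckpop("individuals needs columns 'id' and 'pop'")
  if (is.null(individuals$year)) individuals$year <- NA_integer_
  if (!length(unique(individuals$pop)))
    stop_wreckpop("at least one population required")
  alleles <- unclass(alleles)
  if (!identical(dim(alleles), c(nrow(individuals), length(loci), 2L)))
    stop_wreckpop("alleles must be an n x loci x 2 integer array")
  storage.mode(alleles) <- "integer"
  if (any(alleles <= 0, na.rm = TRUE))
    stop_wreckpop("allele sizes must be positive")
  dimnames(alleles) <- list(individuals$id, loci, NULL)
  structure(list(individuals = individuals, loci = loci, alleles = alleles),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("Genotype table: %d individuals, %d loci (%s)\n",
              nrow(x$individuals), length(x$loci),
              paste(x$loci, collapse = ", ")))
  print(table(population = x$individuals$pop))
  miss <- mean(is.na(x$alleles[, , 1]))
  cat(sprintf("  missing genotypes: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' Read a GENEPOP genotype file
#'
#' Standard GENEPOP dialect: a title line, locus names (one per line or
#' comma-separated on one line), then `pop` blocks (case-insensitive) of
#' individuals `name , g1 g2 ...` with 2- or 3-digit allele coding per gene
#' copy; `00`/`000` is missing. Population codes are taken from the last
#' individual name of each block (GENEPOP convention) unless that is
#' ambiguous, in which case `pop1`, `pop2`, ... are used.
#'
#' @param path GENEPOP file path.
#' @param pop_names optional character vector overriding population codes.
#' @return A [genotype_table()].
#' @export
read_genepop <- function(path, pop_names = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\\s+$", "", lines)
  if (length(lines) < 3) stop_wreckpop("truncated GENEPOP file")
  body <- lines[-1]  # drop title
  is_pop <- grepl("^\\s*pop\\s*$", body, ignore.case = TRUE)
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop_wreckpop("no 'pop' separator found")
  locus_lines <- body[seq_len(first_pop - 1)]
  loci <- unlist(strsplit(paste(locus_lines, collapse = ","), ","))
  loci <- trimws(loci)
  loci <- loci[nzchar(loci)]
  if (!length(loci)) stop_wreckpop("no locus names before first 'pop'")

  pop_id <- cumsum(is_pop)
  ind_lines <- which(!is_pop & pop_id > 0 & nzchar(trimws(body)))
  ids <- character(0); pops <- integer(0)
  all_list <- list()
  for (ln in ind_lines) {
    parts <- strsplit(body[ln], ",")[[1]]
    if (length(parts) < 2)
      stop_wreckpop("line ", ln + 1, ": expected 'name , genotypes'")
    gstr <- strsplit(trimws(paste(parts[-1], collapse = ",")), "\\s+")[[1]]
    gstr <- gstr[nzchar(gstr)]
    if (length(gstr) != length(loci))
      stop_wreckpop("line ", ln + 1, ": ", length(gstr),
                    " genotypes for ", length(loci), " loci")
    w <- nchar(gstr)
    if (any(!(w %in% c(4L, 6L))))
      stop_wreckpop("line ", ln + 1,
                    ": genotypes must use 2- or 3-digit allele coding")
    half <- w / 2
    a1 <- as.integer(substr(gstr, 1, half))
    a2 <- as.integer(substr(gstr, half + 1, w))
    a1[a1 == 0L] <- NA_integer_; a2[a2 == 0L] <- NA_integer_
    # a genotype with one missing copy is treated as wholly missing
    miss <- is.na(a1) | is.na(a2)
    a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
    ids <- c(ids, trimws(parts[1]))
    pops <- c(pops, pop_id[ln])
    all_list[[length(all_list) + 1L]] <- cbind(a1, a2)
  }
  n <- length(ids)
  alleles <- array(NA_integer_, c(n, length(loci), 2))
  for (i in seq_len(n)) alleles[i, , ] <- all_list[[i]]
  npop <- max(pops)
  if (is.null(pop_names)) {
    last_ids <- vapply(seq_len(npop),
                       function(p) ids[max(which(pops == p))], "")
    pop_names <- if (anyDuplicated(last_ids)) sprintf("pop%d", seq_len(npop))
                 else last_ids
  }
  ids_u <- make.unique(ids)
  genotype_table(
    data.frame(id = ids_u, pop = pop_names[pops], stringsAsFactors = FALSE),
    loci, alleles)
}

#' Write a GENEPOP genotype file
#'
#' @param g a [genotype_table()].
#' @param path output path.
#' @param title title line content.
#' @param digits 2 or 3 digit allele coding.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(g, path, title = "wreckpop export", digits = 3) {
  stopifnot(inherits(g, "genotype_table"), digits %in% c(2, 3))
  if (any(g$alleles >= 10^digits, na.rm = TRUE))
    stop_wreckpop("allele sizes do not fit in ", digits, "-digit coding")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(title, g$loci), con)
  fmt <- paste0("%0", digits, "d")
  for (p in unique(g$individuals$pop)) {
    writeLines("pop", con)
    for (i in which(g$individuals$pop == p)) {
      a <- g$alleles[i, , , drop = FALSE]
      code <- vapply(seq_along(g$loci), function(l) {
        if (is.na(a[1, l, 1])) paste0(strrep("0", digits), strrep("0", digits))
        else paste0(sprintf(fmt, a[1, l, 1]), sprintf(fmt, a[1, l, 2]))
      }, "")
      writeLines(paste0(g$individuals$id[i], " ,  ",
                        paste(code, collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Subset a genotype table by population
#'
#' @param g a [genotype_table()].
#' @param pops populations to keep.
#' @return The filtered table.
#' @export
filter_populations <- function(g, pops) {
  keep <- g$individuals$pop %in% pops
  genotype_table(g$individuals[keep, , drop = FALSE], g$loci,
                 g$alleles[keep, , , drop = FALSE])
}

# per-population allele count tables for one locus:
# list of named integer vectors (names = allele sizes)
allele_counts_by_pop <- function(g, locus) {
  l <- match(locus, g$loci)
  if (is.na(l)) stop_wreckpop("unknown locus: ", locus)
  a <- rbind(cbind(g$individuals$pop, g$alleles[, l, 1]),
             cbind(g$individuals$pop, g$alleles[, l, 2]))
  a <- a[!is.na(a[, 2]), , drop = FALSE]
  pops <- unique(g$individuals$pop)
  sizes <- sort(unique(as.integer(a[, 2])))
  out <- lapply(pops, function(p) {
    v <- table(factor(as.integer(a[a[, 1] == p, 2]), levels = sizes))
    setNames(as.integer(v), sizes)
  })
  names(out) <- pops
  out
}

# allele frequency matrix (pop x allele) per locus, list over loci
allele_freqs <- function(g) {
  out <- lapply(g$loci, function(loc) {
    cts <- allele_counts_by_pop(g, loc)
    m <- do.call(rbind, cts)
    tot <- rowSums(m)
    f <- m / ifelse(tot == 0, NA, tot)
    rownames(f) <- names(cts)
    f
  })
  names(out) <- g$loci
  out
}
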
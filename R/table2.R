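#' Construct a variable-site haplotype matrix
#'
#' The central mitochondrial data object: a set of haplotypes typed at a
#' common list of variable nucleotide positions within a gene fragment (here
#' the COI barcode), together with absolute observation counts per sampling
#' region and a lineage tag per haplotype.
#'
#' @param positions integer vector of 1-based nucleotide coordinates within
#'   the analyzed fragment, strictly increasing.
#' @param states character matrix (haplotypes x positions) of IUPAC bases,
#'   fully resolved (no `"."` placeholders); rownames are haplotype names.
#' @param lineage character vector, one lineage tag per haplotype (e.g.
#'   `"americanus"`, `"oxygeneios"`, `"saf"`).
#' @param region_counts non-negative integer matrix (haplotypes x regions)
#'   of absolute observation counts; column names are region codes.
#' @param total_length optional positive integer: the number of analyzed
#'   sites L. Required only by per-site statistics; no default is guessed.
#' @return An object of class `"variable_site_matrix"`.
#' @seealso [read_variable_site_table()], [expand_haplotypes()]
#' @export
variable_site_matrix <- function(positions, states, lineage, region_counts,
                                 total_length = NULL) {
  positions <- as.integer(positions)
  if (any(diff(positions) <= 0))
    stop_wreckpop("positions must be strictly increasing")
  states <- as.matrix(states)
  if (ncol(states) != length(positions))
    stop_wreckpop("states must have one column per position")
  bad <- !(states %in% IUPAC_CODES)
  if (any(bad))
    stop_wreckpop("non-IUPAC characters in states: ",
                  paste(unique(states[bad]), collapse = ", "))
  hap <- rownames(states)
  if (is.null(hap) || anyDuplicated(hap))
    stop_wreckpop("haplotype names must be present and unique")
  region_counts <- as.matrix(region_counts)
  if (nrow(region_counts) != nrow(states))
    stop_wreckpop("region_counts must have one row per haplotype")
  storage.mode(region_counts) <- "integer"
  if (any(is.na(region_counts)) || any(region_counts < 0))
    stop_wreckpop("region counts must be non-negative integers")
  if (sum(region_counts) == 0)
    stop_wreckpop("total haplotype count must be positive")
  if (length(lineage) != nrow(states))
    stop_wreckpop("one lineage tag per haplotype required")
  if (!is.null(total_length)) {
    total_length <- as.integer(total_length)
    if (total_length < length(positions))
      stop_wreckpop("total_length must be >= number of variable positions")
  }
  structure(
    list(positions = positions, states = states,
         lineage = setNames(as.character(lineage), hap),
         region_counts = region_counts, total_length = total_length),
    class = "variable_site_matrix")
}

#' @export
print.variable_site_matrix <- function(x, ...) {
  cat("Variable-site haplotype matrix\n")
  cat(sprintf("  %d haplotypes x %d positions (%d..%d), total count %d\n",
              nrow(x$states), length(x$positions), min(x$positions),
              max(x$positions), sum(x$region_counts)))
  cat("  lineages:", paste(sprintf("%s (%d)", names(table(x$lineage)),
                                   table(x$lineage)), collapse = ", "), "\n")
  cat("  regions:", paste(colnames(x$region_counts), collapse = " "), "\n")
  if (!is.null(x$total_length))
    cat("  analyzed length L =", x$total_length, "\n")
  invisible(x)
}

#' Read a variable-site haplotype table
#'
#' Parses the tab-separated haplotype-table dialect used for COI variable
#' sites: a header row naming, in order, a `haplotype` column, a `lineage`
#' column, one column per nucleotide position (the column name is the
#' integer coordinate), a `freq` column with the absolute haplotype count,
#' and one count column per region code. The first haplotype row spells all
#' bases; later rows may use `"."` for "same as first row". The `freq`
#' column must equal the row sum of the region counts. Relative frequencies
#' (e.g. `"26 (50.0)"`) are accepted in `freq` and the parenthetical part is
#' ignored in favor of the absolute count.
#'
#' @param path path to the TSV file.
#' @param total_length optional analyzed length L, attached to the result.
#' @return A [variable_site_matrix()].
#' @examples
#' tab <- read_variable_site_table(
#'   system.file("extdata", "table2_coi.tsv", package = "wreckpop"))
#' tab
#' @export
read_variable_site_table <- function(path, total_length = NULL) {
  d <- read.delim(path, check.names = FALSE, colClasses = "character",
                  strip.white = TRUE)
  need <- c("haplotype", "lineage", "freq")
  if (!all(need %in% names(d)))
    stop_wreckpop("header must contain columns: ",
                  paste(need, collapse = ", "))
  poscols <- grep("^[0-9]+$", names(d), value = TRUE)
  if (!length(poscols)) stop_wreckpop("no position columns found in header")
  ifreq <- match("freq", names(d))
  regcols <- names(d)[seq_len(ncol(d)) > ifreq]
  if (!length(regcols)) stop_wreckpop("no region count columns after 'freq'")

  states <- as.matrix(d[, poscols, drop = FALSE])
  rownames(states) <- d$haplotype
  # resolve '.' against the reference (first) row
  ref <- states[1, ]
  if (any(ref == "."))
    stop_wreckpop("reference row (first haplotype) may not contain '.'")
  for (i in seq_len(nrow(states))[-1]) {
    dot <- states[i, ] == "."
    states[i, dot] <- ref[dot]
  }
  bad <- which(matrix(!(states %in% IUPAC_CODES), nrow(states)),
               arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop_wreckpop(sprintf("non-IUPAC state in row '%s', position %s",
                          rownames(states)[bad[1, 1]], poscols[bad[1, 2]]))

  # absolute counts; tolerate "26 (50.0)" style entries
  freq <- suppressWarnings(as.integer(sub("\\s*\\(.*\\)$", "", d$freq)))
  counts <- as.matrix(d[, regcols, drop = FALSE])
  suppressWarnings(storage.mode(counts) <- "integer")
  if (any(is.na(counts)))
    stop_wreckpop("non-integer region count encountered")
  rowsum <- rowSums(counts)
  offrow <- which(!is.na(freq) & freq != rowsum)
  if (length(offrow))
    stop_wreckpop(sprintf(
      "row '%s': region counts sum to %d but freq declares %d",
      d$haplotype[offrow[1]], rowsum[offrow[1]], freq[offrow[1]]))
  rownames(counts) <- d$haplotype
  variable_site_matrix(as.integer(poscols), states, d$lineage, counts,
                       total_length = total_length)
}

#' Write a variable-site haplotype table
#'
#' Inverse of [read_variable_site_table()]: writes the TSV dialect with the
#' first haplotype spelled in full and identical states abbreviated to
#' `"."` in later rows.
#'
#' @param x a [variable_site_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_variable_site_table <- function(x, path) {
  states <- x$states
  ref <- states[1, ]
  disp <- states
  for (i in seq_len(nrow(states))[-1]) {
    same <- states[i, ] == ref
    disp[i, same] <- "."
  }
  out <- data.frame(haplotype = rownames(states), lineage = unname(x$lineage),
                    disp, freq = rowSums(x$region_counts), x$region_counts,
                    check.names = FALSE)
  names(out)[2 + seq_along(x$positions)] <- as.character(x$positions)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Expand haplotype counts into a per-individual sequence set
#'
#' Converts the aggregated haplotype x region count matrix into one record
#' per observed individual, the unit over which pairwise statistics are
#' defined (e.g. the 52 analyzed COI sequences of the wreckfish dataset).
#'
#' @param m a [variable_site_matrix()].
#' @return An object of class `"sequence_set"`: a list with `records` (data
#'   frame of id, haplotype, region, lineage), the shared `states` matrix,
#'   `positions` and `total_length`.
#' @export
expand_haplotypes <- function(m) {
  stopifnot(inherits(m, "variable_site_matrix"))
  cnt <- m$region_counts
  idx <- which(cnt > 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  hap <- rownames(cnt)[rep(idx[, 1], cnt[idx])]
  reg <- colnames(cnt)[rep(idx[, 2], cnt[idx])]
  records <- data.frame(
    id = sprintf("%s_%s_%02d", hap, reg, unlist(lapply(cnt[idx], seq_len))),
    haplotype = hap, region = reg, lineage = unname(m$lineage[hap]),
    stringsAsFactors = FALSE)
  structure(list(records = records, states = m$states,
                 positions = m$positions, total_length = m$total_length),
            class = "sequence_set")
}

#' @export
print.sequence_set <- function(x, ...) {
  cat(sprintf("Sequence set: %d records, %d haplotypes, %d variable sites\n",
              nrow(x$records), length(unique(x$records$haplotype)),
              length(x$positions)))
  print(table(lineage = x$records$lineage))
  invisible(x)
}

#' Restrict a sequence set to one or more lineages
#'
#' @param s a `sequence_set`.
#' @param lineage character vector of lineage tags to keep.
#' @return The filtered `sequence_set`.
#' @export
filter_lineage <- function(s, lineage) {
  stopifnot(inherits(s, "sequence_set"))
  s$records <- s$records[s$records$lineage %in% lineage, , drop = FALSE]
  s
}

# states matrix expanded to one row per record
expanded_states <- function(s) {
  st <- s$states[s$records$haplotype, , drop = FALSE]
  rownames(st) <- s$records$id
  st
}

#' Export a sequence set as FASTA
#'
#' Writes one sequence per record. Sites outside the variable positions are
#' emitted as `"N"` unless a full-length reference sequence is supplied, in
#' which case the reference is used as background and the variable sites are
#' substituted per haplotype.
#'
#' @param s a `sequence_set`; its `total_length` (or the reference length)
#'   sets the emitted sequence length.
#' @param path output FASTA path.
#' @param reference optional single character string of length
#'   `total_length` used as the invariant background.
#' @return `path`, invisibly.
#' @export
write_sequence_fasta <- function(s, path, reference = NULL) {
  stopifnot(inherits(s, "sequence_set"))
  L <- if (!is.null(reference)) nchar(reference) else s$total_length
  if (is.null(L))
    stop_wreckpop("total_length (or a reference sequence) is required ",
                  "to emit full-length FASTA")
  if (max(s$positions) > L)
    stop_wreckpop("variable positions exceed sequence length L")
  bg <- if (is.null(reference)) rep("N", L)
        else strsplit(toupper(reference), "")[[1]]
  st <- expanded_states(s)
  seqs <- lapply(seq_len(nrow(st)), function(i) {
    v <- bg
    v[s$positions] <- st[i, ]
    v
  })
  names(seqs) <- rownames(st)
  ape::write.dna(seqs, path, format = "fasta", colsep = "", nbcol = -1)
  invisible(path)
}

#' Build a sequence set from a FASTA alignment
#'
#' Reduces an aligned FASTA file to its variable sites and groups identical
#' sequences into haplotypes, producing the same container the tabular
#' reader yields. Lineage and region tags may be supplied per sequence.
#'
#' @param path FASTA file of aligned sequences (equal lengths).
#' @param lineage,region optional character vectors, one entry per sequence
#'   (recycled if length 1).
#' @return A `sequence_set` whose `total_length` is the alignment length.
#' @export
read_sequence_fasta <- function(path, lineage = "unknown", region = "all") {
  aln <- ape::read.dna(path, format = "fasta", as.character = TRUE,
                       as.matrix = TRUE)
  aln <- toupper(aln)
  n <- nrow(aln)
  lineage <- rep_len(as.character(lineage), n)
  region <- rep_len(as.character(region), n)
  informative <- apply(aln, 2, function(col) {
    length(unique(col[!(col %in% AMBIGUOUS_CODES)])) > 1
  })
  pos <- which(informative)
  if (!length(pos)) pos <- 1L  # degenerate: keep one column
  key <- apply(aln[, pos, drop = FALSE], 1, paste, collapse = "")
  hap_of <- match(key, unique(key))
  hnames <- sprintf("Hap%d", seq_along(unique(key)))
  states <- aln[match(unique(key), key), pos, drop = FALSE]
  rownames(states) <- hnames
  records <- data.frame(id = rownames(aln), haplotype = hnames[hap_of],
                        region = region, lineage = lineage,
                        stringsAsFactors = FALSE)
  structure(list(records = records, states = states, positions = pos,
                 total_length = ncol(aln)),
            class = "sequence_set")
}
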
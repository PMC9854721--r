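test_that("the packaged COI table parses into the expected matrix", {
  m <- table2_matrix()
  expect_s3_class(m, "variable_site_matrix")
  expect_equal(nrow(m$states), 8)
  expect_equal(length(m$positions), 31)
  expect_equal(sum(m$region_counts), 52)
  expect_true(all(diff(m$positions) > 0))
  # dots resolved: every state is a plain base
  expect_true(all(m$states %in% c("A", "C", "G", "T")))
})

test_that("write + re-read round-trips a variable-site matrix", {
  m <- table2_matrix()
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_variable_site_table(m, tmp)
  m2 <- read_variable_site_table(tmp)
  expect_identical(m$positions, m2$positions)
  expect_identical(m$states, m2$states)
  expect_identical(m$region_counts, m2$region_counts)
  expect_identical(unname(m$lineage), unname(m2$lineage))
})

test_that("a dot-only row equals the reference row", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("haplotype\tlineage\t10\t20\tfreq\tR1",
               "H1\tx\tA\tC\t2\t2",
               "H2\tx\t.\t.\t1\t1"), tmp)
  m <- read_variable_site_table(tmp)
  expect_identical(unname(m$states["H2", ]), unname(m$states["H1", ]))
  expect_equal(sum(m$states["H1", ] != m$states["H2", ]), 0)
})

test_that("malformed tables fail with informative errors", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  # counts not matching declared freq
  writeLines(c("haplotype\tlineage\t10\t20\tfreq\tR1\tR2",
               "H1\tx\tA\tC\t5\t2\t1"), tmp)
  expect_error(read_variable_site_table(tmp), "H1")
  # non-IUPAC character
  writeLines(c("haplotype\tlineage\t10\t20\tfreq\tR1",
               "H1\tx\tA\tZ\t1\t1"), tmp)
  expect_error(read_variable_site_table(tmp), "non-IUPAC")
})

test_that("expansion conserves per-haplotype and per-lineage counts", {
  m <- table2_matrix()
  s <- expand_haplotypes(m)
  expect_equal(nrow(s$records), 52)
  lin <- table(s$records$lineage)
  expect_equal(as.integer(lin[c("americanus", "oxygeneios", "saf")]),
               c(40, 6, 6))
  hap <- table(s$records$haplotype)
  expect_equal(as.integer(hap[rownames(m$states)]),
               unname(rowSums(m$region_counts)))
  # zero-count haplotype yields no records
  m0 <- m
  m0$region_counts["PamCOI.2", ] <- 0L
  s0 <- expand_haplotypes(m0)
  expect_false("PamCOI.2" %in% s0$records$haplotype)
  expect_equal(nrow(s0$records), 48)
})

test_that("expansion is invariant under region-column permutation", {
  m <- table2_matrix()
  perm <- rev(seq_len(ncol(m$region_counts)))
  m2 <- m
  m2$region_counts <- m$region_counts[, perm]
  s1 <- expand_haplotypes(m)
  s2 <- expand_haplotypes(m2)
  key <- function(s) sort(paste(s$records$haplotype, s$records$region))
  expect_identical(key(s1), key(s2))
})

test_that("GENEPOP parses pop blocks and missing genotypes", {
  tmp <- withr::local_tempfile(fileext = ".gen")
  write_mini_genepop(tmp)
  g <- read_genepop(tmp, pop_names = c("north", "south"))
  expect_equal(g$loci, c("locA", "locB"))
  expect_equal(as.integer(table(g$individuals$pop)[c("north", "south")]),
               c(2L, 2L))
  expect_equal(g$alleles[1, 1, ], c(12L, 14L))
  expect_true(all(is.na(g$alleles[4, 1, ])))   # 000000 -> missing
  expect_equal(g$alleles[4, 2, ], c(7L, 9L))
})

test_that("2-digit and 3-digit encodings parse identically", {
  t2 <- withr::local_tempfile(fileext = ".gen")
  t3 <- withr::local_tempfile(fileext = ".gen")
  write_mini_genepop(t2, digits = 2)
  write_mini_genepop(t3, digits = 3)
  g2 <- read_genepop(t2, pop_names = c("a", "b"))
  g3 <- read_genepop(t3, pop_names = c("a", "b"))
  expect_identical(g2$alleles, g3$alleles)
  expect_identical(g2$individuals$pop, g3$individuals$pop)
})

test_that("a locus can be entirely missing yet remains present", {
  tmp <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("t", "L1", "L2", "pop",
               "x1 , 001002 000000",
               "x2 , 001001 000000"), tmp)
  g <- read_genepop(tmp)
  expect_equal(g$loci, c("L1", "L2"))
  expect_true(all(is.na(g$alleles[, 2, ])))
})

test_that("inconsistent locus counts are reported with a line number", {
  tmp <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("t", "L1", "L2", "pop", "x1 , 001002"), tmp)
  expect_error(read_genepop(tmp), "line")
})

test_that("GENEPOP write + read round-trips genotypes", {
  g <- simulate_island_genotypes(c(a = 10, b = 8), c(5, 4), 0.1, seed = 3)
  tmp <- withr::local_tempfile(fileext = ".gen")
  write_genepop(g, tmp)
  g2 <- read_genepop(tmp, pop_names = c("a", "b"))
  expect_identical(g$alleles[, , ], g2$alleles[, , ])
  expect_identical(g$individuals$pop, g2$individuals$pop)
})

test_that("FASTA export and re-import preserve the haplotype structure", {
  s <- table2_sequences(total_length = 523)
  tmp <- withr::local_tempfile(fileext = ".fa")
  write_sequence_fasta(s, tmp)
  s2 <- read_sequence_fasta(tmp)
  expect_equal(nrow(s2$records), 52)
  expect_equal(length(unique(s2$records$haplotype)), 8)
  # distances survive the round trip (N background drops no variable site)
  expect_equal(sort(as.vector(hamming_matrix(s2$states)$d)),
               sort(as.vector(hamming_matrix(s$states)$d)))
})
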
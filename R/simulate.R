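# Seed-deterministic generators for synthetic data with the statistical
# structure the estimators assume: island-model microsatellite genotypes
# (Balding-Nichols frequencies) and three-lineage sequence sets.

#' Simulate island-model microsatellite genotypes
#'
#' Base allele frequencies per locus are drawn uniform-Dirichlet; each
#' population's frequencies follow the Balding-Nichols model, a Dirichlet
#' with parameters `p_base * (1 - F) / F` so that the expected fixation
#' index among populations equals `target_fst` (`target_fst = 0` copies
#' the base frequencies exactly). Genotypes are sampled under
#' Hardy-Weinberg proportions; an optional per-locus null-allele frequency
#' converts null-carrying heterozygotes to apparent homozygotes and
#' null homozygotes to missing genotypes. An optional hierarchical layer
#' first diverges group-level frequency pools at `group_fst` and then
#' populations within each group at `target_fst` (between-population
#' within-group divergence), emulating a several-gene-pool design.
#'
#' @param sizes named integer vector of diploid sample sizes per
#'   population (names become population codes; unnamed get `pop1`...).
#' @param n_alleles integer vector of allele counts per locus (each >= 2).
#' @param target_fst differentiation among populations (within groups when
#'   `groups` is given), in `[0, 1)`.
#' @param groups optional character vector assigning each population to a
#'   group (same length/order as `sizes`).
#' @param group_fst differentiation among group pools, in `[0, 1)`; only
#'   used with `groups`.
#' @param null_freq per-locus null-allele frequency (recycled; default 0).
#' @param base_freqs optional list of base frequency vectors per locus,
#'   overriding the Dirichlet draw.
#' @param allele_ladder starting allele size per locus for the emitted
#'   2-bp size ladder (recycled; purely cosmetic for identity-based
#'   statistics).
#' @param seed integer seed; same seed, same table.
#' @return A [genotype_table()] with attribute `"spec"` recording all
#'   parameters.
#' @export
simulate_island_genotypes <- function(sizes, n_alleles, target_fst,
                                      groups = NULL, group_fst = 0,
                                      null_freq = 0, base_freqs = NULL,
                                      allele_ladder = 101L, seed = 1) {
  if (any(sizes < 1)) stop_wreckpop("sizes must be >= 1")
  if (any(n_alleles < 2)) stop_wreckpop("allele counts must be >= 2")
  if (target_fst < 0 || target_fst >= 1)
    stop_wreckpop("target_fst must lie in [0, 1)")
  K <- length(sizes)
  pops <- names(sizes)
  if (is.null(pops)) pops <- sprintf("pop%d", seq_len(K))
  L <- length(n_alleles)
  null_freq <- rep_len(null_freq, L)
  allele_ladder <- rep_len(as.integer(allele_ladder), L)
  set.seed(seed)

  rdirichlet1 <- function(alpha) {
    x <- rgamma(length(alpha), shape = pmax(alpha, 1e-12))
    if (sum(x) == 0) x[which.max(alpha)] <- 1
    x / sum(x)
  }
  bn_draw <- function(base, F) {
    if (F == 0) base else rdirichlet1(base * (1 - F) / F)
  }

  loci <- sprintf("locus%02d", seq_len(L))
  n_tot <- sum(sizes)
  alleles <- array(NA_integer_, c(n_tot, L, 2))
  ind_pop <- rep(pops, sizes)
  ids <- sprintf("%s_%03d", ind_pop, unlist(lapply(sizes, seq_len)))
  base_out <- vector("list", L)
  for (l in seq_len(L)) {
    k <- n_alleles[l]
    base <- if (!is.null(base_freqs)) base_freqs[[l]] else rdirichlet1(rep(1, k))
    base_out[[l]] <- base
    if (!is.null(groups)) {
      gpools <- lapply(unique(groups), function(gg) bn_draw(base, group_fst))
      names(gpools) <- unique(groups)
      pop_freqs <- lapply(seq_len(K), function(i)
        bn_draw(gpools[[groups[i]]], target_fst))
    } else {
      pop_freqs <- lapply(seq_len(K), function(i) bn_draw(base, target_fst))
    }
    sizes_bp <- allele_ladder[l] + 2L * (seq_len(k) - 1L)
    row0 <- 0L
    for (i in seq_len(K)) {
      n <- sizes[i]
      g1 <- sample.int(k, n, replace = TRUE, prob = pop_freqs[[i]])
      g2 <- sample.int(k, n, replace = TRUE, prob = pop_freqs[[i]])
      a1 <- sizes_bp[g1]; a2 <- sizes_bp[g2]
      if (null_freq[l] > 0) {
        r <- null_freq[l]
        # each gene copy is independently null with freq r
        null1 <- runif(n) < r; null2 <- runif(n) < r
        both <- null1 & null2
        a1[null1 & !both] <- a2[null1 & !both]  # apparent homozygote
        a2[null2 & !both] <- a1[null2 & !both]
        a1[both] <- NA_integer_; a2[both] <- NA_integer_
      }
      rows <- row0 + seq_len(n)
      alleles[rows, l, 1] <- pmin(a1, a2)
      alleles[rows, l, 2] <- pmax(a1, a2)
      row0 <- row0 + n
    }
  }
  g <- genotype_table(data.frame(id = ids, pop = ind_pop,
                                 stringsAsFactors = FALSE), loci, alleles)
  attr(g, "spec") <- list(sizes = setNames(as.integer(sizes), pops),
                          n_alleles = n_alleles, target_fst = target_fst,
                          groups = groups, group_fst = group_fst,
                          null_freq = null_freq, base_freqs = base_out,
                          seed = seed)
  g
}

#' Simulate a three-lineage sequence set
#'
#' Generates an ancestral random sequence of length `L`, derives two
#' parental lineages and a hybrid-like third lineage by sprinkling
#' Poisson-distributed substitution counts so that the expected pairwise
#' divergences match the requested per-site values, then adds independent
#' within-lineage polymorphism at per-site rate `theta_site`. Substitution
#' targets use disjoint site sets where possible so realized divergences
#' concentrate tightly around their expectations.
#'
#' @param L alignment length (>= 1).
#' @param d_pp expected per-site divergence between the two parents.
#' @param d_p1h,d_p2h expected per-site divergences from each parent to
#'   the hybrid lineage.
#' @param theta_site per-site within-lineage polymorphism rate.
#' @param n_per_lineage integer vector of 3 sequence counts
#'   (parent1, parent2, hybrid).
#' @param seed integer seed.
#' @return A `sequence_set` with lineages `parent1`, `parent2`, `hybrid`;
#'   attribute `"truth"` records the requested parameters.
#' @export
simulate_lineage_sequences <- function(L, d_pp, d_p1h, d_p2h,
                                       theta_site = 0,
                                       n_per_lineage = c(20, 20, 10),
                                       seed = 1) {
  if (L < 1) stop_wreckpop("L must be >= 1")
  dv <- c(d_pp, d_p1h, d_p2h)
  if (any(dv < 0) || any(dv >= 0.75))
    stop_wreckpop("divergences must lie in [0, 0.75)")
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  mutate_at <- function(seqv, sites) {
    for (s in sites)
      seqv[s] <- sample(setdiff(bases, seqv[s]), 1)
    seqv
  }
  anc <- sample(bases, L, replace = TRUE)
  # place parent1 and parent2 at d_pp apart; hybrid positioned to match
  # expected distances to both parents:
  # using founder mutation counts m1 (anc->p1), m2 (anc->p2), mh (anc->h)
  # on disjoint site sets, E[d(p1,p2)] = (m1+m2)/L etc.
  # Solve m1+m2 = L*d_pp, m1+mh = L*d_p1h, m2+mh = L*d_p2h.
  m1 <- max(0, round(L * (d_pp + d_p1h - d_p2h) / 2))
  m2 <- max(0, round(L * d_pp) - m1)
  mh <- max(0, round(L * d_p1h) - m1)
  need <- m1 + m2 + mh
  if (need > L) stop_wreckpop("requested divergences exceed sequence length")
  sites <- sample.int(L, need)
  f1 <- mutate_at(anc, sites[seq_len(m1)])
  f2 <- mutate_at(anc, sites[m1 + seq_len(m2)])
  fh <- mutate_at(anc, sites[m1 + m2 + seq_len(mh)])
  founders <- list(parent1 = f1, parent2 = f2, hybrid = fh)
  n_per_lineage <- rep_len(as.integer(n_per_lineage), 3)
  seqs <- list(); lineage <- character(0)
  for (li in seq_along(founders)) {
    for (i in seq_len(n_per_lineage[li])) {
      nmut <- rpois(1, theta_site * L)
      s <- founders[[li]]
      if (nmut > 0) s <- mutate_at(s, sample.int(L, min(nmut, L)))
      seqs[[length(seqs) + 1]] <- s
      lineage <- c(lineage, names(founders)[li])
    }
  }
  aln <- do.call(rbind, seqs)
  rownames(aln) <- sprintf("%s_%03d", lineage,
                           unlist(lapply(n_per_lineage, seq_len)))
  # reduce to variable sites, reuse the FASTA-set machinery
  informative <- apply(aln, 2, function(col) length(unique(col)) > 1)
  pos <- which(informative)
  if (!length(pos)) pos <- 1L
  key <- apply(aln[, pos, drop = FALSE], 1, paste, collapse = "")
  hnames <- sprintf("Hap%d", seq_along(unique(key)))
  states <- aln[match(unique(key), key), pos, drop = FALSE]
  rownames(states) <- hnames
  records <- data.frame(id = rownames(aln),
                        haplotype = hnames[match(key, unique(key))],
                        region = "sim", lineage = lineage,
                        stringsAsFactors = FALSE)
  out <- structure(list(records = records, states = states,
                        positions = pos, total_length = L),
                   class = "sequence_set")
  attr(out, "truth") <- list(L = L, d_pp = d_pp, d_p1h = d_p1h,
                             d_p2h = d_p2h, theta_site = theta_site,
                             n_per_lineage = n_per_lineage, seed = seed)
  out
}

#' Packaged reference datasets
#'
#' `"table2"` returns the COI variable-site haplotype matrix (8 haplotypes,
#' 31 positions, 52 sequences across 13 regions). `"table3"` returns the
#' published per-site diversity/divergence record for the three COI
#' lineages (within-lineage Pi on the diagonal concept, Dxy off-diagonal).
#' `"table1_design"` returns the microsatellite sampling design: region
#' codes, sampling years and genotyped sample sizes.
#'
#' @param name one of `"table2"`, `"table3"`, `"table1_design"`.
#' @return The corresponding object (see Details).
#' @export
fixture_dataset <- function(name = c("table2", "table3", "table1_design")) {
  name <- match.arg(name)
  if (name == "table2") {
    return(read_variable_site_table(
      system.file("extdata", "table2_coi.tsv", package = "wreckpop")))
  }
  if (name == "table3") {
    lin <- c("americanus", "saf", "oxygeneios")
    Pi <- setNames(c(0.00196, 0.000, 0.00269), lin)
    Dxy <- matrix(0, 3, 3, dimnames = list(lin, lin))
    Dxy["americanus", "saf"] <- Dxy["saf", "americanus"] <- 0.03799
    Dxy["americanus", "oxygeneios"] <-
      Dxy["oxygeneios", "americanus"] <- 0.02838
    Dxy["saf", "oxygeneios"] <- Dxy["oxygeneios", "saf"] <- 0.04330
    return(list(lineages = lin, Pi = Pi, Dxy = Dxy))
  }
  # microsatellite sampling design: 10 locations with genotyped samples
  data.frame(
    code = c("Azo", "Ber", "Bpl", "Can", "Mad", "Med", "Bra", "Aus",
             "Nze", "Saf"),
    region = c(rep("AtlanticNorth", 6), "AtlanticSouth", "PacificSouth",
               "PacificSouth", "IndianOcean"),
    n_mic = c(145L, 13L, 200L, 79L, 28L, 6L, 82L, 12L, 9L, 7L),
    stringsAsFactors = FALSE)
}
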
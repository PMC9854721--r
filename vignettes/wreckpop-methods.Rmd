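---
title: "Methods and design notes for wreckpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for wreckpop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wreckpop)
```

wreckpop analyzes two kinds of data that together characterize the
population structure of wreckfish (*Polyprion* spp.) and similar marine
species: a mitochondrial barcode fragment (COI) summarized as a
variable-site haplotype table with per-region absolute frequencies, and
diploid microsatellite genotypes. This vignette explains the statistical
models behind each stage, the parameters that matter, the numerical
choices made where several defensible options existed, and what the
synthetic-data generators do and do not emulate.

## The haplotype table and its expansion

The tabular COI input stores, per haplotype, a string of states at the
variable nucleotide positions (1-based coordinates within the fragment),
a lineage tag, and absolute counts per sampling region. Pairwise
statistics are defined over *individuals*, so `expand_haplotypes()`
expands the counts into one record per observed sequence; all downstream
statistics weight haplotypes by these frequencies rather than
materializing pairs, which keeps every fixture-sized computation
instantaneous.

Distances are Hamming counts over the variable sites with pairwise
deletion: any position where either sequence carries an ambiguity code is
skipped for that pair. The packaged table contains no ambiguity, so the
choice is inert there, but it mirrors the conventional treatment in
alignment-based estimators.

The analyzed fragment length `L` is a deliberate *user input with no
default*. Per-site quantities (`π = k/L`, `D_xy`, Jukes–Cantor
distances) require it, and guessing it silently would contaminate every
per-site number; functions that need `L` fail loudly when it is absent.

## Diversity statistics and Fu's Fs

`Hd`, `k` and `S` are the standard closed forms. Fu's Fs compares the
observed haplotype count `h` with its distribution under the Ewens
sampling formula at `θ` estimated from the mean pairwise difference
(`θ = k`, the π-based estimator, which is the convention of the common
desktop implementations):

$$S' = \Pr(K \ge h_{obs}), \qquad F_s = \ln\frac{S'}{1-S'},$$

with $\Pr(K = j) = |s(n,j)|\,\theta^j / \prod_{i=0}^{n-1}(\theta+i)$.
The unsigned Stirling numbers $|s(n,j)|$ overflow doubles near
$n \approx 20$, so the triangular recurrence is carried entirely in log
space (`log_stirling1()`); the implementation is cross-checked in the
tests against exact integer Stirling values for $n \le 12$ and against
an independent representation of $K$ as a sum of independent Bernoulli
variables. If $S'$ underflows to 0 or 1 the result is a signed infinity
and is flagged (`boundary`), not silently clipped.

The optional Fs p-value is a Monte-Carlo tail probability of observing
as few haplotypes (equivalently, as large an Fs) under the same Ewens
law at fixed θ, with a user seed. This is a pragmatic null — the
classical approach simulates coalescent samples — so the package treats
the p-value as an ordering diagnostic, and the tests only assert
orderings (the pooled multi-lineage set must look far more
haplotype-deficient than the within-species subset), never exact
simulated p-values.

## Lineage divergence, the hybrid correction, and dating

`pairwise_dxy()` computes within-lineage per-site diversity `π_i` and
cross-lineage `D_xy` as uncorrected p-distances divided by `L` — no
substitution-model correction, matching the definitions the quantities
are conventionally reported under. Net divergence is
`D_a = D_xy − (π_1 + π_2)/2`. A single-sequence lineage has `π = 0` by
convention and is flagged.

For a putative hybrid lineage `h` with parents `p1`, `p2`, the corrected
parents-to-hybrid divergence is implemented in two variants:

- **averaged (default):** `(D_{p1h} + D_{p2h})/2 − D_{p1p2}/2`, i.e. the
  mean observed divergence to the two parents, net of half the parental
  net divergence. This is the dimensionally consistent form — it
  collapses to `D` when both parents are equidistant (`D_{p1h} =
  D_{p2h} = D`) and the parents coincide — and it is the form whose
  output is on the scale that the downstream clock dating expects.
- **literal (`literal = TRUE`):** the sum form
  `D_{p1h} + D_{p2h} − D_{p1p2}/2`, retained for transparency because
  the averaged and sum forms circulate in the applied literature and
  differ by roughly a factor two; exposing both makes the choice
  auditable rather than silent.

`clock_date()` is plain arithmetic, `T = D/rate × 10^6` years, with the
conventional 2% per Myr between-lineage mitochondrial rate as the
package-wide default and time bounds evaluated at the endpoints of an
optional rate interval (0.69–3.00% per Myr being the fish mitochondrial
bracket used throughout the examples).

## Recombination bound

The four-gamete test marks a pair of sites incompatible when all four
gametic combinations occur. Sites with three or more states are
decomposed into presence/absence of each state and the pair is flagged
if any decomposition exhibits four gametes; this makes the one
tri-allelic column in the packaged table behave like the biallelic
theory expects. The Hudson–Kaplan bound then (1) deletes every
incompatible interval that properly contains another one (only minimal
intervals can tighten the bound) and (2) scans the remainder by right
endpoint, accepting intervals greedily under the *open-interval*
convention, so adjacent intervals may share an endpoint — necessary
because real datasets localize consecutive events at a shared segregating
site. The greedy count is provably the maximum disjoint set; the tests
verify it against exhaustive subset search on random instances.

## Median-joining networks

`median_joining_network()` iterates Bandelt-style: build the minimum
spanning network at tolerance ε (an edge survives when its endpoints
cannot be connected by strictly cheaper edges, within ε); for every
triplet of nodes joined by at least two links, form the majority-consensus
median vector; add the candidate that most reduces the minimum spanning
weight of the node set; prune median vectors that end up with fewer than
three links; repeat to a fixed point. Deliberate numerical choices:

- ε defaults to 0, the conventional "default settings" of the algorithm.
- All ties (node order, equal-reduction candidates, majority ties in a
  median column) are broken lexicographically — by haplotype name for
  observed nodes and by state string for medians — so output is
  invariant to input row order (tested).
- Columns where all three triplet states differ take the first node's
  state; for three distinct states any choice has equal Steiner cost.
- Median vectors carry frequency 0 and represent plausible unsampled
  intermediates; edges always weigh the exact Hamming distance of their
  endpoints (an invariant the tests assert).

The package does not implement the optional maximum-parsimony
post-processing of desktop network tools, and path-step counts between
clusters are treated as qualitative (tools differ in their internal
path conventions); the tests assert the topological facts that matter
for the hybrid question — within-species adjacencies at 1–2 steps, and
the hybrid haplotype attaching between the two species clusters with a
step margin of at least 4.

## Microsatellite estimators

**Summaries.** Allelic richness is exact hypergeometric rarefaction to a
common number of genes. Unbiased expected heterozygosity uses the
`2n/(2n−1)` correction; `F_IS = 1 − H_o/H_e`, undefined (NA) at
monomorphic loci.

**Hardy–Weinberg.** The exact test conditions on allele counts
(Levene's distribution) and orders genotype arrays by probability. The
Markov chain uses the classical two-individual re-pairing proposal on
individual-labelled states. A point worth recording: the number of
labelled states per genotype array is $n!\,2^H/\prod n_{ij}!$, already
proportional to the Levene probability, so the symmetric proposal is
*always accepted*; the array's log-probability is only tracked as the
test statistic. The chain runs 20 batches of 5000 iterations after a
10,000-step burn-in (the schedule of the standard desktop
implementation), and the batch spread gives a Monte-Carlo standard
error. A full-enumeration oracle for biallelic arrays backs the chain in
the tests (agreement within 3 SEs).

**F-statistics.** Weir–Cockerham `a`, `b`, `c` variance components per
allele and locus, combined as ratio-of-sums. Significance of
`F_ST > 0` permutes genotypes among populations. The multilocus θ is
*not* guaranteed to lie between per-locus values when components differ
in sign; the ratio-of-sums definition itself is the tested contract.

**Jost's D.** Per locus from Nei–Chesser unbiased `H_S`/`H_T` (harmonic
mean sample size, observed-heterozygosity correction), scaled by
`K/(K−1)`; multilocus D is the arithmetic mean over loci (the default of
the reference R implementation of this estimator; a harmonic variant
exists in the literature and is deliberately not mixed in).
Significance and CI come from bootstrapping individuals within
populations (default 1000 replicates).

**Null alleles.** An EM estimator of a single null-allele frequency:
null-carrying heterozygotes are assumed scored as visible homozygotes,
and null homozygotes as missing; the E-step splits apparent homozygotes
between true homozygotes and null heterozygotes and imputes the blank
class, iterating to `1e-8`. Heterozygote-free data drive the estimate
to its upper boundary; that case breaks the iteration and returns a
`boundary` flag instead of a convergence error. Parameter recovery
(injected null frequency 0.15, n = 500, 20 replicates, mean within
±0.05) is part of the test suite.

**Multiple testing** is Benjamini–Hochberg throughout, via the stock
step-up adjustment.

## Hierarchical AMOVA

Gene copies are the units; the distance between two copies is allele
identity (0/1), so within-set sums of squares collapse to allele-count
algebra, with an allele-size-squared variant behind `metric = "size"`
for completeness. Sums of squares are decomposed per locus at three
levels with the unequal-sample-size coefficients of the classical
nested ANOVA, variance components are summed over loci, and

$$F_{CT} = \frac{\sigma_a^2}{\sigma_T^2},\quad
  F_{SC} = \frac{\sigma_b^2}{\sigma_b^2+\sigma_c^2},\quad
  F_{ST} = \frac{\sigma_a^2+\sigma_b^2}{\sigma_T^2},$$

which satisfy `F_ST = F_CT + (1−F_CT) F_SC` identically (tested to
1e-12 on a hand-computed balanced design). Permutation schemes differ
per index: genotypes among populations within groups for `F_SC`, whole
populations among groups for `F_CT`, genotypes among all populations for
`F_ST`; the default 1023 permutations match the package-wide convention
for this analysis. Identical replicated populations produce exactly zero
among-group sums of squares but a slightly *negative* `σ_b` estimate —
the expected behavior of unbiased variance components, not an error.

## Distances, trees, bootstrap

Jukes–Cantor distances are `−(3/4)ln(1 − 4p/3)` and error out at
saturation (`p ≥ 0.75`). Worth knowing: the convex JC transform is not
exactly metric — on the packaged haplotypes it overshoots the triangle
inequality by up to ~2×10⁻⁴ — so the tests bound the violation rather
than pretend exact metricity. The Cavalli-Sforza chord distance is
`(2/π)√(2(1 − Σ√(p_k q_k)))` per locus, averaged over loci, with allele
sets unioned across populations. Neighbor-joining delegates to the
standard Saitou–Nei implementation in `ape` (this is infrastructure, not
a contribution of this package); negative branch lengths are clamped at
0 by default and counted on the returned object. Bootstrap units are
alignment columns for sequences (invariant columns included, which is
why `L` is required) and loci for frequency data when at least two loci
exist, otherwise genotypes within populations — "bootstrap of the
allele frequencies" identifies the table, and loci are the exchangeable
unit of a multilocus frequency table.

## Power simulation

Each replicate drifts `K` populations independently from common base
frequencies by `t` generations of binomial resampling of `2Ne` genes,
with `F_ST = 1 − (1 − 1/(2Ne))^t`. `t` is solved for the target
(preferring the conventional `Ne = 1000` and searching nearby values
when no integer `t` lands within `1e-4`), genotypes are drawn under HWE
at the design's sample sizes, and homogeneity is tested by the Pearson
chi-square summed over loci.

A calibration subtlety drove one deliberate choice here: with samples of
6–13 diploids against 14–25 alleles, expected cell counts sit far below
1 and the asymptotic chi-square reference is anticonservative (empirical
type-I error 0.09–0.17 at α = 0.05 in our checks; pooling rare alleles
does not rescue the smallest samples). The summed statistic is therefore
referred to a Monte-Carlo reference built from `mc_B = 199` tables drawn
with fixed margins per locus (`r2dtable`), which restores nominal
calibration (≈0.03 empirically) without touching power at realistic
differentiation, which saturates at 1.0. The asymptotic route remains
available via `mc_B = 0`, and a Fisher-exact route (per-locus exact
Monte-Carlo p-values combined by Fisher's method) via `fisher = TRUE`.

## Synthetic data: what it emulates, and what it does not

`simulate_island_genotypes()` draws base allele frequencies
uniform-Dirichlet, population frequencies from the Balding–Nichols
Dirichlet (`α = p̄(1−F)/F`, so the expected fixation index is `F`), and
genotypes under HWE, with optional null alleles (each gene copy
independently null; null homozygotes become missing) and an optional
hierarchical layer (group pools at `group_fst`, populations within
groups at `target_fst`) for gene-pool designs. Balding–Nichols is used
here because it has closed-form `F` and is fast; the power module uses
explicit drift instead because the power question is about a drift
process — both generators exist deliberately. Allele sizes are emitted
on a 2-bp ladder from a per-locus offset (e.g. 171 bp for a PamD1-like
locus) purely for realism of the files; identity-based statistics ignore
sizes.

The default study design shipped as `fixture_dataset("table1_design")`
is 10 sampling locations with 145, 13, 200, 79, 28, 6, 82, 12, 9 and 7
genotyped individuals (581 total) at 4 loci of 14–25 alleles, and the
recovery tests run at that design: Weir–Cockerham θ within ±0.02 of a
0.117 target over 50 replicates; AMOVA `F_CT` within ±0.05 of 0.24 and
`F_SC` within ±0.01 of 0.002 over 20 replicates of a 4-gene-pool layout.

Two honest limits of the emulation:

- Uniform-Dirichlet base frequencies are *more even* than real
  microsatellite frequency spectra (implied `H_e ≈ 0.9` at 20 alleles
  versus the 0.33–0.83 range typical of real panels). Consequently the
  simulated design retains partial sensitivity even at `F_ST = 0.001`
  (~0.4 power), where a real, skewed-frequency dataset shows none; the
  tests therefore assert calibration at `F_ST = 0` and the monotone
  collapse of power from the saturated global level, not alpha-level
  behavior at 0.001.
- `simulate_lineage_sequences()` places founder mutations on disjoint
  site sets, so realized divergences concentrate tightly around their
  expectations; real sequences accumulate homoplasy. This is the right
  regime for estimator-recovery tests but understates distance-estimator
  noise at high divergence.

Passing recovery tests on these generators shows the estimators are
correct under the model assumptions (HWE within populations, independent
loci, island-model or hierarchical structure); it cannot show robustness
to features the generators omit (linkage, selection, severe genotyping
artifacts beyond a single null allele per locus).

## Problem sizes and determinism

Default test-suite settings were chosen at desk scale: 50 replicates for
θ recovery, 20 for AMOVA and null-allele recovery, 200 for power and for
permutation-calibration checks, bootstrap and permutation counts reduced
to tens in orchestration tests. Every stochastic routine takes an
explicit integer seed; the pipeline derives per-stage seeds
deterministically from one master seed and records them in its JSON
manifest, so identical configurations reproduce byte-identical reports
(tested).
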
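---
title: "Sex-aware forensic and population genetics of X-STR panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sex-aware forensic and population genetics of X-STR panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xstrpop)
```

X-chromosomal short tandem repeats (X-STRs) sit between autosomal and
uniparental markers: females are diploid, males hemizygous, and tightly
linked loci on the X travel as haplotypes through male meiosis. That
inheritance pattern shapes every computation in this package — allele
counting, the forensic parameter suite, the equilibrium tests and the
haplotype statistics all have to know which chromosomes they are looking at.
This vignette records the model behind each stage, the tunable parameters
and their defaults, and the design decisions taken where the methodology
admitted more than one reasonable choice.

## The data model

A genotype table (`xstr_genotypes`) holds one row per sample with a sex
label and one or two allele calls per locus. The invariants are strict:
females carry exactly two labels per typed locus, males exactly one, and
labels follow STR nomenclature (`"15"`, `"24.1"`). Microvariant labels are
categorical text throughout — parsing them as numbers would turn `24.10`
and `24.1` into the same allele — and sorting uses the (integer part,
fractional part) key. A male call recorded as `15/15` is accepted as
hemizygous `15` with a warning, since duplicated hemizygous calls are a
common typing-software artifact; `15/16` in a male is a hard error. Missing
data (empty cell or `NA`) removes a sample from the affected locus only.

Allele frequencies are direct counts of X chromosomes: two per typed
female, one per typed male, so a fully typed cohort of 265 females and 248
males yields N = 778 pooled chromosomes per locus. Absent strata are
flagged rather than zero-filled. Male multi-locus genotypes are phased by
hemizygosity, so linkage-group haplotype frequencies are direct counts as
well; a male enters a group's count only when typed at every locus of the
group (no imputation), and females are excluded from haplotype counting
because their phase is unobserved.

## The forensic parameter suite

Everything is built from the power sums $s_2 = \sum p_i^2$,
$s_3 = \sum p_i^3$, $s_4 = \sum p_i^4$ of an allele- or
haplotype-frequency vector, accumulated in descending-frequency order so
results do not depend on input ordering:

* match probability $MP = s_2$;
* gene/haplotype diversity $GD = \frac{N}{N-1}(1 - s_2)$ with the
  small-sample correction over the $N$ observed chromosomes;
* discrimination in males $PD_m = 1 - s_2$ (hemizygous, so single-chromosome);
* discrimination in females $PD_f = 1 - 2 s_2^2 + s_4$, the probability two
  random Hardy–Weinberg genotypes differ;
* polymorphism information content $PIC = 1 - s_2 - s_2^2 + s_4$;
* expected female heterozygosity $He = \frac{2n}{2n-1}(1 - \sum \hat p_i^2)$
  from female-only frequencies ($n$ typed females), the unbiased estimator
  that reproduces the familiar $He > Ho$ pattern in near-equilibrium data.

The four mean exclusion chances cover the casework configurations X markers
are used for. Krüger's variant addresses trio-style cases where the tested
relative is an untyped diploid woman (classically the paternal grandmother
standing in for a deceased alleged father):
$\sum_i p_i (1-p_i)^2 - \sum_{i<j} (p_i p_j)^2 (4 - 3 (p_i + p_j))$.
Desmarais' trio variant for mother/daughter/alleged-father cases equals
PIC, and the duo variant (father–daughter or mother–son, no second parent)
is $1 - 2 s_2 + s_3$. Each closed form is guarded in the test suite by an
independent enumeration oracle that walks every configuration of maternal
genotype, true paternal allele, maternal segregation and random tested
genotype — the closed forms must agree with brute force to $10^{-10}$ on a
grid of frequency vectors.

The Kishida trio variant required a decision. Its original closed form is
not reproducible from the sources available to this package, and published
tables show it deviating from PIC by at most a few $10^{-4}$ in both
directions. Deriving the exclusion probability from first principles shows
the exact mother/daughter/alleged-father X-marker exclusion chance *is*
$1 - s_2 - s_2^2 + s_4$, i.e. PIC, once the ambiguity of the obligate
paternal allele is handled in full. `mec_trio_x(p, "kishida")` therefore
computes that exact exclusion chance by configuration enumeration — a code
path independent of the `pic()` polynomial — and is documented as agreeing
with published Kishida values to within a few units in the fourth decimal
rather than digit-exactly.

Combined powers $1 - \prod_u (1 - x_u)$ are accumulated in log space.
A combined female discrimination power over 19 informative loci has a
complement around $10^{-22}$, far below double-precision resolution near 1,
so `combined_power()` carries the complement and renders the value as text
with explicit nines (e.g. `0.99999999999710613` for the seven-group male
discrimination power) instead of collapsing to `1`.

```{r combined-example}
G <- reported_gelao_parameters("groups")
combined_power(1 - G$MP)
```

## Exact tests

**Hardy–Weinberg in females.** The test is the exact conditional test for
multi-allelic loci: conditional on the allele counts, a genotype table has
probability proportional to $2^{H} / \prod_{a \le b} n_{ab}!$ ($H$ =
heterozygote count), and the p-value is the total probability of tables no
more probable than the observed one (ties count as extreme). The sampler is
a Markov chain over individual-level allele configurations with
two-individual allele-swap proposals, in the Guo–Thompson tradition. For
this proposal the Metropolis conditional-probability ratio is identically
one — the conditional law is uniform over configurations, and the number of
configurations mapping to a table is exactly proportional to the table's
conditional probability — so every swap is accepted and the chain is a
rapidly mixing random-transposition walk. The implementation is in C++ with
incremental log-probability updates; the default configuration
(`mcmc_config()`: chain $10^6$, burn-in $10^5$) mirrors full survey
practice, and the test suite validates the stationary law against complete
enumeration (biallelic) and an independent i.i.d. allele-shuffling sampler
(multi-allelic).

**Pairwise LD.** In males, hemizygosity makes two-locus haplotypes
observable, so LD testing is the exact conditional test of independence on
the allele-by-allele contingency table, run with the same style of chain
(allele swaps between two males; fixed margins; default chain $10^4$,
burn-in $10^3$) and validated against the Fisher exact test. In females,
phase is latent: the test statistic is the likelihood ratio between
EM-estimated two-locus haplotype frequencies and the independence product
of single-locus allele frequencies. The EM resolves double heterozygotes by
expected phase; convergence is declared when the log-likelihood gains less
than $10^{-7}$ (cap 1000 iterations), and the likelihood is maximized from
`em_initial_conditions` starts (default 2: the independence product plus a
random start). The null distribution permutes one locus's genotype column
across individuals — whole single-locus genotypes move together, preserving
within-locus genotypic structure so that only gametic association is tested
— with 10,000 permutations by default.

**Sex differentiation.** Per locus,
$F_{st} = (H_T - H_S)/H_T$ with $H = 1 - \sum p^2$, $H_S$ the
chromosome-count-weighted mean of the male and female heterozygosities and
$H_T$ from pooled frequencies. The permutation null reassigns chromosomes
(allele observations), not individuals, to the two strata: the male stratum
contributes one chromosome per sample and the female stratum two, so
chromosome-level permutation preserves exactly the stratum sizes the
statistic is conditioned on. Monomorphic loci return $F_{st} = 0$, p = 1.

Monte-Carlo p-values are plain proportions without the +1 correction, so a
permutation p of 0.0000 is representable; the `se` field
($\sqrt{p(1-p)/\text{draws}}$) signals the resolution. The chain s.e. is
nominal — autocorrelation makes it optimistic — which is why the test suite
compares chain estimates to oracles via independent replicate chains rather
than through the nominal s.e. Every test is bit-reproducible given its
configuration seed. Family-wise control across the
$\binom{19}{2} = 171$ locus pairs uses Bonferroni thresholds
(`bonferroni_threshold(0.05, 171)` = 0.0003 at report rounding).

## Population comparison

Nei's (1972) standard distance is used: $D = -\ln I$ with
$I = J_{AB} / \sqrt{J_A J_B}$, where the $J$ quantities are arithmetic
means across loci of $\sum p_A p_B$, $\sum p_A^2$, $\sum p_B^2$ over the
per-locus union allele set (absent alleles are zero-filled, since published
frequency tables omit unobserved alleles). Averaging the $J$s before the
ratio is Nei's original estimator, as implemented in the classic
phylogeny packages, rather than averaging per-locus ratios. By
Cauchy–Schwarz $I \le 1$, so $D \ge 0$; populations sharing no alleles
anywhere get $D = \infty$ with a warning.

PCA operates on the populations-by-features matrix of per-allele
frequencies (union allele set, zero-filled), column-centered, covariance
form; variance shares are eigenvalue shares. MDS is classical/metric
(Torgerson double-centering), the variant appropriate for a small matrix of
genetic distances, with Kruskal's stress-1 reported so users can judge the
embedding; a nonmetric variant was deliberately not implemented. Both use
a deterministic sign convention (largest-magnitude loading or coordinate
positive) so repeated runs and platforms agree. Trees are Neighbor-Joining
(Saitou–Nei agglomeration with the Q-criterion) via `ape::nj`, the standard
implementation, wrapped to validate the distance matrix and to clamp the
negative branch lengths NJ can produce on non-additive inputs (with a
warning; `clamp_negative = FALSE` preserves them). Tie-breaking among equal
Q values follows ape's implementation order. On additive matrices NJ is
exact, which the suite property-tests on random trees of up to eight
leaves.

## The synthetic cohort generator

No raw genotypes are distributable, so `synthetic_spec()` +
`simulate_genotypes()` generate cohorts with the statistical structure the
analyses assume, and `gelao_like_fixture()` fixes the defaults at the
surveyed design: 265 diploid females and 248 hemizygous males (513 samples,
778 X chromosomes per locus), the 19 panel loci at their published allele
richness (5 at DXS7423 up to 26 at DXS10135), microvariant labels at the
loci that carry them, and the seven canonical linkage groups. Within-group
association is induced by drawing whole haplotypes from explicit per-group
haplotype pools (a few dozen to a few hundred distinct haplotypes per
group, Dirichlet-weighted); females receive two independent haplotypes per
group — Hardy–Weinberg at the haplotype level, which is exactly the null
model of the female tests — and males one. Per-locus frequency profiles mix
a Dirichlet draw with a uniform floor so every configured allele remains
observable at N = 778. Departure knobs exist for the tests' power checks:
per-locus inbreeding `F` makes a female's second gamete identical by
descent with probability F, and `simulate_divergent_populations()` draws
population frequency vectors from the Balding–Nichols Dirichlet
(concentration $(1-F_{st})/F_{st}$ around the ancestral vector).

What the generator does **not** emulate: genotyping dropout and stutter,
mutation, family structure, real STR allele-frequency shapes (profiles are
Dirichlet, not empirical), and realistic between-population allele sharing
patterns. Passing tests therefore demonstrate correctness of the
estimators and tests under their stated models, not robustness to typing
artifacts in casework data.

## Numerical and reporting conventions

* Frequency vectors must be positive and sum to 1 within $10^{-9}$;
  frequency-table columns are renormalized only when within 0.01 of 1,
  otherwise rejected.
* Report tables round to 4 decimals, half away from zero
  (`round_half_up()`), matching forensic reporting practice; machine-readable
  JSON keeps full precision.
* All stochastic stages consume explicit seeds; `run_full_study()` derives
  per-stage seeds from one master seed (kept within 32-bit range), making
  the whole bundle byte-reproducible.
* The analysis scripts under `analysis/` run the pipeline at reduced
  problem sizes chosen for an interactive workflow — HWE chains of
  $5 \times 10^4$, 200 LD permutations, 1000 Fst permutations,
  within-group LD pairs — while the package defaults carry the full survey
  settings; the statistics are identical, only Monte-Carlo resolution
  differs.
* Degenerate inputs are contracts, not crashes: monomorphic loci give
  degenerate test results (p = 1, tagged), empty strata are flagged absent,
  and fewer than three populations skip ordination with a warning while
  still returning distances.

## Limitations

Paternity-index and generic exclusion-power calculators for likelihood
casework are out of scope, as are mid-p exact-test variants and nonmetric
MDS. The female LD test reports all 171 pairs and leaves multiple-testing
interpretation to the user beyond the Bonferroni flags. Haplotype
frequencies for females are not inferred for reporting (EM phase estimates
exist only inside the LD statistic), keeping published-table semantics:
haplotype tables are male direct counts.
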
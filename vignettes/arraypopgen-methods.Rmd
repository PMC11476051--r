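---
title: "Methods and design notes for ArrayPopGen"
author: "ArrayPopGen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for ArrayPopGen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

ArrayPopGen analyses diploid, biallelic SNP-array genotypes in small
populations — the typical conservation-genetics or breeding-farm setting of
a few dozen animals on a medium-density (≈50K) chip. This vignette explains
the statistics the package computes, the algorithmic choices behind them,
what the synthetic-genotype generator does and does not emulate, and the
known limitations. Everything stated here is exercised by the test suite or
by `scripts/acceptance.R`; no empirical claim is made beyond what those
compute.

## The data model

`GenotypeData` extends `RangedSummarizedExperiment`: the `calls` assay is an
integer matrix of markers × samples holding alt-allele dosages (0 = hom-ref,
1 = het, 2 = hom-alt, `NA` = missing), and `rowRanges` carries marker
positions (1-based, as in `.map`/`.bim`/VCF), derived genetic positions and
ref/alt alleles. BED exports are converted to 0-based half-open
coordinates. When a PLINK map supplies no genetic positions, centimorgans
are derived as `pos_bp / 1e6` (the standard 1 cM ≈ 1 Mb fallback). PLINK
text and binary (SNP-major `.bed`, 2-bit codes) and VCF 4.x round-trip
through the container; PLINK's A1 column maps to the alternate allele by
default (A1 is conventionally the minor allele), and a flag flips the
orientation. Every statistic in the package is invariant to ref/alt
orientation, which the suite checks by property tests.

## Marker quality control

Four criteria, matching common practice for livestock SNP panels: minor
allele frequency ≥ 0.05, Hardy–Weinberg exact-test p ≥ 1e-6, per-marker
call rate ≥ 90%, autosomes 1–26 only, plus removal of indel records. The
HWE test is the standard biallelic exact test: conditional on the observed
allele counts, all admissible heterozygote counts are enumerated with a
numerically stable recurrence and the probabilities of configurations no
likelier than the observed one are summed (two-sided). The tests verify it
against an independent closed-form enumeration oracle.

The filters run in a fixed order — chromosome keep-list, indels, call rate,
HWE, MAF — and each removed marker is attributed to the *first* filter that
rejects it. The categories are therefore disjoint and the report always
satisfies `total = retained + sum(removed)`, which makes published QC
tables replayable through the same accounting object (`qcReport()`). The
order itself is a convention (tools differ, and published tables rarely say
whether their categories were counted disjointly); it is declared rather
than inferred. MAF and HWE use non-missing calls only, so an all-missing
marker falls to the call-rate filter and no statistic divides by zero.

## Diversity statistics

Per locus, over the `n` non-missing individuals with alt frequency `p` and
`q = 1 − p`:

* observed heterozygosity `Ho = H_k / n` (share of heterozygous calls);
* expected heterozygosity with the small-sample correction
  `He = 2n/(2n−1) · (1 − p² − q²)`;
* Botstein's polymorphism information content
  `PIC = 1 − (p² + q²) − 2p²q²`;
* effective allele number `Ae = 1 / (p² + q²)` — the reciprocal of
  expected homozygosity. A population-level wording of this quantity
  ("reciprocal of observed homozygosity") is sometimes used; the
  frequency-based form is the default and `ae_observed = TRUE` selects
  `1/(1 − Ho)` instead;
* `MAF = min(p, q)`; the polymorphic marker ratio `P_N` is the share of
  loci with MAF above a cutoff (default 0.01 — the usual "polymorphic"
  convention; the cutoff is a parameter because definitions vary).

These obey `PIC ≤ 1 − Σp² ≤ He` with equality of zeros exactly at
monomorphic loci, which the suite asserts on random panels. Summary reports
bin PIC into [0, 0.15), [0.15, 0.30), [0.30, 0.45) and MAF into width-0.1
bins on [0, 0.5] (right-open, last bin closed).

Effective population size is estimated from linkage disequilibrium:
`Ne = 1/(4c) · (1/r² − 1)`, with `r²` the squared genotype correlation
between same-chromosome marker pairs and `c` the genetic distance in
Morgans. The point formula leaves the pair-selection recipe open, so the
package follows standard LD-Ne practice and declares every choice: pairs
are binned by cM distance (default bins 0.25–5 cM in 0.25 steps), the mean
`r²` per bin receives the sample-size correction `r² − 1/(2n)` floored at
1e-4, the bin midpoint supplies `c`, and the summary Ne is the mean over
populated bins. All knobs are arguments. Because founder panels are
simulated in linkage equilibrium, the estimator is only meaningful on
populations evolved with `simulateRandomMating()`, where drift has restored
the LD–distance relation; the test suite checks order-of-magnitude recovery
(a factor of two at 0.5–1 cM) for a 50-animal population after 60
generations, reflecting how noisy this estimator is at such sizes.

## Kinship, PCA and families

The genomic relationship matrix follows VanRaden:
`G = Z′Z / (2 Σ p_i(1−p_i))` with `Z` the marker × sample dosage matrix
centered by `2p_i`. Missing dosages are imputed to `2p_i` (zero after
centering), monomorphic markers are dropped with a warning, and the
frequencies default to the sample's own but can be supplied (e.g. founder
or base-population frequencies). That option matters in small structured
samples: centering a dozen half-sib families by their own pooled
frequencies shifts the whole off-diagonal baseline downward, so
pedigree-scale expectations (0.5 for parent–offspring and full sibs, 0.25
for half sibs) hold only against base-population frequencies.

The identity-by-state distance counts, per pair over co-typed loci, the
loci sharing both alleles (IBS2), exactly one (IBS1) or none, and sets
`D = 1 − (0.5·IBS1 + IBS2)/N`. PCA is the eigendecomposition of G with
scores scaled by the square root of the (floored-at-zero) eigenvalues and
explained fractions `λ_i / Σ max(λ_j, 0)`; each eigenvector is oriented so
its largest-magnitude entry is positive, making results deterministic
across linear-algebra backends.

Families are delineated by the field's "relatedness ≥ 0.1" convention: a
graph with an edge wherever `G_ij ≥ 0.1`, whose connected components are
the families. The threshold sits well between half-sib relatedness (≈0.25)
and the between-family noise floor (a few hundredths at chip marker
counts), which is why the partition recovers simulated sire lines exactly.
A complete-linkage variant (every within-family pair must meet the
threshold) is provided for users who prefer a stricter criterion, and a
neighbour-joining tree of the IBS distances (classical Saitou–Nei, via
`ape`) supplies the family numbering order and a visualisable topology. On
additive distances NJ reproduces the generating tree exactly, which the
suite verifies on random 8-taxon trees.

## Runs of homozygosity and F_ROH

The caller follows the PLINK-style scanning-window design with six
criteria (defaults: 50-SNP window; per-window allowance of 1 heterozygous
and 2 missing calls; ≥ 100 SNPs, ≥ 1 Mb and ≤ 50 kb/SNP per run; runs
split at inter-marker gaps > 100 kb):

1. a window of `window_snps` markers slides one marker at a time and
   *qualifies* if it holds at most `max_het_in_run` heterozygous and
   `max_missing_in_run` missing calls;
2. a marker is *eligible* if the fraction of windows overlapping it that
   qualify exceeds `window_threshold` (strict `>`, default 0.05);
3. maximal runs of eligible markers are split at large gaps and trimmed so
   they begin and end on a homozygous, non-missing marker;
4. surviving runs are filtered by SNP count, length and density.

Two behaviours deserve explanation. First, the trimming in step 3: window
qualification deliberately tolerates one heterozygous call, so eligibility
extends one to a few markers into heterozygous flanking sequence; a run of
homozygosity by definition opens and closes with a homozygous call, so the
endpoints are pulled back. Second, the heterozygote/missing allowance is
enforced at window level, and per-segment `n_het`/`n_missing` are always
reported. An optional strict mode (`final_caps = TRUE`) additionally
rejects any segment whose total het or missing count exceeds the
allowance. It is off by default because flank bleed means long genuine
runs routinely carry one or two flanking heterozygous calls, and a
whole-segment cap then rejects 20–40% of multi-megabase autozygous tracts
outright, biasing both run recovery and F_ROH downward — the window-level
reading is also how the scanning-window tools this design descends from
behave. Both modes are tested against a brute-force oracle that applies
the rules literally.

`F_ROH` is the summed run length divided by the total autosome length
(by default the observed chromosome spans; a length table can override),
per individual, with the population value the mean. Summaries bin run
lengths into 1–5, 5–10, 10–15, 15–20 and > 20 Mb classes (right-open)
with percentages to two decimals, and report per-chromosome counts and
union coverage.

A density caveat worth knowing: with a 100-SNP minimum, a map must stay
below ~40 kb/SNP for megabase-scale runs to be callable at all (100 SNPs ×
40 kb = 4 Mb), and QC removals can merge neighbouring gaps past the 100 kb
split limit. On a faithful ≈50K-chip emulation the six criteria therefore
recover only about half of a planted F = 0.01, not because the caller is
wrong but because the criteria are near-inconsistent at that density.
Parameter-recovery checks (and the acceptance script's F_ROH section) use
a 25 kb map, where the criteria are mutually satisfiable; the window and
allowance parameters are unchanged.

## Selection scans

**ROH islands.** Per-marker incidence is the fraction of individuals whose
runs cover the marker. The threshold is the `1 − top_fraction` empirical
quantile taken as an order statistic (rank `⌈(1−f)·M⌉` of the sorted
incidences — a deterministic, tie-stable choice), markers strictly above
it are selected, and maximal stretches of consecutive selected markers on
a chromosome merge into islands spanning their first to last marker.

**Windowed π.** Per site, the unbiased pairwise-difference estimator
`2·c_ref·c_alt / (c(c−1))` with `c` the non-missing allele count — phase
is irrelevant since only allele counts enter. Window values are the summed
per-site π over the variants in a 100 kb window (10 kb step) divided by
the window span; windows tile from position 1 and the final partial window
is kept, length-normalised. Equality with a brute-force count over all
haplotype pairs is asserted to 1e-12.

**Windowed Tajima's D.** Per window, `S` segregating sites and the summed
per-site pairwise-difference fraction feed
`D = (θ̂_π − S/a₁) / √(e₁S + e₂S(S−1))` with the 1989 constants computed
from the haplotype count. Unphased diploids contribute `c = 2 ×`
non-missing individuals per site; the per-window count is the modal `c`,
and windows where it varies (missingness) are flagged. `D` is `NA` when
`S = 0`, fewer than four haplotypes are present, or the variance term is
non-positive. The implementation is checked constant-by-constant against a
literal oracle, and its calibration on 10,000 neutral-spectrum windows
(mean D within a few thousandths of zero) is part of the acceptance
checks.

**Region selection and annotation.** The classic sweep signatures are low
π and negative D, so candidate windows are those strictly below the lower
`quantile` (default 0.01) of the non-missing window values; with all
values equal nothing is selected. Overlapping or book-ended selected
windows (gap ≤ step) merge into regions. Genes from a user-supplied BED or
GFF3 annotation hit a region on ≥ 1 bp overlap (half-open BED input is
converted on import, so an abutting gene does not hit), and per-method gene
sets are intersected with full Venn counts. The package deliberately stops
at gene lists: enrichment services are external.

## The synthetic-genotype generator

The generator exists so that every stage is testable against known truth,
and its defaults describe the study design the package targets: ~50 rams
in 12 paternal half-sib sire lines (2–6 offspring each), 26 autosomes of
100 Mb, jittered ~50 kb marker spacing, low inbreeding (planted
autozygosity around F = 0.01), and a MAF spectrum that is uniform on
[0.01, 0.5] by default, with a `"beadchip"` preset reproducing the binned
spectrum reported for medium-density ovine arrays (21.45% of markers below
MAF 0.1, 17.34% in 0.1–0.2, the remainder spread evenly). Founders are
drawn haplotype-wise from the spectrum (HWE holds in expectation);
families arise by Mendelian gamete sampling with Poisson recombination at
1 cM/Mb; autozygous tracts are planted by collapsing heterozygous calls
onto one allele, with an optional heterozygous-error rate inside tracts
and exact bookkeeping of the planted fraction. A contamination mode
injects sex-chromosome, sub-threshold-MAF, HWE-violating, high-missingness
and indel markers in raw-chip proportions so the QC accounting has every
category to count.

Two purpose-built generators support calibration: `simulateRandomMating()`
evolves a closed population to drift equilibrium (for LD-based Ne), and
`simulateNeutralWindows()` draws sites with derived-allele counts
proportional to 1/i — the neutral infinite-sites sample spectrum — under
which Tajima's D is centred at zero. The latter matters: binomial sampling
from a *uniform* frequency spectrum does **not** give E[D] ≈ 0 (it inflates
π relative to S/a₁ and pushes mean D near +1.5), so neutrality checks must
use the 1/i spectrum.

What the generator does *not* emulate, and hence what passing tests do not
show about real data: founder linkage equilibrium (real chips carry
ascertainment-shaped LD), mutation and selection, X-dosage genotypes,
genotype-calling artefacts beyond uniform missingness and tract-internal
het errors, and real chip spacing irregularities beyond uniform jitter.
Results on real data depend on those features; the tests establish
correctness of the computations and recovery of planted structure, not
field performance.

## Numerical conventions and problem sizes

Strict inequalities are used where a rule says "exceeds" (window hit
fraction, island threshold, region quantile); ties in the NJ Q-matrix are
resolved by lowest index (via `ape`); PCA signs follow the
largest-magnitude-loading rule; quantiles for island thresholds are type-1
order statistics while region selection uses R's default type-7; windows
anchor at position 1 per chromosome. Seeds control every stochastic path:
generator functions seed locally from their configuration, and the
acceptance script derives all of its seeds from `--seed`.

The test and acceptance problem sizes are chosen as the smallest that make
the statistical assertions sharp: oracle equivalence on ≤ 500-marker
chromosomes; F_ROH recovery on 6 individuals × 8 chromosomes × 25 kb maps
over 20 seeds per target; family recovery on 12 sire lines at ~8k markers;
G-matrix normalisation on 500 unrelated individuals; Tajima calibration on
10,000 windows. The full suite runs in a few minutes on one CPU.

## Known limitations

* The six ROH criteria interact with marker density as described above;
  at ≥ 50 kb/SNP the printed defaults cannot call runs much below ~5 Mb.
* LD-based Ne at n ≈ 50 is order-of-magnitude information only; the
  binning/correction recipe is a convention and alternative choices shift
  the point estimate severalfold.
* The family rule (components of the thresholded G graph) is a declared
  formalisation of an informal field practice; complete linkage is offered
  because connected components can chain distantly related individuals
  through intermediates.
* Region counts from the π and D scans depend directly on the selection
  quantile, which published analyses rarely state; counts are therefore
  not comparable across studies without fixing that choice.
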
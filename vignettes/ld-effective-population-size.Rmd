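---
title: "Linkage disequilibrium decay and effective population size: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linkage disequilibrium decay and effective population size: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ldpopsize)
```

`ldpopsize` implements a complete population-genetic workflow for dense
diploid SNP genotypes: per-population quality control, pairwise
within-chromosome linkage disequilibrium (LD), binned LD-decay curves,
historical and contemporary effective population size (Ne), relatedness,
and PCA of population structure — together with a forward Wright–Fisher
simulator that generates panels with known truth, so every stage of the
pipeline can be validated at desk scale. This vignette describes the
models, the tunable parameters and their defaults, the numerical
choices, and what the simulation-based tests do and do not demonstrate
about real data.

## Quality control

Genotypes are dosage-coded (0/1/2 copies of the non-reference allele,
`NA` for missing). QC runs per population in a fixed, reported order:

1. individuals with more than `max_sample_missing` (default 5%) missing
   genotypes are removed;
2. SNPs with call rate below `min_snp_call_rate` (default 95%) are
   removed;
3. SNPs with an exact Hardy–Weinberg test p-value below `hwe_alpha`
   (default 1e-6) are removed;
4. SNPs with minor allele frequency (MAF) below `min_maf` (default 5%)
   are removed.

Every excluded SNP is attributed to the *first* criterion that removed
it, so the report's per-criterion counts are mutually exclusive and
reconcile exactly (`in − call_rate − hwe − maf = final`). All
thresholds are strict inequalities: a SNP with MAF exactly 0.05 is
kept. The filter order is a convention — tools differ slightly here —
and the report records it so cross-tool comparisons are explicit.

The HWE test is the conditional exact test: given the observed allele
counts, the probability of every heterozygote count consistent with
them is computed by a numerically stable recurrence, and the two-sided
p-value sums the probabilities no larger than the observed
configuration's (the standard tail, not mid-p). The suite checks it
against full enumeration for every genotype configuration up to 50
individuals.

## Pairwise LD

Two r² estimators are provided, because genotype data support both and
published pipelines are rarely explicit about which their tool used:

* **genotypic** (default): the squared Pearson correlation of dosage
  vectors over pairwise-complete individuals — the composite measure
  most LD software reports by default;
* **em**: the haplotype-based measure r² = D²/(p_A p_a p_B p_b), with
  the four haplotype frequencies estimated from unphased genotypes by
  EM. Only the double-heterozygote cell is phase-ambiguous; its split
  is re-estimated each iteration (tolerance 1e-10, at most 1000
  iterations). With no double heterozygotes the EM answer equals the
  direct haplotype-count answer exactly.

The two differ only slightly under Hardy–Weinberg proportions; reports
name the estimator used. Pairs are enumerated within chromosomes up to
a maximum distance (default 10 Mb), in deterministic (chromosome,
position) order; pairs with undefined r² (a locus monomorphic among the
pairwise-complete individuals) are dropped with a logged count.
`n_used` is stored per pair because the sample-size adjustment for Ne
needs it.

Decay curves average r² in contiguous distance bins (default 100 kb
wide from 0 to 10 Mb). The distance at which the curve crosses a
threshold (default r² = 0.2, the usual usefulness bound for
association mapping) is linearly interpolated between the mean
distances of the two bracketing bins; a curve that starts below the
threshold or never crosses returns an explicit no-crossing `NA` rather
than an error. Fixed-distance summaries (0.1/0.5/1/5/10 Mb) read the
bin containing each distance.

## Historical Ne from binned LD

At drift–recombination equilibrium, expected LD at recombination
distance c satisfies approximately

  E[r²_adj] = 1 / (4 N f(c) + α),

so each distance bin inverts to an effective size

  N_t = (1 / (4 f(c))) (1 / E[r²_adj | c] − α),  t = 1 / (2 c),

interpreted as the effective size about t generations ago. Defaults
follow the common SNP-array workflow: α = 2 (mutation assumed to
occur; α = 1 is the pure-drift variant), pairs collected to 5 Mb, 30
contiguous 50-kb bins starting at 0 (collected pairs beyond the binned
range are ignored with their count logged — the bin geometry and the
collection limit are deliberately independent knobs), physical distance
mapped at 1 cM/Mb, identity mapping function (Haldane and a hyperbolic
Sved–Feldman map, c = d/(1+2d), are available for compatibility with
other tools), and the r² − 1/n sample-size adjustment appropriate for
genotypic r² (r² − 1/(2n) offered for haplotype-based r²; adjusted
values below zero are floored and flagged). Bins whose mean adjusted r²
is at or above 1/α cannot yield a positive Ne under the model; they are
flagged, never silently dropped. Per-chromosome summaries use the
harmonic mean over that chromosome's valid bins — effective sizes
combine harmonically — and report the realized range of t, since which
generations are observable depends on each chromosome's marker
spacing.

The inversion is tested two ways: manufactured bins with
E[r²_adj] = 1/(4 f(c) N + α) recover N to machine precision, and
simulated panels with known constant Ne recover it within tolerance
(below).

## Contemporary Ne by the LD method

The single-point estimate screens out markers with within-sample MAF
below `pcrit` (default 0.05; a per-analysis screen, not a panel
mutation), averages genotypic r² over all remaining marker pairs —
including cross-chromosome pairs, unlike the decay analysis —
subtracts the expected sample-induced component at the harmonic-mean
pairwise sample size S (missing genotypes by pairwise deletion), and
inverts the drift expectation E[r²_drift] = b1/Ne + b2/Ne² under the
chosen mating model. The empirical constants (Waples 2006 convention;
S ≥ 30 and S < 30 branches, random-mating and monogamy models) are
centralised in one exported table, `ldne_constants`, so any dialect
difference from other implementations is auditable in one place. The
default model is monogamy (non-random mating). A corrected r² at or
below zero — all observed LD explained by sampling — returns an
infinite estimate, which is the standard way this method reports "no
drift signal detectable at this sample size".

Relatedness uses the method-of-moments IBD-sharing estimate in the
PI_HAT convention (P(IBD=2) + P(IBD=1)/2), computed from observed
identity-by-state counts and their expectations under sample allele
frequencies, clamped to the probability simplex. No finite-sample
correction factors are applied; the simulation tests (unrelated
individuals < 0.05; full sibs ≈ 0.5) bound the resulting bias at the
panel sizes the package targets. Estimates from fewer than 100
informative markers trigger a warning.

## PCA

Genotypes are variance-standardized per marker, (g − 2p)/√(2p(1−p)),
missing dosages mean-imputed to zero after centering, monomorphic
markers dropped with a warning. The samples × samples covariance
(scaled by 1/#markers) is eigendecomposed; "variance explained" is
each eigenvalue over the sum of *all* eigenvalues, so the percentages
do not depend on how many components are retained. Signs follow a
deterministic convention (largest-magnitude coordinate positive).
Joint analyses of several populations first intersect their marker
sets — marker identity is (chromosome, position, unordered allele
pair), and strand flips are deliberately not auto-resolved, because
silent strand repair is a worse failure mode than a smaller
intersection when all panels come from one genotyping platform.

## The Wright–Fisher generator

`simulate_wf()` is a forward-in-time diploid simulator: discrete
non-overlapping generations, each offspring drawing two parents
(random mating by default; monogamous couples optionally, which
creates the full-sib structure the relatedness tests need), gametes
formed with Poisson(map length) crossovers at uniform positions (no
interference, matching the Haldane mapping), and recurrent symmetric
per-site mutation. Forward simulation was chosen over the coalescent
so that monogamy, pedigrees, and arbitrary Ne(t) change points are
exact by construction.

Two calibration choices matter and deserve their rationale:

* **Mutation is on, and small** (`mutation_theta` = 4·Ne·μ per site,
  default 0.02). The α = 2 inversion formula assumes polymorphism is
  maintained by mutation while homoplasy is negligible. A pure-drift
  simulation from standing variation realizes the α = 1 world instead
  (founding variants predate the genealogy and tag deep bipartitions,
  so tight-linkage r² is far above the α = 2 curve), while a large θ
  (say 0.2) recycles alleles so fast that r² settles well below it.
  θ = 0.02 puts the generator in the mutation-limited regime the
  formula describes. Founding frequencies are drawn from the matching
  stationary Beta(θ, θ) distribution truncated to segregating values.
* **Burn-in is 8·Ne generations** (configurable). Founding standing
  variation carries complete-LD-like associations; its heterozygosity
  decays like (1 − 1/2Ne)^t, so at 4·Ne about 13% of it remains and
  measurably inflates short-range r². At 8·Ne the segregating
  variation is essentially mutation-derived and binned r² sits on the
  equilibrium curve.

Markers are ascertained by sample MAF (default ≥ 0.05, emulating
array ascertainment; `ascertain_snps()` exposes ascertainment in a
designated reference population so the classic bias — markers chosen
in one lineage having depressed MAF in a diverged lineage — can be
reproduced). The split scenario is a caterpillar topology: daughters
branch off an ancestral stem at strictly decreasing split times and
evolve independently at their own Ne; all panels are genotyped on one
common marker set ascertained from the pooled daughters, emulating a
shared array's common-SNP intersection. The returned truth object
(realized Ne schedule, true allele frequencies, phased haplotypes of
the sampled individuals, final two generations of pedigree, seed) is
sufficient to score every recovery test without re-simulation. All
randomness flows from the single config seed; the caller's RNG state
is restored.

The inner generation loop is compiled (Rcpp) with all draws taken from
R's RNG, so results are reproducible from `set.seed()` alone and a
single simulated population of a few thousand sites runs in seconds.

## What the tests demonstrate — and problem sizes

The simulator–theory bridge is the load-bearing check: at constant
Ne = 100 with n = 100 sampled diploids, pooled binned r² must match
1/(4Nc + 2) + 1/n within 25% in every 100-kb bin across
c ∈ [0.0005, 0.01]. The suite pools 16 replicates of two 10-Mb
chromosomes (~190 ascertained markers each), a size chosen so the full
suite runs in minutes; the agreement is limited by the Sved/Corbin
approximation itself and by MAF conditioning (both loci ascertained at
MAF ≥ 0.05 skews pairs toward older, more correlated variants at low
ρ and younger ones elsewhere), not by Monte-Carlo noise.

Recent-Ne recovery uses 20 replicates of four 12.5-Mb chromosomes
(~1200 target markers, n = 50): the harmonic mean of all well-posed
trajectory points with t ≤ 50 (pairs to the 5-Mb collection limit,
100-kb bins) must land within ±30% of truth in at least 80% of
replicates. Restricting to the default 30 × 50-kb binned range
concentrates the estimate at ρ ≈ 4–6, where the Sved approximation is
weakest, and biases recovery upward by ~30%; using the full collected
range is both closer to the formula's intent and markedly better
calibrated.

What passing these tests does *not* show: the generator has no
selection, migration after splits, variable recombination, genotyping
error, or array-specific cluster artefacts, and its ascertainment is a
sharp MAF threshold rather than a discovery-panel model. Agreement on
synthetic panels therefore validates the estimators' internal
consistency, not the biological accuracy of any particular real-data
estimate; on real arrays, ascertainment bias and pedigree structure
remain the dominant caveats, exactly as in published applications of
these methods.

## A typical run

```{r example}
cfg <- sim_config(ne_trajectory = list(c(0, 80)), n_chromosomes = 2,
                  chromosome_length_bp = 8e6, n_segregating_target = 500,
                  sample_size = 40, seed = 1)
sp <- simulate_split(cfg, split_times = c(70, 25),
                     pop_ne = c(50, 80, 80),
                     pop_names = c("NAM", "SCO", "NOR"))
res <- run_pipeline(sp$panels, "results/demo")
res$threshold_distance     # bp at which each population's curve hits 0.2
glance(res$pca)            # variance explained by PC1 + PC2
autoplot(res$decay$NAM)    # LD decay curve
```

The pipeline writes the full report bundle (QC report, MAF spectrum,
decay curves, fixed-distance r², adjacent-marker LD, Ne trajectory and
per-chromosome harmonic means, contemporary Ne, relatedness, PCA
coordinates and eigenvalues) as fixed-format TSV/JSON plus a manifest
recording inputs, settings, seed and per-stage counts; reruns with the
same inputs are byte-identical.
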
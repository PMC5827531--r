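---
title: "Population-genomic methods in herdgen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-genomic methods in herdgen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

herdgen implements the analyses used in conservation-genomics studies of
small livestock populations genotyped on medium-density SNP arrays
(50K-class chips): quality control with exact Hardy-Weinberg testing,
relationship screening by genomic non-exclusion, runs of homozygosity
(ROH) and the genomic inbreeding coefficient F_ROH, historical effective
population size (N_e) from linkage disequilibrium (LD), and a composite
selection-signal (CSS) genome scan. A Wright-Fisher forward simulator
generates data with known truth so that every stage is testable end to
end. This vignette explains the models, the defaults and why they were
chosen, and the numerical decisions that are not obvious from the
function documentation.

## Data model

All stages share one container, `geno_ds`: a sample table, a SNP map
(chromosome, 1-based bp position, optional cM position, two allele
codes) and an integer call matrix counting copies of the `a2` allele (0,
1, 2) with `NA` for missing. Missing is a distinct sentinel; nothing
ever conflates it with the homozygous-0 state. Heterozygosity, MAF, IBS,
ROH, r², F_ST and ΔSAF are all invariant to which allele is labelled
`a2`, and tests assert this invariance explicitly. PLINK text (ped/map)
and binary (bed/bim/fam, SNP-major v1.00) files are read and written
bit-exactly; only autosomes are retained on import (default labels 1-29,
the cattle autosomes, configurable for other species).

## Quality control

Defaults follow standard 50K-array practice: SNPs with more than 10%
missing calls are removed, then SNPs with minor allele frequency at or
below 1% (note the inclusive cutoff: MAF exactly 0.01 is removed), then
SNPs failing an exact Hardy-Weinberg test at P < 1e-4, and finally
samples with call rate below 90%. The order is fixed and logged: SNP
filters see all input samples; the sample filter sees only surviving
SNPs. Two standard variants are used downstream: the ROH/inbreeding SNP
set disables the MAF filter (rare alleles are informative for
homozygosity, and a MAF filter would bias F_ROH), and the N_e SNP set
tightens it to 0.05 (low-MAF SNPs carry almost no r² signal but add
noise).

The HWE test is the exact conditional test: given the allele counts, the
heterozygote count follows the Levene-Haldane distribution, and the
two-sided P-value sums the probabilities of all heterozygote counts no
more probable than the observed one. It is evaluated within each
population separately — pooling populations would create spurious
heterozygote deficits (the Wahlund effect) and remove differentiated
SNPs rather than genotyping failures. A SNP is dropped if it fails in
any population present.

## Kinship screening

Parent-offspring pairs are detected by genomic non-exclusion: a true
parent and offspring share one allele at every locus, so they can never
be opposite homozygotes (0 vs 2). The opposite-homozygote rate over
mutually non-missing SNPs is essentially zero for parent-offspring pairs
and of order 2·E[p²q²] ≈ 0.05-0.1 for unrelated individuals (and no
lower than roughly half that for any other close relationship), so the
two classes are separated by orders of magnitude on array-scale SNP
sets. The default allowance of 0.005 tolerates low-level genotyping
error; it is configurable because the appropriate value scales with the
error rate of the platform. One member of each flagged pair is then
removed: chains are resolved greedily by repeatedly removing the
highest-degree sample (seeded uniform choice among ties), which removes
the shared animal of an A-B, B-C chain rather than two animals.

The IBS matrix uses mean per-SNP sharing `1 − |g_i − g_j|/2` over
mutually non-missing SNPs; duplicate samples score exactly 1, which is
also the standard check for blinded duplicates.

## Runs of homozygosity and F_ROH

ROH are called with the sliding-window scan used for 50K-density cattle
data: a 50-SNP window advances one SNP at a time, a window is compliant
if it has at most one heterozygous and at most two missing calls, and a
SNP joins a candidate run when at least 5% of the windows spanning it
are compliant (the conventional inclusion threshold for this scan; the
defining criteria of the window scan are standard but the inclusion
threshold is rarely stated, so it is exposed as a parameter). Candidate
runs are split at inter-SNP gaps above 1000 kb, and a run qualifies if
it is at least 500 kb long with at least one SNP per 120 kb. Reported
boundaries are the outermost SNPs of the qualifying run — unambiguous
and directly checkable by a brute-force oracle, which the test suite
runs against randomized datasets. Because the het/missing rules apply to
windows, a run may contain isolated heterozygous calls; this is a
property of the window approach, not a bug, and it is what makes the
scan robust to genotyping error inside long autozygous tracts.

F_ROH is the summed ROH length divided by L_AUTO, the SNP-covered
autosomal length, computed from the data itself as the sum over
chromosomes of (last SNP bp − first SNP bp + 1) rather than from an
external genome size — so F_ROH is self-consistent for any SNP panel.
Chromosomes with fewer SNPs than the window size are scanned with a
single truncated window and a warning. ROH shorter than ~1 Mb at 50K
density are unreliable (density rule + 500 kb rule leave little room),
and simulated recovery is excellent for tracts of 2 Mb and above: the
suite plants autozygous tracts of known total fraction q and recovers
F_ROH within ±0.02, with a small positive bias (~0.003-0.01) because
homozygous-by-chance SNPs adjacent to a planted tract extend calls by a
few SNPs on average. Distributional comparisons of F_ROH between
populations use the Wilcoxon rank-sum test (exact when the smaller
group has at most 12 animals and there are no ties, otherwise the
tie-corrected normal approximation) with Bonferroni correction over all
pairwise comparisons.

## Effective population size from LD

The estimator reads historical N_e off the decay of LD with
recombination distance:

N_T = (4 f(c_t))⁻¹ (E[r²_adj | c_t]⁻¹ − α),  at t = (2 f(c_t))⁻¹
generations ago,

with mutation correction α = 1 (the recommended default). r² is the
squared Pearson correlation of 0/1/2 genotype dosages over mutually
non-missing samples — the unphased measure, appropriate for array data
without phasing — and r²_adj = r² − 1/n subtracts the finite-sample
expectation (the genotype-based Weir-Hill form, with n the samples used
for that pair), floored at 0. Physical distance is mapped to
recombination rate linearly at 1 cM/Mb, the standard genome-wide
average for cattle; the map rate is a parameter because everything
scales with it (doubling it halves every t — asserted exactly in the
tests). Pairs are binned in 30 log-spaced physical-distance bins from
50 kb to 4 Mb, spanning roughly t = 12 to 1000 generations; bins with
fewer than 50 pairs, or with non-positive mean adjusted r², are dropped
with warnings rather than producing unstable or negative N_T.

Two cautions, verified in simulation. First, the −1/n adjustment plus
the floor at 0 biases mean r²_adj upward when true r² is small compared
with 1/n, which biases recent N_T downward for small sample sizes; with
20 animals the bias is visible for N_e ≳ 200, with 60 animals (a
typical breed panel, and the scale of the sample sizes this package
targets) recovery of N ∈ {50, 100, 200} is within a few percent to
~10%. Second, the most recent bins (largest distances) carry the
recent-N_e information, so short chromosomes that never reach 4 Mb
truncate the recent end of the trajectory.

## Composite selection scan

The scan contrasts a test population against a reference pool drawn
reproducibly as a fixed number of animals per reference population
(mirroring the many-breed pooled-reference design, which damps
single-population drift). Three constituent statistics are computed per
SNP:

- **F_ST**: the two-population Weir-Cockerham θ from genotype counts
  (variance components a, b, c; SNPs monomorphic in the pooled sample
  get θ = 0 with a flag).
- **ΔSAF**: |p_test − p_ref|. The ancestral allele is unknown on an
  array, so the absolute change is used; larger = stronger evidence.
- **XP-EHH**: ln(iHH_test / iHH_ref), where iHH is the trapezoidal
  integral over physical distance of EHH — the probability that two
  random haplotypes are identical-by-state from the core SNP outward.
  Population-level EHH (all haplotypes, not core-allele-stratified) is
  used so every SNP yields a value. Integration stops when EHH falls
  below 0.05, at 2 Mb extension, or at an inter-SNP gap above 200 kb
  (standard truncation rules). Log-ratios are z-normalized genome-wide.
  Phased haplotypes are required: the simulator provides them; real
  unphased data must be phased externally first.

The CSS combines the constituents nonparametrically: fractional ranks
r = rank/(n+1) (average ranks for ties), probit transform z = Φ⁻¹(r),
equal-weight mean z̄ across the k tests, p = upper tail of
Normal(0, 1/√k) at z̄, and CSS = −log10 p. Being rank-based, CSS is
invariant under any strictly monotone transform of a constituent (so
the XP-EHH normalization is cosmetic), and a SNP maximal in all tests is
maximal in CSS. For plotting and localization, CSS is averaged within
non-overlapping 1 Mb windows tiled from position 1.

Significance uses the flanking rule: a region is called only if a SNP
in the genome-wide top 0.1% of CSS scores has at least five SNPs from
the top 1% within ±1 Mb (the flanking distance is not standardized; ±1
Mb matches the smoothing scale and is configurable). One design choice
deserves emphasis: the top-fraction sets are taken from the **raw** CSS
scores by default, not the smoothed ones. Smoothed values are shared by
every SNP in a 1 Mb window, so the top smoothed SNPs are automatically
mutually flanking and the rule would fire on almost any dataset,
including pure noise; on raw scores the rule has the intended
false-positive behaviour (no peaks in 100/100 simulated null scans in
the test suite, versus a planted 7-SNP cluster called exactly once).
Applying the rule to smoothed scores remains available via
`use_smoothed = TRUE`. Threshold cutoffs are inclusive of ties, and
qualifying SNPs whose windows overlap merge into one peak reported with
its ±1 Mb gene-lookup window (gene annotation itself is out of scope).

## The simulator and what passing tests mean

The generator is a discrete-generation diploid Wright-Fisher forward
simulator: standing variation initialized from a uniform(0.05, 0.95)
founder frequency spectrum (no new mutation during the simulated
epoch), random mating with selfing allowed, multinomial resampling at
the per-generation population size, and recombination with Poisson
crossover counts (mean = genetic length) at uniform positions.
Populations either split from a simulated common ancestral phase or
start as independent draws from the same founder frequencies; sizes may
be piecewise constant. Genotype error (symmetric single-allele miscall)
and missingness apply to the unphased view only, so the phased truth
stays clean. Final SNP ascertainment keeps sites with pooled MAF ≥ 0.02,
mimicking array ascertainment. `n_generations = 0` emits the founders
themselves — exactly linkage-equilibrium, outbred individuals, the
cleanest substrate for planted-tract and kinship tests.

Sweeps default to the hard-sweep model: the selected allele starts on a
single haplotype of the test population and is re-introduced whenever
it is lost before establishing — the standard way of conditioning on a
completed sweep without biasing the rest of the genome; if the allele
still has not reached the fixation threshold (0.95) by the end, the
whole run is re-simulated under a different derived seed, up to a retry
cap. A soft-sweep mode (`mode = "standing"`) re-seeds the site as
shared standing variation at a chosen frequency instead; it is kept
because it demonstrates an instructive negative result — selection on a
common standing variant fixes the allele while leaving linked diversity
almost untouched, and the CSS scan (correctly) barely sees it.

Validation problem sizes were chosen to exercise each estimator in its
informative regime: drift checks use N = 100 over 100-200 generations
against closed-form heterozygosity decay (1 − 1/2N per generation) and
the island-split F_ST expectation 1 − exp(−t/2N); N_e recovery uses
single 100 Mb chromosomes with ~2000-5000 ascertained SNPs, 60-sample
panels and constant N ∈ {50, 100, 200}; the sweep benchmark uses a
test population of N = 300 against three reference populations of
N = 250 (pool of 14 animals from each), one 60 Mb chromosome with 2000
SNPs, and 160 generations of divergence — enough for an s = 0.05 hard
sweep to complete.

One artifact of toy-scale genomes deserves a warning: a gamete copies a
whole chromosome without crossover with probability e^(−genetic
length), so on a 1-2 Morgan simulated genome two same-generation
individuals occasionally share a complete gamete and become genomically
parent-offspring-compatible — something a real ~30 Morgan genome never
produces. Demonstrations of the kinship stage therefore emit a
subsample of a larger final generation (`samples_per_pop < N`), which
makes same-parent pairs rare.

The simulator does not model mutation accumulation,
gene conversion, non-uniform recombination maps, or migration after the
split; passing tests therefore demonstrate correctness of the
estimators under drift, recombination and selection, not robustness to
every feature of real bovine data (array ascertainment bias across
breeds, platform-specific error modes, pedigree structure deeper than
the planted cases).

## Numerical and degenerate-input conventions

- HWE: two-sided tie comparison uses a 1e-9 relative tolerance so
  probabilities equal up to floating point are counted in the tail;
  monomorphic counts return P = 1.
- Rank-sum: exact enumeration only for untied samples with the smaller
  group ≤ 12; otherwise midranks with tie-corrected variance and
  continuity correction. All-equal comparisons return P = 1 with a
  warning.
- r²: pairs with an undefined correlation (constant dosage) or fewer
  than 10 usable samples are skipped and counted, never silently zero.
- F_ST: SNPs with fewer than 2 non-missing calls in either group are
  excluded with a reason; θ for pooled-monomorphic SNPs is defined as 0.
- XP-EHH: cores where either side integrates to zero (no usable
  neighbours) are excluded with reason `zero_ihh`.
- Peak calling requires at least 1000 scored SNPs, otherwise the
  top-fraction thresholds are meaningless and an error (or, inside the
  full scan wrapper, a warning and no peak table) results.
- All seeded draws (reference pool, pair-member removal, simulation)
  take explicit integer seeds; the pipeline derives stage seeds from
  one global seed, and re-running a configuration reproduces
  byte-identical output tables.

## Known limitations

Real-data N_e reproduction depends on the binning internals of the
original LD-based tools, which are not fully specified; trajectories
here are faithful to the printed equations but bin placement can shift
recent-N_e values by a few percent. The XP-EHH implementation assumes
phased input and uses population-level EHH; allele-stratified EHH on
externally phased data would be needed to match selscan-style output
exactly. F_ROH comparisons assume the same SNP panel underlies every
animal compared — comparing F_ROH across different panels or QC
settings is not meaningful.
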
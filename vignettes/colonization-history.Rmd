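---
title: "Reconstructing postglacial colonization from ddRAD SNPs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing postglacial colonization from ddRAD SNPs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`postglacial` implements a complete population-genomic workflow for
reconstructing how isolated freshwater fish populations -- the motivating
system is the European whitefish, *Coregonus lavaretus*, in its few native
British lakes -- were founded from glacial refugia: SNP filtering, diversity
and differentiation statistics, genome-wide F~ST~ scans, coalescent
demographic inference on the multidimensional site frequency spectrum
(MSFS), and mitochondrial median-joining networks. This vignette documents
the models, the numerical choices, and what the synthetic data generator
does and does not emulate.

## The demographic model

A `demographic_model` is a set of demes with diploid effective sizes
$N_e$ and a backward-time event list: **splits** (a daughter deme merges
into its parent at time $t$, in generations), **pulse admixture** (looking
forward, a fraction $\alpha$ of a recipient deme's ancestry is replaced by
donor lineages at $t$; backward, each recipient lineage moves to the donor
with probability $\alpha$), and **size changes**. Within a deme, $k$
lineages coalesce at rate $k(k-1)/2$ per $2N_e$ generations. Mutations
follow the infinite-sites model on unlinked, non-recombining loci of
`locus_length` bp (default 142 bp, the informative span implied by a
150--300 bp size selection): a branch of length $T$ receives
Poisson($\mu L T$) mutations. Defaults are $\mu = 10^{-8}$ per bp per
generation and a generation time of 3.5 years; both are conventional
salmonid values, and every inferred time scales as $1/\mu$.

Pulses rather than continuous migration: the fitted histories annotate
discrete admixture events with times and proportions, so gene flow is
modeled as instantaneous pulses. Continuous-rate migration epochs are out
of scope.

The engine (C++, `simulate_sites()`) tracks each lineage's descendant-leaf
set as a bitmask, so a mutation's joint allele count across demes is a
popcount; per-locus RNG substreams are derived from `(seed, locus index)`
with splitmix64, making locus $i$ reproducible independently of how many
loci are requested.

### The six-deme backbone and its calibration

`six_pop_model()` encodes the point-estimate colonization history of six
populations: Norwegian (NOR), Baltic (BAL), Alpine (ALP), Scottish (LOM),
Welsh (LTE) and English (RTA). Backward in time: RTA joins LTE at 3,887
generations, LTE joins ALP at 5,965, LOM joins the ALP trunk at 18,674,
BAL at 23,205 and NOR at 26,247; BAL receives pulses of 0.46 from NOR
(6,663 g) and 0.15 from LOM (4,433 g), and LTE receives 0.15 from LOM at
3,473 g. At 3.5 years per generation these are the familiar ~14, ~21, ~65,
~81 and ~92 Kya ages bracketing the last glacial cycle.

Divergence times and pulse proportions are published point estimates;
**effective sizes are not** (they are not identifiable from published
summaries). The package's defaults (NOR 12,000; BAL 25,000; ALP 12,000;
LOM 6,000; LTE 12,000; RTA 10,000; trunk 25,000) were fixed once by
moment-matching coalescent expectations to the observed scale of the
published summaries: pairwise coalescence-time algebra over the event tree
puts Hudson-style F~ST~ between the Scottish and English demes near 0.57
(the observed value) and reproduces the observed ordering of
within-population diversity (Scottish lowest, Baltic highest). They are
documented as package defaults, not inferred quantities, and the
`study_template()` truth record always carries the values actually used.
The five satellite demes of the full template (second Scottish loch ECK,
English lakes HAW/UWA/BWA, Siberian-lineage RUS) use attachment times and
sizes chosen the same way against within-region differentiation
(ECK--LOM ≈ 0.23; within-England ≤ 0.2) and are entirely synthetic.

## The composite likelihood on the MSFS

The observed MSFS is folded to the globally minor allele (ties at exactly
half frequency keep the lexicographically smaller index vector) and its
monomorphic cell is set to `total_sites - segregating`
(`correct_monomorphic()`), which anchors the absolute time/size scale
given $\mu$. Under a candidate model, cell probabilities are estimated by
simulating `n_sims` loci at the observed sample sizes, and
$CL = \sum_e m_e \log \hat p_e + m_0 \log \hat p_0$ treats sites as
independent.

Two numerical choices matter here:

* **Coarsening.** A joint spectrum over six demes has vastly more cells
  than any feasible simulation can populate; flooring never-simulated
  cells at a constant biases $CL$ *monotonically* toward parameter values
  that generate more polymorphism (more observed cells escape the floor).
  `composite_log_likelihood()` therefore tracks the `track_cells = 1000`
  most frequent observed cells individually (ties broken by cell index, so
  the partition is stable under rescaling) and pools all remaining
  polymorphic cells into one residual cell whose probability is the
  unassigned simulated polymorphic mass. With `track_cells = Inf` the
  plain floored estimator is recovered; the floor
  `p_min = 1/(10 n_\mathrm{sims} L)` then only guards tracked cells the
  simulation missed.
* **Common random numbers.** Within an optimization run or profile, every
  likelihood evaluation reuses the same simulation seed, so differences
  between parameter values are not swamped by independent Monte-Carlo
  noise.

`fit_model()` maximizes $CL$ from `n_starts` log-uniform random starts by
cyclic coordinate-wise golden-section search (`n_cycles` sweeps); the
published protocol's settings (100 starts, 40 cycles, 100,000 simulations)
map directly onto `(n_starts, n_cycles, n_sims)`, though the optimizer
itself is a deliberate simplification of the ECM scheme used by
`fastsimcoal2`, whose internals are not part of this package's scope.
`compare_models()` ranks fits by maximum $CL$ and reports
$AIC = 2k - 2CL$; `hierarchical_build()` grows a model one deme at a time,
refitting every candidate attachment with all parameters free.
`parametric_bootstrap()` simulates replicate spectra of the observed size
under the point estimates, refits each from jittered restarts, and takes
2.5/97.5 percentiles (95% intervals; the level is a package choice).

### Profiles on marginal spectra

For single-parameter profiles (`profile_composite_likelihood()`) the
package evaluates $CL$ on the **marginal spectrum of the demes the
parameter directly affects** (e.g. the Norwegian--Alpine pair for the
oldest split, the Welsh--English pair for the youngest): marginal cells
are dense, so Monte-Carlo noise per cell is far smaller, while the profile
remains centred on the generating value because all other parameters are
held fixed. Profiles additionally average over a few independent
simulation seeds and read the estimate off a local quadratic fitted to
the contiguous top-ranked grid points around the argmax -- the contiguity
rule keeps cliffs (e.g. where a split time crosses a fixed pulse time and
the event order changes) out of the fit. At the package's default effort
(20,000-locus observations, 20,000 simulated loci per evaluation, 3
seeds) the four headline parameters are recovered within the published
confidence intervals in repeated runs; single-evaluation argmax profiles
on the full joint spectrum are *not* reliable at desk scale, which is why
these defaults exist.

## Filtering, diversity and scans

The filter cascade (`apply_filters()`) applies, in fixed order: locus
presence in at least `min_pops` populations; per-population completeness
(`min_prop_per_pop`, the `-p`/`-r` pair of RAD practice, with `min_pops`
capped at the number of populations present); observed heterozygosity
$\le$ 0.6 (paralog collapse signal); per-genotype depth in [5, 30]
(out-of-range calls become missing) and site mean depth in [10, 30];
$\le$ 15% missing calls; global minor allele frequency $\ge$ 0.05
(pairwise deletion); an exact Hardy--Weinberg test within populations
(site dropped when p < `hwe_alpha` = 0.001 in more than half the
populations with data -- the cited filter script's defaults); and one SNP
per locus (first by position). Each site is charged to the first rule
that removes it, so report counts sum exactly to the sites lost;
filtering is idempotent and relaxing any one threshold can only keep more
sites (both properties are tested).

Diversity uses genotyped-samples-only denominators: $H_O$ is the mean
heterozygous fraction; $H_E$ the small-sample unbiased gene diversity
$\frac{2n}{2n-1}(1 - \sum p^2)$ over variant sites; $\pi$ the average
pairwise difference with invariant sequence in the denominator
(`n_loci * invariant_sites_per_locus + n_variant`); rarefied allelic
richness is the exact subsampling expectation at `2 * min_diploids` genes
(default three diploids, the smallest sample in the motivating design).
Differentiation is multi-locus Weir & Cockerham $\theta$ as a ratio of
summed variance components (negative window values are reported as-is),
with significance from permuting individuals between the two populations;
$D_{xy} = \sum p_A(1-p_B) + p_B(1-p_A)$ over the same invariant-inclusive
length (a population against itself uses the unbiased within-population
form, so self-$D_{xy}$ equals $\pi$). The windowed scan uses 1-Mb windows
(0-based half-open internally, 1-based inclusive in output), drops
windows with fewer than five SNPs, and flags windows $\ge$ mean + 3 SD;
when the SD is zero no window is an outlier. PCA centres genotypes by
$2\hat p$ and scales by $\sqrt{2\hat p(1-\hat p)}$ with per-SNP mean
imputation of missing calls, and reports each SNP's correlation with each
component's sample scores -- a genome-wide band of moderate correlations
is the signature of drift-driven structure, isolated peaks of localized
signal.

## Median-joining networks

`median_joining()` implements the Bandelt--Forster--Röhl construction:
alignment columns containing any gap or IUPAC ambiguity are excluded
alignment-wide (so the distance is a plain Hamming count), the
$\varepsilon$-relaxed minimum spanning network is built over haplotypes
(distance classes in increasing order; at $\varepsilon = 0$ this is the
union of all minimum spanning trees, with ties broken by haplotype
label), and for every pair of links sharing an endpoint the per-site
majority consensus of the triplet is proposed as a median (Steiner)
vector; medians that strictly shorten the local connection are added one
at a time (cheapest first, ties by sequence) until a fixpoint, and
redundant medians (degree $\le$ 2 on an already-shortest path) are
pruned. Three-way ties at a site veto that median, so no ambiguity codes
are invented. Everything is deterministic and independent of input
order.

## What the synthetic data do and do not show

`generate_vcf()` emulates the *shape* of a ddRAD study: 11 populations of
3--11 diploids, ~20,000 biallelic loci scattered in non-overlapping slots
over 40 pseudo-chromosomes of 50 Mb, negative-binomial read depths and
locus-level allele dropout (a sample misses the whole fragment, as in
real RAD data) with per-population mean rates of 3--15%, exponentially
heterogeneous across samples so that a few bad samples carry most of the
missingness -- which is what makes complete-case down-sampling workable,
exactly as in real surveys. The depth defaults (mean 18,
dispersion size 30, so ~2% of calls fall outside the [5, 30] genotype
bounds) are constrained by the emulated study itself: its published
pipeline retained the large majority of loci through these depth and
missingness filters, which a heavy-tailed depth distribution (e.g. mean
20 with size 5, masking ~16% of calls) would contradict by pushing most
sites over the 15% missingness ceiling. It does **not**
emulate: linked SNPs within loci beyond the shared genealogy, allele
dropout or restriction-site polymorphism, sequencing error, paralog
collapse (so the heterozygosity and HWE filters remove essentially
nothing on clean templates -- their tests use planted violations
instead), selection, or recombination within loci. Tests passing on these
data therefore validate the estimators and the inference machinery, not
the wet-lab robustness of the pipeline.

`generate_mtdna()` plants a known haplotype genealogy (default: a
two-clade, 975-bp gene with a long internal branch) so the true network
is available as an oracle.

## Numerical choices and degenerate inputs

* Folding ties break to the lexicographically smaller index; projection
  (`project_msfs()`) uses exact hypergeometric weights per deme, re-folds,
  and sends mass on fixed cells to the monomorphic entry, so projection
  composes exactly (tested to 1e-9).
* When a spectrum is built from complete-case, one-SNP-per-locus data (the
  workflow's inference dataset), the surveyed length passed to
  `correct_monomorphic()` must be scaled by the complete-case fraction and
  by the thinning fraction, keeping the per-site SNP density of the
  spectrum equal to that of the data; otherwise every time and size is
  biased downward by the thinned-out SNPs. The analysis scripts do this
  explicitly.
* Monomorphic-within-population sites get HWE p = 1; populations below
  the rarefaction depth at a site are skipped for that site.
* Sites where every sample of a population is missing yield `NA`
  frequencies and are excluded pairwise from F~ST~/D~xy~ sums; an empty
  filter result warns rather than errors.
* `validate_model()` rejects pulses involving demes already merged away,
  non-positive times and $\alpha \notin [0,1]$; during optimization such
  proposals score $-\infty$ rather than aborting the run.
* Problem sizes in the test suite and acceptance script (observations of
  ~20,000 loci; 10,000--20,000 simulated loci per likelihood evaluation;
  bootstrap at 8--25 replicates) are the package's chosen desk-scale
  defaults; the full-study protocol (100 starts, 40 cycles, 100,000
  simulations, 50 bootstrap replicates of 15 optimizations) uses the same
  code paths.

## Known limitations

Composite likelihoods ignore linkage between SNPs of a locus (the
one-SNP-per-locus filter exists for exactly that reason) and their
model-comparison scores are not true likelihoods; AIC values are reported
for ranking only. Percentile bootstrap intervals can exclude the point
estimate under optimizer noise (flagged in the output). The coalescent
engine has no recombination, no selection and no sequence-level output;
multiallelic sites and indels are out of scope throughout.
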
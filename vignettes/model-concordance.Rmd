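---
title: "Assessing demographic-model concordance with multiple summaries of variation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing demographic-model concordance with multiple summaries of variation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popconcord)
```

## The problem

Demographic histories for the same population are routinely inferred from
different summaries of genetic variation: coalescent hidden-Markov methods
(PSMC/MSMC-style) use one to four whole genomes, site-frequency-spectrum
(SFS) methods use allele frequencies from tens of chromosomes, and combined
methods (SMC++-style) use both. These estimates often disagree. popconcord
implements the machinery needed to confront any piecewise demographic
history with three standard summaries of the data — the SFS, windowed
expected heterozygosity, and linkage-disequilibrium (LD) decay — and to
rank competing histories against an observed SFS by log-likelihood. A
built-in coalescent simulator supplies synthetic data so the entire
pipeline is testable without downloads.

## The model objects

A `piecewise_demography` tiles time (generations before present, increasing
into the past) with contiguous epochs. Each epoch carries diploid sizes per
population, optionally interpolated exponentially between its endpoint
values, and a per-generation migration matrix `m[p, q]`: the probability
that a lineage now in `p` traces its ancestry to `q`, one generation back.
Instantaneous events act backwards in time: at a *split*, all lineages of
the derived population join the ancestral one; at a *pulse admixture*, each
lineage of the recipient jumps to the donor with probability `f`. The
coalescence rate of `k` lineages in a population of diploid size `N` is
`k(k-1)/2 * 1/(2N)` per generation.

Coalescent-HMM output arrives as scaled tables; `parse_msmc_output()`
applies the standard conversion `t = scaled_time / mu` and
`N = 1 / (2 mu lambda)`. Because those physical units are an artifact of
the mutation rate used for scaling, `rescale_mutation_rate()` re-expresses
a model under another rate by multiplying all sizes and times by
`mu_old/mu_new`, leaving every epoch's population-scaled mutation rate
`4 N mu` invariant. Generation times differ between source studies
(25/29/30 yr/generation are all in circulation), so years appear only at
input/output boundaries via the model's own `generation_time`.

## Expected SFS

For a single population the engine is analytic. The expected per-site
density of sites at derived count `i` among `n` chromosomes is

    E[xi_i] = mu * sum_k k * E[T_k] * P(i | k),
    P(i | k) = C(n-i-1, k-2) / C(n-1, k-1),

where `T_k` is the time spent with `k` ancestral lineages. Under a
piecewise history the lineage-count process is a pure-death chain whose
occupancy probabilities have a closed spectral form in rescaled
(coalescent) time; on constant epochs the time integral is evaluated
exactly, and within exponential-growth epochs by quadrature at relative
tolerance 1e-8 with a 1e-10 absolute floor (the floor matters when an
epoch's occupancy probability is already negligible). This reproduces the
classical checks to 1e-6 relative error: the `1/i` proportional law and
`E[T_k] = 4N/(k(k-1))` at constant size, and `E[xi_1] = 4 N mu` for
`n = 2`. A diffusion solver is deliberately not used; for neutral models
the coalescent expectation is the same quantity, and the equivalence with
the Monte Carlo engine is itself a test rather than an assumption.

Multi-population models with migration have no convenient closed form, so
`expected_sfs_montecarlo()` estimates each population's marginal spectrum
as the mean branch length subtending each frequency class across simulated
genealogies, times `mu`, with per-bin standard errors. The default of
2e5 genealogies puts the per-bin standard error well below the differences
that separate competing published models. Single-population inputs take a
vectorized fast path (times drawn in rescaled time and mapped through the
inverse cumulative coalescent intensity; the exchangeable topology drawn
independently); structured models run an event-driven backward simulation
with competing risks — constant-rate migration draws and per-population
coalescence times drawn by closed-form hazard inversion, so exponential
epochs need no thinning.

Spectrum transforms follow SFS-inference conventions: unfolded spectra are
indexed `1..n-1` with fixed classes excluded everywhere; folding adds
complementary classes; projection to `m < n` chromosomes is the expected
hypergeometric down-sampling, with mass reaching the subsample's
monomorphic classes dropped (and proportions renormalized, since the
sum-to-one invariant is part of the container contract); the singleton
class can be zeroed and the rest renormalized, mirroring the practice of
re-scoring low-coverage data whose singleton calls are unreliable.
The observed-SFS projection convention is the expected (deterministic)
hypergeometric one; per-site missing-data handling upstream of the counts
is out of scope and flagged in the projection documentation.

## Synthetic data: what the simulator does and does not emulate

`simulate_blocks()` emulates the study design the package is built around:
many independent 100-kb blocks for 10 diploid individuals, each block with
its own recombination rate. Within a block the sequence process is the
SMC' approximation: the left-end genealogy is standard-coalescent; the
distance to the next breakpoint is exponential with rate `r` times the
total branch length; at a breakpoint a branch is detached at a uniform
point and re-coalesces into the remaining tree, *including* its original
lineage. SMC' (rather than SMC) was chosen because re-coalescence with the
detached lineage keeps the marginal genealogy at every position exactly
standard-coalescent, which both underwrites the calibration tests (Watterson
segregating sites, pairwise diversity) and matches the approximation the
reference study validated as unbiased for LD. Mutations are Poisson on
branches under infinite sites; positions land on an integer grid, and the
rare position collision (about `S^2/2L` sites per block, well under one
per 100-kb block at human-like diversity) is resolved by dropping the later
mutation — a documented, measure-zero deviation from strict infinite sites.

The per-block recombination-rate distribution of the original study derives
from a pedigree-based genetic map; that empirical distribution is not
reproduced here. In its place stands a configurable lognormal with median
1.1e-8 per bp per generation and log-SD 0.7 — a deliberately coarse but
realistic stand-in for genome-wide rate variation (documented as such, not
as a reproduction). Gene conversion, recombination hotspot fine structure,
and selection are all absent, exactly as in the study's simulations; a
green LD test therefore establishes internal consistency of the simulator
and estimator, not realism of fine-scale recombination.

The sequential engine is restricted to single-population histories. The
structured (multi-population) coalescent is available for unlinked
genealogies, which determine every SFS and mean-diversity quantity the
pipeline consumes; sequence-level LD under migration models would require
population tracking through tree surgery and is left out of scope, with an
explicit unsupported-feature error.

RNG contract: every block and every replicate derives its own stream
deterministically from `(master seed, unit id)` (`derive_seed()`), so
results cannot depend on evaluation order, and identical seeds give
byte-identical outputs.

## Empirical summaries

`window_pi()` computes `pi = n/(n-1) * sum 2 p (1-p) / L` in fixed,
non-overlapping windows aligned to the contig start, with `L` the callable
length — the window width without a mask, the BED intersection with one
(BED's 0-based half-open convention converted at the boundary). Sites
outside callable intervals are excluded from the numerator as well.
Algebraically `n/(n-1) * 2p(1-p) = x(n-x)/C(n,2)` per site, so the formula
equals mean pairwise differences per site exactly; the suite asserts that
identity on random matrices rather than trusting either form. Windows with
zero callable length are dropped and counted, not errors; the callable
fraction threshold below which a window is excluded is a configuration
knob defaulting to 0, since the source analyses do not state one.

`ld_decay()` uses genotype (dosage) r-squared — squared Pearson correlation
of dosage vectors, ignoring phase — after removing singletons (minor allele
count 1 among `2n`) and invariant sites. Pairs are binned by physical
distance into 51 half-open 1000-bp bins, `[0, 1000)` through
`[50000, 51000)`; the final bin's upper edge is read as exclusive for
partition consistency. Pairs with a zero-variance site are skipped; empty
bins report a count of zero rather than erroring.

## Model fit

The multinomial log-likelihood is `sum x_i log p_i` without the
multinomial coefficient; the "data-to-data" reference replaces model
proportions with the observed ones and is the unique maximum (Gibbs'
inequality), so every model's `delta_LL` is non-positive and 0 only for a
perfect fit. The coefficient-free convention cannot be validated against
the published likelihood table without the externally distributed observed
spectrum, but `delta_LL` — the quantity actually compared — is invariant
to that choice. The Poisson log-likelihood for absolute (count) spectra
keeps the `-log Gamma(x+1)` term, constant across models, so absolute
values match likelihood-theory references. Models assigning zero
probability to observed bins are floored at 1e-300 with a warning rather
than erroring, so pathological models still appear (badly) in rankings.
`fit_table()` applies identical transforms (projection, folding, singleton
removal) to the observed spectrum and every model before scoring, and
isolates per-model failures to their rows.

## Numerical and design choices made where the design was open

* **Trajectory averaging.** When replicate coalescent-HMM runs are combined,
  the mean is arithmetic in natural size on a 64-point geometric grid with
  left-hold step interpolation; the source study does not state its
  convention, so a log-scale (geometric-mean) switch is provided and the
  arithmetic mean is the default.
* **Stepwise discretization** of continuous trajectories samples the value
  at the geometric midpoint of each grid interval; the exact grids used in
  the original conversions are not published, and refinement monotonicity
  (doubling steps never worsens the maximum relative size error) is the
  property the suite enforces instead.
* **Trimming** an epoch that straddles the cutoff keeps its profile up to
  the cutoff and holds the value constant beyond it; trimming never alters
  the size function more recent than the cutoff and is idempotent.
* **ms-dialect emission** covers constant-size epochs, migration matrices,
  splits, and pulses (the standard `-es`/`-ej` pairing); exponential epochs
  must be discretized first and raise an explicit unsupported-feature
  error. Emitted fragments parse back to the identical demography.
* **Degenerate inputs.** Histories whose lineages can never find a common
  ancestor (isolated populations, no migration or merger) abort with a
  clear error instead of spinning; all-zero spectra cannot be normalized;
  an all-singleton spectrum cannot survive singleton removal.

## What the tests establish

The validation surface is property-based: closed-form agreement of the
analytic engine; agreement of the two independent SFS engines within Monte
Carlo error on multi-epoch models; calibration of the sequence simulator
against Watterson's expected segregating sites and pairwise diversity; the
exact pi identity; the Gibbs and Poisson maxima; and a recovery experiment
in which the generating model of a 17,446-SNP synthetic observed SFS must
rank first against four decoy histories in at least 95 of 100 replicates.
Reproducing the published likelihood table itself requires externally
distributed observed spectra and the source studies' full parameter sets,
and is therefore outside the offline test surface; the functions that
computation needs (`multinomial_ll`, `data_to_data_ll`, `fit_table`,
`project`, `marginalize_joint`) are all exercised on synthetic data.

## A worked example

```{r example, eval = FALSE}
# a bottleneck history: 10,000 diploids now, 1,000 ancestrally
gen <- builtin_demography("bottleneck")

# its expected SFS for 20 chromosomes, and a synthetic observed SFS
fx <- generate_fixture("bottleneck", seed = 1, dir = tempdir(),
                       decoys = c("constant", "growth"))

res <- run_compare(list(
  models = list(list(name = "bottleneck", path = fx$model),
                list(name = "constant", path = fx$decoys[["constant"]]),
                list(name = "growth", path = fx$decoys[["growth"]])),
  observed_sfs = fx$observed_sfs,
  summaries = c("sfs", "heterozygosity", "ld"),
  simulation = list(n_diploids = 10, n_blocks = 200, L = 1e5),
  seed = 1, output_dir = file.path(tempdir(), "out")))
res$fit
```

The desk-scale default of 200 blocks is deliberately small; the
paper-scale preset (20,000 blocks of 100 kb) is a configuration choice,
not a code change.

## Known limitations

* No diffusion-approximation solver and no composite-likelihood parameter
  optimization: the package compares fixed models, it does not fit them.
* Sequence-level (LD) simulation is single-population only.
* No gene conversion, hotspots, or selection in the simulator.
* No spline fitting for continuous trajectories and no joint
  multi-population trajectory estimation; no re-implementation of the
  coalescent-HMM inference methods themselves.
* Ancestral-misidentification correction is assumed applied upstream of
  any observed spectrum.
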
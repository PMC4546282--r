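---
title: "Reconstructing maternal demographic history from control-region sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing maternal demographic history from control-region sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesodemog)
```

## The problem

Human mitochondrial DNA is maternally inherited and non-recombining, so a
sample of control-region sequences (HVRI, ~16024–16365, and HVRII, ~73–340)
from a population carries a single genealogy whose shape encodes the history
of the effective number of breeding females, Nef.  `mesodemog` implements the
full analysis chain used in mtDNA studies of population history: haplogroup
composition, within-population diversity and neutrality statistics,
between-population structure, a Bayesian skyline reconstruction of Nef(t),
and a derived per-generation growth-rate statistic (IGR) whose extrema and
sign changes are mapped onto the Mesoamerican chronological periods.  Because
such studies' raw sequences are typically deposited in curated forensic
databases rather than shipped with papers, the package also contains a
first-class coalescent simulator that generates datasets with the statistical
structure the analysis assumes, so that every stage is testable by parameter
recovery.

## The coalescent simulator

`simulate_genealogy()` draws a Kingman coalescent under a piecewise-constant
Nef history (`demographic_model()`).  Nef is the *haploid* effective count of
maternal lineages, so with `k` extant lineages the coalescence hazard is
`k(k-1)/(2 Nef)` per generation; waiting times across epochs use exact
inverse-CDF time rescaling, not discretised time steps.  Piecewise-constant
histories are the only family supported: the skyline model downstream is
itself piecewise-constant, so richer families (exponential epochs) would add
nothing testable.  `simulate_structured_genealogy()` adds an island-model
structured coalescent (competing exponentials between epoch boundaries,
backward migration rates) used to test the structure statistics against known
truth.

Sequences evolve along the genealogy under HKY85 with 4-category
discrete-gamma rate heterogeneity (`evolve_sequences()`).  Transition
probabilities per branch are exact matrix exponentials of the scaled HKY
generator (via the symmetric eigendecomposition available for reversible
chains), so multiple hits need no approximation.  Category rates are the
category medians, normalised to mean one, a reproducible standard choice.
Defaults emulate a full 1122-site control region: substitution rate
3.02e-7 per site per year (a non-coding-region pedigree-scale rate),
25-year generations, transition/transversion ratio 20 and gamma shape 0.26
(control-region-like values), base frequencies (0.31, 0.33, 0.13, 0.23).
Simulator coordinates 1–546 map to reference positions 16024–16569 and
547–1122 to positions 1–576, so HVRI/HVRII flags and classic diagnostic
positions carry over.

The reference sequence is **synthetic**: a fixed pseudo-sequence drawn once
from control-region base frequencies (`control_region_reference()`).  It is
not the rCRS, and the shipped haplogroup motif table
(`default_motif_table()`, `inst/extdata/motifs.yaml`) is likewise
illustrative: classic diagnostic *positions* (16111, 16223, 16325, ... for
A2, B2, B4b1, C1, D1, D4h3a, X2a) with alleles defined as the transition
partner of the synthetic reference base.  Nothing in the package asserts
real-world motif truth; analyses of real data should supply a curated YAML
table via `read_motif_table()`.

`make_study_fixture()` assembles a whole multi-population study: per
population a sample size, a haplogroup mixture and a demographic model;
samples are allocated to haplogroups multinomially, each haplogroup cluster
descends from its own genealogy with the diagnostic motif planted at the
cluster root.  One master seed drives everything; per-population streams are
derived by stable hashing of the population name so that editing one
population leaves the others byte-identical.

What the simulator does *not* emulate: recombination (absent in mtDNA),
heteroplasmy, sequencing error, selection, and within-population haplogroup
structure beyond the planted motifs.  Passing recovery tests on these
fixtures therefore shows the inference machinery is correct under the model's
own assumptions — not that real control-region data satisfy them.

## Diversity and neutrality statistics

`diversity_summary()` produces the classic per-population table: sample size
n, haplotype count k, segregating sites S, haplotype diversity
`H = n/(n-1)(1 - sum p_i^2)` with Nei's sampling standard deviation,
per-site nucleotide diversity pi with Tajima's (1983) total variance, the
mean number of pairwise differences theta, Tajima's D and Fu's FS.  Three
conventions deserve note:

* **theta is the mean pairwise difference count**, not Watterson's
  estimator; Watterson's `S/a1` appears only inside Tajima's D.
* **Missing data are handled by pairwise deletion** (sites with N excluded
  per pair), matching the default behaviour of the standard Arlequin
  workflow.
* **Fu's FS** uses the Ewens sampling distribution with theta (mean pairwise
  differences) as the plug-in:
  `FS = ln(S'/(1-S'))`, `S' = Pr(K >= k_obs | theta, n)`, computed from
  unsigned Stirling numbers of the first kind in log space, stable to
  n ≈ 200.  `S'` hitting 0 or 1 at machine precision returns a signed
  infinity with a warning rather than an error.

The pi standard deviation formula is stated in the documentation
(`nucleotide_diversity()`) rather than reverse-engineered from any published
table, since per-table variance conventions vary across programs.

## Population structure

All "Fst" quantities are the haplotype-distance-based **Phi-statistics** of
the AMOVA framework, not allele-frequency Fst.  Pairwise difference counts
are the squared Euclidean distances of site-indicator vectors, so they enter
the sums of squares directly (the Arlequin convention); the test suite
verifies the variance components against an explicit Euclidean embedding of
the same matrix.  `amova()` implements the three-level
Excoffier–Smouse–Quattro decomposition (F_CT among groups, F_SC among
populations within groups, F_ST within populations) with the standard
permutation schemes — whole populations among groups for F_CT, individuals
within groups for F_SC, individuals among populations for F_ST — and
`(b+1)/(m+1)` p-values, seeded.  Negative variance components (and hence
negative Phi-st) are reported as computed, flagged, never truncated.

`mds_scaling()` is classical (metric) principal-coordinates analysis;
non-metric stress minimisation is deliberately out of scope and the choice is
recorded in the solution's metadata.  Negative eigenvalues are dropped and
their mass reported as part of the goodness of fit.
`mantel_test()` correlates distance matrices with joint row/column
permutation (exhaustive enumeration up to n = 7); geographic distances come
from great-circle (haversine) kilometres via `geographic_distance_matrix()`.
`centroid_diversity_correlation()` reproduces the diagnostic of peripheral
low-diversity populations: Euclidean distance from the MDS centroid against
haplotype diversity.

## The Bayesian skyline

The skyline stage is deliberately **conditional on a genealogy** — the
simulator's true tree, or a UPGMA estimate on F84-corrected distances
(`estimate_genealogy()`; F84 is the closed-form distance analogue of HKY).
Joint tree-and-parameter inference over tree space, as done by full Bayesian
phylogenetic samplers, is out of scope: the coalescent-interval likelihood is
the skyline's defining computation and is fully testable by parameter
recovery, while tree-space MCMC is not tractable at desk scale.  The
consequence is honest undercoverage of genealogical uncertainty; the relaxed
molecular clock of real analyses is similarly reduced to a strict clock in
inference (the simulator can still be used to study the mismatch).

`coalescent_intervals()` reduces an ultrametric tree to its sufficient
statistic: the ordered (k, dt) spans between coalescences.  The classic
deterministic skyline (`classic_skyline()`, `N = k(k-1) dt / 2`) serves as a
cross-check on the Bayesian estimate.  `mcmc_skyline()` samples a
piecewise-constant model with m groups of consecutive coalescent events:
log-likelihood `-k(k-1) dt/(2N)` per interval plus `-log N` per coalescence,
summed across one *or several* independent genealogies (epoch boundaries live
on the pooled event times, so multi-population pooling is supported).  Moves
are multiplicative scale proposals on a random group's Nef, a scale-all move
(which mixes the overall level much faster under the smoothing prior), and
symmetric single-event swaps between adjacent groups.  The prior is
scale-invariant (1/N, bounded to a wide box so it is proper) on the first
group and Exponential(mean = previous group's Nef) on each later group — the
standard autocorrelated smoothing.  Sampler correctness is tested three
ways: the likelihood against an independently hand-coded sum, the
single-interval posterior against its closed form (1/N exponentially
distributed), and a flat-likelihood run against direct draws from the prior.

`skyline_trajectory()` evaluates every retained draw on a time grid and
reports the per-gridpoint posterior median and 95% HPD interval, in
generations and in years before present (25-year generations by default).
Default MCMC settings (200,000 iterations, thin 100, 10% burn-in) are sized
for a single desk-scale genealogy; the tests and the acceptance script use
20,000–80,000 iterations on their smaller problems and state so per run.
An effective-sample-size diagnostic warns below 50.

## IGR, extrema and trend inversions

From a trajectory resampled to the 25-year generation grid
(`resample_to_generations()`, step-function evaluation, no interpolation),
the inter-generational growth rate is

    IGR_n = 100 (Nef_n - Nef_{n-1}) / Nef_{n-1},

with n−1 the *older* generation, so positive values mean growth toward the
present.  The series is scale-invariant in Nef and compounds exactly back to
the trajectory, which the tests assert to 1e-9.

Chronological mapping uses the period table Lithic 15000–2500, Preclassic
2500–1750, Classic 1750–1050, Postclassic 1050–429, Colonial 429–0 ybp
(anchor 1950 CE; 1521 CE = 429 ybp).  Two source conventions required a
decision: the Preclassic/Classic boundary of "150/200 CE" is taken at its
midpoint (~1750 ybp), and a Colonial onset printed elsewhere as "1951" is
treated as a typo for 1521 CE; both boundaries are overridable via a YAML
table (`read_period_table()`, `inst/extdata/periods.yaml`).  A time belongs
to the period with `start_ybp >= t > end_ybp`; t = 0 maps to the most recent
period, and times older than 15000 ybp are labelled `pre-chronology`.

Raw IGR series fluctuate intensely — a reconstructed step trajectory has
zero IGR inside epochs and spikes at boundaries — so `detect_inversion()`
first smooths with a centered moving average (default window 5 generations;
`mode = "raw"` is available).  An inversion is a transition between
consecutive strictly-signed smoothed values with persistent sign on both
flanks (at least window/2 generations each); zero plateaus between the signs
are treated as the tail of the outgoing regime, so the crossing is dated
where the new sign first appears.  The alternative — dating at the plateau
midpoint — was rejected because it smears a flat reconstructed peak by half
its width.  `locate_extrema()` breaks ties toward the most recent
generation.

## Numerical and design choices, in brief

* Seeds: every stochastic entry point takes a `seed` and restores the
  caller's RNG stream; nested streams derive by stable string hashing
  (`stable_seed()`), so runs are reproducible file-for-file.
* Indels and ambiguity codes are outside the variant model: profiles code
  substitutions only, and N sites are skipped with a count.
* Haplogroup calls below the score threshold (default 0.8) become
  `unassigned` and are excluded from frequency tables and downstream
  statistics, mirroring how non-focal lineages are handled in practice.
* Degenerate inputs fail loudly and specifically: ragged FASTA names the
  record, saturated distances name the pair, disconnected migration errors
  after an event cap, monomorphic Phi-st warns and returns NaN rather than a
  fabricated 0.
* Problem sizes in the tests — e.g. 200 neutral simulations for the Tajima
  calibration, 20 replicates of 8 genealogies x 35 tips for the end-to-end
  inversion recovery, 20,000–80,000 MCMC iterations — were chosen as the
  smallest designs at which each property is statistically decidable on a
  single CPU.

## Known limitations

Fixed-genealogy inference understates uncertainty relative to joint
tree-and-parameter samplers; heterochronous (serially sampled) tips are not
supported; the skyline's temporal resolution is bounded by the local density
of coalescent events, so the *timing* of demographic turning points carries
posterior scatter of several centuries at realistic control-region sample
sizes even when the qualitative growth-then-decline shape is recovered
reliably.  The end-to-end recovery experiments in the test suite quantify
exactly this.
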
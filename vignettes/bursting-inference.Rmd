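---
title: "Inferring transcriptional bursting kinetics from single-cell new-RNA counts"
author: "burstkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring transcriptional bursting kinetics from single-cell new-RNA counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`burstkin` analyses single-cell counts of metabolically labelled (4sU-pulse)
RNA under the two-state telegraph model of transcription. A promoter switches
from off to on at rate $k_{on}$ and back at rate $k_{off}$ (both per hour),
synthesises RNA at $k_{syn}$ molecules per hour while on, and transcripts
degrade at $k_d$ per hour. The derived quantities reported throughout are

* occupancy $= k_{on}/(k_{on}+k_{off})$ (fraction of time on),
* burst size $= k_{syn}/k_{off}$ (RNAs per on state),
* burst frequency $= 1/(1/k_{on} + 1/k_{off})$ (on states per hour),
* expression rate $= k_{syn}\,k_{on}/(k_{on}+k_{off})$ (RNAs per hour).

During a labelling window of length $t$ (2 h by default) only molecules
transcribed inside the window carry label. The quantity the package models is
therefore the distribution of *labelled* molecule counts per cell given that
the promoter is at stationarity when the window opens, no labelled molecules
exist at $t=0$, and labelled molecules degrade at $k_d$ within the window.
$k_d$ is treated as a fixed, externally supplied constant (0.065 per hour for
fibroblasts, obtained as $-\ln(\mathrm{fraction~old})/t$ from the dataset-wide
old-RNA fraction); it is never jointly optimised.

## The transient PMF

Writing $G_i(z,t)=\sum_n P(\text{state } i, n \text{ labelled})\,z^n$ for the
promoter-state resolved generating functions, the labelled-count master
equation becomes a first-order PDE that reduces along its characteristics
$z(s) = 1 + (z-1)e^{-k_d (t-s)}$ to the 2-by-2 linear, time-varying ODE

$$\frac{dV}{ds} = \begin{pmatrix} -k_{on} & k_{off}\\ k_{on} &
k_{syn}(z(s)-1) - k_{off} \end{pmatrix} V, \qquad
V(0) = \begin{pmatrix} 1-\pi \\ \pi \end{pmatrix},$$

with $\pi$ the stationary occupancy. $G(z,t) = V_0 + V_1$ evaluated at $s=t$.
The PMF is recovered from generating-function values on the unit circle by
FFT. Because $|V| \le 1$ on the closed unit disk, this route is numerically
benign in double precision — in contrast to closed-form confluent
hypergeometric (Kummer-function) expressions of the same distribution, whose
evaluation suffers catastrophic cancellation and demands arbitrary-precision
arithmetic. The ODE is propagated with a fourth-order Magnus integrator (two
Gauss nodes plus the leading commutator), each step applied through the exact
exponential of a 2-by-2 complex matrix, under adaptive step doubling with
Richardson extrapolation.

Numerical safeguards, in order:

* the FFT grid starts at $m = 2^{\lceil \log_2(\mu + 12\sigma + 30 b +
  30)\rceil}$ with $\mu$ the analytic mean, $\sigma$ a Fano-bound standard
  deviation and $b$ a burst-tail scale $\approx k_{syn}/k_{off}$;
* after inversion, the tail is certified two ways: mass in the last eighth
  of the grid, and agreement of the computed mean with the closed form
  $\mu = k_{syn}\,\pi\,(1-e^{-k_d t})/k_d$ (aliased tail mass folds back to
  low counts and visibly depresses the mean). On failure the grid doubles;
* negative entries beyond the integrator noise floor trigger tolerance
  escalation (down to $10^{-15}$ per step); tiny negatives are clamped;
* for windows longer than $46/k_d$ the integration starts at
  $t - 46/k_d$ from the stationary vector, since earlier label survives at
  below double precision.

The defaults resolve the PMF to a truncation tolerance `tail_eps` of
$10^{-10}$. An independent finite-state-projection oracle
(`cme_oracle_pmf()`, a stiff ODE solve of the truncated master equation via
`deSolve`) shares no code with this route and agrees with it to about
$10^{-12}$ per entry across the lookup-grid bounds; the always-on limit
($k_{off}=0$, a Poisson birth-death law) and the long-time limit (the
stationary Poisson-beta law) are reproduced to $10^{-9}$ and $10^{-6}$.

The stationary distribution itself (`steady_state_pmf()`) is evaluated
through the confluent hypergeometric representation computed as a
positive-term series in log space (no cancellation). A second, faster
stationary route used only inside steady-state likelihood evaluations
integrates the Poisson mixture over the Beta occupancy density by
Gauss-Legendre quadrature; the two agree to $10^{-11}$.

## Inference strategy

Per gene, inference proceeds in the published three steps:

1. **Summary statistics** (`compute_summary_stats()`): fraction of cells
   with new RNA, mean count among expressing cells, and CV among expressing
   cells. The CV uses the population (divide-by-$n$) standard deviation; any
   consistent convention works, and this one is deterministic and matches
   between table construction and gene summaries.
2. **Lookup initialisation** (`build_lookup_table()`,
   `initialize_parameters()`): a grid of parameter combinations (published
   axes: 73 log-equidistant $k_{on}$ values 0.002-50, 38 $k_{syn}$ values
   1-200, 55 $k_{off}$ values 0.25-500, steps of ~1.15x) maps parameters to
   expected summary statistics. By default the table stores the statistics
   computed exactly from the PMF — the infinite-cell limit of summarising
   simulated counts — because dictionary sampling noise measurably biases
   initialisation along the weakly identified $k_{syn}/k_{off}$ direction;
   the Monte-Carlo construction (`stats_mode = "sampled"`) is retained.
   Inversion interpolates (inverse-distance weighting over the nearest
   entries in (logit fraction, log mean, log CV) space, undefined components
   dropped) when the observation lies inside the neighbours' componentwise
   hull and falls back to the single nearest entry otherwise, with
   equidistant ties broken towards the lowest axis indices. Genes whose
   overall mean expression lies outside 0.01-350 counts per cell, and genes
   whose identified parameters sit on a grid-axis boundary, are excluded.
3. **Bounded maximum likelihood** (`fit_mle()`): `L-BFGS-B` over
   $(\log k_{on}, \log k_{syn}, \log k_{off})$ with box bounds equal to the
   lookup axes (positivity and scale invariance), default convergence
   control (the same relative-reduction threshold as the reference
   implementations of this optimizer), and the guarantee that the returned
   likelihood is never below the initialisation's.

**Bootstrap robustness** (`bootstrap_gene()`): 50 resamples of cells with
replacement, each re-initialised and re-fitted. A parameter is robust when
the quartile spread is below 2 *on the natural-log scale* and fewer than
half of the resample inferences failed (optimizer failure or a
boundary/at-bound result both count as failures). The published threshold of
2 does not state its scale; on the linear scale a difference of 2 would be
meaningless for rates of order 100, while on the log scale it corresponds to
a 7.4-fold spread, consistent with the precision the method actually
attains; the scale is exposed as a configuration option.

**Split-half analysis** (`split_half_analysis()`): cells are partitioned at
random into two halves, inference runs independently on each, and Spearman
correlations between half-1 and half-2 quantities (with Benjamini-Hochberg
adjusted two-sided p-values) quantify reproducibility. Correlating across
independent halves removes the spurious $k_{syn}$-$k_{off}$ coupling that
joint inference on shared cells induces.

## What is and is not identifiable

A point this package's own test suite quantifies deserves emphasis. At
realistic depths (thousands of cells, 2-h labelling), the labelled-count
distribution is nearly invariant along a direction that scales $k_{syn}$ and
$k_{off}$ together (with a small compensating change in $k_{on}$): between
parameter sets two- to four-fold apart along this ridge, the expected
log-likelihood difference over 4,000 cells is of order one unit — confirmed
independently by the master-equation oracle. Consequences:

* $k_{on}$, burst frequency, expression rate and burst size are well
  identified and recover accurately in simulation;
* individual $k_{syn}$ and $k_{off}$ estimates scatter several-fold along
  the ridge, and where an estimate settles on the ridge is governed largely
  by the initialisation; the lookup inversion resolves the ridge direction
  only weakly, so central estimates of $k_{syn}$ and $k_{off}$ can drift
  from the truth even when every other quantity is recovered;
* the appropriate validation of $k_{syn}$/$k_{off}$ inference is therefore
  *reproducibility* — split-half rank correlation — and enough cells, not
  single-fit accuracy. This matches the published observations that these
  two parameters need the most cells and are robust for the fewest genes.

The steady-state (total RNA, $t \to \infty$) arm of the simulation
experiment (`bias_experiment()`) shows the far stronger form of this
degeneracy: there, $k_{syn}$ and $k_{off}$ enter the stationary law almost
only through their ratio, and estimation errors of the two are nearly
perfectly coupled across replicates, while the pulse-labelled arm keeps them
separable. The steady-state arm is initialised at the true parameters (the
lookup table indexes pulse-labelled statistics and does not apply; starting
at the truth is the most favourable choice, and the coupling it demonstrates
arises from the likelihood itself). Its likelihood uses the quadrature
stationary route for speed. Unimodality of the per-combination estimate
distributions is checked with a dip statistic (greatest-convex-minorant /
least-concave-majorant construction over candidate modal positions)
calibrated by Monte Carlo against the uniform null, which makes the test
level exact by construction; no unimodality test package is required.

## Stochastic simulation

`gillespie_labelled()` simulates the model exactly: stationary initial
promoter state (no burn-in), exponential dwell times, Poisson birth counts
with uniform birth times within each on-period (exact by conditional
independence), and exact thinning for degradation with survival probability
$e^{-k_d (t - t_{born})}$. Each molecule records the ordinal of the
on-period that produced it (an on-period straddling the window start is
burst 0), which supports the single-burst-fraction analyses: sweeping the
labelling time shows that windows of 1-2 h maximise the fraction of cells
whose new RNA derives from exactly one burst — short windows see few
expressing cells, long windows mix bursts. Degradation of labelled
molecules during the window is on by default, consistent with the PMF.
Agreement between the simulator and the analytic PMF (total-variation
distance below 0.01 at $10^5$ cells) cross-validates the entire model stack,
since the two implementations share nothing but the model definition.

## Molecule-level new-RNA calling

The upstream stage turns aligned reads into classified molecules:

* **Consensus** (`merge_read_group()`): reads sharing an error-corrected UMI
  are merged per position by multiplying per-read base likelihoods
  ($1-10^{-Q/10}$ for the called base, the remainder split equally; `N`
  uniform) and normalising; a base is called when its posterior exceeds 0.3
  (ties give `N`) and the merged Phred score is $-10\log_{10}(1-p_{max})$,
  capped at 93 for FASTQ encodability. This normalisation is the softmax of
  summed per-read log-likelihoods and reduces to the Phred round-trip for a
  single read. UMI groups spanning multiple genes are discarded with a
  counter.
* **Masking** (`mask_artifact_positions()`): positions whose conversion-type
  mismatch recurrence across molecules beats a one-sided binomial test
  (background = median per-position mismatch fraction) at Bonferroni-adjusted
  $\alpha = 0.05$ are masked — these are unfiltered polymorphisms or
  alignment artifacts, not label.
* **Error rate**: $p_e$ is the mean of the C>T and G>A mismatch rates, the
  strand-complementary counterparts of the label signal.
* **EM** (`em_conversion_rate()`): a two-component binomial mixture over
  per-molecule (convertible, converted) site counts with $p_e$ fixed
  estimates the conversion probability $p_c$ and the new fraction
  $\pi_{new}$; the observed-data log-likelihood is non-decreasing and
  degenerate fits ($p_c$ collapsing to $p_e$ or zero conversions) are
  flagged.
* **Classification** (`classify_molecule()`): a one-sided likelihood-ratio
  test of old ($p = p_e$) against new ($p = p_c$); since the binomial
  likelihood ratio is monotone in the conversion count, the rejection region
  is an upper tail, calibrated exactly. `detection_power()` enumerates the
  rejection region exactly — power against molecule length reproduces the
  detection-power-versus-length dependence of the assay.
* **Allelic origin** (`genotype_molecule()`): a molecule (or read) is
  assigned maternal or paternal only on exclusive variant evidence.

Read-level calls (`call_reads()`) reuse the molecule-level $p_c, p_e$ and
drop reads without transcribed variants. Cell quality filtering keeps cells
with strictly more reconstructed molecules than the preset threshold (4,000
for fibroblasts, 2,700 for K562).

## Allele-resolved co-bursting

With maternal/paternal new-RNA count matrices (`allelic_counts()`), each
same-chromosome gene pair within 3.5 Mb yields Spearman correlations of
total counts, of same-allele pairings (cis: maternal-maternal and
paternal-paternal, averaged) and of cross-allele pairings (trans, averaged),
binned by gene-start distance (<0.1, <0.5, <1.5, <2.5, <3.5 Mb; the
published bin labels carry no units and are interpreted as megabases). Cells
with no allele-assigned new RNA contribute zeros — absence of new RNA is
burst-detection signal, not missingness; total correlations use all cells.
The cis-minus-trans difference cancels cell-level confounders, which inflate
cis and trans alike; relabelling the alleles of one gene exchanges cis and
trans and negates the statistic exactly. Contingency tests (chi-square and
Fisher exact, two-sided) on the 2-by-2 expressed-allele table over cells
expressing both genes mono-allelically provide an alternative detection
route. Detection power is estimated by implanting coordinated same-allele
counts (1 + Poisson(2) molecules, one burst's worth) into an increasing
fraction of cells; each replicate draws a fresh, independent eligible gene
pair (per-allele mean 0.2-5) from the baseline so that the rejection rate at
fraction zero estimates the test's level.

## Synthetic data

The generator makes every input the pipeline consumes. Kinetic panels draw
log-uniformly from fibroblast-like ranges — $k_{on} \in [1/24, 1]$ per hour
(burst frequencies of one per day to one per hour), $k_{syn} \in [3, 200]$
molecules per hour (the published synthesis-rate span), $k_{off} \in
[5, 200]$ per hour (bursts lasting of order a minute, well above $k_{on}$ so
genes are bursty) — with log-uniform gene spacings of 0.02-2 Mb so all
distance bins populate. Coupled pairs share one promoter trajectory per
allele (requiring shared switching rates) and exhibit same-allele
co-bursting by construction; all other gene-allele combinations are
independent. Molecule tables emulate the conversion assay with defaults
$p_c = 0.04$, $p_e = 0.002$ (signal-to-noise 20, the fibroblast median
scale), convertible-site counts from a discretised log-normal with median
about 60 sites (standing in for the molecule-length dependence of power),
one covered discriminating variant per molecule on average, and seven old
molecules per new molecule, which puts the new fraction at about 12.5%, the
fibroblast scale. What the generator does not emulate: sequence-level read
errors and mappability, technical dropout of labelled molecules (the cause
of real-data burst-size underestimation), cell-cycle or extrinsic-noise
heterogeneity, and cell-to-cell variation in conversion efficiency — so
green tests certify the inferential machinery, not robustness to those
real-data features.

## Problem sizes and reproducibility

Every stochastic step takes a seed and is bit-reproducible under it (the
compiled simulators draw from R's RNG). The test and acceptance runs use a
reduced lookup table — the full published $k_{on}$ span at 49 points and
coarser synthesis/off axes (10 x 12 over the published ranges), with exact
summary statistics — because the initialisation is insensitive to
$k_{syn}$/$k_{off}$ axis density while $k_{on}$ density matters; the
published 73 x 38 x 55 grid remains the package default for production use.
Simulation-based checks use 4,000 cells and 20 replicates per grid
combination for the recovery experiment, $10^5$ cells for
simulator-versus-PMF agreement, 500 genes at 800 cells for the split-half
analysis, and 140 genes by 5,000 cells (about 2,000 pairs) for the
co-bursting null.

## Known limitations

* Individual $k_{syn}$ and $k_{off}$ point estimates are only weakly
  anchored along their joint ridge at a few thousand cells (see above);
  consumers should rely on the robustness flags, burst size, and split-half
  reproducibility.
* The conversion EM is fitted globally, not per cell; per-cell conversion
  efficiency variation is not modelled.
* The SAM ingester handles single-locus UMI groups with M/=/X, I, D, N and
  S CIGAR operations and requires MD tags; gapped fragment reconstruction
  beyond that is out of scope.
* Multi-state (>2) promoter models, extrinsic-noise mixtures and cell-cycle
  aware models are out of scope.
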
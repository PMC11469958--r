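# burstkin

Transcriptional bursting kinetics from single-cell new-RNA profiles.

Most genes are transcribed in bursts: a promoter flips between an inactive
and an active state, and RNA is made only while it is on. Classic inference
of bursting kinetics from steady-state single-cell RNA counts can estimate
burst frequency and burst size, but cannot separate the synthesis rate from
the off-switching rate that jointly set the burst size. Metabolic labelling
changes that: exposing cells to 4sU for a short window (2 h) marks the RNA
transcribed inside the window with T>C conversions, so each cell reports a
*new-RNA* count whose distribution over cells is far more informative about
the underlying kinetics.

`burstkin` is for analysts of such pulse-labelled single-cell data (and for
simulation studies of the assay). It implements, end to end:

* the **transient telegraph-model PMF** — the probability of observing $n$
  labelled molecules after a window of length $t$ under the two-state model
  with rates $k_{on}$, $k_{off}$ (promoter switching), $k_{syn}$ (synthesis
  while on) and $k_d$ (degradation), with the promoter stationary and zero
  labelled molecules at $t=0$. Evaluated from the generating function along
  the characteristics of the master equation (a 2x2 ODE propagated by exact
  matrix exponentials) and inverted by FFT; an independent
  finite-state-projection oracle verifies it to ~1e-12 per entry,
* **per-gene kinetic inference**: summary statistics, lookup-table
  initialisation over the published 73 x 38 x 55 log-equidistant grid
  (~1.15x steps), bounded `L-BFGS-B` maximum likelihood, 50-fold bootstrap
  robustness flags, and split-half decorrelated analysis,
* derived quantities: occupancy $k_{on}/(k_{on}{+}k_{off})$, burst size
  $k_{syn}/k_{off}$, burst frequency $1/(1/k_{on}{+}1/k_{off})$, expression
  rate $k_{syn}\,k_{on}/(k_{on}{+}k_{off})$,
* an exact **Gillespie simulator** with per-molecule burst bookkeeping
  (which labelling windows catch single bursts?),
* **molecule-level new-RNA calling**: UMI read-group consensus, artifact
  masking, error-rate estimation, binomial-mixture EM for the conversion
  probability, likelihood-ratio new/old classification with exact power,
  and allelic genotyping for F1-cross data,
* **allele-resolved co-bursting statistics**: cis vs trans correlations by
  genomic distance, contingency tests, and implantation-based power,
* a seeded **synthetic-data generator** for every input the pipeline
  consumes, and a thin command line (`exec/burstkin`).

## Worked example

Simulate one bursty gene at fibroblast-like kinetics, then infer its
parameters back:

```r
library(burstkin)

truth <- kinetic_params(k_on = 1.5, k_off = 30, k_syn = 40, k_d = 0.065)
derived_kinetics(truth)
#> occupancy 0.04762 | burst size 1.333 RNAs | burst frequency 1.429 /h | expression rate 1.905 RNAs/h

pmf <- transient_pmf(truth, label_time = 2)
pmf
#> pulse PMF (characteristics): support 0..53, t = 2 h, 1 - sum = 6.12e-11
round(pmf$probs[1:6], 4)
#> [1] 0.1894 0.1448 0.1345 0.1175 0.0982 0.0792

sim <- gillespie_labelled(truth, label_time = 2, n_cells = 4000, seed = 1)
mean(sim$counts)          # analytic mean is 40 * 0.0476 * (1 - e^-0.13)/0.065 = 3.57
#> [1] 3.60575
single_burst_fraction(sim)
#>       frac_expressing single_burst_fraction
#>             0.8035000             0.3960797

tab <- build_lookup_table(lookup_grid_spec(n_kon = 25, n_ksyn = 8, n_koff = 10),
                          seed = 1)
fit <- infer_gene(sim$counts, tab, label_time = 2, k_d = 0.065,
                  seed = 2, n_boot = 20)
fit$estimates
#> telegraph kinetics: k_on=1.448 k_off=38.02 k_syn=52.4 k_d=0.065 (per hour)
fit$derived
#> occupancy 0.03669 | burst size 1.378 RNAs | burst frequency 1.395 /h | expression rate 1.923 RNAs/h
fit$bootstrap$robust
#>  k_on k_syn k_off
#>  TRUE  TRUE  TRUE
```

The PMF sums to one within 1e-10; the simulated mean matches the closed
form; and inference recovers the on-rate (1.45 vs 1.5) and burst size (1.38
vs 1.33 RNAs) with all three bootstrap robustness flags set. Individual
`k_syn`/`k_off` estimates carry more scatter than their ratio — the
distribution constrains them jointly much more strongly than separately;
see the methods vignette (`vignettes/bursting-inference.Rmd`) for the
identifiability analysis and for when to trust which quantity.

For shell use, the same functionality is exposed as subcommands:

```sh
burstkin pmf --kon 1.5 --koff 30 --ksyn 40 --kd 0.065 --time 2 --out pmf.tsv
burstkin synth --genes 50 --cells 2000 --seed 7 --out-prefix synth
burstkin infer --counts counts.tsv --lookup lookup.tsv --out inference.tsv
```

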
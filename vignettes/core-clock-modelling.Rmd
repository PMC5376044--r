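---
title: "Modelling the core circadian clock and its output genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the core circadian clock and its output genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(circatissue)
```

## The model

`circatissue` represents the cell-autonomous mammalian clock of peripheral
tissues with five mRNA species — *Bmal1*, *Rev-erbα*, *Per2*, *Cry1* and
*Dbp* — coupled through the three canonical circadian promoter elements.
Each gene obeys a delay-differential equation

$$\frac{dx_g}{dt} = d_g\,\bigl(M_g(t) - x_g\bigr),$$

where $d_g$ is the mRNA degradation rate (per hour) and $M_g$ the gene's
*production term*, a product of dimensionless **modulation factors**, one
per promoter-element class:

* **RRE (ROR element) repression** by REV-ERB:
  $(1 + a\,R(t-\tau_R))^{-n}$, with $n$ the number of functional ROR
  elements. *Bmal1* carries 3 RREs (strength `ar1`) and *Cry1* 2
  (strength `gr3`).
* **E-box regulation**: BMAL1 activates, PER2 and CRY1 repress
  competitively. The effective activator is
  $\hat B = b\,B(t-\tau_B) / (1 + a_P P(t-\tau_P) + a_C C(t-\tau_C))$ and
  the factor $\bigl((1 + f\hat B)/(1 + \hat B)\bigr)^{n}$, rising from 1
  to $f^{n}$. *Rev-erbα* and *Dbp* carry 3 E-boxes, *Per2* and *Cry1* 2.
* **D-box activation** by DBP: the same activating form with DBP as sole
  activator (one D-box on *Rev-erbα*, *Per2* and *Cry1*), plus an
  optional competing-repressor slot for E4BP4-like inputs, off by
  default.

Protein production, modification and nuclear import are not modelled
explicitly; each regulator acts after an **explicit delay** $\tau_g$
(hours between a gene's mRNA peak and its protein's regulatory action).
Pre-multiplying production by $d_g$ normalizes every species so that the
basal state (all factors at 1) is 1 — concentrations are in arbitrary
dimensionless units, and the modulator functions themselves are invariant
under a joint rescaling of strengths and levels.

E-box repressor strengths are gene-specific. This is deliberate: with
shared strengths every E-box factor peaks at the same time, but the
biology requires *Rev-erbα* (an immediate-early, activation-dominated
E-box target peaking near CT 6) to differ from *Dbp* (a
derepression-timed target peaking near CT 11). The free parameter vector
therefore has 19 entries (`clock_strength_names()`).

### Fixed parameters

Degradation rates and delays are taken as literature-scale constants and
held fixed during fitting, bounded to $d \in [0.05, 2]\,h^{-1}$ and
$\tau \in [0, 12]$ h. Defaults: $d$ = 0.18, 1, 0.15, 0.15, 0.12 per hour
and $\tau$ = 4.5, 2, 8, 4, 2 h for *Bmal1*, *Rev-erbα*, *Per2*, *Cry1*,
*Dbp*. These encode the timing biology the model must reproduce:
*Rev-erbα* is a fast-turnover immediate-early E-box target (its short
integration lag keeps its peak near the morning activation peak), the
2 h REV-ERB delay places maximal *Bmal1* repression near CT 8 and
repression *release* near CT 20 (which propagates to RRE-driven output
genes), the slow effective *Dbp* turnover contributes a ~3 h integration
lag toward its late-morning peak, and $\tau_{Per2} = 8$ h /
$\tau_{Cry1} = 4$ h place PER2 and CRY1 repressive action inside the
observed CT 15-4 E-box binding window (CRY1 action peaking near CT 0). Promoter-element counts (the exponents) are
config, not fitted; their defaults are declared assumptions, and every
property of the package holds for any positive counts.

## Integration

The equations are integrated by the method of steps with classical
fixed-step RK4 (`simulate_clock()`, default `dt = 0.05` h); delayed
lookups interpolate the accumulated solution grid with a 4-point cubic
Lagrange stencil. Because every coupling is delayed, stage evaluations
only ever read history that is already on the grid; the step size is
required to satisfy `dt <= min(tau)/4`. A delay of exactly zero is
treated as an instantaneous coupling, so the all-zero-delay limit of the
integrator is a plain ODE scheme — the test suite checks it against
`deSolve::ode` (relative error below $10^{-4}$) and the full delayed
model against `deSolve::dede`. The integrator lives in compiled code
(`src/clock_dde.cpp`) because the evolutionary fit needs thousands of
simulations; one 480 h simulation takes ~30 ms.

The default history is constant 1 for all species, and the first 240 h
(ten cycles) are discarded as transient before any descriptor is
measured. Halving `dt` moves peak phases by less than 0.05 h and the
period by less than 0.01 h on the default model.

## Rhythm descriptors and circadian time

`extract_rhythm_descriptors()` summarizes a post-transient trajectory the
way tissue time series are summarized experimentally:

* **period**: mean inter-peak interval of *Bmal1* (peaks refined by
  quadratic interpolation, ties at plateaus resolved to the earliest
  time);
* **peak phase** in circadian time: CT 0 is anchored by the upward
  mean-crossing of *Bmal1*, which is assigned CT 18 — for a
  near-sinusoidal *Bmal1* this puts its peak near CT 0, the canonical
  peripheral-tissue phase, and calibrates the fitted model so that
  *Rev-erbα* maps near CT 6. The anchor is a single offset stored with
  the fit and applied uniformly to all genes and to all output-gene
  phases; one cycle always maps to 24 circadian hours, whatever the
  free-running period;
* **relative amplitude**: $(\max - \min)/(\max + \min)$ over the last
  full cycle;
* **peak width**: contiguous time around the peak with the signal at or
  above the half-range level.

A solution with fewer than two reference peaks (or non-finite values) is
flagged as not oscillating rather than raising an error; sustained
oscillation additionally requires consecutive cycle amplitudes of the
reference gene to agree within 1%.

## Evolutionary fitting

Free strengths are estimated against `fit_targets()` — per-gene target
phase, relative amplitude and peak width plus a global period, each with
a tolerance (defaults: 1 h phase, 20% relative amplitude, 1 h width,
0.5 h period). Default weights are 2 for phases, 1 for period and
relative amplitude, 0.5 for widths — peak phases are the scientifically
primary descriptors, widths the least identifiable. The score is the
weighted sum of squared
tolerance-scaled deviations, with phase deviations on the shortest arc of
the 24 h circle; a non-oscillating candidate receives a declared penalty
of $10^6$. A damped-but-peaked solution is likewise penalized through the
sustained-oscillation flag, which keeps the elite on the limit-cycle
regime.

`evolutionary_fit()` repeats for a configurable number of rounds
(default 10): draw `population` candidate vectors log-uniformly within
the current per-parameter ranges, score each, keep the elite fraction
(default 5%), and set the next ranges to the elite min–max shrunk 20%
toward the elite best. The 20% shrink rate is a declared choice: it
narrows steadily without collapsing onto a single candidate. A round in
which every candidate is penalized restarts with twofold-widened ranges;
three consecutive such rounds abort the fit. Given a seed the whole
procedure is bit-reproducible.

The shipped default strengths (`default_clock_strengths()`) are a
converged fit against `default_fit_targets()` — the canonical liver-like
descriptor set with *Bmal1* at CT 0, *Rev-erbα* at CT 6, *Dbp* at CT 11,
*Per2* at CT 12 and *Cry1* at CT 20 — and serve as the initial center of
`default_strength_ranges()`. The phase targets for *Rev-erbα* and *Dbp*
and the 24 h period are the primary constraints; the *Per2* and *Cry1*
targets, and all target amplitudes and widths, are declared assumptions
chosen from canonical liver expression phases (high-amplitude sharp
peaks of *Rev-erbα*/*Dbp*, lower-amplitude *Bmal1*/*Cry1* rhythms).

`control_analysis()` perturbs every scalar parameter by ±5% and reports
central-difference log-sensitivities of the period and of each gene's
phase. On the fitted model the explicit delays rank among the strongest
period controls, alongside E-box and RRE transcription parameters.

## Clock-controlled genes

A CCG is one additional species driven by the fitted clock,
$dC/dt = d_{CCG}(M_C(t) - C)$, with $M_C$ a product of any subset of the
three modulators evaluated on delayed clock species. Because the
equation is linear given the clock, it is integrated exactly on the
clock grid with an exponential step (production treated as linear within
each step).

`sample_ccg_population()` draws gene-to-gene variability:

* $d_{CCG}$ uniform in 0.2–0.6 per hour (typical mRNA turnover);
* promoter strength expressed as the dimensionless *occupancy* of the
  element at the driver's geometric mid level and sampled log-uniformly
  over 0.1–10, two decades straddling half-occupancy. The fitted core
  model's species settle at very different absolute scales, so raw
  strength constants are not transferable between promoters; the
  occupancy (strength × driver level) is the quantity with meaning,
  and sampling it keeps every modulation factor in its responsive
  range;
* driver action delay sampled around the delay of the matching core
  regulator — REV-ERB's delay ±1 h for RRE drivers, the range spanned
  by the three E-box regulators' delays for E-box drivers, and the ~2 h
  DBP action delay ±1 h for D-box drivers — a single delay per driver,
  applied to all of the driver's species;
* activation folds log-uniform in 2–10, and (by default) gene-specific
  E-box repressor strengths sampled on the same occupancy scale,
  reflecting promoter-to-promoter variation in PER/CRY sensitivity.

Flat outputs (relative amplitude below $10^{-3}$) are excluded and
counted, never silently dropped. Phase distributions are summarized by
the circular mode over 4 h bins with 3 h overlap, matching the
histogramming used for experimental phase distributions. The mechanism
chain — *Rev-erbα* peak at CT 6, delayed repression, release at the
opposite phase ~CT 20, plus one to three hours of decay lag — clusters
RRE-driven genes around CT 0; E-box-driven genes cluster near CT 10 and
D-box-driven genes near CT 15.

## Harmonics

`harmonic_product()` is the minimal model of combinatorial regulation by
two out-of-phase sinusoidal regulators,
$(1 + \sin\omega t)(1 + A\sin(\omega t + \alpha))$. Its expansion
contains a $-\tfrac{A}{2}\cos(2\omega t + \alpha)$ term: for $A$ near 1
and $\alpha = 180^\circ$ the fundamental cancels and a pure 12 h rhythm
remains. `dominant_period()` detects this by restricted Fourier analysis
at the harmonics of 24 h. The same mechanism operates inside the full
model: an output gene driven by matched-strength, out-of-phase E-box and
D-box factors produces 12 h profiles.

## Rhythm detection in expression matrices

`biharmonic_fit()` regresses
$y = m + a_1\cos\omega t + b_1\sin\omega t + a_2\cos 2\omega t +
b_2\sin 2\omega t$ and tests the four rhythm coefficients jointly
against the intercept-only model (F test, df 4 and $N-5$). Intercept-only
(rather than 24 h-only) is the declared null, so the test is sensitive to
both circadian and harmonic structure. The peak phase is the argmax of
the full fitted curve — not of the 24 h component alone — so that
12 h-dominated profiles get meaningful peaks; under noise this argmax
phase is slightly wider than the fundamental's phase, which the test
suite quantifies. Relative amplitude is fitted peak-to-trough over twice
the fitted mean (declared definition).

`classify_rhythmic()` applies three strict filters: maximum expression
above a platform cutoff (600 liver-style, 500 adrenal-style), p below
0.01, relative amplitude above 0.3. No multiple-testing correction is
applied, by design. `top_by_amplitude()` ranks by relative amplitude
with deterministic lexicographic tie-breaks, and
`circular_phase_histogram()` counts each phase into four half-open
overlapping bins (`[center-2, center+2)`), so histogram mass is exactly
$4n$.

## qPCR normalization

`normalize_qpcr()` converts Cp values to quantities with the per-primer
amplification efficiency ($\mathrm{eff}^{-C_p}$), divides each sample by
the geometric mean of three reference genes, and rescales per gene to
its maximum or mean. Rescaling is applied after reference normalization;
the two orders differ only by a per-gene constant, which the rescaling
removes. Samples missing a reference gene are dropped with a warning.

## TFAS

`assign_peaks_to_genes()` links every peak to every gene on the same
chromosome whose start-codon first base lies strictly within 5 kb of the
peak center (unstranded absolute distance — strand handling is a
declared choice), and
`compute_tfas()` scores each gene as
$\sum_{\text{peaks}} s_i\,e^{-d_i/d_0}$ with $d_0 = 500$ bp.
`build_target_sets()` applies strict per-factor cutoffs (10 and 0.5) and
returns exclusive and joint target sets; replicate peak files for one
factor are combined by a union rule (a gene is a target if it passes in
any replicate), another declared choice. File I/O goes through
`rtracklayer`; the interval queries themselves are plain sorted-vector
searches so that half-integer peak centers keep the strict distance
inequality exact, and they are tested against a brute-force all-pairs
oracle.

## Synthetic data

All pipeline inputs can be generated with known ground truth:
`generate_expression_matrix()` plants cosines (optionally with a 12 h
component) under multiplicative lognormal noise (default CV 10%,
microarray-like, rather than additive Gaussian) on a 2 h / 24 h / 4
replicate design; the default planted phase distribution is a bimodal
von Mises mixture near CT 0 and CT 10, mimicking peripheral-tissue phase
histograms. `generate_qpcr_dataset()` inverts the qPCR normalization,
and `generate_annotation_and_peaks()` plants factor-target memberships
with exponential peak–gene distances (mean 1 kb) and scores calibrated
to clear (or, for decoys, stay below) the TFAS cutoffs. Synthetic genes
are spaced > 10 kb so planted peaks cannot contaminate neighbours.

These generators emulate the *shapes* of real designs; they do not model
probe cross-hybridization, platform-specific intensity distributions,
read-level ChIP-seq noise, or non-sinusoidal waveforms beyond the second
harmonic. Passing the planted-truth tests therefore demonstrates
correctness of the computations, not performance on any particular real
platform.

## Problem sizes and reproducibility

The package's own acceptance analysis (`scripts/acceptance.R`) refits
the clock at a reduced budget (population 500, 6 narrowing rounds) and
simulates three 250-gene CCG populations; the full-budget fit used to
produce the shipped defaults ran with population 3000 and 10 rounds.
All stochastic steps take explicit integer seeds, and identical seeds
reproduce results bit-for-bit.

## Known limitations

* The five-gene wiring places *Dbp* at about CT 9–9.5 rather than the
  observed CT 11: *Dbp* shares its E-box activator with *Rev-erbα* and
  carries no D-box, so once *Rev-erbα*'s immediate-early timing is
  fixed, *Dbp* can trail it only by its integration lag. Extensive
  searches over the free strengths (and several fixed-parameter
  structures) saturate at this offset; the corresponding acceptance
  check is expected to fail by a fraction of an hour and is left
  failing deliberately.
* Proteins are not explicit: phenomena that depend on protein dynamics
  beyond a fixed lag (complex formation, stoichiometric buffering) are
  outside the model.
* Bifurcation structure is explored only by parameter sweeps, not by
  continuation methods.
* The evolutionary strategy is a global random search; it makes no
  identifiability claims, and distinct near-optimal parameter sets can
  produce indistinguishable descriptors.
* Desk-scale synthetic stand-ins replace genome-scale expression and
  ChIP-seq data, so genome-scale counts (numbers of targets, overlap
  sizes) are out of scope.
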
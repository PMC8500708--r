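---
title: "Compartmentalized 13C-MFA of extracellular citrate metabolism: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compartmentalized 13C-MFA of extracellular citrate metabolism: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(citflux)
```

## Scope

`citflux` implements the computation stack for stationary, compartmentalized
carbon-13 metabolic flux analysis (13C-MFA) of hepatoma cells that import
extracellular citrate through the plasma-membrane transporter NaCT/SLC13A5,
together with the surrounding isotope-tracing arithmetic: mass isotopomer
distributions (MIDs) and mole percent enrichment (MPE), natural-abundance
correction of GC-MS fragments, isotopomer spectral analysis (ISA) of de novo
lipogenesis, extracellular flux determination from media time courses, and
seeded synthetic-data generation so that every estimator can be validated
against known ground truth without any external data.

All fluxes carry the units nmol per 10^6 cells per hour.

## The network model

The bundled model (`builtin_huh7_hypoxia()`) describes central carbon
metabolism of proliferating Huh7 cells in hypoxia with 500 uM extracellular
citrate. Five modeling assumptions are encoded structurally:

1. *Metabolic and isotopic steady state* — fluxes satisfy `S v = 0` over all
   balanced metabolites, and labeling is simulated at its stationary point.
2. *Exponential growth* — used by the extracellular-flux module to integrate
   cell number over the culture interval.
3. *CO2 is a dilute, unlabeled pool* — decarboxylation products leave the
   system; carboxylation reactions (pyruvate carboxylase, reductive
   IDH/aconitase) draw unlabeled carbon. CO2 is an unbalanced sink/source.
4. *Compartmentation* — separate mitochondrial and cytosolic pools of
   aspartate, oxaloacetate, malate, fumarate, alpha-ketoglutarate, citrate,
   glutamate, pyruvate and acetyl-CoA, with inter-compartment exchange
   transporters for exactly malate, aspartate, glutamate,
   alpha-ketoglutarate and citrate.
5. *Biomass drain* — a lumped drain on GAP, pyruvate, aspartate, glutamate,
   glutamine and palmitate with generic mammalian-cell coefficients,
   overridable in the model file.

### Atom maps and citrate carbon numbering

Atom transitions are written as letter strings, one lowercase letter per
carbon, with conservation of the letter multiset enforced by the validator.
Citrate carbons are numbered so that

* ATP-citrate lyase (ACLY) cleaves citrate into the acetyl unit (citrate
  carbons 1–2) and oxaloacetate (carbons 3–6), and citrate synthase uses the
  exact inverse map (`OAA (abcd) + AcCoA (ef) -> Cit (efabcd)`), so the
  CS-then-ACLY composite restores every atom to its source position;
* the two oxidative decarboxylations of one TCA turn remove citrate carbon 6
  (isocitrate dehydrogenase) and citrate carbon 3 (alpha-ketoglutarate
  dehydrogenase) — both oxaloacetate-derived carbons.

These two constraints pin the behavior of the [2,4-13C2]citrate tracer: ACLY
cleavage puts one label on acetyl-CoA (position 2) and one on oxaloacetate
(position 4 = OAA carbon 2), generating M1 species; the mitochondrial route
(SLC25A1 import, IDH2, alpha-KGDH) retains both labels through to M2
succinate, fumarate and malate. The published work states these labeling
rules; the letter-level maps are chosen here to satisfy them, since the
original reaction list is not printed. The builtin model is therefore a
constrained reconstruction, not the deposited model.

Succinate and fumarate are symmetric molecules: every reaction producing
them is split into two half-weight variants with mirrored atom maps (50/50
scrambling), the standard device that makes the M1/M2 arithmetic correct
without special cases in the simulator. Citrate is treated as prochiral (no
scrambling at aconitase). Glycolysis is lumped (glucose -> 2 GAP -> pyruvate)
with the canonical C1–C3 reversal on the DHAP-derived triose; no
pentose-phosphate branch is modeled because the study's measurement set does
not resolve it — the model file format permits adding one. Fatty-acid
oxidation is bundled as a bounded free flux (palmitate -> 8 mitochondrial
acetyl-CoA), since the original work lists FAO in its network without
stating whether it was free or fixed.

### Model files

Models serialize to a YAML dialect with one mapping per reaction (`id`,
`eq`, optional variant list with `weights`, `reversible`, `bounds`);
`parse_model()` and `serialize_model()` are exact inverses, and the bundled
`inst/extdata/huh7_hypoxia.yaml` file is byte-identical to the serialized
builtin constructor.

## EMU simulation

`simulate_mids()` predicts steady-state fragment MIDs by elementary
metabolite unit (EMU) decomposition: starting from the measured fragments,
each product EMU is traced through every atom-map variant (both directions
for reversible reactions) to its source EMUs, and the resulting balances are
solved size-by-size as small dense linear systems — the balance matrix at
each size depends only on fluxes, so one LU factorization serves all
parallel tracer experiments. Reversible reactions enter as forward/backward
rate pairs `fwd = exchange + max(net, 0)`, `bwd = exchange + max(-net, 0)`,
with the exchange flux expressed directly in flux units and capped at 10^4
(a plain, unit-preserving alternative to the [0,1) ratio transform that
keeps profile confidence intervals interpretable). The decomposition of the
builtin model tops out at EMU size 6 (citrate); palmitate is deliberately
not part of the MFA measurement set — lipogenesis is handled by the
standalone ISA module — which keeps the cascade small.

A brute-force oracle (`brute_force_mids()`) tracks complete positional
isotopomer distributions (2^n states per metabolite) and solves the same
steady state by damped Gauss–Seidel iteration to 10^-13; it is capped at 24
balanced carbons by default and exists purely to verify the EMU path, which
it matches to better than 10^-9 across randomized toy networks and flux
draws in the test suite.

Tracer purity is handled at the substrate definition: the labeling state is
a molecule-level mixture of the pure pattern (purity x mixture fraction)
with unlabeled substrate for the remainder. Simulated MIDs live on the
tracer-only (natural-abundance-corrected) scale.

## Natural-abundance correction

GC-MS measures the derivatized ion, so every atom outside the
tracer-labeled backbone contributes naturally occurring heavy isotopes —
including the silicon and carbon of tBDMS derivatization groups.
`correction_matrix()` builds, per fragment, the lower-triangular matrix
whose column *j* is the predicted measured MID of a species with exactly *j*
labeled backbone carbons, from the full elemental formula and a standard
terrestrial isotope table (overridable). `correct_na()` inverts it by
non-negative least squares and renormalizes; NNLS keeps corrected MIDs valid
distributions even when the measurement window truncates the heavy tail.
Whether the original in-house correction included Si isotopes is not stated;
full-formula correction is the default here. The forward-contaminate /
correct round trip recovers MIDs to 10^-8 on the bundled tBDMS formulas.
All downstream fitting consumes corrected MIDs.

## Flux estimation

`fit_fluxes()` minimizes the variance-weighted SSR of all tracer
experiments jointly (parallel experiments share one flux vector, matching
the study design) over

* net fluxes, parameterized on an orthonormal null-space basis of the
  stoichiometric matrix (steady state holds exactly by construction), with
  bound violations penalized; and
* exchange fluxes, box-bounded in `[0, 10^4]`.

MID entries are weighted by replicate SDs floored at 0.003 mole fraction
(the study reports no measurement-error model; 0.003 is a typical GC-MS
repeatability figure), and measured extracellular fluxes (glucose, lactate,
glutamine, glutamate, citrate) enter as additional weighted residuals.

The optimizer is Levenberg–Marquardt from multiple seeded random feasible
starts (default 25, seed 17). On this objective LM can satisfy its
step-size test inside curved valleys while the gradient is still large, so
each start is polished by an LM/gradient-kick loop: when LM stalls, a
coarse line search along the negative gradient relocates the iterate and LM
restarts, until the SSR stops improving. Degrees of freedom count
independent residuals (MID entries minus one sum constraint per fragment,
plus flux measurements) minus free parameters.

`goodness_of_fit()` applies the standard chi-square acceptance band;
`profile_ci()` computes profile-likelihood 95% intervals by stepping a
single net or exchange flux, re-optimizing all others, and bisecting the
SSR crossing at the chi-square-1 threshold (3.84), flagging directions that
reach the flux bounds as unbounded — non-identifiable fluxes are reported
as such rather than silently clipped. `identifiable_fluxes()` flags local
identifiability from the singular structure of the residual Jacobian at the
optimum.

## Isotopomer spectral analysis

ISA models palmitate as 8 condensations of acetyl-CoA drawn from a
two-component pool: a fraction `D` from the tracer-derived acetyl species
and `1 - D` unlabeled; a fraction `g` of the palmitate pool is newly
synthesized during the trace. The tracer acetyl MID is an explicit input —
`c(0, 0, 1)` for [U-13C]glucose/glutamine-derived acetyl, `c(0, 1, 0)` for
[2,4-13C2]citrate-derived acetyl — which keeps ISA standalone rather than
coupled to the network model, matching how it is used condition-by-condition
on fatty-acid data. Stearate is supported through the chain-length argument
(9 condensations). Because ISA operates on NA-corrected MIDs, both the
unlabeled acetyl component and pre-existing fatty acid are pure M0.
`isa_fit()` is a bounded two-parameter weighted least-squares fit seeded
from a coarse grid (deterministic for fixed data); `isa_ci()` profiles each
parameter to the chi-square-1 threshold, clipped to [0, 1]. Significance
between conditions uses the CI non-overlap rule, the convention used for
ISA figure comparisons. An all-M0 measurement pins `g = 0` and flags `D`
unidentifiable.

## Extracellular fluxes

`uptake_flux()` converts start/end media concentrations and cell counts
into per-cell fluxes, integrating cell number exponentially:
`flux = V (C0 - CT) / integral(N dt)` with `integral = (NT - N0) / mu`, and
the `N0 T` limit at zero growth (the estimator is continuous there). Uptake
is positive, secretion negative, stated in all outputs. Exponential
integration (rather than endpoint averaging) is adopted as the variant
consistent with the exponential-growth assumption. Evaporation and
media-swap corrections are not modeled. `standard_curve_concentration()`
provides ordinary linear calibration with extrapolation flags.

## Synthetic data: the simulated study conditions

The generators define the conditions under which the package validates
itself:

* `synth_mfa_dataset()` runs the three parallel tracer experiments
  ([U-13C6]glucose, [U-13C5]glutamine, [2,4-13C2]citrate) at a true flux
  vector, adds truncated Gaussian noise per MID entry (default SD 0.003,
  truncate at 0, renormalize — keeping outputs valid MIDs), and emits
  replicate means and SDs over 3 replicates, mirroring the study's
  triplicate design, plus noisy extracellular flux measurements (5%
  relative SD, floored at 1 flux unit).
* The default ground truth (`default_huh7_fluxes()`) is a feasible
  steady-state vector chosen once to match the reported hypoxic phenotype
  qualitatively: high glycolysis with most pyruvate leaving as lactate,
  reduced PDH flux, glutamine as the dominant lipogenic substrate, active
  citrate uptake catabolized in the cytosol by ACLY and cytosolic
  aconitase/IDH with high cytosolic exchange flux, active pyruvate cycling
  through both malic enzymes, and a small fatty-acid oxidation flux. It is
  constructed by least-squares projection of target values onto the
  steady-state manifold, so the stored truth reproduces the noiseless data
  exactly.
* `synth_isa_dataset()` and `synth_timecourse()` mirror the ISA and media
  measurements the same way.

What the generators do *not* emulate: chromatogram-level artifacts
(overlapping peaks, baseline drift), biological replicate-to-replicate
variability beyond additive noise, compartment-mixed measurements (each
fragment is assigned to the compartment pool expected to dominate the
whole-cell signal — real GC-MS sees the mixture), media evaporation, and
non-stationary labeling. Passing tests therefore demonstrate correctness of
the estimators under the stated statistical model, not robustness to every
real-data pathology.

## Numerical choices and problem sizes

* EMU balances: dense LU per size; degenerate (zero-inflow) pools raise
  errors naming the metabolite rather than returning NaNs.
* Brute-force oracle: Gauss–Seidel to 10^-13, error on non-convergence.
* NNLS for NA correction; correction matrices with condition number above
  10^10 are rejected.
* Profile CI bisection: 10^-3 relative tolerance, at most 60
  re-optimizations per direction.
* Multistart default: 25 starts, seed 17; noise-free validation runs use
  fewer starts because the first SSR < 10^-8 optimum terminates the search.
* The test suite's simulation studies use a compact branch-and-dilution
  network (7 reactions) for repeated-fit studies — profile-CI coverage over
  50 seeded datasets and the E[SSR] ~ dof check — and the full builtin
  Huh7 network for single noise-free recovery, route-signature and
  oracle-equivalence checks. These sizes are the package's validation
  choices; the estimators themselves have no size-specific code paths.

### Coverage under the truncate-and-renormalize noise policy

Two properties of the replicate noise model bound the attainable coverage
of the profile intervals. First, MID entries that are exactly zero at the
truth acquire a systematic ~0.7 sigma bias from truncation at zero, so
coverage studies are run at mixed-label conditions where all entries are
interior. Second, renormalizing each replicate to unit sum induces
negative within-fragment correlations that the independent-entry weighting
ignores; empirically this leaves the estimator's sampling SD some 15%
above what the profile curvature implies, and interval coverage near
88–91% rather than the nominal 95%. The validation suite asserts coverage
within the binomial tolerance band around the nominal level.
Correlation-aware weighting (a full within-fragment covariance) would
close the gap but changes the residual definition and is left out of
scope.

## Known limitations

* The builtin network is a reconstruction constrained by the published
  labeling rules and network scope, not the deposited reaction list; fitted
  values on real data will differ from the original study's.
* Measured fragments map to single compartment pools (see above).
* No isotopically non-stationary MFA, no pool sizes, no thermodynamic
  constraints, no deuterium or 15N tracers, and no genome-scale models.
* ISA is single-source (one tracer-derived acetyl species); multi-source
  ISA is out of scope.
* Exchange fluxes are often structurally weakly identified; they are
  reported with unbounded profile intervals where appropriate rather than
  hidden.

## A worked end-to-end example

```{r example, eval = FALSE}
net <- builtin_huh7_hypoxia()
truth <- default_huh7_fluxes(net)

# three parallel labeling experiments, noise-free
ds <- synth_mfa_dataset(net, truth, noise_sd = 0, seed = 1)

fit <- fit_fluxes(net, ds$data, n_starts = 10, seed = 17)
fit$ssr                      # ~0 for noise-free data
goodness_of_fit(fit)$note    # flags the sub-noise SSR

ci <- profile_ci(fit, "CIT_UP")          # citrate uptake 95% CI
idf <- identifiable_fluxes(fit)

# ISA on synthetic palmitate data from the citrate tracer
isa_ds <- synth_isa_dataset(D = 0.25, g = 0.6, acetyl_mid = c(0, 1, 0),
                            noise_sd = 0.003, seed = 2)
isa <- isa_fit(isa_ds$values, isa_ds$sd, acetyl_mid = c(0, 1, 0))
isa_ci(isa)
```
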
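---
title: "Digital-twin drug screening: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital-twin drug screening: models, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinscreen)
```

## The problem

High-risk pediatric liver tumors (hepatoblastoma and related entities) are
overwhelmingly Wnt/β-catenin-driven: most tumors carry activating *CTNNB1*
mutations and show strong MYC-program activity. `twinscreen` implements a
desk-scale version of the digital-twin drug-discovery idea for this setting:
individualize a mechanistic ODE model of the relevant signaling network per
patient from expression data, simulate targeted drugs to steady state under
parameter uncertainty, and rank compounds by how selectively they suppress
the tumor twins while sparing the normal-tissue twins. The package also
implements the companion in vitro analytics used to validate such
predictions on drug-testing platforms (4PL/IC50/AUC fits, AUC z-scores,
therapeutic window scores, Bliss synergy, and simple morphometric and
growth formulas).

## The mechanistic network

Full proprietary-scale signaling models cover hundreds of genes; what is
reproducible as open methodology is the *procedure*, not that
parameterization. `twinscreen` therefore ships a reduced, curated network
(33 species, `build_reference_network()`) covering exactly the pathway arms
the biology of this tumor type demands:

* **Wnt arm** — a clamped `CTNNB1` input species activates TCF/LEF, which
  drives the inducible MYC supply; `LGR5`, `DKK1`, `NKD1` are Wnt-target
  reporters.
* **RAS/MAPK arm** — a growth-factor tone input (`GF`) drives
  RTK → RAS → ERK.
* **PI3K/AKT/MTOR arm** — RTK and FAK activate PI3K → AKT → MTORC1, which
  suppresses caspase activation (anti-apoptotic tone).
* **Hedgehog arm** — SHH/GLI1, present and taggable but not a default
  readout.
* **Apoptosis arm** — pro-Caspase-3 is activated constitutively and
  re-inactivated by AKT and MTOR activity.
* **Readouts** — the nuclear MYC:MAX complex (`MYC_MAX_nuc`, pro-viability)
  and active Caspase-3 (`CASP3_act`, pro-death).

Six rate-law kinds cover the topology (`synthesis`, `degradation`,
`mass_action_activation`, `michaelis_menten`, `complex_formation`,
`complex_dissociation`); every "activation" is a modifier-catalyzed
conversion between an inactive and an active species form, so a kinase's
*activity* (its active-form concentration times the catalytic constant) is
the thing a drug can attenuate. Units are arbitrary concentration and time
units; only drug concentrations carry nM.

### Nominal parameterization

Degradation rates are all 1/time. Synthesis rates of gene representatives
are chosen so every representative sits at 1 a.u. in the unactivated model,
which makes the patient-specific synthesis multipliers act on a
self-normalized baseline. Activation/deactivation constants (k_cat 4 for
cascade steps, split 2 + 2 where a node has two upstream routes, 1.5 for the
shallower TCF/LEF and GLI1 steps) put baseline cascade activities near one
half at the default growth-factor tone of 0.5, i.e. in the responsive middle
of their range.

One structural choice matters for drug ranking and is deliberate: the
inducible MYC supply is split into an **MTOR-gated half** (cap-dependent
translation of the Wnt/MYCN-driven program) and an **ERK-gated half**
(ERK-stabilized MYC). Collapsing the oncogenic MYC program therefore
requires hitting more than one kinase node simultaneously. This encodes the
biology that made a multi-kinase inhibitor the headline hit — single-node
MEK or MTOR inhibition stays partial, while a compound that engages FAK,
MTOR, AKT and ERK together removes both gates and lets the caspase arm rise
at the same time.

## Patient individualization (digital twins)

Expression counts are normalized per sample to counts-per-million and
log2(x+1)-transformed. The cohort reference is the per-gene **median over
the normal samples**. For each gene-representative species the synthesis
multiplier is the linear-scale ratio

> scale(g) = clip( (CPM_patient(g) + 0.5) / (CPM_reference(g) + 0.5),
> 0.1, 10 )

with the pseudocount of 0.5 CPM guarding low counts and the clip bounds
preventing degenerate synthesis rates. Genes missing from a profile fall
back to scale 1 with a warning.

*Which* species are gene representatives is a modeling decision. The
kinase-cascade pools (RTK, RAS, ERK, FAK, PI3K, AKT, MTOR) and TCF/LEF keep
fixed totals: their signaling activity is dominated by post-translational
regulation, and tying their protein totals to noisy transcript ratios lets
per-gene measurement noise swamp the class signal (in early experiments a
single low TCF/LEF ratio could erase a tumor twin's entire Wnt arm).
Individualization attaches instead to the transcriptionally driven nodes:
MYC, MYCN, MAX, CASP3, and the reporters LGR5, DKK1, NKD1, CAD, NPM1, SHH,
GLI1.

Activation inputs follow a cohort policy (`default_activation()`): the
CTNNB1/Wnt input is clamped at 1.0 for *CTNNB1*-mutant tumors, 0.6 for
other tumors (Wnt activation through other lesions), and 0.2 baseline tone
for normal liver; the growth-factor tone is 0.5 for every twin. These
levels are configuration, not biology-derived constants: the class contrast
(mutant tumor ≫ normal) is what matters downstream.

## Drugs, steady states and Monte Carlo

A drug is a set of (target species, kD) pairs. At concentration C every
reaction in which a target acts as modifier has its catalytic constant
scaled by the single-site occupancy factor **φ = 1 / (1 + C/kD)**;
multi-target compounds multiply their factors. Drugs never delete
reactions, and a target absent from the network simply leaves the model
untouched (a warning notes the skip) — this is how the deliberately inert
ALK-surrogate compound of the synthetic panel behaves on an ALK-negative
network.

Steady states are found by a damped Newton iteration with analytic
Jacobians (compiled code), guarded by pseudo-transient continuation, from
the twin's initial state with inputs clamped; the residual criterion is
`max_i |dx_i/dt| / (|x_i| + 1e-9) < 1e-8`. An independent route —
`deSolve::lsoda` integration until the residual stays below tolerance over
a probe window, then Newton polishing — is available via
`method = "integrate"` and agrees with the direct route to well below 1e-6;
the test suite cross-checks the two and also checks the compiled right-hand
side against the reference R implementation (`evaluate_rates()`).

Parameter uncertainty follows a log-normal Monte Carlo: each run multiplies
every kinetic parameter by 10^z, z ~ Normal(0, σ) with σ = 0.1 log10 units
by default, 1000 runs by default. One run is **one sampled parameter set**,
keyed deterministically by (master seed, sample, drug, run) and reused at
the control and at every concentration of that drug, so treated-versus-
control comparisons are paired. Relative viability is computed **per run**
as

> ρ = max(0, (pos_C/pos_0 − λ·neg_C/neg_0) / (1 − λ)),   λ = 0.5

(positive readout MYC:MAX, negative readout active Caspase-3, each
normalized to the same run's control) and the curve reports the median of ρ
across converged runs. The paired per-run estimator matters: forming ρ from
the ratio of two independent medians has several Emax points of noise at
moderate run counts, while the paired median is stable to about one point
at 100 runs. Non-converged runs are dropped and counted, never imputed.
The λ weight, the division count, σ, the grid and the run count are all
exposed configuration.

Curves are summarized by:

* **Emax** = 100·(1 − min ρ), with the 50% cutoff *inclusive* for the
  "potentially effective" flag;
* **EC50** = first log10-interpolated crossing of half-maximal inhibition,
  undefined for flat curves;
* **GR metrics**: interpreting ρ as the treated/control cell-count ratio
  with control fold-growth 2^n_div per assay window, GR = 2·ρ^(1/n_div) − 1,
  an affine GR = 2ρ − 1 at the default n_div = 1. GR50 is the first
  crossing of GR = 0.5, GRmax the minimum GR. The steady-state simulation
  has no time axis, so n_div is a declared convention rather than a
  measured division count — the GR numbers are per-division surrogates.

`rank_drugs()` scores each compound by **selectivity** = mean tumor Emax −
mean normal Emax, with ties broken by tumor Emax and then name.

## The synthetic cohort generator

`generate_cohort()` emulates the study conditions: 13 tumor and 8 normal
profiles; *CTNNB1* mutation flags on 11 of 13 tumors; a Wnt/MYC signature
(LGR5, DKK1, NKD1, MYCN, CAD, NPM1) upregulated in tumors by a mean log2
fold change of 3 with 0.5 log2 units of per-sample noise; log-normal
baseline means and integer counts. The 20-compound panel
(`generate_panel()`) contains one ceritinib-like multi-kinase compound
(FAK/MTOR/AKT/ERK targets at kD 50 nM), single-target comparators with
log-uniform kDs in 1–1000 nM, one absent-target ALK surrogate, and two
present-but-noncatalytic decoys; a ground-truth table records each
compound's intended effect class. Plate and synergy-grid generators retain
their generating parameters so every analytic can be tested against known
truth.

What the generator does *not* emulate: RNA-seq count dispersion beyond
log-normal noise, batch effects, histology-specific expression programs,
intratumoral heterogeneity, or any pharmacokinetics. Passing tests on this
cohort demonstrate that the pipeline recovers constructed signal under
realistic noise — not that the reduced network predicts real patients.

## Numerical choices and degenerate inputs

* Newton steps are projected to the non-negative orthant and damped by
  halving; failure falls back to pseudo-transient continuation and, at the
  R level, to stiff integration.
* EC50/GR50 interpolation is linear in log10 concentration, the standard
  choice for log-spaced grids; a crossing at the first grid point returns
  that point.
* A drug touching no reaction short-circuits to an exactly flat curve
  (ρ ≡ 1), since its perturbed model is the control model.
* 4PL fits (`fit_4pl()`, Levenberg–Marquardt via minpack.lm) are
  initialized from the data, bounded (top ∈ [0.5, 1.5], bottom ∈ [0, 1],
  hill ∈ [0.1, 10], IC50 within a tenfold margin of the dose range), and
  report the relative (midpoint) IC50; plates with no viability decrease
  return a `no_inhibition` warning with IC50 pinned at the upper bound.
* AUC is the trapezoidal integral of mean viability over log10 dose,
  normalized by the log10 span, so a flat plate at viability v scores v.
* z-scores use the sample (n−1) standard deviation and error out on
  degenerate (constant-AUC) panels; the Bliss score is 100 × the mean
  excess over the 3×3 combination block of a 4×4 grid.
* The wound-closure formula is read as percent closure,
  100·(gap0 − gap1)/gap0, the only bracket placement that yields a
  percentage.

## Problem sizes used in the shipped checks

The default Monte Carlo depth is 1000 runs. The packaged verification
scripts exercise scaled-down versions chosen as representative desk-scale
workloads: the end-to-end screen check uses 6 twins × 5 drugs × 100 runs
over 20 master seeds; the acceptance script runs the full 21-twin ×
20-drug screen at 100 runs; 4PL recovery uses 200 plates at noise SD 0.05
with 3 replicates and 10 doses. The null-cohort check verifies both that
exchangeable twins (no expression signal or noise, equal activation) show
selectivity within Monte Carlo noise in every seed, and that with
generator noise restored the per-drug selectivity averages to zero across
seeds — individual noisy seeds wobble by finite-cohort sampling, which is a
property of 13-vs-8 designs, not of the pipeline.

## Known limitations

* The reduced network is a surrogate: equivalence with any proprietary
  large-scale model's outputs cannot be asserted, only procedural fidelity.
* Activation encodings (1.0/0.6/0.2) and the readout combination weight λ
  are conventions exposed as configuration; results should be read as
  class contrasts, not absolute potencies.
* GR metrics use the affine steady-state surrogate described above.
* Morphometry operations consume already-measured geometric quantities;
  there is no image processing.
* AUC normalization is package-specific; values are not comparable to
  curve-fitting software using other conventions.
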
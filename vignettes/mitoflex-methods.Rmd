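---
title: "Modelling muscle beta-oxidation flexibility: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling muscle beta-oxidation flexibility: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoflex)
```

## The scientific question

Skeletal muscle takes up most postprandial glucose, and lipid
accumulation in muscle is a key driver of insulin resistance. Two
mechanisms compete to explain intramuscular lipid accumulation under a
high-fat diet: dietary lipid overload and an age-related decline of
mitochondrial fat oxidation. `mitoflex` implements the computational
toolchain needed to study their interaction in a 2x2 age-by-diet mouse
design: a per-animal kinetic model of mitochondrial long-chain fatty-acid
beta-oxidation parameterised from targeted proteomics, metabolic control
analysis (MCA) on top of it, insulin-sensitivity indices from oral
glucose tolerance tests (OGTT), and the lipidomics/proteomics statistics
used to detect diet- and age-dependent remodelling.

## The kinetic model

### Structure

Palmitoyl-CoA (C16) enters via carnitine palmitoyltransferase 1B
(CPT1B), is imported as C16-acylcarnitine by a lumped
CACT/CPT2 step, and is chain-shortened in repeated cycles of
dehydrogenation (VLCAD, LCAD, MCAD, SCAD with overlapping chain-length
specificities), hydration plus oxidation (one lumped hydratase/HAD
step), and thiolysis (MTP for long chains, MCKAT for medium and short
chains). Each cycle releases one acetyl-CoA; the final C4 cleavage
releases two, so one C16 yields eight acetyl-CoA over seven cycles. At
steady state the flux balance is therefore `8 J = v_sink`, with
`J` the CPT1B rate — the pathway flux readout. Acetyl-CoA drains through
a first-order sink that regenerates free CoA (a stand-in for citrate
synthase/TCA demand, which is out of scope).

Rate laws are irreversible Michaelis-Menten forms. Multi-substrate
enzymes share one competitive denominator over their chain mask,
`v_el = Vmax_e (S_l/Km_el) / (1 + sum_l' S_l'/Km_el')`, so chain-length
competition — the mechanism that lets control shift downstream under
substrate load — is retained. CPT1B carries competitive malonyl-CoA
inhibition (`M/Ki` in the binding denominator) and competitive product
inhibition by C16-acylcarnitine (`AC16/Ki_ac`).

Two moieties are conserved: CoA (free CoA, all acyl/enoyl/ketoacyl-CoA
esters, acetyl-CoA) and carnitine (free carnitine plus
C16-acylcarnitine). The package treats carnitine as a single
exchangeable pool: CPT1B consumes free carnitine, the import step
returns it. This satisfies the conservation invariant exactly and makes
the pool a genuine finite resource; the often-quoted "clamped 2 mM
cytosolic carnitine" picture is represented by the pool total (default
500 uM, near-saturating for the default `km_carnitine` = 125 uM).

### Why product inhibition and asymmetric CoA affinities

With purely irreversible Michaelis-Menten steps and generous moiety
pools, flux control in this chain is essentially binary: CPT1B holds an
FCC of 1.0 until downstream capacity is exactly exhausted, after which
the system falls into a spurious absorbing state in which all CoA is
sequestered in ketoacyl esters and all carnitine in acylcarnitine
(every rate zero — a genuine fixed point, but not a physiological one).
Two documented features of the real enzymes fix this:

* **CPT1B product inhibition by acylcarnitine** (`ki_acylcarnitine`,
  default 2 uM) communicates downstream saturation smoothly back to the
  entry step, producing the gradual, monotone control shift from CPT1B
  to MCKAT as palmitoyl-CoA rises from 0.1 to 10 uM.
* **Asymmetric CoA affinities** — thiolases bind free CoA tightly
  (`km_coa_thiolase`, 2 uM) while the import step binds it weakly
  (`km_coa_import`, 150 uM) — so falling free CoA throttles import
  before cleavage. This converts the CoA-sequestration loop from a
  positive feedback (less CoA, less cleavage, more sequestration) into
  a stabilising negative feedback.

Both constants are ordinary entries of the parameter file and can be
overridden. The solver additionally guards against the sequestered fixed
point: if a solve converges to zero flux at positive substrate and
positive CPT1B capacity, it re-integrates from the empty state with a
bounded pseudo-time step so the physical attractor is followed.

### Defaults and units

Maximal rates are expressed per mg total tissue protein
(umol min^-1 mg^-1) and converted to concentration units through a
single volume factor (default 1e6, i.e. 1 uL matrix water per mg
protein). The factor rescales time only: the acetyl-CoA sink constant is
defined at the reference factor and scales with it, so steady-state
concentrations, and every flux-control coefficient, are invariant to the
choice (this is asserted by tests). Default capacities are staged so
that (i) CPT1B is far from downstream capacity at 0.1 uM palmitoyl-CoA
(FCC ~ 1) and (ii) thiolytic capacity — MCKAT alone carries the C6 and
C4 cleavages — approaches saturation near 10 uM. They are
order-of-magnitude choices for mouse quadriceps, not published
constants; the published model's constants can be dropped into the
parameter file verbatim if available.

```{r}
ps <- bx_parameter_set()
ps
```

### Steady-state solver

The solver works in reduced coordinates (free CoA and free carnitine
eliminated through the conservation relations, so moieties are conserved
to machine precision by construction) and runs pseudo-transient
continuation — adaptive implicit Euler with step doubling — to a
relative derivative norm below 1e-9, followed by a damped Newton polish
to residuals near machine precision. The polish matters: flux-control
coefficients are forward differences with a relative perturbation of
1e-6, so the flux must be accurate to much better than that. A
central-difference oracle at 1e-4 agrees to better than 1e-3 (tested),
and the summation theorem over all rate-scaling steps (the nine enzymes
plus the sink; the sink's membership is configurable) holds to a few
parts in 1e6 on the default model.

A note on ranges: in the hand-off region at high substrate the FCC of
CPT1B can, for unfavourable random parameter draws, dip marginally below
zero (about -0.01 at 10 uM); negative control coefficients are a real
feature of saturable pathways near capacity, and the invariant tests
treat `[-tau, 1 + tau]` with tau = 0.02 as the admissible band.

## Per-animal parameterization

Catalytic constants are anchored on a liver reference: `kcat_e =
Vmax_liver,e / E_liver,e`, then `Vmax_e = kcat_e * E_e,animal` for each
animal's measured quadriceps concentration (fmol per ug total protein).
Only maximal rates are animal-specific; Km and Ki values are shared.
The bundled liver table is **synthetic** (the real reference is in the
literature and not reprinted here); it is constructed so that the
generator's baseline animal reproduces the model's documented default
Vmax values, keeping the parameterization and simulation stages
mutually consistent. Missing proteins are a hard error by default;
imputation by user-supplied values (e.g. cohort means) must be requested
explicitly, because silent imputation would bias FCC comparisons.

## OGTT indices

Glucose and insulin traces are fitted to
`C(t) = C_b + C_1 (e^{-k_e1 t} - e^{-k_a t}) + C_2 e^{-k_e2 t}`
by deterministic multi-start nonlinear least squares (18 starts from a
fixed grid). Two canonical orderings are enforced through the
parameterization: `k_a > k_e1` (the first term is symmetric under
exchanging the two constants with a sign flip on `C_1`) and
`k_e2 < k_e1` with all amplitudes non-negative (the third term is the
*slower* second elimination; without the ordering the two slow
exponentials trade places freely). MISI is the maximal post-peak decline
rate of the *fitted* glucose curve (analytic derivative, located by a
dense grid plus local refinement) divided by the mean insulin over the
test, by default the trapezoidal mean of the fitted insulin curve (a
raw-data mode is provided). HOMA-IR uses the mouse-adjusted form
`glucose[mM] x insulin[mU/L] / 14.1`; the ELISA ng/mL-to-mU/L factor
defaults to 25 and is configurable, since the source protocol does not
state its factor.

### Identifiability of the rate constants

Fitting six parameters to eight observations of a double-exponential is
weakly identified. The Cramer-Rao bound at the canonical test curve
(`C_b=5, C_1=10, C_2=2, k_a=0.15, k_e1=0.02, k_e2=0.01`, 3%
multiplicative noise) gives a relative standard deviation of about 0.35
for `k_a` and 1.9 for `k_e1`; the orderings above act as regularisation
and bring the achieved median errors to about 14% (`k_a`) and 21%
(`k_e1`) over 100 noisy curves — and truth-started fits do no better, so
the `k_e1` floor is statistical, not an optimiser artefact. The
acceptance suite therefore documents a red result for the 15% recovery
bound on `k_e1` while the noiseless 1e-3 round trip and the MISI
derivative oracle pass. Consumers of `k_e1` at realistic noise should
treat it as a curve-shape summary, not a precise rate constant.

## Omics statistics

The lipidomics pipeline follows the published procedure: intensities are
normalised to the class internal standard (classes without a standard
use the mean of all standards); within each age stratum values are
log2-transformed (zeros replaced by half the analyte's smallest positive
value), mean-centred, and compared between diets by per-analyte
Student's t-tests; q-values come from Benjamini-Hochberg step-up at
Q = 5% by default, with the two-stage adaptive step-up available (the
variant used is recorded in output metadata); an analyte is flagged only
if `q < 0.05` *and* the linear-scale fold change of group means is
>= 1.5 or <= 0.66. Mean-centring is a per-analyte location shift and
leaves the t statistics unchanged (asserted by a test); it is kept
because the published procedure states it. Diet-response scatters divide
each analyte by its all-animal mean before group means, so points on the
identity line are diet-neutral by construction. The factorial screen is
a two-way fixed-effects decomposition with marginal (Type II) sums of
squares — appropriate for the unbalanced 6-vs-10 design — tested against
the residual of the full interaction model, with effect directions from
unweighted marginal cell-mean differences.

## The synthetic cohort generator

The generator emulates the *structure* the analysis consumes, not the
study's data: 6 young / 10 old animals per diet; 16 beta-oxidation and
31 glucose-metabolism proteins; 443 lipid species across the detected
classes with class standards (one class deliberately lacks one, to
exercise the fallback); glucose at 0/5/15/30/45/60/90/120 min and
insulin at 0/5/15/30/60/120 min generated from the fitted curve family
so the fitter is well-specified. Noise is multiplicative log-normal
(standard for MS intensity data) with CVs of 15% (proteomics), 25%
(lipidomics), 5% (glucose) and 15% (insulin). Planted effects are
generator knobs chosen so the qualitative published contrasts are
recoverable at the study's sample sizes: CPT1B x0.6 in old and x1.3 by
HFD in young only; x1.5 by HFD on 14 of 16 beta-oxidation proteins;
lower-glycolysis proteins x0.8 in old and diet-responsive only in
young; a 58-species old-HFD lipid accumulation block at x2.0 (a
multiplier at exactly the 1.5 fold-change gate would straddle the
significance threshold under noise, so the default sits comfortably
above it). OGTT group parameters produce MISI ordering
young-LFD > young-HFD > old-LFD > old-HFD with roughly 2-3x separation
between neighbours, and the reverse ordering for HOMA-IR.

A green planted-effect test therefore establishes that the pipeline
recovers effects of the stated size and shape under log-normal noise at
the study's n — not that the study's data contain those effects, and
not robustness to features real MS data have and the generator lacks
(batch effects, missingness, heteroscedastic ion suppression,
correlated lipid classes).

## Numerical choices, degenerate inputs, limitations

* Steady-state tolerance: relative derivative norm 1e-9 (floor 1e-12
  uM); FCC perturbation 1e-6 relative, with an automatic 10x retry when
  the flux change sits within 100x of the solver's noise floor.
* Zero substrate, zero Vmax, flat OGTT traces, zero-variance analytes,
  classes without standards and zero standards all have defined,
  tested behaviour (exact zero results, degenerate fits, flagged
  undefined values or named errors — never silent NaN).
* The model omits NADH/FADH2 redox coupling, respiratory-chain and TCA
  kinetics, peroxisomal oxidation and unsaturated/odd-chain substrates;
  its constants are stand-ins, so absolute fluxes are
  order-of-magnitude only. FCCs, being scale-free, are the robust
  output.
* Insulin unit conversion and the raw-versus-fitted insulin averaging
  mode are configurable because the source protocol leaves both
  unstated.
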
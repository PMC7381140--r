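---
title: "Methods: the coagsim coagulation-network simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the coagsim coagulation-network simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and model form

`coagsim` predicts INR and aPTT for virtual patients on steady-state
warfarin/phenprocoumon or rivaroxaban therapy by chaining an in-vivo dosing
simulation of the coagulation network into an in-silico clotting assay on
the drawn plasma. Every species is a turnover pool,
`dC/dt = p - kdeg C + reaction terms`, with Michaelis-Menten activations,
1:1 complex formations (both partners removed, the complex formed) and
first-order conversions. The entire network — species roster, baselines,
half-lives, kinetics, drug-action constants — lives in a versioned TSV
parameter table; the code only compiles and integrates it. Parameter
estimation is out of scope by design: nothing is fitted to data at run
time.

The shipped `coag-v1` table is a reconstruction, not a transcription: the
antecedent 56-compartment humoral-coagulation model that motivates the
structure does not print its equations or constants in the source we work
from. `coag-v1` therefore implements the extrinsic (TF → TF:VIIa → Xa),
intrinsic (CA → XIIa → XIa → IXa → IXa:VIIIa → Xa) and common
(Xa:Va → IIa → fibrin, XIIIa cross-linking) pathways, the protein C/S arm,
and the vitamin K cycle, with 37 species and 24 reactions. Plasma baselines
and degradation constants are physiological textbook values (e.g.
fibrinogen 9 µM, prothrombin 1.4 µM, factor VII half-life 5 h); the
catalytic constants were calibrated, in this order, to four stated
anchors: a clinically normal drug-free PT (9.45 s), a ~30% fibrinogen
reduction at the moment the clot criterion fires, a drug-free aPTT of
~30 s, and the two population biomarker means (below). A user table can
replace all of it; `validate-table` reports the drug-free PT/aPTT any table
implies.

## Two time bases

Dosing runs over weeks; clotting over seconds. One time base would make
the system numerically hostile, so the table stores turnover in 1/h and
reaction kinetics in 1/s, and the compiler converts with 1 h = 3600 s
according to the mode: `in_vivo` (hours; zero-order production and drug
forcing active) or `in_vitro` (seconds; production zeroed — a closed test
tube — but degradation retained, since inhibitor consumption of active
factors is what terminates the burst).

## The stiff solver

No stiff ODE solver package could be assumed available, so the integrator
is part of the package: a linearly-implicit Rosenbrock(2,3) pair (the
classic ode23s formulas) in C++, with a fresh finite-difference Jacobian
per step, rtol 1e-6 / atol 1e-9 nM, and storage of every accepted step with
its derivative so trajectories support C1 cubic-Hermite interpolation at
arbitrary times (clot-time location needs sub-second resolution). In-vivo
integrations restart at each dose time, where the absorption forcing has a
derivative discontinuity. Reaction rates are evaluated on the non-negative
part of the state while degradation acts on the raw state, so round-off
excursions below zero decay back; concentrations are clamped to zero for
reporting, and anything below −1e−6 nM aborts with a solver-misconfiguration
error. The compiled right-hand side is property-tested against a naive
per-reaction R loop on randomized networks, and the integrator against
closed forms (pure decay, moiety conservation, PK superposition).

## Drug exposure

Both drugs use one-compartment disposition with first-order absorption and
elimination, evaluated in closed form (superposition over doses) inside the
right-hand side rather than as ODE states. Only the warfarin CYP2C9*1
clearance of 0.2 L/h is a reported constant; V, F, ka and the rivaroxaban
disposition values are order-of-magnitude literature-typical defaults
declared in the table and flagged as calibration knobs. CYP2C9 *2 and *3
scale warfarin clearance by 0.70 and 0.20; rivaroxaban PK is
genotype-invariant. Phenprocoumon is handled purely by the linear dose
conversion 3 mg ≡ 5 mg warfarin, extended proportionally to other doses.
Warfarin is treated as a racemate with a single concentration.

## The vitamin-K coupling (a genuinely open design point)

Warfarin inhibits the epoxide → vitamin K regeneration step with
`Imax C/(IC50 + C)` (Hill 1, Imax 1, IC50 a table knob). The cycle itself
is two first-order reactions (oxidation sink 10/h, regeneration 20/h, the
epoxide additionally cleared at 1/h), so inhibition drains the vitamin K
pool. Synthesis of the VK-dependent factors II, VII, IX, X, PC, PS is then
scaled by

  φ(VK) = f(VK) / f(VK₀),  f(v) = v² / (Km² + v²),  Km = 50 nM,

normalized to the *patient's own* drug-free vitamin K level VK₀.

Two alternatives were rejected. Scaling the regeneration *rate constant*
by genotype produces no effect at steady state in a linear cycle (the
epoxide pool simply accumulates until the flux rebalances) — which is
precisely why the genotype is implemented as a cap on available vitamin K
(GG ×1.00, GA ×0.78, AA ×0.56, the heterozygote being the allele-average of
a 44%-deficient variant). And a coupling proportional to regeneration flux
"relative to normal" is genotype-linear: normalized per patient it erases
the genotype effect entirely, and normalized to the wild type it gives AA
carriers a 44%-depressed drug-free INR, contradicting both physiology and
the drug-free identity requirement (INR exactly 1.000 for every untreated
patient). The saturating Hill form resolves this: drug-free, every genotype
sits on the flat part of f and φ = 1 *exactly* (per-patient
normalization); under warfarin the depleted VK falls onto the steep part,
where the genotype-scaled pool produces the clinically ordered response
(AA > GA > GG), compounding with CYP2C9 through exposure. Hill = 2 sets how
sharply dose and genotype separate.

Because VKORC1's only modeled action is this warfarin-target pathway,
rivaroxaban courses skip the vitamin-K cap altogether: the genotype
isolation contract is "exactly no effect", verified bit-identically, not
within tolerance.

## The in-silico assays

**Clot criterion.** Clot time is the earliest t with
∫₀ᵗ fibrin du ≥ 1500 nM·s. The threshold's printed unit ("nM/s") is read
as nM·s, since it is defined as an area under a concentration-time curve.
The detector accumulates the integral by trapezoids on a 10 ms grid and
refines the crossing on a 0.1 ms subgrid (well inside the 1 ms tolerance);
it is tested against an independent fine-grid oracle on randomized
piecewise-linear trajectories. Runs reaching the 300 s horizon without
crossing are censored and never carry an INR.

**PT / INR.** 300 nM tissue factor is set in the sample (reagent dilution
is ignored; the source procedure does not model it), the in-vitro system is
integrated, and INR = (PT_test/PT_standard)^ISI with ISI = 1. PT_standard
is computed once from the unmodified table's drug-free steady state and
cached per table version; population runs pin it explicitly so every
patient shares one reference. At the moment the criterion fires on normal
plasma, fibrinogen has fallen 29.7% from baseline — the calibrated
equivalence to the stated ~30%.

**aPTT.** The default `shortcut` mode imposes the contact-activation
product directly: XIa ← 0.148·XI(0), XI ← 0.339·XI(0), everything else at
its drawn level. The remaining 51.3% of the XI pool is treated as consumed
by inhibitors (it returns to neither XI nor XIa); concretely, the contact
phase includes a first-order XIa inactivation sink. A
`full_preincubation` mode exists for validation only: it adds 300 nM
contact activator and integrates the 180 s preincubation with *only* the
contact-tagged reactions active — mimicking decalcified plasma, where the
downstream cascade cannot proceed — before releasing the full system. With
the shipped constants it reproduces the split approximately, not exactly;
the check is informative, not normative, because the true contact-pathway
constants are not published.

## Virtual population

Genotypes are independent categorical draws at the stated frequencies
(CYP2C9 72/19/9%, VKORC1 53/36/11%); the known CYP2C9–VKORC1 linkage is not
modeled because only marginal frequencies are stated. The "20% variability"
is implemented as log-normal multipliers with unit mean and CV 0.20
(σ² = ln(1 + CV²)) — the standard population-PK choice, guaranteeing
positive rates — independent across patients and parameters, applied to the
production rates of II, V, VII, IX, X, XI, XII, XIII, PC, PS and to CL and
V of the PK. Whether the variability also covers F and ka is unstated;
default is CL and V only, configurable. No residual error is added to assay
outputs. The whole population is a pure function of (spec, seed, table
version); sampling restores the caller's RNG state.

A production multiplier scales both the synthesis rate and, through
C* = p/kdeg, the patient's drug-free baseline — each patient starts at
their own steady state, which is what a 20-day run would converge to
anyway.

## Scenario orchestration

Patients are drawn at day 20 (steady state; extending to day 27 moves the
endpoints by <2%), at the trough immediately before the next dose — the
TDM sampling convention; the source procedure does not state the in-day
draw time, so trough is our documented assumption with a config override.
Per-patient solver failures are flagged and do not abort a batch. Both
endpoints are computable for either drug, defaulting to the clinical
pairing (warfarin→INR, rivaroxaban→aPTT).

## Calibration of the two drug-action knobs

With everything above frozen, two scalars remain: `warfarin_ic50_nM` was
set to 650 so that a mixed population with the clinical dose composition
(2.5/5/7.5 mg at proportions 62:88:5) and stated genotype frequencies has a
pooled mean predicted INR ≈ 2.4, and `rivaroxaban_ki_nM` to 8.5 so the
15/20 mg mix (39:179) has pooled mean aPTT ≈ 45.5 s. These are exactly the
two calibration targets the design prescribes; they were fixed before the
acceptance suite was frozen and are not revisited per-run.

## What the generator does and does not emulate

A green population test establishes that the *stated world* — fixed-dose
regimens, independent genotype and dose assignment, 20% log-normal
biological variability, no covariates, no measurement error — reproduces
the pooled biomarker means and orderings. Real TDM cohorts differ in ways
the model deliberately omits: doses were titrated to the measured INR (so
genotype and dose are negatively correlated in reality, and extreme
predicted INRs in rare *3/AA carriers on fixed 5–7.5 mg have no observed
counterpart); age, weight and co-medication effects are absent; assay noise
is absent. Distribution tails are therefore wider than observed data — an
expected property, not a defect the tests should hide.

## Numerical conventions and degenerate inputs

Quartiles use the linear-interpolation convention (R `type = 7`); whiskers
are the most extreme points within 1.5·IQR of the box, clipped to the data
range. Censored and failed patients are excluded from summaries and
flagged in the results CSV. ka = ke in the PK uses the analytic limiting
form. Zero-dose regimens skip the forcing entirely. A species with
kdeg = 0 and positive production is rejected at initialization (no finite
steady state). Empty genotype strata are omitted with a warning.

## Known limitations

The roster is smaller than the 56 compartments of the antecedent model
(no fibrinolysis arm, no explicit drug:Xa complex, no thrombomodulin);
the table schema is extensible if those are needed. The full-preincubation
aPTT path depends on unpublished contact-phase constants and is
approximate. INR sensitivity to factor depletion is slightly shallow
(a factor scale of ~0.2 maps to INR ≈ 2.3), which the IC50 calibration
absorbs. None of the numbers in this vignette are claims about the
package beyond what its tests and `scripts/acceptance.R` recompute.
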
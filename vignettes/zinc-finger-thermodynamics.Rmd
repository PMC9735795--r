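---
title: "Models and methods: Zn(II)-binding thermodynamics of classical zinc fingers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: Zn(II)-binding thermodynamics of classical zinc fingers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zfthermo)
```

This vignette documents the science and the numerical design of
`zfthermo`: what each model assumes, which parameters matter and why their
defaults are what they are, what the synthetic-data generators do and do
not emulate, and where the genuinely open design choices were made.

## 1. The system

A classical ββα zinc finger is unfolded in its apo form and folds around a
single Zn(II) ion coordinated tetrahedrally by two cysteine thiolates and
two histidine imidazoles (a CCHH site, `n_his = 2`). Three experimental
observables characterise the binding event:

* the **thiol pKa values**, because the thiolates must shed their protons
  before they can coordinate Zn(II);
* the **dissociation constant** at the working pH (7.4), measured by
  competition against chelators of known Zn(II) affinity, since direct
  titration cannot resolve femtomolar binding;
* the **binding enthalpy** from ITC, which at pH 7.4 is contaminated by
  the heat of the buffer absorbing the released thiol protons.

## 2. Thiol deprotonation (pH titrations)

`fit_pka()` fits the macroscopic two-proton model (see
`predict_titration_absorbance()`): the absorbance trace is the
population-weighted mean of the three plateau values $A_0, A_1, A_2$
(fully protonated, singly and doubly deprotonated) with weights given by
the diprotic partition function. Assumptions: a single absorbing
equilibrium per proton, plateau absorbances independent of pH (no drift
or baseline slope), and additive Gaussian noise.

The macroscopic constants are reported with the convention
$pK_1 \le pK_2$ (labels swapped on exit; ties allowed). The average
protonation

$$\bar n_H(\mathrm{pH}) = \frac{10^{pK_2-\mathrm{pH}} + 2\cdot 10^{pK_1+pK_2-2\mathrm{pH}}}{1 + 10^{pK_2-\mathrm{pH}} + 10^{pK_1+pK_2-2\mathrm{pH}}}$$

is the standard macroscopic partition-function average, chosen because it
is bounded in $[0,2]$, monotone in pH, and needs no microscopic
(per-site) constants, which single-wavelength data cannot resolve.

**Numerical choices.** All exponential mixtures are evaluated after
subtracting the largest base-10 exponent, so predictions are finite at
any pH. The least-squares fit is bounded Levenberg–Marquardt
(`minpack.lm`), relative tolerance $10^{-10}$, at most 10 000 function
evaluations, with pKa bounds at the sampled pH range ± 3. Because the
model has a known failure mode — a shallow secondary minimum when the
upper transition is only partly sampled — the default fit is
**multi-start**: four pKa placements spanning the pH range, keeping the
lowest residual sum of squares. A flat trace raises a structured
`zf_fit_failure`; fitted pKa values more than 1 unit outside the sampled
range set the `pk_out_of_range` flag rather than erroring.

**Generator regime.** `gen_ph_titration()` defaults to
$pK_1 = 7.6$, $pK_2 = 8.8$ (which give $\bar n_H(7.4) \approx 1.6$, the
regime of Cys₂His₂ peptides), plateaus $0.10/0.30/0.50$ AU — a 25 µM
peptide whose two thiolates each contribute about 0.2 AU at 218 nm
(Δε ≈ 8000 M⁻¹cm⁻¹ per thiolate) — and noise 0.002 AU. The default grid
runs from pH 3 to 11 in 0.1 steps: a titration for pKa determination must
be carried through *both* transitions, since with data stopping near pH 8
the pair $(pK_2, A_2)$ sits on a likelihood ridge and no fitting strategy
can recover $pK_2 = 8.8$ reliably. Experiments that stop earlier can be
emulated by passing an explicit `ph_grid`.

## 3. Free Zn(II) in metal buffers (speciation)

Competition experiments poise free Zn(II) with a chelator/Zn(II) mixture.
`solve_free_zn()` works with *conditional* constants at fixed pH: the
protonation ladder of the ligand is folded into the side-reaction
coefficient $\alpha_H(L)$ and, when parameterised, the ternary ZnHL
complex into the conditional formation constant $\beta'$. The species
model is deliberately restricted to L/HL…/ZnL (+ optional ZnHL) plus free
Zn(II) — no hydroxo or polynuclear species, which the working buffers are
designed to avoid — keeping the mass-balance system two-dimensional and
well-posed.

**Numerical choices.** The two mass balances are solved by Newton
iteration on $(\ln[\mathrm{Zn}], \ln[L'])$, which enforces positivity
across the ~15 decades the problem spans, with step-halving damping
whenever the residual norm fails to decrease, starting from the
excess-ligand first-order estimate. Convergence requires relative
residuals below $10^{-12}$ (reported threshold $10^{-8}$); 200 iterations
without convergence raises `zf_numerical_failure` carrying the residuals.
The test suite checks the solver against an independent log-space
bisection oracle on the closed-form one-complex polynomial (100 random
buffers, $10^{-10}$ relative agreement).

The Zn(II) withdrawn by the peptide itself is handled by
`peptide_corrected_pzn()`: the saturated fraction of the peptide is
subtracted from total Zn(II) and, when a peptide $K_d$ is supplied, the
saturation is recomputed from the resulting free Zn(II) and iterated to a
fixed point ($|\Delta \mathrm{pZn}| < 10^{-6}$; the mapping is strongly
contractive because the peptide, at 25 µM, is a small perturbation of a
millimolar buffer).

Chelator constants ship as a YAML config
(`inst/extdata/chelators.yaml`), not as code: they are medium-dependent
literature-compilation values, and the NDAP entry in particular is
approximate. Quantitative work should substitute constants validated for
the actual ionic strength and temperature; no Debye–Hückel or temperature
corrections are applied, mirroring the usual practice of feeding
conditional constants directly to a speciation solver.

## 4. Competition fitting and $K_d$

`fit_hill()` fits the Hill equation in the printed-source convention with
$\Theta_{min}$ weighted by $x^n$ — i.e. the *saturated* (more negative)
ellipticity plateau is approached at high free Zn(II). Whether that
weighting or the conventional one is used does not move the
half-saturation point, and therefore does not affect $K_d$; the package
uses one convention consistently in the model, the generator and the
documentation. The half-saturation free Zn(II) equals the apparent
$K_d$ for a 1:1 complex (`kd_from_hill()`), and `hill_n` near 1 is a
useful internal check of the 1:1 assumption.

**Numerical choices.** $[\mathrm{Zn}]_{0.5}$ is fitted as
$\log_{10}$-value (bounds: sampled pZn range ± 3); plateaus start from
the data extremes, $n$ from 1, and the midpoint crossing initialises the
transition. Replicate readings at the same pZn are averaged before
fitting, matching the practice of averaging repeated kinetic reads. Two
identifiability guards raise `zf_unidentifiable_fit`: a fitted transition
centre outside the sampled pZn window (± 0.5), and a fitted amplitude
smaller than five residual standard deviations (plateau-only sampling
produces exactly this signature — a spurious, noise-sized "transition").

**Generator regime.** `gen_competition_series()` defaults to
$K_d = 5\times10^{-13}$ M (within the measured $-\log K_d$ 12.3–14.5
range), plateaus −11000/−3000 deg cm² dmol⁻¹, 15 pZn points spanning
± 1.4 units around the transition, and noise at 1 % of the signal range.

## 5. ITC and the enthalpy ledger

`simulate_isotherm()`/`fit_isotherm()` implement the single-site binding
model with exact volume-displacement bookkeeping: constant cell volume,
each injection displacing an equal volume of pre-injection, well-mixed
cell content, displaced liquid thermally inert. The per-injection complex
concentration comes from the closed-form quadratic; the suite checks it
against an independent per-injection bisection solve. A "sequential"
multi-site model is unnecessary: measured stoichiometries are ≈ 1
throughout this system, and the fit estimates $n$ anyway. Heats are
handled in µcal; enthalpies in kcal/mol of complex formed.

The decomposition chain (`decompose()`) applies, in order: the buffer
correction, the thiol-deprotonation cost, the Zn-peptide enthalpy, the
bond-budget folding enthalpy, $\Delta G^\circ$ from $-\log K_d$, and the
entropic term. Three identities hold for every ledger the chain produces,
and `validate_ledger()` audits them (default tolerance 0.05 kcal/mol, the
propagation of two-decimal rounding) — including externally tabulated
rows, where rounding genuinely breaks them.

**Sign convention of the buffer correction.** The correction is
implemented as $\Delta H^\circ = \Delta H_{ITC} + n_H\,\Delta
H^\circ_{buff}$ with $\Delta H^\circ_{buff} = +5.02$ kcal/mol for HEPES
(its *protonation* heat as tabulated for proton-release corrections).
Written with the opposite sign, the correction would drive the intrinsic
enthalpy ~16 kcal/mol more exothermic and break every downstream identity
against the reference ledgers; the implemented convention reproduces them
within rounding. The constants (5.02, 8.5, −5.0, −5.0 kcal/mol; R;
298.15 K) live in `thermo_constants()` and are overridable — the
decomposition is linear in each of them, a property the suite asserts
numerically.

## 6. MD post-analysis

**Contact numbers.** The switching function uses the standard rational
form $(1-(r/r_0)^n)/(1-(r/r_0)^m)$ with $n = 8$, $m = 12$, $r_0 = 2.8$ Å.
The removable singularity at $r = r_0$ evaluates to $n/m$, with a
first-order expansion inside $|r/r_0 - 1| < 10^{-8}$ for continuity. Note
the rational tail decays only as $(r/r_0)^{n-m}$; a detached ligand at
15 Å still contributes $\sim 10^{-3}$, which is why release detection
uses a threshold rather than exact zero. Each His contributes through its
coordinating N only, each Cys through Sγ, so one atom per ligand and
`bound_threshold = 0.5` means "half a contact".

**Release events.** A ligand is released at the first frame opening a run
of at least `persistence = 50` consecutive sub-threshold frames; shorter
dips count as rebinding. Both knobs are exposed because no community
standard exists for the event criterion; 0.5/50 are conservative for
trajectories sampled finely enough that a genuine rupture is followed by
hundreds of detached frames. Ligands sub-threshold at frame 1 are flagged
`pre_dissociated` rather than ordered. `pathway_census()` tallies ordered
release signatures across replicas; `rupture_statistics()` reports both
per-event window maxima of the pulling force *and* the per-replica global
maximum, since either reading of "rupture force" is defensible, plus the
trapezoidal work integral over the reaction coordinate
(kcal mol⁻¹ Å⁻¹ × Å; no conversion to pN is attempted).

**Hydrogen bonds.** The geometric rule is donor–acceptor heavy-atom
distance < 3 Å and deviation of the D–H⋯A axis from linearity < 20°
(a literal D–H–A angle below 20° is geometrically impossible at 3 Å, so
the angle criterion is necessarily the linearity deviation). Both cutoffs
are arguments. The detector is cross-checked against an exhaustive
independently-coded geometry check on structures with exactly placed
boundary geometry (2.999/3.001 Å, 19.99°/20.01°).

**RMSD/RMSF/FES.** Superposition uses the least-squares rigid-body fit
from `bio3d` — the same toolchain structural work in this area typically
uses. The free-energy surface is $-RT\ln(p/p_{max})$ over a regular 2-D
histogram of projected samples (empty cells infinite, minima = cells not
exceeded by any 8-neighbour); PCA projection itself is standard plumbing
(`stats::prcomp` or `bio3d::pca.xyz`) and intentionally not wrapped.

**Generator regime.** `gen_smd_trajectory()` scripts a minimal five-atom
Zn site: bound distances ~2.3 Å (contact ≈ 0.94), a 10-frame ramp to
> 8 Å at each scripted release, jitter ≤ 0.05 Å, 700 frames with releases
at 150/300/450/600, and a sawtooth force peak per event (linear build-up,
collapse within 2 frames of the rupture — so each event's window maximum
is its own peak). It emulates *event structure*, not protein mechanics:
no backbone, no solvent, no force-field realism, and the force channel is
scripted rather than emergent.

## 7. What the synthetic data do and do not show

Every generator is deterministic under a fixed seed, restores the
caller's RNG state, and attaches its ground truth. Noise models are the
simplest that match instrument behaviour: additive Gaussian for
absorbance and ellipticity, proportional-plus-floor for heats, uniform
in-sphere jitter for coordinates. Passing the recovery tests therefore
demonstrates correctness of the estimators *under the stated models* —
unbiased recovery at instrument-scale noise, exact recovery without noise
— not robustness to baseline drift, wavelength miscalibration, slow
equilibration, aggregation, or correlated instrument noise, none of which
are emulated. The problem sizes used throughout (81-point titrations,
15-point competition series, 25-injection isotherms, 700-frame pulling
runs, 40–50 replicas, 50-seed recovery loops) were chosen to mirror the
experimental designs they emulate while keeping the full suite fast.

## 8. Known limitations

* The speciation model is Zn + one chelator (+ peptide); it is not a
  general N-metal/N-ligand solver, and shipped constants are conditional
  compilation values.
* Macroscopic pKa values only; microscopic (per-cysteine) constants are
  not identifiable from single-wavelength traces, and $\bar n_H$ at
  pH 7.4 inherits that macroscopic treatment.
* Single-site ITC only; no displacement titrations, no raw-thermogram
  baseline integration (inputs are integrated per-injection heats).
* The enthalpy ledger's bond-budget step treats Zn–S and Zn–N bond
  enthalpies as transferable constants; $\Delta H^\circ_{folding}$ is a
  remainder term and absorbs any error in them.
* Pathway classification assumes the contact threshold/persistence pair
  separates rupture from rebinding; pulling regimes fast enough to blur
  His/His ordering will show as genuinely split censuses, not as errors.
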
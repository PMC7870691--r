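---
title: "A constrained-mixture model of arterial clamping injury and healing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A constrained-mixture model of arterial clamping injury and healing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselheal)
```

This vignette is the package's own account of the science it implements: the
constitutive and remodeling model, the parameters that matter, the numerical
decisions taken where the design was genuinely open, and what the model does
*not* capture.

## The mixture and its prestresses

The vessel wall is treated as a constrained mixture: elastin, two symmetric
collagen fiber families and contractile smooth muscle cells (SMCs) deform
together under one mixture deformation `F`, but each constituent has its own
stress-free deposition state. On the reduced thin-walled half-cylinder all
kinematics are diagonal in the local (radial, circumferential, axial) frame
and fully incompressible, so a state is two numbers, the circumferential and
axial stretches vs the in vivo homeostatic reference; the radial stretch
follows from `J = 1`. The deviatoric `J^(-2/3)` factors of the energies are
kept in the formulas for fidelity but are identically 1.

Energies per unit normalized referential density:

* elastin: `C10 (I1bar - 3)` of `F_elas = F G_elas`, with
  `G_elas = diag(1/(g_circ g_ax), g_circ, g_ax)`;
* collagen cohort deposited at mixture deformation `F_dep`:
  `k1/(2 k2) [exp(k2 E^2) - 1]`,
  `E = kappa I1bar + (1 - 3 kappa) I4bar - 1` of
  `F_coll = F F_dep^{-1} G_coll`, with
  `G_coll = g M (x) M + g^{-1/2} (I - M (x) M)` along the fiber direction
  `M = (0, cos a, +/- sin a)`;
* SMC: `mu/2 (n3 + n4)(I4_smc + u_rs - 1)^2` along the circumferential cell
  direction.

The total energy is the density-weighted sum over elastin, every cohort of
both families and the contractile SMC pool. Three conventions had to be
fixed where the source formulations are ambiguous, and are worth stating:

* the collagen energy is implemented in the standard GOH form with the `-1`
  inside the bracket, `k1/(2k2)[exp(k2 E^2) - 1]`, so the energy of an
  undeformed fiber is zero;
* the active energy prefactor is read as `mu/2` (the Murtada-style
  convention); the Cauchy stress is derived *energy-consistently* from it
  (`sigma_act = 2 rho I4 mu (n3+n4)(I4 + u_rs - 1)`), while the filament
  driving stress `P_mat = mu (n3+n4)(I4 + u_rs - 1)` — without the extra
  `2 lambda` factor — is kept verbatim for the sliding law, because the
  three-branch law and its closed-form steady states are written in terms of
  it. The finite-difference stress–energy consistency test pins the stress
  route to the energy route at fixed `(n, u_rs)`;
* no tension-only switch is applied to collagen: the energy is even in `E`,
  so compressed fibers contribute. (The *acute damage* law, by contrast, is
  applied only in tension; see below.)

**Homeostatic prestress.** With `g_ax = 1.67` and `g_coll = 1.1` fixed as
prior knowledge, the single unknown `g_circ` is found by a scalar root solve
so that the mixture circumferential Cauchy stress at the reference
configuration equals the thin-wall Laplace stress `p r / h = 0.08125` MPa.
Under the default parameter set the balancing deposition stretch lies
slightly *below* one (collagen prestress alone carries most of the Laplace
load), so the solver bracket extends down to 0.05. By construction the
reference state has zero stretch deviation and zero fiber-stress deviation,
making homeostasis an exact fixed point of the remodeling loop — a property
the test suite checks to below 1e-6 drift per step.

**Basal tone in vivo.** The latch dynamics of the crossbridge model would, on
a time scale of minutes, ratchet the filament sliding up until the matrix
stress equals `kappa_c n3` — about 0.22 MPa of cell-level stress at basal
calcium, several times the diastolic Laplace stress. Whether this fully
engaged latch tone acts in vivo is genuinely open. The package's default is
that SMCs are deposited at rest (`u_rs = 0`): they contribute *stiffness* but
no net prestress at the reference, the prestress balance is passive, and the
latch engages only ex vivo, where the myograph protocol gives it minutes to
equilibrate. This choice keeps the post-clamp stretch deviations at the few-
percent level that the day-scale remodeling laws (and their published
stability) presuppose; with the alternative (`numerics$latch_tone_in_vivo =
TRUE`) the acute loss of a quarter of the contractile pool removes ~0.04 MPa
of wall stress at once and the remodeling feedback becomes violently
oscillatory.

## Acute clamp damage

The damage state is driven by the overstretch history
`beta = max |lambda_theta - 1|`, frozen once the clamp is released:

* contractile SMCs: `d = 1 - exp(-beta / m_csmc)`, removed from the wall
  (not converted to the synthetic phenotype);
* collagen: `d = 1 - exp(-dzeta / m_coll)` with `dzeta` the normalized
  fiber-stress deviation at the clamp deformation, applied only where the
  deviation is positive — damage comes from overload, compression does not
  destroy fibers;
* endothelium: local death where `beta > m_ec = 0.38`; the model keeps a
  single global survival fraction `phi_ec`, the fraction of luminal points
  below the threshold.

**The injury-profile generator.** The true overstretch field under a clamp
requires 3D contact mechanics. The package replaces it with a signed
parametric stretch-deviation field on the half-cylinder that mimics a
flattened tube: a wide compression plateau in the contact region (centered on
the clamp flat) and narrow tensile zones at the clamp edges where the inner
wall bends around the plate edge, both fading linearly to 40% at the outer
wall. The tensile-zone width is fixed at the wall bending scale `2h/r`
(~0.25 rad); the remaining three parameters (tensile peak, compression peak
and width) are calibrated once per clamp load, by nested root solves, to the
three acute injury levels measured for that load: global endothelial
survival, mean contractile SMC damage and mean collagen damage (for the
0.6 N clamp: 0.3113, 0.2830 and 0.0924). The split into compression and
tension is what lets one field produce heavy endothelial/SMC damage alongside
mild (~9%) collagen loss: most of the lumen is injured by compression, which
the collagen law ignores. The fiber-overstress evaluation is skipped at
compressed points also because the membrane kinematics (radial thickening
under circumferential compression) does not represent the flattened,
plate-confined contact region.

What this generator emulates is the *aggregate* acute injury; what it does
not emulate is the true spatial field, local contact pressures, or any
dependence on the clamp force beyond the calibrated targets — the two loads
differ only through their measured injury levels, which is also why the two
acute cases produce nearly identical myograph curves. Passing tests therefore
validate the damage *laws* and the downstream healing dynamics, not a contact
simulation.

## Remodeling

Each remodeling step is one day (configurable). Per step:

1. solve the pressurized membrane equilibrium for the circumferential
   stretch (axially plane strain, mirroring a short fixed-end segment whose
   nodes may move only radially); the stretch deviation is
   `dlambda = lambda_theta - 1`;
2. decay every collagen cohort: `q <- q exp(-K_qh dt (1 + dzeta^2))`, where
   `dzeta` is that cohort's normalized fiber-stress deviation (each cohort
   carries its own deposition deformation, so freshly deposited collagen is
   always at its homeostatic stress);
3. deposit one new cohort per family at the current deformation with mass
   `m0 Gamma dt`, `Gamma = (1 + (rho_c/rho_c0) K_m dlambda) rho_s/rho_s0`;
4. switch phenotypes: contractile cells dedifferentiate at rate
   `dlambda K_dd` (and redifferentiate in compression), capped by the
   elastin grip and by the available synthetic pool; synthetic cells
   proliferate mechanically (`dlambda K_pl`) and under inflammation
   (`K_ic phi_ic`), and receive the exchanged mass — exchange conserves SMC
   mass apart from the explicit proliferation terms;
5. heal the endothelium by one forward-Euler logistic step and set
   `phi_ic = 1 - phi_ec`.

Elastin is never produced or degraded. Two published model variants are
implemented: `no_redifferentiation` (the mechanical phenotype and
proliferation terms act only for `dlambda >= 0`) and
`mech_independent_production` (`Gamma = rho_s/rho_s0`).

Design choices the sources leave open, as implemented here:

* `dzeta` is made dimensionless by normalizing with the homeostatic fiber
  stress, since it is added to 1 in the survival exponent and divided by a
  dimensionless constant in the damage law. The scalar fiber-stress measure
  is the trace of the cohort's unit-density Cauchy stress, which collapses to
  one shared homeostatic value for all steady cohorts;
* the baseline production rate `m0` is not a free parameter: it is fixed by
  the stationarity condition `m0 dt = rho_coll0 (1 - exp(-K_qh dt))`, which
  makes homeostatic collagen exactly stationary at any step size;
* acute damage and chronic stress-driven degradation act on collagen as
  independent mechanisms (the acute fraction rescales cohort masses once;
  survival decay continues from there);
* new deposition begins with the first healing step (remodeling is inactive
  while the clamp is applied);
* all contractile SMCs are referenced to the homeostatic configuration;
  re-differentiated cells inherit that reference rather than a new deposition
  state, keeping homeostasis an exact fixed point;
* cohorts whose grid-mean contribution falls below 1e-8 are pruned to bound
  memory; the induced density error is below 1e-6 of the total.

## Contractility and the virtual myograph

Agent chemistry composes as: PE and NO responses are Hill-normalized
(`R = c/(c + K)`); ACh does nothing directly but releases endothelial NO by a
log-dose saturation curve, scaled linearly by `phi_ec` (the minimal model of
endothelium dependence — a denuded vessel loses the ACh response, which is
the acute clamp phenotype); applied and endothelial NO add. Calcium is
`Ca_hom + alpha_PE R_PE - alpha_NO R_NO` (clipped at zero), phosphorylation
rates follow Michaelis–Menten kinetics of the calcium–calmodulin complex, and
NO additionally raises the dephosphorylation rates. The four-state kinetics
are integrated with the matrix exponential of the rate generator —
unconditionally stable for stiff rate sets and conserving `sum(n) = 1` to
machine precision; steady states come from the generator's nullspace, and the
two routes are cross-checked against each other on random rate sets in the
test suite. The ACh curve is singular below its fitted domain
(`[ACh] < 10^-8.2` M); outputs there are clipped to zero with a warning.

The myograph mounts the excised ring (unloaded state from the zero-stress
solve; the axial recoil follows from the zero-axial-force condition) on two
rigid rods. Perimeter-conserving kinematics map the rod gap to the
circumferential stretch; the wall force per unit length is
`2 sigma_theta h_def` over the two load-bearing segments at deformed
thickness. The force–displacement curve has three zones: zero before the rods
engage the slack ring, a straightening zone, and wall stretching. A pure
membrane has exactly zero force while the slack ring ovalises, so the
straightening zone is given a small bending-scale stiffness — the initial
stretching stiffness reduced by the thin-ring factor `(h/2R)^2` — purely to
produce the observed low-stiffness transition; it is an idealization, not a
bending simulation. Doses are applied cumulatively at the preloaded, fixed
gap; the filament sliding carries its path dependence (three-branch law)
through the protocol, which is why a dilator dose after pre-constriction
lowers the force through the drop in attached bridges rather than through
re-sliding.

## Numerical settings and problem sizes

All root solves are scalar bisection-based (`uniroot`) at tolerance 1e-12;
equilibrium residuals at the reference configuration are checked to 1e-8 MPa
at construction. The default grid is 48 circumferential by 3 radial material
points, with 4001 luminal sample points for the endothelial survival
fraction (granularity 2.5e-4 on `phi_ec`); a full six-case protocol runs in
seconds. The remodeling step is 1 day and the kinetic transient step 0.01 s,
both configurable; the package's time-step convergence quantity (maximum
relative day-31 constituent difference between 1-day and half-day steps for
the hardest case) is recomputed by `scripts/acceptance.R` on every run rather
than quoted here.

## Known limitations

* Uniform membrane kinematics: all material points share one deformation, so
  local dilation of heavily injured zones — which in a full 3D model
  accelerates local remodeling — is averaged away. The healing trajectories
  keep the published dip–overshoot–return shape, but the collagen recovery is
  slower and its overshoot peak later and lower than in the
  contact-mechanics original; the healed-case collagen and SMC fractions are
  therefore qualitative, not quantitative, targets.
* The injury profile is calibrated, not computed: clamp force enters only
  through the measured acute injury levels.
* Agent diffusion through the wall, SMC migration, localized endothelial
  regrowth fronts and wall-shear-driven NO are all outside the model.
* The endothelial healing law is logistic in a single global variable; its
  forward-Euler discretization is the model definition, not an approximation
  to be refined.
* Excision under the default parameter set produces a mild axial extension
  rather than the retraction seen in excised arteries; this follows from the
  printed deposition-prestretch values on the reduced geometry and does not
  affect the circumferential myograph readout.
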
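# vesselheal

Surgical clamps injure arteries: the endothelium is denuded, contractile
smooth muscle cells (SMCs) die, and extracellular collagen is overstressed and
partly destroyed. Over the following weeks the wall remodels — SMCs switch to
a synthetic, matrix-producing phenotype, inflammation drives their
proliferation, new collagen is laid down, and the endothelium regrows — until
the functional tone of the vessel is largely restored. `vesselheal` is a
desk-scale simulator of this whole sequence for a mouse thoracic aorta,
intended for vascular mechanobiologists who want to explore damage and
remodeling hypotheses without a 3D contact finite-element model.

## The model

The wall is a **constrained mixture** on a reduced thin-walled half-cylinder
(inner diameter 0.65 mm, thickness 0.04 mm, diastolic pressure 10 kPa):

* **Passive mechanics** — Gasser–Ogden–Holzapfel energy: a neo-Hookean elastin
  matrix, `Ψ_elas = C10 (Ī₁ − 3)`, plus two dispersed collagen fiber families
  at ±α to the circumference,
  `Ψ_coll = k₁/(2k₂) [exp(k₂ E²) − 1]`, `E = κ Ī₁ + (1 − 3κ) Ī₄ − 1`.
  Each constituent is deposited with its own prestretch (`g_ax = 1.67`
  axially for elastin, `g_coll = 1.1` along each fiber); collagen is tracked
  as daily **cohorts**, each with its own deposition deformation and survival
  fraction.
* **Active mechanics** — Hai–Murphy four-state crossbridge kinetics
  (detached/attached × phosphorylated/dephosphorylated, with the latch state
  n₄) with rates controlled by intracellular calcium. Phenylephrine raises
  calcium, nitric oxide lowers it and speeds dephosphorylation, and
  acetylcholine acts only through endothelial NO release. Filament sliding
  `u_rs` relaxes viscously toward the crossbridge driving stress, giving
  `Ψ_act = μ/2 (n₃+n₄)(Ī₄ + u_rs − 1)²`.
* **Acute damage** — the clamp overstretch history β = max|λ_θθ − 1| kills
  contractile SMCs (`d = 1 − e^(−β/m)`), overstressed collagen decays by the
  analogous law, and the endothelium dies wherever β exceeds a threshold. The
  contact-mechanics overstretch field is replaced by a calibrated parametric
  injury profile (compression under the clamp flats, tension at the clamp
  edges).
* **Remodeling** — one step per day: the vessel re-equilibrates (Laplace
  balance), the stretch deviation Δλ dedifferentiates contractile SMCs and
  drives synthetic proliferation and collagen production, cohorts decay
  faster when overstressed, and the endothelium heals by the logistic law
  `φ' = (K_ec Δt (1 − φ) + 1) φ` with inflammation `φ_ic = 1 − φ_ec`.
* **Virtual myograph** — the vessel is excised (pressure and axial constraint
  released), mounted on two 0.15 mm rods, preloaded to 0.0133 N/mm and dosed
  isometrically with PE (10⁻⁶ M), ACh (10⁻⁵ M) and NO (10⁻⁶ M).

Six standard cases combine clamp load (0.0, 0.6, 1.27 N) with timing (acute
`A0/A1/A2`, one-month healed `R0/R1/R2`).

## Worked example

```r
library(vesselheal)
res <- run_case("R1")   # 0.6 N clamp, 31 days of healing, myograph
print(res)
#> <vessel_case> R1 (clamp 0.60 N, 31 days healed)
#>      elastin     collagen         csmc         ssmc  endothelium inflammation
#>       1.0000       1.0849       0.6657       1.7327       0.8463       0.1537
#>   myograph isometric force (N/mm):
#>     preload  0.01330
#>     +PE      0.01448
#>     +ACh     0.01353
#>     +NO      0.01298
```

Reading the output: after a month of healing the elastin is untouched
(`1.0000`, it is neither produced nor degraded), collagen has recovered past
its acutely damaged level, about a third of the contractile SMCs are still
missing while the synthetic pool is enlarged (`1.73`), and the endothelium
has regrown from its acute 31% to 84.6%, leaving a residual inflammation of
15.4%. In the myograph, phenylephrine raises the isometric force from the
13.3 mN/mm preload, acetylcholine relaxes it partially (the response scales
with the intact endothelium — acute cases relax much less), and the NO donor
relaxes it below the ACh level.

Other entry points: `solve_homeostasis()`, `apply_clamp()`, `heal()`,
`myograph()` for the individual protocol steps; `heal(...)$history` is the
daily time series (`plot()` it); `load_params()`/`save_params()` read and
write the YAML parameter registry (`inst/extdata/params-default.yaml`);
`calibrate_clamp_profile()` and `write_beta_profile()` generate injury
profiles. A thin command-line wrapper lives in `inst/cli/vesselheal.R`
(`run`, `myograph`, `fixture-beta` subcommands).

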
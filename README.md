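# isokie

Multi-element kinetic isotope effect (KIE) inference for base-promoted
dehydrochlorination reactions, at toy scale and fully testable.

Degradation of chlorinated pollutants such as lindane
(γ-hexachlorocyclohexane) is characterized in the field by
compound-specific isotope analysis: as the substrate is consumed, its
carbon, chlorine and hydrogen isotope ratios shift, and the per-element
bulk enrichment factors ε fingerprint the bond-cleavage chemistry.
`isokie` implements the full inference chain that connects
position-specific KIEs to those bulk signals, for people who build or
check such interpretations:

* **Vibrational analysis + Bigeleisen engine** — mass-weighted Hessian,
  Eckart-frame rigid-body projection, and the semiclassical harmonic KIE

  `KIE = (ν‡_L/ν‡_H) · g(TS)/g(R)`,
  `g = Π_i (u_L/u_H) e^{(u_H−u_L)/2} (1−e^{−u_H})/(1−e^{−u_L})`,
  `u = hcν̃/k_BT`

* **Fractionation algebra** — unweighted bulk averages,
  `ε = (1 − KIE_av)·1000 ‰`, hybrid primary/secondary assembly, apparent
  KIEs (dilution correction) and the inverse problem for the secondary
  average.

* **Rayleigh module** — simulated batch-degradation experiments
  (first-order isotopolog pools, realistic noise) and through-origin
  regression of `ln(R/R₀) = (ε/1000)·ln(C/C₀)` with calibrated
  confidence intervals.

* **Umbrella sampling + WHAM** — Metropolis window sampling along the
  proton-transfer coordinate `z = r(C–H) − r(H–O)` and the weighted
  histogram equations, with barrier extraction.

* **Path-integral module** — primitive P-bead discretization with exact
  harmonic closed forms, bisection-sampled quantized classical paths
  (BQCP), mass-perturbation FEP between isotopologs, PI KIEs and bead
  convergence tables.

Toy molecular systems with analytic Hessians (`make_toy_reaction()`)
stand in for electronic-structure inputs, so every stage has an
independent closed-form or brute-force oracle. The methods vignette
(`vignettes/multi-element-kie.Rmd`) documents the models, defaults and
numerical choices.

## Worked example

The numbered drivers under `analysis/` run the complete workflow;
`analysis/02_semiclassical_kie.R` computes position-specific KIEs on the
transfer toys and assembles bulk enrichment factors:

```
C  primary KIE 1.0806, bulk KIE_av 1.0158 -> eps -15.84 permil
Cl primary KIE 1.0031, bulk KIE_av 1.0012 -> eps -1.18 permil
H  primary KIE 4.6553, bulk KIE_av 1.6222 -> eps -622.22 permil
bulk H of -160 permil with primary 4.5 needs secondary average 0.492 -- inverse (below unity)
```

Reading: the proton being transferred carries a large normal effect
(KIE ≈ 4.7), the reactive carbon a percent-scale effect, the leaving
chlorine a few permil — and the last line shows the hydrogen paradox:
a primary H KIE of 4–5 is only compatible with a bulk hydrogen ε near
−160 ‰ if the secondary hydrogen effects average *below unity*
(inverse).

`analysis/05_pi_fep.R` exercises the path-integral machinery:

```
   P      F_P   deviation
1  8 3.743757 0.402000721
2 16 4.023721 0.122036960
3 32 4.113379 0.032378139
4 64 4.137534 0.008223487
smallest bead count within 0.02 kcal/mol: P = 64
P=32  dF_qm 2.5502 +/- 0.0044  closed form 2.5505  (-0.08 SE)
H->D mass FEP: -0.9880 +/- 0.0030 kcal/mol (closed form -0.9874, ESS 30299/80000)
```

A 2900 cm⁻¹ C–H stretch at 298 K needs 64 beads before the primitive
path-integral free energy sits within 0.02 kcal/mol of the exact quantum
value; the Monte Carlo BQCP estimator and the mass-perturbation FEP both
land on their closed forms within error.

`analysis/06_demo_report.R` runs the end-to-end demo: three independent
routes to each element's ε (semiclassical, path-integral hybrid, and a
Rayleigh fit of a self-consistent synthetic batch experiment), written
as a machine-readable report under `results/demo/`.

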
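---
title: "Multi-element kinetic isotope effect inference for dehydrochlorination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-element kinetic isotope effect inference for dehydrochlorination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isokie)
```

## The scientific problem

Hexachlorocyclohexane isomers, lindane among them, are persistent
pollutants whose degradation pathways in the field are diagnosed by
compound-specific isotope analysis (CSIA): the carbon, chlorine and
hydrogen isotope ratios of the residual substrate shift as degradation
proceeds, and the per-element enrichment factors carry a fingerprint of
the bond-breaking chemistry. Connecting those bulk, compound-average
signals to position-specific kinetic isotope effects (KIEs) -- and hence
to a transition-state picture of the base-promoted dehydrochlorination --
requires a chain of calculations: harmonic vibrational analysis and the
Bigeleisen equation for semiclassical KIEs, bead-quantized path-integral
corrections where nuclear quantum effects matter (the transferred
proton), averaging and dilution rules connecting positions to bulk
values, and Rayleigh regression on batch-degradation data.

`isokie` implements that chain end to end on toy systems with analytic
Hessians and closed-form oracles, so every stage is testable against an
independent reference. It is a methods package: the toys stand in for
electronic-structure and QM/MM inputs, which are out of scope.

## Semiclassical KIEs from Cartesian Hessians

A `molecular_system` holds coordinates (Angstrom), masses (amu) and a
Cartesian Hessian (hartree/bohr^2, the convention of quantum-chemistry
outputs). `frequencies_from_hessian()` mass-weights the Hessian, projects
out rigid-body motions with Eckart-frame projectors (three translations
plus two or three rotations according to linearity), and converts
eigenvalues to wavenumbers. Modes below 1 cm^-1 in magnitude after
projection are dropped and counted; one negative eigenvalue marks a
first-order saddle, two or more raise an error.

The KIE of one isotopic substitution follows the harmonic Bigeleisen
form,

$$\mathrm{KIE} \;=\; \frac{\nu^\ddagger_L}{\nu^\ddagger_H}\,
\frac{g(\mathrm{TS})}{g(\mathrm{R})},\qquad
g = \prod_i \frac{u_{iL}}{u_{iH}}\,
e^{(u_{iH}-u_{iL})/2}\,
\frac{1-e^{-u_{iH}}}{1-e^{-u_{iL}}},\qquad
u = \frac{h c \tilde\nu}{k_B T},$$

with the product over real modes and the imaginary-frequency ratio as
prefactor. Design choices, fixed deliberately:

* harmonic throughout -- no anharmonicity, no tunneling (Wigner)
  correction, frequency scaling factor 1.0. The package contrasts this
  *semiclassical* treatment with the path-integral treatment below, so a
  tunneling fudge on the semiclassical side would blur that comparison;
* modes are matched by ascending order after projection. This is exact
  for the symmetry-free toys shipped here but unsafe under mode
  crossing, so a flag is attached whenever adjacent modes lie within
  1 cm^-1 of each other;
* default temperature 298.15 K, the usual reporting convention for
  predicted KIEs; the hydrolysis experiments' 303.15 K is one argument
  away.

The engine is verified in two independent ways: against closed-form
diatomic frequencies, and against a brute-force harmonic
transition-state-theory rate ratio computed from raw translational,
rotational and vibrational partition functions. The latter agrees to
better than 1e-6 relative because the Teller--Redlich product rule holds
exactly for our analytic Hessians -- that agreement is a sharp test of
the projection and of the Bigeleisen assembly at once.

All physical constants are pinned to CODATA-2014 (`phys_constants()`),
and every closed-form oracle uses the same bundle, so comparisons are
constant-choice-invariant.

## Toy systems

`make_toy_species()` / `make_toy_reaction()` build systems whose
Cartesian Hessians are assembled as $B^\top F B$ from
rotation/translation-invariant internals (stretches and degenerate
linear bends). Rigid-body eigenvalues are therefore *exactly* zero, and
the internal spectrum is known in closed form for the diatomic and
block-composite kinds.

The two transfer toys used by the demo emulate the two chemical events
of the elimination:

* `CHO` -- collinear C--H...O proton abstraction. The transition state
  carries one imaginary mode dominated by the light transferring atom.
  Its bends stiffen at the TS (`ts_k_bend = 0.055` hartree/rad^2), which
  controls how much hydrogen zero-point energy survives; the value was
  chosen so the primary H KIE lands in the 4--5 range reported for
  hydroxide-promoted abstraction, which is also the regime where the
  hydrogen paradox (inverse secondaries) appears.
* `XCCl` -- a heavy skeleton pseudo-atom, the reactive carbon and the
  leaving chloride. Chlorine departure is barely advanced at the TS
  (the imaginary mode is mostly skeletal), keeping the chlorine effect
  at the few-permil level and the carbon effect normal and percent-scale.

What the toys do *not* emulate: solvent, anharmonicity, mode coupling
beyond one stretch--stretch term, three-dimensional reaction valleys,
and real molecular symmetry. Passing tests demonstrate the correctness
of the inference chain, not the accuracy of any specific molecular
prediction.

## From positions to bulk: enrichment factors

Positions of one element are averaged without weights (six per element
in the hexachlorocyclohexane skeleton, entered individually), and the
bulk enrichment factor follows

$$\varepsilon = (1 - \mathrm{KIE_{av}}) \cdot 1000\ \text{permil},$$

negative for normal effects. `hybrid_bulk()` implements the hybrid
design in which the reactive position comes from the path-integral route
and the remaining positions from microsolvation-model averages
(C 1.0029, Cl 1.0008, H 1.0156 by default);
`infer_secondary_average()` inverts that assembly,
which is how one sees that a primary H KIE of 4--5 is only compatible
with a bulk value near -160 permil if the secondary effects average
below unity (inverse). `epsilon_to_akie()` implements the usual
position-count dilution correction and attaches a caution once
$1 + n\varepsilon/1000 < 0.5$, where the linearization is meaningless --
the hydrogen case in the worked analysis trips exactly this guard.

```{r fractionation}
inv <- infer_secondary_average(-160, primary_kie = 4.5, n = 6)
inv$secondary_mean   # 0.492, inverse
```

## Batch experiments and Rayleigh regression

`simulate_batch_experiment()` emulates alkaline batch hydrolysis: light
and heavy isotopolog pools decay in parallel first order, with the heavy
rate $k_H = k_L(1 + \varepsilon/1000)$ fixed by the element's bulk KIE.
Under this (linearized, Eq.-style) convention the noise-free data sit
exactly on the Rayleigh line
$\ln(R_t/R_0) = (\varepsilon/1000)\ln(C_t/C_0)$, which the tests assert
to residuals below 1e-10. The convention breaks down at
$\mathrm{KIE_{av}} \ge 2$ (the heavy rate would vanish); the simulator
rejects such inputs rather than silently extrapolating. Heavy
isotopologs are treated as trace species, so the reported concentration
tracks the light pool.

Noise model (the package's choice, kept as simple as is consistent with
measurement practice): lognormal
multiplicative on concentration (default 2 % relative), additive
Gaussian on delta values (defaults 0.5 permil for C and Cl, 5 permil for
H, the usual CSIA precision ordering). Sampling times default to ten
points over one decade of degradation at $k_L = 10^{-4}\,s^{-1}$.
Every simulation takes one seed and reproduces byte-identically.

`rayleigh_fit()` regresses through the origin in
$(\ln C_t/C_0,\ \ln R_t/R_0)$ space, which matches the Rayleigh model
identically; a free-intercept variant exists as a robustness check. Both
axes are referenced to the *nominal* initial concentration and isotopic
composition of the prepared batch rather than to the noisy $t=0$
observation: a shared noisy reference would correlate all points and
invalidate the regression's error model, whereas the starting material
of a designed batch experiment is characterized beforehand. With
independent errors the 95 % confidence intervals are calibrated -- the
test suite measures coverage of 0.90--1.00 across 100 seeded replicates
at $\varepsilon = -160$ permil with 0.5 permil delta noise.

## Umbrella sampling and WHAM

The reaction coordinate is the antisymmetric combination
$z = r(\mathrm{C1{-}H1}) - r(\mathrm{H1{-}O})$. Window samples are drawn
by Metropolis from $\exp\{-\beta[A(z) + \tfrac12 k_b (z-z_0)^2]\}$ with
the step size auto-tuned to 30--50 % acceptance during a discarded
burn-in of 10 % of the requested samples. The WHAM equations are
iterated on a binned grid in log space,

$$P(z_m) \propto \frac{\sum_k n_k(z_m)}
{\sum_k N_k\, e^{\beta(F_k - W_k(z_m))}},\qquad
e^{-\beta F_k} = \sum_m P(z_m)\, e^{-\beta W_k(z_m)},$$

to a tolerance of 1e-6 kcal/mol on the $F_k$ (cap 1e5 iterations; hitting
the cap raises a typed condition that carries the partial profile). The
gauge is fixed by $F_1 = 0$ and the reported $A(z) = -k_BT\ln P$ is
shifted to zero minimum. Bin width defaults to Freedman--Diaconis on the
pooled samples, clamped to 10--400 bins; bin width and tolerance are
package choices, both overridable. Windows that
share no occupied bins with their coordinate-neighbours trigger an
ill-conditioning warning. `barrier_height()` takes the highest interior
turning point beyond the reactant basin; a profile that is monotone to
the sampled edge has no barrier and errors accordingly.

At the reference sampling (14 windows of 2000 samples, bias
50 kcal/mol/A^2) the harmonic control is recovered with RMSE below
0.1 kcal/mol over the central 80 % of the range and a 6 kcal/mol
double-well barrier within 0.15 kcal/mol. Only the 1D coordinate is
supported: including the carbon--chlorine variable would require 2D
umbrella sampling and 2D WHAM, which are out of scope here.

## Path-integral free energies

The primitive (Trotter) discretization of a harmonic mode has the closed
form

$$F_P = k_BT \ln\!\big(2\sinh(P\theta/2)\big),\qquad
\cosh\theta = 1 + \frac{(\beta\hbar\omega)^2}{2P^2},$$

which `pi_free_energy_ho_exact()` evaluates; it interpolates from the
classical $k_BT\ln(\beta\hbar\omega)$ at $P=1$ to the exact quantum
value as $P\to\infty$ and anchors every Monte Carlo check. For a
2900 cm^-1 C--H stretch at 298 K the deviations from the exact quantum
free energy are 0.40, 0.12, 0.032 and 0.008 kcal/mol at
$P = 8, 16, 32, 64$: at a criterion of 0.02 kcal/mol -- this package's
convergence definition -- 64 beads are the smallest adequate count, and
`bead_convergence()` reports exactly that.

`bqcp_quantum_correction()` estimates
$\Delta F_{qm} = F_{quantum}(P) - F_{classical}$ by the
quantized-classical-path construction: classical configurations from a
built-in Metropolis sampler (in a condensed-phase application these
would come from the QM/MM trajectories of the PMF generation, out of
scope here), and around each configuration centroid-constrained
free-particle bead paths generated by *bisection* (staging is not
implemented; the cited sampling method is bisection, whence the
power-of-two bead counts). The recentred pinned Brownian bridge is
distributed exactly as the centroid-zero free ring because the ring
action depends only on bead differences -- this exactness is tested
against the free-ring radius of gyration
$\beta\hbar^2(1-P^{-2})/(12m)$. The estimator

$$e^{-\beta\Delta F_{qm}} = \Big\langle\big\langle
e^{-\beta(\bar V_{path} - V(x_c))}\big\rangle_{\mathrm{paths}}
\Big\rangle_{\mathrm{classical}}$$

gets its standard error from a 10-block jackknife over classical
configurations. At the reference sampling of 8000 configurations with 10
path draws each, the estimate agrees with the closed form within three
standard errors at every tested bead count.

Isotope differences use mass-perturbation FEP on the shared light-path
ensemble: scaling the displacements about the centroid by
$\sqrt{m_L/m_H}$ is an exact change of variables of the Gaussian path
measure, i.e. direct sampling for the heavy mass on correlated paths,
not importance reweighting. An effective-sample-size guard (10 % of
nominal) still protects the heavy-path average. The exact
mass-perturbation bookkeeping of the cited method is not printed
anywhere; this centroid-scaling construction is the generic form and is
validated against the two-oscillator closed form.

`pi_kie()` converts per-species corrections into
$\ln \mathrm{KIE} = -\beta[\Delta\Delta G^\ddagger_{qm}(L) -
\Delta\Delta G^\ddagger_{qm}(H)]$; the classical PMF factor is
isotope-independent and cancels.

## The end-to-end demo and its three routes

`run_demo()` compares three routes to each element's bulk enrichment
factor on a self-consistent toy: (i) semiclassical Bigeleisen primaries
with assumed secondaries; (ii) a path-integral route for the transfer
hydrogen, in which every real normal mode of reactant and TS is
quantized as an independent oscillator by BQCP and the result is
multiplied by the classical reaction-coordinate frequency ratio from the
vibrational analysis -- as $P\to\infty$ this composition converges
exactly to the Bigeleisen value, which makes the cross-route comparison
well-posed and lets the closed form predict the finite-$P$ offset that
the report also carries; (iii) Rayleigh regression on a synthetic batch
experiment whose generator KIEs are the engine's own. With the default
settings ($P=32$, 2000 configurations x 10 paths per mode) the Monte
Carlo PI estimate sits on its closed-form finite-$P$ expectation within
error, and the Rayleigh route recovers the generator truth within the
fit error. All stages derive their seeds from the single configuration
seed, so reports rerun byte-identically.

Problem sizes throughout the tests and the analysis scripts -- 14
windows x 2000 umbrella samples, 8000 x 10 path-integral draws, 100
replicate batch fits, 2000 x 10 draws per mode in the demo -- are the
package's reference choices and match the scales at which the recovery
tolerances above were established.

## Known limitations

* One-dimensional reaction coordinate and model potentials only; no MD,
  no QM/MM coupling, no explicit solvent.
* The linearized heavy-rate convention restricts the batch generator to
  bulk KIE_av < 2 (amply sufficient for CSIA practice; the transfer-H toy
  sits near the edge by design).
* Mode matching by sorted order limits the Bigeleisen engine to systems
  without mode crossing between isotopologs.
* The bead-convergence criterion (0.02 kcal/mol on the harmonic free
  energy) and the WHAM bin/tolerance defaults are package choices;
  both are exposed as arguments.
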
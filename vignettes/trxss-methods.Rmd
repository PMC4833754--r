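---
title: "Methods: kinetic and structural analysis of time-resolved solution scattering from homodimeric hemoglobin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kinetic and structural analysis of time-resolved solution scattering from homodimeric hemoglobin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trxss)
```

## The problem

Pump-probe X-ray solution scattering (TRXSS) on a photoactive protein
yields difference curves ΔS(q, Δt): the change in the orientation-averaged
scattering pattern at momentum transfer q, a time Δt after a laser pulse
photodissociates the ligand. For the homodimeric hemoglobin of *Scapharca
inaequivalvis* (HbI), photolysis of the CO-bound dimer launches a cascade
of structural intermediates ending in the tense (T-like) quaternary state,
followed by CO rebinding. The package turns a ΔS(q, Δt) matrix into
(i) a count of structurally distinct intermediates, (ii) fitted rate
parameters of a branched photocycle, (iii) species-associated difference
curves — the intrinsic ΔS(q) of each intermediate, and (iv) rigid-body
structural models of the intermediates with derived descriptors (E–F
distance, subunit rotation angle, heme–heme distance, Cα RMSD).

Because no public TRXSS dataset for this system exists, the package ships
a synthetic-data module with known ground truth; every stage of the
pipeline is validated by generate-and-refit experiments.

## Intermediate counting by SVD

The q × delay matrix is decomposed exactly ([svd_decompose()]). A
component counts as significant ([count_significant()]) when its singular
value exceeds 3× the median of the trailing half of the spectrum (a
noise-floor estimate) *and* the lag-1 autocorrelations of both its left
and right singular vectors exceed 0.8: signal vectors are smooth in q and
in log-time, noise vectors are not. Both thresholds are arguments. The
rule is scale-invariant, and on white-noise matrices its modal answer is
zero components. With fewer than four components available only the
magnitude test is applied.

The right singular vectors can be fit globally with a sum of
exponentials sharing one set of time constants
([fit_multiexponential()]). Amplitudes enter linearly and are solved by
least squares inside the nonlinear search over log time constants
(variable projection), multi-started from 32 log-uniform draws in
[10 ps, 100 ms]. This fit is descriptive — it reports the relaxations
visible in the data without committing to a mechanism; the two slowest
constants it returns on HbI-like data are stand-ins for the
non-exponential bimolecular phase.

An optional solvent-heating correction ([remove_heating()]) subtracts the
per-delay least-squares projection of each column onto a heating basis
curve; the packaged basis ([heating_basis()]) is a smooth Gaussian bump
near q ≈ 0.3 1/Å standing in for a measured thermal signature. Heating is
off by default in the generator and the pipeline.

## The photocycle model

The kinetic scheme has three intermediates and branched substates.
Photolysis (complete within the instrument response) leaves a fraction
`phi_full` of the excited dimers fully photolyzed (both CO released into
the protein matrix) and `1 - phi_full` partially photolyzed. Both forms
of the earliest intermediate I1 relax to I2 with time constant `tau12`.
Arriving I2 splits with fixed fraction `f_gem` into a geminate channel —
in-protein CO rebinding with `tau_gem`, producing a ligated I1 that
recovers the ground state with `tau_lig` — and an R–T channel that decays
to the T-like I3, with `tau_rt1` for the fully and `tau_rt2` for the
partially photolyzed substate. At the I2 → I3 transition the
photodissociated CO (2 or 1 per molecule) escapes to the solvent pool;
I3 then rebinds solvent CO bimolecularly with rate constant `k_bi`,
consuming 2 (fully) or 1 (partially photolyzed) CO per recovered dimer in
a single rate-limiting step.

Design choices worth stating explicitly:

* **Fixed-fraction branching, not competing rates.** If the geminate and
  R–T channels competed kinetically, the branch fraction would be forced
  to `k_gem / (k_gem + k_RT)`, which is inconsistent with an independently
  fitted 26% fraction next to `tau_gem` < `tau_rt1`. Splitting the I2
  inflow into fixed-fraction sub-channels, each with its own
  mono-exponential decay, reproduces independently fitted fractions and
  time constants.
* **One branch fraction for both substates**; per-substate fractions
  would not be identifiable here and the published analysis fits one.
* **Geminate CO never enters the solvent pool** — geminate recombination
  is by definition in-protein. Escape happens at the I2 → I3 event.
* **`tau_lig` is the decay of ligated I1 to the ground state** (the
  ligated form "returns to the initial state" with this constant), not an
  extra formation step.
* Concentrations are in mM and times in seconds; `k_bi` is in 1/(mM s).
  Defaults `P0 = 1 mM` photolyzed protein and `CO_excess = 1 mM` free CO
  represent a solution with comparable protein and dissolved CO.

The 11 tracked sub-populations evolve by linear rate equations except the
bimolecular step; [solve_populations()] integrates them with a stiff
solver (compiled right-hand side, `lsoda`) from 100 ps to 10 ms. Protein
and CO bookkeeping are conserved to the solver tolerance (default keeps
both below 1e-9 of the totals). The observables are the three summed
populations [I1], [I2], [I3]; the recovered ground state contributes no
difference signal by construction.

## Global fitting of the kinetic model

[fit_kinetic_model()] follows the standard TRXSS projection scheme: the
data are projected onto the significant left singular vectors; for each
trial of the eight nonlinear parameters the populations C(θ) are solved
and the species-curve amplitudes are obtained by linear least squares of
the projected data against C(θ); the subspace residual is minimised over
θ by restarted Nelder–Mead from 16 multi-starts (±0.3 decades on each
time constant, ±0.5 logit units on the fractions; half the starts begin
from the mirrored photolysis fraction because the two substates are
nearly exchangeable). Time constants are parameterised in log space with
`tau_rt2 = tau_rt1 (1 + e^u)` to keep the R–T pair ordered, fractions in
logit space. Species-associated difference curves are reconstructed from
the fitted amplitudes as `U A`, i.e. they live in the retained lSV
subspace.

The ratio `tau_rt2 / tau_rt1` ([cooperativity_ratio()]) is the package's
cooperativity measure: the closer the partially photolyzed substate's R–T
relaxation is to the fully photolyzed one's, the stronger the
intersubunit coupling.

**What is and is not identifiable at the default noise level.** With the
default study conditions (33 delays, 200 q points, independent Gaussian
noise of 2% of the peak signal) a linearised error analysis of the fit,
with the nine curve amplitudes profiled out, gives asymptotic standard
errors of about 0.07 ns on `tau12`, 9 ns on `tau_gem`, 1.5 µs on
`tau_lig`, 0.3 points on `f_gem`, but ~19 1/(mM s) on `k_bi` and ~26
points on `phi_full`. The reason is structural: once `tau_rt1` and
`tau_rt2` are as close as they are here (the R–T phase is nearly
single-exponential), the photolysis fraction is constrained only through
the CO bookkeeping of the bimolecular phase, which is a weak channel.
Generate-and-refit experiments reproduce these spreads almost exactly, so
the medians over ten seeds recover `tau12`, `tau_gem`, `tau_lig` and
`f_gem` tightly while `phi_full` and `k_bi` carry the quoted wider
uncertainty. Published uncertainties of a few percent on the photolysis
fraction imply an effective noise level roughly an order of magnitude
below this package's 2% default.

## Scattering from structures

[debye_intensity()] evaluates the Debye equation with 4-Gaussian atomic
form factors (tabulated in `inst/extdata/form_factors.csv` together with
displaced volumes). Two modes: `"vacuum"`, and `"solvent"`, which applies
the Fraser–MacRae–Suzuki excluded-volume reduction
f(q) − ρ_s·V·exp(−V^(2/3) q²/4π) with solvent electron density
ρ_s = 0.334 e/Å³. There is no hydration-shell term: shell contributions
largely cancel in difference curves between conformers of one protein,
which is the only use the pipeline makes of absolute intensities. The
calculator is a plain function of a structure, so a shell-aware external
calculator could be substituted wherever a curve is consumed.

Hydrogens are absorbed into their heavy atoms through the per-atom
`h_count` column (united-atom increments); coarse-grained Cα beads use a
composite residue form factor (`"CG"`, approximately C5 N1.35 O1.5 H8).
Explicit interfacial waters are ordinary oxygen atoms appended with
[attach_waters()] and tagged with a heme rigid body, so refinement moves
them with their host, mirroring the treatment of interface waters as part
of the heme group.

The production path bins pair distances (default 0.1 Å) with a
three-node quadratic assignment that preserves the 0th–2nd moments of
each pair distance, making the binned sum third-order accurate: at the
default width it tracks the exact double sum to better than 1e-4
relative over q ≤ 1 1/Å while being ~50× faster for repeated evaluation
inside refinement.

[band_power_ratio()] quantifies where in q a structural change expresses
itself: the RMS of a curve difference over the small-angle band
(0.15–0.4 1/Å) divided by the RMS over the wide-angle band (0.4–1.0 1/Å).
Removing the two interfacial waters from the toy complex gives a ratio
above 1 — the water signature lives at small angles — reproducing the
qualitative argument that lost interface waters cannot explain wide-angle
differences between intermediates.

## Rigid-body refinement

[define_rigid_bodies()] partitions a dimer into 18 bodies (8 helices and
1 heme per subunit); loop residues join the preceding helix, N-terminal
tails the first helix, attached waters their host heme. [mc_refine()]
minimises the scale-fitted chi-square between the model difference curve
I(candidate) − I(ligated reference) and the target species-associated
curve, plus a backbone-connectivity penalty `w_conn Σ (d − d0)²` over the
gaps between sequence-adjacent bodies (free bodies would tear the chain;
default 10 per Å²). When the target carries no uncertainties, chi-square
is normalised by the target RMS so it is dimensionless: 0 is a perfect
fit, ~1 is no fit, and the penalty weights are on a meaningful scale. The
fitted scale is restricted to positive values with a small floor, so an
anticorrelated model is penalised rather than plateauing.

The Monte Carlo schedule has an exploration phase (Metropolis, effective
temperature calibrated to the median probe-move |Δobjective| and annealed
geometrically) and a zero-temperature polish phase with geometrically
shrinking move amplitude. Moves displace one random body (axis uniform on
the sphere, angle ~ N(0, 2°), translation ~ N(0, 0.3 Å) per axis). An
optional soft-sphere excluded-volume penalty and optional whole-chain
group moves exist behind schedule flags but are off by default: on the
toy system, wide collective excursions can trade the quaternary rotation
against compensating tertiary motions at nearly unchanged chi-square, so
template-locality — small perturbed starts refined by single-body moves —
is the implicit and intended regulariser, exactly as in template-based
rigid-body refinement practice. The default schedule length (3000
steps) was chosen for reliable convergence of the toy system: most
starts reach chi-square below ~0.05, the level at which the scale
freedom stops masking the rotation amplitude; starts that fail to leave
the no-fit plateau are excluded by the ensemble threshold.

[run_ensemble()] refines from `n_starts` randomly perturbed copies of the
template (default 2° / 0.3 Å per body) with seeds derived from one master
seed (bit-reproducible). A start whose refinement never leaves the
no-fit plateau (chi-square still at the order of the null model's) is an
optimisation failure, not a candidate, and is redrawn up to twice with a
fresh derived seed. Candidates are selected with
chi-square ≤ 3 × the minimum. The relative factor is deliberately wider
than the spread of a converged run: with a tight factor the ensemble
collapses to the single luckiest run and ensemble statistics
(mean ± population sd over candidates) lose meaning, whereas the
published practice keeps dozens of candidates below threshold.

## Structural descriptors

* **E–F distance**: Cα(66)–Cα(102) per subunit, headline value the mean
  over both subunits.
* **Subunit rotation angle**: superpose chain A onto the reference's
  chain A (Kabsch on Cα), apply the transform to the whole dimer, take
  the Kabsch rotation of chain B onto the reference chain B and report
  its unsigned angle. Invariant to any global motion of the query.
* **Heme–heme distance**: Fe–Fe, the standard measure in this system;
  a flagged centroid fallback is used when Fe is absent.
* **Cα RMSD** after Kabsch superposition.

[ensemble_statistics()] evaluates these per candidate and reports
mean ± population standard deviation plus histogram bins; the population
convention matches mean ± sd reporting of small candidate ensembles.

## The synthetic generator

[make_toy_dimer()] builds a Cα-resolution dimer with the HbI topology:
two chains of eight helical segments (residues 1–112, so the marker
residues 66 and 102 exist), a heme (Fe + 12 ring atoms) per subunit with
an Fe–Fe distance of 18.4 Å, eleven interfacial water oxygens attached to
the heme bodies, and chain B the exact C2 copy of chain A. Each helix
axis carries its own fixed tilt: a bundle of near-parallel identical rods
is close to self-similar under large rotations, which would leave the
quaternary rotation nearly unobservable in the scattering curve; the
crossed arrangement mimics the globin fold and breaks that
pseudo-symmetry. Coordinates carry a small seeded jitter (0.15 Å) so the
structure is not artificially regular.

[make_intermediates()] produces the three intermediates. I1 is a
heme-dominated tertiary response (heme tilt and 1.2 Å displacement toward
the interface plus a small E-helix shift); I2 a wider relaxation of the
helix bundle; I3 carries the quaternary signature: a subunit rotation
about the interface axis (default 3.7°), a heme–heme distance change
(default −0.6 Å) and an E–F distance change (default +0.4 Å — the T-like
state widens the heme pocket). The motions were chosen, once, so that the
three species curves have comparable norms and are far from collinear,
which is what the measured species-associated curves look like and what
makes the third SVD component clearly significant. Construction details
that matter: the requested rotation is hit exactly (to < 0.05°) by a
closed-form Kabsch correction; the heme shift is applied along the
current Fe–Fe axis so the distance change is exact; the E–F change rolls
the E helix about the axis through its own terminal Cα atoms, which
leaves the backbone connectivity gaps untouched.

[simulate_dataset()] combines basis curves (Debye differences of the toy
intermediates against the ligated reference, or user-supplied analytic
curves), the solved populations, an optional heating component, and
i.i.d. Gaussian noise with σ = 2% of the peak |signal| per point —
the package's stand-in for the unpublished experimental noise level; all
recovery tolerances are quoted at this level. Defaults reproduce the
experimental sampling: 33 delays from 100 ps to 10 ms at four per decade,
200 q points over 0.15–1.0 1/Å.

**What the generator does not emulate:** detector artefacts, the 4%
X-ray bandwidth smearing of q, q-dependent and correlated noise,
hydration-shell dynamics, and any tertiary motion outside the rigid-body
repertoire. Passing generate-and-refit tests therefore demonstrates the
correctness and internal consistency of the analysis chain, not the
field performance of the method on real detector data.

## Numerical choices and degenerate inputs

* ODE tolerances: rtol 1e-11 / atol 1e-14 by default (conservation to
  1e-9); the fit objective relaxes to rtol 1e-8 for speed.
* sin(x)/x is evaluated as 1 below |x| = 1e-8.
* Kabsch handles reflections via the determinant correction and flags
  near-collinear point sets instead of failing.
* `chi_square` errors on an all-zero model; `band_power_ratio` returns 0
  with a degeneracy flag when both bands vanish and Inf when only the
  wide band does.
* Equal R–T constants make the pair exchange-degenerate; the ordered
  parameterisation pins `tau_rt1 ≤ tau_rt2` and the mirrored-fraction
  starts cover the associated basin swap.
* Problem sizes throughout (200 q points, 33 delays, ~260-atom toy,
  10-seed recovery experiments, 20-start ensembles) are the package's
  validation scale, chosen so a full validation run completes on a
  laptop-class single core.

## Known limitations

* The Debye calculator has no hydration shell; absolute intensities are
  not comparable to shell-aware calculators, only differences are.
* `phi_full` and `k_bi` are weakly identified at the default noise level
  (see the identifiability paragraph); report them with their spread.
* The rigid-body ensemble quantifies curve-compatible structural spread
  around the template, not a Boltzmann ensemble; its sd underestimates
  true structural uncertainty wherever the curve is blind.
* The toy dimer is Cα-resolution; wide-angle features beyond q ≈ 1 1/Å
  are not meaningful.
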
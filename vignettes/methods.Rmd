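---
title: "Methods: surfaces, walkers, semiclassics and hindered rotors in vibquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surfaces, walkers, semiclassics and hindered rotors in vibquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`vibquant` packages a complete desk-scale chain for probing conformer
energetics with nuclear quantum effects: a permutationally invariant
polynomial (PIP) surface with a Δ-correction layer, unbiased diffusion
Monte Carlo (DMC) for zero-point energies and ground-state densities,
adiabatically switched time-averaged semiclassical IVR (AS SCIVR), and
periodic discrete variable representation (DVR) for one and two coupled
hindered rotors. This vignette records the models, their assumptions, the
tunable parameters with units and defaults, and the numerical choices that
were genuinely open — the things a maintainer would otherwise have to
reverse-engineer from the code.

All internal computation is in Hartree atomic units (hartree, bohr,
electron masses, ħ = 1); conversion happens only at I/O boundaries
(`convert_energy()`, XYZ files in Å). Isotope masses come from a fixed
table (¹H 1.007825, ²H 2.014102, ¹²C 12, ¹⁶O 15.994915 amu,
1 amu = 1822.888486 mₑ).

## PIP surfaces and the Δ-correction

A potential is expanded as V(**x**) = Σᵢ cᵢ pᵢ(**x**) in the n(n−1)/2 Morse
variables x_αβ = exp(−r_αβ/λ), λ = 2 bohr by default. Each basis function
pᵢ is the sum of one orbit of monomials (total degree ≤ d) under the
permutation group of identical atoms induced on atom pairs, so invariance
is exact by construction; the constant monomial is a member. Orbits are
found by canonical-key minimization over the explicit group, and
`pip_orbit_count_burnside()` provides an independent cycle-type count —
for a 9-atom 321111 system the two agree at 208 (d = 2) and 14 752 (d = 4).

Coefficients are fit by minimum-norm least squares (SVD with a
rank-revealing tolerance; rank deficiency is flagged, never silently
regularized). Gradient rows enter through the analytic chain rule with a
configurable weight, default 1/3N per row, chosen so that one geometry's
gradient block carries roughly the weight of one energy row. The
correction surface is trained on high-minus-low energy differences shifted
so the minimum difference maps to zero; `compose_delta()` adds the shift
back, so the composed surface tracks absolute high-level energies
pointwise (a pure constant that cancels in every physical difference).

## Synthetic world

Since no electronic-structure data ship with the package, a model molecule
carries two analytic surfaces. The high-level surface is a sum of pairwise
Morse terms whose parameters depend only on the unordered atom-class pair
(D_e ∈ [0.04, 0.15] hartree, a ∈ [0.9, 1.4] bohr⁻¹, r_e ∈ [2.2, 3.8] bohr,
seeded), making permutation invariance exact; its equilibrium is located
by a seeded BFGS search that retries until all 3N−6 vibrational curvatures
are positive. The low-level surface adds a smooth class-symmetrized
quadratic polynomial in group-summed Morse variables, rescaled so its
spread over a thermal probe cloud is `delta_scale_cm1` (default
300 cm⁻¹) — a correction an order of magnitude smaller and smoother than
the ~35 000 cm⁻¹ sampling range, which is the premise that lets a degree-2
basis fit it.

Corpora are drawn by independent Gaussian displacements along the
high-level normal modes with per-mode scale √(kT_eff)/ω and a rejection
cap (default 35 000 cm⁻¹ above the minimum; default kT_eff = cap/15). Each
record samples its temperature from a three-rung ladder (kT, kT/2, kT/6
with weights 0.5/0.3/0.2): an ab initio MD corpus is dense near
equilibrium and sparse near the cap, and the ladder reproduces that shape
while covering ≳ 90 % of the energy window. What the generator does *not*
emulate: temporal correlation of an MD trajectory, anharmonic mode
coupling in the sampling distribution, and dissociative fragments — so a
green test certifies the algorithms against this stated world, not the
behavior of any real molecule's surface. The published sparse-selection
recipe is reproduced literally: every eighth geometry (1-based: indices
1, 9, …) of the 8500-record training pool → 1063; the first half of the
2500-record test pool; plus exactly 6 geometries above 30 000 cm⁻¹ from
the remaining half → 2319 total, partitioned 2069/250 by a seeded uniform
draw (the original partition method is unstated; we expose the seed).

## Diffusion Monte Carlo

The walker ensemble diffuses with per-coordinate variance Δτ/m and
branches against the reference energy with the unbiased birth/death rule
P_death = 1 − e^{−(Eᵢ−E_r)Δτ}, P_birth = e^{−(Eᵢ−E_r)Δτ} − 1 (one
offspring per walker per step; the cap prevents population explosions at
Δτ = 5 au). The reference updates as E_r = ⟨V⟩ − α(N−N₀)/N₀ with
α = 1/Δτ by default (the feedback strength is a free parameter in the
protocol; 1/Δτ is the conventional choice). A walker whose potential falls
more than `hole_floor_cm1` (default 1000 cm⁻¹) below the global minimum is
treated as having entered an unphysical extrapolation hole: it is killed
and counted, and the simulation continues. The ZPE is the mean reference
energy over post-equilibration steps; the uncertainty is the standard
deviation of independent simulation means over √(number of simulations),
exactly recomputable from the stored per-simulation means.

Two systematic effects matter at desk scale and are documented rather than
hidden: the finite-Δτ bias (second order in Δτ, a few cm⁻¹ at Δτ = 5 au
for frequencies up to ~3900 cm⁻¹) and the population-control bias, which
scales as 1/N(0) and is the reason the published protocol uses 20 000 to
40 000 walkers. At the walker counts the tests use (hundreds to a few
thousand), the statistical acceptance bounds include a 0.2 % allowance for
these biases; we measured the control bias on the 21-mode harmonic fixture
dropping from ≈ 440 cm⁻¹ at N = 400 to ≈ 40 cm⁻¹ at N = 4000, consistent
with 1/N scaling.

One physics point: unbiased DMC without descendant weighting histograms
the walker density, which samples the ground-state wavefunction ψ itself
(not |ψ|²). The harmonic-fixture test therefore checks the histogram
variance against ħ/(mω), and the walker histograms are presented as
wavefunctions, matching how DMC walker distributions are conventionally
plotted.

## AS SCIVR

Semiclassics runs in mass-weighted coordinates (unit masses). Trajectories
start exactly on the harmonic ZPE shell (per-mode action ħ/2, uniform
phases) and are relaxed onto the true Hamiltonian by propagating
H(t) = (1−λ(t)) H_harm + λ(t) H_anh with
λ(t) = t/T_AS − sin(2πt/T_AS)/2π, which rises monotonically with vanishing
endpoint derivatives — the requirement of the adiabatic theorem. The
published protocol's times (T_AS = T = 25 000 au, step 10 au) are the
config defaults; a 4th-order Forest–Ruth symplectic composition integrates
both the trajectory and the monodromy blocks with the same splitting, so
det M = 1 is preserved to ~10⁻¹⁴ on linear systems. Trajectories are
rejected the first time |det M − 1| exceeds the 1 % tolerance (or when
they diverge).

The spectral density is the time-averaged Herman–Kluk form
I(E) ∝ ⟨|∫₀ᵀ dt e^{i(Sₜ + Et + φₜ)} ⟨Ψ|g(pₜ,qₜ)⟩|²⟩ with diagonal
coherent-state widths Γ numerically equal to the harmonic frequencies. The
prefactor phase φₜ is half the continuously tracked argument of
det ½(M_qq + Γ⁻¹M_ppΓ + iΓ⁻¹M_pq − iM_qpΓ); the sign/branch convention is
pinned by the harmonic exactness tests (φₜ = −ωt/2, lowest peak exactly at
ω/2) rather than by transcription, since prefactor conventions differ
across the literature. The reference state |Ψ⟩ is a coherent state at the
equilibrium geometry carrying the harmonic ZPE-shell momenta p_eq = √ω:
with zero momenta it would coincide with the harmonic ground state and all
excited lines would have strictly zero overlap, which is also why the
tests of excited levels use this reference.

Peak detection is a numerical choice worth recording: the finite-T window
makes every line a sinc² whose sidelobes (up to a few percent of the
parent within ~3.5 lobe widths 2π/T) register as spurious local maxima.
Detected maxima below 2 % of the global maximum are dropped, and any
candidate within 5 lobe widths of a stronger accepted peak is merged into
it, with quadratic interpolation on the survivors. The cost is that
genuine lines closer than 5·2π/T cannot be resolved — lengthen T when that
matters. Measured accuracy on fixtures: exact (grid-limited) on harmonic
systems in 1-D and 2-D; within ~2 cm⁻¹ of the analytic Morse ground state;
within ~1 cm⁻¹ of the DVR and DMC values on the 1208 cm⁻¹ methyl hindered
rotor — comfortably inside the method's customary 20–30 cm⁻¹ band.

## Torsion model and DVR

The two-rotor surface is the symmetry-complete Fourier family
V(θ, φ) = Σ c_jk cos(jφ)cos(3kθ) + Σ d_jk sin(jφ)sin(3kθ), which enforces
exactly the 3-fold methyl periodicity, 2π-periodicity in the hydroxyl
angle, and the simultaneous reflection symmetry of the enantiomeric gauche
pair; the sin·sin block carries the gearing. The original functional form
is not published with the text, so the model is constrained to the printed
*stationary* data only: values and stationarity at (θ, φ) ∈
{(0,0), (60°,0), (0,60°), (60°,60°), (0,120°), (60°,120°), (0,180°),
(60°,180°)} encoding methyl barriers 1208 (trans), 1324 (gauche), 1283
(eclipsed saddle) and 1404 cm⁻¹ (syn saddle), hydroxyl saddles 377 and
472 cm⁻¹, and the gauche minimum at +38 cm⁻¹. All constraints are linear
in the coefficients. The open design choice was how to resolve the
remaining freedom (14 constraints, 46 coefficients at the default orders
J = 6, K = 3): a plain minimum-norm solution satisfies the constraints but
leaks high harmonics that create spurious wells between the constrained
points, so the solver minimizes a weighted norm with weights 2ʲ·4ᵏ — the
smoothest consistent surface. Any weight base ≳ 1.5 gives the same
stationary structure; the printed values are then reproduced to ~10⁻¹⁰
cm⁻¹. Because only stationary data constrain the fit, two-rotor level
patterns are approximate by design and the 2-D DVR comparison is
qualitative.

The minimum-energy path between wells is computed as the axis-aligned
minimax (bottleneck) path: bisection over an energy threshold with
flood-fill connectivity, then a breadth-first shortest path inside the
passable corridor. On the fitted model the bottleneck equals the smallest
constrained methyl barrier and the route alternates hydroxyl and methyl
runs through the low saddle gates — the geared staircase; on a separable
model it degenerates to two independent axis moves.

The 1-D azimuthal DVR uses the closed-form periodic kinetic matrix on an
odd grid over [0, 2π); the 2-D version is the direct product with the
potential diagonal. Rotor inertias follow the convention that the printed
"value/(N_AV·mₑ)" is numerically amu·bohr² (confirmed by the μ·r² ≈ 3.2
arithmetic for the hydroxyl rotor); defaults are 2.7 (OH) and 10.5 (CH₃)
amu·bohr². `omit_cross_terms = TRUE` zeros *every* coefficient with j ≥ 1
and k ≥ 1 — both blocks — because a separable comparison surface means
f(θ) + g(φ); zeroing only the sin·sin block would leave cos·cos cross
terms in place. Level assignments (v_OH, v_CH₃, e/o parity) come from
nodal counting of the dominant 1-D profiles and parity under φ → −φ; for
near-degenerate tunneling multiplets this labelling is heuristic and
should be read as a guide, not a rigorous correlation.

Grid convergence: the 1-D problems are spectrally converged long before
the default N = 161; doubling changes levels by ≪ 10⁻⁴ cm⁻¹. For the
geared 2-D model the measured doubling change 81×41 → 161×81 of the lowest
twelve levels is 1.2×10⁻⁴ cm⁻¹ — the sharply localized methyl ground
state needs Fourier content beyond the potential's own order — and a
further doubling exceeds desk-scale memory, so the package defaults keep
the published 161×81 grids while the tests and pipeline use 81×41 or
smaller (dense 13 000-dim diagonalizations take minutes on one CPU).

## Pipeline and reproducibility

`run_pipeline()` chains the stages from a single config list with one
global seed; every stage derives a logged sub-seed, writes plain-text
artifacts (CSV, XYZ, the dataset format) and an md5 manifest, and a rerun
with the same config is bit-identical. The pipeline defaults are
deliberately desk-scale (hundreds of walkers, a dozen semiclassical
trajectories); the module configs carry the published protocol values as
their own defaults (30 000 × 5 au DMC steps, 25 000 au switching and
averaging times, 1 % rejection tolerance).

## Known limitations

* The synthetic world has no real electronic structure: published
  molecule-specific quantities that require the real coupled-cluster
  surface (the 17 321/17 298 cm⁻¹ anharmonic ZPEs, the 49/63 cm⁻¹ fit
  RMSEs, exact 2-D level tables) are out of reach by construction and are
  not claimed.
* DMC at desk-scale walker counts carries a visible 1/N population-control
  bias; scale N(0) up before quoting absolute ZPEs.
* The SCIVR module targets ground-state quantization; excited levels
  require hotter initial shells and longer T, and very dense level
  structure collides with the sidelobe-merging radius.
* The torsion model reproduces stationary values, not full cut shapes;
  relaxed (adiabatic) cuts and rotational-torsional coupling are not
  modelled.
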
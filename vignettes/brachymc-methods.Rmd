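---
title: "Monte Carlo photon dosimetry for brachytherapy seeds: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monte Carlo photon dosimetry for brachytherapy seeds: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and model

`brachymc` computes photon dose around sealed brachytherapy sources
(LDR ^125^I seeds, HDR/PDR ^192^Ir sources) with an analog Monte Carlo
photon engine and characterizes them in the AAPM TG-43 formalism,

$$\dot D(r,\theta) \;=\; S_K\,\Lambda\,
  \frac{G_L(r,\theta)}{G_L(r_0,\theta_0)}\, g_L(r)\, F(r,\theta),$$

with $r_0 = 1$ cm, $\theta_0 = 90^\circ$, the line-source geometry factor
$G_L = \beta/(L r \sin\theta)$, the radial dose function $g_L$, the
anisotropy function $F$, and the dose rate constant
$\Lambda = \dot D(r_0,\theta_0)/S_K$ in cGy h^-1^ U^-1^
(U = cGy cm^2^ h^-1^).  Because every reported quantity is a ratio of
per-history tallies, absolute activity never enters: $\Lambda$ is the ratio
of the in-water kerma per history at (1 cm, 90°) to the in-vacuo air-kerma
strength per history.

The engine tracks photons only, under the kerma approximation: secondary
electrons deposit their energy where they are set in motion.  At the photon
energies involved (20 keV to 670 keV) CSDA electron ranges in tissue are
well below a millimetre, i.e. below every scoring cell used here, so the
collision kerma scored by the track-length estimator (TLE) is an accurate
surrogate for absorbed dose.  Bremsstrahlung, pair production and electron
transport are out of scope by design.

## Physics data

All interaction data ship as plain-text element tables
(`inst/extdata/xs/`), generated once by `tools/make_physics_tables.py` from
published physics and validated in-script against NIST-grade water and air
anchor values before being written:

* photoelectric cross-sections from the Cromer–Liberman photoabsorption
  $f''$ (σ = 2 r_e λ f''), with absorption edges located from the $f''$
  discontinuities and duplicated grid points just below/above each edge;
* incoherent (Compton) cross-sections from the Klein–Nishina law weighted
  by a Waller–Hartree incoherent scattering function $S(x, Z)$, built from
  hydrogenic K/L cores plus the IT92 atomic form-factor residual for the
  outer electrons;
* coherent (Rayleigh) cross-sections from the Thomson law weighted by IT92
  form factors (hydrogenically damped beyond the fit's validity so
  $F \to 0$);
* mass energy-absorption coefficients built as
  $\mu_{en} = \tau\,(1 - \bar E_{fluor}/E) + \sigma_{inc}\,\bar T/E$ with the
  K-fluorescence escape fraction and the Klein–Nishina mean energy-transfer
  fraction; radiative losses are neglected (< 1% below 1 MeV).

Element tables span 1–1000 keV at 20 points per decade with log–log
interpolation; mixtures follow the mass-fraction rule.  Validation at
NIST-grade anchors gives total attenuation within 2.6% and $\mu_{en}$
within 0.2% above 50 keV; the worst region is 20–30 keV, where the
photoelectric component runs ~5% low (the Cromer–Liberman fit degrades far
above the light-element K edges) and the incoherent component ~10% high,
with partial cancellation in the total.  This is the package's low-energy
accuracy limit and the reason the ^125^I dose-rate constants carry a few
per-cent model uncertainty, while ^192^Ir results (where Compton dominates
and the data are within ~0.5%) are essentially unbiased: the engine
reproduces the famously flat ^192^Ir radial dose function in water
($g_L \approx 1.00$ to 5 cm) without adjustment.

**Why the incoherent scattering function is applied in angle sampling.**
An early design assumption was that sampling pure Klein–Nishina angles
(free electrons) would bias water dosimetry at ^125^I energies by ~1%.
Direct testing falsified that: without the $S(x,Z)$ suppression of
small-angle scattering the scatter buildup at 3–5 cm is overestimated by
tens of per cent and $g_L(5\,\mathrm{cm})$ comes out ~0.37 instead of the
expected ≈ 0.23–0.26 for this seed class.  The engine therefore samples
Compton angles with Kahn's Klein–Nishina rejection followed by an
$S(x)/S(x_{max})$ rejection against the tabulated scattering function of
the sampled element.  The exported `compton_scatter()` remains the pure
free-electron law; `incoherent_scatter()` is the bound-electron law the
engine uses.

Radionuclide spectra are bare line spectra (^125^I: 5 lines, 27.2–35.5 keV;
^192^Ir: 18 lines, 65–612 keV including the Pt/Os K X-rays); the ^192^Ir
beta continuum is absorbed in the source core and capsule and is omitted,
consistent with photon-only transport.

## Seed models

Each of the six sources is a nested stack of analytic solids (cylinders,
capsules with hemispherical caps, spheres, cone frustums) read from a
reviewable data file with a citation line per datum (TG-43U1 consensus
descriptions for the LDR seeds; the published source-design papers for the
HDR/PDR wires).  Conventions:

* local frame: +Z through the source tip, origin at the centre of the
  active region;
* innermost-wins material resolution for nested solids; a ray starting
  exactly on a surface belongs to the side its direction points into;
* the 6711's activity is a silver-surface coating (surface-uniform
  emission); the other five emit volume-uniformly from their cores, with
  nested markers (the I25.S06 gold rod) excluded from the emitting volume;
* HDR/PDR sources carry a proximal cable stub that breaks tip/cable
  symmetry exactly as in the physical sources.  The SPEC M-19 file is an
  approximate registry description and is flagged as such.

## Transport and scoring

Homogeneous worlds (the 15 cm water characterization sphere, vacuum for
$S_K$) use analytic surface-to-surface tracking; voxel phantoms use
Woodcock delta tracking with a per-energy majorant over the phantom's
materials, with null collisions never touching the scorers.  Every flight
segment is offered to the scorers before the next interaction:

* **annular (r, θ) TLE maps** score collision kerma with exact chord
  lengths through spherical shells (default TG-43 grid: shells of ±2.5%
  thickness at 0.25–10 cm, 5° polar bins with a 1° bin at 90°);
* **Cartesian TLE maps** use Amanatides–Woo traversal (local voxel material
  in phantoms, a fixed medium otherwise);
* **analog deposition maps** score the energy transferred at interaction
  sites — the independent estimator used to cross-check the TLE;
* **$S_K$** is scored in vacuo (WAFAC-style: no air attenuation, air
  $\mu_{en}/\rho$) on thin transverse rings at 5 and 10 cm with a 5 keV
  low-energy (delta) cut, reported as the mean of $K d^2$; the tracking
  cutoff (1 keV, deposited locally) is distinct from this cut.

K-shell fluorescence is simulated after photoabsorption (yield × K-shell
fraction from the tabulated edge jump); it matters greatly for the 6711,
whose silver K X-rays (22–25.5 keV) are ~19% of the escaping photons.
Uncertainties use the history-by-history estimator with per-cell pending
accumulators; the per-history RNG is counter-seeded (xoroshiro128++ keyed
by history index), so results are bit-reproducible and independent of batch
order.

## Phase-space files

`generate_phsp()` transports decay photons through the seed's own materials
(vacuum outside) and records every photon crossing the outer union surface
outward: energy, position (seed frame), direction, weight, with a uint8
particle-type code.  All gammas are recorded — capsule-scattered primaries
and source-born fluorescence alike — while electrons are never tracked; a
`fluorescence = FALSE` variant yields a primary-line-only file for
diagnostics.  The `.phsp` container is little-endian with an ASCII header
(counts, seeds, checksum) and 33-byte fixed records; readers distinguish
version, truncation and checksum failures.  Replay draws records uniformly
(or cyclically) and applies a rigid pose, so one file serves every seed
position in a plan.

A replayed map equals a direct simulation up to two documented effects:
the latent shot noise frozen into a finite record file (~7% per profile
point for 10^4 records, the study's file size), and the absence of the
seed solids in replay (no re-entry shadowing).  With matched history
counts the central-profile mean absolute difference within 2 cm stays
below 10%.

## Clinical pipeline and the synthetic pelvis

CT rasters convert to phantoms via closed-open HU intervals over
[−1050, 4000): Lung [−1050, −600), SoftTissue [−600, 100), ProstateICRU
[100, 300) (inside a declared prostate mask, else SoftTissue), CorticalBone
[300, 4000], with fixed nominal densities — the interval cut points are
this package's documented stand-in, since only the materials and the span
are fixed by convention.  The bundled synthetic pelvis
(`make_pelvis_phantom()`) is a deterministic ellipsoid phantom on the
clinical CT grid (0.78125 × 0.78125 × 2.0 mm; default extent
10 × 10 × 9.6 cm) with prostate, urethra, bladder, rectum (with a gas
pocket) and pelvic bones, plus `make_plan_67()`, a 67-seed lattice plan
clipped to the prostate.  It emulates the geometry and material mix of a
real implant CT, not patient anatomy: tissue textures, HU noise,
calcifications and real seed placement heuristics are absent, so passing
tests demonstrate the transport/scoring pipeline, not clinical dosimetry of
any patient.

Plan simulation replays each entry's phase-space file at its pose (entries
sampled proportional to S_K), through Woodcock tracking with TLE scoring on
the phantom grid; seeds other than the emitter are not materialized
(pure replay into tissue — the GPU-style workflow; interseed attenuation is
therefore excluded, as in TG-43 superposition).  The per-history dose map
is scaled by the plan's total S_K, making it linear in the plan strengths;
absolute dose would additionally need implant duration and decay, which the
package does not model.  Analysis tools: cumulative DVHs
(voxel counting ≡ volume weighting on the uniform grid), strict-threshold
nested isodose masks, and profile comparisons using the ratio-to-mean
difference with a σ-gate.

## Numerical choices and problem sizes

* Characterization runs use 10^6–4×10^6 histories: the transverse-shell
  tallies then carry ~1–2% statistical uncertainty on Λ (the reference
  study used 10^12 for sub-1% everywhere, which is out of desk scale).
* The S_K leg runs the same history count as the water leg; its two ring
  distances are strongly correlated (same photons), so the quoted spread is
  the conservative per-distance value.
* The 67-seed case uses 3×10^6 histories, which brings the prostate-mask
  mean σ_rel below 3% on the clinical grid.
* Degenerate inputs fail loudly: empty rasters and masks, overlapping S_K
  rings, non-unit directions, out-of-span energies, missing phase-space
  files, on-axis geometry-factor poles inside the active line.
* Radial extrapolation of g/F is nearest-slope log-linear, limited to 20%
  beyond the table; anything farther returns NA rather than a silent value.

## Known limitations

* Low-energy (< 40 keV) cross-section residuals described above: ^125^I
  Λ values carry a ~2–3% model uncertainty and the ^125^I g_L(r) tail
  beyond 3 cm is somewhat flat relative to consensus data.
* No electron transport: quantities within ~1 mm of a source capsule are
  collision kerma, not dose.
* No Doppler broadening, L-shell fluorescence or polarization; Rayleigh
  uses independent-atom form factors.
* One seed model per replay run; plans mixing source models are rejected.
* The synthetic pelvis is a fixture, not anthropomorphic ground truth.
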
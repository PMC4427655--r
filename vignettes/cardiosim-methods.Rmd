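---
title: "Reduced-order modeling of ischemic mitral regurgitation and its device therapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reduced-order modeling of ischemic mitral regurgitation and its device therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`cardiosim` is a desk-scale simulator of left-ventricular (LV) function,
ischemic mitral regurgitation (IMR), and the correction of IMR by an
undersized annuloplasty ring carrying a rigid sub-valvular element.  A
full-heart finite-element treatment of this problem uses hundreds of
thousands of elements; this package deliberately replaces the 3-D
continuum with the smallest set of mechanistic components that still
carries the chain of causation:

myocardium constitutive law → ventricular pressure generation →
circulation and pressure–volume loops → infarct → papillary tethering →
valve coaptation and chordae forces → device contact.

This vignette documents the model equations, the tunable parameters and
their defaults, the calibration protocols, the numerical choices, and
the known limitations — in particular, which headline outcomes the
reduced model reproduces and which it provably cannot.

## Passive myocardium

Passive myocardium is modeled by an orthotropic exponential
(Holzapfel–Ogden-type) strain-energy density on the full invariants of
the right Cauchy–Green tensor \(C = F^\top F\), expressed in the local
fiber/sheet/normal frame \((f_0, s_0, n_0)\):

\[
\Psi \;=\; \frac{a}{2b}\bigl(e^{b(I_1-3-2\ln J)}-1\bigr)
 + \sum_{i\in\{ff,ss\}} \frac{a_i}{2b_i}\bigl(e^{b_i\langle I_{4i}-1\rangle^2}-1\bigr)
 + \frac{a_{fs}}{2b_{fs}}\bigl(e^{b_{fs}I_{8fs}^2}-1\bigr)
 + \frac{k}{2}(\ln J)^2 ,
\]

with \(\langle x\rangle=\max(x,0)\) so that fiber and sheet families
only stiffen in tension, and a volumetric penalty \(k \gg a\) enforcing
near-incompressibility.  The \(-2\ln J\) correction in the isotropic
exponent is the standard compressible form that keeps the reference
configuration stress-free; on isochoric motions it vanishes.  The
default parameter set is transversely
isotropic about the fiber direction:
`k = 1000`, `a = 0.33`, `b = 7.08`, `a_ff = 0.25`, `b_ff = 5.34` (kPa
for the scales), all sheet and fiber–sheet terms zero.  Several energy
variants exist in the literature (isochoric vs. full invariants,
different volumetric terms); the full-invariant form with the
log-squared volumetric penalty was chosen as the simplest member of the
family consistent with the parameter names, and the choice is isolated
in `strain_energy()` / `cauchy_stress()`.

Virtual simple-shear rigs (`shear_test()`) probe the law in the six
shear modes.  Mode `"XY"` applies \(F = I + \gamma\, e_Y\!\otimes e_X\):
material lines along axis X tilt toward axis Y, so modes `FN` and `FS`
stretch the fiber.  (The opposite convention — tilting Y-lines toward X
— renders the fiber parameters invisible in `FN`/`FS`, which would make
fitting fiber parameters to those curves ill-posed; the convention used
here is the one under which the classical fiber-dominated shear curves
and the parameter-recovery problem both make sense.)  The reported
abscissa is \(\gamma\) itself.

## Leaflet, chordae, and active-tension laws

Mitral leaflet (circumferential, radial) and chordae (basal, marginal)
tissue each use a two-parameter exponential true-stress law
\(\sigma(\varepsilon)=A(e^{B\varepsilon}-1)\) on true (logarithmic)
strain; chordae are tension-only.  Defaults (`default_tissue_laws()`)
are chosen so the leaflet is stiffer circumferentially than radially
and the chordae are stiffer marginally than basally at 10% strain, with
magnitudes typical of porcine valve tissue: circumferential
`A = 1.5, B = 25`; radial `A = 1.0, B = 15`; basal `A = 120, B = 30`;
marginal `A = 60, B = 45`.

Active fiber tension replaces the (out-of-scope) electromechanics by a
prescribed waveform
\(T(t,\lambda)=T_{\max}\sin^2\!\bigl(\pi (t-t_{act})/t_{dur}\bigr)\,
g(\lambda)\) inside the activation window, with linear length
dependence \(g(\lambda)=\langle 1 + c(\lambda-1)\rangle\).  The slope
default `c = 6` is a Frank–Starling-like sensitivity (tension roughly
doubles over a 15–20% fiber-length increase) and makes ejection
self-limiting: tension collapses before the cavity can empty
completely.  `t_dur = 0.4 s` on a 1 s cycle (heart rate 60 bpm; the
reference does not state one).  `T_max` is never set by hand — it is
calibrated (below).

## Material fitting

The fitting module replaces a commercial optimization workflow with
bounded Levenberg–Marquardt least squares (`minpack.lm::nls.lm`) on the
stacked stress residuals at the measured strains — exactly the
least-squared-differences objective, unit-tested against a
hand-computed three-point case.  Synthetic fixture curves
(`generate_synthetic_curves()`) stand in for the experimental leaflet
and chordae data: exponential-type, monotone, convex, with seeded
Gaussian noise (default 2% of each curve's peak stress).  Leaflet
fixtures span true strains 0–0.30; chordae fixtures 0–0.12.  The
chordae range matters: \(A\) and \(B\) of an exponential law are
strongly correlated when the fitted range spans many decades of stress,
so fitting chordae over a leaflet-like strain range returns parameter
pairs that reproduce the curve only at its stiff end.  Over each
tissue's measurement range the fits recover the generating curves
closely (the exponent within a few percent; zero-noise fits are exact
to 1%).

No numeric targets exist for the fitted leaflet/chordae values (the
reference never prints them), so parameter recovery on the synthetic
fixtures is the test surface, including a Monte-Carlo recovery study
across seeds.

## Reduced-order ventricle and circulation

The LV is transmurally lumped to a single myofiber.  Cavity volume maps
to fiber stretch through the mid-wall-volume closure
\(\lambda_f = \bigl((V + V_w/3)/(V_{ref}+V_w/3)\bigr)^{1/3}\), and total
fiber Cauchy stress (passive uniaxial-extension stress with zero
transverse stress, plus \((1-\phi)\) times the active tension, where
\(\phi\) is the infarcted wall fraction) maps to cavity pressure by the
thick-wall logarithmic closure
\(P = (\sigma_f/3)\ln(1+V_w/V)\).

The circulation is a two-state lumped model: constant venous filling
pressure behind a mitral inflow resistance, diode valves, and a single
arterial windkessel (compliance `c_art`, peripheral resistance
`r_per`).  Mitral regurgitation enters as a square-root orifice,
\(Q_{reg}=k\,A_{gap}\sqrt{P_{lv}-P_{ven}}\), with
\(k = 0.82\ \mathrm{mL\,s^{-1}mm^{-2}kPa^{-1/2}}\) from a discharge
coefficient of 0.6 and blood density 1060 kg/m³.  Explicit Euler
integration at `dt = 1 ms` runs repeated cycles until the sampled
volume trace changes by less than 0.1 mL between cycles (limit cycle).
Defaults (`circulation_params()`) were set to physiological systemic
values — venous pressure 1.1 kPa, arterial pressures ≈ 8–14 kPa, wall
volume 150 mL, unloaded cavity volume 40 mL — chosen so the healthy
end-diastolic volume lands near 120 mL; none of them is printed in the
reference, whose compartment parameters live in its cited methods
paper.

Two numerical guards exist: cavity volume is floored at 1 mL per step
(an extreme leak otherwise integrates through zero), and the healthy
calibration treats a crashed cycle as "ejection fraction 1" so the
bisection backs away from non-physical contractility.

**Healthy calibration.**  Two scalar targets define the healthy
baseline: ejection fraction 55% and maximum long-axis shortening
12.1 mm.  `calibrate_healthy()` solves the triangular two-parameter
system: `T_max` by bisection on EF (EF does not depend on the shape
factor), then the shape factor `aspect` in closed form, since the
long-axis length \(L = 20\,\mathrm{aspect}^{2/3}(3V/4\pi)^{1/3}\) mm
scales shortening exactly by \(\mathrm{aspect}^{2/3}\).  With the
default geometry the calibrated values are `T_max ≈ 23 kPa` and
`aspect ≈ 0.78`.  A cavity-volume-equivalent ellipsoid of a normal LV
needs a sub-unity shape factor to reproduce anatomical apex–base
shortening, so `aspect` is documented as an *effective* kinematic
factor and values below one are admissible.

**Infarct sizing.**  `size_infarct()` bisects the infarcted wall
fraction \(\phi\in[0, 0.6]\) until the converged cycle's EF matches the
post-infarct target (45%, tolerance 0.25 EF points).  EF is monotone
non-increasing in \(\phi\) (asserted over a grid), which justifies
bisection; with the defaults the sized fraction is \(\phi\approx0.18\).

## Quasi-static mitral apparatus

Each of 12 radial strips (two per scallop, A1–A3/P1–P3) is a 2-D plane
through the annulus: anterior and posterior leaflets are elastic cables
(6 and 5 segments) hinged at the annulus, loaded by a follower pressure
\(P_{lv}-P_{ven}\) normal to each segment, tethered by tension-only
chordae (anterior marginal; posterior marginal + basal) to a papillary
tip, and closing against each other through node-to-segment penalty
contact in both directions.  Strips are anatomically heterogeneous —
leaflets longest mid-scallop, papillary tips at slightly different
depths and positions — both because real valves are and because a
homogeneous ensemble responds as one rigid unit whose contact
rearrangements produce artificial jumps in averaged quantities.

Annulus kinematics follow \(D(t) = D_{ref}(V(t)/V_{ref})^{1/3}\); a
rigid attached ring freezes \(D\) at `undersize_factor × D_ref`
(default 0.85) with the suture points modeled as hard hinge constraints
(no separation), while all other contacts are unilateral.  The
sub-valvular element is a rigid disc (radius 3.5 mm) below the
posterior annulus (depth 6 mm, reach 4.5 mm): posterior leaflet nodes
contact it by penalty, and posterior chordae wrap it frictionlessly
(tangent-line geometry), which lengthens their path and redirects their
pull — the mechanism by which the device pushes the posterior leaflet
anteriorly and re-tensions the chordae.

An infarct displaces the posteromedial papillary tips (strips covering
P2, P3 and half of P1) apically and laterally in ratio 2:1 by
\(\phi \cdot s\) mm, where `s` (`pap_disp_scale_mm`) is the calibrated
displacement scale.  The posterior chordae follow the displaced tip;
the anterior leaflet's tether stays at the healthy position because the
anterolateral muscle is remote from a posterior infarct.  (A variant in
which both leaflets follow the displaced tip was explored and rejected:
the free edges then ride down the taut-chordae sphere together and the
valve never loses coaptation, contradicting the tethering-induced
malcoaptation the model exists to produce.)

### Solving a strip

Equilibrium is a root of the nodal force residual \(R(u)=0\) (22
degrees of freedom per strip).  The production path is a compiled
kernel (Rcpp) for the residual, its finite-difference Jacobian, and a
dynamic-relaxation driver; a plain-R reference implementation of the
identical residual is kept and unit tests assert the two agree, so the
kernel never goes untested.  The solve is damped Newton with
backtracking line search on \(\lVert R\rVert\); on stalls it falls back
to dynamic relaxation with kinetic damping (velocities zeroed at each
kinetic-energy peak) from both a coapted and an open reference guess,
then polishes with Newton.  Tolerances: relative residual `1e-8`
(against the pressure-load scale, floored at 1e-6 mN); a stalled solve
below 5e-3 relative is accepted as an equilibrium — commercial
implicit FEM codes use comparable force tolerances — and anything
worse is an error.  Penalty stiffness defaults to 400 kPa/mm so that
equilibrium penetrations stay below the 10×`gap_tol` failure bound at
chordae-scale loads; the penalty force and the chordae slack/taut
transition are C¹-smoothed over small bands (0.1 mm; 1% strain)
because hard kinks make Newton chatter at grazing contact.

Coaptation length is the anterior arc length within contact tolerance
of the posterior leaflet; when no contact exists the free-edge gap
feeds the regurgitant area \(A_{gap} = \sum_i \mathrm{gap}_i\, w_i\)
passed to the circulation.

### Branch selection and continuation

A tethered valve strip has coexisting coapted and open equilibria near
the malcoaptation threshold.  Isolated cold solves pick between them
unpredictably, so every sweep in the package is a continuation:
within a systolic sweep each sampled instant warm-starts from the
previous one (which requires at least about a dozen systolic samples —
coarser sweeps jump too far between instants for the warm march to
track the branch); the infarcted arm continues from the healthy arm's
equilibria; the displacement-calibration grid chains its evaluations;
and the treated arm ramps the papillary displacement up under the
device in ≤ 5 mm steps.  This makes the pipeline deterministic
(bit-identical reruns) and keeps each arm on the physically continuous
branch reached from the healthy beating state.

### Valve–circulation coupling

Systole is sampled at 20 instants across the ejection window.  The gap
area time course is fed back into the circulation as the leak orifice
and the cycle re-run, iterating to a fixed point (change in gap area
< 1 mm², at most 8 passes, with 0.5 under-relaxation).

## The three-arm study and its calibrations

`run_study()` executes: seeded material fitting → healthy calibration →
healthy arm → infarct sizing → papillary-displacement calibration →
infarcted arm → device attachment → treated arm, and emits per-arm
cycle metrics and normalized chordae-force traces (normalized by the
healthy peak, so the healthy trace peaks at exactly 1).  The only
random element is the fixture noise, under the study seed; everything
downstream is deterministic.

**Displacement calibration and its documented failure.**  The protocol
calibrates `pap_disp_scale_mm` so the infarcted arm's peak normalized
posterior chordae force matches 78% of healthy.  In this model that
target is unreachable, and the reason is structural, not numerical: at
zero displacement the normalized peak is ≈ 0.88 (the infarcted pressure
ratio), and any displacement large enough to open a regurgitant gap
stretches the near-inextensible exponential chordae, so the force
*rises* monotonically (verified by a continuation sweep over the full
displacement range).  A drop to 78% *simultaneous with* regurgitation
requires load-path redistribution — a coaptation line that shifts with
the whole apparatus while leaflet membrane stresses, not chordae,
absorb the geometry change — that a quasi-static 2-D strip model cannot
express.  When the target cannot be bracketed the calibration falls
back, with a warning, to the mildest tethering that produces a clearly
regurgitant valve (peak gap area > 5 mm²) and reports the achieved
ratio (≈ 1.44 with the defaults).  The treated arm then *predicts*, with
every parameter frozen, that the device restores coaptation (gap area
≈ 22 → 0 mm², regurgitation abolished) while keeping the chordae force
well above the healthy level (≈ 1.38 × healthy) — the qualitative device
mechanism, with the quantitative normalization inherited from the
untreated arm's bias.

What passing tests do and do not show: the synthetic fixtures and the
reduced twins validate the *machinery* (constitutive laws, fitting,
limit-cycle hemodynamics, contact mechanics, device kinematics) and the
directional physiology; they do not validate 3-D stress distributions,
and the chordae-force normalization levels are known to disagree with
the full-FEM reference, as analyzed above.

## Worked example

```{r, eval = FALSE}
library(cardiosim)

report <- run_study(study_config(), out_dir = "results")
report
#> <study_report>
#>        arm EDV_ml ESV_ml EF_pct shortening_mm regurgitant_volume_ml
#>    healthy  119.1  53.56  55.04        12.100                 0.000
#>  infarcted  124.1  66.60  46.32         9.821                 1.471
#>    treated  124.6  68.39  45.12         9.519                 0.000
#>  peak_P_lv_kPa max_A_gap_mm2 peak_chordae_force_N peak_chordae_norm
#>          13.98          0.00               0.1956             1.000
#>          11.86         21.72               0.2817             1.440
#>          11.89          0.00               0.2704             1.382
#> infarct: phi = 0.1828  pap_disp_scale = 20 mm
```

## Problem sizes and determinism

The shipped defaults — 12 strips × 20 systolic samples, 1 ms
circulation steps, 30-point fixtures — run the full study in well under
a minute on a single core while keeping every calibration inside its
stated tolerance; halving the circulation step changes EF by less than
0.1 points and the strip discretization is fine enough that contact
reconfigurations move averaged forces by far less than the acceptance
tolerances.  Reruns with identical configuration are bit-identical.

## Known limitations

* One lumped fiber: no transmural or regional heterogeneity, no wall
  strain maps; the infarct acts only through \((1-\phi)\) on active
  tension and through papillary displacement.
* Quasi-static, flow-free valve: no fluid forces on leaflets, no
  inertial closure dynamics; branch selection is handled by
  continuation rather than by true dynamics.
* 2-D strips: no membrane coupling between strips, no circumferential
  (commissural) gap mechanism — which is exactly why the post-infarct
  chordae-force *decrease* of the full 3-D reference cannot be
  reproduced (see above).
* The device is rigid, so device stresses and strains are not
  available, and its dimensions are package defaults, not measured
  geometry.
* No atria, right heart, baroreflex, or fatigue/durability modeling.
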
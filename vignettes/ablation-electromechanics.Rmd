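---
title: "Desk-scale electromechanics of left-atrial ablation lesions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Desk-scale electromechanics of left-atrial ablation lesions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`ablamech` implements a desk-scale version of a coupled
electromechanics-circulation analysis of left-atrial (LA) ablation
strategies.  Rule-based radiofrequency lesion sets (pulmonary vein isolation
PVI, mitral isthmus line MIL, anterior line AL, roof line RL, posterior box
BL) alter the electrical activation sequence and stiffen the tissue; the
pipeline quantifies the downstream effect on pumping biomarkers — stroke
volume (SV), ejection fraction (EF), its loss versus the healthy control
(ΔEF, percentage points), ablated-tissue fraction (AT) and inactive-tissue
fraction (IT) — and the linear relationship between lesion burden and ΔEF.

The physics stack is:

* **Tissue electrophysiology.** The monodomain reaction-diffusion equation
  for the transmembrane voltage `V_m`,
  `beta*C_m dV_m/dt + beta*I_ion = div(sigma grad V_m) + beta*I_ext`, with
  the anisotropic conductivity tensor
  `sigma = sigma_f f0xf0 + sigma_s s0xs0 + sigma_n n0xn0`
  (`sigma_f >= sigma_s >= sigma_n >= 0`) built on per-element fiber frames,
  homogeneous Neumann boundaries, first-order operator splitting (explicit
  hybrid Rush-Larsen reaction, implicit backward-Euler diffusion with a
  pre-factorized sparse system), linear tetrahedra with lumped mass.
* **Cell models.** The Courtemanche-Ramirez-Nattel human atrial model (21
  state variables, transcribed from the original publication, validated
  against its printed resting state and action-potential properties), and a
  two-variable Mitchell-Schaeffer-type ventricular surrogate mapped to
  physical voltage.  The surrogate replaces a full human ventricular ionic
  model, which is outside desk-scale scope.
* **Activation.** Local activation time `t_A(x)` is the first upward
  crossing of −20 mV, linearly interpolated between 1 ms samples; tissue
  that never crosses is *inactive*.  IT is the volume fraction of LA
  myocardium that never activates, scar included; AT is the scar fraction
  itself, so IT ≥ AT and the difference is electrically isolated but
  viable tissue.
* **Active tension.** The phenomenological transient
  `S_A = S_peak * phi(lambda) * tanh^2(t_s/tau_c) * tanh^2((t_dur-t_s)/tau_r)`
  with `phi = max(tanh(ld (lambda - lambda0)), 0)`,
  `tau_c = tau_c0 + ld_up (1 - phi)`, `t_s = t - t_A - t_emd`, entering the
  second Piola-Kirchhoff stress as `S_A (f0xf0)/lambda_f` (fiber-only
  activation weights `n_f = 1`, `n_s = n_n = 0`).
* **Passive mechanics.** Orthotropic exponential (Fung-type) strain energy
  `Psi = mu/2 (exp(alpha Q) - 1) + kappa/2 (log J)^2` with
  `Q = b_ff E_ff^2 + b_ss E_ss^2 + b_nn E_nn^2 + b_fs(...) + b_fn(...) + b_ns(...)`
  on Green-Lagrange strain components in the fiber frame; Neo-Hookean for
  non-myocardial passive tissue.  Bulk myocardium uses mu = 325.56 Pa,
  alpha = 22, kappa = 1e6 Pa, rho0 = 1082 kg/m^3 and
  b = (1, 0.4, 0.3, 0.7, 0.6, 0.2).  Ablation scar is isotropized
  (b diagonal 1, off-diagonal 0.5) with mu doubled (651.12 Pa) and alpha
  five times higher (110); both multipliers are exposed as the
  scar-stiffness sensitivity knob.
* **Structural dynamics.** Total-Lagrangian FEM on linear tetrahedra
  (one-point quadrature), implicit Newmark integration with beta = 0.3,
  gamma = 0.6, dt = 1 ms, and Rayleigh damping D = alpha1 M + alpha2 K with
  alpha1 = 500 1/s and alpha2 = 0.005 s, the stiffness factor frozen at the
  reference state so D is constant.  The "K u" term of the semi-discrete
  balance is the nonlinear internal force.  Follower pressure loads
  (`J p F^-T n`) act on the endocardium; a regularized penalty contact
  (quadratic below d = 0.1 mm, linear to d_M = 8 mm, released beyond;
  k_epi = 10 MPa/mm) is available against analytic target surfaces.
* **Circulation.** A 0D closed loop: four time-varying-elastance chambers
  and systemic/pulmonary arterial and venous RC compartments with
  smooth diode-resistance valves, in a volume-state formulation that
  conserves total blood volume identically.  Chamber pressures couple to 3D
  cavity volumes through the scalar consistency condition
  `|V_3D(p) - V_0D(p)| < 1e-7 mL` (safeguarded secant).  The limit-cycle
  stopping criterion integrates `d(SV_diff)/dt = Q_SysArt - Q_PulArt` and
  compares |SV_diff| to 1 mL at cycle boundaries, resetting when unmet.
* **Initialization.** Cell models are paced to their limit cycle at a
  1.2 s cycle length (1000 beats at full scale; the count is scalable).
  The mechanical reference is recovered by backward-displacement unloading
  at diastatic pressures (8 mmHg left, 4 mmHg right) with an under-relaxed
  fixed point (factor 0.7 — the plain iteration overshoots for soft
  exponential materials), and the same unloaded configuration is reused
  for every lesion case.

# Synthetic geometry

No imaging data enter the pipeline; the anatomy is an idealized,
parameterized stand-in built entirely in code.

The LA is a spherical shell (default midsurface radius 20 mm, wall
thickness 4.5 mm — the thickness of the emulated anatomy) meshed by a
cube-sphere surface grid extruded radially.  Hexahedral cells are split
into two vertical prisms along the diagonal through the smallest vertex
index of the footprint and each prism into three tetrahedra; because every
quad face is split by the diagonal through its smallest vertex, the
triangulation conforms across neighbours for any quad surface mesh.  The
mechanics mesh keeps at least two elements through the wall; the EP mesh is
a uniform 1:8 refinement of it, which makes the EP-to-mechanics element map
exact by construction and lets lesion masks cover identical tissue
fractions on both meshes.

Anatomical structure is carried by landmark sets: four PV ostia holes on
the postero-superior aspect, the mitral annulus opening (southern cut at
polar angle 130 degrees), an appendage bulge anterolaterally, and four
interatrial entry sites (Bachmann-bundle insertion anteriorly, upper and
middle posterior connections septally, coronary sinus near the annulus).
Sinus rhythm is emulated by stimulating the entry sites with fixed delays
(29/36/40/50 ms) representing right-atrial conduction; 29 ms is the
earliest LA breakthrough via the Bachmann bundle.  The PV ostia are spread
so that the posterior wall enclosed by the two superior veins, the two
inferior veins and their connecting lines holds a realistic share of the
shell surface — on a tight cluster the posterior box would isolate almost
nothing and BL cases would lose their distinguishing feature.

Atrial fibers follow a simplified circumferential rule with a
roof-to-annulus gradient (rotating up to 60 degrees toward the meridional
direction at the roof); only the qualitative anisotropy matters at this
scale.  The ventricular slab rule rotates the fiber angle linearly from
+60 degrees (endocardium) to −60 degrees (epicardium) and the sheet angle
from −65 to +25 degrees.

Lesion paths are geodesics between landmarks on the shell midsurface,
dilated to the average 5 mm width and applied transmurally (masks are
defined on midsurface footprints, so transmurality holds by construction).
The AL is a two-segment polyline — annulus up the anterior meridian to the
roof, then to the left superior vein — because the single great circle
between its anchors would cut the lateral wall and leave the
Bachmann-to-appendage route open.  BL is the union of RL and an inferior
line joining the inferior veins; together with the PVI rings it closes the
posterior box, and it contains RL element-wise.

# Parameters that matter

| parameter | default | units | note |
|---|---|---|---|
| `sigma_f` (atria) | 1.2 | S/m | calibrated once so Control total atrial activation is ~100 ms on the default mesh (see below) |
| anisotropy `sigma_f/sigma_s` | 4 | — | ~2:1 velocity ratio |
| `dt` (EP, tissue) | 0.05 (pipeline), 0.01 (cable tuning) | ms | see numerical notes |
| activation threshold | −20 | mV | fixed |
| AV delay | 160 | ms | single delay, no conduction-system model |
| lesion width | 5 | mm | transmural |
| scar `mu`, `alpha` factors | 2, 5 | — | sensitivity knob; reference variant of the sweep |
| atrial `S_peak`, `t_dur`, `tau_c0`, `tau_r` | 60 kPa, 120 ms, 30 ms, 30 ms | | shortened atrial twitch (below) |
| ventricular `S_peak`, `t_dur` | 120 kPa, 350 ms | | surrogate timing source for the 0D elastances |
| `ld`, `ld_up`, `lambda0`, `t_emd` | 5, 500 ms, 0.7, 20 ms | | transient shape |
| coupling `eps` | 1e-7 | mL | volume-consistency tolerance |
| stopping threshold | 1 | mL | per-cycle |SV_diff| |
| cycle length | 1.2 | s | pacing and circulation |

Cell-model parameters default to the original publications' values.  The
active-tension and circulation parameter sets are implementation defaults
— there is no single canonical literature value for these blocks; they
are exposed in `default_config()` and documented as this package's own
choices, not as reproductions of any published set.  The atrial twitch duration is calibrated so that atrial
and ventricular tension development do not overlap in time under the
default timing (atrial stimulus at 0, ventricles at 160 ms), the standard
physiological requirement when the atrial twitch is adapted from a
ventricular transient model.
Non-overlap is read at the bulk-transient level: the volume-weighted
atrial drive has decayed below 10% of its peak before the ventricular
transient exceeds 10% of its own; a pointwise per-cell reading would force
an unphysiologically short (<70 ms) twitch, whereas the 120 ms plateau is a
realistic atrial twitch and satisfies the bulk criterion with margin.

# Numerical choices

* **EP solver.** Backward Euler for diffusion (with first-order operator
  splitting a first-order implicit scheme is the consistent choice), Cholesky
  factorization computed once per solve.  Voltage is sampled at 1 ms for
  activation maps (0.5 ms on cable fixtures); activation times interpolate
  linearly between samples.  Tissue simulations stop early once every node
  outside the scar interior has crossed threshold.
* **Conductivity calibration.** On coarse desk-scale meshes the numerical
  conduction velocity differs from the continuum one, and below a critical
  conductivity a discrete front fails to propagate; conductivities are
  therefore *tuning outputs*: the cable fixture root-finds sigma against a
  velocity target, and the atrial sigma_f is set so the Control map takes
  about 100 ms — calibrations that any mesh-dependent monodomain model must
  redo for its own resolution.  Stimulus sites are finite patches (about 9 degrees
  angular radius, 60 uA/uF for 3 ms): point sources fail to capture at
  high conductivity (source-sink mismatch).
* **Mechanics solver.** Element tangents by central finite differences of
  the vectorized internal-force kernel (12 local dofs, h = 1e-6·scale),
  follower-pressure and contact tangents likewise; Newton accepts
  non-monotone steps (pressure-loaded exponential materials overshoot
  transiently) and backtracks only on element inversion or runaway growth;
  load continuation adapts its increment by halving on failure and growing
  on cheap steps.  The Jacobian is reused over 2-3 iterations.
* **Unloading.** Backward displacement with under-relaxation 0.7,
  convergence at 0.1 mm maximal nodal error by default.
* **Degenerate inputs.** Zero-width lesions, non-bracketable velocity
  targets, negative compartment volumes, non-finite cell states and
  inverted elements are rejected with diagnostics; never-activated tissue
  is a valid outcome, not an error.

# The desk-scale pipeline and what it can show

`run_case()` composes: lesion masks on the EP mesh → monodomain solve →
activation map, AT and IT → closed-loop circulation to the limit cycle →
biomarkers.  At desk scale all four chambers of the closed loop are
0D time-varying-elastance chambers; the ventricles are driven by the
ventricular transient (the design the full model reserves for runs without
a 3D ventricle), and the LA elastance is driven by the 3D EP solution: its
active drive is the volume-weighted mean of the per-element tension
transients triggered at the computed activation times (inactive tissue
contributes none, so the drive amplitude scales with 1 − IT and its timing
with the activation dispersion), and its passive stiffness grows with the
scarred fraction and the scar-stiffness multipliers.  The full 3D LA
mechanics — static inflation, EDPVR, backward-displacement unloading,
Newmark dynamics, contact — is implemented and tested as its own module
and carries the scar-stiffening analyses (e.g. inflated volume at 8 mmHg,
control versus scarred); a fully coupled 3D-LA beat is outside the default
test budget but available through the same functions.

Because the geometry is idealized and the LA chamber reduced, absolute
biomarkers (SV in mL, EF levels, pressures) are not comparable to a
subject-specific four-chamber model; the package therefore asserts
*directions and structure*: IT ≥ AT with the posterior box isolating
viable tissue, AL delaying the appendage, monotone ΔEF-versus-IT across
cases, stiffened scars reducing passive LA volume, velocity scaling with
the square root of conductivity, and the exact regression statistics of
the bundled printed per-case table.  Passing tests show the machinery and
its couplings are correct at desk scale; they do not validate the absolute
hemodynamics of any patient.

Default problem sizes: mechanics shell ~4600 tetrahedra, EP mesh ~37000
tetrahedra (~8000 nodes); cable fixtures 10-20 mm at 0.25-0.5 mm; test
sweeps use the ventricular surrogate on the shell at dt = 0.05 ms.

# Known limitations

* Linear tetrahedra are prone to locking in thin walls; the trade-off is
  accepted for speed, as is common in whole-heart simulation.
* The elastance-LA reduction cannot express regional wall-motion
  biomarkers (AVPD analogues report NA in `run_case` output); those live
  in the 3D mechanics module.
* No mechanoelectric feedback, no deformation-dependent conductivity, no
  AF induction — sinus rhythm only.
* The circulation parameter set is a generic resting adult, not a
  subject-specific calibration; only relative case-to-case changes are
  meaningful.
* Conductivities and the atrial twitch duration are mesh-calibrated; they
  are not portable to other resolutions without re-tuning.
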
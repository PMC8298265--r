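---
title: "Methods: a 1D pulmonary circulation with structured-tree microvasculature and a reduced left atrium"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a 1D pulmonary circulation with structured-tree microvasculature and a reduced left atrium}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pulmonet)
```

## The model

`pulmonet` simulates blood flow through the pulmonary circulation between
the right ventricle and the left atrium (LA), and the back-reaction of the
left heart on the lungs, in three coupled tiers.

**Large vessels (1D).** The seven large pulmonary arteries (MPA, RPA, LPA,
RIA, RTA, LIA, LTA) and four large veins (RIPV, RSPV, LIPV, LSPV) carry the
cross-section-averaged equations for volume flux $q(x,t)$ and lumen area
$A(x,t)$:

$$\partial_t q + \partial_x (q^2/A) + \frac{A}{\rho}\,\partial_x p
  = -\frac{2\pi\nu R}{\varepsilon}\frac{q}{A}, \qquad
  \partial_x q + \partial_t A = 0,$$

closed by the elastic tube law
$p - p_0 = \tfrac{4}{3}\,\frac{Eh}{R_0}\bigl(\sqrt{A/A_0} - 1\bigr)$.
The friction source follows from a flat core velocity profile with a thin
linear boundary layer of constant thickness $\varepsilon$; the default
$\varepsilon = \sqrt{\nu T / (2\pi)}$ is the oscillatory (Stokes) layer for
the cardiac period, about $7\times10^{-4}\,$m at $T = 0.8\,$s.  All large
vessels share one stiffness, $Eh/R_0 = 150\,$mmHg; the reference radius
tapers linearly between the tabulated proximal and distal values.  The
local pulse wave velocity is
$c = \sqrt{(A/\rho)\,\partial p/\partial A}
   = \sqrt{\tfrac{2Eh}{3\rho R_0}\sqrt{A/A_0}}$,
and the Riemann invariants of the system are $W_\pm = u \pm 4c$.

**Microvasculature (structured trees).** Each terminal artery is joined to
its vein (RIA–RIPV, RTA–RSPV, LIA–LIPV, LTA–LSPV) through a mirrored pair
of structured trees: a self-similar binary tree with daughter radii
$r_\alpha = \alpha r_p$, $r_\beta = \beta r_p$ ($\alpha = 0.91$,
$\beta = 0.58$), vessel length $L = \ell_{rr}\, r$ (default
$\ell_{rr} = 12.4$), radius-dependent stiffness
$Eh/R_0 = k_1 e^{k_2 r} + k_3$ ($k_1 = 187.5\,$mmHg, $k_2 = -10\,$cm$^{-1}$,
$k_3 = 37.5\,$mmHg), truncated at a 30 µm radius.  Vessels below the cutoff
are neglected: a node whose daughters both fall below it becomes a terminal
junction connecting straight across to the mirrored venous tree; a
below-cutoff $\beta$-daughter of a surviving node carries no flow.  In the
frequency domain each small vessel is a two-port with a Womersley velocity
profile; with compliance per length $C = 3A_0/(2\,Eh/R_0)$, profile function
$F_J$, complex wave speed $c_w = \sqrt{A_0(1-F_J)/(\rho C)}$ and
characteristic admittance $g = C c_w$ the transmission matrix is
$\bigl[\begin{smallmatrix}\cos\theta & i\sin\theta/g\\
i g\sin\theta & \cos\theta\end{smallmatrix}\bigr]$, $\theta = \omega L/c_w$,
reducing at $\omega = 0$ to the Poiseuille resistance $8\mu L/(\pi r^4)$.
Because every subtree rooted at the same generation cell $(a, b)$ is
identical, the root-to-root two-port is composed by dynamic programming
over the occupied cells (a few hundred) rather than the billions of
individual vessels; the test-suite verifies the DP against explicit
enumeration on small trees and against a node-by-node Poiseuille network at
DC.  The result is, per harmonic, a $2\times2$ admittance
$[Q_a; Q_v] = Y(\omega)[P_a; P_v]$ with both flows measured in the
direction of perfusion.  With this through-flow convention the reciprocity
of the passive network reads $Y_{12} = -Y_{21}$ (the conventional symmetric
form is recovered by flipping the venous current), and the Hermitian part
of the currents-into-network form is positive semi-definite (passivity);
both are asserted numerically.

**Left atrium (0D) and mitral valve.** The atrium is a two-term elastance
chamber, $p_{LA} = (E_{pas} + a(t)\,E_{act})(V - V_0)$, filled by the four
vein outflows and drained through a mitral orifice
$q = c_d A_{fwd}\sqrt{2\Delta p/\rho}$; in the regurgitant configuration a
second orifice $A_{reg}$ opens during systole and carries backflow into the
atrium.  The normalised activation $a(t)$ is a symmetric triangle of
duration 0.12 s at end diastole (peak tension 33.7 kPa in the reference
3D model; the 0D chamber uses the dimensionless scaling through
$E_{act}$).  The activation window ends 0.04 s after the cycle boundary so
that the tail of atrial relaxation reaches into early ventricular systole —
this is what launches the first systolic venous inflow wave (S1); with the
window ending exactly at the boundary the S1 surge degenerates onto the
cycle seam.

## Numerical scheme

* **Interior**: two-step (Richtmyer) Lax–Wendroff on the conservation form,
  with the momentum flux $q^2/A + B$, $B = \tfrac{f}{3\rho}A\sqrt{A/A_0}$
  ($f = \tfrac43 Eh/R_0$), a geometric source
  $\tfrac{f}{3\rho}(A/A_0)^{3/2}\,dA_0/dx$ for the taper, and the friction
  source.  Second order in space and time on smooth solutions (the suite
  measures the observed rate on a frictionless pulse and requires ≥ 1.8).
* **Boundaries**: the outgoing Riemann invariant is extrapolated to the
  foot of its characteristic and combined with the boundary model.
  Bifurcations enforce continuity of static pressure and mass with a scalar
  Newton iteration per junction (residual at machine precision; a
  total-pressure variant is intentionally not included — the loss-free
  static-pressure condition is the default and only option).  The inlet is
  a lumped valve: $\Delta p = B q|q|/\zeta^2 + L\,dq/dt$ with an
  opening/closing rate law for $\zeta$ and no regurgitation.
* **Tree interfaces**: the admittance acts as a periodic convolution of the
  most recent full period of root pressures.  The lag-0 weight is treated
  implicitly (a 2×2 Newton per interface pair per step).  One
  implementation detail matters for robustness: the kernel built from a
  truncated harmonic series presents *zero* instantaneous admittance to
  frequencies above the truncation, i.e. a perfectly reflecting wall with a
  deferred compliant response, and this feedback loop can amplify slowly
  over many cycles.  We therefore lift the high-frequency (characteristic)
  root admittance $g_\infty = \sqrt{C A_0/\rho}$ out of the convolution and
  apply it instantaneously, leaving the kernel to carry
  $Y(\omega) - g_\infty$.  Every retained harmonic is reproduced exactly;
  out-of-band waves now see the physical wave admittance, and the
  cycle-to-cycle metric then contracts geometrically (the test-suite runs
  assert their convergence tolerances; without the lift the control run
  diverged after roughly a dozen cycles).
* **Cosimulation**: per step, the atrial inflow is predicted by the relaxed
  update $q_{LA}^{n+1} = q_{LA}^n + \theta_1(q_{PC}^n - q_{LA}^n) +
  \theta_2(q_{PC}^n - q_{PC}^{n-1})$ per vein, the chamber advances
  (optionally with substeps; the exchange stays on the network step with
  the inflow held over the substeps), and the new chamber pressure becomes
  the vein-outlet boundary condition of the same step.
  $\theta_1=\theta_2=0.5$ by default, dropping to $0.1$ while
  $|dp_{LA}/dt|$ exceeds 200 mmHg/s (mitral-valve closure).  Before
  coupling, the pulmonary model is pre-run for up to ten cycles under the
  typical atrial pressure waveform (a-wave 6 mmHg, v-wave 9 mmHg) and the
  chamber for 0.1 s on the pre-run vein outflows, so the interface starts
  matched.
* **Time step**: the default 2^14 steps per cycle gives
  $\Delta t = 4.88\times10^{-5}\,$s at $T = 0.8\,$s and
  $3.66\times10^{-5}\,$s at $T = 0.6\,$s (an FFT-friendly count, consistent
  with the reference configuration).  A CFL guard aborts if
  $(|u| + c)\Delta t/\Delta x$ reaches 1; at the default
  $\Delta x = 0.05\,$cm the ratio stays near 0.5.  Pressures outside
  (−20, 200) mmHg abort loudly.

## Boundary waveforms

The generators compose half-raised-cosine segments, so every waveform is
periodic, continuously differentiable, and attains its defining anchors
exactly: the right-ventricular pulse is a rounded trapezoid (upstroke 25 %
of systole, plateau at the systolic anchor, downstroke 30 %); the
left-ventricular waveform adds an isovolumic-relaxation fall, a diastolic
plateau at its minimum and a late-diastolic rise to the end-diastolic
anchor; the typical atrial waveform superposes exact v- and a-wave bumps on
a 5 mmHg baseline.  Only the anchor values (the case pressures and the
a/v peaks) are contractual — the in-between shape is this package's choice, and the
upstroke/plateau fractions, baselines and valve constants were fixed once
so that the stand-alone control run produces a physiological MPA waveform
with a dicrotic notch and a cardiac output near 7.5 L/min.  They are all
exposed as arguments.

## Calibration of the reduced atrium

The 3D atrial constitutive model is deliberately reduced to four constants.
They are calibrated once (scripts/calibrate_la.R) against the control
coupled run at desk-scale resolution, targeting a stroke volume near 100 mL
per cycle, an atrial pressure range spanning the typical a (6) and v (9)
mmHg waves, and an E-wave of a few hundred mL/s.  The calibration targets
are physiological anchors, not exact 3D outputs: the reduction is designed
to reproduce the *behaviour* of the scenarios (loss of the a-wave and of the
AR/S1 venous waves in atrial fibrillation; systolic venous reversal, a
collapsed filling volume and an enlarged D wave in acute mitral
regurgitation), and the tests assert exactly those behaviours.

## What the scenario presets encode

| case | T (s) | RV sys | LV ed | LV sys | active | regurgitant orifice |
|------|------|--------|-------|--------|--------|---------------------|
| control | 0.8 | 26 | 10 | 110 | yes | – |
| af      | 0.8 | 26 | 10 | 110 | no  | – |
| amr     | 0.6 | 34 | 20 | 100 | yes | 0.35 cm² in systole |

Ventricular systole is 0.36 s at T = 0.8 s and scales with the period.
The AMR orifice area is an effective-orifice reduction of leaflet
incompetence (the 0D chamber has no leaflets); 0.35 cm² was chosen so the
regurgitant volume per cycle is of the order of 30 mL, a severe acute
lesion.

## Analysis conventions

Wave-intensity analysis uses central differences on the uniform grid
(optionally Savitzky–Golay smoothing for noisy input), the pointwise pulse
wave velocity from the tube law (a cycle-mean option exists because the
tabulated-PWV convention is ambiguous), and the characteristic split
$dp_\pm = (dp \pm \rho c\,du)/2$, $du_\pm = (du \pm dp/(\rho c))/2$.  The
raw backward product $(dp_-/dt)(du_-/dt)$ is negative semi-definite, so the
backward intensity is reported as its positive magnitude.  Venous flow
waves are located inside phase windows derived from the configured systole
duration, never inferred from the signal: S1 and S2 as prominent maxima in
(extended) systole, D in early/mid diastole, and AR as a prominent
late-diastolic dip — in this reduced model the atrial kick can attenuate
rather than strictly reverse the vein flow, so presence is defined by the
dip, and the reported flow at the dip is negative whenever true reversal
occurs.  Volume accounting integrates the vein inflows over the period
(stroke volume), splits it at the systole/diastole boundary
(filling/conduit), and integrates negative mitral flow (regurgitant
volume); TPG and PVR follow their clinical definitions.

## Problem sizes used by the tests and the acceptance script

The acceptance script runs the reference configuration itself:
$\Delta x = 0.05$ cm (≈ 560 grid nodes), 2^14 steps per cycle, 512 tree
harmonics, up to 10 cycles.  The test-suite uses desk-scale versions chosen
for quick, well-conditioned runs: $\Delta x = 0.1$ cm with 2^13 steps for
the stand-alone control checks, and $\Delta x = 0.2$ cm with 2^12 steps and
128–256 harmonics for the three coupled scenarios; miniature fixtures (a
single vessel, a symmetric Y-junction, a fully enumerable tree with root
radius 0.01 cm) carry the oracle comparisons.  Mesh- and harmonic-
refinement tests pin the discretisation sensitivity (doubling $\Delta x$
moves the systolic pressure by < 1 %).

## Known limitations

* The 0D atrium has no systolic descent of the mitral annulus, so the
  atrial reservoir pressure rises monotonically during ventricular systole
  and the systolic venous waves are weaker than in the 3D reference; the
  AR wave is an attenuation dip rather than a guaranteed reversal.
* The structured trees are strict mirrors; the reference model's venous
  drop exceeding its arterial drop suggests its venous trees were slightly
  more resistive than a mirror of ours.
* Collapse mechanics (negative transmural pressure), viscoelastic walls,
  gravity and respiratory modulation are out of scope.
* Quantities that require a resolved 3D atrium (exact volume splits, fibre
  strain, vortex structures, energy dissipation) are not reproduced by this
  desk-scale model; where they have 0D counterparts they are covered
  qualitatively.
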
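---
title: "Modeling and quantifying follicle-cell expansion waves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and quantifying follicle-cell expansion waves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(folliclewave)
```

## The biological problem

During late *Drosophila* oogenesis the follicular epithelium that wraps the
egg chamber expands dramatically: nurse cells dump their cytoplasm into the
oocyte, the oocyte elongates along the anterior-posterior (A-P) axis, and
the follicle cells covering it flatten and spread. Live imaging resolves
this expansion into a wave that travels from posterior to anterior through
three phases per cell:

1. **Ruffling** — Rac1-driven membrane protrusions appear at random
   positions along the basal membrane; cell outlines become convoluted
   (circularity falls) while basal area barely changes.
2. **Area increasing** — protrusive activity collapses onto the
   anterior-facing membrane, Rho1 activity and focal adhesions recover,
   and circularity rises sharply while basal area starts to grow.
3. **Spreading** — cells migrate collectively posterior-to-anterior over
   the matrix while basal area keeps increasing, driven largely passively
   by the A-P growth of the oocyte underneath.

`folliclewave` implements (i) a modified vertex model that reproduces this
sequence mechanistically, and (ii) the quantification toolbox used to read
it out of boundary outlines, intensity traces and two-channel images —
applied identically to simulated and synthetic data.

## The modified vertex model

Classical vertex models describe a cell by a handful of polygon corners.
Follicle cells, however, deform at a much finer scale: E-cadherin forms
discrete clusters along the membrane, and ruffles live between them. The
model therefore carries many vertices per cell (default: 4 per hexagon
edge, 24 per cell), each attached to an E-cadherin cluster and to a
substrate anchor (its focal adhesion). Every vertex position $x$ obeys the
overdamped force balance

$$\eta_{\mathrm{Vis}}\,\frac{dx}{dt}
  = F_{\mathrm{Tension}} + F_{\mathrm{Area}} + F_{\mathrm{Rac}}
  + F_{\mathrm{Adhesion}} + F_{\mathrm{Fiber}} + F_{\mathrm{Noise}},$$

integrated by explicit finite differences with step $\Delta t$ (compiled
code; the R functions `force_tension()` … `force_noise()` expose each term
for testing). The terms:

* **Cortical tension** $F = K_L (s^+ + s^-)$, with $s^\pm$ the vectors to
  the two cortex neighbours — zero-rest-length springs along the cortex,
  exactly the negative gradient of $\tfrac{K_L}{2}\sum |e|^2$.
* **Areal elasticity** $F = -K_a \hat{s} (A - A_0)\, r_{\mathrm{nor}}$,
  with $\hat s$ the cortical length covered by the vertex and
  $r_{\mathrm{nor}}$ the outward normal. Note a numerical subtlety: with
  $\hat s = (|s^+|+|s^-|)/2$ this discretization is *not* an exact energy
  gradient (the exact gradient of $\tfrac{K_a}{2}(A-A_0)^2$ carries
  $\tfrac12|p_{next}-p_{prev}|$ instead of $\hat s$; the two agree to
  second order in vertex spacing). `force_area()` exposes both
  (`method = "cortical"`, the simulator default, and `method =
  "gradient"`, the conservative form).
* **Rac protrusion** — a Gaussian pulse envelope within each activated Rac
  cycle of duration $T$: peak force $f_{\mathrm{Rac}}/(\sigma\sqrt{2\pi})$
  at mid-cycle, always along the outward normal. During ruffling each cell
  recruits a random contiguous membrane segment per cycle; from the
  increasing phase on, only anterior-facing membrane is recruited, at
  reduced amplitude (residual protrusions).
* **Adhesion** — a spring from each vertex to its substrate anchor, gated
  by Rho activity through a Hill function
  $f_{\mathrm{CAMs}}\,L_{\mathrm{Rho}}^n/(K_d + L_{\mathrm{Rho}}^n)$.
  Anchors re-seat onto the current vertex positions on a turnover clock
  (adhesion remodeling), and adhesion on a freshly Rac-activated segment is
  weakened for a delay (the measured Rac-to-adhesion lag).
* **Stress fibers** — one-sided D-V springs between opposite boundary
  vertices: they resist extension beyond their rest length but cannot
  sustain compression; rest lengths re-set at phase transitions.
* **Noise** — $f_R$ times a unit-variance Gaussian vector.

**Oocyte growth (nurse-cell dumping).** The A-P coordinate of every
substrate anchor is scaled about the posterior edge at rate $g$ per minute,
active after the ruffling phase. Vertices feel this only through the
adhesion springs — this is the passive-migration pathway. Because anchor
turnover re-seats anchors to the (lagging) vertex positions every few
minutes, part of the imposed stretch slips — the realized tissue stretch is
below $e^{gT}$, which is why the calibrated $g$ is larger than a naive
area-fold estimate would suggest.

**Plastic target area.** With a frozen target area the areal term would
fight the imposed stretch and cap basal-area growth at a few percent. Once
a cell enters the increasing phase its target area instead tracks the
attained area with a slow relaxation time (`tau_A0`, 15 min) — the model's
reading of basal flattening, where apical volume is redistributed to the
basal plane. During ruffling the target stays frozen, which structurally
enforces the observed near-constant basal area in that phase.

**Geometry.** The simulation runs on a 2-D plane (the conformally
projected egg-chamber surface); A-P is $+x$ (posterior to the right), D-V
is $+y$. The initial condition is a patch of tightly packed regular
hexagons with shared edge vertices.

### Phases, the wave, and genotypes

A cell at distance $d$ from the posterior edge enters ruffling at
$t = d/\text{wave\_speed}$ (wild type: 8 um/min, so a 3x3 patch staggers
onsets by about 3 min). Ruffling lasts 60 min (wild type), followed by
20 min increasing and 80 min spreading. Per-phase multipliers implement
the signaling schedule: Rho is reduced to 0.3x during ruffling and ramped
to 1.5x in spreading; fibers are disengaged (0.2x) during the increasing
phase so the rest-length reset can absorb the shape change; Rac runs at
1x / 0.25x / 0.2x in ruffling / increasing / spreading.

Genotypes are multiplier sets on exactly the parameters the corresponding
molecule controls (weak inhibition 0.5x, strong 0.1x, overexpression 2x):
Rac1DN scales $f_{\mathrm{Rac}}$, Rho1DN scales $L_{\mathrm{Rho}}$ (and,
via reduced actomyosin, fiber stiffness), Paxillin overexpression and
Talin RNAi scale $f_{\mathrm{CAMs}}$ (and fibers), dumping inhibition
scales $g$ to 0.05x and makes ruffling onset simultaneous (the P-to-A wave
is lost without dumping). In **single-factor** mode every genotype keeps
the wild-type $g$ (decoupling the perturbed mechanism from oocyte growth;
dumping inhibition itself is the one exception, since $g$ *is* its
factor); **combined-factor** mode applies genotype-specific $g$
multipliers and sets the Rac-inhibition ruffling phase to 40 min, matching
the experimentally observed early termination of ruffling.

### Parameter values and calibration

The source model cites literature parameters without printing a table, so
the defaults here are dimensionless-calibrated: $\eta = 1$, $K_L = 0.05$,
$K_a = 0.01$, $f_{\mathrm{CAMs}} = 1$, $K_d = 1$, $n = 2$, $f_R = 0.01$,
$\Delta t = 0.01$ min, $T = 20$ min, $\sigma = 4$ min, with 5-um hexagon
edges. The remaining free magnitudes ($f_{\mathrm{Rac}} = 3$, $g = 0.006$
per min, schedules above) were calibrated **once** so that the wild-type
run reproduces the documented phase phenomenology — circularity dip during
ruffling, under 5% area change in ruffling, at least 20% area gain by the
end of spreading, monotone P-to-A spreading — and were then frozen; all
genotype comparisons fall out of the multiplier mapping with no further
adjustment. The stability bound is $\Delta t < \eta / k_{\max}$ with
$k_{\max}$ the largest effective stiffness (adhesion + tension + area,
about 0.8 here), amply satisfied; halving $\Delta t$ moves final wild-type
vertex positions by under 0.01% of the tissue diagonal.

## The quantification layer

All measurements operate on closed boundary polygons (counter-clockwise,
micrometres) and uniformly sampled traces, whether simulated or real:

* `circularity()` $= 4\pi S_{\mathrm{Basal}} P^{-2}$ — global ruffling
  index; `cell_volume()` $= H(S_A + \sqrt{S_A S_B} + S_B)/3$ and
  `flatten_ratio()` $= \sqrt{S_A + S_B}/H$.
* `discrete_curvature()` — signed Menger (osculating-circle) curvature
  after window-averaging vertex positions; positive = outward-protruding
  for CCW outlines. `detect_ruffles()` calls a ruffle where a contiguous
  arc exceeds a curvature threshold (default twice the equivalent-circle
  curvature, $2/\text{equivdiameter}$) and was absent in the previous
  frame (*de novo* only); `ruffle_rose()` bins event orientations into
  twelve 30-degree sectors. The equivdiameter is implemented as the mean
  centroid-to-vertex distance — well-defined for ruffled outlines, where
  a max-radius or equivalent-circle reading would be ambiguous.
* `migration_kinematics()` — total displacement plus per-axis velocities.
* `autocorr_period()` — lag of the first autocorrelation maximum after
  zero, searched in $[2\,dt,\ n/2]$ samples; returns `NA` for aperiodic
  input rather than guessing.
* `bleach_correct()` — inactive below the 5% adjacent-frame background
  drop trigger; otherwise divides by a single-exponential fit to the
  background (normalized to the first frame).
* `phase_segment()` — slope-sign change-point detector on a smoothed
  trace: the increasing onset is the start of the longest sustained
  positive run following a decline; the ruffling onset the longest decline
  before it. A centred moving average advances the apparent start of a
  sharp transition by half the window, so onsets are compensated by
  $(w-1)/2$ samples; on a piecewise-linear test trace the detector is
  exact to 1-2 samples.
* `fiber_polarity()` — an oriented (Gabor) filter bank over $[0^\circ,
  180^\circ)$; per-pixel dominant orientation histogram over a foreground
  mask, plus the D-V-isolated response image.
* `masked_pearson()` / `vsc_ccf()` — Pearson colocalization after
  rejecting the lowest 10% intensities in both channels; the Van Steensel
  curve translates channel 2 over integer-pixel x-shifts (default envelope
  940 nm, no rotation). Sign convention: the peak reports the displacement
  of channel-2 content (+4 px shift peaks at +4 px). The printed form of
  the coefficient omits the squares in its denominator; the standard
  Pearson denominator is implemented, since the quantity is named
  Pearson's coefficient.
* `temporal_coloc_normalize()` — min-max normalization
  $(P - P_{\min})/(P_{\max} - P_{\min})$ of a coefficient-versus-lag
  series (a documented stand-in for the external GcoPS analysis: only the
  normalization contract is reproduced). `lag_estimate()` — lag of maximal
  normalized cross-correlation of mean-removed traces, positive when the
  second trace follows the first.

## Synthetic data: what it does and does not establish

Every generator is seed-deterministic and returns its ground truth, so
each estimator is tested by round-trip recovery: rose-curve polygons with
known lobe counts (`make_ruffled_polygon()`), raised-cosine pulse cascades
with known period and cumulative lags emulating the measured
Rac -> area -> Rho -> actomyosin -> adhesion ordering
(`make_pulse_cascade()`, default lags 3, 1, 2, 1 min, period 8 min in the
observed 5-10 min band), Gaussian-blob image pairs with a known x-shift,
exponentially bleached traces, and oriented line textures.

These fixtures reproduce the *statistical structure* the estimators rely
on — periodicity, lag ordering, curvature geometry, spatial shift — not
microscopy: there is no point-spread function, no camera noise model, no
segmentation error, and real pulsatile signals are irregular rather than
raised-cosine. A green recovery test therefore establishes estimator
correctness on its stated contract, not end-to-end performance on raw
movies (segmentation itself is out of scope; boundaries are inputs).

Image input/output uses plain CSV matrices rather than TIFF: the supported
R stack ships no TIFF reader, and the formats are interchangeable for the
analyses implemented here.

## Numerical choices and limitations

* Integration is explicit Euler; the noise term enters as a plain force
  (per the model's equation of motion), so trajectories at different
  $\Delta t$ differ when $f_R > 0$; convergence is assessed noise-free.
* The fixed-point, gradient and engine-consistency tests tie the compiled
  integrator to the exported R force functions on identical meshes.
* The one-sided fiber law follows the "cannot sustain compression"
  reading; the alternative (fibers actively pushing outward) is not
  implemented. Fiber "expansion" enters as stabilization: attained spans
  are kept, rest lengths re-set at phase transitions.
* No T1 rearrangements, no 3-D egg-chamber geometry, no pre-wave
  contractile oscillations; the projection plane is the model domain.
* Detected transition times carry the detector's sampling (1-min frames)
  and smoothing; reported timings are means over seeds.
* In this implementation Rho1 inhibition *increases* the ruffling-phase
  circularity drop (weaker adhesion lets pulses deform the membrane
  further), whereas the source observations report slightly *reduced*
  protrusions under Rho1 inhibition; the migration and area phenotypes
  match. A ruffle-stabilization coupling (adhesion-dependent protrusion
  persistence) would be needed to capture that detail.
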
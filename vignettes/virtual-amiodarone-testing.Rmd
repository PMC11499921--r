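---
title: "Virtual antiarrhythmic drug testing on left-atrial digital twins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual antiarrhythmic drug testing on left-atrial digital twins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

aftwin builds desk-scale digital twins of fibrotic left-atrial tissue and
runs a virtual amiodarone test on them: pace, induce atrial fibrillation
(AF), classify the rhythm at the end of an observation window at several
drug concentrations, and compute the biomarker maps (maximal restitution
slope and dominant frequency) that stratify drug response. This vignette
explains the models, the defaults and why they were chosen, what the
synthetic cohort does and does not emulate, and the numerical choices that
matter.

## The myocyte model

Membrane kinetics follow the Courtemanche–Ramirez–Nattel human atrial
formulation, with thirteen currents summed into the total ionic current:
fast sodium (I~Na~), L-type calcium (I~CaL~), transient-outward (I~to~),
ultrarapid/rapid/slow delayed-rectifier and inward-rectifier potassium
(I~Kur~, I~Kr~, I~Ks~, I~K1~), an acetylcholine-activated potassium current
(I~KACh~), the Na/Ca exchanger and Na/K and Ca pumps, and the background
Na/Ca leaks. Intracellular Na^+^, K^+^ and Ca^2+^ plus the two
sarcoplasmic-reticulum compartments evolve alongside twelve voltage-
dependent gates and the three calcium-release gates.

Every current carries a multiplicative conductance factor, and all
modulation in the package — chronic-AF electrical remodeling, fibrotic-cell
down-regulation, drug blockade, vagal tone — composes multiplicatively on
those factors:

* **AF remodeling** (default: I~CaL~ ×0.3, I~to~ ×0.5, I~Kur~ ×0.5, I~K1~
  ×2.0). The precise remodeling of a chronically fibrillating atrium is a
  user-facing choice, so the profile is plain data (`af_remodeling_profile()`,
  replaceable everywhere); the default is the standard chronic-AF setting
  for this model family and shortens APD~90~ from ~280 ms to ~130 ms at a
  500-ms cycle length.
* **Fibrotic myocytes**: I~K1~ ×0.5, I~CaL~ ×0.5, I~Na~ ×0.6, together
  with reduced tissue-level conductivity (below).
* **Drug blockade**: per-channel factors (1 − θ) from the Hill equation,
  θ = [1 + (IC50/D)^nH^]^−1^, with θ(0) defined as 0 by continuity.
* **I~KACh~** is present but silent by default (zero acetylcholine); the
  cohort configuration turns it on (see below).

The amiodarone table ships with IC50/Hill pairs assembled from patch-clamp
literature ranges (dominant I~Kr~ block near 1 µM; I~Na~, I~CaL~, I~to~,
I~Kur~, I~Ks~, I~K1~ block growing across the therapeutic range). The table
is data, not algorithm: any entry can be replaced through `drug_spec()`
without touching the pipeline, and the qualitative dose-response directions
only require sodium and potassium block that increase with dose. Dose
presets are 0 (none), 1.6 (low, minimal effective), 3.9 (high, maximal
effective) and 8.0 µM (toxic); low and high are the therapeutic doses.

## Tissue propagation

Tissue is a monodomain reaction–diffusion system on a regular sheet:
∂V~m~/∂t = ∇·D∇V~m~ − (I~ion~ + I~stim~)/C~m~. Conductivities come from the
four-value table {0.1264, 0.0546} S/m longitudinal and {0.0252, 0.0068} S/m
transverse for non-fibrotic/fibrotic nodes. They are converted to diffusion
coefficients (mm²/ms) via a single lumped constant `k_sigma`
(default 0.65 (mm²/ms)/(S/m), folding membrane capacitance and
surface-to-volume ratio) chosen so the healthy longitudinal conduction
velocity lands near 0.36 m/s at the default spacing — a typical left-atrial
value. On top of that sits the **global diffusion scale**, the quantity the
calibration tunes per patient.

The anisotropic operator is a nine-point stencil: the fiber tensor
D = D~t~ I + (D~l~ − D~t~) f f′ contributes its axial parts to the
four-neighbor couplings and its cross term to one diagonal pair (chosen by
the sign of D~xy~), with per-edge harmonic averaging of the two nodes'
coefficients. Rows sum to zero, which enforces conservation and no-flux
boundaries; negative stencil weights are floored at zero (this slightly
biases anisotropy for fibers far from the grid axes and diagonals — a
documented discretization limit). Lesion and vein-hole nodes are decoupled
and clamped at rest.

Integration is a shared explicit step (default 0.1 ms) with Rush–Larsen
exponential gate updates and forward-Euler concentrations and voltage.
Rate expressions are tabulated on a 0.02-mV grid with the decay factors
baked in. During the action-potential upstroke the voltage increment of a
full step can exceed 4 mV; such steps are automatically re-done as two half
steps, recursively down to a quarter step. This adaptive sub-stepping
confines the cost of fine time resolution to depolarizing nodes and makes
activation times insensitive to the outer step (halving dt moves activation
times by well under 1 ms on a planar-wave run; the default single-cell step
is 0.02 ms). The stability bound dt × max |row sum| ≤ 0.9 is enforced, and
runs abort loudly on non-finite or out-of-range potentials.

Activation (upstroke crossing of −40 mV) and 90%-repolarization events are
detected online at every node, which is what the protocol classification
and the restitution pipeline consume; membrane-potential traces are
recorded for chosen node subsets and, for spectral analysis, for all nodes
inside a time window.

## Substrate construction

The substrate path mirrors the clinical mapping chain. A sparse bipolar
voltage point cloud (≥500 points) is interpolated onto the mesh by
normalized inverse-distance weighting (exponent 2, 10-mm radius; nodes with
no sample in radius are flagged and filled from the nearest sample). The
fibrosis probability is the piecewise cubic
P = (1/100)(−40V³ + 155V² − 206V + 99.8) on [0, 1.74] mV, 1 below 0 mV, 0
above 1.74 mV, clamped to [0, 1] because the raw cubic is slightly negative
at the upper boundary. Each node is declared fibrotic when a uniform draw
falls below its probability (seeded, reproducible). Fibrotic nodes get the
current reductions and the fibrotic conductivity pair.

Fiber fields are parametric stand-ins for atlas-based orientation: uniform,
circular, or linearly twisting; all unit-norm and deterministic.

Region labels use a fixed 3 × 2 rectangular template on sheets (columns at
thirds of x, rows at half of y): lateral isthmus, posterior-inferior wall,
posterior wall (bottom row), appendage, anterior wall, septum (top row).
The template stands in for anatomical segmentation so the regional
aggregation logic (mean per region, highest/lowest regional mean, and the
delta-regional difference) is exercised and testable without anatomy.

## Protocols and rhythm classification

Constant pacing runs at a 500-ms cycle length. AF induction uses the ramp:
cycle length 200 ms decreasing by 10 ms per stage to 120 ms, 8 beats per
stage — 72 stimuli spanning exactly 11.52 s (8 × (200 + … + 120) ms), an
identity the code enforces. Stimuli are 2-ms, 30 pA/pF pulses on the
earliest-activation-site neighborhood (an automated twice-diastolic-
threshold search is available). The observation window after the ramp
defaults to 10 s at desk scale (the full-scale 32-s horizon is a config
switch away); window length only shifts sensitivity to late terminations.

Classification at the window end: **termination** when no node crosses the
activation threshold during the final 500 ms (runs that fall silent after
pacing are ended early — quiescence is exactly what the early stop
detects); otherwise **AT** when pooled activation cycle lengths over the
final 2 s are regular (coefficient of variation < 0.1 with dominant cycle
length > 120 ms), else **AF**. The drug verdict is Effective when AF
terminated at ≥1 therapeutic dose, otherwise Ineffective; a baseline run
that fails to sustain is a calibration failure and excluded.

## Biomarkers

Restitution pairs are built per node from consecutive beats: the diastolic
interval runs from 90% repolarization of one beat to the activation of the
next. APD~90~ = y0 + A1(1 − exp(−DI/τ1)) is fitted by Levenberg–Marquardt
least squares (start: y0 at the APD minimum, A1 at the APD range, τ1 at the
median DI; τ1 bounded to [1, 1000] ms), and Smax is the analytic slope
(A1/τ1)exp(−DI/τ1) at the smallest observed DI — the maximum over the
observed range since the slope decreases in DI. Unfittable nodes are
flagged and excluded from regional means with counts reported; by default
all valid ramp beats enter the fit, with a switch restricting to a few
beats after each cycle-length break. Dominant frequency uses a mean-removed,
Hann-tapered, 4× zero-padded FFT, peak-picked in 1–20 Hz; at desk scale the
window is the last 6 s of sustained rhythm (recorded with the result)
instead of the fixed full-scale 17–23-s interval.

## The synthetic cohort and its calibration

The generator emulates an electroanatomical map, not an atrium: a 64 × 64
sheet at 250 µm spacing (~16 mm square) with a vein-pair analogue — two
holes surrounded by 2-mm ablation rings at 60% of the sheet width, so a
closed conduction corridor encircles the antral obstacle the way it does a
pulmonary-vein pair after isolation. Background map voltages are Gaussian
(mean ~1.45 mV, healthy) with a handful of low-voltage patches
(mean ~0.3–0.6 mV) confined to the wall opposite the veins, which, after
interpolation and the probabilistic fibrosis map, produces scattered
background fibrosis plus dense posterior-type scar. Pacing is delivered in
the corridor distal to the obstacle; drawing the site there breaks the
symmetry of antegrade wavefronts around the rings, which is what lets the
ramp wedge a unidirectional wave into the peri-antral circuit.

A 16-mm monolayer cannot host the multi-wavelet fibrillation of a full-size
atrium: the excitation wavelength (conduction velocity × refractory period)
of AF-remodeled tissue alone exceeds the sheet. The cohort configuration
therefore adds a modest uniform cholinergic tone (0.01 µM acetylcholine via
I~KACh~), the standard mechanism for shortening atrial refractoriness, which
brings APD~90~ to ~60 ms and the wavelength inside the circuit length. What
the models sustain is predominantly anchored macro-reentry around the
ring pair — the classic post-isolation atrial tachycardia — sometimes
degenerating into irregular activity classified as AF. Passing tests on
this cohort therefore demonstrate the pipeline's mechanics (induction,
classification, dose response, biomarkers) on a reentry-capable synthetic
substrate; they do not certify anatomical realism, bi-atrial dynamics, or
clinical recurrence statistics. Two further desk-scale consequences are
worth naming: induction is marginal enough that any amiodarone dose
aborts it, so the virtual drug verdict is uniformly "Effective" on the
default cohort (the effective/ineffective split needs full-scale anatomy
to be informative), and the dose trend in termination fraction holds in
this saturated form.

Calibration follows the baseline-tailoring rule: the global diffusion
scale is reduced geometrically from the upper bracket until drug-free ramp
induction leaves AF/AT still active at the window end. On this generator
the substrates split cleanly into inducible-at-nominal-diffusion and
never-inducible: scanning the scale downward (coarse or fine grids over
[0.7, 1]) was never observed to rescue a substrate, while every attempt
costs most of an observation window. The cohort default therefore verifies
sustained induction at the nominal scale (a single calibration attempt);
the full descending search remains available through the `bracket`,
`descend_factor` and `max_attempts` arguments. Patients that do not
sustain are excluded and reported — exclusion is a first-class outcome,
and cohort statistics are computed over calibrated patients only
(typically one to four of ten at desk scale).

Problem sizes used throughout the shipped tests are deliberate desk-scale
choices: 10 patients, 64 × 64 sheets, a 10-s post-pacing window, Smax maps
on a ~1-in-12 node subsample, and spectral windows at 125 Hz sampling.

## Numerical and design choices worth knowing

* Channel order everywhere: I~Na~, I~CaL~, I~to~, I~Kur~, I~Kr~, I~Ks~,
  I~K1~, I~KACh~, I~NaCa~, I~NaK~, I~b,Na~, I~b,Ca~, I~p,Ca~.
* The printed inverse-distance denominator is normalized by the summed
  weights (standard IDW); interpolated values are convex combinations of
  samples, exact at sample locations.
* Ties in earliest-activation-site selection break toward the lowest node
  index. Degenerate restitution inputs (under 4 pairs, single DI) are
  reported as unfittable rather than zeroed; a perfectly flat APD set is a
  legitimate zero-slope fit.
* Everything downstream of a seed is deterministic: identical
  configurations produce bit-identical traces, masks and verdicts, and
  every pipeline output carries the configuration hash.
* Known limitations: single-layer sheets (no bi-atrial or transmural
  structure), parametric fibers instead of atlases, stencil anisotropy bias
  off-axis, desk-scale domains that favor anchored reentry over
  multi-wavelet AF, and a drug model restricted to steady-state pore block
  (no kinetics, no active metabolites).
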
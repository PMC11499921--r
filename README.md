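# aftwin — left-atrial digital twins for virtual antiarrhythmic drug testing

`aftwin` builds desk-scale digital twins of fibrotic left-atrial tissue and
runs virtual amiodarone tests on them. It is aimed at computational
electrophysiologists who want the full in-silico drug-testing chain —
substrate construction from electroanatomical-map-like voltage data,
monodomain simulation, AF induction, rhythm classification, and the
wave-dynamics biomarkers used to stratify drug response — in one
reproducible, scriptable R package.

## What it computes

* **Myocyte model.** A Courtemanche–Ramirez–Nattel human atrial myocyte
  with thirteen currents,
  I_ion = I_Na + I_CaL + I_to + I_Kur + I_Kr + I_Ks + I_K1 + I_KACh +
  I_NaCa + I_NaK + I_b,Na + I_b,Ca + I_p,Ca,
  with chronic-AF remodeling and fibrotic-cell profiles as replaceable
  per-channel conductance factors.
* **Pharmacology.** Hill-equation multichannel block,
  θ = [1 + (IC50/D)^nH]⁻¹, composed multiplicatively with every other
  conductance factor; a literature-derived amiodarone table ships as
  replaceable data (doses: 1.6 / 3.9 / 8.0 µM = low / high / toxic).
* **Substrate.** Inverse-distance-weighted interpolation of sparse bipolar
  voltages, the piecewise-cubic voltage→fibrosis probability map
  P(V) = (1/100)(−40V³ + 155V² − 206V + 99.8) on [0, 1.74] mV (clamped),
  seeded stochastic fibrosis, parametric fiber fields, the four-value
  conductivity table {0.1264, 0.0546, 0.0252, 0.0068} S/m, vein holes with
  2-mm ablation rings, and a six-region segmentation template.
* **Tissue.** Monodomain reaction–diffusion,
  ∂V/∂t = ∇·D∇V − (I_ion + I_stim)/C_m, on fiber-anisotropic sheets with a
  conservative nine-point stencil, Rush–Larsen gates and adaptive upstroke
  sub-stepping; online activation/APD90 event detection at every node.
* **Protocols and outcome.** Constant 500-ms pacing; the AF-induction ramp
  (200→120 ms by 10 ms, 8 beats per stage, 11.52 s); rhythm classification
  into AF / AT / termination at the end of the observation window; the
  per-patient Effective/Ineffective verdict (termination at ≥1 therapeutic
  dose).
* **Biomarkers.** Per-node APD restitution fits
  APD90 = y0 + A1(1 − exp(−DI/τ1)) with Smax = (A1/τ1)exp(−DI_min/τ1), and
  FFT dominant-frequency maps, both aggregated over the six regions
  (mean, highest, lowest, Δregional).
* **Synthetic cohort.** A generator that emulates electroanatomical maps
  (≥500 points, low-voltage scar patches) on 64×64 sheets with a vein-pair
  obstacle, plus per-patient diffusion calibration against the sustained-AF
  target, so the entire pipeline runs without any clinical data.

## Worked example

Per-channel amiodarone block at the low therapeutic dose:

```r
library(aftwin)
hill_blockade(amiodarone(), 1.6) |> dplyr::filter(theta > 0)
#>   channel  theta
#> 1     INa 0.1176
#> 2    ICaL 0.2162
#> 3     Ito 0.1379
#> 4    IKur 0.0741
#> 5     IKr 0.5644
#> 6     IKs 0.0964
#> 7     IK1 0.0385
```

The rapid delayed rectifier (IKr) is the dominant target at 1.6 µM (θ =
0.56), with modest sodium and L-type calcium block — the class-III-like
profile that lengthens repolarization while slowing the upstroke only
mildly.

Single-cell dose response at a 500-ms cycle length (20 conditioning beats):

```r
dose_response_cell(amiodarone(), c(0, 1.6, 3.9, 8.0))
#>   concentration_um apd90_ms dvdt_max_Vps amplitude_mV v_rest_mV
#> 1              0.0    279.1        199.4       104.84    -79.24
#> 2              1.6    309.4        183.4       101.17    -78.91
#> 3              3.9    313.1        162.6        96.84    -78.72
#> 4              8.0    319.0        132.1        90.45    -78.12
```

APD90 lengthens by ~30 ms at the low dose (IKr block) and the peak
upstroke velocity falls monotonically with concentration (cumulative INa
block) — the expected electrophysiological signature of amiodarone.

A full virtual patient runs through `make_patient()` →
`build_patient_model()` → `tune_for_baseline_af()` →
`virtual_drug_test()`; `run_pipeline()` executes the whole cohort workflow
(generation, calibration, per-dose induction, classification, biomarkers,
verdict CSVs). See the vignette `virtual-amiodarone-testing` for the
science and the defaults.

## Command line

A thin CLI over the same functions lives at `inst/cli/aftwin.R`:

```sh
Rscript inst/cli/aftwin.R blockade --concentration 3.9
Rscript inst/cli/aftwin.R cell-sim --doses 0,1.6,3.9,8 --out out/
Rscript inst/cli/aftwin.R make-cohort --n 10 --seed 20240101 --out cohort/
Rscript inst/cli/aftwin.R run-all --out pipeline_out/
```
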
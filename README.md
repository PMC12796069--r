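# atriaPET

Automated estimation of left and right atrial volumes (LAV, RAV) from a
single non-gated dynamic cardiac PET scan, together with the parametric
maps of a quantitative myocardial perfusion study.

## The problem

Atrial enlargement marks elevated ventricular filling pressures and
cardiovascular risk, but no dedicated acquisition for atrial volumetrics
exists in a standard PET perfusion protocol. During the first pass of an
injected tracer bolus the blood arrives in the cardiac chambers in a
fixed order — SVC → RA → RV → lungs → LA → LV → aorta — with arrival-time
differences of only a few seconds. `atriaPET` exploits this: it maps the
bolus transit voxel by voxel, segments both ventricles from kinetic
parametric images, and then isolates the atria from the remaining blood
pool purely by bolus timing, with no ECG gating and no user interaction.
The package targets researchers in quantitative cardiac PET who want
atrial volumes as a by-product of a standard 6-minute dynamic
[¹⁵O]-water perfusion scan.

## The method

For every voxel the first-pass peak of the time–activity curve C(t) is
extracted and summarized by its centroid time and area,

    t_mid = Σ t·C(t) / Σ C(t),        AUC = Σ C(t)·Δt,

giving 3-D bolus arrival-time and blood-volume images. AUC is normalized
so the LV blood pool has area 1; the blood region is AUC > 2/3 with
t_mid < 1.5 min. Arterial and venous input functions C_A(t), C_RV(t)
come from k-means cluster analysis (6 clusters) of the high-AUC voxel
TACs, and parametric images of MBF, PTF, V_A and V_RV are fitted with a
basis-function implementation of the single-tissue compartment model

    C_T(t) = PTF·MBF·C_A(t) ⊗ exp(−MBF/V_T·t) + V_A·C_A(t) + V_RV·C_RV(t)

with the water distribution volume fixed at V_T = 0.91 mL/g. The images
are reoriented to the short axis; both ventricular walls are segmented
by circumferential profiling of the PTF image (V_A-guided for the LV,
V_RV-guided for the RV) and the cavities are the enclosed blood at least
1.3 cm from the wall. The LA is then the blood region arriving between
the lungs and t_LV plus two heartbeats, split from the aorta along the
LV outflow tract; the RA mirrors the rule at t_RV, with the SVC removed
as a tube-like structure. Volumes are reported in mL and BSA-indexed
(Du Bois) in mL/m².

A fully synthetic 4-D cardiac phantom (gamma-variate boluses with known
delays, myocardial kinetics from the same compartment model, Gaussian
point-spread function, seeded noise) provides ground truth for every
stage, so the whole pipeline is testable without patient data.

## Worked example

```r
library(atriaPET)
spec <- phantomSpec(noise_scale = 0)       # 96^3 grid, 2 mm voxels
ph   <- generatePhantom(spec)              # series + ground truth
res  <- runPipeline(ph$series)
res$report
```

```
VolumeReport
  LAV 63.6 mL  RAV 80.6 mL  (BSA 1.810 m^2)
  LAVI 35.1  RAVI 44.5 mL/m^2
  t_RV 11.1 s  t_lungs 17.1 s  t_LV 25.8 s  AUC_LV 662.6
  flags: none
```

The phantom's true volumes are LAV 73.0 mL and RAV 92.1 mL: the
pipeline reads ~13% low because the 2/3 AUC threshold sits slightly
inside the blurred chamber boundary (see the methods vignette). The
timing line shows the recovered transit order RV → lungs → LV; `flags:
none` means every structure was segmented automatically. `res$labels`
holds the 8-structure label map and `saveOutputs()` writes NIfTI maps
plus CSV/JSON reports. A thin command-line front end is included:

```sh
Rscript inst/cli/atriaflow.R run --series s.nii.gz --timing t.json --out out/
Rscript inst/cli/atriaflow.R phantom --seed 7 --out phantom/
Rscript inst/cli/atriaflow.R retest --pairs 20 --out retest/
```

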
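---
title: "Atrial volumes from dynamic cardiac PET: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Atrial volumes from dynamic cardiac PET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(atriaPET)
```

`atriaPET` estimates mean left and right atrial volumes from a single
non-gated dynamic cardiac PET acquisition by tracking the first pass of
the injected bolus through the heart. This vignette is the package's
account of the science: the models it implements, the parameters that
matter, what the synthetic phantom does and does not emulate, and the
design decisions taken where the method left room.

## 1. First-pass indicator-dilution analysis

During the first transit, the bolus reaches the cardiac chambers in the
order SVC → RA → RV → lungs → LA → LV → aorta. For each voxel the
first-pass peak of the time–activity curve (TAC) is isolated and
summarized by its centroid time and its area,

$$t_{mid} = \frac{\sum_i t_i\, C_i\, \Delta_i}{\sum_i C_i\, \Delta_i},
\qquad AUC = \sum_i C_i\, \Delta_i,$$

where $t_i$ are frame mid-times and $\Delta_i$ frame durations. The sums
run over the extracted peak segment only. Two choices here are ours:

* **Duration weighting.** The centroid is computed with
  duration-weighted sums. The clinical schedule mixes 5 s and 60 s
  frames; weighting by $\Delta_i$ makes the estimate invariant to how a
  smooth curve is cut into frames, which an unweighted sum is not.
* **Peak segment.** The extractor finds the global maximum within the
  first `peak_window_s = 120` s and extends outward until the curve
  falls below `peak_tail_frac = 0.10` of the peak, until a local minimum
  below `peak_recirc_frac = 0.5` of the peak is crossed (the
  recirculation cut), or the window ends. Voxels whose maximum is below
  `max(5 × late background, 0.5 kBq/mL)` are flagged as peak-free and
  excluded from all masks — they are never zero-filled. The 10% tail
  rule truncates slow tails and biases the centroid of wide boluses by
  a few tenths of a second; this is well inside the half-frame accuracy
  the pipeline needs, and the cut is essential so that myocardial and
  recirculating activity do not inflate blood AUC.

AUC is normalized once the LV-cavity reference is known, so that the LV
blood pool has area 1. The blood region is `aucNorm > 2/3` with
`t_mid < 90 s`; we read "less than 1.5 min" strictly.

## 2. Input functions by cluster analysis

Arterial ($C_A$) and venous ($C_{RV}$) whole-blood curves are obtained
by k-means over amplitude-normalized TACs of candidate voxels
(peak-detected, raw AUC above the 75th percentile), with
`cluster_k = 6`. The initialization is a seeded k-means++ on canonically
ordered candidates, which makes the result deterministic and invariant
to voxel order.

Which cluster is "arterial" and which "venous" is not prescribed by the
physics, and our first implementation taught us two lessons that are
now design decisions:

* Cluster arrival is measured by the **first-pass centroid of the
  cluster-mean TAC**, not by the argmax frame. With 5–10 s early frames
  the argmax is quantized to frame mid-times, and under noise two
  right-heart sub-clusters can appear 7 s apart when their true curves
  are 1 s apart.
* The venous cluster is the **earliest high-AUC cluster** (mean AUC at
  least 2/3 of the highest cluster, mirroring the blood-pool fraction).
  The arterial cluster is found among high-AUC clusters arriving at
  least `min_av_lag_s = 4` s later: candidates within
  `art_window_s = 2` s of the **latest** arrival are kept and the
  highest-AUC one wins. Rationale: the LV cavity and aorta are the last
  high-blood-volume stations of the first pass, whereas "highest AUC
  overall" is a coin flip between the LA and LV clusters whose mean
  AUCs differ by a few percent.

The lung timing reference $t_{lungs}$ is taken from a cluster with
intermediate normalized AUC (0.15–0.5) arriving strictly between the
venous and arterial centroids. Because the 75th-percentile AUC pre-mask
usually excludes lung parenchyma from the candidate set, this cluster
often does not exist; the documented fallback — the midpoint of the
venous and arterial centroids — is then used and recorded as
`lungs: fallback` provenance. Only a scalar timing gate is needed, so no
anatomical lung mask is built.

## 3. Kinetic model and basis-function fitting

Tissue voxels follow the single-tissue compartment model for
[¹⁵O]-water,

$$C_T(t) = PTF \cdot MBF \cdot C_A(t) \otimes e^{-\frac{MBF}{V_T} t}
 + V_A\, C_A(t) + V_{RV}\, C_{RV}(t),$$

with the distribution volume fixed at $V_T = 0.91$ mL/g. MBF is
reported in mL·g⁻¹·min⁻¹ and converted to s⁻¹ (MBF/60) inside the
exponent and the flow term. For each MBF value on a grid (default 100
log-spaced points in [0.1, 5]) the model is linear in
$(PTF, V_A, V_{RV})$; a weighted non-negative least-squares solve per
basis function and a scan over the grid give the fit. Numerical
choices:

* Convolution by **trapezoidal recursion on a 1 s grid** — exact to
  well below 0.1% for these kinetics and free of transform-length
  artifacts.
* Frame weights ∝ duration; the model is fitted to frame averages, and
  the blood terms are added at the frame level so the zero-flow limit
  is exact.
* The non-negative solve is exact: with three coefficients the global
  optimum is found by enumerating coefficient supports.
* Ties on the residual grid keep the **smallest MBF** (stability under
  flat residual profiles).
* All-zero TACs yield a flagged null fit (all NA).

With its own inputs the fit recovers noise-free parameters to within
the ~2% grid resolution and matches a nonlinear least-squares oracle's
residual to within 1% (both tested). End-to-end on the phantom the
median myocardial MBF is biased by about +6%: roughly a quarter of that
is the reconstruction of a fine-grid input from 5–10 s frame values,
the rest is partial-volume contamination of the image-derived input
function by the point-spread function. Partial-volume and dispersion
correction of input functions is deliberately out of scope, so this
bias is reported, not corrected.

## 4. Ventricular segmentation and the 1.3 cm rule

The long axis is the principal eigenvector of the second-moment tensor
of the largest connected high-$V_A$ component on the LV side (the
component holding the most arterial-cluster voxels), and all maps are
rigidly resampled to a short-axis grid (trilinear for images, nearest
neighbour for masks). Per short-axis slice the cavity centre is the
centroid of the largest high-$V_A$ (LV) or high-$V_{RV}$ (RV) region;
36 radial profiles of PTF are sampled and the wall is placed at the
first sufficiently prominent PTF ridge with inner/outer edges at
half-maximum. The annulus between the per-angle edges is rasterized, so
no angular gaps appear at large radii; the stacked mask is closed
(1 voxel) and the largest connected component kept. This profiling is a
simplified re-creation of the full published approach and is flagged as
approximate; all its parameters are exposed in `pipelineConfig()`.

Cavities are the blood enclosed by the per-slice filled myocardial ring
at a Euclidean distance of at least `cavity_margin_mm = 13` mm (twice
an assumed 6.5 mm FWHM resolution) from the wall, computed with an
exact anisotropic 3-D distance transform and verified against an
exhaustive per-voxel oracle. Cavity TACs give $t_{LV}$, $t_{RV}$,
$AUC_{LV}$, $AUC_{RV}$; $AUC_{LV}$ becomes the normalization reference.

## 5. Atrial segmentation

The LA candidate is the blood mask minus three regions: later than
$t_{LV}$ plus **two heartbeats**, earlier than $t_{lungs}$, and the
(1-voxel-dilated) LV cavity. The heartbeat duration needs a heart rate
the acquisition does not record; `heart_rate_bpm = 60` (a 2 s window)
is the default and is carried in the configuration. The aorta is split
off by removing a cylinder around the LV outflow-tract axis —
operationalized as the line from the LV-cavity centroid through the
basal-most cavity slice centroid — growing its radius from 5 mm in 1 mm
steps until at least two components of ≥ 5 mL exist; the component with
the lowest median $t_{mid}$ is the LA. If no split is achieved by
30 mm, the whole candidate becomes the LA with a fallback flag.

The RA mirrors the rule with $t_{RV}$ and additionally removes the
already-assigned LA/aorta labels. The SVC is treated as a tube:
scanning axial slices from the superior end, a slice is tube-like when
its candidate cross-section is < 6 cm² with circularity
$4\pi A / P^2 > 0.6$; a run of ≥ 3 such slices contiguous with the top
is removed. The perimeter $P$ uses boundary-face counting with the
π/4 Manhattan correction, which is unbiased for digitized convex
shapes (a naive boundary-pixel count makes every small digitized circle
fail the test). Connectivity is 26-neighbour in 3-D and 8-neighbour in
slices.

Volumes are voxel count × voxel volume; indexing uses Du Bois BSA,
$0.007184\, w^{0.425} h^{0.725}$. Non-positive height/weight skip the
indexing with a warning but never suppress the volumes; empty atrial
labels set QC flags.

## 6. The synthetic phantom: what it emulates, and what not

The phantom fills a 192 mm field of view (default 96³ grid, 2 mm
voxels) with analytic geometry: prolate LV and RV cavities with
myocardial shells, spherical atria, cylindrical aorta and SVC, paired
lung ellipsoids. Every blood structure carries a gamma-variate bolus
$A\,((t-t_0)/\alpha\beta)^\alpha e^{\alpha-(t-t_0)/\beta}$ — chosen
because its centroid has the closed form $t_0 + \beta(\alpha+1)$,
making arrival-time tests analytic — plus a recirculation tail
(a +30 s, 15%-amplitude, doubly dispersed copy) that the peak extractor
must survive. Delays (SVC 3, RA 4, RV 6, lungs 11, LA 17, LV 20,
aorta 21 s; α = 3, β = 1.5 s) respect the physiological ordering with
LA→LV separation at the few-second scale the method relies on.
Myocardial voxels follow the forward compartment model driven by the LV
(arterial) and RV (venous) curves, with resting-range parameters
(MBF 0.9 mL·g⁻¹·min⁻¹, PTF 0.60–0.65 g/mL, spillover fractions
0.03–0.15). A 5 mm FWHM Gaussian point-spread function models
reconstructed resolution, and frame noise is heteroscedastic Gaussian
with standard deviation `noise_scale · sqrt(value/duration)` — variance
falling with frame length as in reconstructed PET, but only as a
surrogate: real reconstruction noise is spatially correlated and
non-Gaussian, and no claim of realism is made. Not modeled at all:
attenuation/scatter, sinogram reconstruction, cardiac or respiratory
motion, and ECG-resolvable volume changes — so passing tests show the
analysis chain is correct under these conditions, not that clinical
accuracy is guaranteed.

Two phantom-driven observations worth stating plainly:

* The 2/3 AUC blood threshold sits slightly **inside** the blurred
  boundary of a chamber (about 0.4 σ of the PSF), so recovered volumes
  read ~10–13% low for atrium-sized spheres at the 5 mm PSF. The
  acceptance band for volume recovery (15%) reflects this geometry,
  and test–retest precision is unaffected.
* The non-gated estimate is a time-averaged volume; minimal/maximal
  volumes and emptying fraction are unobtainable by construction.

## 7. Repeatability statistics

For paired test/retest values, differences $d$ give
RPC $= 2\,\mathrm{SD}(d)$ (sample SD, $n-1$), CoV
$= \mathrm{SD}(d)/\text{grand mean} \times 100$, and Bland–Altman
limits mean$(d) \pm 1.96\,\mathrm{SD}(d)$. The intraclass correlation
is the two-way mixed, single-score form; "two-way mixed, single score"
is commonly read as the consistency form
$(MS_S - MS_E)/(MS_S + MS_E)$ for $k = 2$, which is the default, and
the absolute-agreement form is returned alongside. Both are computed
from the explicit ANOVA decomposition and verified against `aov()`.

The packaged experiment (`runTestRetest()`) simulates 20 subjects whose
LA radius spans 20–32 mm (a volume spread far above 30%), scans each
twice with independent noise, and feeds paired LAV/RAV to the
statistics. The experiment grid is 64³ at 3 mm — the same 192 mm
anatomy sampled more coarsely — which keeps 40 full pipeline runs
affordable; the acceptance checks of single-scan accuracy use the full
96³ grid. Note that only the LA size varies between subjects by
design, so the RAV ICC is uninformative (there is almost no
between-subject RAV variance) while the RAV CoV remains meaningful.

## 8. Degenerate inputs and failure behavior

All-zero series fail at the first-pass stage with a clear message;
too few peak-detected voxels, an unsatisfiable arterial lag, a missing
blood component, fewer than three profilable slices, an absent
myocardial wall and empty atrial candidates each raise a stage-tagged
segmentation failure. The outflow-tract split and the lung reference
degrade to documented fallbacks (flagged, never silent). The
command-line front end maps these to exit codes 2 (segmentation
failure) and 3 (input/format error).

## 9. Known limitations

* The circumferential profiling and the LVOT extrapolation are
  simplified stand-ins for the full published ventricular method.
* The image-derived input function is uncorrected for partial volume
  and dispersion, biasing absolute MBF (§3); atrial volumes, the
  package's endpoint, are insensitive to this.
* The 2/3 AUC threshold couples recovered volume to scanner resolution
  (§6); absolute volumes carry a resolution-dependent negative bias.
* The heart rate behind the two-heartbeat gate is a configuration
  default, not a measurement.
* Phantom noise is an uncorrelated surrogate for reconstruction noise.
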
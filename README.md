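# petmcsim

Cardiac and respiratory motion blur dynamic PET data and bias the kinetic
parameters fitted from them — in myocardial perfusion imaging, the uptake
rate K1 (mL·min⁻¹·mL⁻¹), which tracks myocardial blood flow. Gating
"freezes" motion but discards most counts; warping each motion phase's
reconstruction into a reference phase with motion fields measured by
simultaneous MR keeps all counts. `petmcsim` is a self-contained simulation
laboratory for quantifying that trade-off: it generates a moving digital
thorax phantom with a non-transmural perfusion defect, simulates dynamic
PET (and spoiled-GRE MR) data from it, reconstructs static (ST), gated
(GA), non-motion-corrected (NMC) and motion-corrected (MC) series, fits
voxelwise K1 maps, and compares ROI bias and variance across Poisson noise
realizations. It is aimed at researchers prototyping PET-MR motion
correction and kinetic-fitting pipelines who need ground truth that real
scans cannot provide.

## The model in brief

Tissue activity follows a one-tissue compartment model driven by an
arterial input function Cp(t):

    Ct(t) = K1 · Cp(t) ⊗ exp(−k2 t)

with generating values K1 = 0.80, k2 = 0.17 (healthy myocardium) and
K1 = 0.36, k2 = 0.21 (defect). The measured myocardial concentration in
frame t_m includes left/right-ventricular spillover:

    C_PET(t_m) = f_LV·C_LV(t_m) + f_RV·C_RV(t_m)
               + (1 − f_LV − f_RV) · (1/Δt_m) ∫ Ct dτ

Noise-free sinograms follow the forward model **ȳ = A G P x** (Gaussian
PSF P of 4.5-mm FWHM in image space, Siddon ray-traced parallel-beam
projector G, Beer–Lambert attenuation factors A), calibrated so the last
(4-min) frame carries 50,000 true counts for the 3-mm slice, with Poisson
noise per bin. Reconstruction is attenuation-precorrected filtered
back-projection; motion fields come from multi-resolution Thirion demons
registration of analytic spoiled-GRE MR phase images; fitting is
unweighted least squares over (K1, k2, f_LV, f_RV). Per ROI and method M,
the package reports the mean and (N−1) SD of K1 across realizations, the
bias b = (K̄₁ᴹ − K̄₁ˢᵀ)/K̄₁ˢᵀ, the bias against the generating truth, and
the SD reduction δ = |σᴹᶜ − σᴳᴬ|/σᴳᴬ.

## Worked example

```r
library(petmcsim)

study <- run_study(study_config(motion = "CRM", n_realizations = 25, seed = 1))
tidy(study)
```

```
   study roi       n mean_K1  sd_K1 bias_vs_ST truth_bias sd_reduction_vs_GA
 1 ST    ROI1      1   0.744 NA       0           -0.0695             NA
 2 ST    ROI2      1   0.728 NA       0           -0.0903             NA
 3 ST    ROI3      1   0.586 NA       0           -0.0419             NA
 4 ST    ROI4      1   0.703 NA       0           -0.122              NA
 5 GA    ROI1     25   1.59   0.857   1.13         0.986              NA
 ...
 9 NMC   ROI1     25   0.575  0.247  -0.228       -0.282               0.711
13 MC    ROI1     25   0.768  0.214   0.0317      -0.0400              0.751
16 MC    ROI4     25   0.703  0.122   0.000452    -0.121               0.858
```

The ST rows are the noise-free static gold standard: mid-wall ROI K1 sits
within about ten percent of the generating 0.80 (partial-volume blur
accounts for the shortfall), and the defect ROI (ROI3) reads low because
it mixes defect and adjacent healthy pixels. The GA/NMC/MC rows summarize
the noisy studies across 25 realizations: under combined
cardiac+respiratory motion the uncorrected study is strongly biased
(NMC ROI1: −23% vs ST) where motion correction nearly removes the bias
(MC ROI1: +3%), and the gated study is by far the noisiest — MC cuts the
K1 standard deviation by 71–86% relative to GA (`sd_reduction_vs_GA`, the
δ statistic above) while using all of the counts.

```r
glance(study)         # defect contrast per method, mask size, scale
autoplot(study)       # ST / GA / NMC / MC K1 maps side by side
plot_roi_summary(study)
```

`defect_contrast(study)` shows the motion-correction payoff directly: the
healthy-minus-defect K1 contrast (0.14 in the static truth) collapses to
−0.13 for NMC and is restored to 0.23 by MC in the run above.

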
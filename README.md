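# dixonmra

Analysis tools for **subtractionless contrast-enhanced peripheral MR
angiography** based on two-point modified Dixon (mDixon) water–fat
separation, with the conventional pre/post-contrast subtraction
reconstruction as the comparator.

Peripheral CE-MRA traditionally suppresses background by subtracting a
pre-contrast from a post-contrast acquisition. That subtraction inflates the
noise standard deviation by √2 (the two acquisitions carry uncorrelated
noise) and is vulnerable to misregistration from patient or organ motion. A
dual-gradient-echo acquisition reconstructed with a two-point Dixon method
instead yields an inherently fat-suppressed water image from the
post-contrast data alone. Its noise behaviour is governed by the echo
spacing ΔTE = TE₂ − TE₁ and the fat–water resonance offset Δf_F (≈ −421.5 Hz
at 3 T):

- SNR of the subtraction image: `SNR_S = (S₂ − S₁) / (√2 σ)`
- SNR gain of the water–fat separation: `√(1 − cos(2π ΔTE Δf_F))`,
  maximal (= √2) at `ΔTE = 1 / (2 |Δf_F|)`
- total SNR gain of the subtractionless reconstruction over subtraction:
  `√2 · √(1 − cos(2π ΔTE Δf_F))`, at most **2**.

The package implements, as testable R code:

- a **synthetic dual-echo angiography phantom** (`phantom_spec()`,
  `build_phantom()`, `simulate_dual_echo()`, `simulate_noise_only()`): a
  branching arterial tree with stenoses/occlusions in mixed water/fat
  tissue, multi-peak fat spectral phase evolution, a smooth off-resonance
  field, contrast enhancement of the lumen, complex Gaussian noise, and
  noise-only acquisitions (RF excitation disabled);
- **two-point Dixon separation with flexible echo times**
  (`separate_water_fat()`): per-voxel candidate solutions, water/fat swap
  resolution by seeded region growing on the field phasor (Rcpp), and a
  demodulated linear solve;
- the **subtraction reconstruction, coronal MIPs and multi-station
  stitching** (`subtract()`, `mip_coronal()`, `stitch()`);
- the semi-automated **vessel-to-background contrast** (VBC) analysis
  (`segment_roi()`, `compute_vbc()`, `transfer_segmentation()`):
  cylindrical ROIs, 10-maxima search, innermost-seed selection, flood-fill
  lumen segmentation, branch/hyperintense removal, and
  `VBC = (mean_vessel − mean_background) / SD_background`;
- the **SNR propagation theory and noise-only empirical gain**
  (`separation_gain()`, `total_gain()`, `optimal_echo_spacing()`,
  `empirical_gain()`);
- **reader-agreement statistics** (`quadratic_weighted_kappa()`,
  `summarize_scores()`);
- an end-to-end **study driver** (`run_study()`) that reproduces the full
  three-station exam design on synthetic subjects: 23 vessel segments × 3
  ROIs = 69 ROIs per subject, stitched 1210 mm panoramas, and per-station
  theoretical and measured SNR gains.

Results are tibbles; fitted bundles have `tidy()`/`glance()` methods and
`autoplot()`/`plot_vbc()` visualisations.

## Worked example

```r
library(dixonmra)

snr_gain_table()
#> # A tibble: 3 × 6
#>   station_label te1_ms te2_ms delta_te_ms separation_gain total_gain
#>   <chr>          <dbl>  <dbl>       <dbl>           <dbl>      <dbl>
#> 1 abdominal       1.48   2.84        1.36            1.38       1.95
#> 2 upper_leg       1.51   2.83        1.32            1.39       1.97
#> 3 lower_leg       1.58   2.88        1.3             1.40       1.98

st <- run_study(pipeline_config(n_subjects = 1, seed = 42))
st
#> <mra_study> 1 subject(s), 69 ROIs/method
#>   mean VBC: mdixon 44.58 vs subtraction 26.81 (ratio 1.66)
#>   SNR gain: theory 1.96, noise-only measurement 1.96
```

The gain table is the closed-form theory at the three stations' echo times:
the water–fat separation contributes a factor 1.38–1.40 and dropping the
subtraction another √2, for a total SNR gain just below the theoretical
optimum of 2. The study line reports that, on one synthetic subject, the
segmentation-transferred VBC is higher on the water image than on the
subtraction image in all 69 ROIs on average (the direction expected from
the noise theory), and that pushing pure noise through both reconstructions
measures an SNR gain equal to the closed-form prediction.

Reader agreement on the 0–3 quality scale:

```r
quadratic_weighted_kappa(c(3,3,2,3,1,2,3,3), c(3,2,2,3,2,2,3,3))
#> <mra_kappa> 0.667 (good agreement), n = 8
```

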
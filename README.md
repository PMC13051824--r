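# mdtmap

Simulation and estimation toolkit for **Mean Diffusivity of Tissue (MDT)
mapping** — a diffusion MRI technique that estimates cortical and
subcortical tissue diffusivity free of cerebrospinal-fluid (CSF)
partial-volume contamination.

## The problem and the method

Conventional mean-diffusivity (MD/ADC) maps are computed from the signal
decay between b = 0 and a moderate b-value. At b = 0 every compartment in
a voxel contributes fully, so a voxel containing both cortex and CSF
(which is unavoidable when voxels are not much smaller than the cortical
ribbon) yields a diffusivity estimate biased far above the tissue value —
a 30 % CSF fraction inflates the ADC of 0.7 µm²/ms tissue by about 45 %.

MDT sidesteps the confound by estimating the log-slope between **two high
b-values** acquired with **spherical tensor encoding**:

    MDT = [ln s(b1) − ln s(b2)] / (b2 − b1),   b1 = 1500, b2 = 2500 s/mm²

Free water diffuses at ~3.0 µm²/ms, so at b = 2500 s/mm² CSF retains
exp(−7.5) ≈ 0.055 % of its signal — effectively nothing. The slope
between the two shells therefore reflects tissue alone. Spherical
(isotropic) b-tensor encoding makes each Gaussian compartment's
attenuation depend only on its mean diffusivity (trace/3), never on fiber
orientation. The thin through-plane resolution needed for SNR is bought
back by acquiring thick slices (5.2 mm, in-plane 1.53 × 1.53 mm²) in six
stack rotations about the anterior–posterior axis and solving a
super-resolution reconstruction (SRR) problem per shell,

    argmin_x Σ_r ‖A_r x − y_r‖² + λ‖L x‖²,

where `A_r` rotates, blurs along the slice axis, and decimates; the
output grid is isotropic 1.53 mm. Because the CSF signal is nulled, MDT
maps can be displayed with a tight window (0.5–0.9 µm²/ms) that makes
subtle diffusivity changes conspicuous.

The package provides, end to end:

* a multi-compartment Gaussian signal model under b-tensor encoding with
  Rician noise (`compartment_attenuation`, `mixture_signal`,
  `add_rician_noise`);
* digital brain phantoms with cortex / white matter / CSF / deep-nuclei
  compartments, anti-aliased partial-volume boundaries, insertable
  lesions and exact ground truth (`build_phantom`, `insert_lesion`,
  `ground_truth_tissue_md`);
* a forward simulator of the rotated thick-slice multi-shell acquisition
  (`simulate_session`, `average_repetitions`);
* model-based SRR by regularized least squares with a monotone
  conjugate-residual solver (`reconstruct_all_shells`);
* the MDT estimator with comparison ADC maps, cortical masking, display
  windowing and CSF-fraction-stratified bias reports (`compute_mdt`,
  `mdt_map_from_shells`, `apply_cortical_mask`, `render_window`,
  `pv_bias_report`);
* NIfTI I/O, YAML/JSON configuration, an in-memory and on-disk pipeline
  (`run_pipeline`, `run_pipeline_to_dir`) and a CLI
  (`inst/cli/mdtmap.R`).

## Worked example

Insert a focal cortical lesion (+0.15 µm²/ms, the magnitude of a subtle
dysplasia-like change) into a 48³ phantom, simulate the full protocol
(b = 0/1500/2500 s/mm² in 1/16/24 repetitions, six rotations, SNR ≈ 20),
reconstruct, and estimate:

```r
library(mdtmap)

les <- lesion_spec("focal_hyperintense", center = c(17.4, 0, 0),
                   radius = 7, delta_md = 0.15)
cfg <- pipeline_config(phantom_shape = c(48L, 48L, 48L),
                       lesions = list(les), sigma = 0.05, seed = 1)
res <- run_pipeline(cfg)

res$recon
#> <srr_result> 3 shell(s) on a 31x31x31 grid @ 1.53 mm isotropic
#>   b0: 76 solver iteration(s), relative residual 9.74e-07
#>   b1500: 80 solver iteration(s), relative residual 9.29e-07
#>   b2500: 84 solver iteration(s), relative residual 9.23e-07

str(res$lesion_stats[[1]])
#> List of 5
#>  $ lesion_mean       : num 0.996
#>  $ contralateral_mean: num 0.833
#>  $ difference        : num 0.163
#>  $ n_lesion          : int 100
#>  $ n_contralateral   : int 103
```

The lesion ROI mean sits ~0.16 µm²/ms above the mirrored contralateral
ROI — the inserted +0.15 recovered through noise, thick-slice sampling
and reconstruction. The bias report stratifies estimator error by CSF
fraction; `adc_bias` grows steeply with CSF content while `mdt_bias`
stays an order of magnitude flatter in the noiseless closed form (the
noisy end-to-end table also contains reconstruction and noise error):

```r
round(res$bias_report, 4)
#>   bin_lo bin_hi    n mdt_bias mdt_rmse adc_bias adc_rmse
#> 1    0.0    0.1 6372   0.0388   0.3960  -0.0224   0.2261
#> 2    0.1    0.2  366   0.0951   0.5358  -0.0224   0.2561
#> 3    0.2    0.3  133   0.1267   0.5862   0.0414   0.2895
#> 4    0.3    0.4  179   0.1373   0.8451   0.3019   0.4946
#> 5    0.4    0.5   71   0.1854   1.0921   0.3356   0.4599
```

The closed-form voxel arithmetic behind the CSF-suppression claim:

```r
mix <- compartment_mixture(
  diffusion_compartment(0.7, fraction = 0.7),          # tissue
  diffusion_compartment(FREE_WATER_MD, fraction = 0.3)) # CSF
compute_mdt(mixture_signal(mix, 1500), mixture_signal(mix, 2500))
#> 0.7121504   # +1.7 % vs the 0.7 truth
compute_adc(mixture_signal(mix, 0), mixture_signal(mix, 1000), 1000)
#> 1.014604    # +45 %
```

The command-line pipeline mirrors the R API:

```sh
Rscript inst/cli/mdtmap.R run-all --config demo.yaml --seed 1 --out out/ --verbose
```

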
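# sphmicro

Rotationally invariant spherical convolutional networks for diffusion-MRI
microstructure estimation, in pure R.

## The problem

Diffusion MRI (dMRI) probes tissue at the micrometre scale by measuring
signal attenuation along many diffusion-encoding directions and strengths.
For Gaussian compartment models the voxel signal is a spherical convolution
of a fibre **orientation distribution function** (ODF) with an axially
symmetric microstructural kernel

S(n̂) = ∫ ODF(u) K(uᵀn̂) du,  K(n̂) = S₀ Σᵢ fᵢ exp(−**b** : **D**ᵢ),

where **b** is the diffusion-encoding b-tensor (ms/μm²) and **D**ᵢ the
compartment diffusion tensor (μm²/ms). Recovering the ODF and the kernel's
scalar parameters — e.g. intra-neurite diffusivity *d* and signal fraction
*f* of the constrained two-compartment (stick + zeppelin) model, or the
apparent soma parameters (d_i, f_i, d_sph, f_sph) of the three-compartment
model under tensor-valued encoding — is a hard, noise-sensitive inverse
problem, and a clinically useful estimator must be *rotationally
invariant*: the estimates must not depend on head orientation.

`sphmicro` implements, end to end:

* real even-degree spherical-harmonic transforms (least-squares fits, zonal
  convolution, Wigner-D rotations, spectral truncation) and the HEALPix and
  SO(3) sampling grids;
* linear/planar b-tensor acquisition schemes, powder averaging, and the
  voxelwise SNR rule (1/sd of normalized b0 signals);
* an efficient frequency-domain simulator of compartment-model signals with
  Rician noise, plus a synthetic Watson-mixture ODF sampler;
* an SO(3)-equivariant **spherical CNN** (six spectral zonal-convolution
  layers, spatial leaky-ReLU on the HEALPix grid, spectral pooling, global
  mean pooling into a small fully connected head; 78,258 trainable
  parameters in the two-compartment configuration) and an **MLP** baseline
  (614,447 parameters), both with hand-written, finite-difference-verified
  forward/backward passes and Adam training on freshly simulated batches;
* the **SMT** baseline: closed-form powder-average fit plus a minimal
  constrained spherical deconvolution for the ODF;
* benchmarks for test-set MSE (ODF, d, f) and rotational variance
  (mean std of estimates over SO(3) rotation grids), and voxelwise map
  generation for 4-D NIfTI volumes with FSL bval/bvec (and b-tensor
  sidecar) gradient tables.

The methods vignette (`vignettes/spherical-microstructure.Rmd`) documents
the model, the architecture reconstruction, the simulator's normalization,
and every numerical choice.

## Worked example

Train a desk-scale sCNN on the two-shell HARDI protocol (b = 1 and
2.2 ms/μm², 60 directions each, SNR 50) and compare it with the MLP and SMT:

```r
library(sphmicro)
scheme <- hardi_scheme()

scnn <- train(scnn_init(scnn_config(), seed = 1601), scheme,
              train_config(n_batches = 320, batch_size = 48, rotate = TRUE,
                           snr = 50, data_seed = 1602L,
                           noise_seed = 101602L))$model
mlp <- train(mlp_init(mlp_config(), seed = 1603), scheme,
             train_config(n_batches = 3200, batch_size = 48, rotate = TRUE,
                          snr = 50, data_seed = 1604L,
                          noise_seed = 101604L))$model

test <- make_batch(1200, scheme, snr = 50, rotate = TRUE,
                   seed = 1606, noise_seed = 101606)
r_scnn <- test_mse(scnn_estimator(scnn, scheme), test)
r_mlp  <- test_mse(mlp_estimator(mlp, scheme), test)
r_smt  <- test_mse(smt_estimator(scheme), test)
```

On this configuration (about 12 minutes on one CPU core) the run prints,
in units of 10⁻³ (MSE over 1200 test voxels):

```
          ODF     d (um^2/ms)   f
sCNN     2.4           10.4         12.3
MLP      4.6            9.3          9.5
SMT      6.1           11.6         24.3
```

The networks beat the SMT fit on the scalar parameters, and the rotational
variance benchmark separates the architectures sharply:

```r
rv_scnn <- rotational_variance(scnn_estimator(scnn, scheme), scheme,
                               n_configs = 20, rotations = so3_grid(5),
                               seed = 1607)
rv_mlp  <- rotational_variance(mlp_estimator(mlp, scheme), scheme,
                               n_configs = 20, rotations = so3_grid(5),
                               seed = 1607)
```

mean std over 125 rotations × 20 noiseless configurations, ×10⁻³:
sCNN d 0.10, f 0.04; MLP d 13.3, f 8.1 —
the equivariant network is more than an order of magnitude less
rotationally variant, while the SMT fit is rotation invariant by
construction (≈ 0.1·10⁻³ solver noise). Absolute values depend on
the synthetic ODF prior and the reduced training budget; the orderings are
the stable result.

## Command line

`inst/cli/sphmicro.R` is a thin dispatcher over the exported functions:

```sh
Rscript inst/cli/sphmicro.R simulate --seed 1 --config cfg.yaml --out sim
Rscript inst/cli/sphmicro.R train --seed 1 --config cfg.yaml --out ckpt
Rscript inst/cli/sphmicro.R predict --in dwi.nii.gz --bval dwi.bval \
    --bvec dwi.bvec --mask mask.nii.gz --model ckpt --out maps
Rscript inst/cli/sphmicro.R fit-smt --in dwi.nii.gz --bval dwi.bval \
    --bvec dwi.bvec --out smt
Rscript inst/cli/sphmicro.R snr --in dwi.nii.gz --bval dwi.bval \
    --bvec dwi.bvec --out qc
```
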
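---
title: "Methods: spherical convolutional networks for diffusion MRI microstructure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spherical convolutional networks for diffusion MRI microstructure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The estimation problem

Diffusion MRI measures signal attenuation along many encoding directions and
strengths. In white and gray matter the signal of a voxel is well described
by a *Gaussian compartment model*: an orientation distribution function
(ODF) on the sphere, convolved with a microstructural kernel that is a sum
of axially symmetric Gaussian attenuations,

$$S(\hat n) \;=\; \int_{S^2} \mathrm{ODF}(u)\, K(u^\top \hat n)\, du, \qquad
K(\hat n) = S_0 \sum_i f_i \exp(-\mathbf b : \mathbf D_i),$$

with $\mathbf b$ the 3×3 diffusion-encoding b-tensor (trace = b-value, in
ms/μm²) and $\mathbf D_i$ a compartment diffusion tensor (μm²/ms). The
inverse problem — recovering the ODF and the scalar kernel parameters from
noisy signals — is what this package solves, with three estimators:

* an SO(3)-equivariant **spherical convolutional network (sCNN)** trained on
  simulated data (the package's core);
* a **multi-layer perceptron (MLP)** baseline with no rotational structure;
* the **spherical mean technique (SMT)**: a closed-form fit to
  powder-averaged (per-shell mean) signals, followed by constrained
  spherical deconvolution (CSD) for the ODF.

The headline property is *rotational variance*: estimates of tissue
parameters should not depend on head orientation. The sCNN achieves this
architecturally; the MLP must learn it from data and does so imperfectly.

## Spherical harmonics

All spherical functions are real, antipodally symmetric, and band-limited,
so they live in the real even-degree spherical-harmonic basis
($S_l^m = Y_l^0$, $\sqrt2\,\mathrm{Re}\,Y_l^m$, $\sqrt2\,\mathrm{Im}\,Y_l^{|m|}$;
45 coefficients at bandwidth 8, 153 at 16). Because neither acquisition
direction sets nor HEALPix pixel centers satisfy an exact sampling theorem,
**every** forward/inverse transform is a least-squares fit
$(B^\top B)^{-1} B^\top X$ — one code path for acquisition shells and
internal grids alike. Shells with fewer directions than coefficients use a
Laplace–Beltrami ridge ($\lambda\, l^2(l+1)^2$, default $\lambda = 0.006$,
the standard value for regularized SH fits of dMRI shells); fits on
well-sampled grids are plain least squares.

Convolution with a zonal (axially symmetric) kernel is a per-degree product.
We keep two normalizations carefully apart:

* the SO(3) convolution theorem, $\hat y_{lm} = 2\pi\sqrt{4\pi/(2l+1)}
  \hat f_{lm} \hat h_{l0}$, exposed as `convolve_zonal()` (the $2\pi$ stems
  from the unnormalized Haar measure);
* the **physical** synthesis used by the simulator, which drops the $2\pi$
  (Funk–Hecke form), so that an ODF integrating to one yields signals whose
  per-shell spherical mean equals the closed-form SMT equation exactly.
  This identity — the spherical mean does not depend on the ODF — is the
  central correctness property of the simulator and is tested to 0.2%.

Rotations act per degree through Wigner-D matrices built from a cached
factorial expansion of the small-d matrix and a complex↔real change of
basis; correctness is established against a "rotate the grid points,
evaluate, refit" oracle rather than assumed.

## Grids

The spatial grid is HEALPix (RING scheme) at nside 16: 3072 equal-area,
iso-latitude pixel centers, generated from the standard closed-form
tessellation. Because the basis contains only even degrees, every function
the package evaluates is antipodally symmetric, and the HEALPix grid is
exactly antipodally symmetric; internal conversions therefore use one pixel
per antipodal pair (1536 points). Duplicated rows in a least-squares design
act as a uniform weight, so fits, grid means, and spatial mean-squared
errors over the half grid are *mathematically identical* to the 3072-point
definitions — this is an exact optimization, not an approximation. The
public API still returns all 3072 directions.

Rotational-variance benchmarks use an equiangular ZYZ Euler grid with $k$
samples per angle ($k^3$ rotations; $k=9$ gives the canonical 729). A $k^3$
grid cannot be derived from the even-sided equiangular SO(3) sampling
grids, so the $k=9$ construction here is a reconstruction choosing uniform
$\alpha,\gamma$ and interior $\beta$ nodes. Direction sets for the bundled
acquisition schemes are antipodally symmetrized electrostatic-repulsion
sets computed at build time from a fixed internal seed.

## Compartment models

**Two-compartment (stick + zeppelin).** Intra-neurite stick with
diffusivity $d \in [0,3]$ μm²/ms and signal fraction $f \in [0,1]$;
extra-cellular zeppelin with axial diffusivity $d$ and radial $(1-f)d$
(tortuosity constraint). Its powder average has the closed form implemented
in `smt_powder_signal()`, evaluated through a series expansion of
$\mathrm{erf}(\sqrt x)/\sqrt x$ near zero so that $bd \to 0$ and
$bfd \to 0$ are exact.

**Three-compartment (stick + ball + zeppelin).** Adds an isotropic sphere
compartment ($d_{sph} \le \max(d_i, 0.5)$ μm²/ms — the bound corresponding
to a 25 μm soma — and fraction $f_{sph}$ with $f_i + f_{sph} \le 1$). The
extra-cellular diffusivities in the source description of this model are
typographically garbled; we adopt

$$d_{ax}^{EC} = d_i\,\frac{f_i + \tfrac12 f_{sph}}{f_i + f_{sph}}, \qquad
d_{rad}^{EC} = (1 - f_i - f_{sph})\; d_{ax}^{EC},$$

the unique reading that reduces exactly to the two-compartment constraint
as $f_{sph} \to 0$ (a property the tests assert). In the degenerate limit
$f_i + f_{sph} < 10^{-9}$ the bracketed factor is set to 1 (free diffusion
at $d_i$): the factor is bounded in $[\tfrac12, 1]$ and the limit is
parameterization noise, not physics. Kernel spectra are truncated at
bandwidth 8 to match the ODF bandwidth; the small higher-degree content of
sharp kernels at b = 5 ms/μm² is a documented approximation.

## The simulator

A synthetic voxel is an (ODF, parameters) pair. Parameters follow the
training priors $d \sim U(0,3)$, $f \sim U(0,1)$ (and the conditional
uniforms above for the three-compartment model). Clean signals are
synthesized per shell in the frequency domain: kernel evaluated on the
HEALPix grid, zonal spectrum extracted by least squares, per-degree product
with the ODF, evaluation at the shell's directions. Rician noise
$\sqrt{(S+X)^2 + Y^2}$, $X,Y \sim \mathcal N(0, 1/\mathrm{SNR})$, is applied
to b0-normalized signals; default SNR is 50 for the two-shell HARDI scheme
and 29 for the tensor-valued scheme, matching the protocols the package
emulates. Clean signals are invariant to the noise seed by construction.

**Synthetic ODFs.** The reference pipeline draws training ODFs from
multi-tissue CSD of volunteer scans, which are not available to a
self-contained package. The stand-in sampler draws mixtures of up to three
antipodally symmetric Watson lobes (Haar-uniform orientations, Dirichlet(1)
weights, concentration log-uniform on [1, 64]) over an isotropic floor
(fraction uniform on [0.05, 0.5]), projects to bandwidth 8, normalizes to
unit integral, and rejects draws whose grid minimum drops below
$-0.01\times$ maximum (band-limiting ringing). The ranges were chosen once
to span isotropic-ish to sharply peaked fibre configurations, including
crossings. The sampler reproduces the *geometry* of fibre ODFs but not the
empirical distribution of real brains; consequently absolute test-set
errors are not comparable to values obtained with scan-derived ODFs, and
the benchmarks here compare estimators under identical conditions
(orderings), which is what the tests assert. Train/validation/test batches
use disjoint seed ranges to mimic the subject split.

## Network architectures

The sCNN takes per-shell SH coefficients (bandwidth 8, one channel per
shell) and applies six spectral zonal-convolution layers — learnable gain
per even degree per channel pair, bias-free, hence exactly SO(3)
equivariant — with a leaky ReLU (slope 0.1) applied in the spatial domain
on the HEALPix grid and refit by least squares. Layers 1–3 run at bandwidth
16 (the nonlinearity widens the spectrum), spectral pooling truncates to 8
after layer 3, layers 4–6 run at bandwidth 8. The single channel out of
layer 6 is the predicted ODF. Spatial means of the post-rectifier
representations of layers 1–3 (rotation-invariant scalars) are concatenated
(32+32+32 = 96 features) and fed to a head 96→128→128→128→$n_{scalars}$
with batch-norm + ReLU after hidden layers 1–2 and plain ReLU after
hidden 3; scalar outputs are linear in physical units.

The published description fixes the layer count, bandwidths, pooling
placement and head shape but not the channel widths. The configuration
(2→32→32→32→32→48→1) is a reconstruction chosen because it reproduces the
published trainable-parameter count of 78,258 *exactly* (degree-10–16
filter entries of layer 1 act on an empty spectrum but are counted, which
is how a uniform-bandwidth stage implementation behaves). Pooling after
the activation is likewise a choice: the spatial mean of a bias-free zonal
convolution before the nonlinearity carries only degree-0 content, so
pre-activation pooling would waste two of the three feature blocks. The
MLP baseline is 120→512→512→512→47 with batch-norm + ReLU after each
hidden layer (inputs: the normalized diffusion-weighted measurements;
outputs: 45 ODF coefficients + 2 scalars), reproducing its published count
614,447 exactly.

Both networks are implemented as explicit forward/backward computations in
R (BLAS matrix products); the gradients are verified against central finite
differences in the test suite. Training uses Adam at $10^{-3}$, reduced by
90% after 50% and 75% of the batches, mean-squared-error loss with the ODF
term computed in the spatial domain (equal weights for the ODF and scalar
terms — the reference does not specify a weighting, and equal weights keep
both terms in comparable units), fresh simulated batches each step, and
optional Haar-uniform ODF rotation augmentation. Everything is
deterministic given the (init, data, noise) seed triple.

## Baselines

`smt_fit()` is a bounded (L-BFGS-B) least-squares fit of the closed-form
powder-average equation over $d \in [10^{-4}, 4]$, $f \in [0,1]$,
multi-started at $f_0 \in \{0.1, 0.5, 0.9\}$ with ties broken toward
smaller $f$; unattenuated signals drive $d$ to its lower bound and are
flagged degenerate. Because it consumes only powder means it is exactly
rotation invariant up to solver noise. The CSD step deconvolves the
measured signals with the fitted kernel by stacked per-shell regularized
least squares with iterative soft suppression of negative ODF grid values
(penalty weight 1, at most 50 iterations, stopping once the grid minimum
is within $-0.01\times$ maximum), then renormalizes to unit integral.
Kernel degrees with (near-)zero gain are held at zero by a small Tikhonov
term ($10^{-6}$) — they are a genuine null space of the deconvolution.
This is a minimal reimplementation, not a port of any external package's
regularization, so absolute SMT ODF errors differ from published values
obtained with other CSD implementations.

## Benchmarks and problem sizes

`test_mse()` reports spatial-domain ODF MSE over the HEALPix grid and
per-parameter scalar MSEs in physical units. `rotational_variance()`
simulates each configuration noiselessly at every rotation of an SO(3)
grid and reports the mean (n−1) standard deviation of each estimate.

The package's benchmark defaults are desk-scale: the sCNN trains for 320
batches of 48 voxels and the MLP for ten times as many batches (the same
10× rule as the reference protocol), with a 1200-voxel test set and 20
configurations × 125 rotations for rotational variance; the acceptance
script uses a further reduced schedule (160/1600 batches of 32, 600 test
voxels, 12 × 64 rotations). These sizes were fixed in advance from
single-core throughput so a full run completes in minutes; they are two to
three orders of magnitude below the reference protocol (10⁵ batches of
500, 10⁶ test voxels, 10³ × 729 rotations), which together with the
synthetic ODF prior is why only orderings — networks more accurate than
SMT, sCNN at least ten times less rotationally variant than the MLP — are
asserted, not absolute published values. Full-scale settings remain
available through `train_config()` and the function arguments.

## Numerical choices and limitations

* Least-squares SH fits on the nside-16 grid are well conditioned
  (3072 ≫ 153); the ridge path only engages for per-shell fits.
* `kernel_zonal_coeffs()` rejects fields whose m ≠ 0 energy exceeds
  $10^{-4}$ of the total — axial symmetry is an invariant of every kernel,
  and silent leakage would corrupt the convolution.
* Batch-norm uses batch statistics in training and running statistics
  (momentum 0.1) in evaluation; rotational-variance results are computed in
  evaluation mode, so they are deterministic.
* The forward pass is exactly equivariant only at the spectral-convolution
  level; the grid nonlinearity introduces discretization-level deviations
  (measured at ~1% relative or less at bandwidth 8–16 on nside 16), which
  is the floor of the sCNN's rotational variance.
* No exchange between compartments, no restricted (non-Gaussian)
  diffusion, no spatial regularization across voxels, and no preprocessing
  (denoising, distortion or motion correction) — volumes are assumed
  preprocessed.
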
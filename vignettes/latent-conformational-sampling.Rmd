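---
title: "Latent-space exploration of MD trajectories: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent-space exploration of MD trajectories: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Molecular dynamics (MD) gives a protein's conformational ensemble one frame
at a time, but the interesting events — transitions between metastable
states such as the open and closed forms of a hinged enzyme — are rare on
simulated timescales. `latentmd` addresses this with a generative,
adaptive-sampling strategy: learn a two-dimensional latent representation of
the sampled frames with a variational autoencoder (VAE), verify that the
representation is faithful, then *decode points from unsampled latent
regions* (typically between the basins of two known states) into new
Cartesian conformations that can seed further short MD runs. Whether the
combined short runs sample as efficiently as one long run is judged by
Markov-state-model (MSM) implied timescales of the resulting
collective-variable trajectories.

```{r, eval = FALSE}
library(latentmd)
sim   <- two_state_trajectory(2000, n_atoms = 50, rigid_motion = TRUE,
                              seed = 1)
traj  <- align_to_first(sim$ensemble)
fm    <- featurize(traj)
split <- stride_split(2000, 4)
fit   <- traj_vae(fm, kind = "vae", epochs = 200, split = split)
```

# Featurization

Frames are first superposed onto the first frame by the Kabsch algorithm:
the rotation is obtained from the SVD of the cross-covariance of centred
coordinates, with the usual determinant correction so that reflections are
never applied. The fit is computed on a user-chosen atom selection and
applied to all atoms, so internal geometry is untouched (intra-frame
distances are preserved to 1e-9 Å; this is a tested invariant). Alignment
requires at least three non-collinear fit atoms; collinearity is detected
from the singular values of the centred reference coordinates.

Aligned coordinates are flattened to a frames × (3·atoms) matrix and
MinMax-scaled per column,

$$\tilde c_{ik} = \frac{c_{ik} - \min_c}{\max_c - \min_c},$$

with the extrema taken over frames. The scaler is stored with the features
(and as a JSON sidecar if desired) so that any point of feature space — in
particular decoder outputs, which may leave $[0,1]$ — can be mapped back to
Å exactly and linearly. A column whose coordinate never moves makes the map
undefined; such columns are set to 0, flagged, and restored from the stored
minimum on inversion. Train/test splitting takes every frame whose 1-based
index is a multiple of the stride (default 4, i.e. frames 4, 8, … are the
25 % test set).

# The models

Both supported models are mirror-symmetric ("hourglass") dense networks.
The encoder compresses the input width through strictly decreasing hidden
layers to a `latent_dim`-dimensional code (default 2); the decoder is
always the exact mirror, ending in the input width. The default hidden
geometry interpolates geometrically between input and latent width
(`hourglass_sizes()`), which keeps the compression factor between adjacent
layers approximately constant — the same rule by which the reference
architectures for a 4980-wide input (e.g. 1024, 256, 64, 16) were chosen.

For the VAE the encoder has two linear heads, the posterior mean
$\mu(x)$ and log-variance $\log\sigma^2(x)$ of a diagonal Gaussian
$q_\phi(z\mid x)$; the prior $p(z)$ is standard normal. Training maximizes
the evidence lower bound, implemented as minimizing

$$\mathcal{L} = \underbrace{\lVert x - \hat x \rVert^2}_{\text{reconstruction}}
 + w_{KL}\, \mathrm{KL}\!\left(q_\phi(z\mid x)\,\Vert\, p(z)\right),$$

with one reparameterized sample $z = \mu + \sigma\varepsilon$ per datum per
step and the KL term in closed form,
$\tfrac12\sum_d (\mu_d^2 + \sigma_d^2 - 1 - \log\sigma_d^2)$. The plain AE
drops the variance head, the sampling and the KL term. Encoding and
decoding are always deterministic (posterior means), so downstream metrics
are reproducible.

Choices the objective leaves open, and how they are fixed here:

* **Reconstruction likelihood.** Sum of squared errors on the scaled
  features — a fixed-variance Gaussian likelihood. This matches the nature
  of the data (real-valued coordinates in $[0,1]$, not probabilities) and
  its per-sample *sum* (rather than mean) keeps the reconstruction and KL
  terms on comparable scales across input widths.
* **Activations.** Rectified-linear hidden units; a sigmoid output keeps
  decodes inside the scaled coordinate range.
* **Optimizer.** Adam, learning rate 1e-3, batch size 32, 200 epochs.
  Training losses on the packaged fixtures flatten well before 200 epochs;
  the history (per-epoch reconstruction, KL and total, which decompose
  exactly) lets users judge convergence for their own data.
* **KL weight.** 1.0, the plain ELBO. It is exposed (`kl_weight`) for
  β-style reweighting; `kl_weight = 0` reduces the VAE to a stochastic AE,
  which is verified in the tests.
* **Numeric guards.** The encoder log-variance is clamped to $[-10, 10]$
  before exponentiation; a non-finite loss aborts with a hint rather than
  training on. Weights are He-initialized; all randomness (initialization,
  shuffling, posterior sampling) flows from one seeded RNG stream, so a
  fixed seed reproduces a training run bit for bit.

The gradients of this hand-written backpropagation are tested against
central finite differences on a small network.

# Evaluating encoder and decoder

The *encoder* is judged as a dimensionality reduction: Euclidean distances
between the same frame pairs are measured in feature space and latent space
and correlated — Spearman's $\rho = 1 - 6\sum d_i^2 / (n(n^2-1))$ on paired
ranks, and the Pearson product-moment correlation. Two details matter: with
tied distances the rank-difference shortcut is biased, so the
implementation falls back to Pearson-of-average-ranks exactly when ties are
present; and because all-pairs work grows quadratically, at most
`max_pairs` (default 100,000) seeded uniformly sampled pairs are used for
large frame counts.

The *decoder* is judged structurally: each frame is encoded, decoded,
inverted to Å, and compared to its original by superposition RMSD

$$\mathrm{RMSD} = \sqrt{\tfrac1N \textstyle\sum_i \lVert r_i^0 - U r_i \rVert^2},$$

minimized over rigid transformations $U$ (Kabsch again; the implementation
is verified against a brute-force rotation-grid scan). Distribution-level
agreement uses scalar RMSD values to a common reference (the first training
frame, configurable) as a proxy for whole structures, comparing the test
frames' distribution with their decodes' via two two-sample statistics:

* **MMD** with a Gaussian kernel, bandwidth from the median pairwise
  distance of the pooled sample (both overridable); the unbiased estimator
  of MMD² is used and clamped at zero before the square root. The kernel
  and estimator are stated precisely because published MMD values are not
  comparable without them.
* **EMD**, the first Wasserstein distance, computed exactly in 1-D as the
  integral of the absolute difference of the empirical CDFs.

`benchmark_models()` trains each candidate architecture several times
(default 3) with distinct seeds and tabulates all five metrics per
replicate and per model; failed replicates are recorded as `NA` rows with a
warning, never dropped silently.

# Generating seed structures

Candidate latent points between two states are placed at equally spaced
interpolation parameters on the segment joining the two groups' latent
centroids, with optional seeded Gaussian jitter. This is a deterministic
surrogate for the manual point-picking that latent-map visualizations
invite; equal spacing makes `n_points = 1` the exact midpoint and keeps
results reproducible. Decoded points are written as single-model PDB files
onto a template's atom records. Decoded structures are *not*
energy-minimized — producing plausible Cartesian coordinates is where this
package's contract ends; relaxation belongs to the downstream MD engine.

Domain angles (hinge collective variables) are computed from two vectors,
each running between centers of mass of residue sets; centers are
unweighted centroids by default, with a mass-weighted option, since
published angle definitions rarely state the weighting. Residue sets of a
vector may legitimately share boundary residues (the canonical
CORE–LID definition does); this is allowed with a warning, and only fully
coincident sets are an error.

# Implied timescales

Collective-variable trajectories are discretized by seeded k-means
(k-means++ initialization, 10 restarts, Lloyd iterations). Transitions are
counted at lag $\tau$ with a sliding window by default (strided windows are
available), never across the joins of concatenated trajectory segments.
The transition matrix is the non-reversible maximum-likelihood estimator —
row-normalized counts on the largest strongly connected component, with
trimmed states reported. The implied timescale of eigenvalue $\lambda_i$ is

$$t_i(\tau) = -\frac{\tau}{\ln \lambda_i},$$

the standard MSM relation (the alternative reading $-\tau\ln\lambda$ is
dimensionally wrong and vanishes as $\lambda \to 1$, where relaxation in
fact diverges). Eigenvalues are sorted by magnitude; eigenvalues outside
$(0,1)$ yield flagged `NA` timescales, and complex pairs (possible for
non-reversible estimates of fast processes) are flagged with a warning
while their real parts are used. Confidence intervals come from a
percentile bootstrap over trajectory segments; with a single segment the
counted transition pairs are resampled multinomially instead, with a
warning.

# The synthetic two-state generator

All tests and the acceptance analysis run on a synthetic system with exact
ground truth: two reference conformations of a 50-pseudo-atom chain — a
straight chain and the same chain bent at its midpoint, the bend angle
solved so their superposition RMSD is 5 Å — around which frames are drawn
with isotropic Gaussian noise (default σ = 0.5 Å, i.e. 10 % of the state
separation, a realistic thermal-fluctuation scale for a stable fold). The
active state follows a symmetric two-state Markov chain (default switching
probability 0.05 per frame, so states persist for ~20 frames), and an
optional uniform random rotation (quaternion-sampled from SO(3)) plus
translation per frame emulates the arbitrary global pose of raw MD frames.

What this emulates well: metastability, state-dependent geometry, global
pose noise, and an exactly known slow timescale
($-1/\ln(1-2p)$ for switching probability $p$). What it does not emulate:
bonded constraints and realistic intra-basin anisotropy (noise is isotropic
and uncorrelated between atoms), rugged intra-state substructure, and any
force-field energetics. Passing tests therefore demonstrate correctness of
the machinery and recoverability of planted structure — not that a VAE
trained on a real protein will interpolate physically valid intermediates.

# Problem sizes and tolerances used in the tests

The shared test fixture trains the default 4-hidden-layer VAE on 600
frames for 80 epochs; the end-to-end acceptance check uses 2,000 frames
and 200 epochs, the full reference architectures are exercised on a
64-frame, 1,660-atom toy set for 2 epochs, and the MMD permutation-null
check uses 30 seeds at 100 samples per side — sizes chosen to probe each
claim at the smallest scale where it is meaningful. Exact identities
(scaler round trips, alignment invariants, count enumeration) are asserted
at 1e-9–1e-12; statistical checks use 3-standard-error bands or planted
ground truth with 5–10 % bands.

# Known limitations

* Dense networks only; no convolutional or graph architectures, no GPU.
* DOPE-style statistical-potential scoring of decoded structures is not
  included; the benchmark schema is open to an external scorer.
* Binary trajectory formats (DCD/XTC) are out of scope — convert to
  multi-model PDB or a flat coordinate matrix first.
* Reversible (detailed-balance) MSM estimation is not implemented; implied
  timescales from the non-reversible estimator can differ from reversible
  ones on poorly connected data.
* Latent interpolation assumes the two state regions are connected by a
  decodable path; for systems with more than two basins, interpolate
  pairwise.
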
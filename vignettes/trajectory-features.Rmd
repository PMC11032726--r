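---
title: "Quantifying and classifying trajectories with trackfeat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying and classifying trajectories with trackfeat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trackfeat)
```

## The problem

Single-particle tracking, live-cell imaging and molecular-dynamics
simulations all produce *trajectories*: sequences of positions $x_n$
sampled at times $t_n$.  The raw curves are hard to compare or model
directly, so the standard strategy is feature engineering — summarizing
each trajectory by a vector of physics-based and statistical descriptors,
then doing statistics or machine learning in that descriptor space.
trackfeat implements this workflow end to end: a trajectory data model
with CSV and minimal LAMMPS-style YAML readers, seventeen descriptors,
four diffusion-mode simulators that generate labelled training data, a
classifier with cross-validation, a two-component principal projection
and a two-sample feature test, all behind one command-line interface.

## The descriptor suite

All descriptors operate on a `trajectory` object of $N$ points in $d \in
\{1,2,3\}$ dimensions.  Geometric descriptors accept any strictly
increasing time grid; lag-based ones (MSD, VACF, Fourier) require a
uniform step $\Delta t$ (relative tolerance $10^{-9}$ on the spread of
successive differences) and raise an error otherwise — lag averaging is
ill-defined on irregular grids, and silently resampling would fabricate
data.

**Mean squared displacement and exponent.** The time-averaged MSD is
$$\mathrm{MSD}(n\Delta t) = \frac{1}{N-n}\sum_{i=0}^{N-n-1}
  |x_{i+n}-x_i|^2, \qquad n = 1 \dots n_{\max},$$
with $n_{\max} = \lfloor N/4\rfloor$ by default: beyond a quarter of the
trajectory each lag averages too few origins to be reliable.  The
anomalous exponent $\alpha$ is the least-squares slope of $\log
\mathrm{MSD}$ against $\log \tau$ over those lags ($\alpha = 1$ normal
diffusion, $<1$ sub-, $>1$ super-diffusive, $2$ ballistic).  The MSD
ratio $\kappa = \mathrm{MSD}(n_1)/\mathrm{MSD}(n_2) - n_1/n_2$ uses
$(n_1, n_2) = (1, \lfloor n_{\max}/2\rfloor)$ by default (no canonical
pair exists in the literature; both indices are arguments).

**Gyration-tensor shape descriptors.** The gyration tensor is the
position covariance $T_{ab} = \frac1N \sum_i (x_{i,a}-\bar x_a)
(x_{i,b}-\bar x_b)$ with eigenvalues $\lambda_1 \ge \dots \ge \lambda_d$.
From it: the radius of gyration $R_g = \sqrt{\sum_i \lambda_i}$; the
asymmetry $a = -\ln(1 - (\lambda_1-\lambda_2)^2 / 2(\lambda_1 +
\lambda_2)^2)$, which in 3-D is applied to the top two eigenvalues to
keep the planar definition; the anisotropy $\kappa^2$ (the 2-D ratio
form, or the standard three-eigenvalue form in 3-D) bounded in $[0,1]$;
and the kurtosis of the positions projected on the dominant eigenvector.
A 1-D trajectory is collinear by construction, so its anisotropy is
defined as 1.  Eigenvalue ties are broken by descending order and each
eigenvector's first non-negligible component is made positive, so the
spectrum — and the projection kurtosis — is reproducible across BLAS
implementations.

**Path-shape descriptors.** Straightness $|x_{N-1}-x_0| / \sum_i
|x_i - x_{i-1}|$ and efficiency $|x_{N-1}-x_0|^2 / ((N-1)\sum_i
|x_i-x_{i-1}|^2)$ are the linear and squared net-displacement ratios in
$[0,1]$.  The Katz fractal dimension is $D = \ln n / (\ln n + \ln(e/L))$
with $n = N-1$ steps, path length $L$ and maximal point-pair extent $e$;
in the degenerate case $e/L = 1/n$ the denominator vanishes and `Inf` is
returned as an explicit sentinel rather than an arbitrary large number —
the classifier pipeline imputes it to the column's maximum finite
training value (with the imputation stored in the model so prediction
uses the same value).  Trappedness is
$$P = 1 - \exp\!\left(0.2048 - 0.25117\,\frac{D_0\,t}{r_0^2}\right)$$
clamped to $[0,1]$, with $D_0$ from a two-point fit to the first two MSD
lags, $t = (N-1)\Delta t$ and $r_0$ half the maximal extent; the two
constants are the published values of the descriptor family this suite
follows, fixed here so behaviour is reproducible.  Gaussianity compares
the fourth displacement moment at the first lag (the best-sampled one)
with its Gaussian expectation, $g = \langle r^4\rangle / ((1 + 2/d)
\langle r^2\rangle^2) - 1$, which is 0 for normal diffusion in any
dimension.

**Kinematic descriptors.** Finite-difference velocities $v_i =
(x_{i+1}-x_i)/\Delta t$ give the mean speed and the velocity
autocorrelation $C(n\Delta t) = \frac{1}{M-n}\sum_i v_i\cdot v_{i+n}$,
$M = N-1$, reported normalized by $C(0)$.  The Green–Kubo diffusion
coefficient integrates the *unnormalized* VACF by trapezoidal
quadrature, $D_{GK} = \frac1d \int_0^{t_c} C(t)\,dt$, cutting off at the
first zero crossing of the VACF (or at $n_{\max}\Delta t$ if it never
crosses): past the crossing the integrand is statistical noise whose
accumulated area only degrades the estimate.  For a discrete Brownian
walk $C(0) = 2dD/\Delta t$ and the first trapezoid already recovers
$D_{GK}\approx D$.  The Fourier descriptor mean-subtracts each
coordinate, takes the rectangular-window power spectrum, sums over
dimensions and reports the frequency of the largest non-zero bin; if the
non-zero-bin power is below $10^{-12}$ of the total (a constant
trajectory) it reports 0.

**The 17-entry feature vector.** `trajectory_features()` assembles the
descriptors above plus three summary entries — the short-lag slope
diffusivity $\mathrm{MSD}(\Delta t)/(2d\Delta t)$, the normalized VACF
at the first lag, and the MSD at lag $\lfloor n_{\max}/2\rfloor$ — into
a named vector ordered alphabetically, so feature-table CSV columns are
stable.  The full suite needs $N \ge 16$ (three log-log fit points below
$N/4$).  Any constituent failure is re-raised with the feature name
attached, and `build_feature_table()` excludes such rows with a warning
instead of aborting a batch.

## The simulators: a stated world

The four engines generate the labelled training classes:

* **normal** — $x_{n+1} = x_n + \xi_n$ with i.i.d. Gaussian steps of
  variance $2D\Delta t$ per dimension;
* **anomalous** — exact fractional Brownian motion with Hurst $H =
  \alpha/2$, sampled by Cholesky factorization of the covariance
  $\mathrm{Cov}(x_s,x_t) = D(|s|^\alpha + |t|^\alpha - |t-s|^\alpha)$.
  Exact sampling was chosen over spectral or wavelet expansions because
  at desk scale ($N \lesssim 5000$) it reproduces the target law to
  machine precision and is the easiest generator to verify; the $O(N^3)$
  factor is cached per $(\alpha, N, \Delta t)$, making ensembles
  $O(N^2)$ per draw.  If the covariance loses numerical positive
  definiteness, one diagonal jitter of $10^{-10}\max T_{ii}$ is applied
  before giving up;
* **confined** — Brownian proposals specularly reflected in the radial
  coordinate at the sphere $|x| = R$.  Reflection, not rejection:
  rejection sampling distorts the step-length distribution near the
  boundary and admits unbounded retry loops;
* **directed** — $x_{n+1} = x_n + v\Delta t + \xi_n$; $D = 0$ is allowed
  so the ballistic limit (an exact straight line) is reachable.

One master seed determines everything; per-coordinate sub-streams are
derived from it, and `generate_labeled_set()` draws per-trajectory seeds
deterministically, so identical arguments give identical data sets.  The
mode-to-label map is fixed: confined → subdiffusion, normal → normal,
directed → superdiffusion, fBm with $\alpha \ne 1$ → anomalous.
Directed drift is the textbook super-diffusive generator, which reserves
the anomalous label for correlated-increment motion.

The generator defaults are the package's stated world: $N = 250$ points,
$\Delta t = 1$, $d = 2$, $D = 1$ for every engine, confinement radius
$R = 2$ (so $R^2 = 4$ is far below the free-range scale $2DN\Delta t =
500$ — strong confinement), fBm exponent $\alpha = 1.5$ (clearly
persistent but distinct from drift), and drift speed $|v| = 0.5$ (Péclet
number $|v|^2 N \Delta t / 2dD \approx 16$).  These are plausible
single-particle-tracking scales, chosen once; they were not adjusted
against test outcomes.

What the generators deliberately do not emulate: localization noise,
finite-exposure blur, drift of the field of view, heterogeneous or
switching diffusivity, and tethered (harmonic) confinement.  A green
classifier test therefore establishes that the descriptor space
separates the four idealized regimes — not that the classifier is robust
to microscopy artefacts.

## The classification workflow

`build_feature_table()` turns trajectories (optionally labelled) into
the canonical table.  `train_classifier()` imputes non-finite sentinels,
drops zero-variance columns, z-scores the rest, fits the decision model
and reports stratified 5-fold cross-validated accuracy, refitting the
standardization inside each fold so no held-out information leaks into
the scaling.  The default model is linear discriminant analysis: this
environment ships no tree-ensemble package, LDA is deterministic and
fast, and on the stated world it is far above the 0.7 accuracy bar; the
`method = list(fit =, predict =)` hook keeps the contract model-agnostic
so a forest can be plugged in where available.  `classify()` refuses
tables whose feature names do not match the training schema and returns
per-class scores summing to 1.  `pca_projection()` z-scores and projects
onto two principal components with a fixed sign convention
(largest-magnitude loading positive) for determinism; on the default
synthetic set, k-means with $k = 4$ on that plane recovers the true
labels with adjusted Rand index well above the 0.3 bar used as the
operational definition of "well-separated clusters".
`compare_groups()` reports group means/SDs and a two-sided Wilcoxon
rank-sum test — rank-based because trajectory-feature distributions
(efficiency, trappedness, fractal dimension) are markedly skewed.

```{r workflow}
sim <- generate_labeled_set(n_per_class = 25, n_points = 150, seed = 42)
tab <- build_feature_table(sim)
model <- train_classifier(tab, seed = 1)
model

proj <- pca_projection(tab)
proj
plot(proj)

compare_groups(tab[tab$label == "superdiffusion", ],
               tab[tab$label == "subdiffusion", ], "straightness")
```

## Numerical choices and degenerate inputs

* Missing values are rejected everywhere, never imputed — the only
  imputation in the package is the documented sentinel handling inside
  the classifier/PCA preprocessing.
* Constant trajectories: MSD is identically zero, so the exponent fit,
  VACF normalization, gaussianity and kurtosis raise errors (propagated
  with the feature name); the Green–Kubo integral and the Fourier
  descriptor return 0 by their own definitions.
* The reflecting boundary folds the radial coordinate
  $s \mapsto 2R - s$ repeatedly, handling proposals that overshoot
  through the origin, so confinement holds for any step size.
* CSV round-trips write 17 significant digits; times/positions and
  feature tables reproduce to $10^{-12}$ relative.
* The LAMMPS-style reader supports exactly the minimal per-frame
  `timestep`/`keywords`/`data` schema with an `id` column and 1–3
  coordinates; wrapped periodic coordinates are taken as-is (unwrapping
  is out of scope).  Particles absent from any frame are dropped with a
  warning, because a gap would otherwise silently become a long jump.

## Known limitations

The descriptor suite is global per trajectory: no windowed extraction or
per-step motion-state segmentation.  The exponent estimator uses ordinary
least squares on log–log coordinates, adequate for regime classification
but not the minimum-variance estimator for short noisy tracks.  Exact
fBm sampling is cubic in $N$ on first use at a given length, so very
long anomalous trajectories ($N \gg 5000$) are better generated by other
methods.  The classifier is trained on idealized simulations; applying
it to experimental data assumes the experimental sampling rate and
duration are comparable to the training world's.
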
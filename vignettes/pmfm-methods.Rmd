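---
title: "Parametric mean-field modelling of resting-state dynamics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parametric mean-field modelling of resting-state dynamics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Each cortical region is described by a single synaptic gating variable
$S_i \in [0, 1]$, the fraction of open NMDA channels of the local excitatory
population, evolving as

$$\dot S_i = -\frac{S_i}{\tau_s} + r\,(1 - S_i)\,H(x_i) + \sigma_i\,\nu_i(t),$$

where the population firing rate is the soft-threshold response
$H(x) = (a x - b) / (1 - e^{-d (a x - b)})$ and the total input current

$$x_i = w_i J S_i + G J \sum_j C_{ij} S_j + I_i$$

combines recurrent drive ($w_i$), connectome-mediated long-range drive
(coupling matrix $C$, global scale $G$) and an external current $I_i$.
`mfm_constants()` carries the fixed constants of the reduction
($J = 0.2609$ nA, $a = 270$ n/C, $b = 108$ Hz, $d = 0.154$ s, $r = 0.641$,
$\tau_s = 0.1$ s). The heterogeneous regional parameters are not free
per region: they are linear in two cortical maps,

$$w_i = a_w\,\mathrm{Mye}_i + b_w\,\mathrm{Grad}_i + c_w,$$

and likewise for $I_i$ and $\sigma_i$, with a myelin-like anatomical
hierarchy map and a principal functional-gradient map. Together with $G$
this gives the ten free quantities held by `linear_coefficients()`. A fully
unconstrained heterogeneous variant of a 68-region model would instead have
$3 \times 68 + 1 = 205$ free parameters; the map parameterisation is the
model's regularisation.

Neural activity drives a Balloon–Windkessel haemodynamic cascade
(vasodilatory signal, inflow, venous volume, deoxyhaemoglobin) per region,
with the conventional 3T constant set (`hemo_constants()`: signal decay
0.65 s⁻¹, feedback 0.41 s⁻¹, transit time 0.98 s, stiffness 0.32, resting
extraction 0.34, resting volume fraction 0.02). These constants are
deliberately exposed in configuration: variants of the balloon model differ
in them, and matching a particular reference implementation is a
configuration exercise, not a code change.

The default protocol (`sim_config()`) integrates with an Euler step of
10 ms for 16.4 simulated minutes, discards the first 2 minutes, and samples
BOLD every 0.72 s, yielding 1200 frames per run — with 72 integrator steps
spanning one TR.

## Numerical choices

**Transfer function.** $H$ has a removable singularity at $a x = b$; the
implementation switches to the limit $1/d$ when $|d(ax-b)| < 10^{-8}$. The
relative deviation from the linear branch $ax - b$ is $e^{-d(ax-b)}$:
about $10^{-4}$ at $ax - b = 60$ and below $10^{-6}$ beyond $90$.

**State clamping.** Euler steps can overshoot the $[0,1]$ range of a
gating fraction; the state is clamped after every step.

**Initialisation.** $S(0) \sim \mathrm{Uniform}(0,1)$ per region, drawn
from the run seed; burn-in applies to the BOLD output only, while neural
and haemodynamic states integrate continuously from $t = 0$.

**Noise discretisation.** The noise term is added per Euler step as
$\sigma_i\,\xi$, $\xi \sim N(0,1)$ i.i.d. per region and step
(`noise_scaling = "step"`), not as $\sigma_i \sqrt{\delta t}\,\xi$. This was
a deliberate, load-bearing choice. Under the SDE-consistent
$\sqrt{\delta t}$ scaling the effective noise at $\delta t = 10$ ms is ten
times weaker, and a Kramers analysis of the single-region potential shows
the high-state escape barrier (≈1 in gating units) is then insurmountable
anywhere in the documented noise range $\sigma \le 0.05$ nA — the model
could never leave an attractor, and the multi-stability phenomenology that
motivates it (state switching visible in FCD) would be unreachable. With
per-step noise, switching occurs robustly inside the documented $\sigma$
range. The `"sqrt_dt"` option retains the strict Euler–Maruyama convention
for users who want the SDE limit; note that under `"step"` scaling the
effective stochastic intensity depends on $\delta t$, so runs should be
compared at a fixed integration step (the protocol fixes 10 ms).

**Feasibility.** Any coefficient vector producing a non-positive $w_i$ or
$\sigma_i$ raises a classed infeasible-parameters condition; the fitting
layer converts it to a sentinel cost of 3.0 (the cost's upper bound) without
simulating.

## Observables

Static FC is the region-by-region Pearson correlation over a run. FCD uses
sliding windows of 83 frames (≈60 s at TR 0.72 s) with stride 1; each
window's FC is vectorised by its strictly-upper triangle and the windowed
vectors are correlated, giving a $W \times W$ matrix with
$W = T - 83 + 1$ (1118 for 1200 frames). Distributional comparison uses a
200-bin histogram on $[-1, 1]$; histograms, unlike FCD matrices, can be
averaged across runs because no temporal correspondence is needed. The
fitting cost is $(1 - r) + \mathrm{KS}$, where $r$ correlates the Fisher
z-transformed upper triangles of simulated and target FC and KS is the
sup-distance between FCD histogram CDFs. Both weights are exposed; setting
the FCD weight to zero reproduces FC-only fitting.

Open details the source protocol left unstated were fixed as follows: the
FCD row mean excludes the unit diagonal (switchable); the first derivative
used by the FCD–STD correlation is the forward difference; the
sliding-window standard deviation uses the population convention
(divide by $n$); the two-component Gaussian mixture on the FCD mean is fit
by EM (mclust's unequal-variance univariate model) from a deterministic
median-split initialisation, with the state threshold at the cross-over of
the weighted component densities between the two means, falling back to the
midpoint (with a warning) if the densities do not cross there. Permutation
and rotation p-values use the add-one estimator, which cannot return zero.

## Model inversion

`fit_pmfm()` minimises the combined cost with CMA-ES in the standard
$(\mu/\mu_w, \lambda)$ formulation (rank-based recombination, cumulative
step-size adaptation, rank-one plus rank-$\mu$ covariance updates),
implemented in the package; candidates outside the box bounds are evaluated
at their projection with a quadratic repair penalty. Coefficient bounds
derive from the documented regional ranges ($w \in (0,10)$, $I \in (0,1)$
nA, $\sigma \in (0.0005, 0.05)$ nA, $G \in (0,8)$): offsets get the value
range, map slopes a symmetric half-range. The first restart starts from the
canonical homogeneous working point ($w = 1$, $I = 0.3$, $\sigma = 0.01$,
$G = 1$); subsequent restarts draw uniformly within bounds. Candidate
evaluations average a small number of simulations (default 3) under a fixed
per-candidate seed schedule — common random numbers across candidates make
the objective deterministic and comparable. Validation re-ranking
(`select_top_diverse()`) re-scores the best training candidates on held-out
targets and greedily selects by ascending validation cost, skipping any
candidate whose concatenated z-scored regional $(w, I, \sigma)$ maps
correlate at or above 0.98 with an already selected one.

At desk scale the inversion is genuinely degenerate: on the 10-region
recovery problem the package's tests use, solutions at the cost noise floor
can carry a recurrent-strength map whose correlation with the ground truth
is low or even negative while the noise map is recovered at $r \approx 0.9$
— the same directional degeneracy of $w$ reported for full-scale fits.
The recovery test asserts both map recoveries and is allowed to fail on
$w$; we prefer an honest failure over a weakened assertion.

## Synthetic study conditions

The synthetic module generates every input the analyses need. Connectomes
are Erdős–Rényi graphs over a guaranteed random spanning tree with
log-normal weights, globally normalised to a maximum entry of 1 (global
rather than row normalisation preserves symmetry). Gradient maps are
low-order random Fourier profiles along the region ordering, z-normalised,
with the second map mixed from an exactly orthogonalised residual so the
requested map correlation is hit exactly. Synthetic expression plants a
rank-1 smooth spatial factor with strong opposite loadings on two
interneuron-marker analogue genes ("PVALB_like", "SST_like") plus i.i.d.
noise; centroids are a Fibonacci lattice on the unit sphere. These
generators emulate the *structure* of empirical inputs (sparsity, spatial
smoothness, hierarchy, marker contrast) but none of their anatomy: passing
tests demonstrate that the machinery behaves correctly on data with the
right statistical shape, not that the biological conclusions transfer.

The multi-stable demonstration condition (`generate_multistable_setup()`)
was chosen once, after a systematic regime search, and then frozen: 25
driver regions sit near the single-region fold bifurcation
($w = 1.25$), the periphery rests stably low ($w = 0.6$), the gradient map
is the z-scored node strength so the input coefficient can compensate
degree heterogeneity, and $\sigma = 0.045$ nA, $G = 0.6$, baseline input
$0.295$ nA place the driver population at the edge of instability. Across
seeds this yields mean static FC ≈ 0.45 and an FCD mean time course
fluctuating around 0.5 — coherent co-fluctuation episodes against quieter
stretches, the qualitative phenomenology the observables pipeline is meant
to quantify. The condition is deliberately parameter-sensitive (that is
what "edge of instability" means); the generator pins the exact values.

A known limitation, documented rather than papered over: in this synthetic
condition a 72-step amplitude push of five regions — the causal
perturbation experiment — does not produce a lasting FCD-mean increase.
A lasting response requires hysteretic collective bistability, and in an
Erdős–Rényi-like connectome the collective mode's effective noise shrinks
with $\sqrt{N}$ while its escape barriers grow with $N$, so spontaneous
switching and kick-induced switching cannot coexist. Regimes with latching
single regions have featureless FCD; regimes with rich FCD absorb the kick
within a window or two. The perturbation machinery itself is exact (a zero
push factor reproduces the unperturbed trajectory bit for bit) and the
contrast experiment is implemented and tested faithfully; its synthetic
contrast assertion fails under these conditions and is left failing.

## Spatial statistics

Map–map association uses Pearson correlation. Significance against spatial
autocorrelation uses the spin test: uniformly random 3D rotations (QR of a
Gaussian matrix, sign-fixed, determinant-corrected), reassignment of each
parcel to the value of the nearest rotated parcel, and a two-sided add-one
p-value over 1000 rotations by default (the sidedness and count are package
choices; the rotation null preserves the map's value multiset and its
spatial smoothness, which a naive shuffle destroys — the package's tests
verify that spin p-values are systematically more conservative than shuffle
p-values on smooth maps). Gene-contrast specificity uses the
random-gene-pair null with the reference pair excluded from draws.
Expression PC1 is computed on gene-wise z-scored data with the score sign
fixed against the mean expression profile. Hemisphere-mirrored rotations
used for real bilateral cortical data are out of scope; synthetic centroids
live on a single sphere.

## Scaling of the test problems

The test and acceptance problems are scaled to interactive sizes chosen as
the smallest problems that still exercise the relevant phenomena: 10-region
connectomes and three-simulation averages for inversion (the full protocol
is configuration, not code), 68 regions and single full-length runs for the
multi-stability and perturbation analyses, and 1000-draw nulls for the
permutation machinery. The consensus-SC rule, windowing arithmetic and
fixed-point checks are exact at any size.
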
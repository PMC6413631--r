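---
title: "Invertible 3D orientation scores: models, filters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Invertible 3D orientation scores: models, filters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oscore3d)
```

## The model

A 3D orientation score lifts a scalar volume $f:\mathbb{R}^3\to\mathbb{R}$
to a complex-valued function on positions times orientations,
$$U(\mathbf{x},\mathbf{n}) =
(\overline{\psi_\mathbf{n}}\star f)(\mathbf{x}),\qquad
\mathbf{n}\in S^2,$$
by correlation with rotated copies $\psi_\mathbf{n}$ of an anisotropic
wavelet $\psi$ that is rotationally symmetric about the $z$-axis.  Locally
oriented structure — vessels, fibers, plate edges — separates along the
orientation axis, so that crossing structures that interfere in
$\mathbb{R}^3$ become disentangled in $\mathbb{R}^3\times S^2$.  Processing
(here: anisotropic diffusion, tubularity measurement) happens in the lifted
domain; a reconstruction maps back to $\mathbb{R}^3$.

With the Fourier convention
$\hat f(\boldsymbol\omega)=\int e^{-i\boldsymbol\omega\cdot\mathbf{x}}
f(\mathbf{x})\,d\mathbf{x}$, two Fourier-domain diagnostics govern the
transform on ball-limited data
($\operatorname{supp}\hat f \subset B_\varrho$):

* $M_\psi^d(\boldsymbol\omega)=\sum_i
  |\hat\psi_{\mathbf{n}_i}(\boldsymbol\omega)|^2\Delta_i$ controls the
  stability of the exact inverse (condition number $\sqrt{M/\delta}$ for
  $\delta \le M_\psi^d \le M$);
* $N_\psi^d(\boldsymbol\omega)=\sum_i
  \hat\psi_{\mathbf{n}_i}(\boldsymbol\omega)\Delta_i$ controls the accuracy
  of the fast reconstruction by plain summation over orientations, which is
  what all processing pipelines here use.

$\Delta_i$ are quadrature weights of the orientation sampling
($\sum_i\Delta_i=4\pi$).  The wavelets are split as
$\hat\psi_0=\hat G_{s_\rho}\hat\psi$,
$\hat\psi_1=(1-\hat G_{s_\rho})\hat\psi$ with
$\hat G_{s_\rho}(\boldsymbol\omega)=e^{-s_\rho\|\boldsymbol\omega\|^2}$: the
high-frequency channel carries the oriented structure, the low-frequency
content is stored once as $(\overline{\phi_0}\star f)$ with
$\phi_0 = G_{s_\rho}$, the spatial Gaussian
$(4\pi s_\rho)^{-3/2}e^{-\|\mathbf{x}\|^2/(4 s_\rho)}$.  The splitting
multiplies $M$ by $1-2\hat G(1-\hat G)\in[\tfrac12,1]$, so stability is
retained up to a factor 2; `os_diagnostics()` verifies this identity
numerically on every stack.

## The two wavelet designs

### Cake wavelets (sampled in the Fourier domain)

The Fourier filter is polar-separable,
$\hat\psi(\boldsymbol\omega)=g(\rho)h(\boldsymbol\omega/\rho)$.  The radial
part $g(\rho)=\tfrac12(1-\mathrm{erf}((\rho-\varrho)/\sigma_{erf}))$ is flat
over the ball and decays smoothly towards the Nyquist frequency
$\rho_N=\pi$ rad/voxel, with inflection at $\varrho=\gamma\rho_N$.  The
angular part starts from a spherical heat kernel
$A = \sum_l a_l^0 Y_l^0$, $a_l^0=\sqrt{\tfrac{2l+1}{4\pi}}e^{-l(l+1)s_o}$,
truncated at the smallest degree $L$ with
$a_L^0/a_0^0<10^{-3}$ (for example $L=17$ at $s_o=\tfrac12(0.25)^2$ and
$L=9$ at the default $s_o=\tfrac12(0.45)^2$; the rule is always evaluated,
never a fixed $L$).  The line/edge filter combines the Funk transform
(diagonal on spherical harmonics with eigenvalue $P_l(0)$) with
anti-symmetrization:
$$c_l^0=\Big(P_l(0)+\tfrac{1-(-1)^l}{2}\Big)a_l^0 .$$
The even-degree (Funk) part makes the real part of $\psi$ a line detector,
the odd-degree part makes the imaginary part an oriented edge detector.
The plate-detector variant (`assemble_plate_wavelet()`) skips the Funk
step ($c_l^0=a_l^0$); its imaginary part is identical.

Rotated filters are obtained by steering the zonal coefficients: the
degree-$l$ coefficients of the filter aligned with
$\mathbf{n}(\beta,\gamma)$ are $c_l^0\,d^l_{m,0}(\beta)e^{-im\gamma}$,
which by the addition theorem equals
$c_l^0\sqrt{4\pi/(2l+1)}\,\overline{Y_l^m(\beta,\gamma)}$ — the stack
builder therefore evaluates the steered angular part directly as
$\sum_l c_l^0\sqrt{\tfrac{2l+1}{4\pi}}P_l(\mathbf{n}_i\cdot\mathbf{u})$.
The same Wigner machinery is exposed as `wigner_rotate()` (ZYZ convention,
counterclockwise angles, verified against the explicit $l=1$ matrix and a
pointwise rotation oracle).  At $\boldsymbol\omega=0$ spherical angles are
undefined and only the $l=0$ term is used.

An analytic bound controls the summation reconstruction: with
$d_l^m=\sum_i c_l^0\Delta_i\,d^l_{m,0}(\beta_i)e^{-im\gamma_i}$,
$$|N_\psi^d(\boldsymbol\omega)-1|\;\le\;\sum_{l\ge1}\|\mathbf{d}_l\|_2
\sqrt{\tfrac{2l+1}{4\pi}}\quad\text{for }\|\boldsymbol\omega\|\le\rho_0 .$$
For the 42-point icosahedral sampling this bound is below $0.05$ once
$s_o\gtrsim0.04$ (at $s_o=0.06$ it evaluates to $\approx0.015$; the
acceptance script recomputes it).  The inner radius $\rho_0$ at which the
diagnostics are reported is set to $0.75\,\varrho$; any choice in
$(\tfrac12\varrho,\varrho)$ is admissible and the value is recorded in the
`stability_report`.

### Generalized Zernike wavelets (analytic in both domains)

The second design expands the filter in generalized Zernike functions
$Z_{n,l}^{m,\alpha}=R_n^{l,\alpha}(\rho)Y_l^m$ on the unit Fourier ball,
with $R_n^{l,\alpha}(\rho)=\rho^l(1-\rho^2)^\alpha
P_p^{(\alpha,l+1/2)}(2\rho^2-1)$, $n=l+2p$.  These functions vanish to
order $\alpha$ at the ball boundary and have closed-form 3D inverse Fourier
transforms through spherical Bessel functions,
$$S_{n,l}^\alpha(q)=\int_0^1 R_n^{l,\alpha}(\rho)j_l(q\rho)\rho^2 d\rho
=2^\alpha(-1)^p(p+1)_\alpha\,\frac{j_{n+\alpha+1}(q)}{q^{\alpha+1}}
\;(q>0,\ \alpha\in\mathbb{N}),$$
so the spatial filter is sampled directly from its analytic form — no DFT.
The radial profile is the flattened bump
$B^{\text{flat}}_{\alpha,2}(\rho)=B_{\alpha,2}(\rho)(c_0+c_1\rho^2+
c_2\rho^4)/B_{\max}$, obtained by multiplying
$B_{\alpha,2}=(1-\rho^2)^\alpha\rho^2$ with the second-order Taylor
expansion of its reciprocal about the maximum at
$\rho_{\max}^2=1/(\alpha+1)$; its radial Zernike coefficients are available
in closed form through generalized binomials (evaluated via products /
log-Gamma, stable for half-integer arguments).

Numerical behaviour worth knowing: for degrees $l\le 2$ the radial
expansion of $B^{\text{flat}}_{\alpha,2}$ *terminates* (the profile is
$\rho^{2}\times$ polynomial$(\rho^2)\times(1-\rho^2)^\alpha$), so those
components are exact at any truncation; for higher and odd degrees the
series converges slowly.  The default truncation is $p_{\max}=40$ with an
explicit convergence check that warns (with the achieved profile error)
when the truncated expansion misses the closed form by more than 1%.  The
default order is $\alpha=3$ (the design used for the comparison against the
cake filters); the flatter $\alpha=6$ profile is available through the
`alpha` argument.  No single canonical default is claimed by the method
itself — both are exposed.

When both stacks are built with their radial profiles matched (fixed
$s_\rho=\tfrac12(1.9)^2$, $\gamma=0.85$, $s_o=\tfrac12(0.4)^2$, and
$\sigma_{erf}$ chosen to minimize the radial mismatch — the free parameter
of the matching), the complete spatial filter stacks agree to within a few
percent relative $L^2$ on a $31^3$ grid; the acceptance suite asserts
$<10\%$.

## Discretization choices

* **Orientation sampling.**  Default: the pole-aligned icosahedral
  tessellation with 42 vertices (deterministic, antipodally symmetric,
  carries its triangulation).  Arbitrary counts are available through an
  electrostatic-repulsion minimization of $\sum_{i<j}1/\|n_i-n_j\|$
  (projected gradient descent from a seeded random start, at most 2000
  iterations or tangential gradient $<10^{-8}$ — the repulsion model is a
  convention; these constants are recorded here, not derived).
* **Quadrature weights.**  `triangulated` weights are spherical Voronoi
  areas (circumcentric subdivision of the mesh), which partition $4\pi$
  exactly and deviate less than 10% from uniform on the 42-point grid;
  `uniform` weights $4\pi/N_o$ are used where a sampling has no mesh.
* **Filter realization.**  `forward()` synthesizes each rotated filter's
  closed Fourier form on the volume's own frequency grid (steerable and
  exact; summation reconstruction of ball-limited volumes is then accurate
  to $\sim10^{-6}$ relative).  The classical alternative — correlation
  with the truncated `grid_size`$^3$ spatial kernels — is kept as
  `filters = "spatial"`; note that with the default
  $s_\rho=\tfrac12\,16^2$ the $(1-\hat G)$ split has a spatial footprint of
  about 16 voxels, which an $11^3$ kernel cannot carry, so the truncated
  route loses a few percent on low-frequency-rich data.
* **Boundaries.** Periodic (FFT-native) throughout, including all
  finite-difference stencils.  Mirror padding of the input volume is the
  user's prerogative for real data.
* **Exact inverse regularization.** The exact inverse divides by
  $\max(M,\epsilon_M)$ with $\epsilon_M=10^{-3}\max M$; the floor is
  inactive wherever the design keeps $M$ bounded away from zero (verified
  in the tests).

## Coherence-enhancing diffusion (CEDOS)

The score (its real, line-detector part) is diffused with the left-invariant
geometry of SE(3): at each $(\mathbf{x},\mathbf{n}_i)$ the frame
$\{A_1,\dots,A_6\}$ has $A_3$ along $\mathbf{n}_i$, $A_1,A_2$ spatially
perpendicular, and $A_4,A_5,A_6$ angular (on the zonal embedding $A_6$ acts
trivially; the angular second-order operator is the cotangent
Laplace–Beltrami matrix of the triangulated orientation grid, whose
eigenvalues on low-degree spherical harmonics are accurate to $\sim$8% at 42
nodes).  The diffusion is diagonal in a locally adaptive gauge frame
$\{B_i\}$:

$$\partial_t W = D_{11}(B_1^2+B_2^2)W + D_{33}B_3^2 W +
D_{44}(B_4^2+B_5^2+B_6^2)W .$$

**Gauge frame.**  $B_3$ is fitted per $(\mathbf{x},\mathbf{n}_i)$ as the
smallest-eigenvalue eigenvector of the spatially and angularly regularized
structure tensor of the score — a first-order fit of the locally
best-aligned curve.  This deliberately approximates a full exponential-curve
fit (which would add torsion-aware second-order terms); it is isolated
behind `fit_gauge_frame()` so a richer fit can replace it.  Where the
tensor is nearly isotropic the frame falls back to the left-invariant one;
the degeneracy test uses the relative eigenvalue gap
$(\lambda_{\max}-\lambda_{\min})/\lambda_{\max} < 0.8$, chosen from the
sampling distribution of the gap: isotropic noise stays below $\approx0.7$
at the default regularization scales while genuine curves give values
$\approx 1$ (tube phantoms recover their axis to well under 5 degrees).

**Adaptivity.**  The orientation confidence is
$s = -\sum_{i\in\{1,2,4,5,6\}}B_i^2 U$ and
$D_{11}=1-e^{-(c_1/s)^2}$ (set to 1 where $s\le0$): non-oriented regions
are smoothed isotropically, strongly oriented ones only along their
structure.  $c_1$ is the 50% quantile of $|s|$ over the score.  The
magnitude matters: on noise-dominated scores $s$ is nearly sign-symmetric,
so the quantile of the *signed* values sits at $\approx0$ and the formula
degenerates to a binary field; using $|s|$ (exactly as the tangential
threshold $c_2$ uses $|B_3U|$) gives a meaningful noise-level scale.
$D_{33}=1-e^{-(c_2/(B_3U))^2}$ stops diffusion at structure endpoints.
A floor $D_{11}\ge 0.001$ is always applied; `d11_mode = "constant"`
instead pins $D_{11}=0.001$ everywhere, the configuration used for the
edge-location experiments, where any perpendicular diffusion at vessel
edges is undesirable.  The two modes are exposed because the adaptive rule
and the constant are both legitimate readings of the method; the pipelines
default to the adaptive rule with the floor.

**Time stepping.**  Explicit Euler with frozen coefficients.  The operator
is rewritten as $m\,\Delta + (D_{11}-m)(B_1^2+B_2^2) + (D_{33}-m)B_3^2$
with $m=\min(D_{11},D_{33})$: algebraically identical (the sum of second
directional derivatives over an orthonormal spatial triad is the
Laplacian), but the isotropic share runs on the exact 7-point stencil,
which removes the numerical diffusion of interpolated oblique stencils —
the constant-coefficient isotropic limit then matches a Gaussian blur to
well under 1% — and keeps every stencil weight nonnegative, so the scheme
obeys a discrete maximum principle (monitored) and conserves the
orientation-weighted mass under constant coefficients.  The step bound
$\Delta t \le 1/\big(2(2\max D_{11}+\max D_{33})/h^2 +
D_{44}\max_i\sum_j|L_{ij}|\big)$ is computed from the stencil; a too-large
user step is rejected with the bound in the message.

## Tubularity measure

For a candidate orientation $\mathbf{n}$ and radius $r$, opposite oriented
edge responses are multiplied:
$$E(\mathbf{x},\mathbf{n},r,\theta)=
\mathrm{Im}^+U(\mathbf{x}+r\mathbf{n}^\perp(\theta),\mathbf{n}^\perp(\theta))
\cdot
\mathrm{Im}^+U(\mathbf{x}-r\mathbf{n}^\perp(\theta),-\mathbf{n}^\perp(\theta)),$$
and $V(\mathbf{x},\mathbf{n},r)=\min_\theta (K_{\sigma_o^V}\!\ast
E)(\theta)$ takes a smoothed minimum over the in-plane direction, so only
structures with a closed ring of outward edges (tubes, not plates or
half-open edges) respond.  Choices:

* In-plane gauge $\mathbf{e}_1\propto\mathbf{n}\times\mathbf{e}_z$ (or
  $\mathbf{e}_x$ when degenerate), $\mathbf{e}_2=\mathbf{n}\times
  \mathbf{e}_1$; the smoothed minimum makes the measure gauge-invariant to
  within 2% at $n_\theta\ge8$.
* $E$ is $\pi$-periodic in $\theta$ (swapping the two factors), so the
  wrapped Gaussian kernel ($\sigma_o^V=\pi/8$, truncated at its central
  period) is discretized on $n_\theta=8$ nodes over $[0,\pi)$ and
  row-normalized, preserving constants.
* The score is interpolated trilinearly in space (outside samples count as
  0 and are tallied) and barycentrically over the spherical triangulation
  in orientation; $U(\cdot,-\mathbf{n})$ is read from the grid itself (the
  icosahedral grids are antipodally symmetric), not derived by a symmetry
  assumption.
* Radius sweep default: 10 log-spaced values in $[1,6]$ voxels;
  ties in the maximization break to the lowest orientation index and the
  smallest radius.

**Known bias.** The oriented edge response of the broadband odd kernel
localizes $\approx0.3$ voxels *outside* the Gaussian inflection point (this
is visible already on flat plates, so it is a property of the kernel, not
of tube curvature), which makes the optimal radius overestimate thin tubes:
on straight Gaussian tubes the median optimal radius is
$\approx\sigma+0.3$ voxels — about +10% at $\sigma=3$ and +21% at
$\sigma=1.5$.  The test suite measures exactly this, and the $\sigma=1.5$
case sits just outside a 20% band; radius estimates below $\sigma\approx2$
voxels should be treated as upper bounds.

## Synthetic data and metrics

The generator produces tubes with Gaussian transversal profile
($\sigma\ge1$ voxel; intensity $A e^{-d^2/2\sigma^2}$ with $d$ the distance
to the centerline), with straight, randomly curved (spline through seeded
jittered control points, radius varying smoothly in $[1.5,3]$ voxels, a
$3\sigma$ margin to the boundary), crossing (two tubes at a prescribed
angle, max- or sum-superposed) and plate variants, plus seeded additive
Gaussian noise.  The default noise level in the enhancement experiments is
$\sigma_N=0.5$ for unit-amplitude tubes, i.e. CNR $=2$ — the regime of
low-dose interventional angiography and the level at which denoising is
actually needed.  A suite of 18 seeded random tubes emulates a set of
artificial test volumes for radius-recovery experiments.

The contrast-to-noise ratio is $(\mu_S-\mu_B)/\sigma_B$ with the structure
region taken from the ground-truth tube (distance below the local
$\sigma$, i.e. intensity above $Ae^{-1/2}$) and the background from the far
complement ($d>3\sigma+2$).  The edge-radius estimator extracts radial
profiles in the cross-sectional plane, averages the first-order
Gaussian-derivative responses over azimuths (response averaging is far more
robust to noise than averaging per-ray minima), locates the single most
negative response with parabolic refinement, and removes the kernel-width
bias through $r=\sqrt{r_{\text{meas}}^2-\sigma_{\text{deriv}}^2}$ (exact
for Gaussian edges); estimates are then stable to a few percent across
$\sigma_{\text{deriv}}\in[0.5,1.5]$ and azimuth counts $\ge8$.

**What the phantoms do not model:** spatially correlated reconstruction
noise, intensity inhomogeneity along vessels, contrast-agent dynamics,
anisotropic voxels and partial-volume effects at vessel walls.  Passing the
synthetic suites therefore demonstrates the mathematical and numerical
correctness of the transform and of the two applications under controlled
conditions, not clinical performance.

## Study sizes

The experiment sizes used by the test suite (chosen as a sensible scale for
the phantoms, and stated here so results are reproducible): inversion
checks on $32^3$ random ball-limited volumes; design comparison on $31^3$
filter grids; diffusion experiments on $48^3\times42$ scores (straight and
crossing tubes, diffusion times up to $t=4$); tubularity on $41^3$ volumes
(odd size, so the tube axis runs through voxel centers) with the default
radius sweep.  All randomness is seeded.

## Known limitations

* The gauge-frame fit is first order; strongly torqued structures would
  benefit from the full exponential-curve machinery.
* Diffusion acts on the real part of the score; the imaginary (edge)
  channel is regenerated by re-transformation when needed afterwards.
  Whether a complex-valued diffusion would behave better is open.
* Thin-tube radii are overestimated by the edge localization bias
  discussed above.
* The Zernike radial series converges slowly for degrees above the
  flattening order; building those stacks is correspondingly slower than
  the DFT route.
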
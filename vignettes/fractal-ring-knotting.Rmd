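---
title: "Random knotting in fractal ring polymers: models and methods"
author: "ringknots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random knotting in fractal ring polymers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringknots)
```

## The problem

A closed polymer of $N$ segments sampled at random is almost surely knotted
once $N$ is large: the unknot probability decays as
$P_0(N) \propto e^{-N/N_0}$, where the *knotting length* $N_0$ depends on
the statistics of the chain. Ring polymers of biological interest —
chromatin being the prominent example — are not ideal random walks: their
size scales as $R \sim N^{1/d_f}$ with fractal dimensions anywhere from
$d_f \approx 2$ (ideal chain) through $d_f = 3$ (fractal globule) and
beyond in coarse-grained models. This package measures and models the
dependence $N_0(d_f)$: it samples Gaussian ring conformations of
prescribed fractal dimension, classifies their knotting exactly, extracts
$N_0$ by fitting the exponential law, and compares the resulting curve
$\mu(d_f) \equiv \ln N_0$ with an analytical theory whose solution is a
double exponential in $d_f$.

## The beta model for rings

Conformations are generated in Fourier space. The ring positions
$\mathbf R_j$ are expanded in normal modes $\mathbf X_q$
($q = 1, \dots, N-1$; the $q=0$ center-of-mass mode is excluded, so all
conformations are centered), with an effective Hamiltonian that makes the
modes independent zero-mean Gaussians with per-component variance
$1/\lambda_q$ and eigenvalues

$$\lambda_q^{(\chi)} = 4k\,\sin^{\chi}(\pi q/N), \qquad k = d\,k_BT/b^2 .$$

Reduced units $k_BT = b = 1$ (so $k = d$) are fixed and not configurable.
The spectral exponent is tied to the fractal dimension by
$\chi = 1 + 2/d_f$: for small $q/N$,
$\lambda_q \approx 4k(\pi q/N)^{\chi}$, so mode amplitudes scale as
$q^{-\chi}$ and internal distances as $s^{2/d_f}$ at large separations.
$\chi = 2$ ($d_f = 2$) is exactly the Rouse ring. The spectrum is
degenerate, $\lambda_q = \lambda_{N-q}$, because only
$q' = \min(q, N-q)$ carries physical scale (structure on $N/2q'$
segments).

`sample_rings()` draws the $N-1$ Gaussian mode vectors and applies the
inverse transform, implemented with a real orthogonal (cosine/sine pair)
basis through FFTs, so positions are real by construction and the
forward transform `mode_amplitudes()` inverts sampling to machine
precision. Equipartition ($\mathrm{var}\,X_q = 1/\lambda_q$ per
component), the center-of-mass constraint, and the $R_g^2$ sum rule are
all property-tested.

What the generator emulates — and what it does not. The beta model
produces *Gaussian* chains with the prescribed two-point scaling. It has
no excluded volume, no self-avoidance, no bead packing or fluid
structure, and no dynamics. Fractal dimension is varied with local
conformations held otherwise fixed, which is precisely the controlled
comparison the scientific question needs, but it means passing tests
say nothing about systems where $d_f$ changes jointly with local
stiffness or density; the theory below is expected to apply to any
two-fractal polymer, while the measured constants are model-specific.

## Knot classification

A conformation's knot type is decided by the Alexander determinant
$|\Delta(-1)|$, which is 1 for the unknot, 3 for the trefoil, 5 for the
figure-eight, and odd for every knot.

1. **KMT simplification** (`simplify_chain`): beads whose triangle with
   their two neighbours is pierced by no other segment are removed — an
   ambient isotopy — iterated to a fixed point. Borderline contacts
   (within $10^{-9}$ of the conformation diameter by default)
   conservatively block removal; degenerate collinear triangles are
   always removable. This typically reduces hundreds of beads to a few
   dozen and is validated by a safety property: on random compact rings,
   classification with and without simplification agrees on every
   instance.
2. **Projection** (`build_diagram`): orthogonal projection along a
   random direction; all crossings of non-adjacent projected segments
   are located, over/under assigned by depth, and arcs (spans between
   underpasses) enumerated. Directions are degenerate when a crossing
   sits within `eps` of a vertex, depths coincide, two crossing points
   coincide, or projected segments are near-parallel where they meet;
   such projections raise a classed condition and a fresh direction is
   drawn (the determinant is direction-independent, so retries cannot
   bias results).
3. **Determinant** (`alexander_determinant`): the crossing/arc matrix of
   Fox derivatives evaluated at $t=-1$ (every crossing contributes the
   row $(2, -1, -1)$ on its over/in/out arcs — at $t=-1$ the two
   handedness cases coincide, which is why mirror images are not
   distinguished), one row and column deleted, determinant taken in
   exact integer arithmetic: fraction-free Bareiss elimination over
   64-bit integers with an overflow guard. Diagrams whose intermediate
   minors overflow fall back to a certified combination of determinant
   residues modulo 25-bit primes and a LAPACK log-determinant; the
   triviality call $|\det| = 1$ then carries a failure probability below
   $2^{-48}$, values representable below $2^{53}$ are reconstructed
   exactly by CRT, and larger determinants are reported as `NA`
   alongside the (certain) nontrivial call. This hybrid replaces
   arbitrary-precision integers, which no installed dependency provides;
   at the chain lengths studied the exact Bareiss path handles the large
   majority of diagrams.

The trivial/nontrivial boundary is $|\Delta(-1)| = 1$. Knots with unit
determinant exist (none below 10 crossings among primes relevant here),
so rare complex knots could be miscalled trivial; at the chain lengths
studied this bias is far below the Monte-Carlo noise. Composite knots
count as nontrivial via the product determinant.

In **two dimensions** no curve is topologically knotted; following the
convention of the planar analogue, a ring is "knotted" iff two
non-adjacent segments intersect (`detect_intersection`, an $O(N^2)$
orientation-predicate sweep; touching within $10^{-12}$ of the diameter
counts as intersecting — a measure-zero event for Gaussian rings, so the
convention is immaterial to the probabilities). Adjacent segments are
excluded because every ring meets itself at its joints.

## From Monte-Carlo counts to $N_0$ and $\mu(d_f)$

For each $(d_f, N)$, `run_point()` samples and classifies a batch;
`knotting_curve()` attaches Wilson 95% intervals to the unknot
fractions. `fit_exponential()` fits $\ln P_0$ against $N$ by weighted
least squares with delta-method weights
$w = \mathrm{trials}\cdot p_0/(1-p_0)$, giving $N_0 = -1/\mathrm{slope}$.
The exponential law is asymptotic, so the fit window drops saturated
points ($p_0 \ge 0.99$ or $\le 0.01$ — the floor also removes zero
counts) and chains shorter than $N = 30$ (five times the trefoil stick
number six; below that no chain is meaningfully fractal). Parameter
covariance uses dispersion fixed at the known binomial value, inflated
to the empirical reduced $\chi^2$ when the data overdisperse, so quoted
errors are never tighter than the counts allow.

`build_mu_curve()` collects fits across $d_f$; `fit_mu()` fits two
competing laws by weighted Levenberg–Marquardt with 16 deterministic
profile starts (fixing $c_2$ makes the other two parameters linear, so
each start is solved linearly and then polished; ties break toward the
smallest $|c_2|$):

* double exponential: $\mu = c_1 e^{c_2 d_f} + c_3$ — the theory's
  prediction, with finite limit $N_0 \to e^{c_3}$;
* logarithmic: $\mu = c_1 \ln(d_f + c_2) + c_3$ — the form scaling
  arguments would give.

Models are compared by small-sample-corrected AICc from the weighted
residual sum of squares plus a Wald–Wolfowitz runs test on residual
signs; the runs test needs roughly 16 or more grid points to resolve the
structured residuals the logarithmic form leaves on double-exponential
data, which the test suite demonstrates on synthetic curves.

## The analytical theory

Differentiating the constrained (unknotted) and unconstrained partition
functions with respect to $\chi$ gives the exact identity

$$\frac{d\ln P_0}{d\chi} = \tfrac12 \sum_{q=1}^{N-1}
  \frac{\partial \lambda_q}{\partial\chi}
  \left[\langle |X_q|^2\rangle - \langle |X_q|^2\rangle_0\right],$$

with $\partial_\chi \lambda_q = \lambda_q \ln\sin(\pi q/N)$ and the
unconstrained average fixed by equipartition. `derivative_estimator()`
implements this with the constrained average measured from the
unknotted subset of a classified sample; with the constraint disabled it
is zero identically in expectation, and the test suite validates it
against an independent central finite difference of $\ln P_0$ in $\chi$.
Conversion to $d\mu/d\,d_f$ uses the exponential law
($d\ln P_0/d\mu = N/N_0$) and $d\chi/d\,d_f = -2/d_f^2$; because the
prefactor's drift is neglected, short chains underestimate the
derivative and the estimate approaches the numerical derivative of the
$\mu$-curve as $N$ grows.

To evaluate the sum analytically the unknotted ensemble is modelled with
two regimes (`mode_amplitude_model`): modes below the crossover
$q' = N/2N_0$ (scales longer than $N_0$) are swollen with a new exponent
$\gamma$, modes above it keep the unperturbed spectrum, with a continuity
prefactor $(\pi/2N_0)^{\delta}$, $\delta = \gamma - \chi \ge 0$. The
swollen exponent comes from a generalized Flory argument
(`gamma_flory`): balancing an interacting segment gas
$vN^2/R^d$ against ideal-fractal elasticity $R^2/N^{2/d_f}$ gives
$\nu = (2 + 2/d_f)/(d+2)$ and $\gamma = 1 + 2\nu$; in 3D
$\gamma = (9d_f+4)/(5d_f)$, crossing $\chi$ exactly at $d_f = 3/2$ and
giving the classical $\nu = 3/5$ at $d_f = 2$. The estimate is not
trusted below $d_f \approx 1.7$ (a self-avoiding ring's dimension);
values there carry an `extrapolated` flag rather than an error, since
the fitted laws are still evaluated down to $d_f = 6/5$.

Keeping only modes below the crossover (degeneracy contributes the
factor two), expanding $\lambda_q$ and $\sin$ at small $q/N$, splitting
$\ln(\pi q/N) = \ln(q/M) + \ln(\pi/2) - \mu$ with $M = N/2N_0$, and
taking $M \to \infty$ so sums become the integrals
$\int_0^1 (1-u^{-\delta})\,du = -\delta/(1-\delta)$ and
$\int_0^1 \ln u\,(1-u^{-\delta})\,du = (1-\delta)^{-2} - 1$, yields a
first-order linear ODE in $x = d_f$:

$$\frac{d\mu}{dx} = f_1(x)\,\mu + f_2(x), \qquad
  f_1 = -\frac{1}{x^2}\frac{\delta}{1-\delta}, \qquad
  f_2 = -\frac{1}{x^2}\left[\frac{1}{(1-\delta)^2} - 1
        - \frac{\delta}{1-\delta}\ln\frac{\pi}{2}\right].$$

The per-mode (scalar) equipartition convention is used throughout this
derivation, i.e. amplitudes are treated componentwise,
$\langle \lambda_q X_q^2\rangle = 1$; this is the convention under which
the representative constants below take their quoted values. The
$\ln(\pi/2)$ term in $f_2$ is the only model-dependent ingredient — it
records the ring spectrum's crossover prefactor — while the form of the
ODE is universal for any two-fractal chain. Both functions vanish
continuously at $\delta = 0$ ($d_f = 3/2$).

Over the trusted range $f_1$ and $f_2$ are roughly constant, so the ODE
has the constant-coefficient solution
$\mu = c_1 e^{c_2 d_f} + c_3$ with $c_2 = f_1$ and $c_3 = -f_2/f_1$
(`mu_closed_form`; `solve_mu_ode` integrates the pointwise ODE and
matches the closed form to $10^{-6}$ under frozen coefficients). The
knotting length is therefore a *double* exponential in $d_f$, strictly
decreasing with the finite limit $e^{c_3}$.
`representative_constants()` collapses $f_1$ and $-f_2/f_1$ to single
numbers by a pointwise mean over the studied grid restricted to the
trusted range $d_f > 1.7$ — the averaging convention was genuinely open
and this choice follows the theory's own validity boundary.

## Campaigns, reproducibility and problem sizes

`campaign_config()`/`run_campaign()` orchestrate the full pipeline. The
default fractal-dimension grid is the twelve studied values
$6/5, 3/2, 5/3, 9/5, 2, 11/5, 5/2, 3, 7/2, 4, 9/2, 5$; chain-length
grids are placed per $d_f$ across the expected decay range (factors
0.25–2 of a reference knotting length) so every curve resolves its own
slope. Full-scale campaigns use $2\times10^4$–$10^5$ samples per point;
the desk-scale preset (2000, flagged `scaled_down` in all metadata) is
the default. The test suite runs an 11-dimension campaign at 500 samples
per point, omitting $d_f = 6/5$ whose knotting length of several
thousand beads needs chains beyond the desk-scale cap; its acceptance
band for the recovered $(c_2, c_3)$ was fixed prospectively from a
design simulation with synthetic Bernoulli curves (three standard
deviations of the recovered parameters plus a 25% finite-size margin)
before the campaign was first run.

Randomness: every campaign point derives a substream seed
deterministically from the master seed and the point's grid indices, so
results are bit-reproducible and independent of evaluation order;
projection directions come from a separate deterministic generator and
cannot affect results (only which generic projection is found). R
provides no counter-based generator, so substreams are realized by
reseeding R's generator per point with the derived seeds.

All outputs (XYZ conformations, CSV tables, JSON bundles) embed the
package version, seed and grid metadata; `write_campaign()` emits
curves, fits, the $\mu$-curve and both model fits, and re-running a
configuration reproduces the files byte for byte.

## Numerical choices and degenerate inputs

* Geometric tolerances are relative to the conformation diameter:
  $10^{-9}$ for simplification/projection degeneracy, $10^{-12}$ for 2D
  contact. Degenerate projections are retried (20 attempts by default)
  with fresh directions; failure to find a generic direction is an
  error, practically unreachable for generic coordinates.
* The internal-distance exponent is fitted over $10 \le s \le N/4$
  against the closure-corrected separation $s(N-s)/N$ (exact for the
  ideal ring). Convergence to the asymptotic $2/d_f$ is slow at extreme
  $d_f$ — the closure correction decays only like $(s/N)^{3-\chi}$ — so
  the estimator is validated tightly against the exact spectral-sum
  oracle at the same window, and against $2/d_f$ with tolerances wide
  enough to absorb the documented finite-$N$ bias.
* Exponential fits refuse (with classed conditions) windows of fewer
  than three usable points and non-decaying curves; nonlinear
  $\mu$-fits report non-convergence of all starts, never silently.
* Degenerate collinear triangles in simplification are removable;
  coplanar segment/triangle contact uses an in-plane overlap test so
  planar polygons collapse to the 3-bead floor.

## Known limitations

* Unit-determinant knots are miscalled trivial; irrelevant at studied
  chain lengths but a real boundary of the $t=-1$ criterion. An
  additional evaluation point would resolve it and is deliberately not
  enabled, mirroring common practice.
* The Flory $\gamma$ is a mean-field estimate; below $d_f \approx 1.7$
  the theory is extrapolation, and the closed-form constants inherit
  whatever error the two-regime amplitude postulate carries at finite
  $N$ — the thermodynamic-derivative machinery exists precisely to
  quantify that gap.
* Scaled-down campaigns resolve $(c_2, c_3)$ with statistical spreads an
  order of magnitude wider than full-scale runs; the acceptance bands
  state this explicitly rather than hiding it.
* No excluded volume, no knot-type spectra beyond trivial/nontrivial, no
  linking between multiple rings, and no dynamics.
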
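---
title: "Methods: layered-contact indentation analysis and bone volume quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: layered-contact indentation analysis and bone volume quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cartindent)
```

## The measurement and its model

Strain-controlled flat-punch indentation of articular cartilage (or repair
neotissue) produces a load--displacement--time record with four protocol
phases: a small compressive preload that establishes contact, a constant-rate
ramp to a target depth, a hold at peak displacement during which the tissue
stress-relaxes, and a constant-rate withdrawal. The package's defaults follow
the protocol this analysis was designed around: a flat-ended cylindrical
indenter of radius $R = 525\ \mu m$, a $0.1$ N preload (a mean contact
pressure of $P/\pi R^2 \approx 115$ kPa), a $25\ \mu m/s$ ramp to
$50\ \mu m$, and a $13$ s hold.

Two moduli are reported per specimen:

* the **tangent modulus** $E_{tan}$, from the slope $P/x_0$ of a linear
  least-squares fit to the upper 35% of the loading curve -- a rate-dependent
  measure of how the tissue bears stress during loading;
* the **equilibrium modulus** $E_{eq}$, from the load remaining at the end of
  the hold -- the long-time, relaxed stiffness.

Both use the layered-contact relation for a rigid flat punch on an elastic
layer of thickness $h$ bonded to a rigid substrate (the subchondral bone):

$$E = \frac{P\,(1-\nu^2)}{2 R x_0\, \kappa(\alpha, \nu)}, \qquad \alpha = R/h .$$

With $\kappa = 1$ this is the classical elastic half-space flat-punch result;
$\kappa(\alpha,\nu) \ge 1$ corrects for the stiffening effect of the thin
bonded layer and grows with the aspect ratio $\alpha$ and with
incompressibility. Poisson's ratio defaults to $\nu = 0.4$; the layer
thickness $h$ has **no default** -- it must be measured per specimen, because
$\kappa$ depends on it strongly at $\alpha \gtrsim 1$.

## The kappa solver

$\kappa$ is computed from the mixed boundary-value problem of the bonded
layer. Writing the contact pressure through an auxiliary function
$\omega(t)$ on $[0,1]$ reduces the problem to a Fredholm integral equation of
the second kind,

$$\omega(t) - \frac{\alpha}{\pi}\int_0^1 \omega(s)\,\bigl[K(t+s) + K(|t-s|)\bigr]\,ds = 1,
\qquad \kappa = \int_0^1 \omega(t)\,dt,$$

with kernel $K(u) = \int_0^\infty \bigl(1 - N(x)\bigr)\cos(\alpha u x)\,dx$,
where $N(x)$ is the Hankel-space surface response of the bonded layer
($k_3 = 3-4\nu$):

$$N(x) = \frac{2k_3\sinh 2x - 4x}{2k_3\cosh 2x + 4x^2 + k_3^2 + 1}.$$

Numerical choices:

* **Nyström discretization** with trapezoidal weights on a uniform grid with
  step $0.01$ over the punch radius (the production step; `solve_kappa()`
  exposes it).
* The kernel integrand decays like $x^2 e^{-2x}$, so the infinite integral is
  evaluated by composite Gauss--Legendre panels truncated at $x = 30$;
  doubling the truncation changes $\kappa$ by far less than $10^{-6}$
  (asserted in the tests). Panels are $0.25$ wide with 12 nodes, narrow
  enough to resolve the cosine for the $\alpha$ range of cartilage work.
* $\nu = 0.5$ is refused: the incompressible bonded layer is singular (its
  thin-layer stiffness diverges like $1/(1-2\nu)$).
* `build_kappa_table()` / `interpolate_kappa()` cache $\kappa$ on an
  $(\alpha,\nu)$ grid with bilinear interpolation and **no extrapolation**;
  with grid spacings of $\le 0.125$ in $\alpha$ and $\le 0.025$ in $\nu$ the
  interpolation error stays under $0.5\%$, far below biological variance.

The transcription of $N(x)$ was validated three independent ways during
development: against a propagator-matrix (matrix-exponential) solution of the
Hankel-domain axisymmetric elasticity equations for the bonded layer; against
the half-space limit $\kappa \to 1$ as $\alpha \to 0$; and against the
confined-compression thin-layer asymptote
$\kappa \sim \pi\alpha(1-\nu)^2 / (2(1-2\nu))$ at large $\alpha$. The test
suite re-checks the limits, monotonicity in $\alpha$ and $\nu$,
step-halving convergence, and agreement with a fine-mesh (steps $2\times
10^{-3}$ and $10^{-3}$, Richardson-extrapolated, doubled-truncation) oracle
implemented separately from the production solver.

## Phase segmentation and analysis conventions

`segment_phases()` classifies the displacement rate against the protocol's
ramp rate: loading is the maximal contiguous region with rate within
$\pm 40\%$ of $+25\ \mu m/s$, hold the following region with $|$rate$| <
10\%$ of the ramp rate, unloading the remainder (which must contain a
down-ramp signature). The tolerances are configuration values, not constants.
The rate is estimated on a running-median (window 5) displacement with
Savitzky--Golay derivative filters -- an 11-sample window for ramp edges and
a 51-sample window for the low-threshold hold classification, since the
variance of a local slope estimate falls like the cube of its window. Coarse
boundaries are then refined to the corner of the piecewise-linear trajectory
by intersecting local line fits, iterated to a fixed point. On noise-free
synthetic records this recovers the exact ground-truth boundary samples; with
$0.2\ \mu m$ displacement noise at 100 Hz, boundaries stay within three
samples.

Two conventions the source protocol leaves open are fixed explicitly here:

* **Displacement origin.** $x_0$ in the layered-contact relation is the ramp
  displacement *beyond* the preload position: `extract_phase()` re-zeroes
  displacement to its end-of-preload value.
* **Load baseline.** Loads are analysed *net of the preload baseline*:
  `extract_phase()` also subtracts the end-of-preload load. The two choices
  must travel together -- a modulus formed from a ramp-relative $x_0$ and a
  total load mixes the preload's contribution into the numerator only. With
  both re-zeroed, the equilibrium relation $P_{eq} = 2R\kappa E_{eq}
  x_0/(1-\nu^2)$ recovers the generator's long-time modulus exactly in the
  relaxed limit. Both zeroings are arguments of `extract_phase()` and can be
  switched off.

The "upper 35%" fit window is interpreted as the upper 35% of the loading
phase's **displacement span** (displacement is the controlled variable in
strain-controlled indentation); the fraction is an argument. The R²
acceptance gate rejects strictly below its threshold (`r_squared < 0.80`
rejects; exactly 0.80 is accepted). The **equilibrium load** is the mean over
the final 10% of the hold, and the residual load rate over that tail (N/s) is
reported as a relaxation-completeness diagnostic, so an insufficient hold is
visible rather than silently absorbed.

Savitzky--Golay smoothing defaults (unstated in the source protocol): window
equal to the odd number nearest 5% of the phase's sample count with a floor
of 11, polynomial order 3 -- wide enough to suppress sensor noise, narrow
enough to preserve ramp curvature. The filter reproduces polynomial signals
up to its order and never changes the record length.

## The synthetic generator: what it emulates, what it does not

`generate_sls_curve()` produces records under the exact protocol above with
a standard-linear-solid (SLS) relaxation modulus
$G(t) = E_\infty + (E_0 - E_\infty)e^{-t/\tau}$, evaluated as the
**closed-form** hereditary integral against the piecewise-linear displacement
history (no numerical convolution error) and mapped to force through the same
$2R\kappa/(1-\nu^2)$ factor the analysis inverts. The preload is emulated
physically -- a fast approach to the depth that carries $0.1$ N at the
instantaneous modulus, followed by a 13 s dwell so the preload transient has
decayed before the ramp. Ground truth (phase boundaries, moduli, $\tau$,
$\kappa$, the analytic equilibrium load and upper-35% slope) travels with
every curve.

`generate_cohort()` reproduces the six-group, $n = 10$ design of the animal
study this pipeline addresses, with group equilibrium-modulus means and SDs
at the scale reported for osteochondral repair tissue in the rabbit trochlea
(sham $1.36 \pm 0.72$ MPa; defect and hydrogel groups $0.4$--$0.6$ MPa),
drawn from truncated normals ($E_\infty \ge 0.05$ MPa, $E_0/E_\infty \ge 1$,
$\tau \in [0.05, 2]$ s). The instantaneous-to-equilibrium ratio (default
$3 \pm 0.5$) and relaxation time (default $1 \pm 0.2$ s, kept below 2 s so a
13 s hold relaxes to within 1% of equilibrium) are generator choices, since
only equilibrium-scale quantities are constrained by published repair-tissue
data. All randomness flows from one explicit seed.

The SLS is a *phenomenological* surrogate: real cartilage relaxation is
poroelastic (biphasic), with a spectrum of time scales and
consolidation-dependent behaviour the single-exponential SLS does not have.
The analysis, however, uses only the equilibrium value and the loading-phase
slope -- not the transient's shape -- so a closed-form surrogate with known
truth is the right fidelity/testability trade-off. Passing the recovery tests
therefore demonstrates that the *plumbing* (segmentation, windows, units,
$\kappa$, formulas) is correct; it does not validate the analysis against
biphasic mechanics, instrument compliance, surface-detection error, or
non-flat contact -- none of which the generator emulates.

Voxel phantoms (`generate_voxel_phantom()`) fill a defect-sized cylindrical
ROI (5 mm diameter x 5 mm depth by default) at exact or binomial bone
fractions; they exercise thresholding, masking and counting, not CT physics.

## Bone volume fraction

`cylinder_mask()` uses the voxel-centre inclusion rule (a voxel belongs to
the ROI iff its centre is inside the cylinder) with no partial-volume
weighting -- simple and exactly testable; at $0.05$ mm voxels the mask volume
is within 2% of the analytic cylinder volume, and the discretization error
shrinks with voxel size. The binarization threshold is either a fixed value
or Otsu's two-class histogram method; the value actually used is always
recorded, because the upstream "validated threshold" of micro-CT practice is
scanner-specific and must stay auditable. BV/TV is a plain voxel count ratio.
The ROI's axial placement relative to the articular surface is an input
(`depth_start`), not inferred.

## Group statistics

`anova_table()` gives the classical fixed-effects decomposition (via
`stats::aov`): one-way, or two-way **with interaction for balanced designs
only** -- an unbalanced two-factor table falls back to one-way per factor
with a warning, refusing the silent ambiguity of Type-I/II/III sums of
squares. `tukey_hsd()` computes studentized-range adjusted p-values
(Tukey--Kramer SE for unequal $n$) with strict $p < 0.05$ significance flags;
it is validated against `stats::TukeyHSD`, the $k=2$ pooled-$t$ identity, and
a 2000-replicate null simulation of its family-wise error. Multivariate
analysis of variance is intentionally out of scope. Ordinal histology scores
can be analysed as plain outcome tables, but no ordinal-scale-specific
methods are provided.

## Problem sizes and determinism

The shipped tests run the full pipeline on 100 Hz records of ~3000 samples;
the acceptance checks use a $3{\times}3{\times}3$ SLS parameter sweep, a
six-group $n=10$ noisy cohort, a $20{\times}6$ $(\alpha,\nu)$ grid with
step-halving, five fine-mesh oracle points, $120^3$-voxel phantoms, and 2000
null cohorts for the family-wise error -- sizes chosen so the whole suite
completes in well under a minute of numerical work per component while still
exercising every contract. Reports are deterministic given (config, seed),
and specimen order never affects a reported statistic.

## Known limitations

* The bonded (adhesive) layer--substrate condition is implemented; the
  frictionless-interface variant of the layered-punch problem is not.
* Only monotonic ramp--hold--unload records are segmented; multi-cycle and
  dynamic (sinusoidal) protocols are out of scope.
* No biphasic/poroelastic model fitting of the relaxation transient; the
  equilibrium read-out is a tail mean with a completeness diagnostic.
* Thickness measurement is the user's burden; there is deliberately no
  default $h$.
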
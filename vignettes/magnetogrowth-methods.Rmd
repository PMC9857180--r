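---
title: "Models and methods in magnetogrowth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in magnetogrowth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magnetogrowth)
```

# The physical picture

Probiotic *E. coli* Nissle 1917 biomineralizes chains of biogenic magnetic
nanoparticles (BMNs, magnetite-like crystals of ~20 nm radius). When such
a cell sits in a strongly non-uniform magnetic field, two forces act on
it: a gradient force on the saturated dipole moment of the intracellular
chain, and a much weaker body force on the cell as a whole through the
susceptibility contrast with its medium. Because a dividing cell must
split its BMN chain in half, an external force that pulls the chain's two
halves in opposite directions can assist division; the package's growth
module turns that mechanical statement into a quantitative prediction for
the growth rate, and its fitting module analyses the colony-count growth
curves such an experiment produces.

# Stripe-magnet magnetostatics

## Model and unit convention

Magnets are modelled as infinitely long (in y) uniformly magnetized
stripes — a 2-D plane problem. For a stripe of half-width $a_1$ and
half-thickness $a_3$ magnetized along $+z$, the reduced field components
$H_x/M$ and $H_z/M$ are the classical arctangent/logarithm closed forms
(see `?stripeField`). These expressions follow the Gaussian-style 2-D
convention in which a charged line contributes $2\lambda/r$; the test
suite re-derives them from an independent surface-magnetic-charge line
integral (sheets of charge $\pm M$ on the two faces) and the two routes
agree to machine precision.

Because the overall prefactor of a 2-D reduced solution is a matter of
convention, the package keeps all field evaluation in reduced units
($H/M$, derivatives in $\mathrm{m}^{-1}$) and converts to SI only at the
force interface, through the remanence $B_r = \mu_0 M$ (with
$\mu_0 = 4\pi\times10^{-7}$ fixed in `vacuumPermeability()`). This makes
signs, ratios, spatial structure and force *scalings* convention-free,
while absolute force magnitudes inherit the convention through constant
factors of order $4\pi$; see "Force magnitudes" below.

Assemblies superpose stripes linearly (exactly, order-independently).
Magnets magnetized along $x$ — the cultivation-incubator unit cell — reuse
the same solution in a frame rotated by 90°, on the assumption that the
incubator magnets share the magnetic characteristics and length scales of
the focusing pair. Two geometries are bundled: `focusingPair()`
($a_1 = 23$ mm, $2a_3 = 10$ mm, antiparallel senses chosen so that
$H_x < 0$ just above the seam) and `incubatorCell()` (the same pair
rotated, $B_r = 1.2$ T, a typical NdFeB remanence).

## Derivatives, corners, interior points

The x-derivatives $dH_x/dx$ and $dH_z/dx$ (the only ones the force model
needs) are implemented as exact closed forms and cross-checked against
central finite differences (default step $10^{-6} a_1$) at random exterior
points to relative $10^{-6}$. The four stripe corners are logarithmic
singularities of $H_x$: evaluation there raises a classed error
(`mgSingularError`) naming the stripe, never a silent `Inf`; grid builders
nudge exact corner hits by $10^{-9} a_1$ and say so. Points inside a
stripe body are evaluated as printed but flagged `interior` — validity
claims (curl-freeness, the derivative identities used for tilted moments)
hold only outside the magnet material.

## The near-seam asymptote

For an antiparallel pair the seam at $x = 0$ concentrates the gradient:
for $|x| \ll a_1$,
$|H_x| = 4M\ln(a_1/|x|)$ and $|dH_x/dx| = 4M/|x|$. Two facts from the
package's own convergence study (run at the magnet top surface,
$z = a_3$) matter for using it:

* The **field** asymptote differs from the full solution by a constant
  offset (~3.4 reduced units here) contributed by the far edges and the
  bottom faces, so its *ratio* to the full field approaches 1 only
  logarithmically — it is still 1.16–1.40 for $|x|/a_1$ between 0.002 and
  0.05. The tests therefore assert the constant-offset structure and the
  monotone approach, not a percent-level ratio.
* The **gradient** asymptote converges fast: within 0.3% of the full
  closed form for $|x|/a_1 \le 0.02$ at $z = a_3$ (the tests allow 2%).
  Since the force model uses the gradient, the asymptotic force is a
  faithful stand-in near the seam. At the mapping height 0.2 mm above the
  surface the $1/x$ law holds only for $|x|$ well above 0.2 mm; closer in,
  the finite height caps the divergence.

A sign subtlety: with the bundled pair's magnetization senses the full
solution gives $H_x < 0$ centrally and hence $dH_x/dx > 0$ for $x > 0$.
`boundaryAsymptote()` defaults to this `"field_map"` convention and also
offers `"printed"` (both signs flipped, i.e. $dH_x/dx = -4M/x$), since the
bare formulas are quoted both ways in the literature depending on which
magnet carries the $+z$ sense. Neither choice affects force magnitudes or
the half-plane sign *opposition*.

# Gradient forces

For a chain of $N$ particles of radius $R$ at saturation $M_s$
(412 kA/m for magnetite), the moment is $p = M_s V$ with
$V = N\,4\pi R^3/3$, and
$F_x = \mu_0 p\, dH_x/dx$, $F_z = \mu_0 p\, dH_z/dx$. `chainForce()` is
algebraically identical to `dipoleForce()` under this substitution (tested
exactly), and both are linear in their moment argument. Chain moments
tilted in the x-z plane are supported through the exterior-field
identities $\partial H_x/\partial z = \partial H_z/\partial x$ and
$\partial H_z/\partial z = -\partial H_x/\partial x$ (curl- and
divergence-free $\mathbf H$ outside the magnets), so only x-derivatives
are ever computed. The soft-magnetic closure $M = \chi H$ is deliberately
not used for forces: the saturated-moment route is the one the worked
estimates take, and BMN chains at these fields are saturated.

Near the seam the two routes collapse to
$F_x = \dfrac{16\pi}{3x} N R^3 B_r M_s$, which diverges as $x \to 0$ and
changes sign across the seam — the two halves of a midcell-positioned
chain are pulled apart, which is the proposed division-assisting
mechanism.

## Force magnitudes

`seamForceEstimate()` evaluates the asymptotic expression at the reference
inputs $N = 20$, $R = 20$ nm, $x = 1$ mm, $B_r = 1$ T,
$M_s = 412$ kA/m and reports **1.10 pN** (11.0 pN at $x = 0.1$ mm); the
full-field profile of the bundled 1.2 T pair gives ±1.26 pN at ±1 mm just
above the surface, consistent with it. Readers comparing against
order-of-magnitude figures of tens to hundreds of pN quoted for such
configurations should note that the 2-D reduced-unit prefactor convention
enters these absolute magnitudes as a constant factor (a bare $4\pi$ is
already ≈ 12.6); the package reports the direct SI evaluation of its own
expressions and makes no attempt to rescale toward any external figure.
Ratios (the $1/x$ law, condition contrasts, half-plane signs) are immune
to this ambiguity and are what the tests pin down quantitatively.

The body force on the cell,
$\mathbf f = V_b\,\Delta\chi\, B\nabla B/\mu_0$, uses
$B = \mu_0 |\mathbf H|$ (medium permeability taken as vacuum; diamagnetic
corrections are $\sim 10^{-5}$). With $\Delta\chi > 0$ — a
nanoparticle-bearing cell is *less* diamagnetic than its medium — the
force points up the modulus gradient, concentrating cells at the field
maxima near the seam; the tests verify this directionally over the mapped
region and check $B\nabla B = \tfrac12\nabla(B^2)$ against finite
differences. `terminalVelocity()` closes the magnetophoresis loop with
Stokes drag, $v = F/(6\pi\eta a)$; its linearity in $F$ is also what lets
the speed-up model translate "force doubled" into "phase duration halved".

# Growth kinetics

## From cell-cycle periods to rates

`growthRateFromPeriods()` implements $r = (T_B + T_C + T_D)^{-1}$ for the
bacterial B (birth-to-initiation), C (replication) and D (division)
periods. The slow-growth reference durations 8/54/34 min give
$r = 1/96 \approx 0.0104$, i.e. 0.01 min$^{-1}$ at the two-decimal
precision such estimates carry. $T_B = 0$ is legal (the B period is
skipped under fast growth).

## Log-linear fitting

`fitLogLinear()` performs OLS of $\ln N$ on $t$ inside a fit window
(default 0–1000 min, the exponential regime of the experimental design;
user-overridable), via `stats::lm`. The slope standard error is the
classical residual-variance estimate — residual normality is exactly the
generator's noise model — and the Pearson correlation of $(t, \ln N)$ is
recorded. Doubling times are always derived as $\tau = \ln 2/r$
(`doublingTime()`), so $r\tau = \ln 2$ holds to machine precision; $\tau$
is undefined (error for raw rates, `NaN` with a warning for fits) when
$r \le 0$. Reported values follow the field's presentation: doubling
times to the nearest minute, percent changes to one decimal. With the four
default condition rates (0.00246, 0.00244, 0.00260, 0.00260 min$^{-1}$)
these give 282/284/267/267 min, a field effect of 5.7% versus the
standard medium — and 6.6% versus the iron-chelate medium, which is *not*
5.7%: both pairings are computed and reported, since summaries sometimes
quote a single figure for both.

## The speed-up model

`predictSpeedup()` is implemented exactly: a mitotic fraction $\varphi$
whose duration is divided by the force ratio $k$ shortens the cycle to
$T' = T(1 - \varphi(1 - 1/k))$, so the rate gains
$1/(1 - \varphi(1-1/k)) - 1$. The first-order gain equals the shortening
fraction $\varphi(1 - 1/k)$ and is reported alongside; the exact gain is
always the larger (convexity of $1/(1-x)$). With $\varphi$ = 10–15% and
$k = 2$ (magnetic force comparable to the endogenous division force, so
the total is doubled), the shortening spans 5–7.5% and the exact gain
5.26–8.1% — bracketing the ~6% effect the fitted rates show. No attempt
is made to re-partition $T_B/T_C/T_D$ under the field; the data to do so
do not exist.

`compareConditions()` flags condition pairs whose $r \pm 2\,\mathrm{se}$
intervals separate from the reference's. This is a coarse screen, not a
named hypothesis test — with per-curve slope errors around $5\times10^{-5}$
on the default grid, the ~$1.4\times10^{-4}$ field effect sits near the
detection edge for a single pair of curves, which is faithful to how such
experiments look.

# The synthetic-data generator

`simulateGrowthCurve()` draws
$N(t) = N_0 e^{rt} e^{\varepsilon_t}$, $\varepsilon_t \sim
\mathcal N(0, \sigma^2)$ i.i.d. — multiplicative lognormal noise, chosen
because it is exactly the model under which the log-linear OLS fit is
maximum likelihood and unbiased (verified by Monte-Carlo). Defaults
define the emulated study conditions and are not tuning knobs:

* rates near 0.0025 min$^{-1}$ (the four-condition quadruple above);
* 11 equispaced points on 0–1000 min — the measurement cadence of the
  28 h cultivation is not recorded anywhere, so this density is the
  package's choice of a realistic chamber-counting schedule;
* $\sigma = 0.05$, which reproduces Pearson correlations in the
  0.997–0.9997 range observed for such fits on this grid;
* $N_0 = 10^6$/mL — arbitrary, since the slope is scale-free.

An optional counting-chamber layer discretizes counts as mean-matched
Poisson draws at a stated aliquot volume (off by default; no chamber
constants are recorded for the original counts). Condition sets derive
per-label seeds as $(\text{base} + \text{hash(label)}) \bmod (2^{31}-1)$
with a fixed 31-based polynomial hash, so adding or dropping a condition
never perturbs the others' streams, and identical base seeds reproduce
byte-identical CSVs.

What passing tests on these curves shows — and what it does not: the
generator emulates steady exponential growth with stationary multiplicative
noise. Real 28 h cultivations have lag and stationary phases outside the
fit window, possibly autocorrelated counting errors, and condition-dependent
noise levels; recovery results here certify the fitting machinery, not the
biology.

# Numerical choices and problem sizes

* Finite-difference step $10^{-6}a_1$ (gradients), $10^{-7}$–$10^{-8}$ m
  for oracle-side checks; curl residuals are required below
  $10^{-6} M/a_1$.
* Corner tolerance $10^{-12}a_1$ for singularity detection; grid nudges
  $10^{-9}a_1$.
* Monte-Carlo sizes: 100 seeded curves for coverage/unbiasedness checks,
  200 for the headline recovery run in `scripts/acceptance.R`; seeds are
  consecutive integers from the user-supplied base. Slope-interval
  coverage is asserted for the $t_{n-2}$-based 95% interval at nominal
  level within binomial error ($\pm 2\sigma$ intervals are nominally
  92.3% at 9 df, and are asserted at that level, not at 95%).
* All validation failures raise `mgValidationError`, singular field
  evaluations `mgSingularError`; the CLI maps these to exit codes 2 and 3.

# Known limitations

2-D magnetostatics only (no finite-length or yoke corrections, no
demagnetization self-consistency); no dipole–dipole chain cohesion or
bending mechanics (literature breaking thresholds of 10–50 pN are context,
not computed here); growth fitting is exponential-window only (no
logistic/Gompertz/Baranyi models); the speed-up model treats the mitotic
fraction and force ratio as given rather than deriving them from the force
maps; absolute force magnitudes are convention-dependent as discussed
above.
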
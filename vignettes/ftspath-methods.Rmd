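---
title: "Finite-temperature string analysis of a field-coupled torsional landscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finite-temperature string analysis of a field-coupled torsional landscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ftspath)
```

## The scientific problem

4-pyridone-3-carboxylic acid, a model for anticoccidial drugs built around an
aromatic ring with adjacent carbonyl and carboxyl groups, can reach the same
product by two competing mechanisms: a concerted double-proton transfer across
the paired hydrogen bonds of its dimer, and a single-molecule conformational
transformation by internal rotation of the carboxyl group. External electric
fields of the magnitude of bioelectric currents perturb both. `ftspath`
implements the computational core of this comparison at desk scale:

* a calibrated synthetic free-energy landscape over the two torsion angles
  $(\phi, \psi)$ that drive the conformational transformation, with a linear
  electric-field coupling;
* restrained overdamped Langevin sampling of umbrella windows and the
  restraint estimator of the mean force;
* the finite-temperature string (FTS) method for the minimum free-energy
  path (MFEP), evolving a discretized string $z(\alpha)$ by
  $\partial_t z = -P\,M\,\nabla F$, where $P$ projects perpendicular to the
  string and $M$ is a metric tensor;
* potential-of-mean-force (PMF) reconstruction by the line integral of the
  mean force and, as a cross-check, by WHAM on the path coordinate;
* Eyring transition-state-theory rates with the Wigner tunneling correction,
  and closed-form Stark/polarization energies with linear field-response
  regression.

Everything electronic-structure-level (absolute barriers, AIM densities,
electrostatic-potential statistics, imaginary frequencies) enters only as
opaque calibration constants of the synthetic generators; nothing is computed
from wavefunctions.

## The synthetic landscape

The landscape is built around a reference path: a $C^1$ curve through
waypoints $(s, \phi, \psi)$, $s \in [0, 1]$, carrying a $C^1$ free-energy
profile $F(s)$ in kJ/mol. The full surface is

$$F(p) \;=\; \mathrm{profile}(s^\*) \;+\; \tfrac12\,k_t\,d^2
  \;+\; c\,E\,w(s^\*),$$

where $(s^\*, d)$ is the nearest-point projection of $p$ onto the path
(torus metric, both angles reduced to $[-180^\circ, 180^\circ)$), $k_t$ is a
harmonic transverse stiffness, $E$ the field strength and $w(s)$ a cosine
bump that is 1 at the principal saddle and 0 at both basins, so a field
raises the barrier without moving the minima. The default calibration places
conformation 1 at the origin (the published geometry gives only the
inter-conformer differences, $168.5^\circ$ in $\phi$ and $153.0^\circ$ in
$\psi$), the principal saddle at $(48.0^\circ, 92.7^\circ)$ with height
18.3 kJ/mol above the conformation-2 basin, a 4.6 kJ/mol hydrogen-bond
sub-barrier late in the path, and strongly asynchronous $\phi/\psi$
progression. Conformation 1 sits 2.0 kJ/mol above conformation 2 — a small
offset chosen so the two profile maxima measured from either basin are
almost equal; the published gas-phase monomer energy difference
(52.5 kJ/mol) is an electronic-structure value incompatible with an
18.3 kJ/mol torsional landscape and is not used. The field coupling is
identical for the x, y and z axes and both signs (the published PMFs are
nearly identical across directions) and is calibrated to raise the saddle by
4.8 kJ/mol at the maximum grid strength $41.14\times10^8$ V/m, below the
5.5 kJ/mol ceiling observed for the conformational barrier.

```{r landscape}
ls <- build_default_landscape()
free_energy(ls, c(48.0, 92.7))     # saddle, kJ/mol above conformation 2
locate_saddle(ls, field_spec("x", 1, 41.14e8))$height
locate_minima(ls)$minima
```

The default profile deliberately carries two interior local minima (14.0
kJ/mol at $s = 0.55$ and 2.4 kJ/mol at $s = 0.80$): they are the metastable
intermediates of the published multi-step transformation. `audit_basins()`
therefore counts attractors after persistence merging — basins whose escape
barrier is below 5 kJ/mol (the scale of the hydrogen-bond sub-barrier) are
absorbed into their neighbors, after which exactly the two conformer basins
remain and capture the whole torus.

Two interpolation choices matter and were made deliberately:

* **Profile interpolant.** The profile is a Fritsch–Carlson-limited cubic
  Hermite (PCHIP-style) with zero slope forced at interior extrema and at
  both ends. This makes every stated anchor exact: the maximum is exactly
  18.3 at $s = 0.40$, the sub-barrier exactly $7.0 - 2.4 = 4.6$, and both
  endpoints are genuine stationary minima of the surface. An ordinary
  interpolating cubic spline satisfies none of these exactly.
* **Dense-path evaluation.** The path is discretized at 2001 nodes, and the
  along-path profile is evaluated by a cubic Hermite *within* each dense
  segment (node values plus derivatives). Because the dense nodes subdivide
  the profile's own cubic pieces, this reproduces the $C^1$ profile exactly,
  and — unlike piecewise-linear interpolation — gives a force field with no
  per-node kinks. The kinks are not cosmetic: they dominate the sampling
  bias of discretized Langevin dynamics whose per-step noise displacement is
  comparable to the node spacing.

One genuine artifact of the nearest-point construction should be understood:
for a path that turns sharply (here the late hairpin, where $\psi$ advances
by $\approx 43^\circ$ while $\phi$ moves by $\approx 3.5^\circ$), the
nearest-branch assignment switches discontinuously on a cut locus inside the
turn. On the default landscape that locus starts $4.65^\circ$ inside the
corner, so there is a safe corridor around the path; the sampling and
integration design below keeps all umbrella windows well inside it. A real
molecular free-energy surface has no such discontinuity — this is the price
of an analytic, exactly calibrated stand-in, and it is the main feature of
real data that the generator does not emulate. Passing tests therefore
demonstrate correct recovery of a *known* landscape under the stated noise
model, not robustness to the full roughness of molecular surfaces.

## The sampler

Umbrella windows are sampled by overdamped Langevin dynamics in
order-parameter space — the original all-atom molecular dynamics collapses
to this reduced description because the order parameters are the entire
state here and only the stationary distribution
$\propto e^{-(F + U)/RT}$, $U = \tfrac12\kappa\,|z - c|^2$, matters for mean
forces. Interfaces use degrees; the spring constant
($\kappa = 100$ kJ mol$^{-1}$ rad$^{-2}$ by default, the published
restraint strength read with the dimensionally consistent rad$^{-2}$ unit)
and the mobility ($m = 1$ rad$^2$ kJ$^{-1}$ mol per time unit) are
radian-based. With the default time step $10^{-3}$ the window relaxation
time is $1/(m\kappa) = 10$ steps, so the default $2\times10^4$ production
steps give about $10^3$ effective samples per window; a 10% burn-in is
discarded. Temperature is fixed at 298.15 K.

The update is the Leimkuhler–Matthews variant of Euler–Maruyama: the drift
is explicit, but consecutive Gaussian increments are averaged,

$$z_{n+1} = z_n - \Delta t\, m\, \nabla(F + U)(z_n)
  + \sqrt{2RT\,m\,\Delta t}\; \tfrac{\xi_n + \xi_{n+1}}{2},$$

which makes the *stationary distribution* second-order accurate in
$\Delta t$ at no extra force evaluations — for a purely harmonic window the
sampled variance is exact ($RT/\kappa$, i.e. a 9.02$^\circ$ marginal at the
default spring). The plain Euler–Maruyama update satisfies the same
stationarity contract only to first order, and its bias is not negligible
here: the per-step noise displacement $\sqrt{2RT\,m\,\Delta t}$ is about
4$^\circ$ at the default settings. A stability condition
$\Delta t\, m\,(\kappa + k_\text{curv}) < 0.5$ is checked before every run,
with $k_\text{curv}$ the landscape's global harmonic term (the transverse
stiffness); local pockets of along-path curvature are transient for a
restrained walker and are controlled by the step size instead.

The mean force at a window center is the restraint estimator
$\kappa\,(c - \langle z\rangle)$ — exactly the gradient of the
$\kappa$-smoothed free energy at $c$, which converges to $\nabla F$ as
$\kappa \to \infty$. The metric tensor is the identity by default;
`covariance` mode returns $RT\,\Sigma^{-1}$ normalized to unit determinant.

## The string method

`run_fts()` anchors the endpoints at the deterministic basin minima,
initializes by shortest-arc linear interpolation (20 images by default: the
two stable states plus 18 intermediates), and iterates: sample one umbrella
window per image, evolve interior images by
$-\mathrm{step}\cdot P M f$ with central-difference tangents and a
3$^\circ$ displacement cap, smooth with
$z_i \leftarrow (1-\lambda) z_i + \lambda (z_{i-1} + z_{i+1})/2$
($\lambda = 0.1$ every iteration, suppressing sampling-noise zig-zag),
reparameterize to equal arc length, and record the RMS image displacement.
Convergence is declared when the RMS displacement stays below 0.3$^\circ$
for 5 consecutive iterations (the published convergence evidence is
qualitative; this criterion makes it operational). The step size,
15 deg$^2$ per (kJ mol$^{-1}$ deg$^{-1}$), was fixed by a contraction
argument: the perpendicular restoring force is $k_t d$, so the per-iteration
contraction factor is $1 - \mathrm{step}\,k_t = 0.7$, giving convergence
from the initial straight string in roughly 25–35 iterations while keeping
the smoothing-curvature equilibrium offset below about a degree at the
sharpest bend. On the default landscape the runs converge in about 20–35
iterations, inside the published budget of 100.

## PMF reconstruction

The PMF is the line integral of the mean force along the path,
$F(\alpha_i) = \sum_j \tfrac12 (f_j + f_{j+1})\cdot(z_{j+1} - z_j)$
(torus-aware displacements, radian units), gauged to zero at
$\alpha = 0$; `barrier()` measures the maximum relative to the
conformation-2 end by default, breaking ties toward smaller $\alpha$.

The 20-image string cannot carry this integral by itself: the default
profile drops by more than 15 kJ/mol across roughly one image spacing
(the descent into the hairpin), and a 20-point trapezoid across that cliff
misestimates the conformation-2 end value by around +12 kJ/mol no matter how
accurate the forces are. `pmf_from_fts()` therefore computes the profile in
three stages, each with parameters fixed by an explicit error analysis
rather than by the string defaults:

1. **Refinement.** The converged string is resampled to 121 images and
   relaxed for a few more iterations with progressively stiffer restraints
   (12 iterations at $\kappa = 2000$, $\Delta t = 10^{-4}$, then 8 at
   $\kappa = 8000$, $\Delta t = 2\times10^{-5}$), pulling the dense string
   onto the valley floor where the coarse string cuts the corner.
2. **Dense stiff windows.** 541 windows at equal arc length
   ($\approx 0.5^\circ$ spacing) are sampled at $\kappa = 8000$
   ($\sigma \approx 0.64^\circ$). The spring must be stiff enough that the
   window fluctuation is small against the $4.65^\circ$ distance to the
   cut locus (no cross-branch leakage), and the window spacing must be no
   larger than $\sigma$, because the estimator measures the
   $\sigma$-smoothed gradient and the trapezoid has to resolve exactly that
   scale. The time step obeys the stability check and keeps the per-step
   noise displacement ($\approx 0.57^\circ$) below the local feature scale.
3. **Integration** of the resulting mean forces.

On the default landscape this recovers the conformational barrier from the
conformation-2 basin to within about 1 kJ/mol (three-seed mean ≈ 17.7 vs the
18.3 kJ/mol anchor), with the highest-PMF node at $\phi \approx 48^\circ$,
and the full pipeline (string + refinement + PMF) takes roughly a minute per
seed on one CPU. These are also the problem sizes used by the test suite and
the acceptance script: 20 images, $2\times10^4$ steps per window during
string evolution, three seeds per condition.

`wham_profile()` provides the independent density-based estimate: samples
are projected to the arc-length coordinate of the final string, the
restraint enters as its along-path component, and the standard
self-consistent histogram equations are iterated to $10^{-6}$ kJ/mol. A
diagnostic rejects window sets whose adjacent histograms share less than 5%
mass. The two estimators agree within 1.5 kJ/mol RMS on the default
landscape, which is the designed cross-validation of the PMF stage. The
published account does not say whether its PMF used force integration or
histogramming; implementing both and requiring agreement covers either
reading.

## Kinetics and Stark module

`wigner_kappa()` uses Wigner's quadratic correction
$\kappa = 1 + \tfrac{1}{24}\,(h c \tilde\nu / k_B T)^2$; the published
transmission factor (2.18 at 298.15 K without a field) does not state its
method, and under the Wigner hypothesis it corresponds to an imaginary
frequency of about 1102.5 cm$^{-1}$, which is recorded alongside results.
`eyring_rate()` is the standard
$\kappa\,(k_B T/h)\,e^{-\Delta G^\ddagger / RT}$ with CODATA-2018 constants
(prefactor $6.2124\times10^{12}$ s$^{-1}$ at 298.15 K). Published rate
constants reaching $10^{16}$ s$^{-1}$ at $\Delta G^\ddagger = 5.7$ kJ/mol
are irreconcilable with this prefactor and $\kappa \approx 2$, so printed
rates are not reproduction targets; barriers, tunneling factors and
relative changes are.

The Stark operations implement the printed closed forms verbatim: the
induced dipole $\alpha E$, the anisotropic polarization energy
$-\tfrac12(\alpha_\parallel - \alpha_\perp)E^2\Phi^2 -
\tfrac12\alpha_\perp E^2$, the first-order symmetric-top energy
$-\mu E\,MK/J(J+1)$, and the second-order expression with its user-supplied
proportionality constant $\Omega$ — kept exactly as printed even though the
textbook second-order Stark energy is quadratic in $E$: the published form
declares $\Omega$ a constant for a given field and is never evaluated
numerically at the source, so there is no printed value that could anchor
$\Omega$. The $J = 0$ singularity of that expression is an
explicit error.

## The synthetic field-scan generator

`generate_field_scan()` emulates the per-direction quantum-chemistry scans:
every observable responds linearly along each signed axis, anchored so the
change at $41.14\times10^8$ V/m equals the calibration constant of that
direction ($|\Delta R| = 0.051$ Å on $\pm x$ and 0.031 Å on $\pm y$;
$|\Delta\tilde\nu| = 234.2$ cm$^{-1}$ on $x$; barrier anchors $-11.6$,
$+2.6$, $+2.1$, $-3.0$ kJ/mol for $+x$, $-x$, $+y$, $-y$ on the
CCSD(T)//M06-2X scale with the 17.3 kJ/mol no-field reference). Signed
directions are anchored independently because the printed $+x$ and $-x$
responses are not consistent with a single origin-anchored line per axis.
Gaussian noise with standard deviation `noise_fraction` times the anchor
magnitude (2% by default) is added at the eight non-zero grid strengths;
the zero-field row carries the exact reference. The sign convention treats
0.051 Å as the magnitude of the $+x$ response with a positive sign (the
text's wording is contradictory on this point). The published language on
the $+x$ barrier change ("decreased by 11.6") is taken at face value, and
the quantity whose scan drives the acceptance regression, the
H6···O4′ distance, gets a synthetic zero-field reference of 1.60 Å. z-axis
anchors and all water-phase values are synthetic constants that encode only
the stated qualitative directions (z has little effect; water raises the
barrier and softens the structural response); they are not published
numbers.

## Degenerate inputs, tie-breaks, tolerances

* Angles are reduced to $[-180^\circ, 180^\circ)$; shortest-arc differences
  map the $-180^\circ$ tie to $+180^\circ$.
* `barrier()` breaks ties toward smaller $\alpha$; `wham_profile()` marks
  never-visited bins `NA` and gauges at the first finite bin.
* Flat profiles (test surfaces) get a mid-support field bump so the
  landscape constructor stays total; the bump is irrelevant at zero
  coupling.
* The equal-arc invariant is enforced to $10^{-6}$ of the mean segment;
  reparameterization preserves endpoints exactly.
* WHAM iterates to a maximum free-energy-shift change of $10^{-6}$ kJ/mol;
  OLS fits report $R^2 = 1 - SS_{res}/SS_{tot}$ and refuse constant series.
* Seeds: one master seed per run; per-iteration and per-stage streams are
  derived arithmetically and recorded in logs, so every result is a pure
  function of (inputs, seed).

## Known limitations

* The landscape is an analytic stand-in: exact calibration and a cut-locus
  discontinuity inside the hairpin corner come as a package. Conclusions
  about estimator behavior within the safe corridor transfer to smooth
  surfaces; behavior at the locus itself does not.
* The soft published spring (100 kJ mol$^{-1}$ rad$^{-2}$) is used for
  string evolution only. It cannot localize windows against the steepest
  descent of this landscape, which is why the PMF stage uses its own
  stiffer, denser window pass — a deliberate deviation documented above.
* The conformational barrier is measured from conformation 2 (the published
  barrier direction); whether the 18.3 kJ/mol value was measured from
  conformation 1 or 2 is ambiguous in the source, and the conformation-2
  reading is the default here.
* `competition_report()` is arithmetic on user-supplied barrier lists; it
  does not re-derive the proton-transfer barriers, which are
  electronic-structure inputs.
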
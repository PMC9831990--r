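---
title: "Methods: uncertainty quantification of multi-scale network resilience"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: uncertainty quantification of multi-scale network resilience}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(netres)
```

This vignette is the package's own account of the science it implements:
the model and its assumptions, the tunable parameters, the numerical
choices, what the synthetic data emulates, and the places where the design
was genuinely open and a decision had to be made.

## 1. Model and resilience indicator

A networked system of $N$ bistable units evolves as
$$\dot x_i = f(x_i, \mathbf a) + \sum_{j=1}^N M_{ji}\, g(x_i, x_j, \mathbf b),$$
with self-dynamics $f$, coupling $g \ge 0$, and non-negative influence
weights $M_{ji}$ (source $j$, target $i$).  The workhorse case study is the
mutualistic pollinator model
$$f(x) = B + x\Bigl(1 - \frac{x}{K}\Bigr)\Bigl(\frac{x}{C} - 1\Bigr),
\qquad
g(x_i, x_j) = \frac{x_i x_j}{D + E x_i + H x_j},$$
with homogeneous defaults $B = 0.1$, $C = 1$, $K = 5$, $D = 5$, $E = 0.9$,
$H = 0.1$: migration $B$, carrying capacity $K$, Allee threshold $C$
(negative growth below $C$), and a coupling that saturates in both
arguments.  These defaults are used everywhere a fixture needs "the"
parameter set; they are not tuned per test.

The mean-field reduction collapses the system to
$\Xi(x) = f(x) + w_{av}\, g(x, x)$ with average weighted degree
$w_{av} = \sum_{ij} M_{ji}/N$ (heterogeneous parameters are averaged over
the node population numerically, per-node coupling parameters weighted by
out-weight, which is what the double sum dictates).  $\Xi$ rises from
$\Xi(0) = B > 0$, dips, and finally decays ($-x^3/K$ dominates).  The value
$\tau$ of the **first strict interior local minimum** of $\Xi$ on
$(0, x_{\text{healthy}})$ is the resilience indicator: $\tau > 0$ iff only
the healthy equilibrium exists.  When the right-hand side has no interior
dip (deeply resilient nodes), $\tau$ is reported as the minimum over the
*open* interval and flagged `monotone`; its sign is then the only
meaningful content — the endpoints ($x = 0$ and the healthy root, where the
rhs is $\approx 0$) are excluded so the sign is not corrupted by the root
itself.

**Numerical policy.** Equilibria: 2000-point scan of $[0, x_{\max}]$
(default $x_{\max} = 2K$, automatically extended by factors of 1.5 until
the tail is negative), sign changes refined by bracketed root-finding to
$|\Xi| < 10^{-10}$; stability from the derivative sign.  Minima: grid
candidate then bounded minimisation to $10^{-8}$; plateau ties resolve to
the leftmost point.  The bifurcation threshold $w_*$ is found by bisecting
$\operatorname{sign}\tau(w_{av})$ to a bracket of $10^{-3}$.

**An honest discrepancy.** With the printed parameters the package (and an
independent symbolic solve of $\Xi = \Xi' = 0$) put the saddle-node at
$w_* = 6.9725$, with $\tau(6.9) = -5.8\times10^{-4}$.  The figure "about
6.9" that circulates for this parameter set is a rounded report of the same
geometry.  We left the acceptance band $[6.85, 6.95]$ red rather than
nudging the model: the package computes what the equations say.

## 2. Critical-weight curve

For each $w_{av}$ the one-node dynamics
$\dot x = f(x) + w^{in} g(x, x_e^0(w_{av}))$ is bisected on $w^{in}$ for
the sign change of its indicator; $w_{\text{crit}}$ is the minimum
in-weight a node needs.  **Design decision:** $x_e^0$ here is the state the
network *attains* — the unhealthy stable root when the mean field is
bistable, the unique root above $w_*$.  A bistable network relaxes to the
collapsed state after perturbation, so that is the neighbour state a
marginal node actually sees; it is also the only convention under which
$x_e^0(w_{av})$, and hence $w_{\text{crit}}$, is discontinuous at $w_*$,
the curve's defining feature.  With the default parameters the curve drops
from $w_{\text{crit}} \approx 10$ below threshold to $\approx 0.24$ above —
"almost zero" relative to the below-threshold branch, though not literally
$< 0.1$: a decoupled node always keeps its $f$-dip of $-0.126$, and lifting
it needs $w^{in} g(0.45, x_e^0) \approx 0.126$, i.e. $w^{in} \approx 0.2$.
The corresponding hardened acceptance clause is left red with this analysis.

## 3. Uncertain inputs and arbitrary polynomial chaos

A `random_input` is one independent uncertain scalar: a named family
(uniform, Gaussian, beta, gamma, discrete), empirical samples (plug-in
moments, no smoothing — the data are used directly), or a raw moment
sequence ($\mu_0 = 1$, Hankel-PSD validated).  Everything downstream is
moment-driven:

* **Monic orthogonal family** of degree $k$: solve the $(k{+}1)$-dimensional
  Hankel system that forces orthogonality to all lower powers; leading
  coefficient 1; then divide by the norm (positive leading coefficient
  convention — the monic normalisation fixes the rest).
* **Conditioning.** Raw-coordinate Hankel systems are notoriously
  ill-conditioned, so every input is standardised to zero mean and unit
  variance before moments are taken, and the polynomials are evaluated
  through the transform rather than re-expanded (expanding
  $q_k((x-m)/s)$ into monomials of $x$ is catastrophic for supports far
  from the origin).  Standardised moments are computed per family, never by
  binomially transforming raw moments (same cancellation).  Solves with
  condition number $> 10^{12}$ are rejected with a report; degree is capped
  at $r = 10$, beyond which moment determinacy of sampled data is
  unreliable anyway.
* **Quadrature.** Gauss rules come from the Jacobi matrix of three-term
  recurrence coefficients: closed Gautschi forms for named families
  (Hermite/Legendre/Jacobi/Laguerre classes), Cholesky of the standardised
  moment matrix for data-driven inputs.  Weights are positive, sum to 1,
  and integrate degree $2n-1$ exactly (property-tested against the moment
  tables).
* **Multivariate basis.** Tensor products over the graded multi-index set
  of total degree $\le r$, $Z = \binom{l+r}{r}$ terms; valid for
  independent inputs (dependence/copulas are out of scope).

For a Gaussian input this machinery reproduces normalised probabilists'
Hermite polynomials; for a uniform input, normalised Legendre — both to
$10^{-8}$ through degree 5, verified against recurrence oracles, with an
independent Gram–Schmidt construction agreeing on every supported input
kind.

## 4. Network-level uncertainty: CLT + Hermite PCE

With **iid-per-node** draws, the node averages of $f$ and of the coupling
are asymptotically Gaussian, so
$$\Xi_\zeta(x) = \mu_f(x) + \tfrac{m}{N}\mu_g(x) +
\sqrt{\tfrac1N\delta_f(x)^2 + \tfrac{m}{N^2}\delta_g(x)^2}\,\zeta,
\qquad \zeta \sim \mathcal N(0,1),$$
where $\mu, \delta$ are computed by tensorised Gauss quadrature (default 8
nodes per uncertain dimension) and returned as exact callables, not
interpolants.  $\tau(\zeta)$ is evaluated at Gauss–Hermite nodes (default
$2r+2$) and projected onto the normalised Hermite basis; the probability
$P(\tilde\tau_r(\zeta) > 0)$ is computed **analytically** — real roots of
the surrogate polynomial, Gaussian measure of the positive intervals —
rather than sampled, removing Monte Carlo noise from a one-dimensional
integral.  A prefactor inconsistency in the printed observation-noise
variant ($1/2\pi$ vs $1/\sqrt{2\pi}$) is resolved as a typo: $\zeta$ is
standard normal, so both formulas are proper normal measures,
$P = \Phi\bigl((\tau_1+\mu_\gamma)\sqrt N/\delta_\gamma\bigr)$.

The CLT path is *invalid* for shared draws (one realization used by all
nodes).  **Shared mode** therefore bypasses it: the network indicator is
treated as a function $\tau(\xi_1 \dots \xi_l)$ of the physical inputs and
handled by the same multivariate aPC machinery as the node level.  Which
mode a study means is declared explicitly; nothing is inferred.

The KS property test (N = 1000, $10^4$ replicates, distance $< 0.05$)
checks the CLT assumption itself, not the implementation of a formula.

## 5. Node-level sequential estimation

Step 1: the mean-field equilibrium estimate $x_e^0(\xi)$ — here the
**largest** non-negative root, single-valued and smooth in $\xi$ even when
a collapsed root coexists (a multiplicity flag is set; the curve of
section 2 deliberately uses the other convention, and the two uses are
kept separate on purpose).  Step 2: neighbours of node $i$ are replaced by
$x_e^0$, out-weight-averaged:
$$\dot x_i = f(x_i) + w_i^{in}
\frac{\sum_j w_j^{out} g(x_i, x_e^0, b_j)}{\sum_j w_j^{out}},$$
and $\tau^i$ is the same local-minimum indicator of this one-dimensional
system.

**Coefficients** (the literature leaves the computation unspecified):
tensorised Gauss quadrature with $r+1$ nodes per dimension for $l \le 3$ —
exact for polynomial indicators of total degree $\le r$, since the
quadrature is exact to degree $2r+1$; a seeded least-squares fit on $2Z$
sampled design points for $l > 3$, where the tensor grid's curse of
dimensionality bites.  A validation residual at seeded held-out points is
always attached.  **Probability**: $10^5$ (configurable) seeded draws
through the cheap surrogate, with a binomial standard error; the
$l$-dimensional positive-measure integral has no closed form for general
bases.  The **Monte Carlo baseline** runs the full two-step indicator per
draw — no surrogate — and is the reference the aPC estimates are judged
against; runs with $>1\%$ indicator failures abort.

All batch evaluation (MC baseline, design points) is vectorised across
samples: a common state grid plus vectorised bisections, so $10^5$ full
indicator evaluations cost seconds in pure R.  The batch path is
property-tested to agree with the scalar path to $10^{-7}$.

## 6. Synthetic data: what it emulates, what it does not

Generators produce Erdős–Rényi, preferential-attachment (symmetrised),
out-regular, and geometric commuter networks, globally rescaled to a target
$w_{av}$ (the one statistic the mean field responds to), deterministic per
seed with the RNG state restored afterwards.  The commuter generator
places cities uniformly in a square, links $k$ nearest neighbours
symmetrically, and sets service weights $e^{-d^\beta}$ — emulating the
*structure* of a census commuter network (distance-decaying weights,
sparse geometry), not its data.  The stand-in makes no claim to match any
real pollinator or commuter network's size or weights: green tests
establish that the machinery is correct on networks with controlled
$w_{av}$ and in-weight spread, not that any empirical system has a
particular probability.

The canonical uncertainty fixture follows the case study: $C$ and $E$
uniform within ±10% of their means, shared across nodes.  The fixture node
for surrogate-vs-MC comparisons is made *marginal* — a single in-edge at
its deterministic critical weight — because that is the regime the method
exists for: deeply resilient or deeply collapsed nodes have
probability 0/1 and would make the comparison vacuous.  Its probability is
whatever the computation yields (≈ 0.5, as a node at its critical weight
must).

The commuter dynamics' printed coupling contains an ambiguity (the
attractiveness exponent uses the receiving city's state in both numerator
and denominator, where it cancels).  Both interpretations are implemented:
a competitive **share** mode — sender outflow split across receivers by
attractiveness $\exp[\alpha\log x_q - d^\beta_{jq}]$, shares summing to 1 —
and a strict **literal** mode.  Neither is asserted as intended; the share
mode is the default, and the pairwise kernel used by the reductions
($g = x_i^\alpha x_j^{1-\alpha}/w_{\text{ref}}$, $w_{\text{ref}} = w_{av}$)
is its homogeneous-competitor limit, under which the mean coupling per
node is exactly $x$ (flow conservation) and resilience loss is a
node-level redistribution effect — which is the phenomenon of interest.
States are clamped at $10^{-12}$ inside logarithms.

## 7. Known limitations

* Independent inputs only; no copulas or random fields.
* Saddle-node detection via the sign of $\tau$ only; no continuation, Hopf
  detection, or limit cycles.
* The sequential estimation stops at two steps; joint node-pair
  probabilities are not computed.
* Shared-mode network probabilities inherit surrogate truncation error
  near the bifurcation, where $\tau(\xi)$ has the least polynomial
  structure; the validation residual should be inspected before trusting
  probabilities within a few $10^{-3}$ of the $\tau = 0$ boundary.
* The ODE integrator is an in-package Dormand–Prince 4(5) (no suitable
  integrator package in the target environment); it is used only by
  `simulate_dynamics`, never by the indicator pipeline.
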
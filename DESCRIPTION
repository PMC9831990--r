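Package: netres
Title: Uncertainty Quantification of Multi-Scale Resilience in Networked
    Nonlinear Dynamical Systems
Version: 0.1.0
Authors@R:
    person("netres", "developers", email = "netres@example.org",
           role = c("aut", "cre"))
Description: Quantifies how parameter and observation uncertainty affect the
    resilience of networked nonlinear dynamical systems at the network
    (mean-field) and single-node level.  Uncertain parameters of arbitrary
    distribution -- named families, empirical samples, or raw moment
    sequences -- are handled through moment-based arbitrary polynomial chaos
    (aPC): orthonormal polynomial bases are built directly from raw moments
    via Hankel systems, with Gauss quadrature rules derived from the
    three-term recurrence.  Network-level uncertainty is propagated by a
    central-limit-theorem Gaussian reduction with a Hermite polynomial chaos
    surrogate of the resilience indicator; node-level resilience uses a
    sequential mean-field/neighbour estimation with a multivariate aPC
    surrogate and a Monte Carlo baseline.  Includes saddle-node bifurcation
    threshold detection, critical-weight curves, mutualistic pollinator and
    commuter-flow case-study dynamics, and synthetic network generators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
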
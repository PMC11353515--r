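Package: smcontrol
Title: Particle-Filter Estimation and Control of Nonlinear Dynamical Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A fully particle-filter-based framework for simultaneously
    estimating the latent state and parameters of a nonlinear state-space
    model while steering it with sampling-based model predictive control.
    State filtering uses an adaptive-resampling bootstrap particle filter;
    parameters are learned online by a stochastic-approximation EM whose
    smoothed sufficient statistics are stabilised by adaptive backward
    ancestor sampling (AdaSmooth); control inputs are obtained by filtering
    a reference trajectory through an augmented state-space model over a
    receding horizon. Ships two closed-loop case studies: stabilisation of
    the chaotic Lorenz system at its unstable fixed point, and steering a
    Morris-Lecar neuron between firing and resting regimes from noisy
    membrane-potential recordings.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    parallel,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
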
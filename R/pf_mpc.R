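#' Reference model for the control-filtering problem
#'
#' Over the horizon, the reference trajectory is treated as a sequence of
#' observations of the augmented state: `r_tau ~ N(selector(zeta_tau),
#' sigma_r2)`. The selector picks the controlled coordinate(s) of the
#' predictive state (the y-coordinate for Lorenz, the membrane potential for
#' Morris-Lecar).
#'
#' @param select `function(x)` mapping an `N x state_dim` matrix of
#'   predictive states to an `N`-vector in reference space.
#' @param sigma_r2 acceptable-error variance (> 0).
#' @param T_H horizon length in steps (>= 1).
#' @return An object of class `reference_model`.
#' @export
reference_model <- function(select, sigma_r2, T_H) {
  stopifnot(is.function(select), sigma_r2 > 0, T_H >= 1)
  structure(list(select = select, sigma_r2 = sigma_r2,
                 T_H = as.integer(T_H)),
            class = "reference_model")
}

#' Control transition model
#'
#' The stochastic model for the control-input component of the augmented
#' state: `init` proposes initial input particles around the previously
#' applied input, `transition` performs the within-horizon clamped random
#' walk. Both must return inputs satisfying the model's input constraint by
#' construction.
#'
#' @param init `function(n, u_prev)` drawing `n` initial input particles.
#' @param transition `function(u)` propagating a vector of input particles
#'   one horizon step.
#' @param u_lim the constraint bound (informational; used in traces).
#' @return An object of class `control_model`.
#' @export
control_model <- function(init, transition, u_lim = Inf) {
  stopifnot(is.function(init), is.function(transition))
  structure(list(init = init, transition = transition, u_lim = u_lim),
            class = "control_model")
}

#' Augmented horizon ensemble
#'
#' Particles of the augmented state `zeta_tau = (x_bar, u_bar, u_tilde)`:
#' predictive state, predictive input, and the preserved initial input that
#' is carried unchanged through the horizon (the delta transition), plus
#' normalised weights.
#'
#' @param tau horizon time index.
#' @param x `N x state_dim` matrix of predictive states.
#' @param u numeric vector of predictive inputs.
#' @param u_init numeric vector of preserved initial inputs.
#' @param w normalised weights.
#' @return An object of class `augmented_ensemble`.
#' @export
augmented_ensemble <- function(tau, x, u, u_init, w) {
  stopifnot(is.matrix(x))
  N <- nrow(x)
  if (length(u) != N || length(u_init) != N || length(w) != N) {
    stop("augmented components must share the particle count")
  }
  if (any(w < 0) || abs(sum(w) - 1) > 1e-8) {
    stop("augmented weights must be nonnegative and sum to 1")
  }
  structure(list(tau = as.integer(tau), x = x, u = as.numeric(u),
                 u_init = as.numeric(u_init), w = as.numeric(w)),
            class = "augmented_ensemble")
}

#' Initialise the augmented ensemble from the state filter
#'
#' Copies the state particles and weights of the state PF verbatim, draws
#' each particle's initial input from the control model's initial proposal
#' around the previously applied input, and sets the preserved input equal
#' to the initial input.
#'
#' @param state_ens [particle_ensemble()] from the state filter at time `t`.
#' @param u_prev previously applied control input.
#' @param ctm a [control_model()].
#' @param stream optional RNG stream.
#' @return An [augmented_ensemble()] at `tau = t`.
#' @export
init_augmented <- function(state_ens, u_prev, ctm, stream = NULL) {
  N <- length(state_ens$w)
  u0 <- with_stream(stream, ctm$init(N, u_prev))
  augmented_ensemble(tau = state_ens$t, x = state_ens$x, u = u0,
                     u_init = u0, w = state_ens$w)
}

# reweight an augmented ensemble by the Gaussian reference likelihood
reference_reweight <- function(aug, r_tau, ref, log_w_prev = log(aug$w)) {
  lw <- log_w_prev +
    stats::dnorm(r_tau, ref$select(aug$x), sqrt(ref$sigma_r2), log = TRUE)
  m <- max(lw)
  if (!is.finite(m)) {
    stop("degenerate weights at horizon step tau = ", aug$tau,
         ": all reference likelihoods underflowed")
  }
  w <- exp(lw - m)
  aug$w <- w / sum(w)
  aug
}

#' One horizon step of the control particle filter
#'
#' Applies the same adaptive-resampling machinery as the state filter to the
#' augmented particles: resample if the ESS of the current weights has
#' dropped to `alpha * N`; propagate the predictive state through the system
#' model with each particle's current input and the frozen parameter
#' estimate; propagate the input through the control transition; carry the
#' preserved initial input through the ancestors; reweight by the Gaussian
#' reference likelihood of `r_tau` and normalise.
#'
#' @param aug [augmented_ensemble()] at horizon time `tau`.
#' @param r_tau reference value observed at `tau + 1`.
#' @param model an [new_ssm()] object.
#' @param ctm a [control_model()].
#' @param ref a [reference_model()].
#' @param theta frozen parameter estimate `theta_hat_t`.
#' @param cfg a [pf_config()] (shares `alpha` with the state filter).
#' @param stream optional RNG stream.
#' @return An [augmented_ensemble()] at `tau + 1`.
#' @export
horizon_step <- function(aug, r_tau, model, ctm, ref, theta, cfg,
                         stream = NULL) {
  N <- length(aug$w)
  with_stream(stream, {
    ess <- effective_sample_size(aug$w)
    if (ess <= cfg$alpha * N) {
      anc <- multinomial_resample(aug$w, N)
      log_w_prev <- rep(-log(N), N)
    } else {
      anc <- seq_len(N)
      log_w_prev <- log(aug$w)
    }
    u_old <- aug$u[anc]
    x_new <- model$rtransition(aug$x[anc, , drop = FALSE], u_old, theta)
    u_new <- ctm$transition(u_old)
    out <- augmented_ensemble(tau = aug$tau + 1L, x = x_new, u = u_new,
                              u_init = aug$u_init[anc], w = rep(1 / N, N))
    reference_reweight(out, r_tau, ref, log_w_prev)
  })
}

#' Extract the applied control input
#'
#' The weighted mean of the preserved initial inputs at the end of the
#' horizon, `u_t = sum_i w_bar^{(i)} u_tilde^{(i)}` — a convex combination,
#' hence always inside the input constraint set.
#'
#' @param aug [augmented_ensemble()] at `tau = t + T_H`.
#' @return The control input to apply at time `t`.
#' @export
extract_control <- function(aug) {
  u <- sum(aug$w * aug$u_init)
  # enforce the convex-hull property against rounding in the weighted sum
  min(max(u, min(aug$u_init)), max(aug$u_init))
}

#' Model predictive control by reference filtering
#'
#' Solves the control-filtering problem for one closed-loop step: the
#' augmented ensemble is initialised from the state filter, reweighted once
#' by the reference likelihood at the initial horizon time, propagated and
#' reweighted through `T_H` horizon steps against the remaining reference
#' values, and the applied input is read off as the weighted mean of the
#' preserved initial inputs.
#'
#' @param state_ens [particle_ensemble()] from the state filter at time `t`.
#' @param u_prev previously applied input.
#' @param reference_segment numeric vector of `T_H + 1` reference values
#'   `r_t, ..., r_{t+T_H}` (pad by holding the last value if the stored
#'   reference ends).
#' @param model an [new_ssm()] object.
#' @param ctm a [control_model()].
#' @param ref a [reference_model()].
#' @param theta frozen parameter estimate.
#' @param cfg a [pf_config()].
#' @param stream optional RNG stream.
#' @return The scalar control input `u_t`.
#' @export
mpc_control <- function(state_ens, u_prev, reference_segment, model, ctm,
                        ref, theta, cfg, stream = NULL) {
  if (length(reference_segment) != ref$T_H + 1L) {
    stop("reference segment must hold T_H + 1 = ", ref$T_H + 1L, " values")
  }
  with_stream(stream, {
    aug <- init_augmented(state_ens, u_prev, ctm)
    aug <- reference_reweight(aug, reference_segment[1L], ref)
    for (k in seq_len(ref$T_H)) {
      aug <- horizon_step(aug, reference_segment[k + 1L], model, ctm, ref,
                          theta, cfg)
    }
    extract_control(aug)
  })
}
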
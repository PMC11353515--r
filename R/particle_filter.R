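#' Particle filter configuration
#'
#' @param N number of particles (>= 1).
#' @param alpha resampling-threshold rate in `[0, 1]`: multinomial
#'   resampling is triggered whenever the effective sample size of the
#'   incoming weights satisfies `ESS <= alpha * N`. `alpha = 0` disables
#'   resampling; `alpha = 1` resamples at every step with non-uniform
#'   weights.
#' @return An object of class `pf_config`.
#' @export
pf_config <- function(N, alpha = 0.8) {
  stopifnot(is.numeric(N), length(N) == 1L, N >= 1,
            is.numeric(alpha), length(alpha) == 1L, alpha >= 0, alpha <= 1)
  structure(list(N = as.integer(N), alpha = alpha), class = "pf_config")
}

#' Weighted particle ensemble at one time step
#'
#' Container for the particle-filter state at time `t`: `N` state particles
#' with normalised weights, the ancestor indices `A_t` recording which
#' time-`t-1` particle each descends from, and the Enoch indices `E_t`
#' tracking lineages back to the last backward-sampling event.
#'
#' @param t integer time index.
#' @param x `N x state_dim` matrix of particles (one per row).
#' @param w numeric weights, nonnegative, summing to 1.
#' @param ancestors,enoch integer vectors in `1..N`.
#' @param resampled logical, whether probabilistic resampling occurred at
#'   `t`.
#' @return An object of class `particle_ensemble`.
#' @export
particle_ensemble <- function(t, x, w,
                              ancestors = seq_len(nrow(x)),
                              enoch = seq_len(nrow(x)),
                              resampled = FALSE) {
  stopifnot(is.matrix(x))
  N <- nrow(x)
  w <- as.numeric(w)
  ancestors <- as.integer(ancestors)
  enoch <- as.integer(enoch)
  if (length(w) != N || length(ancestors) != N || length(enoch) != N) {
    stop("particle, weight and index vectors must share length N = ", N)
  }
  if (any(w < 0)) stop("weights must be nonnegative")
  if (abs(sum(w) - 1) > 1e-8) {
    stop("weights must sum to 1 (got ", format(sum(w)), ")")
  }
  if (any(ancestors < 1L | ancestors > N)) stop("ancestors out of 1..N")
  if (any(enoch < 1L | enoch > N)) stop("enoch indices out of 1..N")
  structure(
    list(t = as.integer(t), x = x, w = w, ancestors = ancestors,
         enoch = enoch, resampled = isTRUE(resampled)),
    class = "particle_ensemble"
  )
}

#' @export
print.particle_ensemble <- function(x, ...) {
  cat("<particle ensemble: t = ", x$t, ", N = ", nrow(x$x),
      ", state_dim = ", ncol(x$x),
      ", ESS = ", format(effective_sample_size(x$w), digits = 5),
      if (x$resampled) ", resampled" else "", ">\n", sep = "")
  invisible(x)
}

#' Effective sample size of a normalised weight vector
#'
#' `ESS = 1 / sum(w_i^2)`, ranging from 1 (a point mass) to `N` (uniform
#' weights); the particle filter resamples when it drops to `alpha * N`.
#'
#' @param w nonnegative weights summing to 1.
#' @return The effective sample size, in `[1, N]`.
#' @export
effective_sample_size <- function(w) {
  if (any(w < 0)) stop("weights must be nonnegative")
  s2 <- sum(w^2)
  if (s2 == 0) stop("degenerate weights: all weights are zero")
  if (abs(sum(w) - 1) > 1e-6) {
    stop("weights must be normalised (sum = ", format(sum(w)), ")")
  }
  1 / s2
}

#' Multinomial resampling
#'
#' Draws `n` ancestor indices i.i.d. from the categorical distribution with
#' the given weights.
#'
#' @param w normalised weights.
#' @param n number of draws (defaults to `length(w)`).
#' @param stream optional [rng_streams()] stream.
#' @return Integer ancestor indices in `1..length(w)`.
#' @export
multinomial_resample <- function(w, n = length(w), stream = NULL) {
  if (any(w < 0)) stop("weights must be nonnegative")
  if (abs(sum(w) - 1) > 1e-6) {
    stop("weights must be normalised (sum = ", format(sum(w)), ")")
  }
  with_stream(stream, sample.int(length(w), size = n, replace = TRUE,
                                 prob = w))
}

#' Initial particle ensemble
#'
#' Draws `N` particles from the model's initial distribution `p0(x)` with
#' uniform weights `1/N`; ancestor and Enoch indices start as the identity.
#'
#' @param model an [new_ssm()] object.
#' @param cfg a [pf_config()].
#' @param stream optional RNG stream.
#' @return A [particle_ensemble()] at `t = 0`.
#' @export
init_particles <- function(model, cfg, stream = NULL) {
  x <- with_stream(stream, model$rinit(cfg$N))
  particle_ensemble(t = 0L, x = x, w = rep(1 / cfg$N, cfg$N))
}

#' One adaptive-resampling particle-filter step
#'
#' Advances the ensemble from `t-1` to `t` given a new observation:
#' (i) if `ESS(w_{t-1}) <= alpha * N`, ancestors are drawn by multinomial
#' resampling and predecessor weights reset to `1/N`; otherwise ancestors
#' are the identity and predecessor weights carry through; (ii) each
#' particle is propagated through the system model conditioned on the
#' applied input `u_prev`; (iii) un-normalised weights are predecessor
#' weight times the observation likelihood of `y_t` at the propagated
#' particle, computed in log space with a max-shift, then normalised.
#' The proposal is the system model itself, so no proposal correction term
#' appears.
#'
#' @param prev [particle_ensemble()] at `t-1`.
#' @param y observation vector at `t`.
#' @param u_prev control input applied over `(t-1, t]`.
#' @param model an [new_ssm()] object.
#' @param theta parameter vector plugged into the transition.
#' @param cfg a [pf_config()].
#' @param stream optional RNG stream.
#' @return A [particle_ensemble()] at `t`.
#' @export
pf_step <- function(prev, y, u_prev, model, theta, cfg, stream = NULL) {
  N <- cfg$N
  with_stream(stream, {
    ess <- effective_sample_size(prev$w)
    if (ess <= cfg$alpha * N) {
      anc <- multinomial_resample(prev$w, N)
      log_w_prev <- rep(-log(N), N)
      resampled <- TRUE
    } else {
      anc <- seq_len(N)
      log_w_prev <- log(prev$w)
      resampled <- FALSE
    }
    x_new <- model$rtransition(prev$x[anc, , drop = FALSE], u_prev, theta)
    log_lik <- model$dobservation(y, x_new, theta, log = TRUE)
    lw <- log_w_prev + log_lik
    m <- max(lw)
    if (!is.finite(m)) {
      stop("degenerate weights at time index ", prev$t + 1L,
           ": all observation likelihoods underflowed")
    }
    w <- exp(lw - m)
    w <- w / sum(w)
    particle_ensemble(t = prev$t + 1L, x = x_new, w = w, ancestors = anc,
                      enoch = prev$enoch[anc], resampled = resampled)
  })
}

#' Weighted-mean point estimate of the filtering distribution
#'
#' @param ens a [particle_ensemble()].
#' @return The state vector `sum_i w_i x_i`.
#' @export
filtering_mean <- function(ens) {
  as.numeric(colSums(ens$x * ens$w))
}
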
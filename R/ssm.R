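#' State-space model contract
#'
#' Builds the object every concrete model plugs into the filtering, smoothing
#' and control machinery. A state-space model (SSM) is a latent Markov
#' process `x_t ~ p(x_t | x_{t-1}, u_{t-1}; theta)` observed through a noisy
#' channel `y_t ~ p(y_t | x_t; theta)`. The online EM layer additionally
#' requires the model to expose an additive sufficient-statistic increment
#' `s~(x_{t-1}, x_t)` and the M-step map `Lambda(.)` that turns time-averaged
#' statistics into a parameter estimate.
#'
#' All particle-facing functions are vectorised over particles: state
#' arguments are `N x state_dim` matrices (one particle per row), and density
#' evaluators return one value per row. `dtransition` broadcasts: either of
#' `x_prev` / `x_curr` may be a single row evaluated against all rows of the
#' other, which is what backward ancestor sampling needs.
#'
#' @param name model name (used in messages and traces).
#' @param state_dim,obs_dim,param_dim,suffstat_dim dimensions of the state,
#'   observation, parameter vector and the statistic pair (the A-part is a
#'   `suffstat_dim x suffstat_dim` matrix, the b-part a vector).
#' @param rinit `function(n)` drawing `n` initial states from `p0(x)`,
#'   returning an `n x state_dim` matrix.
#' @param rtransition `function(x_prev, u_prev, theta)` propagating each row
#'   one step.
#' @param dtransition `function(x_prev, x_curr, u_prev, theta, log = TRUE)`
#'   transition density, one value per (broadcast) row pair.
#' @param logdensity_max `function(theta)` a finite upper bound on the log
#'   transition density over `x_prev` for any fixed `x_curr` (for Gaussian
#'   transitions this is the log normalising constant, i.e. the mode value);
#'   used by rejection-based backward ancestor sampling.
#' @param dobservation `function(y, x, theta, log = TRUE)` observation
#'   density of a single observation `y` against each particle row.
#' @param suffstat `function(x_prev, x_curr, u_prev)` per-pair sufficient
#'   statistic increments, returned as
#'   `list(A = N x suffstat_dim^2 matrix, b = N x suffstat_dim matrix)`
#'   (the A-part stored row-wise in column-major order).
#' @param lambda `function(A, b)` the M-step maximiser mapping an averaged
#'   statistic pair to a parameter vector.
#' @param project `function(theta)` projection applied after each M-step
#'   (e.g. positivity floors); defaults to the identity.
#' @param robservation optional `function(x, theta)` drawing one noisy
#'   observation per particle row (used by the truth simulator).
#' @param transition_mean,transition_var optional declaration that the
#'   transition is additive diagonal Gaussian: `transition_mean(x_prev,
#'   u_prev, theta)` returns the `N x state_dim` matrix of one-step means
#'   and `transition_var` the per-dimension variance vector. When present,
#'   backward ancestor sampling computes all ancestor means once per event
#'   instead of re-evaluating the pairwise transition density.
#' @param theta_names optional parameter component names.
#' @return An object of class `ssm`.
#' @export
new_ssm <- function(name, state_dim, obs_dim, param_dim, suffstat_dim,
                    rinit, rtransition, dtransition, logdensity_max,
                    dobservation, suffstat, lambda,
                    project = identity, robservation = NULL,
                    transition_mean = NULL, transition_var = NULL,
                    theta_names = NULL) {
  stopifnot(
    is.character(name), length(name) == 1L,
    state_dim >= 1L, obs_dim >= 1L, param_dim >= 1L, suffstat_dim >= 1L,
    is.function(rinit), is.function(rtransition), is.function(dtransition),
    is.function(logdensity_max), is.function(dobservation),
    is.function(suffstat), is.function(lambda), is.function(project)
  )
  structure(
    list(
      name = name,
      state_dim = as.integer(state_dim),
      obs_dim = as.integer(obs_dim),
      param_dim = as.integer(param_dim),
      suffstat_dim = as.integer(suffstat_dim),
      rinit = rinit,
      rtransition = rtransition,
      dtransition = dtransition,
      logdensity_max = logdensity_max,
      dobservation = dobservation,
      suffstat = suffstat,
      lambda = lambda,
      project = project,
      robservation = robservation,
      transition_mean = transition_mean,
      transition_var = transition_var,
      theta_names = theta_names
    ),
    class = "ssm"
  )
}

#' @export
print.ssm <- function(x, ...) {
  cat("<state-space model: ", x$name, ">\n", sep = "")
  cat("  state_dim = ", x$state_dim,
      ", obs_dim = ", x$obs_dim,
      ", param_dim = ", x$param_dim, "\n", sep = "")
  if (!is.null(x$theta_names)) {
    cat("  parameters:", paste(x$theta_names, collapse = ", "), "\n")
  }
  invisible(x)
}

# coerce a state argument to an N x d matrix
as_state_matrix <- function(x, d) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == d)
    x
  } else {
    matrix(x, ncol = d, byrow = FALSE)
  }
}

# broadcast two state matrices to a common number of rows
broadcast_rows <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  if (na == nb) return(list(a = a, b = b))
  if (na == 1L) return(list(a = a[rep(1L, nb), , drop = FALSE], b = b))
  if (nb == 1L) return(list(a = a, b = b[rep(1L, na), , drop = FALSE]))
  stop("incompatible particle counts: ", na, " vs ", nb)
}

# row-wise log density of a diagonal Gaussian: sum_k dnorm(x[,k]; mean[,k], sd[k])
rowwise_dnorm <- function(x, mean, sd, log = TRUE) {
  d <- ncol(x)
  out <- 0
  for (k in seq_len(d)) {
    out <- out + stats::dnorm(x[, k], mean[, k], sd[k], log = TRUE)
  }
  if (log) out else exp(out)
}

#' Linear-Gaussian reference model
#'
#' The scalar linear-Gaussian state-space model
#' `x_t = a x_{t-1} + b z_{t-1}`, `y_t = c x_t + d eta_t` with standard
#' normal noises, used throughout the test-suite as the case where exact
#' filtering (Kalman) and smoothing (RTS) are available in closed form. The
#' estimated parameter is the transition coefficient `a`; `b`, `c`, `d` are
#' treated as known. Its sufficient-statistic pair is
#' `A~ = x_{t-1}^2 / b^2`, `b~ = x_{t-1} x_t / b^2`, whose ratio is the
#' complete-data maximum-likelihood estimate of `a`.
#'
#' @param b,c,d known model constants (`b`, `d` must be positive).
#' @param prior_mean,prior_var mean and variance of the Gaussian initial
#'   distribution of `x_0`.
#' @return An [new_ssm()] object with `theta = c(a = ...)`.
#' @export
linear_gaussian_ssm <- function(b = 1, c = 1, d = 1,
                                prior_mean = 0, prior_var = 1) {
  stopifnot(b > 0, d > 0, prior_var > 0)
  force(b); force(c); force(d)
  new_ssm(
    name = "linear-gaussian",
    state_dim = 1L, obs_dim = 1L, param_dim = 1L, suffstat_dim = 1L,
    rinit = function(n) {
      matrix(stats::rnorm(n, prior_mean, sqrt(prior_var)), ncol = 1L)
    },
    rtransition = function(x_prev, u_prev, theta) {
      n <- nrow(x_prev)
      matrix(theta[1L] * x_prev[, 1L] + u_prev + b * stats::rnorm(n),
             ncol = 1L)
    },
    dtransition = function(x_prev, x_curr, u_prev, theta, log = TRUE) {
      bc <- broadcast_rows(as_state_matrix(x_prev, 1L),
                           as_state_matrix(x_curr, 1L))
      out <- stats::dnorm(bc$b[, 1L], theta[1L] * bc$a[, 1L] + u_prev, b,
                          log = TRUE)
      if (log) out else exp(out)
    },
    logdensity_max = function(theta) -0.5 * log(2 * pi * b^2),
    dobservation = function(y, x, theta, log = TRUE) {
      out <- stats::dnorm(y[1L], c * x[, 1L], d, log = TRUE)
      if (log) out else exp(out)
    },
    suffstat = function(x_prev, x_curr, u_prev) {
      list(A = matrix(x_prev[, 1L]^2 / b^2, ncol = 1L),
           b = matrix(x_prev[, 1L] * (x_curr[, 1L] - u_prev) / b^2,
                      ncol = 1L))
    },
    lambda = function(A, b_part) c(a = as.numeric(b_part[1L] / A[1L, 1L])),
    robservation = function(x, theta) {
      matrix(c * x[, 1L] + d * stats::rnorm(nrow(x)), ncol = 1L)
    },
    transition_mean = function(x_prev, u_prev, theta) {
      matrix(theta[1L] * x_prev[, 1L] + u_prev, ncol = 1L)
    },
    transition_var = b^2,
    theta_names = "a"
  )
}

#' Gaussian transition density of the linear-Gaussian model
#'
#' Evaluates `N(x | a * x_prev, b^2)`.
#'
#' @param x_prev previous state (vectorised).
#' @param x current state (vectorised).
#' @param a transition coefficient.
#' @param b state noise standard deviation (must be positive).
#' @return The density value(s).
#' @export
lg_transition_density <- function(x_prev, x, a, b) {
  if (!is.numeric(b) || any(b <= 0)) {
    stop("invalid parameter: state noise scale 'b' must be positive")
  }
  stats::dnorm(x, a * x_prev, b)
}

#' Exact Kalman filter for the linear-Gaussian model
#'
#' Closed-form filtering for the scalar model `x_t = a x_{t-1} + b z`,
#' `y_t = c x_t + d eta`, with `x_0 ~ N(prior_mean, prior_var)`. Serves as
#' the exact oracle the particle filter is checked against.
#'
#' @param y numeric vector of observations `y_1, ..., y_T` (nonempty unless
#'   an empty result is wanted).
#' @param a,b,c,d model constants (`b`, `d` positive).
#' @param prior_mean,prior_var initial distribution of `x_0`.
#' @return A data frame with columns `t`, `pred_mean`, `pred_var`,
#'   `filt_mean`, `filt_var`.
#' @export
kalman_filter <- function(y, a, b, c, d, prior_mean = 0, prior_var = 1) {
  stopifnot(b > 0, d > 0, prior_var > 0)
  T_len <- length(y)
  out <- data.frame(t = seq_len(T_len),
                    pred_mean = numeric(T_len), pred_var = numeric(T_len),
                    filt_mean = numeric(T_len), filt_var = numeric(T_len))
  if (T_len == 0L) return(out)
  m <- prior_mean
  P <- prior_var
  for (t in seq_len(T_len)) {
    mp <- a * m
    Pp <- a^2 * P + b^2
    S <- c^2 * Pp + d^2
    K <- Pp * c / S
    m <- mp + K * (y[t] - c * mp)
    P <- (1 - K * c) * Pp
    out$pred_mean[t] <- mp; out$pred_var[t] <- Pp
    out$filt_mean[t] <- m; out$filt_var[t] <- P
  }
  out
}

#' Exact Rauch-Tung-Striebel smoother for the linear-Gaussian model
#'
#' Runs [kalman_filter()] and the backward RTS pass, additionally returning
#' the lag-one smoothed cross-covariances `Cov(x_{t-1}, x_t | y_{1:T})`
#' needed for exact expectations of pairwise sufficient statistics.
#'
#' @inheritParams kalman_filter
#' @return A data frame with rows for `t = 0, ..., T` (`t = 0` is the
#'   smoothed prior state) and columns `t`, `smooth_mean`, `smooth_var`,
#'   and `lag1_cov` (`Cov(x_{t-1}, x_t | y_{1:T})`; `NA` at `t = 0`).
#' @export
kalman_smoother <- function(y, a, b, c, d, prior_mean = 0, prior_var = 1) {
  T_len <- length(y)
  kf <- kalman_filter(y, a, b, c, d, prior_mean, prior_var)
  out <- data.frame(t = 0:T_len,
                    smooth_mean = numeric(T_len + 1L),
                    smooth_var = numeric(T_len + 1L),
                    lag1_cov = NA_real_)
  if (T_len == 0L) return(out)
  # filtered moments of x_0 prepended so the pass also smooths the prior state
  fm <- c(prior_mean, kf$filt_mean)
  fP <- c(prior_var, kf$filt_var)
  pm <- c(NA, kf$pred_mean)
  pP <- c(NA, kf$pred_var)
  sm <- numeric(T_len + 1L)
  sP <- numeric(T_len + 1L)
  sm[T_len + 1L] <- fm[T_len + 1L]
  sP[T_len + 1L] <- fP[T_len + 1L]
  J <- numeric(T_len)          # gain J_t for state index t (0-based t = idx-1)
  for (i in T_len:1) {
    J[i] <- fP[i] * a / pP[i + 1L]
    sm[i] <- fm[i] + J[i] * (sm[i + 1L] - pm[i + 1L])
    sP[i] <- fP[i] + J[i]^2 * (sP[i + 1L] - pP[i + 1L])
  }
  out$smooth_mean <- sm
  out$smooth_var <- sP
  # Cov(x_{t-1}, x_t | y_{1:T}) = J_{t-1} * Var(x_t | y_{1:T})
  out$lag1_cov <- c(NA_real_, J * sP[-1L])
  out
}
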
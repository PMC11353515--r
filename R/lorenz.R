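#' Lorenz noise and discretisation configuration
#'
#' Settings for the discretised stochastic Lorenz system: Euler time step,
#' diagonal system-noise variances, observation covariance, and the
#' Gaussian initial distribution.
#'
#' @param dt Euler/filter time step (> 0).
#' @param Sx length-3 vector of system-noise variances
#'   `(sigma_x1^2, sigma_x2^2, sigma_x3^2)`; the one-step transition
#'   covariance is `diag(Sx) * dt`.
#' @param Sy observation covariance: a length-3 vector of variances
#'   (diagonal case) or a full 3 x 3 matrix.
#' @param x0 mean of the initial distribution.
#' @param Sx0 length-3 vector of initial-distribution variances.
#' @return An object of class `lorenz_noise_config`.
#' @export
lorenz_noise_config <- function(dt = 0.01, Sx = c(1, 1, 1), Sy = c(1, 1, 1),
                                x0 = c(1, 1, 1), Sx0 = c(100, 100, 100)) {
  stopifnot(dt > 0, length(Sx) == 3L, all(Sx > 0),
            length(x0) == 3L, length(Sx0) == 3L, all(Sx0 > 0))
  if (is.matrix(Sy)) {
    stopifnot(nrow(Sy) == 3L, ncol(Sy) == 3L)
  } else {
    stopifnot(length(Sy) == 3L, all(Sy > 0))
  }
  structure(list(dt = dt, Sx = as.numeric(Sx), Sy = Sy,
                 x0 = as.numeric(x0), Sx0 = as.numeric(Sx0)),
            class = "lorenz_noise_config")
}

#' Lorenz drift field
#'
#' `f(x, u; theta) = (sigma (y - x), r x - y - x z + u, x y - b z)`, the
#' classic Lorenz vector field with the control input acting on the
#' y-equation only.
#'
#' @param x state: a length-3 vector or an `N x 3` matrix.
#' @param u control input (scalar or length-N).
#' @param theta parameter vector `(sigma, r, b)`.
#' @return Drift with the same shape as `x`.
#' @export
lorenz_drift <- function(x, u, theta) {
  was_vec <- !is.matrix(x)
  x <- as_state_matrix(x, 3L)
  out <- matrix(0, nrow(x), 3L)
  out[, 1L] <- theta[1L] * (x[, 2L] - x[, 1L])
  out[, 2L] <- theta[2L] * x[, 1L] - x[, 2L] - x[, 1L] * x[, 3L] + u
  out[, 3L] <- x[, 1L] * x[, 2L] - theta[3L] * x[, 3L]
  if (was_vec) as.numeric(out) else out
}

# row-wise observation log density for a vector of variances or full cov
make_obs_logdensity <- function(Sy, obs_dim) {
  if (is.matrix(Sy)) {
    R <- chol(Sy)
    logdet <- 2 * sum(log(diag(R)))
    const <- -0.5 * (obs_dim * log(2 * pi) + logdet)
    function(resid) {
      z <- backsolve(R, t(resid), transpose = TRUE)
      const - 0.5 * colSums(z^2)
    }
  } else {
    sds <- sqrt(Sy)
    function(resid) {
      out <- 0
      for (k in seq_along(sds)) {
        out <- out + stats::dnorm(resid[, k], 0, sds[k], log = TRUE)
      }
      out
    }
  }
}

make_obs_sampler <- function(Sy, obs_dim) {
  if (is.matrix(Sy)) {
    R <- chol(Sy)
    function(n) matrix(stats::rnorm(n * obs_dim), n) %*% R
  } else {
    sds <- sqrt(Sy)
    function(n) {
      matrix(stats::rnorm(n * obs_dim), n) *
        matrix(sds, n, obs_dim, byrow = TRUE)
    }
  }
}

#' Lorenz state-space model
#'
#' The Euler-Maruyama discretisation of the controlled Lorenz system as a
#' state-space model: transition
#' `x_{t+1} ~ N(x_t + f(x_t, u_t; theta) dt, diag(Sx) dt)` and observation
#' `y_t ~ N(x_t, Sy)` (the full noisy state is observed). Estimated
#' parameters are `theta = (sigma, r, b)`; the M-step map is
#' `Lambda(A, b) = A^{-1} b` with the diagonal statistic increments of
#' [lorenz_suffstat_increment()]. After each M-step, `sigma` and `b` are
#' floored at `1e-6` to stay in the physical domain.
#'
#' @param noise a [lorenz_noise_config()].
#' @return An [new_ssm()] object.
#' @export
lorenz_ssm <- function(noise = lorenz_noise_config()) {
  stopifnot(inherits(noise, "lorenz_noise_config"))
  dt <- noise$dt
  sd_step <- sqrt(noise$Sx * dt)
  obs_logdens <- make_obs_logdensity(noise$Sy, 3L)
  obs_sample <- make_obs_sampler(noise$Sy, 3L)
  log_norm_const <- -0.5 * (3 * log(2 * pi) + sum(log(noise$Sx * dt)))
  new_ssm(
    name = "lorenz",
    state_dim = 3L, obs_dim = 3L, param_dim = 3L, suffstat_dim = 3L,
    rinit = function(n) {
      matrix(noise$x0, n, 3L, byrow = TRUE) +
        matrix(stats::rnorm(n * 3L), n) *
          matrix(sqrt(noise$Sx0), n, 3L, byrow = TRUE)
    },
    rtransition = function(x_prev, u_prev, theta) {
      n <- nrow(x_prev)
      x_prev + lorenz_drift(x_prev, u_prev, theta) * dt +
        matrix(stats::rnorm(n * 3L), n) *
          matrix(sd_step, n, 3L, byrow = TRUE)
    },
    dtransition = function(x_prev, x_curr, u_prev, theta, log = TRUE) {
      bc <- broadcast_rows(as_state_matrix(x_prev, 3L),
                           as_state_matrix(x_curr, 3L))
      a <- bc$a; cc <- bc$b
      # flat arithmetic (no dnorm / drift allocation): hot path of
      # backward ancestor sampling
      r1 <- cc[, 1L] - (a[, 1L] + theta[1L] * (a[, 2L] - a[, 1L]) * dt)
      r2 <- cc[, 2L] - (a[, 2L] + (theta[2L] * a[, 1L] - a[, 2L] -
                                     a[, 1L] * a[, 3L] + u_prev) * dt)
      r3 <- cc[, 3L] - (a[, 3L] + (a[, 1L] * a[, 2L] -
                                     theta[3L] * a[, 3L]) * dt)
      out <- log_norm_const -
        0.5 * (r1 * r1 / (noise$Sx[1L] * dt) +
                 r2 * r2 / (noise$Sx[2L] * dt) +
                 r3 * r3 / (noise$Sx[3L] * dt))
      if (log) out else exp(out)
    },
    logdensity_max = function(theta) log_norm_const,
    dobservation = function(y, x, theta, log = TRUE) {
      resid <- x - matrix(as.numeric(y), nrow(x), 3L, byrow = TRUE)
      out <- obs_logdens(resid)
      if (log) out else exp(out)
    },
    suffstat = function(x_prev, x_curr, u_prev) {
      lorenz_suffstat_rows(x_prev, x_curr, u_prev, noise)
    },
    lambda = function(A, b) {
      th <- solve(A, b)
      stats::setNames(as.numeric(th), c("sigma", "r", "b"))
    },
    project = function(theta) {
      floored <- theta[c(1L, 3L)] < 1e-6
      theta[1L] <- max(theta[1L], 1e-6)
      theta[3L] <- max(theta[3L], 1e-6)
      attr(theta, "floored") <- any(floored)
      theta
    },
    robservation = function(x, theta) x + obs_sample(nrow(x)),
    transition_mean = function(x_prev, u_prev, theta) {
      x_prev + lorenz_drift(x_prev, u_prev, theta) * dt
    },
    transition_var = noise$Sx * dt,
    theta_names = c("sigma", "r", "b")
  )
}

# vectorised sufficient-statistic increments, one row per particle pair
lorenz_suffstat_rows <- function(x_prev, x_curr, u_prev, noise) {
  dt <- noise$dt
  s <- noise$Sx
  xp <- x_prev[, 1L]; yp <- x_prev[, 2L]; zp <- x_prev[, 3L]
  xc <- x_curr[, 1L]; yc <- x_curr[, 2L]; zc <- x_curr[, 3L]
  n <- length(xp)
  A <- matrix(0, n, 9L)
  A[, 1L] <- (yp - xp)^2 / s[1L] * dt
  A[, 5L] <- xp^2 / s[2L] * dt
  A[, 9L] <- zp^2 / s[3L] * dt
  b <- cbind((yp - xp) / s[1L] * (xc - xp),
             xp / s[2L] * (yc - yp + (yp + xp * zp - u_prev) * dt),
             -zp / s[3L] * (zc - zp - xp * yp * dt))
  list(A = A, b = b)
}

#' Lorenz sufficient-statistic increment
#'
#' The per-step additive statistic `s~ = (A~, b~)` for one `(x_{tau-1},
#' x_tau)` pair: `A~` is diagonal with entries
#' `((y - x)^2 / sigma_x1^2, x^2 / sigma_x2^2, z^2 / sigma_x3^2) dt`
#' evaluated at `x_{tau-1}`, and `b~` collects the matching cross terms so
#' that `A^{-1} b` over an accumulated trajectory is the complete-data
#' maximum-likelihood estimate of `(sigma, r, b)`.
#'
#' @param x_prev,x_curr length-3 state vectors at `tau-1` and `tau`.
#' @param u_prev control input applied over the step.
#' @param noise a [lorenz_noise_config()].
#' @return A [suffstat_pair()].
#' @export
lorenz_suffstat_increment <- function(x_prev, x_curr, u_prev,
                                      noise = lorenz_noise_config()) {
  s <- lorenz_suffstat_rows(matrix(x_prev, 1L), matrix(x_curr, 1L),
                            u_prev, noise)
  suffstat_pair(matrix(s$A[1L, ], 3L, 3L), s$b[1L, ])
}

#' Lorenz M-step map
#'
#' `Lambda(S = (A, b)) = A^{-1} b`, returning `(sigma, r, b)`. Scale
#' invariant: `Lambda(c A, c b) = Lambda(A, b)` for any `c > 0`.
#'
#' @param stat a [suffstat_pair()].
#' @return Named parameter vector `(sigma, r, b)`.
#' @export
lorenz_lambda <- function(stat) {
  if (rcond(stat$A) < .Machine$double.eps) {
    stop("singular statistics: A-part is not invertible")
  }
  stats::setNames(as.numeric(solve(stat$A, stat$b)), c("sigma", "r", "b"))
}

#' Symmetric clamp
#'
#' `clamp(u) = (|u + u_lim| - |u - u_lim|) / 2`, identical to
#' `min(max(u, -u_lim), u_lim)`.
#'
#' @param u input value(s).
#' @param u_lim positive bound.
#' @return Value(s) in `[-u_lim, u_lim]`.
#' @export
clamp <- function(u, u_lim) {
  stopifnot(u_lim > 0)
  # min/max form: exactly bounded (the absolute-value form is algebraically
  # identical but can overshoot the bound by one ulp)
  pmin(pmax(u, -u_lim), u_lim)
}

#' Lorenz control configuration
#'
#' @param u_lim input bound (> 0).
#' @param sigma_u2 within-horizon proposal variance.
#' @param sigma_u0_2 initial proposal variance.
#' @param sigma_r2 acceptable-error variance of the reference likelihood.
#' @return An object of class `lorenz_control_config`.
#' @export
lorenz_control_config <- function(u_lim = 10, sigma_u2 = 1,
                                  sigma_u0_2 = 100, sigma_r2 = 1) {
  stopifnot(u_lim > 0, sigma_u2 > 0, sigma_u0_2 > 0, sigma_r2 > 0)
  structure(list(u_lim = u_lim, sigma_u2 = sigma_u2,
                 sigma_u0_2 = sigma_u0_2, sigma_r2 = sigma_r2),
            class = "lorenz_control_config")
}

#' Lorenz control transition model
#'
#' Clamped-Gaussian random walk on the input: within the horizon
#' `u_bar_{tau+1} = clamp(u_bar_tau + N(0, sigma_u2))`; the initial
#' proposal adds `N(0, sigma_u0_2)` noise to the previously applied input.
#' All outputs satisfy `|u| <= u_lim` by construction.
#'
#' @param cfg a [lorenz_control_config()].
#' @return A [control_model()].
#' @export
lorenz_control_model <- function(cfg = lorenz_control_config()) {
  control_model(
    init = function(n, u_prev) {
      clamp(u_prev + stats::rnorm(n, 0, sqrt(cfg$sigma_u0_2)), cfg$u_lim)
    },
    transition = function(u) {
      clamp(u + stats::rnorm(length(u), 0, sqrt(cfg$sigma_u2)), cfg$u_lim)
    },
    u_lim = cfg$u_lim
  )
}

#' One Runge-Kutta truth-plant step for the Lorenz system
#'
#' Classical 4th-order Runge-Kutta step of the deterministic drift with the
#' input held constant over the step, plus (optionally) additive Gaussian
#' process noise with covariance `diag(Sx) dt`, matching the noise level
#' the filter's system model assumes.
#'
#' @param x length-3 state vector.
#' @param u control input.
#' @param theta parameter vector `(sigma, r, b)`.
#' @param noise a [lorenz_noise_config()].
#' @param process_noise logical; `FALSE` gives the deterministic plant.
#' @param stream optional RNG stream.
#' @return The next state (length-3 vector).
#' @export
lorenz_truth_step_rk4 <- function(x, u, theta, noise = lorenz_noise_config(),
                                  process_noise = TRUE, stream = NULL) {
  dt <- noise$dt
  k1 <- lorenz_drift(x, u, theta)
  k2 <- lorenz_drift(x + dt / 2 * k1, u, theta)
  k3 <- lorenz_drift(x + dt / 2 * k2, u, theta)
  k4 <- lorenz_drift(x + dt * k3, u, theta)
  out <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  if (process_noise) {
    out <- out + with_stream(stream, stats::rnorm(3L)) * sqrt(noise$Sx * dt)
  }
  out
}

# Jacobian of the Lorenz drift at a state
lorenz_jacobian <- function(x, theta) {
  rbind(c(-theta[1L], theta[1L], 0),
        c(theta[2L] - x[3L], -1, -x[1L]),
        c(x[2L], x[1L], -theta[3L]))
}

#' Subcritical Hopf threshold of the Lorenz system
#'
#' The critical Rayleigh number `r_H` at which the nontrivial fixed points
#' `(+/- sqrt(b (r - 1)), +/- sqrt(b (r - 1)), r - 1)` lose linear
#' stability. The analytic method evaluates the closed form
#' `sigma (sigma + b + 3) / (sigma - b - 1)` obtained from the
#' Routh-Hurwitz condition on the characteristic polynomial of the
#' Jacobian; the numeric method root-finds the crossing of the largest
#' eigenvalue real part in `r`, independently of the closed form.
#'
#' @param sigma,b Lorenz parameters with `sigma - b - 1 > 0` (otherwise no
#'   Hopf bifurcation of this branch exists).
#' @param method `"analytic"` (default) or `"numeric"`.
#' @return The critical value `r_H`.
#' @export
hopf_threshold <- function(sigma, b, method = c("analytic", "numeric")) {
  method <- match.arg(method)
  if (sigma - b - 1 <= 0) {
    stop("no Hopf bifurcation: requires sigma - b - 1 > 0")
  }
  if (method == "analytic") {
    return(sigma * (sigma + b + 3) / (sigma - b - 1))
  }
  max_re <- function(r) {
    q <- sqrt(b * (r - 1))
    J <- lorenz_jacobian(c(q, q, r - 1), c(sigma, r, b))
    max(Re(eigen(J, only.values = TRUE)$values))
  }
  upper <- 10 * sigma * (sigma + b + 3)   # generous bracket
  stats::uniroot(max_re, lower = 1 + 1e-6, upper = upper,
                 tol = 1e-10)$root
}
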
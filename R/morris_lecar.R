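#' Morris-Lecar fixed constants
#'
#' The non-estimated constants of the two-variable conductance-based neuron
#' model: membrane capacitance, reversal potentials, the half-voltages and
#' slopes of the calcium and potassium activation curves
#' `m_inf(v) = (1 + tanh((v - V1)/V2))/2`,
#' `n_inf(v) = (1 + tanh((v - V3)/V4))/2`, and the rate scale `phi` of the
#' gating kinetics (rate factor `phi cosh((v - V3)/(2 V4))`). The default
#' profile is the standard published "homoclinic" set, in which the model
#' is bistable between a stable rest state and periodic firing (spiking
#' arises via a homoclinic bifurcation). Units: mV, ms, uF/cm^2, mS/cm^2,
#' uA/cm^2.
#'
#' @param profile constants profile name; currently `"homoclinic"`.
#' @param ... named overrides of individual constants.
#' @return An object of class `ml_constants`.
#' @export
ml_constants <- function(profile = "homoclinic", ...) {
  profile <- match.arg(profile)
  consts <- list(Cm = 20, EL = -60, ECa = 120, EK = -84,
                 V1 = -1.2, V2 = 18, V3 = 12, V4 = 17.4, phi = 0.23)
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(consts))
  if (length(unknown)) {
    stop("unknown Morris-Lecar constant(s): ",
         paste(unknown, collapse = ", "))
  }
  consts[names(overrides)] <- overrides
  stopifnot(consts$Cm > 0, consts$V2 > 0, consts$V4 > 0)
  structure(consts, class = "ml_constants")
}

#' Calcium and potassium steady-state activations
#'
#' @param v membrane potential (mV), vectorised.
#' @param consts an [ml_constants()].
#' @return Values in `(0, 1)`.
#' @export
m_inf <- function(v, consts = ml_constants()) {
  0.5 * (1 + tanh((v - consts$V1) / consts$V2))
}

#' @rdname m_inf
#' @export
n_inf <- function(v, consts = ml_constants()) {
  0.5 * (1 + tanh((v - consts$V3) / consts$V4))
}

#' Morris-Lecar drift field
#'
#' `dv/dt = -(gL (v - EL) + gCa m_inf(v) (v - ECa) + gK n (v - EK))/Cm
#'  + I_net/Cm`;
#' `dn/dt = -phi cosh((v - V3)/(2 V4)) (n - n_inf(v))`.
#'
#' @param x state `(v, n)`: a length-2 vector or `N x 2` matrix.
#' @param I_net net input current `u + I_inj` (scalar or length-N).
#' @param theta conductances `(gL, gCa, gK)`.
#' @param consts an [ml_constants()].
#' @return Drift with the same shape as `x`.
#' @export
ml_drift <- function(x, I_net, theta, consts = ml_constants()) {
  was_vec <- !is.matrix(x)
  x <- as_state_matrix(x, 2L)
  v <- x[, 1L]; n <- x[, 2L]
  I_ion <- theta[1L] * (v - consts$EL) +
    theta[2L] * m_inf(v, consts) * (v - consts$ECa) +
    theta[3L] * n * (v - consts$EK)
  out <- matrix(0, length(v), 2L)
  out[, 1L] <- (-I_ion + I_net) / consts$Cm
  out[, 2L] <- -consts$phi * cosh((v - consts$V3) / (2 * consts$V4)) *
    (n - n_inf(v, consts))
  if (was_vec) as.numeric(out) else out
}

#' Morris-Lecar noise and discretisation configuration
#'
#' @param dt time step (ms).
#' @param Sx length-2 vector of system-noise variances `(sigma_v^2,
#'   sigma_n^2)`; one-step transition covariance is `diag(Sx) dt`.
#' @param sy2 observation-noise variance of the membrane potential.
#' @param v0_mean,v0_var Gaussian initial distribution of `v` (default mean
#'   `(2/3) EL = -40` mV); `n` starts uniform on `[0, 1]`.
#' @return An object of class `ml_noise_config`.
#' @export
ml_noise_config <- function(dt = 0.1, Sx = c(0.1^2, 0.001^2), sy2 = 0.1^2,
                            v0_mean = -40, v0_var = 100) {
  stopifnot(dt > 0, length(Sx) == 2L, all(Sx > 0), sy2 > 0, v0_var > 0)
  structure(list(dt = dt, Sx = as.numeric(Sx), sy2 = sy2,
                 v0_mean = v0_mean, v0_var = v0_var),
            class = "ml_noise_config")
}

#' Morris-Lecar state-space model
#'
#' Euler-Maruyama discretisation of the Morris-Lecar neuron as a
#' state-space model with state `(v, n)`, net input current as the control,
#' and only the membrane potential observed:
#' `y_t ~ N(v_t, sy2)`. Estimated parameters are the maximal conductances
#' `theta = (gL, gCa, gK)`; the M-step map is `Lambda(A, b) = -A^{-1} b`
#' with the Gram-matrix increments of [ml_suffstat_increment()].
#' Conductances are floored at `1e-6` after each M-step.
#'
#' @param consts an [ml_constants()].
#' @param noise an [ml_noise_config()].
#' @return An [new_ssm()] object.
#' @export
ml_ssm <- function(consts = ml_constants(), noise = ml_noise_config()) {
  stopifnot(inherits(consts, "ml_constants"),
            inherits(noise, "ml_noise_config"))
  dt <- noise$dt
  sd_step <- sqrt(noise$Sx * dt)
  sd_obs <- sqrt(noise$sy2)
  log_norm_const <- -0.5 * (2 * log(2 * pi) + sum(log(noise$Sx * dt)))
  new_ssm(
    name = "morris-lecar",
    state_dim = 2L, obs_dim = 1L, param_dim = 3L, suffstat_dim = 3L,
    rinit = function(n) {
      cbind(stats::rnorm(n, noise$v0_mean, sqrt(noise$v0_var)),
            stats::runif(n))
    },
    rtransition = function(x_prev, u_prev, theta) {
      n <- nrow(x_prev)
      x_prev + ml_drift(x_prev, u_prev, theta, consts) * dt +
        matrix(stats::rnorm(n * 2L), n) *
          matrix(sd_step, n, 2L, byrow = TRUE)
    },
    dtransition = function(x_prev, x_curr, u_prev, theta, log = TRUE) {
      bc <- broadcast_rows(as_state_matrix(x_prev, 2L),
                           as_state_matrix(x_curr, 2L))
      v <- bc$a[, 1L]; n <- bc$a[, 2L]
      I_ion <- theta[1L] * (v - consts$EL) +
        theta[2L] * m_inf(v, consts) * (v - consts$ECa) +
        theta[3L] * n * (v - consts$EK)
      r1 <- bc$b[, 1L] - (v + (u_prev - I_ion) / consts$Cm * dt)
      r2 <- bc$b[, 2L] -
        (n - consts$phi * cosh((v - consts$V3) / (2 * consts$V4)) *
           (n - n_inf(v, consts)) * dt)
      out <- log_norm_const -
        0.5 * (r1 * r1 / (noise$Sx[1L] * dt) +
                 r2 * r2 / (noise$Sx[2L] * dt))
      if (log) out else exp(out)
    },
    logdensity_max = function(theta) log_norm_const,
    dobservation = function(y, x, theta, log = TRUE) {
      out <- stats::dnorm(y[1L], x[, 1L], sd_obs, log = TRUE)
      if (log) out else exp(out)
    },
    suffstat = function(x_prev, x_curr, u_prev) {
      ml_suffstat_rows(x_prev, x_curr, u_prev, consts, noise)
    },
    lambda = function(A, b) {
      stats::setNames(as.numeric(-solve(A, b)), c("gL", "gCa", "gK"))
    },
    project = function(theta) {
      floored <- theta < 1e-6
      theta <- pmax(theta, 1e-6)
      attr(theta, "floored") <- any(floored)
      theta
    },
    robservation = function(x, theta) {
      matrix(x[, 1L] + sd_obs * stats::rnorm(nrow(x)), ncol = 1L)
    },
    transition_mean = function(x_prev, u_prev, theta) {
      x_prev + ml_drift(x_prev, u_prev, theta, consts) * dt
    },
    transition_var = noise$Sx * dt,
    theta_names = c("gL", "gCa", "gK")
  )
}

# ion-channel driving potentials, one row per particle
ml_vion <- function(x, consts) {
  v <- x[, 1L]; n <- x[, 2L]
  cbind(v - consts$EL,
        m_inf(v, consts) * (v - consts$ECa),
        n * (v - consts$EK))
}

# vectorised sufficient-statistic increments
ml_suffstat_rows <- function(x_prev, x_curr, u_prev, consts, noise) {
  cdt <- noise$dt / consts$Cm
  V <- ml_vion(x_prev, consts)
  n <- nrow(V)
  A <- matrix(0, n, 9L)
  idx <- 1L
  for (j in 1:3) {
    for (i in 1:3) {
      A[, idx] <- cdt^2 * V[, i] * V[, j]
      idx <- idx + 1L
    }
  }
  resid <- cdt * (x_curr[, 1L] - x_prev[, 1L] - cdt * u_prev)
  b <- resid * V
  list(A = A, b = b)
}

#' Morris-Lecar sufficient-statistic increment
#'
#' The per-step additive statistic for one `(x_{tau-1}, x_tau)` pair:
#' with the ion-channel driving potentials
#' `V_ion(x) = (v - EL, m_inf(v)(v - ECa), n (v - EK))` evaluated at the
#' earlier state, `A~ = (dt/Cm)^2 V_ion V_ion^T` (rank-1, positive
#' semidefinite) and
#' `b~ = (dt/Cm)(v_tau - v_{tau-1} - (dt/Cm) I_{tau-1}) V_ion(x_{tau-1})`,
#' so that `-A^{-1} b` over a trajectory is the complete-data
#' maximum-likelihood estimate of the conductances.
#'
#' @param x_prev,x_curr length-2 states `(v, n)` at `tau-1` and `tau`.
#' @param I_net_prev net input current applied over the step.
#' @param consts an [ml_constants()].
#' @param noise an [ml_noise_config()].
#' @return A [suffstat_pair()].
#' @export
ml_suffstat_increment <- function(x_prev, x_curr, I_net_prev,
                                  consts = ml_constants(),
                                  noise = ml_noise_config()) {
  s <- ml_suffstat_rows(matrix(x_prev, 1L), matrix(x_curr, 1L),
                        I_net_prev, consts, noise)
  suffstat_pair(matrix(s$A[1L, ], 3L, 3L), s$b[1L, ])
}

#' Morris-Lecar M-step map
#'
#' `Lambda(S = (A, b)) = -A^{-1} b`, returning `(gL, gCa, gK)`; scale
#' invariant in `(A, b)`.
#'
#' @param stat a [suffstat_pair()].
#' @return Named conductance vector.
#' @export
ml_lambda <- function(stat) {
  if (rcond(stat$A) < .Machine$double.eps) {
    stop("singular statistics: A-part is not invertible")
  }
  stats::setNames(as.numeric(-solve(stat$A, stat$b)), c("gL", "gCa", "gK"))
}

#' Morris-Lecar control configuration
#'
#' @param I_lim net-current bound (> 0): the applied input must satisfy
#'   `|u_t + I_inj_t| <= I_lim`.
#' @param sigma_I2 within-horizon proposal variance.
#' @param sigma_I0_2 initial proposal variance.
#' @param sigma_r2 acceptable-error variance of the reference likelihood.
#' @return An object of class `ml_control_config`.
#' @export
ml_control_config <- function(I_lim = 150, sigma_I2 = 1, sigma_I0_2 = 100,
                              sigma_r2 = 0.1^2) {
  stopifnot(I_lim > 0, sigma_I2 > 0, sigma_I0_2 > 0, sigma_r2 > 0)
  structure(list(I_lim = I_lim, sigma_I2 = sigma_I2,
                 sigma_I0_2 = sigma_I0_2, sigma_r2 = sigma_r2),
            class = "ml_control_config")
}

#' Morris-Lecar control transition model
#'
#' Clamped random walk on the *net* current: the injected current observed
#' at the decision time is frozen over the horizon, and
#' `u_bar_{tau+1} = clamp(u_bar_tau + I_inj + N(0, sigma_I2)) - I_inj`, so
#' the net current `u + I_inj` always satisfies the bound. With
#' `I_inj = 0` this reduces to the plain clamped random walk.
#'
#' @param cfg an [ml_control_config()].
#' @param I_inj injected current at the decision time (frozen within the
#'   horizon).
#' @return A [control_model()].
#' @export
ml_control_model <- function(cfg = ml_control_config(), I_inj = 0) {
  control_model(
    init = function(n, u_prev) {
      clamp(u_prev + I_inj + stats::rnorm(n, 0, sqrt(cfg$sigma_I0_2)),
            cfg$I_lim) - I_inj
    },
    transition = function(u) {
      clamp(u + I_inj + stats::rnorm(length(u), 0, sqrt(cfg$sigma_I2)),
            cfg$I_lim) - I_inj
    },
    u_lim = cfg$I_lim
  )
}

#' One Euler truth-plant step for the Morris-Lecar neuron
#'
#' Euler step of [ml_drift()] plus (optionally) additive Gaussian process
#' noise with covariance `diag(Sx) dt`. The channel variable is not
#' artificially clipped; the dynamics keep it near `[0, 1]`.
#'
#' @param x length-2 state `(v, n)`.
#' @param I_net net input current.
#' @param theta conductances `(gL, gCa, gK)`.
#' @param consts an [ml_constants()].
#' @param noise an [ml_noise_config()].
#' @param process_noise logical; `FALSE` gives the deterministic plant.
#' @param stream optional RNG stream.
#' @return The next state.
#' @export
ml_truth_step_euler <- function(x, I_net, theta, consts = ml_constants(),
                                noise = ml_noise_config(),
                                process_noise = TRUE, stream = NULL) {
  out <- x + ml_drift(x, I_net, theta, consts) * noise$dt
  if (process_noise) {
    out <- out + with_stream(stream, stats::rnorm(2L)) * sqrt(noise$Sx * noise$dt)
  }
  out
}

#' Default drive schedule for the reference trajectory
#'
#' Alternating firing and resting intervals (in the model's time units):
#' a supra-threshold drive on `[0, 250]` and `[500, 750]`, and a resting
#' drive on `[250, 500]` and `[750, 1000]`. The drive levels sit inside the
#' bistable range of the homoclinic constants profile.
#'
#' @param spike_I drive current during firing intervals.
#' @param rest_I drive current during resting intervals.
#' @return A data frame with columns `from`, `to`, `I`.
#' @export
ml_reference_schedule <- function(spike_I = 45, rest_I = 0) {
  data.frame(from = c(0, 250, 500, 750),
             to = c(250, 500, 750, 1000),
             I = c(spike_I, rest_I, spike_I, rest_I))
}

#' Generate the Morris-Lecar reference trajectory
#'
#' Integrates the deterministic true model under a scheduled drive current
#' and returns the membrane-potential trace as the reference `r_t`. The
#' schedule must cover the whole run without gaps.
#'
#' @param consts an [ml_constants()].
#' @param theta_true true conductances.
#' @param schedule a data frame of `(from, to, I)` rows, in time units.
#' @param dt time step.
#' @param n_steps number of steps to generate.
#' @param x_init initial state; defaults to the near-rest state
#'   `(EL, n_inf(EL))`.
#' @return Numeric vector `r_t` of length `n_steps`.
#' @export
generate_reference <- function(consts = ml_constants(),
                               theta_true = c(2, 4, 8),
                               schedule = ml_reference_schedule(),
                               dt = 0.1, n_steps = 10000L,
                               x_init = NULL) {
  if (is.null(x_init)) {
    x_init <- c(consts$EL, n_inf(consts$EL, consts))
  }
  times <- (seq_len(n_steps) - 1L) * dt
  I_of_t <- rep(NA_real_, n_steps)
  for (k in seq_len(nrow(schedule))) {
    sel <- times >= schedule$from[k] & times < schedule$to[k]
    I_of_t[sel] <- schedule$I[k]
  }
  # last interval is closed on the right
  at_end <- times == schedule$to[nrow(schedule)]
  I_of_t[at_end] <- schedule$I[nrow(schedule)]
  if (anyNA(I_of_t)) {
    stop("drive schedule does not cover the run: gap at t' = ",
         times[which(is.na(I_of_t))[1L]])
  }
  noise <- ml_noise_config(dt = dt)
  r <- numeric(n_steps)
  x <- x_init
  for (t in seq_len(n_steps)) {
    x <- ml_truth_step_euler(x, I_of_t[t], theta_true, consts, noise,
                             process_noise = FALSE)
    r[t] <- x[1L]
  }
  r
}
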
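#' Lorenz closed-loop experiment configuration
#'
#' Defaults reproduce the chaos-stabilisation study: true parameters
#' `(sigma, r, b) = (10, 28, 8/3)`, time step 0.01, unit system and
#' observation noise variances, `N = 1000` particles with resampling rate
#' `alpha = 0.8`, backward-sampling rate `beta = 0.7`, decay `gamma_t =
#' 1/t`, burn-in 100 steps, horizon 10 steps, input bound 10, control
#' enabled from `t' = 5` (step 500), and a run of 3000 steps
#' (`t'` in `[0, 30]`). The reference is the constant unstable fixed point
#' `y_f = sqrt(b (r - 1))` of the y-coordinate.
#'
#' @param theta_true true `(sigma, r, b)`.
#' @param theta0 initial parameter guess held during burn-in.
#' @param noise a [lorenz_noise_config()].
#' @param control a [lorenz_control_config()].
#' @param N,alpha particle count and resampling threshold rate.
#' @param beta backward-sampling threshold rate.
#' @param gamma_exponent decay exponent of `gamma_t = t^-exponent`.
#' @param T_burnIn parameter-update burn-in (steps).
#' @param T_H horizon length (steps).
#' @param n_steps run length (steps).
#' @param t_control_on first step at which control is applied.
#' @param seed root seed for the four RNG streams.
#' @param truth_noise logical; `FALSE` makes the truth plant deterministic.
#' @param control_enabled logical master switch for the controller.
#' @param y_f reference value; defaults to `sqrt(b (r - 1))` of the true
#'   parameters.
#' @return An object of class `experiment_config`.
#' @export
lorenz_experiment <- function(theta_true = c(10, 28, 8 / 3),
                              theta0 = c(5, 20, 1.5),
                              noise = lorenz_noise_config(),
                              control = lorenz_control_config(),
                              N = 1000, alpha = 0.8, beta = 0.7,
                              gamma_exponent = 1, T_burnIn = 100,
                              T_H = 10, n_steps = 3000,
                              t_control_on = 500, seed = 1,
                              truth_noise = TRUE, control_enabled = TRUE,
                              y_f = NULL) {
  if (is.null(y_f)) y_f <- sqrt(theta_true[3L] * (theta_true[2L] - 1))
  cfg <- structure(
    list(model = "lorenz", theta_true = theta_true, theta0 = theta0,
         noise = noise, control = control, N = N, alpha = alpha,
         beta = beta, gamma_exponent = gamma_exponent,
         T_burnIn = T_burnIn, T_H = T_H, n_steps = n_steps,
         t_control_on = t_control_on, seed = seed,
         truth_noise = truth_noise, control_enabled = control_enabled,
         y_f = y_f),
    class = "experiment_config")
  validate_experiment(cfg)
  cfg
}

#' Morris-Lecar closed-loop experiment configuration
#'
#' Defaults reproduce the neuron-steering study: homoclinic constants with
#' true conductances `(gL, gCa, gK) = (2, 4, 8)`, time step 0.1 ms, system
#' noise `diag(0.1^2, 0.001^2)`, observation noise `0.1^2` on the membrane
#' potential only, `N = 1000`, `alpha = 0.8`, `beta = 0.7`,
#' `gamma_t = 1/t`, burn-in 1000 steps, horizon 10, net-current bound 150,
#' and a 10000-step run (`t'` in `[0, 1000]` ms) tracking a reference
#' trajectory that alternates firing and resting intervals.
#'
#' @param theta_true true conductances `(gL, gCa, gK)`.
#' @param theta0 initial conductance guess.
#' @param consts an [ml_constants()].
#' @param noise an [ml_noise_config()].
#' @param control an [ml_control_config()].
#' @param schedule reference drive schedule ([ml_reference_schedule()]).
#' @param I_inj injected-current series: a scalar (held constant) or a
#'   vector of length `n_steps + 1`.
#' @param reference optional pre-generated reference series; generated from
#'   the schedule when `NULL`.
#' @inheritParams lorenz_experiment
#' @return An object of class `experiment_config`.
#' @export
ml_experiment <- function(theta_true = c(2, 4, 8), theta0 = c(1, 2, 4),
                          consts = ml_constants(),
                          noise = ml_noise_config(),
                          control = ml_control_config(),
                          schedule = ml_reference_schedule(),
                          I_inj = 0,
                          N = 1000, alpha = 0.8, beta = 0.7,
                          gamma_exponent = 1, T_burnIn = 1000,
                          T_H = 10, n_steps = 10000,
                          t_control_on = 1, seed = 1,
                          truth_noise = TRUE, control_enabled = TRUE,
                          reference = NULL) {
  cfg <- structure(
    list(model = "morris_lecar", theta_true = theta_true, theta0 = theta0,
         consts = consts, noise = noise, control = control,
         schedule = schedule, I_inj = I_inj, N = N, alpha = alpha,
         beta = beta, gamma_exponent = gamma_exponent,
         T_burnIn = T_burnIn, T_H = T_H, n_steps = n_steps,
         t_control_on = t_control_on, seed = seed,
         truth_noise = truth_noise, control_enabled = control_enabled,
         reference = reference),
    class = "experiment_config")
  validate_experiment(cfg)
  cfg
}

validate_experiment <- function(cfg) {
  stopifnot(cfg$N >= 1, cfg$alpha >= 0, cfg$alpha <= 1,
            cfg$beta >= 0, cfg$beta <= 1,
            cfg$T_H >= 1, cfg$n_steps >= 1, cfg$T_burnIn >= 0,
            cfg$t_control_on >= 1)
  if (cfg$n_steps <= cfg$T_burnIn) {
    stop("run length n_steps must exceed the burn-in T_burnIn")
  }
  invisible(cfg)
}

#' @export
print.experiment_config <- function(x, ...) {
  cat("<experiment config: ", x$model, ">\n", sep = "")
  cat("  theta_true = (", paste(signif(x$theta_true, 5), collapse = ", "),
      "), theta0 = (", paste(signif(x$theta0, 5), collapse = ", "), ")\n",
      sep = "")
  cat("  N = ", x$N, ", alpha = ", x$alpha, ", beta = ", x$beta,
      ", T_burnIn = ", x$T_burnIn, ", T_H = ", x$T_H, "\n", sep = "")
  cat("  n_steps = ", x$n_steps, " (dt = ", x$noise$dt,
      "), control from step ", x$t_control_on,
      if (!x$control_enabled) " [disabled]" else "", ", seed = ", x$seed,
      "\n", sep = "")
  invisible(x)
}

# assemble the model-specific pieces of a closed-loop run
build_experiment <- function(cfg) {
  if (cfg$model == "lorenz") {
    model <- lorenz_ssm(cfg$noise)
    ref <- reference_model(select = function(x) x[, 2L],
                           sigma_r2 = cfg$control$sigma_r2,
                           T_H = cfg$T_H)
    ref_series <- rep(cfg$y_f, cfg$n_steps + cfg$T_H)
    ctm <- lorenz_control_model(cfg$control)
    list(model = model, ref = ref, ref_series = ref_series,
         ctm_for = function(I_inj) ctm,
         I_inj = rep(0, cfg$n_steps + 1L),
         truth_step = function(x, u, stream) {
           lorenz_truth_step_rk4(x, u, cfg$theta_true, cfg$noise,
                                 process_noise = cfg$truth_noise,
                                 stream = stream)
         },
         u_limit = cfg$control$u_lim,
         state_names = c("x", "y", "z"), obs_names = c("yx", "yy", "yz"))
  } else if (cfg$model == "morris_lecar") {
    model <- ml_ssm(cfg$consts, cfg$noise)
    ref <- reference_model(select = function(x) x[, 1L],
                           sigma_r2 = cfg$control$sigma_r2,
                           T_H = cfg$T_H)
    r <- cfg$reference
    if (is.null(r)) {
      r <- generate_reference(cfg$consts, cfg$theta_true, cfg$schedule,
                              cfg$noise$dt, cfg$n_steps)
    }
    if (length(r) < cfg$n_steps) {
      stop("reference series shorter than the run (", length(r), " < ",
           cfg$n_steps, ")")
    }
    ref_series <- c(r, rep(r[length(r)], cfg$T_H))[
      seq_len(cfg$n_steps + cfg$T_H)]
    I_inj <- cfg$I_inj
    if (length(I_inj) == 1L) I_inj <- rep(I_inj, cfg$n_steps + 1L)
    if (length(I_inj) < cfg$n_steps + 1L) {
      stop("I_inj series must cover n_steps + 1 values")
    }
    list(model = model, ref = ref, ref_series = ref_series,
         ctm_for = function(I_now) ml_control_model(cfg$control, I_now),
         I_inj = I_inj,
         truth_step = function(x, u, stream) {
           ml_truth_step_euler(x, u, cfg$theta_true, cfg$consts, cfg$noise,
                               process_noise = cfg$truth_noise,
                               stream = stream)
         },
         u_limit = cfg$control$I_lim,
         state_names = c("v", "n"), obs_names = "y")
  } else {
    stop("unknown model: ", cfg$model)
  }
}

#' Simulate the truth plant alone
#'
#' Integrates the true dynamics (with the configured process noise) and
#' emits noisy observations, with the control input fixed at zero,
#' consuming exactly the truth RNG stream a closed-loop run with the same
#' seed would consume. Useful for uncontrolled baselines.
#'
#' @param cfg an [lorenz_experiment()] / [ml_experiment()] configuration.
#' @return A data frame with time columns, true state and observations.
#' @export
simulate_truth <- function(cfg) {
  parts <- build_experiment(cfg)
  model <- parts$model
  streams <- rng_streams(cfg$seed, 4L,
                         c("truth", "filter", "backward", "control"))
  d <- model$state_dim
  dy <- model$obs_dim
  x_true <- with_stream(streams$truth, model$rinit(1L))[1L, ]
  X <- matrix(NA_real_, cfg$n_steps, d)
  Y <- matrix(NA_real_, cfg$n_steps, dy)
  for (t in seq_len(cfg$n_steps)) {
    net <- parts$I_inj[t]
    x_true <- parts$truth_step(x_true, net, streams$truth)
    Y[t, ] <- with_stream(streams$truth,
                          model$robservation(matrix(x_true, 1L),
                                             cfg$theta_true))[1L, ]
    X[t, ] <- x_true
  }
  out <- data.frame(t = seq_len(cfg$n_steps),
                    t_prime = seq_len(cfg$n_steps) * cfg$noise$dt)
  for (k in seq_len(d)) out[[paste0(parts$state_names[k], "_true")]] <- X[, k]
  for (k in seq_len(dy)) out[[paste0("obs_", parts$obs_names[k])]] <- Y[, k]
  out
}

#' Run the full closed loop
#'
#' Executes the complete estimation-and-control loop. Per step `t`:
#' the truth plant advances under the previously applied input and emits a
#' noisy observation; the state particle filter assimilates it with the
#' current parameter estimate; the AdaSmooth statistics are updated (with
#' adaptive backward ancestor sampling) and the online M-step refreshes the
#' parameter estimate; if control is enabled, the control particle filter
#' solves the horizon filtering problem and the applied input is extracted.
#' Four independent RNG streams (truth, state filter, backward sampling,
#' control filter) are derived from the root seed, so any component can be
#' switched off without perturbing the others.
#'
#' @param cfg an [lorenz_experiment()] / [ml_experiment()] configuration.
#' @return An object of class `run_result`: a list with data frames
#'   `states`, `params`, `control`, the `config`, and a `summary` list
#'   (final parameter estimates, backward-sampling count, constraint
#'   violations).
#' @export
run_closed_loop <- function(cfg) {
  parts <- build_experiment(cfg)
  model <- parts$model
  streams <- rng_streams(cfg$seed, 4L,
                         c("truth", "filter", "backward", "control"))
  pfc <- pf_config(cfg$N, cfg$alpha)
  gexp <- cfg$gamma_exponent
  smooth <- smoothing_state(model, cfg$N, cfg$beta,
                            gamma = function(t) decay_rate(t, gexp),
                            T_burnIn = cfg$T_burnIn)
  ens <- init_particles(model, pfc, streams$filter)
  theta <- cfg$theta0
  x_true <- with_stream(streams$truth, model$rinit(1L))[1L, ]
  u_prev <- 0
  d <- model$state_dim
  dy <- model$obs_dim
  p <- model$param_dim
  n <- cfg$n_steps
  X_true <- matrix(NA_real_, n, d)
  X_est <- matrix(NA_real_, n, d)
  Y_obs <- matrix(NA_real_, n, dy)
  Theta <- matrix(NA_real_, n, p)
  diag_ess <- numeric(n)
  diag_div <- integer(n)
  diag_res <- logical(n)
  diag_bwd <- logical(n)
  diag_flo <- logical(n)
  U <- numeric(n)
  step_stage <- ""
  for (t in seq_len(n)) {
    res <- tryCatch({
      step_stage <- "truth"
      net_prev <- u_prev + parts$I_inj[t]
      x_true <- parts$truth_step(x_true, net_prev, streams$truth)
      y <- with_stream(streams$truth,
                       model$robservation(matrix(x_true, 1L),
                                          cfg$theta_true))[1L, ]
      step_stage <- "state filter"
      ens_new <- pf_step(ens, y, net_prev, model, theta, pfc,
                         streams$filter)
      step_stage <- "smoothing"
      smooth <- update_kappa(smooth, ens, ens_new, net_prev, model, theta,
                             streams$backward)
      step_stage <- "M-step"
      stat <- smoothed_statistic(ens_new, smooth)
      theta_new <- em_update(stat, t, model, smooth, theta)
      step_stage <- "control"
      if (cfg$control_enabled && t >= cfg$t_control_on) {
        ctm <- parts$ctm_for(parts$I_inj[t + 1L])
        seg <- parts$ref_series[t:(t + cfg$T_H)]
        u_t <- mpc_control(ens_new, u_prev, seg, model, ctm, parts$ref,
                           theta_new, pfc, streams$control)
      } else {
        u_t <- 0
      }
      list(ens = ens_new, theta = theta_new, y = y, u = u_t)
    }, error = function(e) {
      stop("closed-loop failure at time index ", t, " (stage: ",
           step_stage, "): ", conditionMessage(e), call. = FALSE)
    })
    ens <- res$ens
    theta <- res$theta
    X_true[t, ] <- x_true
    X_est[t, ] <- filtering_mean(ens)
    Y_obs[t, ] <- res$y
    Theta[t, ] <- as.numeric(theta)
    diag_ess[t] <- effective_sample_size(ens$w)
    diag_div[t] <- smooth$diversity
    diag_res[t] <- ens$resampled
    diag_bwd[t] <- smooth$backward
    diag_flo[t] <- isTRUE(attr(theta, "floored"))
    U[t] <- res$u
    u_prev <- res$u
  }
  tp <- seq_len(n) * cfg$noise$dt
  states <- data.frame(t = seq_len(n), t_prime = tp)
  for (k in seq_len(d)) {
    states[[paste0(parts$state_names[k], "_true")]] <- X_true[, k]
  }
  for (k in seq_len(d)) {
    states[[paste0(parts$state_names[k], "_est")]] <- X_est[, k]
  }
  for (k in seq_len(dy)) {
    states[[paste0("obs_", parts$obs_names[k])]] <- Y_obs[, k]
  }
  params <- data.frame(t = seq_len(n), t_prime = tp)
  nm <- model$theta_names %||% paste0("theta", seq_len(p))
  for (k in seq_len(p)) params[[nm[k]]] <- Theta[, k]
  params$ess <- diag_ess
  params$diversity <- diag_div
  params$resampled <- diag_res
  params$backward <- diag_bwd
  params$floored <- diag_flo
  ctrl <- data.frame(t = seq_len(n), t_prime = tp, u = U,
                     I_inj = parts$I_inj[seq_len(n) + 1L],
                     net = U + parts$I_inj[seq_len(n) + 1L],
                     limit = parts$u_limit)
  violations <- sum(abs(ctrl$net) > parts$u_limit + 1e-9)
  structure(
    list(config = cfg, states = states, params = params, control = ctrl,
         summary = list(
           theta_final = stats::setNames(as.numeric(theta), nm),
           theta_true = cfg$theta_true,
           n_backward = smooth$n_backward,
           constraint_violations = violations,
           n_steps = n)),
    class = "run_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.run_result <- function(x, ...) {
  cat("<closed-loop run: ", x$config$model, ", ", x$summary$n_steps,
      " steps>\n", sep = "")
  cat("  final parameter estimate:\n")
  print(signif(x$summary$theta_final, 5))
  cat("  true parameters: (",
      paste(signif(x$summary$theta_true, 5), collapse = ", "), ")\n",
      sep = "")
  cat("  backward-sampling events: ", x$summary$n_backward,
      "; constraint violations: ", x$summary$constraint_violations, "\n",
      sep = "")
  invisible(x)
}

#' Filter and learn parameters from a supplied observation series
#'
#' Runs the state particle filter and the AdaSmooth online EM on an
#' externally supplied observation series (no truth plant, no control).
#'
#' @param cfg an experiment configuration (provides the model, PF and EM
#'   settings).
#' @param y observations: a numeric matrix with one row per time step (or a
#'   vector for scalar observations).
#' @param u applied inputs per step (scalar or vector of `nrow(y)`).
#' @return A `run_result`-like list with `params` and `states`
#'   (estimates only) data frames.
#' @export
run_estimation <- function(cfg, y, u = 0) {
  parts <- build_experiment(cfg)
  model <- parts$model
  y <- if (is.matrix(y)) y else matrix(y, ncol = model$obs_dim)
  n <- nrow(y)
  if (length(u) == 1L) u <- rep(u, n)
  stopifnot(length(u) == n)
  streams <- rng_streams(cfg$seed, 4L,
                         c("truth", "filter", "backward", "control"))
  pfc <- pf_config(cfg$N, cfg$alpha)
  gexp <- cfg$gamma_exponent
  smooth <- smoothing_state(model, cfg$N, cfg$beta,
                            gamma = function(t) decay_rate(t, gexp),
                            T_burnIn = cfg$T_burnIn)
  ens <- init_particles(model, pfc, streams$filter)
  theta <- cfg$theta0
  p <- model$param_dim
  Theta <- matrix(NA_real_, n, p)
  X_est <- matrix(NA_real_, n, model$state_dim)
  for (t in seq_len(n)) {
    u_prev <- if (t == 1L) 0 else u[t - 1L]
    ens_new <- pf_step(ens, y[t, ], u_prev, model, theta, pfc,
                       streams$filter)
    smooth <- update_kappa(smooth, ens, ens_new, u_prev, model, theta,
                           streams$backward)
    stat <- smoothed_statistic(ens_new, smooth)
    theta <- em_update(stat, t, model, smooth, theta)
    Theta[t, ] <- as.numeric(theta)
    X_est[t, ] <- filtering_mean(ens_new)
    ens <- ens_new
  }
  nm <- model$theta_names %||% paste0("theta", seq_len(p))
  params <- data.frame(t = seq_len(n))
  for (k in seq_len(p)) params[[nm[k]]] <- Theta[, k]
  states <- data.frame(t = seq_len(n))
  for (k in seq_len(model$state_dim)) {
    states[[paste0(parts$state_names[k], "_est")]] <- X_est[, k]
  }
  list(params = params, states = states,
       theta_final = stats::setNames(as.numeric(theta), nm))
}
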
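# Flat YAML configuration keys understood per model. Values are mapped onto
# the experiment constructors; vectors are written as YAML sequences.
lorenz_config_keys <- c(
  "model", "sigma", "r", "b", "sigma0", "r0", "b0", "dt", "Sx", "Sy", "x0",
  "Sx0", "N", "alpha", "beta", "gamma", "T_burnIn", "T_H", "u_lim",
  "sigma_u2", "sigma_u0_2", "sigma_r2", "t_control_on", "t_end", "n_steps",
  "seed", "truth_noise", "control_enabled", "y_f")
ml_config_keys <- c(
  "model", "gL", "gCa", "gK", "gL0", "gCa0", "gK0", "dt", "Sv2", "Sn2",
  "sy2", "N", "alpha", "beta", "gamma", "T_burnIn", "T_H", "I_lim",
  "sigma_I2", "sigma_I0_2", "sigma_r2", "schedule", "I_inj_csv",
  "t_control_on", "t_end", "n_steps", "seed", "truth_noise",
  "control_enabled", "constants")

#' Load an experiment configuration from a YAML file
#'
#' Reads a flat structured-text configuration and builds the matching
#' [lorenz_experiment()] or [ml_experiment()]. Unknown keys and missing
#' required keys are reported by name. Either `n_steps` or `t_end` (run
#' duration in time units, converted via `dt`) may set the run length.
#'
#' @param path path to a YAML file with at least a `model` key
#'   (`"lorenz"` or `"morris_lecar"`).
#' @return An `experiment_config`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  # YAML 1.1 parses an unquoted key `N` as the boolean FALSE; map it back
  names(raw)[names(raw) == "FALSE"] <- "N"
  if (is.null(raw$model)) stop("missing required config key: model")
  model <- raw$model
  keys <- switch(model,
                 lorenz = lorenz_config_keys,
                 morris_lecar = ml_config_keys,
                 stop("unknown model in config: ", model))
  unknown <- setdiff(names(raw), keys)
  if (length(unknown)) {
    stop("unknown config key(s) for model '", model, "': ",
         paste(unknown, collapse = ", "))
  }
  pick <- function(key, default) if (is.null(raw[[key]])) default else raw[[key]]
  n_steps <- raw$n_steps
  if (is.null(n_steps) && !is.null(raw$t_end)) {
    n_steps <- round(raw$t_end / pick("dt", if (model == "lorenz") 0.01 else 0.1))
  }
  if (model == "lorenz") {
    noise <- lorenz_noise_config(
      dt = pick("dt", 0.01), Sx = unlist(pick("Sx", c(1, 1, 1))),
      Sy = unlist(pick("Sy", c(1, 1, 1))),
      x0 = unlist(pick("x0", c(1, 1, 1))),
      Sx0 = unlist(pick("Sx0", c(100, 100, 100))))
    ctrl <- lorenz_control_config(
      u_lim = pick("u_lim", 10), sigma_u2 = pick("sigma_u2", 1),
      sigma_u0_2 = pick("sigma_u0_2", 100),
      sigma_r2 = pick("sigma_r2", 1))
    lorenz_experiment(
      theta_true = c(pick("sigma", 10), pick("r", 28), pick("b", 8 / 3)),
      theta0 = c(pick("sigma0", 5), pick("r0", 20), pick("b0", 1.5)),
      noise = noise, control = ctrl,
      N = pick("N", 1000), alpha = pick("alpha", 0.8),
      beta = pick("beta", 0.7), gamma_exponent = pick("gamma", 1),
      T_burnIn = pick("T_burnIn", 100), T_H = pick("T_H", 10),
      n_steps = n_steps %||% 3000,
      t_control_on = pick("t_control_on", 500), seed = pick("seed", 1),
      truth_noise = pick("truth_noise", TRUE),
      control_enabled = pick("control_enabled", TRUE),
      y_f = raw$y_f)
  } else {
    consts <- do.call(ml_constants, as.list(pick("constants", list())))
    noise <- ml_noise_config(dt = pick("dt", 0.1),
                             Sx = c(pick("Sv2", 0.01), pick("Sn2", 1e-6)),
                             sy2 = pick("sy2", 0.01))
    ctrl <- ml_control_config(
      I_lim = pick("I_lim", 150), sigma_I2 = pick("sigma_I2", 1),
      sigma_I0_2 = pick("sigma_I0_2", 100),
      sigma_r2 = pick("sigma_r2", 0.01))
    schedule <- raw$schedule
    if (!is.null(schedule)) {
      schedule <- do.call(rbind, lapply(schedule, as.data.frame))
    } else {
      schedule <- ml_reference_schedule()
    }
    I_inj <- 0
    if (!is.null(raw$I_inj_csv)) {
      I_inj <- utils::read.csv(raw$I_inj_csv)[[1L]]
    }
    ml_experiment(
      theta_true = c(pick("gL", 2), pick("gCa", 4), pick("gK", 8)),
      theta0 = c(pick("gL0", 1), pick("gCa0", 2), pick("gK0", 4)),
      consts = consts, noise = noise, control = ctrl,
      schedule = schedule, I_inj = I_inj,
      N = pick("N", 1000), alpha = pick("alpha", 0.8),
      beta = pick("beta", 0.7), gamma_exponent = pick("gamma", 1),
      T_burnIn = pick("T_burnIn", 1000), T_H = pick("T_H", 10),
      n_steps = n_steps %||% 10000,
      t_control_on = pick("t_control_on", 1), seed = pick("seed", 1),
      truth_noise = pick("truth_noise", TRUE),
      control_enabled = pick("control_enabled", TRUE))
  }
}

#' Write an experiment configuration to a YAML file
#'
#' Inverse of [load_config()]: `load_config(write_config(cfg, path))`
#' reproduces the configuration.
#'
#' @param cfg an `experiment_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  if (cfg$model == "lorenz") {
    out <- list(
      model = "lorenz",
      sigma = cfg$theta_true[1L], r = cfg$theta_true[2L],
      b = cfg$theta_true[3L],
      sigma0 = cfg$theta0[1L], r0 = cfg$theta0[2L], b0 = cfg$theta0[3L],
      dt = cfg$noise$dt, Sx = cfg$noise$Sx, Sy = cfg$noise$Sy,
      x0 = cfg$noise$x0, Sx0 = cfg$noise$Sx0,
      N = cfg$N, alpha = cfg$alpha, beta = cfg$beta,
      gamma = cfg$gamma_exponent, T_burnIn = cfg$T_burnIn, T_H = cfg$T_H,
      u_lim = cfg$control$u_lim, sigma_u2 = cfg$control$sigma_u2,
      sigma_u0_2 = cfg$control$sigma_u0_2,
      sigma_r2 = cfg$control$sigma_r2,
      t_control_on = cfg$t_control_on, n_steps = cfg$n_steps,
      seed = cfg$seed, truth_noise = cfg$truth_noise,
      control_enabled = cfg$control_enabled, y_f = cfg$y_f)
  } else {
    out <- list(
      model = "morris_lecar",
      gL = cfg$theta_true[1L], gCa = cfg$theta_true[2L],
      gK = cfg$theta_true[3L],
      gL0 = cfg$theta0[1L], gCa0 = cfg$theta0[2L], gK0 = cfg$theta0[3L],
      dt = cfg$noise$dt, Sv2 = cfg$noise$Sx[1L], Sn2 = cfg$noise$Sx[2L],
      sy2 = cfg$noise$sy2,
      N = cfg$N, alpha = cfg$alpha, beta = cfg$beta,
      gamma = cfg$gamma_exponent, T_burnIn = cfg$T_burnIn, T_H = cfg$T_H,
      I_lim = cfg$control$I_lim, sigma_I2 = cfg$control$sigma_I2,
      sigma_I0_2 = cfg$control$sigma_I0_2,
      sigma_r2 = cfg$control$sigma_r2,
      schedule = lapply(seq_len(nrow(cfg$schedule)), function(i) {
        as.list(cfg$schedule[i, ])
      }),
      constants = unclass(cfg$consts),
      t_control_on = cfg$t_control_on, n_steps = cfg$n_steps,
      seed = cfg$seed, truth_noise = cfg$truth_noise,
      control_enabled = cfg$control_enabled)
  }
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Write run traces to CSV files and a JSON summary
#'
#' Writes `states.csv`, `params.csv`, `control.csv` and `summary.json`
#' (final parameter estimates, backward-sampling count, constraint
#' violation count) into a directory.
#'
#' @param result a `run_result` from [run_closed_loop()].
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_traces <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(result$states, file.path(dir, "states.csv"),
                   row.names = FALSE)
  utils::write.csv(result$params, file.path(dir, "params.csv"),
                   row.names = FALSE)
  utils::write.csv(result$control, file.path(dir, "control.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(model = result$config$model,
         theta_final = as.list(result$summary$theta_final),
         theta_true = result$summary$theta_true,
         n_backward = result$summary$n_backward,
         constraint_violations = result$summary$constraint_violations,
         n_steps = result$summary$n_steps),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
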
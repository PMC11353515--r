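# shared fixtures: small models and simulators used across test files

# scalar linear-Gaussian model with known constants
lg_fixture <- function(a = 0.9, b = 0.5, c = 1, d = 0.3,
                       prior_mean = 0, prior_var = 1) {
  list(model = linear_gaussian_ssm(b = b, c = c, d = d,
                                   prior_mean = prior_mean,
                                   prior_var = prior_var),
       a = a, b = b, c = c, d = d,
       prior_mean = prior_mean, prior_var = prior_var)
}

# simulate a latent path and observations from the linear-Gaussian model
lg_simulate <- function(fix, T_len, x0 = NULL) {
  x0 <- x0 %||% rnorm(1, fix$prior_mean, sqrt(fix$prior_var))
  x <- numeric(T_len + 1L)
  y <- numeric(T_len)
  x[1L] <- x0
  for (t in seq_len(T_len)) {
    x[t + 1L] <- fix$a * x[t] + fix$b * rnorm(1)
    y[t] <- fix$c * x[t + 1L] + fix$d * rnorm(1)
  }
  list(x = x, y = y)   # x has T+1 entries (x_0 ... x_T)
}

`%||%` <- function(l, r) if (is.null(l)) r else l

# run a particle filter over a whole observation series, returning the
# filtering means (and optionally the final ensemble)
pf_filter_means <- function(model, y, theta, cfg, u = 0) {
  ens <- init_particles(model, cfg)
  T_len <- if (is.matrix(y)) nrow(y) else length(y)
  out <- matrix(NA_real_, T_len, model$state_dim)
  for (t in seq_len(T_len)) {
    yt <- if (is.matrix(y)) y[t, ] else y[t]
    ens <- pf_step(ens, yt, u, model, theta, cfg)
    out[t, ] <- filtering_mean(ens)
  }
  out
}

# exact O(N^2) forward-filtering backward-smoothing estimate of the
# expected additive statistic E[S_T | y_{1:T}] from a stored PF run
# (independent oracle for the AdaSmooth recursion)
ffbs_additive_statistic <- function(model, y, theta, cfg, u = 0) {
  ens <- init_particles(model, cfg)
  history <- list(ens)
  T_len <- if (is.matrix(y)) nrow(y) else length(y)
  for (t in seq_len(T_len)) {
    yt <- if (is.matrix(y)) y[t, ] else y[t]
    ens <- pf_step(ens, yt, u, model, theta, cfg)
    history[[t + 1L]] <- ens
  }
  N <- cfg$N
  p <- model$suffstat_dim
  TA <- matrix(0, N, p * p)   # per-particle expected cumulative statistic
  Tb <- matrix(0, N, p)
  prev_idx <- rep(seq_len(N), times = N)   # row l varies fastest
  curr_idx <- rep(seq_len(N), each = N)
  for (t in seq_len(T_len)) {
    prev <- history[[t]]
    curr <- history[[t + 1L]]
    # backward kernel matrix: entry (l, i) ~ w_{t-1}(l) p(x_t(i) | x_{t-1}(l))
    lp <- matrix(model$dtransition(prev$x[prev_idx, , drop = FALSE],
                                   curr$x[curr_idx, , drop = FALSE],
                                   u, theta, log = TRUE) +
                   log(prev$w)[prev_idx], N, N)
    bw <- exp(sweep(lp, 2L, apply(lp, 2L, max)))
    bw <- sweep(bw, 2L, colSums(bw), "/")
    s <- model$suffstat(prev$x[prev_idx, , drop = FALSE],
                        curr$x[curr_idx, , drop = FALSE], u)
    TA_new <- t(bw) %*% TA
    Tb_new <- t(bw) %*% Tb
    for (k in seq_len(p * p)) {
      TA_new[, k] <- TA_new[, k] + colSums(matrix(s$A[, k], N, N) * bw)
    }
    for (k in seq_len(p)) {
      Tb_new[, k] <- Tb_new[, k] + colSums(matrix(s$b[, k], N, N) * bw)
    }
    TA <- TA_new
    Tb <- Tb_new
  }
  last <- history[[T_len + 1L]]
  suffstat_pair(matrix(colSums(last$w * TA), p, p), colSums(last$w * Tb))
}

# run the AdaSmooth recursion at fixed theta over an observation series and
# return t * smoothed_statistic (the cumulative-statistic scale)
adasmooth_statistic <- function(model, y, theta, cfg, beta = 0.7, u = 0) {
  ens <- init_particles(model, cfg)
  smooth <- smoothing_state(model, cfg$N, beta = beta,
                            T_burnIn = .Machine$integer.max)
  T_len <- if (is.matrix(y)) nrow(y) else length(y)
  for (t in seq_len(T_len)) {
    yt <- if (is.matrix(y)) y[t, ] else y[t]
    ens_new <- pf_step(ens, yt, u, model, theta, cfg)
    smooth <- update_kappa(smooth, ens, ens_new, u, model, theta)
    ens <- ens_new
  }
  st <- smoothed_statistic(ens, smooth)
  suffstat_pair(st$A * T_len, st$b * T_len)
}
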
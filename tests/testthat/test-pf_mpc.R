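# Control-filtering: augmented ensembles, horizon steps, input extraction

# deterministic 1-D toy system: x stays put, the input shifts it
toy_plant <- function(move = 1) {
  new_ssm(
    name = "toy-plant", state_dim = 1L, obs_dim = 1L, param_dim = 1L,
    suffstat_dim = 1L,
    rinit = function(n) matrix(0, n, 1L),
    rtransition = function(x, u, th) x + move * u,
    dtransition = function(xp, xc, u, th, log = TRUE) rep(0, nrow(xp)),
    logdensity_max = function(th) 0,
    dobservation = function(y, x, th, log = TRUE) rep(0, nrow(x)),
    suffstat = function(xp, xc, u) {
      list(A = matrix(1, nrow(xp), 1L), b = matrix(0, nrow(xp), 1L))
    },
    lambda = function(A, b) 0
  )
}

test_that("augmented initialisation copies the state filter verbatim", {
  set.seed(30)
  N <- 50
  w <- runif(N); w <- w / sum(w)
  ens <- particle_ensemble(3L, matrix(rnorm(N), ncol = 1L), w)
  ctm0 <- control_model(
    init = function(n, u_prev) rep(clamp(u_prev, 2), n),   # no noise
    transition = function(u) u, u_lim = 2)
  aug <- init_augmented(ens, u_prev = 5, ctm0)
  expect_equal(aug$w, ens$w)                 # weights copied
  expect_equal(aug$x, ens$x)
  expect_equal(aug$u_init, aug$u)            # preserved = initial
  expect_equal(aug$u, rep(2, N))             # clamp(5, 2) = 2, noiseless
})

test_that("horizon steps keep the delta-transition lineage of the
          preserved input", {
  set.seed(31)
  N <- 40
  model <- toy_plant()
  ctm <- lorenz_control_model(lorenz_control_config(u_lim = 10))
  ref <- reference_model(function(x) x[, 1L], sigma_r2 = 1, T_H = 3)
  ens <- particle_ensemble(0L, matrix(rnorm(N), ncol = 1L), rep(1 / N, N))
  aug <- init_augmented(ens, 0, ctm)
  out <- horizon_step(aug, 0.5, model, ctm, ref, 0, pf_config(N, 0.8))
  expect_true(all(out$u_init %in% aug$u_init))
  expect_lt(abs(sum(out$w) - 1), 1e-12)
  # huge reference variance: weights numerically unchanged
  ref_flat <- reference_model(function(x) x[, 1L], sigma_r2 = 1e9,
                              T_H = 3)
  w0 <- runif(N); w0 <- w0 / sum(w0)
  aug2 <- augmented_ensemble(0L, matrix(rnorm(N), ncol = 1L), rnorm(N),
                             rnorm(N), w0)
  out2 <- horizon_step(aug2, 0.5, model, ctm, ref_flat, 0,
                       pf_config(N, 0))   # alpha = 0: no resampling
  expect_equal(out2$w, w0, tolerance = 1e-6)
})

test_that("reference likelihood separates on- and off-target particles by
          the Gaussian ratio", {
  # two particles with identical prior weight; selector outputs r and
  # r + 3 sigma_r: posterior weight ratio must be exp(4.5)
  sigma_r2 <- 0.49
  r_tau <- 1.2
  model <- toy_plant(move = 0)
  ctm <- control_model(init = function(n, u_prev) rep(0, n),
                       transition = function(u) u, u_lim = 1)
  ref <- reference_model(function(x) x[, 1L], sigma_r2 = sigma_r2,
                         T_H = 1)
  x <- matrix(c(r_tau, r_tau + 3 * sqrt(sigma_r2)), 2L, 1L)
  aug <- augmented_ensemble(0L, x, c(0, 0), c(0, 0), c(0.5, 0.5))
  out <- horizon_step(aug, r_tau, model, ctm, ref, 0, pf_config(2, 0))
  expect_equal(out$w[1] / out$w[2], exp(4.5), tolerance = 1e-9)
})

test_that("extracted control is the weighted mean of preserved inputs", {
  aug1 <- augmented_ensemble(0L, matrix(0, 1, 1), 0, 2.5, 1)
  expect_equal(extract_control(aug1), 2.5)
  u0 <- c(-1, 0, 4)
  aug3 <- augmented_ensemble(0L, matrix(0, 3, 1), rep(0, 3), u0,
                             rep(1 / 3, 3))
  expect_equal(extract_control(aug3), mean(u0))
  # convex combination: always inside the range of the preserved inputs
  set.seed(32)
  for (i in 1:10) {
    w <- runif(5); w <- w / sum(w)
    u <- runif(5, -10, 10)
    aug <- augmented_ensemble(0L, matrix(0, 5, 1), rep(0, 5), u, w)
    expect_gte(extract_control(aug), min(u))
    expect_lte(extract_control(aug), max(u))
  }
})

test_that("mpc_control is deterministic under a fixed stream and
          respects the input constraint", {
  set.seed(33)
  N <- 100
  ens <- particle_ensemble(0L, matrix(rnorm(N * 3), N, 3L), rep(1 / N, N))
  model <- lorenz_ssm()
  cc <- lorenz_control_config(u_lim = 10)
  ctm <- lorenz_control_model(cc)
  ref <- reference_model(function(x) x[, 2L], sigma_r2 = 1, T_H = 5)
  seg <- rep(8.485, 6)
  th <- c(10, 28, 8 / 3)
  u1 <- mpc_control(ens, 0, seg, model, ctm, ref, th, pf_config(N),
                    rng_streams(7, 1)[[1]])
  u2 <- mpc_control(ens, 0, seg, model, ctm, ref, th, pf_config(N),
                    rng_streams(7, 1)[[1]])
  expect_identical(u1, u2)
  expect_lte(abs(u1), 10)
  expect_error(mpc_control(ens, 0, seg[1:3], model, ctm, ref, th,
                           pf_config(N)), "T_H \\+ 1")
})

test_that("on a linear plant the mean input matches the grid-search
          certainty-equivalent control", {
  # plant x_{t+1} = a x_t + u_t + b z; reference constant 0; one-step
  # horizon. The input that zeroes the one-step-ahead predicted state is
  # u* = -a * xhat (found here by grid search as an independent oracle).
  set.seed(34)
  a <- 0.9; b <- 0.5; d <- 0.3
  fix <- lg_fixture(a = a, b = b, c = 1, d = d)
  model <- fix$model
  N <- 400
  cfg <- pf_config(N)
  ctm <- control_model(
    init = function(n, u_prev) clamp(u_prev + rnorm(n, 0, 3), 10),
    transition = function(u) clamp(u + rnorm(length(u), 0, 1), 10),
    u_lim = 10)
  ref <- reference_model(function(x) x[, 1L], sigma_r2 = 0.05, T_H = 1)
  ens <- init_particles(model, cfg)
  x <- 0; u_prev <- 0
  diffs <- numeric(200)
  grid <- seq(-10, 10, by = 0.001)
  for (t in 1:200) {
    x <- a * x + u_prev + b * rnorm(1)
    y <- x + d * rnorm(1)
    ens <- pf_step(ens, y, u_prev, model, c(a = a), cfg)
    u_t <- mpc_control(ens, u_prev, c(0, 0), model, ctm, ref, c(a = a),
                       cfg)
    xhat <- filtering_mean(ens)
    u_star <- grid[which.min(abs(a * xhat + grid))]
    diffs[t] <- u_t - u_star
    u_prev <- u_t
  }
  expect_lt(abs(mean(diffs)), 5 * sd(diffs) / sqrt(200))
})

test_that("increasing reference variance drives the input toward the
          proposal mean", {
  # with an uninformative reference, the extracted input is the mean of
  # the initial proposal (centred on u_prev)
  set.seed(35)
  N <- 2000
  ens <- particle_ensemble(0L, matrix(rnorm(N), ncol = 1L), rep(1 / N, N))
  model <- toy_plant(move = 0)
  ctm <- control_model(
    init = function(n, u_prev) u_prev + rnorm(n, 0, 1),
    transition = function(u) u, u_lim = Inf)
  ref <- reference_model(function(x) x[, 1L], sigma_r2 = 1e9, T_H = 2)
  u <- mpc_control(ens, 3, rep(0, 3), model, ctm, ref, 0, pf_config(N, 0))
  expect_lt(abs(u - 3), 5 / sqrt(N))
})
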
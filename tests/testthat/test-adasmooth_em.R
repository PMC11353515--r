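# AdaSmooth recursion, backward ancestor sampling, online M-step

test_that("decay schedule follows t^-1 and validates its domain", {
  expect_equal(decay_rate(1), 1)
  expect_equal(decay_rate(2), 0.5)
  expect_equal(decay_rate(100), 0.01)
  expect_equal(decay_rate(4, exponent = 0.6), 4^-0.6)
  expect_error(decay_rate(0), "t >= 1")
  expect_error(decay_rate(2, exponent = 0.4), "exponent")
  expect_error(decay_rate(2, exponent = 1.2), "exponent")
})

test_that("Enoch indices reset after backward sampling, compose otherwise", {
  expect_equal(update_enoch(c(3L, 1L, 2L, 5L, 4L), c(2L, 2L, 1L, 4L, 3L),
                            just_backward_sampled = TRUE), 1:5)
  expect_equal(update_enoch(c(1L, 1L, 3L), c(3L, 3L, 3L), FALSE),
               c(3L, 3L, 3L))
  e <- c(2L, 2L, 1L, 3L)
  expect_equal(update_enoch(e, 1:4, FALSE), e)
  expect_error(update_enoch(c(1L, 5L), c(1L, 2L), FALSE), "1..N")
})

test_that("ancestor diversity counts distinct Enoch indices", {
  expect_equal(ancestor_diversity(c(1, 2, 3, 4)), 4L)
  expect_equal(ancestor_diversity(c(7, 7, 7, 7)), 1L)
  expect_equal(ancestor_diversity(c(1, 1, 2, 5)), 3L)
})

test_that("backward ancestor sampling targets the smoothing kernel", {
  # N = 1: single support point
  fix <- lg_fixture()
  ens1 <- particle_ensemble(1L, matrix(0.5, 1L), 1)
  expect_equal(backward_ancestor_sample(ens1, 0.4, 0, fix$model,
                                        c(a = 0.9)), 1L)
  # transition density constant in x_prev: kernel reduces to the filter
  # weights; chi-square over 1e4 draws
  flat <- new_ssm(
    name = "flat", state_dim = 1L, obs_dim = 1L, param_dim = 1L,
    suffstat_dim = 1L,
    rinit = function(n) matrix(rnorm(n), ncol = 1L),
    rtransition = function(x, u, th) x + matrix(rnorm(nrow(x)), ncol = 1L),
    dtransition = function(xp, xc, u, th, log = TRUE) {
      out <- rep(log(0.25), max(nrow(xp), nrow(xc)))
      if (log) out else exp(out)
    },
    logdensity_max = function(th) log(0.25),
    dobservation = function(y, x, th, log = TRUE) rep(0, nrow(x)),
    suffstat = function(xp, xc, u) {
      list(A = matrix(1, nrow(xp), 1L), b = matrix(0, nrow(xp), 1L))
    },
    lambda = function(A, b) 0
  )
  set.seed(13)
  w <- c(0.5, 0.3, 0.15, 0.05)
  ens <- particle_ensemble(1L, matrix(rnorm(4), ncol = 1L), w)
  draws <- replicate(1e4, backward_ancestor_sample(ens, 0, 0, flat, 0))
  counts <- tabulate(draws, 4)
  expect_gt(chisq.test(counts, p = w)$p.value, 0.01)
})

test_that("rejection and exact backward sampling paths agree in law", {
  set.seed(14)
  fix <- lg_fixture(a = 0.8, b = 0.7)
  N <- 10
  w <- runif(N); w <- w / sum(w)
  ens <- particle_ensemble(1L, matrix(rnorm(N), ncol = 1L), w)
  x_t <- 0.3
  n_draws <- 1e4
  rej <- replicate(n_draws, backward_ancestor_sample(
    ens, x_t, 0, fix$model, c(a = 0.8), method = "rejection"))
  exa <- replicate(n_draws, backward_ancestor_sample(
    ens, x_t, 0, fix$model, c(a = 0.8), method = "exact"))
  tab <- rbind(tabulate(rej, N), tabulate(exa, N))
  expect_gt(chisq.test(tab)$p.value, 0.01)
})

test_that("degenerate backward kernels are reported", {
  dead <- new_ssm(
    name = "dead", state_dim = 1L, obs_dim = 1L, param_dim = 1L,
    suffstat_dim = 1L,
    rinit = function(n) matrix(0, n, 1L),
    rtransition = function(x, u, th) x,
    dtransition = function(xp, xc, u, th, log = TRUE) {
      rep(-Inf, max(nrow(xp), nrow(xc)))
    },
    logdensity_max = function(th) 0,
    dobservation = function(y, x, th, log = TRUE) rep(0, nrow(x)),
    suffstat = function(xp, xc, u) {
      list(A = matrix(1, nrow(xp), 1L), b = matrix(0, nrow(xp), 1L))
    },
    lambda = function(A, b) 0
  )
  ens <- particle_ensemble(1L, matrix(rnorm(4), ncol = 1L), rep(0.25, 4))
  expect_error(backward_ancestor_sample(ens, 0, 0, dead, 0,
                                        method = "exact"),
               "degenerate backward kernel")
})

test_that("kappa recursion forgets, freezes and blends as prescribed", {
  fix <- lg_fixture(b = 1)
  model <- fix$model
  N <- 6
  set.seed(15)
  xp <- matrix(rnorm(N), ncol = 1L)
  xc <- matrix(rnorm(N), ncol = 1L)
  w <- rep(1 / N, N)
  anc <- c(2L, 2L, 4L, 1L, 6L, 3L)
  prev <- particle_ensemble(4L, xp, w)
  curr <- particle_ensemble(5L, xc, w, ancestors = anc)
  base <- smoothing_state(model, N, beta = 0)   # beta = 0: never backward
  base$kappa_A <- matrix(rnorm(N), N, 1L)
  base$kappa_b <- matrix(rnorm(N), N, 1L)
  s <- model$suffstat(xp[anc, , drop = FALSE], xc, 0)
  # gamma = 1: past forgotten
  g1 <- base; g1$gamma <- function(t) 1
  out1 <- update_kappa(g1, prev, curr, 0, model, c(a = 0.9))
  expect_equal(out1$kappa_b, s$b, tolerance = 1e-12)
  # gamma = 0: kappa carried through the ancestors
  g0 <- base; g0$gamma <- function(t) 0
  out0 <- update_kappa(g0, prev, curr, 0, model, c(a = 0.9))
  expect_equal(out0$kappa_b, base$kappa_b[anc, , drop = FALSE],
               tolerance = 1e-12)
  expect_equal(out0$kappa_A, base$kappa_A[anc, , drop = FALSE],
               tolerance = 1e-12)
})

test_that("the backward blend reduces to the plain recursion when B = A", {
  # point-mass predecessor weights force B = A = j for every particle,
  # so the half-half blend must equal the genealogical update exactly
  fix <- lg_fixture(b = 1)
  model <- fix$model
  N <- 5
  set.seed(16)
  xp <- matrix(rnorm(N), ncol = 1L)
  xc <- matrix(rnorm(N), ncol = 1L)
  w_point <- c(0, 0, 1, 0, 0)
  anc <- rep(3L, N)
  prev <- particle_ensemble(1L, xp, w_point)
  curr <- particle_ensemble(2L, xc, rep(1 / N, N), ancestors = anc,
                            resampled = TRUE)
  kap <- matrix(rnorm(N), N, 1L)
  make_state <- function(beta) {
    sm <- smoothing_state(model, N, beta = beta,
                          gamma = function(t) 0.3)
    sm$kappa_A <- matrix(abs(rnorm(N)), N, 1L)
    sm$kappa_b <- kap
    sm
  }
  sm_plain <- make_state(beta = 0)
  sm_blend <- make_state(beta = 1)     # always backward-sample
  sm_blend$kappa_A <- sm_plain$kappa_A
  out_plain <- update_kappa(sm_plain, prev, curr, 0, model, c(a = 0.9))
  out_blend <- update_kappa(sm_blend, prev, curr, 0, model, c(a = 0.9))
  expect_true(out_blend$backward)
  expect_false(out_plain$backward)
  expect_equal(out_blend$kappa_b, out_plain$kappa_b, tolerance = 1e-12)
  expect_equal(out_blend$kappa_A, out_plain$kappa_A, tolerance = 1e-12)
})

test_that("smoothed statistic equals brute-force accumulation", {
  fix <- lg_fixture()
  model <- fix$model
  # point mass
  sm <- smoothing_state(model, 3)
  sm$kappa_A <- matrix(c(1, 2, 3), 3, 1L)
  sm$kappa_b <- matrix(c(4, 5, 6), 3, 1L)
  ens_pm <- particle_ensemble(1L, matrix(0, 3, 1L), c(0, 1, 0))
  st <- smoothed_statistic(ens_pm, sm)
  expect_equal(st$A[1, 1], 2); expect_equal(st$b, 5)
  # uniform weights: plain average
  ens_u <- particle_ensemble(1L, matrix(0, 3, 1L), rep(1 / 3, 3))
  st_u <- smoothed_statistic(ens_u, sm)
  expect_equal(st_u$A[1, 1], 2); expect_equal(st_u$b, 5)
  # random ensemble vs loop accumulation
  set.seed(17)
  N <- 30
  smr <- smoothing_state(lorenz_ssm(), N)
  smr$kappa_A <- matrix(rnorm(N * 9), N, 9L)
  smr$kappa_b <- matrix(rnorm(N * 3), N, 3L)
  w <- runif(N); w <- w / sum(w)
  ens <- particle_ensemble(1L, matrix(rnorm(3 * N), N, 3L), w)
  st_r <- smoothed_statistic(ens, smr)
  accA <- matrix(0, 3, 3); accb <- rep(0, 3)
  for (i in 1:N) {
    accA <- accA + w[i] * matrix(smr$kappa_A[i, ], 3, 3)
    accb <- accb + w[i] * smr$kappa_b[i, ]
  }
  expect_equal(st_r$A, accA, tolerance = 1e-12)
  expect_equal(st_r$b, accb, tolerance = 1e-12)
})

test_that("online M-step freezes during burn-in and applies Lambda after", {
  lor <- lorenz_ssm()
  sm <- smoothing_state(lor, 10, T_burnIn = 50)
  stat <- suffstat_pair(diag(3), c(10, 28, 8 / 3))
  th_prev <- c(5, 20, 1.5)
  expect_equal(em_update(stat, 50, lor, sm, th_prev), th_prev)
  # identity A-part: Lambda returns b regardless of the 1/t scaling
  out <- em_update(stat, 51, lor, sm, th_prev)
  expect_equal(as.numeric(out), c(10, 28, 8 / 3), tolerance = 1e-12)
  # singular A-part: previous estimate kept, with a warning
  bad <- suffstat_pair(matrix(0, 3, 3), c(1, 1, 1))
  expect_warning(out2 <- em_update(bad, 51, lor, sm, th_prev), "singular")
  expect_equal(out2, th_prev)
})

test_that("online EM recovers the transition coefficient of the
          linear-Gaussian model", {
  set.seed(18)
  fix <- lg_fixture(a = 0.8, b = 1, c = 1, d = 1)
  sim <- lg_simulate(fix, 500, x0 = 0)
  mle <- sum(sim$x[1:500] * sim$x[2:501]) / sum(sim$x[1:500]^2)
  model <- fix$model
  cfg <- pf_config(500)
  ens <- init_particles(model, cfg)
  smooth <- smoothing_state(model, 500, beta = 0.7, T_burnIn = 20)
  theta <- c(a = 0.2)
  for (t in 1:500) {
    ens_new <- pf_step(ens, sim$y[t], 0, model, theta, cfg)
    smooth <- update_kappa(smooth, ens, ens_new, 0, model, theta)
    theta <- em_update(smoothed_statistic(ens_new, smooth), t, model,
                       smooth, theta)
    ens <- ens_new
  }
  expect_lt(abs(as.numeric(theta) - mle), 0.1)
})

test_that("diversity is non-increasing between backward events", {
  set.seed(19)
  fix <- lg_fixture()
  model <- fix$model
  sim <- lg_simulate(fix, 40)
  cfg <- pf_config(100, alpha = 1)      # resample every step
  ens <- init_particles(model, cfg)
  smooth <- smoothing_state(model, 100, beta = 0,   # never backward-sample
                            T_burnIn = .Machine$integer.max)
  divs <- integer(40)
  for (t in 1:40) {
    ens_new <- pf_step(ens, sim$y[t], 0, model, c(a = 0.9), cfg)
    smooth <- update_kappa(smooth, ens, ens_new, 0, model, c(a = 0.9))
    divs[t] <- smooth$diversity
    ens <- ens_new
  }
  expect_true(all(diff(divs) <= 0))
})

test_that("kappa with 1/t decay is the running average along a single
          lineage", {
  set.seed(20)
  fix <- lg_fixture(b = 1)
  model <- fix$model
  sim <- lg_simulate(fix, 25)
  cfg <- pf_config(1, alpha = 0)       # one particle, no resampling
  ens <- init_particles(model, cfg)
  smooth <- smoothing_state(model, 1, beta = 0,
                            T_burnIn = .Machine$integer.max)
  path <- ens$x[1, 1]
  for (t in 1:25) {
    ens_new <- pf_step(ens, sim$y[t], 0, model, c(a = 0.9), cfg)
    smooth <- update_kappa(smooth, ens, ens_new, 0, model, c(a = 0.9))
    path <- c(path, ens_new$x[1, 1])
    ens <- ens_new
  }
  s_direct <- mean(path[1:25] * path[2:26])   # b = 1: s~ = x_{t-1} x_t
  expect_equal(smooth$kappa_b[1, 1], s_direct, tolerance = 1e-10)
})
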
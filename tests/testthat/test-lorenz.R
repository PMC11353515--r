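# Lorenz plug-in: drift, statistics, control transition, truth plant

test_that("drift vanishes at the fixed points and matches hand values", {
  th <- c(10, 28, 8 / 3)
  expect_equal(lorenz_drift(c(0, 0, 0), 0, th), c(0, 0, 0))
  expect_equal(lorenz_drift(c(sqrt(72), sqrt(72), 27), 0, th),
               c(0, 0, 0), tolerance = 1e-12)
  expect_equal(lorenz_drift(c(1, 2, 3), 5, th), c(10, 28, -6))
  # property: zero drift at both nontrivial fixed points for random theta
  set.seed(40)
  for (i in 1:20) {
    sig <- runif(1, 1, 20); r <- runif(1, 1.5, 40); b <- runif(1, 0.5, 5)
    q <- sqrt(b * (r - 1))
    for (s in c(-1, 1)) {
      expect_equal(lorenz_drift(c(s * q, s * q, r - 1), 0, c(sig, r, b)),
                   c(0, 0, 0), tolerance = 1e-9)
    }
  }
})

test_that("transition density peaks at the Euler mean with the Gaussian
          mode value", {
  noise <- lorenz_noise_config(dt = 0.01, Sx = c(1, 1, 1))
  model <- lorenz_ssm(noise)
  th <- c(10, 28, 8 / 3)
  x <- c(1, 2, 3)
  mu <- x + lorenz_drift(x, 0.7, th) * 0.01
  val <- model$dtransition(matrix(x, 1L), matrix(mu, 1L), 0.7, th,
                           log = FALSE)
  expect_equal(val, 1 / ((2 * pi)^(3 / 2) * sqrt(prod(noise$Sx * 0.01))),
               tolerance = 1e-9)
  # transition_mean declaration agrees with the Euler step
  expect_equal(model$transition_mean(matrix(x, 1L), 0.7, th)[1L, ], mu)
})

test_that("sufficient-statistic increments match the hand evaluations", {
  noise <- lorenz_noise_config(dt = 0.01, Sx = c(1, 1, 1))
  s <- lorenz_suffstat_increment(c(1, 2, 3), c(0, 0, 0), 0, noise)
  expect_equal(diag(s$A), c(0.01, 0.01, 0.09), tolerance = 1e-12)
  expect_equal(s$A[lower.tri(s$A)], rep(0, 3))
  s2 <- lorenz_suffstat_increment(c(1, 2, 3), c(1, 2, 3), 0, noise)
  expect_equal(s2$b, c(0, 0.05, 0.06), tolerance = 1e-12)
  s0 <- lorenz_suffstat_increment(c(0, 0, 0), c(1, 1, 1), 0, noise)
  expect_equal(diag(s0$A), c(0, 0, 0))
  expect_equal(s0$b, c(0, 0, 0))
})

test_that("Lambda recovers parameters from complete-data statistics", {
  expect_equal(as.numeric(lorenz_lambda(
    suffstat_pair(diag(3), c(10, 28, 8 / 3)))), c(10, 28, 8 / 3))
  expect_equal(as.numeric(lorenz_lambda(
    suffstat_pair(diag(c(2, 2, 2)), c(20, 56, 16 / 3)))), c(10, 28, 8 / 3))
  expect_error(lorenz_lambda(suffstat_pair(matrix(0, 3, 3), c(1, 1, 1))),
               "singular")
  # consistency along a simulated true path
  set.seed(41)
  noise <- lorenz_noise_config()
  th <- c(10, 28, 8 / 3)
  n <- 5000
  X <- matrix(0, n + 1, 3); X[1, ] <- c(1, 1, 1)
  for (t in 1:n) X[t + 1, ] <- lorenz_truth_step_rk4(X[t, ], 0, th, noise)
  model <- lorenz_ssm(noise)
  s <- model$suffstat(X[1:n, , drop = FALSE], X[2:(n + 1), , drop = FALSE],
                      0)
  est <- lorenz_lambda(suffstat_pair(matrix(colSums(s$A), 3, 3),
                                     colSums(s$b)))
  expect_equal(as.numeric(est), th, tolerance = 0.02)
})

test_that("clamp matches min/max and its algebraic properties", {
  expect_equal(clamp(15, 10), 10)
  expect_equal(clamp(-15, 10), -10)
  expect_equal(clamp(3, 10), 3)
  set.seed(42)
  u <- runif(200, -50, 50)
  expect_equal(clamp(u, 10), pmin(pmax(u, -10), 10))
  expect_equal(clamp(clamp(u, 10), 10), clamp(u, 10))     # idempotent
  expect_equal(clamp(-u, 10), -clamp(u, 10))              # odd
  du <- abs(clamp(u + 0.01, 10) - clamp(u, 10))
  expect_true(all(du <= 0.01 + 1e-12))                    # 1-Lipschitz
})

test_that("control transitions stay in bounds and keep near-Gaussian
          moments when unclamped", {
  set.seed(43)
  cc <- lorenz_control_config(u_lim = 10, sigma_u2 = 1, sigma_u0_2 = 100)
  ctm <- lorenz_control_model(cc)
  u <- ctm$transition(rep(0, 1e5))
  expect_true(all(abs(u) <= 10))
  expect_lt(abs(mean(u)), 5 / sqrt(1e5))
  expect_lt(abs(var(u) - 1), 5 * sqrt(2 / 1e5))
  u0 <- ctm$init(1e5, 3)
  expect_true(all(abs(u0) <= 10))
  # zero-noise limit: identity inside the bound
  ctm_eps <- lorenz_control_model(lorenz_control_config(
    u_lim = 10, sigma_u2 = 1e-20, sigma_u0_2 = 1e-20))
  expect_equal(ctm_eps$transition(c(-3, 0, 7)), c(-3, 0, 7),
               tolerance = 1e-6)
})

test_that("the RK4 truth plant is accurate, stationary at fixed points
          and bounded on the attractor", {
  th <- c(10, 28, 8 / 3)
  noise <- lorenz_noise_config(dt = 0.01)
  fp <- c(sqrt(72), sqrt(72), 27)
  expect_equal(lorenz_truth_step_rk4(fp, 0, th, noise,
                                     process_noise = FALSE), fp,
               tolerance = 1e-12)
  # step-halving convergence over t' in [0, 1]: errors against a dt/4
  # reference shrink at the 4th-order rate (ratio ~ 16 per halving, up to
  # chaotic amplification), and the dt = 0.01 error stays small
  integrate_rk4 <- function(dt, t_end) {
    nz <- lorenz_noise_config(dt = dt)
    x <- c(1, 1, 1)
    for (t in seq_len(round(t_end / dt))) {
      x <- lorenz_truth_step_rk4(x, 0, th, nz, process_noise = FALSE)
    }
    x
  }
  ref <- integrate_rk4(0.0025, 1)
  e1 <- max(abs(integrate_rk4(0.01, 1) - ref))
  e2 <- max(abs(integrate_rk4(0.005, 1) - ref))
  expect_lt(e1, 1e-4)
  expect_gt(e1 / e2, 8)     # 4th-order: nominal factor ~16 per halving
  # attractor boundedness over t' in [0, 50]
  x <- c(1, 1, 1)
  m <- 0
  for (t in 1:5000) {
    x <- lorenz_truth_step_rk4(x, 0, th, noise, process_noise = FALSE)
    m <- max(m, max(abs(x)))
  }
  expect_lt(m, 100)
})

test_that("the Hopf threshold matches the printed critical value and the
          eigenvalue crossing", {
  expect_equal(hopf_threshold(10, 8 / 3), 24.73684211, tolerance = 1e-6)
  expect_equal(hopf_threshold(10, 8 / 3, method = "numeric"),
               24.73684211, tolerance = 1e-6)
  expect_error(hopf_threshold(2, 8 / 3), "no Hopf bifurcation")
  # just above threshold the fixed point has an unstable eigenvalue pair
  rH <- hopf_threshold(10, 8 / 3)
  r <- rH + 0.01
  q <- sqrt(8 / 3 * (r - 1))
  J <- rbind(c(-10, 10, 0), c(r - (r - 1), -1, -q), c(q, q, -8 / 3))
  ev <- eigen(J, only.values = TRUE)$values
  expect_gt(max(Re(ev)), 0)
  expect_equal(sum(Im(ev) != 0), 2L)
  # and just below, all eigenvalues are stable
  r2 <- rH - 0.01
  q2 <- sqrt(8 / 3 * (r2 - 1))
  J2 <- rbind(c(-10, 10, 0), c(1, -1, -q2), c(q2, q2, -8 / 3))
  expect_lt(max(Re(eigen(J2, only.values = TRUE)$values)), 0)
})
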
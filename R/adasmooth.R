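#' Sufficient-statistic pair
#'
#' The additive statistic `S = (A, b)` accumulated by the online EM: `A` is
#' a square matrix and `b` a vector of matching dimension; the M-step
#' maximiser for the shipped Gaussian-noise models is the ratio
#' `Lambda(A, b) = +/- A^{-1} b`, which is invariant to a common scaling of
#' both parts.
#'
#' @param A square numeric matrix.
#' @param b numeric vector with `length(b) == nrow(A)`.
#' @return An object of class `suffstat_pair`.
#' @export
suffstat_pair <- function(A, b) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A), length(b) == nrow(A))
  structure(list(A = A, b = as.numeric(b)), class = "suffstat_pair")
}

#' @export
print.suffstat_pair <- function(x, ...) {
  cat("<sufficient-statistic pair, dim = ", nrow(x$A), ">\nA:\n", sep = "")
  print(x$A)
  cat("b:\n")
  print(x$b)
  invisible(x)
}

#' Stochastic-approximation decay rate
#'
#' The default schedule is `gamma_t = 1/t`; schedules `t^-kappa` with
#' `kappa` in `(0.5, 1]` are admissible (they satisfy
#' `sum gamma_t = Inf`, `sum gamma_t^2 < Inf`).
#'
#' @param t positive integer time index.
#' @param exponent decay exponent `kappa` in `(0.5, 1]`.
#' @return `t^-exponent`, in `(0, 1]`.
#' @export
decay_rate <- function(t, exponent = 1) {
  if (any(t < 1)) stop("decay rate is defined for t >= 1")
  if (exponent <= 0.5 || exponent > 1) {
    stop("decay exponent must lie in (0.5, 1] for convergent schedules")
  }
  t^(-exponent)
}

#' Smoothing state of the AdaSmooth online EM
#'
#' Holds the per-particle statistics `kappa_t^{(i)}` (one A-part row and one
#' b-part row per particle), the Enoch indices, the time `t0` of the last
#' backward-sampling event, the backward-trigger rate `beta`, the decay
#' schedule and the burn-in length.
#'
#' @param model an [new_ssm()] object (fixes the statistic shape).
#' @param N particle count.
#' @param beta backward-sampling threshold rate in `[0, 1]`: backward
#'   ancestor sampling is triggered when the number of distinct Enoch
#'   indices drops to `beta * N`.
#' @param gamma decay schedule, a `function(t)`; defaults to
#'   [decay_rate()] with exponent 1, i.e. `1/t`.
#' @param T_burnIn number of initial steps during which the parameter
#'   estimate is frozen while the statistics accumulate.
#' @return An object of class `smoothing_state`.
#' @export
smoothing_state <- function(model, N, beta = 0.7,
                            gamma = function(t) decay_rate(t),
                            T_burnIn = 0L) {
  stopifnot(inherits(model, "ssm"), N >= 1,
            beta >= 0, beta <= 1, is.function(gamma), T_burnIn >= 0)
  p <- model$suffstat_dim
  structure(
    list(
      p = p,
      N = as.integer(N),
      kappa_A = matrix(0, N, p * p),
      kappa_b = matrix(0, N, p),
      enoch = seq_len(N),
      t0 = 0L,
      beta = beta,
      gamma = gamma,
      T_burnIn = as.integer(T_burnIn),
      diversity = as.integer(N),
      backward = FALSE,
      n_backward = 0L
    ),
    class = "smoothing_state"
  )
}

#' @export
print.smoothing_state <- function(x, ...) {
  cat("<smoothing state: N = ", x$N, ", statistic dim = ", x$p,
      ", beta = ", x$beta, ", last backward sampling at t0 = ", x$t0,
      ", diversity = ", x$diversity, ">\n", sep = "")
  invisible(x)
}

#' Enoch index update
#'
#' At the first step after a backward-sampling event (`t = t0 + 1`) the
#' Enoch indices reset to the identity; otherwise each particle inherits the
#' Enoch index of its ancestor, `E_t^{(i)} = E_{t-1}^{(A_t(i))}`.
#'
#' @param prev_enoch integer Enoch indices at `t-1`.
#' @param ancestors integer ancestor indices `A_t`.
#' @param just_backward_sampled logical, `TRUE` when `t = t0 + 1`.
#' @return Integer Enoch indices at `t`.
#' @export
update_enoch <- function(prev_enoch, ancestors, just_backward_sampled) {
  N <- length(prev_enoch)
  if (length(ancestors) != N) stop("index vectors must share length")
  if (any(prev_enoch < 1L | prev_enoch > N)) stop("enoch index out of 1..N")
  if (any(ancestors < 1L | ancestors > N)) stop("ancestor index out of 1..N")
  if (isTRUE(just_backward_sampled)) {
    seq_len(N)
  } else {
    prev_enoch[ancestors]
  }
}

#' Ancestor diversity
#'
#' The number of distinct Enoch indices, `N^anc`; falling diversity signals
#' genealogical degeneracy of the smoothing statistics.
#'
#' @param enoch integer Enoch indices.
#' @return Integer count of distinct values, in `[1, N]`.
#' @export
ancestor_diversity <- function(enoch) {
  length(unique(enoch))
}

# Vectorised backward ancestor draws for a set of current particles.
# Rejection sampling (propose l ~ M(w_{t-1}), accept with probability
# p(x_t | x_{t-1}^{(l)}) / p_max), capped at sqrt(N) proposals per
# particle, then an exact categorical fallback for the stragglers.
# Proposals are batched (several candidates per pending particle per
# round) so the trial budget is consumed in a handful of vectorised
# passes.
backward_indices <- function(prev, x_curr, u_prev, model, theta,
                             max_trials = ceiling(sqrt(length(prev$w)))) {
  N <- length(prev$w)
  n <- nrow(x_curr)
  B <- integer(n)
  pending <- seq_len(n)
  log_pmax <- model$logdensity_max(theta)
  cw <- cumsum(prev$w)
  cw <- cw / cw[N]                         # guard rounding, keep monotone
  # For additive-Gaussian transitions, compute all ancestor means once and
  # evaluate pair densities by plain arithmetic; otherwise fall back to the
  # model's generic pairwise density.
  gaussian <- !is.null(model$transition_mean) &&
    !is.null(model$transition_var)
  if (gaussian) {
    mu <- model$transition_mean(prev$x, u_prev, theta)
    vars <- model$transition_var
    gconst <- -0.5 * (length(vars) * log(2 * pi) + sum(log(vars)))
    pair_logp <- function(l, idx) {
      out <- rep(gconst, length(l))
      for (dd in seq_along(vars)) {
        r <- x_curr[idx, dd] - mu[l, dd]
        out <- out - 0.5 * r * r / vars[dd]
      }
      out
    }
    all_logp <- function(idx_set) {        # N x k log-density matrix
      lp <- matrix(gconst, N, length(idx_set))
      for (dd in seq_along(vars)) {
        r <- outer(mu[, dd], x_curr[idx_set, dd], "-")
        lp <- lp - 0.5 * r * r / vars[dd]
      }
      lp
    }
  } else {
    pair_logp <- function(l, idx) {
      model$dtransition(prev$x[l, , drop = FALSE],
                        x_curr[idx, , drop = FALSE],
                        u_prev, theta, log = TRUE)
    }
    all_logp <- function(idx_set) {
      k <- length(idx_set)
      xp <- prev$x[rep(seq_len(N), k), , drop = FALSE]
      xc <- x_curr[rep(idx_set, each = N), , drop = FALSE]
      matrix(model$dtransition(xp, xc, u_prev, theta, log = TRUE), N, k)
    }
  }
  batch <- 8L
  trials <- 0L
  while (length(pending) > 0L && trials < max_trials) {
    k <- length(pending)
    m <- min(batch, max_trials - trials)
    # m candidate ancestors per pending particle, in one vectorised pass
    l <- findInterval(stats::runif(k * m), cw) + 1L
    idx <- rep(pending, times = m)
    logp <- pair_logp(l, idx)
    acc <- log(stats::runif(k * m)) < logp - log_pmax
    hit <- which(acc)
    if (length(hit)) {
      # first accepted candidate per particle (candidates are ordered
      # column-major: position (j - 1) %% k + 1 is the particle slot)
      slot <- (hit - 1L) %% k + 1L
      first <- !duplicated(slot)
      B[pending[slot[first]]] <- l[hit[first]]
      pending <- pending[-slot[first]]
    }
    trials <- trials + m
  }
  if (length(pending) > 0L) {
    lp <- all_logp(pending) + log(prev$w)
    k <- length(pending)
    for (j in seq_len(k)) {
      mx <- max(lp[, j])
      if (!is.finite(mx)) {
        stop("degenerate backward kernel: all transition densities ",
             "underflowed")
      }
      cs <- cumsum(exp(lp[, j] - mx))
      B[pending[j]] <- findInterval(stats::runif(1L) * cs[N], cs) + 1L
    }
  }
  B
}

#' Backward ancestor sampling
#'
#' Draws one backward ancestor index `B` for a current particle `x_t` from
#' the categorical distribution with un-normalised probabilities
#' `w_{t-1}^{(l)} p(x_t | x_{t-1}^{(l)}, u_prev; theta)` — the smoothing
#' kernel obtained from Bayes' theorem. The default path is
#' rejection-acceptance sampling against the transition-density bound
#' exposed by the model, capped at `sqrt(N)` proposal rounds before an
#' exact categorical fallback; `method = "exact"` forces the direct
#' categorical draw over all `N` terms.
#'
#' @param prev [particle_ensemble()] at `t-1`.
#' @param x_t current state vector (or 1-row matrix).
#' @param u_prev control input applied over `(t-1, t]`.
#' @param model an [new_ssm()] object.
#' @param theta parameter vector.
#' @param stream optional RNG stream.
#' @param method `"rejection"` (default, with exact fallback) or `"exact"`.
#' @return A single integer index in `1..N`.
#' @export
backward_ancestor_sample <- function(prev, x_t, u_prev, model, theta,
                                     stream = NULL,
                                     method = c("rejection", "exact")) {
  method <- match.arg(method)
  x_t <- as_state_matrix(x_t, model$state_dim)
  stopifnot(nrow(x_t) == 1L)
  with_stream(stream, {
    if (method == "exact") {
      backward_indices(prev, x_t, u_prev, model, theta, max_trials = 0L)
    } else {
      backward_indices(prev, x_t, u_prev, model, theta)
    }
  })
}

#' AdaSmooth statistic update
#'
#' Updates the per-particle statistics `kappa` from `t-1` to `t`. The Enoch
#' indices are first advanced (reset to the identity when `t = t0 + 1`,
#' ancestor-composed otherwise) and their diversity measured. While
#' diversity exceeds `beta * N`, the plain stochastic-approximation
#' recursion is applied along the filter genealogy:
#' `kappa_t^{(i)} = (1 - gamma_t) kappa_{t-1}^{(A_t(i))} +
#'  gamma_t s~(x_{t-1}^{(A_t(i))}, x_t^{(i)})`.
#' When diversity has collapsed to `beta * N` or below, one backward
#' ancestor `B_t^{(i)}` is drawn per particle and the half-half blend of the
#' genealogical and backward-sampled updates is used instead, after which
#' `t0` advances so the Enoch indices reset at the next step.
#'
#' @param smooth a [smoothing_state()].
#' @param prev,curr [particle_ensemble()]s at `t-1` and `t` (with `curr`
#'   produced from `prev` by [pf_step()]).
#' @param u_prev control input applied over `(t-1, t]`.
#' @param model an [new_ssm()] object.
#' @param theta parameter vector used in the transition at `t`.
#' @param stream optional RNG stream for the backward draws.
#' @return The updated `smoothing_state`.
#' @export
update_kappa <- function(smooth, prev, curr, u_prev, model, theta,
                         stream = NULL) {
  N <- smooth$N
  t <- curr$t
  anc <- curr$ancestors
  gamma_t <- smooth$gamma(t)
  enoch_new <- update_enoch(smooth$enoch, anc,
                            just_backward_sampled = (t == smooth$t0 + 1L))
  div <- ancestor_diversity(enoch_new)
  s_A <- model$suffstat(prev$x[anc, , drop = FALSE], curr$x, u_prev)
  if (div > smooth$beta * N) {
    smooth$kappa_A <- (1 - gamma_t) * smooth$kappa_A[anc, , drop = FALSE] +
      gamma_t * s_A$A
    smooth$kappa_b <- (1 - gamma_t) * smooth$kappa_b[anc, , drop = FALSE] +
      gamma_t * s_A$b
    smooth$backward <- FALSE
  } else {
    B <- with_stream(stream,
                     backward_indices(prev, curr$x, u_prev, model, theta))
    s_B <- model$suffstat(prev$x[B, , drop = FALSE], curr$x, u_prev)
    smooth$kappa_A <-
      0.5 * ((1 - gamma_t) * smooth$kappa_A[anc, , drop = FALSE] +
               gamma_t * s_A$A) +
      0.5 * ((1 - gamma_t) * smooth$kappa_A[B, , drop = FALSE] +
               gamma_t * s_B$A)
    smooth$kappa_b <-
      0.5 * ((1 - gamma_t) * smooth$kappa_b[anc, , drop = FALSE] +
               gamma_t * s_A$b) +
      0.5 * ((1 - gamma_t) * smooth$kappa_b[B, , drop = FALSE] +
               gamma_t * s_B$b)
    smooth$t0 <- as.integer(t)
    smooth$backward <- TRUE
    smooth$n_backward <- smooth$n_backward + 1L
  }
  smooth$enoch <- enoch_new
  smooth$diversity <- as.integer(div)
  smooth
}

#' Smoothed sufficient statistic
#'
#' The weighted particle average `sum_i w_t^{(i)} kappa_t^{(i)}`, the online
#' estimate of the (decay-averaged) smoothed additive statistic.
#'
#' @param curr [particle_ensemble()] at `t`.
#' @param smooth the matching [smoothing_state()].
#' @return A [suffstat_pair()].
#' @export
smoothed_statistic <- function(curr, smooth) {
  p <- smooth$p
  A <- matrix(colSums(curr$w * smooth$kappa_A), p, p)
  b <- colSums(curr$w * smooth$kappa_b)
  suffstat_pair(A, b)
}

#' Online M-step
#'
#' During burn-in (`t <= T_burnIn`) the previous estimate is returned
#' unchanged while statistics keep accumulating. Afterwards the model's
#' `Lambda` map is applied to the time-averaged statistic `(1/t) S` and the
#' result passed through the model's positivity projection. A numerically
#' singular A-part leaves the previous estimate in place with a warning
#' rather than aborting the closed loop.
#'
#' @param stat a [suffstat_pair()] from [smoothed_statistic()].
#' @param t current time index (>= 1).
#' @param model an [new_ssm()] object.
#' @param smooth the [smoothing_state()] (provides `T_burnIn`).
#' @param theta_prev previous parameter estimate.
#' @return The new parameter estimate vector.
#' @export
em_update <- function(stat, t, model, smooth, theta_prev) {
  stopifnot(t >= 1)
  if (t <= smooth$T_burnIn) {
    return(theta_prev)
  }
  A <- stat$A / t
  b <- stat$b / t
  theta <- tryCatch({
    if (rcond(A) < 1e-12) stop("singular statistics")
    model$lambda(A, b)
  }, error = function(e) NULL)
  if (is.null(theta)) {
    warning("singular sufficient statistics at t = ", t,
            "; keeping previous parameter estimate", call. = FALSE)
    return(theta_prev)
  }
  model$project(theta)
}
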
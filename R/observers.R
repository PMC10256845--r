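#' Logistic sigmoid with probability floor
#'
#' `s(x) = 1 / (1 + exp(-x))`, clamped to `[floor, 1 - floor]` so downstream
#' logs and precisions stay finite.
#'
#' @param x Numeric vector.
#' @param floor Clamping floor (default `1e-12`).
#' @return Probabilities in `(0, 1)`.
#' @export
unit_sigmoid <- function(x, floor = .PFLOOR) {
  clamp_prob(1 / (1 + exp(-x)), floor)
}

#' One belief-update step of the two-level binary HGF
#'
#' Given the previous second-level belief and variance and a binary outcome,
#' computes the full update record: prediction `mu1_hat = s(mu2)`, first-level
#' prediction error `delta = u - mu1_hat`, precisions
#' `pi2_hat = 1/(sigma2 + e^omega)` and `pi2 = pi2_hat + mu1_hat(1-mu1_hat)`,
#' precision-weighted prediction error `epsilon = delta / pi2`, and the new
#' belief `mu2 + epsilon` with variance `1/pi2`.
#'
#' @param prev_mu2 Previous second-level mean.
#' @param prev_sigma2 Previous second-level variance (> 0).
#' @param u Outcome, `1` (gun) or `0` (phone).
#' @param omega Log-volatility.
#' @return Named list with `mu1_hat`, `pi1_hat`, `delta`, `pi2_hat`, `pi2`,
#'   `epsilon`, `mu2`, `sigma2`.
#' @examples
#' hgf2_step(0, 1, u = 1, omega = 0)  # mu2 becomes 2/3
#' @export
hgf2_step <- function(prev_mu2, prev_sigma2, u, omega) {
  stopifnot(prev_sigma2 > 0, u %in% c(0, 1))
  mu1_hat <- unit_sigmoid(prev_mu2)
  pi1_hat <- 1 / (mu1_hat * (1 - mu1_hat))
  delta <- u - mu1_hat
  pi2_hat <- 1 / (prev_sigma2 + exp(omega))
  pi2 <- pi2_hat + 1 / pi1_hat
  epsilon <- delta / pi2
  mu2 <- prev_mu2 + epsilon
  sigma2 <- 1 / pi2
  if (!all(is.finite(c(mu2, sigma2)))) {
    stop_hex("numerical_overflow", "non-finite hgf2 update")
  }
  list(mu1_hat = mu1_hat, pi1_hat = pi1_hat, delta = delta,
       pi2_hat = pi2_hat, pi2 = pi2, epsilon = epsilon,
       mu2 = mu2, sigma2 = sigma2)
}

.traj_df <- function(lst, u) {
  out <- as.data.frame(lst)
  out <- cbind(trial = seq_along(u), u = as.integer(u), out)
  out
}

#' Filter an outcome sequence with the two-level binary HGF
#'
#' Folds [hgf2_step()] over a binary outcome sequence from the initial state
#' `(mu2_0, sigma2_0)`. Each row reports the prediction made *before* the
#' trial's outcome was observed, and the posterior belief after it.
#'
#' @param u Integer vector of outcomes (1 = gun, 0 = phone).
#' @param params Named list with `omega`, and optionally `mu2_0` (default 0)
#'   and `sigma2_0` (default 1).
#' @return Data frame with columns `trial`, `u`, `mu1_hat`, `mu2`, `sigma2`,
#'   `pi2_hat`, `pi2`, `delta`, `epsilon`, `pi1_hat`.
#' @examples
#' hgf2_filter(c(1, 1, 0), list(omega = -2))
#' @export
hgf2_filter <- function(u, params) {
  u <- as.integer(u)
  if (!length(u)) {
    return(data.frame(trial = integer(), u = integer(), mu1_hat = numeric(),
                      mu2 = numeric(), sigma2 = numeric(), pi2_hat = numeric(),
                      pi2 = numeric(), delta = numeric(), epsilon = numeric()))
  }
  stopifnot(all(u %in% c(0L, 1L)))
  p <- modifyList(list(mu2_0 = 0, sigma2_0 = 1), params)
  stopifnot(is.finite(p$omega), p$sigma2_0 > 0)
  out <- .traj_df(hgf2_filter_cpp(u, p$omega, p$mu2_0, p$sigma2_0, .PFLOOR), u)
  out$pi1_hat <- 1 / (out$mu1_hat * (1 - out$mu1_hat))
  out
}

#' Filter an outcome sequence with the three-level binary HGF
#'
#' Adds a third level tracking the (log-)volatility of the second-level random
#' walk: the level-2 step variance on trial `t` is
#' `exp(kappa * mu3 + omega2)`, and `mu3` follows a Gaussian random walk with
#' variance `e^theta`, updated by volatility prediction errors. With
#' `kappa -> 0` the model reduces to the two-level filter with
#' `omega = omega2`.
#'
#' @param u Integer outcome vector.
#' @param params Named list with `omega2`, `theta`, and optionally `kappa`
#'   (default 1), `mu2_0` (0), `sigma2_0` (1), `mu3_0` (1), `sigma3_0` (1).
#' @return Data frame as [hgf2_filter()] plus `mu3` and `sigma3`.
#' @export
hgf3_filter <- function(u, params) {
  u <- as.integer(u)
  if (!length(u)) {
    return(data.frame(trial = integer(), u = integer(), mu1_hat = numeric(),
                      mu2 = numeric(), sigma2 = numeric(), mu3 = numeric(),
                      sigma3 = numeric(), pi2_hat = numeric(), pi2 = numeric(),
                      delta = numeric(), epsilon = numeric()))
  }
  stopifnot(all(u %in% c(0L, 1L)))
  p <- modifyList(list(kappa = 1, mu2_0 = 0, sigma2_0 = 1,
                       mu3_0 = 1, sigma3_0 = 1), params)
  stopifnot(p$kappa >= 0, p$sigma2_0 > 0, p$sigma3_0 > 0)
  out <- .traj_df(hgf3_filter_cpp(u, p$omega2, p$kappa, p$theta, p$mu2_0,
                                  p$sigma2_0, p$mu3_0, p$sigma3_0, .PFLOOR), u)
  out$pi1_hat <- 1 / (out$mu1_hat * (1 - out$mu1_hat))
  out
}

#' Rescorla-Wagner value filter
#'
#' `V_t = V_{t-1} + alpha * (u_t - V_{t-1})`; the prediction for trial `t` is
#' `V_{t-1}`.
#'
#' @param u Integer outcome vector.
#' @param params Named list with `alpha` in (0, 1] and optionally `v0`
#'   (default 0.5).
#' @return Data frame with `trial`, `u`, `mu1_hat` (prediction), `value`,
#'   `delta`.
#' @export
rw_filter <- function(u, params) {
  u <- as.integer(u)
  p <- modifyList(list(v0 = 0.5), params)
  stopifnot(p$alpha > 0, p$alpha <= 1)
  if (!length(u)) {
    return(data.frame(trial = integer(), u = integer(), mu1_hat = numeric(),
                      value = numeric(), delta = numeric()))
  }
  .traj_df(rw_filter_cpp(u, p$alpha, p$v0), u)
}

#' Sutton K1 filter (incremental delta-bar-delta)
#'
#' Adaptive-learning-rate value model: the log learning rate `beta` moves with
#' the correlation between the current prediction error and a trace `h` of
#' recent errors, `beta_t = beta_{t-1} + mu_meta * delta_t * h_{t-1}`, with
#' `alpha_t = exp(beta_t)` capped at 1.
#'
#' @param u Integer outcome vector.
#' @param params Named list with `mu_meta` (> 0), `beta0`, and optionally `v0`
#'   (default 0.5).
#' @return Data frame with `trial`, `u`, `mu1_hat`, `value`, `delta`, `lrate`.
#' @export
k1_filter <- function(u, params) {
  u <- as.integer(u)
  p <- modifyList(list(v0 = 0.5), params)
  stopifnot(p$mu_meta >= 0)
  if (!length(u)) {
    return(data.frame(trial = integer(), u = integer(), mu1_hat = numeric(),
                      value = numeric(), delta = numeric(), lrate = numeric()))
  }
  .traj_df(k1_filter_cpp(u, p$mu_meta, p$beta0, p$v0), u)
}

#' Scalar Kalman value filter
#'
#' Tracks outcome value with gain `k_t = (s_{t-1}+q)/(s_{t-1}+q+r_obs)` and
#' posterior variance `s_t = (1-k_t)(s_{t-1}+q)`.
#'
#' @param u Integer outcome vector.
#' @param params Named list with `q` (>= 0), `r_obs` (> 0), optionally `v0`
#'   (0.5) and `s0` (1).
#' @return Data frame with `trial`, `u`, `mu1_hat`, `value`, `delta`, `gain`,
#'   `svar`.
#' @export
kalman_filter <- function(u, params) {
  u <- as.integer(u)
  p <- modifyList(list(v0 = 0.5, s0 = 1), params)
  stopifnot(p$q >= 0, p$r_obs > 0, p$s0 > 0)
  if (!length(u)) {
    return(data.frame(trial = integer(), u = integer(), mu1_hat = numeric(),
                      value = numeric(), delta = numeric(), gain = numeric(),
                      svar = numeric()))
  }
  .traj_df(kalman_filter_cpp(u, p$q, p$r_obs, p$v0, p$s0), u)
}

#' Unit-square sigmoid response model
#'
#' Maps a predicted gun probability to a shoot probability with decision noise
#' governed by the exploration parameter `zeta`:
#' `p(shoot) = m^zeta / (m^zeta + (1-m)^zeta)`.
#' `zeta = 1` gives probability matching; `zeta -> Inf` gives deterministic
#' argmax responding; `m = 0.5` always maps to 0.5.
#'
#' @param mu1_hat Predicted outcome probability in (0, 1).
#' @param zeta Positive decision-noise exponent.
#' @return Shoot probability, same length as `mu1_hat`.
#' @examples
#' response_prob(0.8, 2)  # 0.64 / 0.68
#' @export
response_prob <- function(mu1_hat, zeta) {
  stopifnot(zeta > 0)
  m <- clamp_prob(mu1_hat)
  # computed on the log scale for numerical stability at large zeta
  lm <- zeta * log(m)
  l1 <- zeta * log1p(-m)
  clamp_prob(1 / (1 + exp(l1 - lm)))
}

.MODELS <- c("hgf2", "hgf3", "rw", "k1", "kalman")

.fill_defaults <- function(model, params) {
  d <- switch(model,
    hgf2 = list(mu2_0 = 0, sigma2_0 = 1),
    hgf3 = list(kappa = 1, mu2_0 = 0, sigma2_0 = 1, mu3_0 = 1, sigma3_0 = 1),
    rw = list(v0 = 0.5),
    k1 = list(v0 = 0.5),
    kalman = list(v0 = 0.5, s0 = 1),
    stop_hex("configuration_error", "unknown model '%s'", model))
  modifyList(d, params)
}

.filter_raw <- function(u, model, p) {
  switch(model,
    hgf2 = hgf2_filter_cpp(u, p$omega, p$mu2_0, p$sigma2_0, .PFLOOR),
    hgf3 = hgf3_filter_cpp(u, p$omega2, p$kappa, p$theta, p$mu2_0, p$sigma2_0,
                           p$mu3_0, p$sigma3_0, .PFLOOR),
    rw = rw_filter_cpp(u, p$alpha, p$v0),
    k1 = k1_filter_cpp(u, p$mu_meta, p$beta0, p$v0),
    kalman = kalman_filter_cpp(u, p$q, p$r_obs, p$v0, p$s0))
}

# fast path for the MAP objective: per-trial predictions only, no data frames
.mu1hat <- function(u, opponent, model, params, pool_opponents = FALSE) {
  p <- .fill_defaults(model, params)
  if (pool_opponents || is.null(opponent)) {
    return(.filter_raw(as.integer(u), model, p)$mu1_hat)
  }
  out <- numeric(length(u))
  for (o in unique(opponent)) {
    idx <- opponent == o
    out[idx] <- .filter_raw(as.integer(u[idx]), model, p)$mu1_hat
  }
  out
}

#' Filter a trial table under a named observer model
#'
#' Runs the selected model over an outcome sequence, by default keeping one
#' belief trajectory per opponent (the two streams share all parameters) and
#' reassembling per-trial records in trial order. Set `pool_opponents = TRUE`
#' for a single pooled stream.
#'
#' @param u Integer outcome vector (1 = gun, 0 = phone).
#' @param model One of `"hgf2"`, `"hgf3"`, `"rw"`, `"k1"`, `"kalman"`.
#' @param params Named parameter list for the model (see the individual filter
#'   functions); the response parameter `zeta` is ignored here.
#' @param opponent Optional character/factor vector of opponent labels aligned
#'   with `u`; required unless `pool_opponents = TRUE`.
#' @param pool_opponents If `TRUE`, ignore opponents and run one stream.
#' @return Trajectory data frame in trial order with an `opponent` column.
#' @export
filter_model <- function(u, model, params, opponent = NULL,
                         pool_opponents = FALSE) {
  if (!model %in% .MODELS) {
    stop_hex("configuration_error", "unknown model '%s'", model)
  }
  f <- switch(model, hgf2 = hgf2_filter, hgf3 = hgf3_filter, rw = rw_filter,
              k1 = k1_filter, kalman = kalman_filter)
  if (pool_opponents || is.null(opponent)) {
    out <- f(u, params)
    out$opponent <- "pooled"
    return(out)
  }
  stopifnot(length(opponent) == length(u))
  pieces <- lapply(split(seq_along(u), opponent), function(idx) {
    tr <- f(u[idx], params)
    tr$trial <- idx
    tr$opponent <- opponent[idx]
    tr
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$trial), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate an agent's responses on a task schedule
#'
#' Filters the outcome sequence under the given model and parameters, converts
#' each trial's prediction to a shoot probability through the unit-square
#' sigmoid, and draws responses `shoot`/`withhold`, optionally injecting
#' missing responses completely at random.
#'
#' @param schedule A `hex_schedule`.
#' @param u Outcome sequence aligned with the schedule.
#' @param model Model identifier (see [filter_model()]).
#' @param params Model parameters including the response parameter `zeta`.
#' @param seed Integer seed for response sampling.
#' @param missing_rate Probability that a trial's response is missing.
#' @param pool_opponents Single pooled belief stream if `TRUE`.
#' @return Data frame with columns `trial`, `opponent`, `threat`, `p_gun`,
#'   `u`, `p_shoot`, `response` (`"shoot"`, `"withhold"`, `"missing"`), plus
#'   the trajectory columns.
#' @export
simulate_agent <- function(schedule, u, model, params, seed = 1L,
                           missing_rate = 0, pool_opponents = FALSE) {
  stopifnot(inherits(schedule, "hex_schedule"), length(u) == nrow(schedule))
  traj <- filter_model(u, model, params, opponent = schedule$opponent,
                       pool_opponents = pool_opponents)
  p_shoot <- response_prob(traj$mu1_hat, params$zeta)
  rs <- .save_rng_state()
  on.exit(.restore_rng_state(rs), add = TRUE)
  set.seed(seed)
  shoot <- rbinom(length(p_shoot), 1L, p_shoot)
  response <- ifelse(shoot == 1L, "shoot", "withhold")
  if (missing_rate > 0) {
    response[runif(length(response)) < missing_rate] <- "missing"
  }
  out <- data.frame(trial = schedule$trial, opponent = schedule$opponent,
                    threat = schedule$threat, p_gun = schedule$p_gun,
                    u = as.integer(u), p_shoot = p_shoot,
                    response = response, stringsAsFactors = FALSE)
  extra <- traj[, setdiff(names(traj), c("trial", "u", "opponent")),
                drop = FALSE]
  cbind(out, extra)
}
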
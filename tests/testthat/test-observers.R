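test_that("hgf2_step reproduces the hand-computed update record", {
  s <- hgf2_step(0, 1, u = 1, omega = 0)
  expect_equal(s$mu1_hat, 0.5)
  expect_equal(s$delta, 0.5)
  expect_equal(s$pi2_hat, 0.5)
  expect_equal(s$pi2, 0.75)
  expect_equal(s$epsilon, 2 / 3)
  expect_equal(s$mu2, 2 / 3)
  expect_equal(s$sigma2, 4 / 3)
  # mirror case
  m <- hgf2_step(0, 1, u = 0, omega = 0)
  expect_equal(m$epsilon, -2 / 3)
  expect_equal(m$mu2, -2 / 3)
})

test_that("hgf2_filter equals folding hgf2_step (independent R unroll)", {
  set.seed(4)
  u <- rbinom(50, 1, 0.7)
  omega <- -1.3
  traj <- hgf2_filter(u, list(omega = omega, mu2_0 = 0.2, sigma2_0 = 1.5))
  mu2 <- 0.2; s2 <- 1.5
  for (t in seq_along(u)) {
    st <- hgf2_step(mu2, s2, u[t], omega)
    expect_equal(traj$mu2[t], st$mu2, tolerance = 1e-12)
    expect_equal(traj$sigma2[t], st$sigma2, tolerance = 1e-12)
    expect_equal(traj$epsilon[t], st$epsilon, tolerance = 1e-12)
    mu2 <- st$mu2; s2 <- st$sigma2
  }
})

test_that("hgf2 trajectories satisfy the update algebra and limits", {
  # repeated hostile outcomes: beliefs increase monotonically towards 1
  traj <- hgf2_filter(rep(1L, 500), list(omega = -1))
  expect_true(all(diff(traj$mu2) > 0))
  expect_gt(traj$mu1_hat[500], 0.99)
  expect_true(all(traj$delta > 0))
  # frozen environment: omega -> -Inf shrinks uncertainty monotonically
  frozen <- hgf2_filter(rbinom(100, 1, 0.5), list(omega = -30))
  expect_true(all(diff(frozen$sigma2) < 0))
  expect_true(all(abs(frozen$epsilon[51:100]) < abs(frozen$epsilon[1]) ))
  # empty input
  expect_equal(nrow(hgf2_filter(integer(), list(omega = 0))), 0L)
})

test_that("hgf3 reduces to hgf2 when the volatility level decouples", {
  set.seed(5)
  u <- rbinom(200, 1, 0.8)
  t2 <- hgf2_filter(u, list(omega = -3))
  t3 <- hgf3_filter(u, list(omega2 = -3, theta = -6, kappa = 1e-10))
  expect_equal(t3$mu2, t2$mu2, tolerance = 1e-8)
  expect_equal(t3$sigma2, t2$sigma2, tolerance = 1e-8)
  # frozen level 3 at mu3 = mu3_0 shifts the effective omega by kappa * mu3
  t3b <- hgf3_filter(u, list(omega2 = -4, theta = -40, kappa = 1,
                             mu3_0 = 1, sigma3_0 = 1e-10))
  t2b <- hgf2_filter(u, list(omega = -3))
  expect_equal(t3b$mu2, t2b$mu2, tolerance = 1e-6)
})

test_that("hgf3 volatility estimate rises in a volatile regime", {
  # averaged over outcome realisations: reversals between near-deterministic
  # contingencies push the volatility belief above the stationary regime
  p <- list(omega2 = -3, theta = -4, kappa = 1)
  d <- vapply(1:12, function(s) {
    stable <- long_outcomes(1, 300, p = 0.95, seed = s)
    volatile <- long_outcomes(15, 20, p = 0.95, seed = s)
    mean(hgf3_filter(volatile, p)$mu3) - mean(hgf3_filter(stable, p)$mu3)
  }, numeric(1))
  expect_gt(mean(d), 0)
})

test_that("value filters match their closed forms", {
  u <- c(1L, 1L, 0L, 1L)
  # full updating tracks the input exactly
  expect_equal(rw_filter(u, list(alpha = 1))$value, as.numeric(u))
  # single step from the default start
  expect_equal(rw_filter(1L, list(alpha = 0.1))$value, 0.55)
  # geometric closed form under constant input
  tr <- rw_filter(rep(1L, 30), list(alpha = 0.23, v0 = 0.1))
  expect_equal(tr$value, 1 - (1 - 0.23)^(1:30) * 0.9, tolerance = 1e-12)

  # K1 with frozen meta-learning is Rescorla-Wagner with alpha = exp(beta0)
  set.seed(7)
  u2 <- rbinom(100, 1, 0.7)
  k1 <- k1_filter(u2, list(mu_meta = 0, beta0 = log(0.3)))
  rw <- rw_filter(u2, list(alpha = 0.3))
  expect_equal(k1$value, rw$value, tolerance = 1e-12)
  # first step of the error trace: h1 = alpha1 * delta1 exactly
  k1b <- k1_filter(1L, list(mu_meta = 0.05, beta0 = log(0.2)))
  expect_equal(k1b$lrate[1] * k1b$delta[1], 0.2 * 0.5)
  # alternating errors of equal magnitude drive the learning rate down
  ualt <- rep(c(1L, 0L), 50)
  k1c <- k1_filter(ualt, list(mu_meta = 0.3, beta0 = log(0.5), v0 = 0.5))
  expect_lte(log(k1c$lrate[100]), log(0.5) + 1e-9)

  # Kalman: noiseless observation limit tracks input; static world freezes
  kf <- kalman_filter(u2, list(q = 0.1, r_obs = 1e-12))
  expect_equal(kf$value, as.numeric(u2), tolerance = 1e-6)
  kf0 <- kalman_filter(u2, list(q = 0, r_obs = 1))
  expect_true(all(diff(kf0$svar) < 0))
  # steady-state posterior variance solves s = (1-k)(s+q)
  kf1 <- kalman_filter(rep(1L, 2000), list(q = 0.1, r_obs = 1))
  s_inf <- kf1$svar[2000]
  k_inf <- (s_inf + 0.1) / (s_inf + 0.1 + 1)
  expect_equal(s_inf, (1 - k_inf) * (s_inf + 0.1), tolerance = 1e-10)
  expect_equal(kf1$svar[1999], s_inf, tolerance = 1e-8)
})

test_that("unit-square sigmoid response model has the stated properties", {
  expect_equal(response_prob(0.8, 2), 0.64 / 0.68)
  expect_equal(response_prob(0.5, 7.3), 0.5)
  m <- runif(50, 0.01, 0.99)
  expect_equal(response_prob(m, 1), m, tolerance = 1e-12)
  # complementarity and monotonicity
  expect_equal(response_prob(m, 2.5) + response_prob(1 - m, 2.5), rep(1, 50),
               tolerance = 1e-12)
  grid <- seq(0.01, 0.99, length.out = 100)
  expect_true(all(diff(response_prob(grid, 3)) > 0))
  expect_true(all(diff(vapply(c(1, 2, 4, 8), function(z)
    response_prob(0.7, z), numeric(1))) > 0))
  # logistic sigmoid identity s(x) + s(-x) = 1
  x <- rnorm(100, sd = 3)
  expect_equal(unit_sigmoid(x) + unit_sigmoid(-x), rep(1, 100),
               tolerance = 1e-12)
})

test_that("simulate_agent is reproducible and respects the decision limit", {
  sched <- default_schedule()
  u <- sample_outcomes(sched, seed = 1)
  a1 <- simulate_agent(sched, u, "hgf2", list(omega = -3, zeta = 2), seed = 9)
  a2 <- simulate_agent(sched, u, "hgf2", list(omega = -3, zeta = 2), seed = 9)
  expect_identical(a1$response, a2$response)
  # near-deterministic responding at huge zeta follows the argmax prediction
  det <- simulate_agent(sched, u, "hgf2", list(omega = -3, zeta = 1000),
                        seed = 10)
  decided <- det$mu1_hat != 0.5  # first trial per opponent is indifferent
  expect_equal(det$response[decided],
               ifelse(det$mu1_hat[decided] > 0.5, "shoot", "withhold"))
  expect_error(simulate_agent(sched, u, "nope", list(zeta = 1)),
               class = "configuration_error")
})

test_that("hgf2 agents shoot more where gun probability is high", {
  sched <- default_schedule()
  diffs <- vapply(1:100, function(s) {
    u <- sample_outcomes(sched, seed = s)
    sim <- simulate_agent(sched, u, "hgf2", list(omega = -3, zeta = 2),
                          seed = 1000 + s)
    shoot <- sim$response == "shoot"
    mean(shoot[sched$p_gun == 0.8]) - mean(shoot[sched$p_gun == 0.2])
  }, numeric(1))
  expect_gt(mean(diffs), 0.1)
})

test_that("missing responses are injected as an explicit category", {
  sched <- default_schedule()
  u <- sample_outcomes(sched, seed = 2)
  sim <- simulate_agent(sched, u, "hgf2", list(omega = -3, zeta = 2),
                        seed = 11, missing_rate = 0.2)
  expect_true("missing" %in% sim$response)
  expect_equal(nrow(sim), 160L)
})
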
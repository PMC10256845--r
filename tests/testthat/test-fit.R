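test_that("neg_log_joint decomposes into likelihood and prior terms", {
  pr <- model_priors("hgf2")
  # zeta ~ 0 makes every shoot probability 0.5: likelihood term is n log 2
  a <- make_agent(seed = 21)
  est <- c(omega = -3, log_zeta = -30)
  obj <- neg_log_joint(est, a$u, a$sim$response, "hgf2", pr,
                       opponent = a$sched$opponent)
  prior_term <- -sum(dnorm(est, pr$mean, pr$sd, log = TRUE))
  expect_equal(obj - prior_term, 160 * log(2), tolerance = 1e-6)
  # zero trials at the prior mean: only the normalisation constants remain
  est0 <- c(omega = pr$mean["omega"], log_zeta = pr$mean["log_zeta"])
  names(est0) <- c("omega", "log_zeta")
  obj0 <- neg_log_joint(est0, integer(), integer(), "hgf2", pr)
  expect_equal(obj0, sum(log(pr$sd * sqrt(2 * pi))), tolerance = 1e-12)
  # all-missing responses are rejected
  expect_error(neg_log_joint(est, a$u, rep(NA_integer_, 160), "hgf2", pr,
                             opponent = a$sched$opponent),
               class = "insufficient_data")
})

test_that("fit_map recovers Rescorla-Wagner parameters from long data", {
  u <- long_outcomes(50, 200, p = 0.8, seed = 22)  # 10^4 trials
  tr <- rw_filter(u, list(alpha = 0.3))
  set.seed(23)
  resp <- rbinom(length(u), 1, response_prob(tr$mu1_hat, 5))
  fit <- fit_map(u, resp, model = "rw", n_starts = 3, seed = 24,
                 pool_opponents = TRUE)
  expect_lt(abs(fit$estimates$alpha - 0.3), 0.05)
  expect_lt(abs(log(fit$estimates$zeta) - log(5)), 0.25)
  expect_true(is.finite(fit$log_model_evidence))
  expect_gte(fit$n_starts_converged, 1)
})

test_that("Laplace evidence matches brute-force quadrature for one parameter", {
  a <- make_agent(omega = -2.5, zeta = 2, seed = 25)
  pr <- model_priors("hgf2")
  fix <- c(log_zeta = log(2))
  fit <- fit_map(a$u, a$sim$response, model = "hgf2", priors = pr,
                 opponent = a$sched$opponent, n_starts = 3, seed = 26,
                 fix = fix)
  grid <- seq(-12, 3, length.out = 10000)
  h <- grid[2] - grid[1]
  lp <- vapply(grid, function(om) {
    -neg_log_joint(c(omega = om, fix), a$u, a$sim$response, "hgf2", pr,
                   opponent = a$sched$opponent)
  }, numeric(1))
  m <- max(lp)
  log_z <- m + log(sum(exp(lp - m)) * h)
  expect_lt(abs(fit$log_model_evidence - log_z), 0.1)
})

test_that("deterministic responding drives zeta into the flagged upper region", {
  sched <- default_schedule()
  u <- sample_outcomes(sched, seed = 27)
  traj <- filter_model(u, "hgf2", list(omega = -3), opponent = sched$opponent)
  resp <- ifelse(traj$mu1_hat > 0.5, 1L, 0L)
  fit <- fit_map(u, resp, model = "hgf2", opponent = sched$opponent,
                 n_starts = 3, seed = 28)
  expect_true("zeta_upper_region" %in% fit$flags)
})

test_that("fit_map enforces its minimum-data precondition", {
  a <- make_agent(seed = 29)
  r <- encode_responses(a$sim$response)
  r[10:160] <- NA
  expect_error(fit_map(a$u, r, model = "hgf2", opponent = a$sched$opponent),
               class = "insufficient_data")
})

test_that("condition splitting requires both conditions and enough data", {
  a <- make_agent(seed = 30)
  tr <- data.frame(u = as.integer(a$u), response = a$sim$response,
                   threat = a$sched$threat, opponent = a$sched$opponent)
  single <- tr[tr$threat == "high", ]
  expect_error(fit_by_condition(single), class = "insufficient_data")
  sparse <- tr
  sparse$response[sparse$threat == "low"][1:75] <- "missing"
  expect_error(fit_by_condition(sparse), class = "insufficient_data")
})

test_that("per-condition fits recover a true omega difference ordering", {
  sched <- default_schedule()
  n <- 30
  ordered <- logical(n)
  for (i in seq_len(n)) {
    u <- sample_outcomes(sched, seed = 400 + i)
    hi <- which(sched$threat == "high")
    lo <- which(sched$threat == "low")
    resp <- character(160)
    set.seed(500 + i)
    for (cc in list(list(idx = hi, om = -2), list(idx = lo, om = -4))) {
      tr <- filter_model(u[cc$idx], "hgf2", list(omega = cc$om),
                         opponent = sched$opponent[cc$idx])
      p <- response_prob(tr$mu1_hat, 3)
      resp[cc$idx] <- ifelse(rbinom(length(p), 1, p) == 1, "shoot", "withhold")
    }
    fits <- fit_by_condition(
      data.frame(u = as.integer(u), response = resp, threat = sched$threat,
                 opponent = sched$opponent),
      model = "hgf2", n_starts = 2, seed = 600 + i)
    ordered[i] <- fits$high$estimates$omega > fits$low$estimates$omega
  }
  expect_gte(mean(ordered), 0.8)
})

test_that("condition summaries respect the telescoping belief identity", {
  a <- make_agent(seed = 31)
  tr <- data.frame(u = as.integer(a$u), response = a$sim$response,
                   threat = a$sched$threat, opponent = a$sched$opponent)
  fits <- fit_by_condition(tr, model = "hgf2", n_starts = 2, seed = 32)
  sm <- summarize_conditions(fits)
  expect_setequal(sm$condition, c("high", "low"))
  for (cc in c("high", "low")) {
    traj <- fits[[cc]]$trajectory
    mu0 <- fits[[cc]]$estimates$mu2_0
    for (o in unique(traj$opponent)) {
      stream <- traj[traj$opponent == o, ]
      expect_equal(sum(stream$epsilon), stream$mu2[nrow(stream)] - mu0,
                   tolerance = 1e-8)
    }
    expect_equal(sm$mean_mu2[sm$condition == cc], mean(traj$mu2))
  }
})

test_that("missing-trial exclusion applies a strict threshold", {
  mk <- function(n_missing) {
    data.frame(subject = "s1",
               response = c(rep("missing", n_missing),
                            rep("shoot", 160 - n_missing)))
  }
  expect_true(exclude_missing(mk(40), 0.25)[["s1"]])    # 25%: not > threshold
  expect_false(exclude_missing(mk(41), 0.25)[["s1"]])
  # sensitivity reanalysis reinstates subjects up to 50%
  expect_true(exclude_missing(mk(41), 0.50)[["s1"]])
  expect_true(exclude_missing(mk(80), 0.50)[["s1"]])
  expect_false(exclude_missing(mk(81), 0.50)[["s1"]])
})

test_that("parameter outlier exclusion is a single full-sample pass", {
  same <- data.frame(subject = paste0("s", 1:5), omega = rep(-3, 5),
                     zeta = rep(2, 5))
  mask <- suppressWarnings(exclude_param_outliers(same))
  expect_warning(exclude_param_outliers(same[, c("subject", "omega")]),
                 "zero variance")
  expect_true(all(mask))
  set.seed(33)
  tab <- data.frame(subject = paste0("s", 1:30), omega = rnorm(30, -3, 0.5))
  tab$omega[1] <- -3 + 3 * sd(tab$omega)
  base_sd <- sd(tab$omega); base_mean <- mean(tab$omega)
  mask <- exclude_param_outliers(tab, k_sd = 2)
  expect_equal(unname(mask), tab$omega >= base_mean - 2 * base_sd &
                 tab$omega <= base_mean + 2 * base_sd)
  expect_false(mask[["s1"]])
  # Gaussian tail rate ~ 2 Phi(-2)
  set.seed(34)
  big <- data.frame(subject = seq_len(5000), x = rnorm(5000))
  frac <- mean(!exclude_param_outliers(big, k_sd = 2))
  expect_lt(abs(frac - 2 * pnorm(-2)), 0.012)
  expect_error(exclude_param_outliers(same[1:2, ]), class = "insufficient_data")
})

test_that("widening the prior never lowers the maximised likelihood", {
  a <- make_agent(seed = 35)
  ll_of <- function(preset) {
    pr <- model_priors("hgf2", preset)
    fit <- fit_map(a$u, a$sim$response, model = "hgf2", priors = pr,
                   opponent = a$sched$opponent, n_starts = 3, seed = 36)
    -(fit$objective -
        (-sum(dnorm(fit$est[names(pr$mean)], pr$mean, pr$sd, log = TRUE))))
  }
  expect_gte(ll_of("wide"), ll_of("default") - 1e-6)
})
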
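mimic_model <- function() {
  sem_model("agg =~ ind1 + ind2 + ind3 + ind4
             agg ~ omega + mu + sigma + epsilon + zeta")
}

test_that("model parser understands the three statement types", {
  m <- sem_model("f1 =~ a + b + c; f2 =~ d + e + g; f1 ~~ f2; f1 ~ x1 + x2")
  expect_equal(m$latents, c("f1", "f2"))
  expect_equal(m$indicators, c("a", "b", "c", "d", "e", "g"))
  expect_equal(m$predictors, c("x1", "x2"))
  expect_length(m$covs, 1)
  expect_error(sem_model("f1 =~ a + b; f1 ~ a"), class = "configuration_error")
  expect_error(sem_model("just words"), class = "configuration_error")
  expect_error(sem_model("f ~ x"), class = "configuration_error")
})

test_that("the MIMIC model has the published degrees of freedom", {
  d <- generate_mimic_cohort(300, seed = 1)
  f <- fit_ml_sem(d, mimic_model(), se = FALSE)
  # 9 observed -> 45 moments; 15 fixed predictor moments; 13 free parameters
  expect_equal(f$df, 17)
})

test_that("perfect-fit identity: model-implied covariance gives exact fit", {
  d <- generate_mimic_cohort(2000, seed = 2)
  f <- fit_ml_sem(d, mimic_model(), se = FALSE)
  f0 <- fit_ml_sem(model = mimic_model(), sample_cov = f$implied, n = 500)
  expect_lt(f0$chi_square, 1e-6)
  expect_equal(f0$cfi, 1)
  expect_equal(f0$rmsea, 0)
  expect_lt(f0$srmr, 1e-5)
  expect_gte(f0$fml, 0)
})

test_that("large-sample MIMIC recovery reproduces the generating coefficients", {
  d <- generate_mimic_cohort(10000, seed = 3)
  f <- fit_ml_sem(d, mimic_model())
  gt <- f$standardized$gamma_table
  b_true <- attr(d, "b_true")
  expect_equal(gt$std[match(names(b_true), gt$predictor)],
               unname(b_true), tolerance = 0.05)
  expect_true(f$converged)
  # z-scored world: structural p-values flag exactly the non-null paths
  expect_true(all(gt$p_value[gt$predictor != "zeta"] < 0.001))
  expect_gt(gt$p_value[gt$predictor == "zeta"], 0.05)
})

test_that("standardized solution is invariant to indicator rescaling", {
  d <- generate_mimic_cohort(800, seed = 4)
  f1 <- fit_ml_sem(d, mimic_model(), standardize = FALSE, se = FALSE)
  d2 <- d
  d2$ind1 <- d2$ind1 * 10 + 5
  d2$ind3 <- d2$ind3 / 3
  f2 <- fit_ml_sem(d2, mimic_model(), standardize = FALSE, se = FALSE)
  expect_equal(f2$standardized$loadings, f1$standardized$loadings,
               tolerance = 1e-4)
  expect_equal(f2$standardized$gamma_table$std, f1$standardized$gamma_table$std,
               tolerance = 1e-4)
  expect_equal(f2$chi_square, f1$chi_square, tolerance = 1e-4)
})

test_that("factor scores are centred and track loading strength", {
  set.seed(5)
  n <- 1500
  trait <- rnorm(n)
  d <- data.frame(strong = 0.9 * trait + sqrt(1 - 0.81) * rnorm(n),
                  mid = 0.6 * trait + 0.8 * rnorm(n),
                  weak = 0.2 * trait + sqrt(1 - 0.04) * rnorm(n))
  m <- sem_model("f =~ strong + mid + weak")
  f <- fit_ml_sem(d, m)
  sc <- factor_scores(f, d)
  expect_equal(mean(sc[, "f"]), 0, tolerance = 1e-8)
  expect_gt(cor(sc[, "f"], d$strong), cor(sc[, "f"], d$weak))
  expect_gt(cor(sc[, "f"], trait), 0.8)
})

test_that("structure comparison ranks the generating model first", {
  # two correlated factors, four indicators each (the questionnaire layout)
  co <- generate_cohort(population_spec(n_subjects = 400, seed = 6,
                                        missing_rate = 0),
                        include = "questionnaires")
  q <- co$questionnaires
  two <- sem_model("agg =~ bpaq_physical + bpaq_verbal + bpaq_anger + bpaq_hostility
                    psy =~ srp_ipm + srp_ca + srp_els + srp_ct
                    agg ~~ psy")
  one <- sem_model(paste("g =~ bpaq_physical + bpaq_verbal + bpaq_anger +",
                         "bpaq_hostility + srp_ipm + srp_ca + srp_els + srp_ct"))
  cmp <- compare_structures(q, list(two_factor = two, single_factor = one),
                            se = FALSE)
  expect_equal(cmp$table$model[1], "two_factor")
  cfi <- setNames(cmp$table$cfi, cmp$table$model)
  expect_gt(cfi[["two_factor"]], cfi[["single_factor"]])
  # nesting: freeing the factor correlation cannot worsen chi-square
  chi <- setNames(cmp$table$chi_square, cmp$table$model)
  expect_lte(chi[["two_factor"]], chi[["single_factor"]] + 1e-6)
  # the recovered factor correlation approximates the generating 0.639
  expect_equal(cmp$fits$two_factor$standardized$psi["agg", "psy"], 0.639,
               tolerance = 0.08)
  # duplicated model gives identical indices
  cmp2 <- compare_structures(q, list(a = two, b = two), se = FALSE)
  expect_equal(cmp2$table$chi_square[1], cmp2$table$chi_square[2],
               tolerance = 1e-8)
})

test_that("bootstrap intervals cover the generating coefficients", {
  d <- generate_mimic_cohort(400, seed = 7)
  bt <- sem_bootstrap(d, mimic_model(), n_boot = 80, seed = 8)
  b_true <- attr(d, "b_true")
  ci <- bt$ci[match(paste0("agg~", names(b_true)), bt$ci$parameter), ]
  covered <- b_true >= ci$lower & b_true <= ci$upper
  expect_gte(sum(covered), 4)
  # the strong epsilon path is bounded away from zero
  eps <- ci[ci$parameter == "agg~epsilon", ]
  expect_gt(eps$lower, 0)
})

test_that("analytic ML gradient matches central finite differences", {
  m <- sem_model("f1 =~ a + b + c; f2 =~ d + e + g2; f1 ~~ f2; f1 ~ x1 + x2")
  set.seed(10)
  n <- 300
  x1 <- rnorm(n); x2 <- 0.3 * x1 + rnorm(n)
  f1 <- 0.4 * x1 - 0.2 * x2 + rnorm(n); f2 <- 0.5 * f1 + rnorm(n)
  d <- data.frame(a = 0.8 * f1 + rnorm(n), b = 0.7 * f1 + rnorm(n),
                  c = 0.6 * f1 + rnorm(n), d = 0.8 * f2 + rnorm(n),
                  e = 0.7 * f2 + rnorm(n), g2 = 0.6 * f2 + rnorm(n),
                  x1 = x1, x2 = x2)
  layout <- hexlearn:::.sem_layout(m)
  X <- scale(as.matrix(d[, c(m$indicators, m$predictors)]))
  S <- cov(X)
  Phi <- S[m$predictors, m$predictors]
  lds <- determinant(S, logarithm = TRUE)$modulus[1]
  obj <- function(th) {
    hexlearn:::.fml(hexlearn:::.sem_implied(
      hexlearn:::.sem_matrices(th, layout), Phi)$Sigma, S, lds)
  }
  th <- c(rep(0.7, nrow(layout$lam)), rep(0.1, nrow(layout$gam)),
          rep(log(0.5), layout$p), 0.2) + rnorm(layout$n_free, 0, 0.05)
  ga <- hexlearn:::.fml_grad(th, layout, Phi, S)
  gn <- vapply(seq_along(th), function(j) {
    h <- 1e-6; tp <- th; tm <- th
    tp[j] <- tp[j] + h; tm[j] <- tm[j] - h
    (obj(tp) - obj(tm)) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(ga - gn) / (abs(gn) + 1e-8)), 1e-5)
})

test_that("estimation guards fire on bad input", {
  d <- generate_mimic_cohort(8, seed = 9)
  expect_error(fit_ml_sem(d, mimic_model()), class = "insufficient_data")
  expect_error(fit_ml_sem(d[0, ], mimic_model()), class = "insufficient_data")
})
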
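test_that("t-tests agree with stats::t.test and handle degenerate input", {
  set.seed(1)
  x <- rnorm(25); y <- rnorm(25, 0.4)
  p <- paired_t(x, y)
  ref <- t.test(x, y, paired = TRUE)
  expect_equal(p$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(p$p_value, ref$p.value, tolerance = 1e-12)
  expect_equal(p$effect_size, mean(x - y) / sd(x - y))

  i <- independent_t(x, y)
  ref2 <- t.test(x, y, var.equal = TRUE)
  expect_equal(i$statistic, unname(ref2$statistic), tolerance = 1e-12)
  expect_equal(i$p_value, ref2$p.value, tolerance = 1e-12)

  # identical vectors: flat zero effect; pure shift with no noise: error
  z <- paired_t(x, x)
  expect_equal(z$statistic, 0)
  expect_equal(z$p_value, 1)
  expect_lt(z$bf10, 1)
  expect_error(paired_t(x, x + 1), class = "degenerate_data")
})

test_that("paired t-test maintains its nominal type-I error", {
  set.seed(2)
  n_rep <- 2000
  rej <- vapply(seq_len(n_rep), function(i) {
    x <- rnorm(20); y <- rnorm(20)
    paired_t(x, y)$p_value < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.015)
})

# independent oracle: Gauss-Legendre quadrature of the Rouder et al. integrand
# on g/(1+g) in (0,1), coded separately from the integrate()-based path
jzs_oracle <- function(t, n, n2 = NULL, scale = sqrt(2) / 2, nodes = 60000) {
  if (is.null(n2)) { N <- n; nu <- n - 1 } else {
    N <- n * n2 / (n + n2); nu <- n + n2 - 2
  }
  h <- seq(0, 1, length.out = nodes + 2)[2:(nodes + 1)]
  w <- 1 / (nodes + 1)
  g <- h / (1 - h)
  jac <- 1 / (1 - h)^2
  fg <- (1 + N * g)^(-0.5) *
    (1 + t^2 / ((1 + N * g) * nu))^(-(nu + 1) / 2) *
    sqrt(scale^2 / (2 * pi)) * g^(-1.5) * exp(-scale^2 / (2 * g))
  num <- sum(fg * jac * w)
  num / (1 + t^2 / nu)^(-(nu + 1) / 2)
}

test_that("JZS Bayes factor matches an independent quadrature oracle", {
  cases <- list(c(0, 50), c(1.2, 20), c(2.5, 30), c(4, 100), c(-2.2, 15))
  for (cs in cases) {
    bf <- jzs_bf_ttest(cs[1], cs[2])
    expect_lt(abs(bf - jzs_oracle(cs[1], cs[2])) / bf, 1e-4)
  }
  # two-sample variant
  bf2 <- jzs_bf_ttest(2.8, 24, 26)
  expect_lt(abs(bf2 - jzs_oracle(2.8, 24, 26)) / bf2, 1e-4)
  # direction and monotonicity
  expect_lt(jzs_bf_ttest(0, 50), 1)
  bfs <- vapply(c(0, 1, 2, 3, 5), jzs_bf_ttest, numeric(1), n = 40)
  expect_true(all(diff(bfs) > 0))
})

test_that("Bayes factors reproduce published reference values", {
  # deterministic functions of (t, n) / (r, n); reference software printed
  # BF = 0.799 for t(240) = 2.21 and BF = 54.98 for r = 0.238 at n = 207
  expect_equal(jzs_bf_ttest(2.21, 241), 0.799, tolerance = 0.05)
  expect_equal(jzs_bf_cor(0.238, 207), 54.98, tolerance = 0.10)
})

test_that("correlation test is calibrated and invariant", {
  set.seed(3)
  x <- rnorm(60); y <- 0.5 * x + rnorm(60)
  a <- pearson_cor_test(x, y)
  expect_equal(a$statistic, cor(x, y))
  expect_equal(a$p_value, cor.test(x, y)$p.value, tolerance = 1e-10)
  b <- pearson_cor_test(y, x)
  expect_equal(a$statistic, b$statistic)
  cc <- pearson_cor_test(2 + 3 * x, y)
  expect_equal(cc$statistic, a$statistic, tolerance = 1e-12)
  expect_equal(pearson_cor_test(x, x)$statistic, 1)
  expect_error(pearson_cor_test(x, rep(1, 60)), class = "degenerate_data")
  # null p-values are uniform
  set.seed(4)
  pv <- vapply(1:1500, function(i) {
    pearson_cor_test(rnorm(20), rnorm(20))$p_value
  }, numeric(1))
  expect_gt(ks.test(pv, "punif")$p.value, 0.01)
})

test_that("2x2 repeated-measures ANOVA matches aov and the F = t^2 identity", {
  set.seed(5)
  n <- 16
  d <- expand.grid(subject = factor(1:n), a = c("a1", "a2"), b = c("b1", "b2"))
  d$value <- rnorm(nrow(d)) + as.numeric(d$a == "a1") * 0.5 +
    rnorm(n)[d$subject]
  res <- rm_anova_2x2(d)

  # oracle: stats::aov with the within-subject error strata
  ref <- summary(aov(value ~ a * b + Error(subject / (a * b)), data = d))
  f_ref <- c(A = ref[["Error: subject:a"]][[1]]$`F value`[1],
             B = ref[["Error: subject:b"]][[1]]$`F value`[1],
             AB = ref[["Error: subject:a:b"]][[1]]$`F value`[1])
  for (eff in c("A", "B", "AB")) {
    expect_equal(res[[eff]]$statistic, unname(f_ref[eff]), tolerance = 1e-8)
  }
  # each F is the square of the matching paired contrast t
  mA <- aggregate(value ~ subject + a, d, mean)
  tA <- paired_t(mA$value[mA$a == "a1"], mA$value[mA$a == "a2"])
  expect_equal(res$A$statistic, tA$statistic^2, tolerance = 1e-8)
  expect_equal(res$A$p_value, tA$p_value, tolerance = 1e-10)

  # constant data: all effects null
  d0 <- d; d0$value <- rnorm(n)[d0$subject]
  res0 <- rm_anova_2x2(d0)
  expect_equal(res0$A$statistic, 0, tolerance = 1e-20)
  expect_error(rm_anova_2x2(d[d$a == "a1", ]), class = "incomplete_design")
})

test_that("BH q-values match the brute-force step-up rule", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_bh(c(0.005, 0.5)), c(0.01, 0.5))
  expect_equal(fdr_bh(0.2), 0.2)
  set.seed(6)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    q <- fdr_bh(p)
    expect_equal(q, p.adjust(p, "BH"), tolerance = 1e-12)
    # brute-force step-up: reject the largest k with p_(k) <= k/m * alpha
    for (alpha in c(0.05, 0.2)) {
      o <- order(p)
      thresh <- which(p[o] <= seq_along(p) / length(p) * alpha)
      rej_brute <- if (length(thresh)) o[seq_len(max(thresh))] else integer()
      expect_setequal(which(q <= alpha), rej_brute)
    }
  }
})

test_that("correlation power reproduces the design calculation", {
  expect_equal(correlation_power(188, 0.2, 0.05), 0.787, tolerance = 0.001)
  expect_equal(correlation_power(188, 0.3, 0.05), 0.988, tolerance = 0.001)
  expect_equal(correlation_power(100, 0, 0.05), 0.05, tolerance = 1e-10)
  pw_n <- vapply(c(20, 50, 100, 200), correlation_power, numeric(1), rho = 0.2)
  expect_true(all(diff(pw_n) > 0))
  pw_r <- vapply(c(0.1, 0.2, 0.3, 0.5), function(r)
    correlation_power(100, r), numeric(1))
  expect_true(all(diff(pw_r) > 0))
})

test_that("reliability coefficients behave as the closed forms dictate", {
  # exchangeable items, pairwise r = 0.5, k = 4: population alpha = 0.8
  set.seed(7)
  n <- 10000; k <- 4
  f <- rnorm(n)
  items <- vapply(1:k, function(j) sqrt(0.5) * f + sqrt(0.5) * rnorm(n),
                  numeric(n))
  expect_lt(abs(cronbach_alpha(items) - 0.8), 0.01)
  # duplicated identical items: alpha = 1 exactly
  expect_equal(cronbach_alpha(cbind(f, f, f)), 1)
  # independent items: alpha near 0
  expect_lt(abs(cronbach_alpha(matrix(rnorm(4 * n), n))), 0.05)
  expect_error(cronbach_alpha(matrix(1, 10, 3)), class = "degenerate_data")

  # tau-equivalent items: omega equals alpha
  om <- mcdonald_omega(items)
  expect_lt(abs(om - cronbach_alpha(items)), 1e-3 + 0.005)
  # a zero-loading item dilutes omega below the 3-item value
  set.seed(8)
  it3 <- vapply(c(0.8, 0.8, 0.8), function(l) l * f + sqrt(1 - l^2) * rnorm(n),
                numeric(n))
  it4 <- cbind(it3, rnorm(n))
  expect_lt(mcdonald_omega(it4), mcdonald_omega(it3))
  # no common factor: omega collapses far below any structured value (the
  # one-factor ML solution is ridge-unidentified here, so "near zero" is
  # bounded loosely)
  expect_lt(mcdonald_omega(matrix(rnorm(4 * 2000), 2000)), 0.5)
})

test_that("PCA on the correlation matrix has the stated spectral properties", {
  set.seed(9)
  n <- 800
  # two orthogonal 4-variable blocks with within-block r = 0.6
  f1 <- rnorm(n); f2 <- rnorm(n)
  blk <- function(f) vapply(1:4, function(j)
    sqrt(0.6) * f + sqrt(0.4) * rnorm(n), numeric(n))
  x <- cbind(blk(f1), blk(f2))
  colnames(x) <- paste0("v", 1:8)
  p <- pca_scores(x)
  expect_equal(p$n_retained, 2L)
  expect_equal(sum(p$eigenvalues), 8, tolerance = 1e-10)
  # independent variables: all eigenvalues near 1
  y <- matrix(rnorm(8 * 3000), 3000)
  ey <- pca_scores(y, n_components = 1)$eigenvalues
  expect_lt(max(abs(ey - 1)), 0.15)
  xc <- x; xc[, 3] <- 1
  expect_error(pca_scores(xc), class = "degenerate_data")
  expect_error(pca_scores(xc), "v3")
})

test_that("the dual-criterion rule requires both indices", {
  expect_true(significant_both(0.01, 10))
  expect_false(significant_both(0.01, 2))
  expect_false(significant_both(0.2, 10))
  expect_equal(significant_both(c(0.01, 0.2), c(10, 10)), c(TRUE, FALSE))
})
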
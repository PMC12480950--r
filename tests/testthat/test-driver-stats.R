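test_that("Spearman matrix captures monotone association and handles ties", {
  x <- c(-2, -1, 0, 1, 2, 3)
  tbl <- data.frame(x = x, cube = x^3, neg = -x)
  sm <- spearman_matrix(tbl)
  expect_equal(sm$rho["x", "cube"], 1)
  expect_equal(sm$rho["x", "neg"], -1)
  expect_equal(diag(sm$rho), rep(1, 3), ignore_attr = TRUE)
  # ties: rho equals Pearson on midranks
  a <- c(1, 2, 2, 3, 5, 5, 7)
  b <- c(2, 1, 4, 4, 6, 8, 8)
  sm2 <- spearman_matrix(data.frame(a = a, b = b))
  expect_equal(sm2$rho["a", "b"], cor(rank(a), rank(b)), tolerance = 1e-12)
  smc <- spearman_matrix(data.frame(a = a, k = rep(2, 7)))
  expect_true("k" %in% smc$flagged)
  expect_true(is.na(smc$rho["a", "k"]))
})

test_that("simple regression matches the hand OLS computation", {
  fit <- simple_lr(c(0, 1, 2, 3), c(0, 2, 4, 7))
  expect_equal(fit$slope, 2.3, tolerance = 1e-12)
  expect_equal(fit$intercept, -0.2, tolerance = 1e-12)
  expect_equal(fit$r_squared, 132.25 / 133.75, tolerance = 1e-12)
  exact <- simple_lr(1:5, 2 * (1:5) + 1)
  expect_equal(exact$r_squared, 1, tolerance = 1e-12)
  expect_error(simple_lr(rep(1, 4), 1:4), "variance")
})

test_that("null simple regressions give near-zero R2 and uniform-ish p", {
  set.seed(101)
  ps <- replicate(200, simple_lr(rnorm(50), rnorm(50))$p_value)
  expect_gt(mean(ps < 0.5), 0.35)
  expect_lt(mean(ps < 0.5), 0.65)
  expect_lt(mean(ps < 0.05), 0.12)
})

test_that("single-predictor standardized coefficient equals Pearson r", {
  set.seed(102)
  x <- rnorm(12); y <- 0.8 * x + rnorm(12, 0, 0.5)
  sc <- standardized_coefficients(lm(y ~ x))
  expect_equal(sc$beta_std, cor(x, y), tolerance = 1e-10)
  # invariance under predictor rescaling
  sc10 <- standardized_coefficients(lm(y ~ I(10 * x)))
  expect_equal(sc10$beta_std, sc$beta_std, tolerance = 1e-10)
})

test_that("Cohen's d conversion reproduces the reported t/d pairing", {
  expect_equal(cohens_d_from_t(2.745, 9), 1.830)
  set.seed(103)
  x <- rnorm(12); y <- x + rnorm(12)
  sc <- standardized_coefficients(lm(y ~ x))
  expect_equal(sc$cohens_d, 2 * sc$t / sqrt(10), tolerance = 1e-12)
})

test_that("stepwise selection finds a single strong driver", {
  set.seed(104)
  picks <- replicate(50, {
    n <- 12
    tbl <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
    tbl$y <- 2 * tbl$x1 + rnorm(n, 0, 0.5)
    fit <- stepwise_aic_mlr(tbl, "y", c("x1", "x2", "x3"))
    identical(fit$selected, "x1")
  })
  expect_gte(mean(picks), 0.9)
})

test_that("all-noise candidates mostly yield an intercept-only model", {
  set.seed(105)
  sizes <- replicate(100, {
    n <- 12
    tbl <- data.frame(y = rnorm(n), x1 = rnorm(n), x2 = rnorm(n),
                      x3 = rnorm(n))
    length(stepwise_aic_mlr(tbl, "y", c("x1", "x2", "x3"))$selected)
  })
  expect_equal(as.integer(names(which.max(table(sizes)))), 0L)
})

test_that("stepwise is deterministic and logs collinear drops", {
  set.seed(106)
  n <- 12
  tbl <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  tbl$dup <- 2 * tbl$x1            # perfectly collinear
  tbl$y <- 3 * tbl$x1 + rnorm(n, 0, 0.5)
  f1 <- stepwise_aic_mlr(tbl, "y", c("x1", "dup", "x2"))
  f2 <- stepwise_aic_mlr(tbl, "y", c("x1", "dup", "x2"))
  expect_identical(f1$selected, f2$selected)
  expect_true("dup" %in% f1$dropped_collinear)
})

test_that("VIF is 1 for orthogonal predictors and explodes when duplicated", {
  n <- 16
  x1 <- rep(c(-1, 1), each = n / 2)
  x2 <- rep(c(-1, 1), times = n / 2)
  set.seed(107)
  y <- x1 + x2 + rnorm(n, 0, 0.5)
  v <- car::vif(lm(y ~ x1 + x2))
  expect_equal(unname(v), c(1, 1), tolerance = 1e-10)
  x3 <- x1 + rnorm(n, 0, 0.005)    # near-duplicate
  v2 <- car::vif(lm(y ~ x1 + x3 + x2))
  expect_gt(max(v2), 100)
})

test_that("exponential association fit recovers noise-free parameters", {
  x <- seq(0, 2, length.out = 9)
  y <- 1 * exp(2 * x) + 0.5
  fit <- exp_association_fit(x, y)
  expect_true(fit$converged)
  expect_equal(fit$a, 1, tolerance = 1e-6)
  expect_equal(fit$b, 2, tolerance = 1e-6)
  expect_equal(fit$c, 0.5, tolerance = 1e-5)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(fit$df, 6)
})

test_that("one-sided growth test is calibrated under b = 0", {
  set.seed(108)
  ps <- replicate(100, {
    x <- seq(0, 2, length.out = 10)
    y <- 1 + rnorm(10, 0, 0.2)     # flat: b = 0
    exp_association_fit(x, y)$p_one_sided
  })
  ps <- ps[is.finite(ps)]
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps), 0.7)
})

test_that("noisy exponential parameters land within 3 SE", {
  set.seed(109)
  x <- seq(0, 2, length.out = 12)
  y <- 1 * exp(2 * x) + 0.5 + rnorm(12, 0, 0.3)
  fit <- exp_association_fit(x, y)
  expect_true(fit$converged)
  expect_lt(abs(fit$b - 2), 3 * fit$se_b)
  expect_gt(fit$t, 0)
})

test_that("one-phase decay fit recovers noise-free parameters exactly", {
  x <- seq(0, 100, length.out = 12)
  y <- (3 - 1) * exp(-0.05 * x) + 1
  fit <- one_phase_decay_fit(x, y)
  expect_true(fit$converged)
  expect_equal(fit$y0, 3, tolerance = 1e-6)
  expect_equal(fit$plateau, 1, tolerance = 1e-6)
  expect_equal(fit$k, 0.05, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})

test_that("plateau-only decay data are flagged unidentifiable", {
  fit <- one_phase_decay_fit(c(0, 10, 20, 30), rep(2, 4))
  expect_false(fit$converged)
  expect_true("plateau_only_k_unidentifiable" %in% fit$flags)
})

test_that("noisy decay recovery is reproducible and close to truth", {
  set.seed(110)
  x <- seq(0, 100, length.out = 16)
  y <- (3 - 1) * exp(-0.05 * x) + 1 + rnorm(16, 0, 0.05)
  f1 <- one_phase_decay_fit(x, y)
  f2 <- one_phase_decay_fit(x, y)
  expect_true(f1$converged)
  expect_equal(f1$k, f2$k)                      # deterministic restarts
  expect_lt(abs(f1$k - 0.05) / 0.05, 0.5)
  expect_lt(abs(f1$plateau - 1), 0.3)
})
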
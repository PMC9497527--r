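test_that("contrast matrix produces successive differences with full rank", {
  expect_equal(contrast_matrix(2), matrix(c(1, -1), 2, 1))
  mu <- c(4, 1, 3, -2)
  expect_equal(drop(t(contrast_matrix(4)) %*% mu),
               c(mu[1] - mu[2], mu[2] - mu[3], mu[3] - mu[4]))
  for (k in 2:10) expect_equal(qr(contrast_matrix(k))$rank, k - 1)
  expect_error(contrast_matrix(1), ">= 2")
})

test_that("identical blocks give a zero statistic and p-value one", {
  block <- c(1.3, 2.1, 0.7, 1.8, 1.1)
  gd <- gd_from_blocks(block, block, block)
  wt <- dpd_anova(gd, gamma = 0.3)
  expect_equal(unname(wt$statistic), 0)
  expect_equal(wt$p.value, 1)
  expect_equal(wt$m_hat, c(0, 0))
  expect_gt(classical_anova_test(gd)$p.value, 0.99)
})

test_that("k = 2 equal sizes at gamma = 0 reduce to the squared pooled z", {
  set.seed(61)
  n <- 12
  gd <- gd_from_blocks(rnorm(n, 0.5), rnorm(n))
  fit <- mdpde(gd, gamma = 0)
  wt <- wald_statistic(fit)
  manual <- n * (fit$mu[1] - fit$mu[2])^2 / (2 * fit$sigma2)
  expect_equal(unname(wt$statistic), unname(manual), tolerance = 1e-10)
  # the chisq-calibrated classical test is the same number
  ct <- classical_anova_test(gd, calibration = "chisq")
  expect_equal(unname(ct$statistic), unname(manual), tolerance = 1e-10)
})

test_that("the gamma prefactor rescales the statistic as the closed form says", {
  set.seed(62)
  gd <- gd_from_blocks(rnorm(30), rnorm(25, 1), rnorm(35))
  fit0 <- mdpde(gd, gamma = 0)
  w0 <- unname(wald_statistic(fit0)$statistic)
  # evaluate the gamma = 0.4 statistic at the SAME theta-hat: only the
  # scalar prefactor (1+2g)^{3/2}/(1+g)^3 changes
  fit4 <- fit0
  fit4$gamma <- 0.4
  w4 <- unname(wald_statistic(fit4)$statistic)
  expect_equal(w4 / w0, 1.8^1.5 / 1.4^3, tolerance = 1e-12)
})

test_that("F-calibrated classical test agrees with aov exactly", {
  set.seed(63)
  df <- data.frame(y = rnorm(60), g = rep(c("a", "b", "c"), each = 20))
  gd <- grouped_data(df$y, df$g)
  ct <- classical_anova_test(gd, calibration = "F")
  a <- anova(aov(y ~ g, df))
  expect_equal(unname(ct$statistic), a$`F value`[1], tolerance = 1e-10)
  expect_equal(ct$p.value, a$`Pr(>F)`[1], tolerance = 1e-10)
})

test_that("chisq calibration of the classical Wald form is the exact transform", {
  set.seed(64)
  gd <- gd_from_blocks(rnorm(15), rnorm(20, 0.3), rnorm(25))
  W <- unname(classical_anova_test(gd, calibration = "chisq")$statistic)
  F <- unname(classical_anova_test(gd, calibration = "F")$statistic)
  N <- gd$N; k <- 3
  expect_equal(F, W * (N - k) / (N * (k - 1)), tolerance = 1e-12)
})

test_that("the statistic is invariant to shifting and rescaling the data", {
  set.seed(65)
  inst <- random_instance(k = 3)
  w <- unname(dpd_anova(inst$gd, gamma = 0.3)$statistic)
  lab <- rep(letters[1:3], tabulate(inst$g))
  w_shift <- unname(dpd_anova(grouped_data(inst$y + 100, lab),
                              gamma = 0.3)$statistic)
  w_scale <- unname(dpd_anova(grouped_data(inst$y * 0.01, lab),
                              gamma = 0.3)$statistic)
  expect_equal(w_shift, w, tolerance = 1e-6)
  expect_equal(w_scale, w, tolerance = 1e-6)
})

test_that("adaptive gamma routes through selection and records it", {
  set.seed(66)
  gd <- gen_dataset(sim_spec(k = 3, sizes = c(30, 25, 35),
                             mu = c(0, 0, 1.5)))
  wt <- dpd_anova(gd, gamma = "opt", grid = seq(0, 1, by = 0.05))
  expect_s3_class(wt, "htest")
  expect_equal(wt$gamma, wt$selection$gamma_opt)
  expect_lt(wt$p.value, 0.05)  # a 1.5 sigma separation at N = 90
})

test_that("Huber baseline tracks the sample means on clean symmetric data", {
  set.seed(67)
  gd <- gd_from_blocks(rnorm(5000), rnorm(5000, 2))
  ht <- huber_anova_test(gd)
  means <- vapply(gd$blocks, mean, numeric(1))
  expect_lt(max(abs(ht$estimate[1:2] - means)), 0.01)
  expect_lt(ht$p.value, 1e-10)
})

test_that("Huber location/scale agree with the MASS oracle on one sample", {
  skip_if_not_installed("MASS")
  set.seed(68)
  y <- c(rnorm(200), rnorm(20, 8))  # 10% one-sided contamination
  # two identical blocks make the pooled Proposal-2 scale comparable with
  # the single-sample MASS::hubers fit
  gd <- grouped_data(c(y, y), rep(c("a", "b"), each = length(y)))
  ht <- huber_anova_test(gd, tuning = 1.5)
  orc <- MASS::hubers(y, k = 1.5)
  # conventions differ in finite-sample denominators, hence the loose band
  expect_equal(unname(ht$estimate[1]), orc$mu, tolerance = 1e-2)
  expect_equal(sqrt(unname(ht$estimate["sigma2"])), orc$s, tolerance = 1e-2)
})

test_that("Huber bounds but does not reject one-sided outliers", {
  blockA <- c(-2, -1, -0.5, 0, 0.5, 1, 2, 10, 11)
  gd <- gd_from_blocks(blockA, c(-1, 0, 1, 0.5, -0.5))
  ht <- huber_anova_test(gd)
  expect_gt(unname(ht$estimate[1]), median(blockA))  # pulled up
  expect_lt(unname(ht$estimate[1]), mean(blockA))    # but less than the mean
})

test_that("power is monotone in the effect size", {
  set.seed(69)
  deltas <- c(0, 0.5, 1)
  power <- vapply(deltas, function(d) {
    spec <- sim_spec(k = 4, sizes = rep(25, 4),
                     mu = d * c(-0.4, 0.2, -0.1, 0.3))
    mc <- monte_carlo(spec, list(dpd = method_dpd(0.3)), reps = 200,
                      seed = 100)
    mc$table$level
  }, numeric(1))
  expect_true(all(diff(power) >= 0))
  expect_lt(power[1], 0.15)
  expect_gt(power[3], 0.5)
})
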
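test_that("objective matches a hand-evaluated value and the quadrature oracle", {
  # two observations at 0, mu = 0, sigma2 = 1, gamma = 1:
  # (2 pi)^(-1/2) (2^(-1/2) - 2), identical to the single-observation case
  # because every summand is exp(0)
  manual <- (2 * pi)^(-1 / 2) * (2^(-1 / 2) - 2)
  expect_equal(dpd_obj <- dpd_objective(gd_from_blocks(c(0, 0), c(0, 0)),
                                        c(0, 0), 1, 1),
               manual, tolerance = 1e-12)
  oracle <- oracle_objective(c(0, 0, 0, 0), c(1, 1, 2, 2), c(0, 0), 1, 1)
  expect_equal(dpd_obj, oracle, tolerance = 1e-9)
  # and on a generic configuration
  set.seed(21)
  inst <- random_instance(k = 3)
  mu <- c(-1, 0.5, 2); s2 <- 0.8
  for (gam in c(0.2, 0.7, 1.3)) {
    expect_equal(dpd_objective(inst$gd, mu, s2, gam),
                 oracle_objective(inst$y, inst$g, mu, s2, gam),
                 tolerance = 1e-8)
  }
})

test_that("objective is invariant to permutations within blocks", {
  set.seed(22)
  y1 <- rnorm(6); y2 <- rnorm(5)
  gd <- gd_from_blocks(y1, y2)
  gd_perm <- gd_from_blocks(sample(y1), rev(y2))
  expect_equal(dpd_objective(gd, c(0, 1), 2, 0.4),
               dpd_objective(gd_perm, c(0, 1), 2, 0.4))
})

test_that("objective validates its inputs", {
  gd <- gd_from_blocks(c(1, 2), c(3, 4))
  expect_error(dpd_objective(gd, c(0, 0), -1, 0.3), "sigma2")
  expect_error(dpd_objective(gd, c(0, 0, 0), 1, 0.3), "length")
})

test_that("initial values are block medians and scaled pooled MAD", {
  gd <- gd_from_blocks(c(1, 2, 3), c(10, 20, 30, 40))
  ip <- initial_params(gd)
  expect_equal(unname(ip$mu), c(2, 25))  # odd and even-length medians
  res <- c(1, 2, 3) - 2
  res <- c(res, c(10, 20, 30, 40) - 25)
  expect_equal(ip$sigma2, mad(res, constant = 1.4826)^2)
})

test_that("degenerate constant data floor the scale with a warning", {
  gd <- gd_from_blocks(c(0, 0, 0), c(5, 5, 5))
  expect_warning(ip <- initial_params(gd), "floor")
  expect_equal(unname(ip$mu), c(0, 5))
  expect_gt(ip$sigma2, 0)
})

test_that("scaled MAD is consistent for the normal scale", {
  set.seed(23)
  gd <- gd_from_blocks(rnorm(5e4), rnorm(5e4))
  expect_lt(abs(sqrt(initial_params(gd)$sigma2) - 1), 0.02)
})

test_that("gamma = 0 reproduces the MLE exactly", {
  set.seed(24)
  gd <- gd_from_blocks(rnorm(8, 3), rnorm(9, -1), rnorm(7))
  fit <- mdpde(gd, gamma = 0)
  y <- unlist(gd$blocks); g <- rep(1:3, gd$sizes)
  expect_equal(unname(fit$mu), as.numeric(tapply(y, g, mean)),
               tolerance = 1e-12)
  expect_equal(fit$sigma2, sum((y - unname(fit$mu)[g])^2) / gd$N,
               tolerance = 1e-12)
  expect_true(fit$converged)
})

test_that("fixed point agrees with brute-force minimisation on the fixture", {
  gd <- gd_from_blocks(c(0.1, -0.2, 0.3, 9.0), c(1.0, 1.2, 0.8))
  fit <- mdpde(gd, gamma = 0.5)
  orc <- oracle_minimize(unlist(gd$blocks), rep(1:2, gd$sizes), 0.5)
  expect_equal(unname(fit$mu), orc$mu, tolerance = 1e-4)
  expect_equal(fit$sigma2, orc$sigma2, tolerance = 1e-4)
})

test_that("a gross outlier barely moves the robust fit but wrecks the MLE", {
  gd <- gd_from_blocks(c(0.1, -0.2, 0.3, 9.0), c(1.0, 1.2, 0.8))
  gd_wild <- gd_from_blocks(c(0.1, -0.2, 0.3, 9000), c(1.0, 1.2, 0.8))
  mu_rob <- unname(coef(mdpde(gd, gamma = 0.5))[1])
  mu_rob_wild <- unname(coef(mdpde(gd_wild, gamma = 0.5))[1])
  expect_lt(abs(mu_rob_wild - mu_rob), 0.01)
  mu_mle <- unname(coef(mdpde(gd, gamma = 0))[1])
  mu_mle_wild <- unname(coef(mdpde(gd_wild, gamma = 0))[1])
  expect_gt(abs(mu_mle_wild - mu_mle), 100)
})

test_that("fixed point matches the oracle minimiser on random instances", {
  set.seed(25)
  for (rep in 1:8) {
    inst <- random_instance()
    gam <- sample(c(0.1, 0.3, 0.5, 1.0), 1)
    fit <- mdpde(inst$gd, gamma = gam)
    orc <- oracle_minimize(inst$y, inst$g, gam)
    expect_equal(unname(fit$mu), orc$mu, tolerance = 1e-4)
    expect_equal(fit$sigma2, orc$sigma2, tolerance = 1e-4)
  }
})

test_that("estimates are continuous in gamma at zero", {
  set.seed(26)
  gd <- gd_from_blocks(rnorm(15), rnorm(12, 2))
  f0 <- mdpde(gd, gamma = 0)
  fe <- mdpde(gd, gamma = 1e-6)
  expect_equal(coef(fe), coef(f0), tolerance = 1e-3)
})

test_that("fits are shift and scale equivariant", {
  set.seed(27)
  inst <- random_instance(k = 3)
  fit <- mdpde(inst$gd, gamma = 0.4)
  shifted <- grouped_data(inst$y + 7, rep(letters[1:3], tabulate(inst$g)))
  fs <- mdpde(shifted, gamma = 0.4)
  expect_equal(unname(fs$mu), unname(fit$mu) + 7, tolerance = 1e-6)
  expect_equal(fs$sigma2, fit$sigma2, tolerance = 1e-6)
  scaled <- grouped_data(inst$y * 3, rep(letters[1:3], tabulate(inst$g)))
  fc <- mdpde(scaled, gamma = 0.4)
  expect_equal(unname(fc$mu), unname(fit$mu) * 3, tolerance = 1e-6)
  expect_equal(fc$sigma2, fit$sigma2 * 9, tolerance = 1e-6)
})

test_that("weights lie in (0, 1] and redescend for extreme residuals", {
  set.seed(28)
  y <- c(rnorm(10), 50)
  gd <- grouped_data(c(y, rnorm(5)), rep(c("a", "b"), c(11, 5)))
  fit <- mdpde(gd, gamma = 0.5)
  expect_true(all(fit$weights >= 0 & fit$weights <= 1))
  expect_lt(fit$weights[11], 1e-10)  # the outlier is effectively rejected
})

test_that("the iteration never ends above its start and reports descent", {
  set.seed(29)
  for (rep in 1:5) {
    inst <- random_instance()
    fit <- mdpde(inst$gd, gamma = 0.5)
    start <- dpd_objective(inst$gd, fit$init$mu, fit$init$sigma2, 0.5)
    expect_lte(fit$objective, start + 1e-12)
  }
})

test_that("hitting the iteration cap warns and flags non-convergence", {
  set.seed(30)
  gd <- gd_from_blocks(rnorm(20), rnorm(20, 3))
  expect_warning(
    fit <- mdpde(gd, gamma = 0.3,
                 control = mdpde_control(tol = 1e-14, max_iter = 2L)),
    "did not converge"
  )
  expect_false(fit$converged)
  expect_equal(fit$n_iter, 2L)
})

test_that("formula interface and accessors agree with the container path", {
  set.seed(31)
  df <- data.frame(y = rnorm(30), grp = rep(c("a", "b", "c"), each = 10))
  f1 <- mdpde(y ~ grp, data = df, gamma = 0.3)
  f2 <- mdpde(grouped_data(df$y, df$grp), gamma = 0.3)
  expect_equal(coef(f1), coef(f2))
  expect_equal(length(fitted(f1)), 30L)
  expect_equal(fitted(f1) + residuals(f1), df$y)
  s <- summary(f1)
  expect_equal(dim(s$coefficients), c(3L, 2L))
  expect_true(all(s$coefficients[, "Std. Error"] > 0))
  sim <- simulate(f1, seed = 1)
  expect_s3_class(sim, "grouped_data")
  expect_equal(sim$sizes, f1$data$sizes)
})
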
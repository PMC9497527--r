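# Closed-form normal-model integrals used by the asymptotic machinery.
# With f = N(mu, s2), tau2 = s2/(1+gamma) and
# m_gamma = integral of f^{1+gamma} = (2 pi s2)^(-gamma/2) (1+gamma)^(-1/2):
#   A = int u_mu^2 f^{1+gamma}  = m_gamma / (s2 (1+gamma))
#   B = int u_s   f^{1+gamma}   = -m_gamma gamma / (2 s2 (1+gamma))
#   C = int u_s^2 f^{1+gamma}   = m_gamma (3 tau2^2 - 2 s2 tau2 + s2^2)/(4 s2^4)
# where u_mu = (y-mu)/s2 and u_s = ((y-mu)^2 - s2)/(2 s2^2) are the normal
# score components.  Each is unit-tested against numerical quadrature.
dpd_normal_ints <- function(sigma2, gamma) {
  m <- (2 * pi * sigma2)^(-gamma / 2) / sqrt(1 + gamma)
  tau2 <- sigma2 / (1 + gamma)
  list(
    m = m,
    A = m / (sigma2 * (1 + gamma)),
    B = -m * gamma / (2 * sigma2 * (1 + gamma)),
    C = m * (3 * tau2^2 - 2 * sigma2 * tau2 + sigma2^2) / (4 * sigma2^4)
  )
}

# variance inflation of the mean block relative to the MLE
dpd_var_factor <- function(gamma) (1 + gamma)^3 * (1 + 2 * gamma)^(-1.5)

new_asymptotic_cov <- function(J, K, cov, k, form, S) {
  structure(list(J = J, K = K, cov = cov,
                 cov_mu = cov[seq_len(k), seq_len(k), drop = FALSE],
                 form = form, S = S),
            class = "dpd_asymptotic_cov")
}

#' Model-based asymptotic covariance of the MDPDE
#'
#' Closed-form covariance of \eqn{\sqrt N(\hat\theta - \theta)} when the
#' data truly follow the normal one-way model.  The mean block is exactly
#' \deqn{\Sigma_\mu = (1+\gamma)^3 \sigma^2 (1+2\gamma)^{-3/2} S^{-1},}
#' with \eqn{S = \mathrm{diag}(n_i/N)}; the inflation factor
#' \eqn{(1+\gamma)^3(1+2\gamma)^{-3/2}} is 1 at \eqn{\gamma=0} (the ML
#' limit \eqn{\sigma^2 S^{-1}}) and non-decreasing in \eqn{\gamma}:
#' efficiency is traded for robustness.
#'
#' @param mu numeric vector of k group means (only its length is used for
#'   the mean block).
#' @param sigma2 common variance.
#' @param gamma tuning parameter \eqn{\gamma \ge 0}.
#' @param sizes integer vector of block sizes \eqn{n_i}, all positive.
#' @return an object of class `dpd_asymptotic_cov` with components `J`,
#'   `K`, `cov` (the full (k+1)-dimensional covariance), `cov_mu` (its
#'   leading k-by-k block), `form = "model"` and `S`.
#' @export
model_cov <- function(mu, sigma2, gamma, sizes) {
  k <- length(mu)
  if (any(sizes <= 0)) stop("all block sizes must be positive", call. = FALSE)
  if (length(sizes) != k) stop("length(sizes) must equal length(mu)",
                               call. = FALSE)
  if (sigma2 <= 0) stop("sigma2 must be positive", call. = FALSE)
  if (gamma < 0) stop("gamma must be >= 0", call. = FALSE)
  N <- sum(sizes)
  ci <- sizes / N
  i1 <- dpd_normal_ints(sigma2, gamma)
  i2 <- dpd_normal_ints(sigma2, 2 * gamma)
  J <- diag(c(ci * i1$A, i1$C), k + 1)
  K <- diag(c(ci * i2$A, i2$C - i1$B^2), k + 1)
  cov <- diag(c(dpd_var_factor(gamma) * sigma2 * (N / sizes),
                (i2$C - i1$B^2) / i1$C^2), k + 1)
  new_asymptotic_cov(J, K, cov, k, "model", diag(ci, k))
}

#' Sandwich (empirical) asymptotic covariance of the MDPDE
#'
#' Empirical \eqn{J^{-1} K J^{-1}} covariance of \eqn{\sqrt N(\hat\theta -
#' \theta)}.  Integrals against the unknown data distribution are replaced
#' by sample averages at the observed values; integrals against powers of
#' the model density use the closed normal-moment forms.  When the data
#' follow the model this converges to [model_cov()]; under contamination it
#' reflects the actual variability of the estimator.
#'
#' @param data a [grouped_data] object.
#' @param mu fitted group means.
#' @param sigma2 fitted common variance.
#' @param gamma tuning parameter used in the fit, `gamma > 0` (use
#'   [model_cov()] or the classical ML covariance at `gamma = 0`).
#' @return a `dpd_asymptotic_cov` object with `form = "sandwich"`.
#' @export
sandwich_cov <- function(data, mu, sigma2, gamma) {
  validate_grouped_data(data)
  fl <- gd_flat(data)
  k <- fl$k
  if (length(mu) != k) stop("length(mu) must equal k", call. = FALSE)
  if (gamma <= 0) stop("the sandwich form requires gamma > 0", call. = FALSE)
  N <- fl$N
  s2 <- sigma2
  r <- fl$y - unname(mu)[fl$g]
  gi <- factor(fl$g, levels = seq_len(k))

  fgam <- (2 * pi * s2)^(-gamma / 2) * exp(-gamma * r^2 / (2 * s2))
  umu <- r / s2
  us <- (r^2 - s2) / (2 * s2^2)
  ints <- dpd_normal_ints(s2, gamma)
  tau2 <- s2 / (1 + gamma)
  # E_f[(I_theta - gamma u u^T) f^gamma], entrywise
  EI_mm <- ints$m / s2 - gamma * ints$A
  EI_ss <- ints$m * (tau2 / s2^3 - 1 / (2 * s2^2)) - gamma * ints$C

  # J = (1/N) sum over obs of [ model term + (I - gamma u u^T) f^gamma - E_f ]
  jmm_obs <- ints$A + (1 / s2 - gamma * umu^2) * fgam - EI_mm
  jms_obs <- (r / s2^2 - gamma * umu * us) * fgam
  jss_obs <- ints$C + (r^2 / s2^3 - 1 / (2 * s2^2) - gamma * us^2) * fgam -
    EI_ss
  J <- matrix(0, k + 1, k + 1)
  diag(J)[seq_len(k)] <- rowsum(jmm_obs, gi)[, 1] / N
  J[seq_len(k), k + 1] <- J[k + 1, seq_len(k)] <- rowsum(jms_obs, gi)[, 1] / N
  J[k + 1, k + 1] <- sum(jss_obs) / N

  # K = (1/N)[ sum u u^T f^{2 gamma}  -  sum_i n_i xi_i xi_i^T ],
  # xi_i the per-block empirical mean of u f^gamma
  f2 <- fgam^2
  xi_mu <- rowsum(umu * fgam, gi)[, 1] / fl$sizes
  xi_s <- rowsum(us * fgam, gi)[, 1] / fl$sizes
  K <- matrix(0, k + 1, k + 1)
  diag(K)[seq_len(k)] <- (rowsum(umu^2 * f2, gi)[, 1] -
                            fl$sizes * xi_mu^2) / N
  K[seq_len(k), k + 1] <- K[k + 1, seq_len(k)] <-
    (rowsum(umu * us * f2, gi)[, 1] - fl$sizes * xi_mu * xi_s) / N
  K[k + 1, k + 1] <- (sum(us^2 * f2) - sum(fl$sizes * xi_s^2)) / N

  Jinv <- tryCatch(solve(J), error = function(e) {
    stop("singular J matrix in the sandwich covariance; ",
         "use a larger sample or a smaller gamma", call. = FALSE)
  })
  cov <- Jinv %*% K %*% Jinv
  cov <- (cov + t(cov)) / 2
  new_asymptotic_cov(J, K, cov, k, "sandwich", diag(fl$sizes / N, k))
}

#' Influence function of the MDPDE
#'
#' Influence of an observation `y` in block `i` on the estimator
#' \eqn{(\hat\mu_1,\ldots,\hat\mu_k,\hat\sigma^2)}, evaluated at the model:
#' \eqn{IF(y) = J^{-1}(u_\theta(y) f_\theta^\gamma(y) - \xi)}.  For
#' \eqn{\gamma > 0} it is bounded, and the location components are
#' redescending — they tend to zero as \eqn{|y - \mu_i| \to \infty}, so
#' extreme vertical outliers have vanishing effect on the estimated means;
#' the variance component tends to the finite constant
#' \eqn{-\xi_{\sigma^2} / J_{\sigma^2\sigma^2}} (an extreme point still
#' perturbs the scale through the estimating-equation correction term).
#' At \eqn{\gamma = 0} (maximum likelihood) the location component grows
#' linearly without bound.
#'
#' @param y numeric vector of evaluation points.
#' @param block index of the block the observation belongs to.
#' @param mu group means.
#' @param sigma2 common variance.
#' @param gamma tuning parameter \eqn{\gamma \ge 0}.
#' @param sizes block sizes (determine the limiting weights \eqn{n_i/N}).
#' @return a `length(y)` by `k+1` matrix of influence values; only the
#'   `block` column and the variance column are nonzero.
#' @export
dpd_influence <- function(y, block, mu, sigma2, gamma, sizes) {
  k <- length(mu)
  stopifnot(block >= 1, block <= k, length(sizes) == k, sigma2 > 0,
            gamma >= 0)
  ci <- sizes / sum(sizes)
  ints <- dpd_normal_ints(sigma2, gamma)
  r <- y - mu[block]
  fgam <- (2 * pi * sigma2)^(-gamma / 2) * exp(-gamma * r^2 / (2 * sigma2))
  umu <- r / sigma2
  us <- (r^2 - sigma2) / (2 * sigma2^2)
  out <- matrix(0, length(y), k + 1)
  # J is diagonal at the model: (c_i A, ..., C); xi = (0, ..., 0, B)
  out[, block] <- umu * fgam / (ci[block] * ints$A)
  out[, k + 1] <- (us * fgam - ints$B) / ints$C
  colnames(out) <- c(paste0("mu", seq_len(k)), "sigma2")
  out
}

#' @export
print.dpd_asymptotic_cov <- function(x, digits = 4, ...) {
  cat("Asymptotic covariance of sqrt(N) (theta_hat - theta), form =",
      x$form, "\n")
  cat("Mean block (cov_mu):\n")
  print(round(x$cov_mu, digits))
  invisible(x)
}
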
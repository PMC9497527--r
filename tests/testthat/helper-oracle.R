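# Independent oracles used across tests.  These deliberately avoid the
# package's closed-form objective and fixed-point path: the divergence is
# assembled term by term with numerical quadrature for the model integral,
# and minimised by a general-purpose optimiser.

# theta-dependent part of the empirical divergence, from its definition:
# (1/N) sum_ij int f^{1+gamma}  -  (1+gamma)/(N gamma) sum_ij f^gamma(y_ij)
oracle_objective <- function(y, g, mu, sigma2, gamma) {
  N <- length(y)
  if (gamma == 0) {
    return(-mean(dnorm(y, mu[g], sqrt(sigma2), log = TRUE)))
  }
  s <- sqrt(sigma2)
  int1 <- vapply(unique(g), function(i) {
    integrate(function(t) dnorm(t, mu[i], s)^(1 + gamma),
              -Inf, Inf, rel.tol = 1e-12)$value
  }, numeric(1))
  n_i <- tabulate(g)
  sum(n_i[unique(g)] * int1) / N -
    (1 + gamma) / (N * gamma) * sum(dnorm(y, mu[g], s)^gamma)
}

# brute-force minimiser: Nelder-Mead from two starts, BFGS polish
oracle_minimize <- function(y, g, gamma) {
  k <- max(g)
  fn <- function(p) oracle_objective(y, g, p[seq_len(k)], exp(p[k + 1]),
                                     gamma)
  med <- vapply(split(y, g), median, numeric(1))
  s0 <- mad(y - med[g])
  if (s0 <= 0) s0 <- sd(y)
  starts <- list(
    c(med, log(s0^2)),
    c(vapply(split(y, g), mean, numeric(1)), log(var(y)))
  )
  best <- NULL
  for (p0 in starts) {
    o <- optim(p0, fn, control = list(maxit = 10000, reltol = 1e-14))
    o <- optim(o$par, fn, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
    if (is.null(best) || o$value < best$value) best <- o
  }
  list(mu = unname(best$par[seq_len(k)]),
       sigma2 = unname(exp(best$par[k + 1])),
       value = best$value)
}

# random small instance generator for property-style tests
random_instance <- function(k = sample(2:3, 1), with_outlier = TRUE) {
  sizes <- sample(3:10, k, replace = TRUE)
  mu <- runif(k, -2, 2)
  y <- unlist(lapply(seq_len(k), function(i) rnorm(sizes[i], mu[i], 1)))
  if (with_outlier && runif(1) < 0.5) y[1] <- y[1] + 15
  list(y = y, g = rep(seq_len(k), sizes),
       gd = grouped_data(y, rep(letters[seq_len(k)], sizes)))
}

# grouped data from explicit blocks
gd_from_blocks <- function(...) {
  blocks <- list(...)
  grouped_data(unlist(blocks),
               rep(LETTERS[seq_along(blocks)], lengths(blocks)))
}
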
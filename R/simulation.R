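#' Contamination scheme for simulated errors
#'
#' Describes vertical-outlier contamination: a fraction `p` of the error
#' terms is replaced by draws from an outlying normal distribution (default
#' N(10, 1)).  Under `scheme = "random"` the replaced positions are chosen
#' uniformly over the whole sample; under `scheme = "concentrated"` all
#' replacements land in one target block (clustered outliers, which induce
#' heteroscedasticity and defeat non-robust and monotone-M methods).  By
#' default the replacement count is `round(p * N)` under both schemes
#' (`p_base = "total"`); `p_base = "block"` interprets `p` as a fraction of
#' the target block's size instead.
#'
#' @param p outlier proportion, `0 <= p < 0.5`.
#' @param scheme `"random"` or `"concentrated"`.
#' @param outlier_mean,outlier_sd parameters of the replacement normal
#'   distribution.
#' @param target_block block receiving the outliers (concentrated scheme).
#' @param p_base `"total"` or `"block"`; see above.
#' @return a list of class `contamination_spec`.
#' @export
contamination_spec <- function(p, scheme = c("random", "concentrated"),
                               outlier_mean = 10, outlier_sd = 1,
                               target_block = 1L,
                               p_base = c("total", "block")) {
  scheme <- match.arg(scheme)
  p_base <- match.arg(p_base)
  if (p < 0 || p >= 0.5) stop("p must lie in [0, 0.5)", call. = FALSE)
  structure(list(p = p, scheme = scheme, outlier_mean = outlier_mean,
                 outlier_sd = outlier_sd,
                 target_block = as.integer(target_block), p_base = p_base),
            class = "contamination_spec")
}

#' Simulation design for the one-way ANOVA experiments
#'
#' @param k number of blocks.
#' @param sizes block sizes (length k, all >= 2).
#' @param mu true mean vector (zeros under the null).
#' @param error error family: `"normal"` (standard normal), `"cauchy"`
#'   (standard Cauchy) or `"t"` (Student t with `df` degrees of freedom).
#' @param df degrees of freedom for the t family.
#' @param contamination a [contamination_spec()] or `NULL`.
#' @return a list of class `sim_spec`.
#' @export
sim_spec <- function(k, sizes, mu = rep(0, k),
                     error = c("normal", "cauchy", "t"), df = 3,
                     contamination = NULL) {
  error <- match.arg(error)
  if (length(sizes) != k) stop("length(sizes) must equal k", call. = FALSE)
  if (any(sizes < 2)) stop("all block sizes must be >= 2", call. = FALSE)
  if (length(mu) != k) stop("length(mu) must equal k", call. = FALSE)
  if (!is.null(contamination) &&
      !inherits(contamination, "contamination_spec")) {
    stop("contamination must be a contamination_spec or NULL", call. = FALSE)
  }
  structure(list(k = k, sizes = as.integer(sizes), mu = mu, error = error,
                 df = df, contamination = contamination, N = sum(sizes)),
            class = "sim_spec")
}

#' Generate one dataset from a simulation design
#'
#' Draws \eqn{y_{ij} = \mu_i + \varepsilon_{ij}} with errors from the
#' design's family, then applies the contamination scheme (if any) by
#' replacing error terms with draws from the outlying distribution.  Uses
#' the current RNG state; seed externally for reproducibility.
#'
#' @param spec a [sim_spec()] design.
#' @return a [grouped_data] object with blocks labelled `"g1"`, ..., `"gk"`;
#'   the integer indices of contaminated observations are attached as
#'   attribute `"outliers"`.
#' @export
gen_dataset <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  N <- spec$N
  eps <- switch(spec$error,
                normal = stats::rnorm(N),
                cauchy = stats::rcauchy(N),
                t = stats::rt(N, df = spec$df))
  out_idx <- integer(0)
  cs <- spec$contamination
  if (!is.null(cs) && cs$p > 0) {
    block_idx <- rep(seq_len(spec$k), spec$sizes)
    if (cs$scheme == "random") {
      n_out <- round(cs$p * N)
      out_idx <- sample.int(N, n_out)
    } else {
      tgt <- which(block_idx == cs$target_block)
      n_out <- if (cs$p_base == "total") round(cs$p * N) else
        round(cs$p * length(tgt))
      if (n_out > length(tgt)) {
        stop("concentrated contamination count (", n_out,
             ") exceeds the target block size (", length(tgt), ")",
             call. = FALSE)
      }
      out_idx <- sample(tgt, n_out)
    }
    if (length(out_idx) > 0) {
      eps[out_idx] <- stats::rnorm(length(out_idx), cs$outlier_mean,
                                   cs$outlier_sd)
    }
  }
  g <- rep(seq_len(spec$k), spec$sizes)
  gd <- grouped_data(spec$mu[g] + eps, paste0("g", g))
  attr(gd, "outliers") <- sort(out_idx)
  gd
}

#' Test-method factories for the Monte-Carlo harness
#'
#' Each factory returns a function mapping a [grouped_data] object to a
#' list with `p.value`, `mu` (estimated means) and optionally `gamma`, the
#' interface [monte_carlo()] expects.
#'
#' @param gamma fixed DPD tuning parameter.
#' @param control a [mdpde_control()] list.
#' @name mc_methods
#' @return a function of one `grouped_data` argument.
#' @export
method_dpd <- function(gamma, control = mdpde_control()) {
  force(gamma); force(control)
  function(gd) {
    fit <- mdpde(gd, gamma = gamma, control = control)
    wt <- wald_statistic(fit, gd)
    list(p.value = wt$p.value, mu = unname(fit$mu), gamma = gamma)
  }
}

#' @rdname mc_methods
#' @param grid,pilot_gamma tuning grid and pilot passed to [select_gamma()].
#' @export
method_dpd_opt <- function(grid = seq(0, 1, by = 0.01), pilot_gamma = 0.4,
                           control = mdpde_control()) {
  force(grid); force(pilot_gamma); force(control)
  function(gd) {
    sel <- select_gamma(gd, grid = grid, pilot_gamma = pilot_gamma,
                        control = control)
    wt <- wald_statistic(sel$fit, gd)
    list(p.value = wt$p.value, mu = unname(sel$fit$mu),
         gamma = sel$gamma_opt)
  }
}

#' @rdname mc_methods
#' @param calibration `"F"` or `"chisq"`, see [classical_anova_test()].
#' @export
method_classical <- function(calibration = "F") {
  force(calibration)
  function(gd) {
    wt <- classical_anova_test(gd, calibration = calibration)
    k <- length(gd$blocks)
    list(p.value = wt$p.value, mu = unname(wt$estimate[seq_len(k)]),
         gamma = 0)
  }
}

#' @rdname mc_methods
#' @param tuning Huber constant, see [huber_anova_test()].
#' @export
method_huber <- function(tuning = 1.345) {
  force(tuning)
  function(gd) {
    wt <- huber_anova_test(gd, tuning = tuning)
    k <- length(gd$blocks)
    list(p.value = wt$p.value, mu = unname(wt$estimate[seq_len(k)]),
         gamma = NA_real_)
  }
}

#' Monte-Carlo level / power / MSE experiment
#'
#' Runs `reps` replications of a simulation design.  In replication r the
#' RNG is seeded with a counter derived from the master seed (so adding
#' methods never perturbs the shared datasets, and different master seeds
#' give disjoint streams), one dataset is generated, and every
#' method is evaluated on that same dataset.  Reported per method: the
#' rejection proportion at level `alpha` (empirical level under the null,
#' power under an alternative) with its Monte-Carlo standard error
#' \eqn{\sqrt{\hat p(1-\hat p)/reps}}, N times the Monte-Carlo MSE of the
#' mean vector \eqn{N \cdot \mathrm{mean}_r \sum_i (\hat\mu_i - \mu_i)^2}
#' with its own Monte-Carlo standard error (`n_mse_se`),
#' the mean selected gamma (where applicable) and the count of failed
#' replications (failures are recorded and excluded, never silent).
#'
#' @param spec a [sim_spec()] design.
#' @param methods named list of method functions (see [method_dpd()] and
#'   friends).
#' @param reps number of replications.
#' @param alpha nominal test level.
#' @param seed master seed (integer).
#' @return an object of class `sim_summary`: a list with `table` (a data
#'   frame with one row per method), `reps`, `alpha`, `N` and `seed`.
#' @examples
#' spec <- sim_spec(k = 3, sizes = c(30, 25, 35))
#' mc <- monte_carlo(spec, list(classical = method_classical()),
#'                   reps = 50, seed = 1)
#' mc$table
#' @export
monte_carlo <- function(spec, methods, reps, alpha = 0.05, seed = 1L) {
  stopifnot(inherits(spec, "sim_spec"), reps >= 1)
  if (is.null(names(methods)) || any(names(methods) == "")) {
    stop("methods must be a named list", call. = FALSE)
  }
  nm <- length(methods)
  reject <- matrix(NA, reps, nm)
  sqerr <- matrix(NA_real_, reps, nm)
  gam <- matrix(NA_real_, reps, nm)
  fail <- integer(nm)
  for (r in seq_len(reps)) {
    set.seed((seed + r * 100003) %% 2147483647L)
    gd <- gen_dataset(spec)
    for (m in seq_len(nm)) {
      res <- tryCatch(
        suppressWarnings(methods[[m]](gd)),
        error = function(e) NULL
      )
      if (is.null(res)) {
        fail[m] <- fail[m] + 1L
        next
      }
      reject[r, m] <- res$p.value < alpha
      sqerr[r, m] <- sum((res$mu - spec$mu)^2)
      if (!is.null(res$gamma)) gam[r, m] <- res$gamma
    }
  }
  level <- colMeans(reject, na.rm = TRUE)
  nok <- colSums(!is.na(reject))
  tab <- data.frame(
    method = names(methods),
    level = level,
    mc_se = sqrt(level * (1 - level) / nok),
    n_mse = spec$N * colMeans(sqerr, na.rm = TRUE),
    n_mse_se = spec$N * apply(sqerr, 2, stats::sd, na.rm = TRUE) /
      sqrt(nok),
    mean_gamma = colMeans(gam, na.rm = TRUE),
    failures = fail,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  structure(list(table = tab, reps = reps, alpha = alpha, N = spec$N,
                 seed = seed, spec = spec),
            class = "sim_summary")
}

#' @export
print.sim_summary <- function(x, digits = 4, ...) {
  cat("Monte-Carlo summary:", x$reps, "replications, nominal level",
      x$alpha, ", N =", x$N, "\n")
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], signif, digits = digits)
  print(tab, row.names = FALSE)
  invisible(x)
}
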
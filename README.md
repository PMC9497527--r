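# dpdanova

Robust one-way ANOVA via minimum density power divergence estimation.

## The problem

The classical one-way ANOVA test of equal group means assumes normal,
homoscedastic errors and no outliers.  In biomedical data — recovery times,
lab measurements, survival-adjacent endpoints — a handful of gross outliers
or a heavy-tailed error distribution can inflate the pooled variance enough
to mask a real treatment effect, or shift one group enough to fabricate
one.  `dpdanova` implements a robust alternative for the generalized
one-way fixed-effects model

    y_ij = mu_i + e_ij,   i = 1..k,  j = 1..n_i,   N = sum(n_i)

where the *target* error distribution is N(0, sigma^2) but the realised
errors may follow a contaminated normal law
g = (1 − p)·N(0, sigma^2) + p·chi, with contamination fraction p < 0.5 and
an arbitrary outlying distribution chi.

## The estimator and test

Parameters theta = (mu_1, ..., mu_k, sigma^2) are estimated by the
**minimum density power divergence estimator (MDPDE)**: the minimiser of
the empirical density power divergence between the normal model and the
data,

    d_gamma(theta) = (2*pi)^(-gamma/2) * sigma^(-gamma) *
        [ (1+gamma)^(-1/2)
          - (1+gamma)/(N*gamma) * sum_ij exp(-gamma*(y_ij-mu_i)^2/(2*sigma^2)) ]

indexed by a tuning parameter gamma >= 0.  At gamma = 0 this is maximum
likelihood; for gamma > 0 each observation enters with weight
w_ij = exp(-gamma*(y_ij-mu_i)^2/(2*sigma^2)), an exponentially redescending
down-weighting of outlying points.  The estimator solves the weighted
fixed-point equations

    mu_i    = sum_j w_ij y_ij / sum_j w_ij
    sigma^2 = sum_ij w_ij (y_ij - mu_i)^2 /
              ( sum_ij w_ij - N*gamma*(1+gamma)^(-3/2) )

iterated from block medians and a scaled-MAD scale.  Under the model,
sqrt(N)*(mu_hat - mu) has covariance
Sigma_mu = (1+gamma)^3 * sigma^2 * (1+2*gamma)^(-3/2) * S^(-1) with
S = diag(n_i/N), which prices the efficiency cost of robustness and yields
the **Wald-type test** of H0: mu_1 = ... = mu_k,

    W_N = N * sigma_hat^(-2) * (1+gamma)^(-3) * (1+2*gamma)^(3/2) *
          m_hat' [M' S^(-1) M]^(-1) m_hat  ~  chi^2(k-1)  under H0,

where m_hat collects the successive mean differences.  gamma can be fixed
(0.1–0.4 are standard choices) or selected adaptively by iterated
minimisation of the estimated mean squared error of the mean vector
(`select_gamma()`).

## Worked example

Three groups (n = 30, 25, 35), true means (0, 0, 0.8), with 5% of the
third block (2 of 35 observations) replaced by vertical outliers from
N(10, 1):

```r
library(dpdanova)
set.seed(42)
spec <- sim_spec(k = 3, sizes = c(30, 25, 35), mu = c(0, 0, 0.8),
                 contamination = contamination_spec(
                   0.05, "concentrated", target_block = 3,
                   p_base = "block"))
gd <- gen_dataset(spec)

summary(mdpde(gd, gamma = 0.3))
#> MDPDE one-way ANOVA fit, gamma = 0.3 ( model standard errors )
#>
#>    Estimate Std. Error
#> g1   0.1373     0.1905
#> g2  -0.0293     0.2087
#> g3   1.0007     0.1764
#>
#> sigma^2 = 1.003   iterations = 15   converged = TRUE

dpd_anova(gd, gamma = "opt")
#> 	DPD Wald-type test (adaptive gamma = 0.18)
#>
#> data:  3 groups, N = 90
#> W = 17.586, df = 2, p-value = 0.0001518
#> sample estimates:
#>          g1          g2          g3      sigma2
#>  0.11335000 -0.04908868  0.97169474  1.03994202

classical_anova_test(gd)
#> 	Classical one-way ANOVA (F test)
#>
#> data:  3 groups, N = 90
#> F = 7.2202, df1 = 2, df2 = 87, p-value = 0.001256
#> sample estimates:
#>          g1          g2          g3      sigma2
#>  0.06858683 -0.07978881  1.48096495  3.15556460
```

The two outliers triple the ML variance estimate (3.16 vs the true 1) and
drag the third group mean to 1.48; the robust fit selects gamma = 0.18,
recovers sigma^2 = 1.04 and mu_3 = 0.97, and its standard errors reflect
the uncontaminated bulk of the data.  On file-based data use
`read_grouped_table("data.csv", group_col, value_col)` (or the
`value ~ group` formula interface), and `huber_anova_test()` for a
monotone-M baseline.  A command-line front end for fit / test /
select-gamma / simulate lives at `inst/scripts/dpdanova-cli.R`.

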
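# rebifactor

Exploratory bifactor analysis for very small samples, with a regularized
extraction engine and the full Monte Carlo machinery to study how well
bifactor structure is recovered when you have tens — not hundreds — of
observations.

## The problem

Behavioral-science datasets (comparative psychology, behavior genetics,
animal behavior) are often tiny: factor analyses on 10–50 observations are
common. The standard exploratory route to a bifactor structure — one general
factor over all items plus orthogonal group factors over disjoint item
clusters — is the Schmid-Leiman orthogonalization of a second-order factor
solution:

1. extract *f* primary factors from the correlation matrix **R**;
2. rotate obliquely (direct quartimin);
3. extract a second-order factor from the primary factor correlation matrix
   **Φ̂**;
4. orthogonalize: each item's general loading is its primary loading times
   the second-order loading γ_k, and its group loading is the primary
   loading times the square root of the disturbance u²_k = 1 − γ²_k.

At these sample sizes the usual extraction engine, unweighted least squares
principal factoring (ULS), frequently fails: it produces Heywood cases
(negative unique-variance estimates) or does not converge, and such
improper solutions must be discarded.

Regularized exploratory factor analysis (REFA) avoids this by construction.
Unique variances are modelled as

    Ψ = λ · L̂,

where **L̂** is a non-iterative tentative estimate (here 1 − SMC, the
squared multiple correlation read off the inverse correlation matrix) and
λ > 0 is the *single* parameter estimated, by minimizing the
maximum-likelihood discrepancy `ln det Σ(λ) + tr(R Σ(λ)⁻¹)` with
`Σ(λ) = Λ(λ)Λ(λ)′ + λ diag(L̂)`. For each λ the loadings Λ(λ) follow in
closed form from the top-*m* eigenpairs of `R − λ diag(L̂)` (eigenvalues
floored at zero). Because λL̂ > 0 always, REFA cannot produce a negative
unique variance.

The package implements both engines behind one pipeline (`fit_bifactor()`),
plus the recovery metrics used to compare them against a known population:
the overall Tucker congruence

    φ = tr(P′F) / √(tr(P′P) · tr(F′F))

computed after orthogonal Procrustes rotation, and the root mean squared
error `RMSE = √(tr(E′E)/(p·m))`, `E = P − F`, computed separately for the
general column and the group block after permutation/reflection alignment.

The Monte Carlo engine reproduces a 144-cell factorial design — sample size
N ∈ {10, 20, 30, 50}, variables per factor ∈ {4, 8}, group factors
∈ {2, 4}, loading ∈ {0.40, 0.55, 0.70}, factor correlation
∈ {0.30, 0.50, 0.70} — with ULS-driven screening of improper solutions and
paired evaluation of both methods on every retained sample.

## Worked example

```r
library(rebifactor)

pop <- population_model(4, 2, 0.55, 0.5)   # 8 items, 2 group factors
pop
#> Independent-clusters population model
#>   p = 8 variables, f = 2 factors (4 per factor)
#>   loading = 0.55, factor correlation = 0.50
#>   communalities = 0.3025, unique variances = 0.6975

ds  <- sample_dataset(pop$implied_corr, 30, seed = 42)
fit <- fit_bifactor(ds$sample_corr, 2, method = "REFA")
fit
#> Schmid-Leiman bifactor solution (REFA): 8 variables, 2 group factor(s)
#>   proper = TRUE
#>   second-order loadings: 0.3920 0.3920
#>   disturbances:          0.8463 0.8463

evaluate_replication(fit, pop$bifactor_target)
#> Recovery: phi = 0.9040, RMSE(general) = 0.2123, RMSE(group) = 0.1453
```

The fitted solution at N = 30 is proper, its overall congruence with the
population bifactor target is 0.90 (above the conventional 0.85
fair-similarity threshold), and the general-factor loadings are off by 0.21
root-mean-square — the magnitude of estimation error to expect from 30
observations at communalities of 0.30.

Simulation entry points:

```r
cfg <- simulation_config(n_keep = 30, master_seed = 1)
res <- run_study(cfg)                       # screened, paired main study
aggregate_results(res, by = "loading")      # means / MC SEs / paired diffs
partial_eta_squared_method(res)             # method effect size
improper_rate_study(cfg)                    # unscreened ULS failure rates
```

A thin command-line wrapper with `fit`, `simulate`, and `improper-rate`
subcommands is installed under `inst/cli/rebifactor.R`.

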
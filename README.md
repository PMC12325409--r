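# ednaconc

Hierarchical Bayesian inference of environmental-DNA (eDNA) concentration
across sites and time from qPCR cycle-threshold (CT) survey data.

## Who this is for

Ecologists and biostatisticians running qPCR-based eDNA surveys who want
*concentration* estimates — not just presence/absence — with uncertainty
that honestly propagates every stage of the data-generating process:
availability in the environment, collection into samples, and PCR analysis,
including plate-to-plate calibration drift, CT heteroscedasticity,
right-censored non-amplifications, and sporadically contaminated or
inhibited replicates.

## The model

For site $i$, occasion $t$, sample $m$, replicate $k$ on plate $p$:

$$
\begin{aligned}
l_{i,1} &\sim N(\beta_{b,0} + X^b_{i,1}\beta_b,\ \tau_1^2), &
l_{i,t} &\sim N(\rho_i (l_{i,t-1} - X^b_{i,t-1}\beta_b) + X^b_{i,t}\beta_b,\ \tau^2),\\
v_{imt} &\sim N(l_{i,t} + X^w_{imt}\beta_w,\ \sigma^2), &
w_{imt} &= e^{v_{imt}},
\end{aligned}
$$

and each replicate's uncensored CT follows a three-component mixture driven
by a latent status $\gamma \in \{0,1,2\}$ (unaffected / contaminated with
probability $p_c$ / inhibited with probability $p_h$):

$$
\tilde C \sim
\begin{cases}
N(\mu,\ \sigma_y^2(w)) & \gamma = 0\\
\mathrm{TN}_{0,\mu}(\mu,\ \sigma_c^2) & \gamma = 1\\
\mathrm{TN}_{\mu,\infty}(\mu,\ \sigma_c^2) & \gamma = 2
\end{cases}
\qquad
\mu = \alpha^1_p + \alpha^2_p \log w,
\qquad
\log \sigma^2_y(w) = a_1 + a_2 \log w,
$$

censored to `NA` at `CT.max`. Plate coefficients are hierarchically pooled
and informed by standards of known concentration; the mixture probabilities
obey the identifiability constraint $p_c + p_h < 1 - (p_c + p_h)$, enforced
by joint rejection inside the MCMC. Model variants `const_var` (constant CT
variance) and `no_mixture` ($p_c = p_h = 0$) quantify what heteroscedasticity
and the mixture each contribute.

See `vignettes/edna-concentration-model.Rmd` for the full account:
assumptions, priors, sampler design, and known limitations.

## Worked example

```r
library(ednaconc)
design <- survey_design(n_sites = 4, n_times = 6, samples_per_occasion = 2,
                        replicates_per_sample = 3)
sim <- simulate_survey(sim_config(design, seed = 42))
sim$dataset
#> qPCR survey design: 4 sites x 6 occasions, 48 samples, 144 replicates, 24 plates, CT.max = 40
#>   replicates: 144 (10 censored); standards: 504 (6 censored)
#>   covariates: 2 site-level, 2 sample-level

fit <- fit_edna(sim$dataset, variant = "full",
                control = mcmc_control(preset = "test", seed = 1))
ps <- posterior_summary(fit)         # means, 95% intervals, R-hat, ESS
rownames(ps) <- ps$param
round(ps[c("beta_b1", "beta_b2", "beta_w1", "beta_w2", "a2", "p_c", "p_h"),
         c("mean", "lower", "upper")], 3)
#>           mean  lower  upper
#> beta_b1  0.735  0.279  1.129
#> beta_b2  0.065 -1.350  1.193
#> beta_w1  1.147  0.705  1.564
#> beta_w2 -0.125 -0.859  0.794
#> a2      -0.250 -0.275 -0.222
#> p_c      0.020  0.011  0.034
#> p_h      0.101  0.081  0.131

interval_metrics(fit$l, as.vector(sim$latent$l))$coverage
#> [1] 0.9583333
```

The survey was generated with $\beta_b = (1,-1)$, $\beta_w = (1,-1)$,
$a_2 = -0.25$, $(p_c, p_h) = (0.05, 0.1)$. On this deliberately small survey
(4 sites, 144 replicates) the continuous-covariate coefficients and the
variance slope are recovered with intervals covering truth, the binary
covariates are not yet identifiable (their intervals straddle zero — more
replication is what fixes this, which is the point of `run_sim_study()`),
the inhibition probability is recovered, the contamination probability is
underestimated by design (contamination of abundant replicates is
undetectable), and 96% of latent log-DNA values fall inside their 95%
credible intervals.

Simulation studies over design grids:

```r
res <- run_sim_study(data.frame(M = 2, K = 2, p_c = 0.05, p_h = 0.1),
                     variants = c("full", "no_mixture"), N = 5,
                     control = mcmc_control(preset = "test"), seed = 1)
res$cells   # MSE, mean 95% interval width, coverage for log-availability
```

## Command line

```sh
Rscript -e 'quit(status = ednaconc::edna_cli())' simulate --config sim.json --seed 17 --out data/
Rscript -e 'quit(status = ednaconc::edna_cli())' fit --data data/ --model full --seed 7 --out draws/
Rscript -e 'quit(status = ednaconc::edna_cli())' summarize --draws draws/ --out summary/
Rscript -e 'quit(status = ednaconc::edna_cli())' simstudy --grid grid.json --n 5 --seed 1 --out results/
```

Every command validates its inputs first, writes a JSON manifest (command,
arguments, seed, package version) next to its outputs, and is byte-for-byte
reproducible given the seed.

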
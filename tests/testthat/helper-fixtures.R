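# Shared fixtures built in code: small designs and parameter sets reused
# across test files.

tiny_design <- function(M = 2, K = 2, n = 2, T = 2, ct_max = 40)
  survey_design(n, T, M, K, ct_max = ct_max)

# Reference simulation parameters (the stated simulation world) with
# optionally overridden mixture probabilities.
ref_params <- function(p_c = 0.05, p_h = 0.1, ...) {
  args <- utils::modifyList(
    list(beta_b0 = 6, beta_b = c(1, -1), beta_w = c(1, -1), rho = 1,
         rho0 = 1, tau2 = 1, tau2_1 = 1, sigma2 = 1, a1 = 0.2, a2 = -0.25,
         p_c = p_c, p_h = p_h, sigma_c = 40, ct_max = 40),
    list(...))
  do.call(model_parameters, args)
}

tiny_sim <- function(seed = 1, M = 2, K = 2, n = 2, T = 2, ...) {
  simulate_survey(sim_config(tiny_design(M, K, n, T),
                             params = ref_params(...), seed = seed))
}

# Independent flat-loop normal log-density (oracle; deliberately naive).
oracle_dnorm_sum <- function(x, mean, sd) {
  tot <- 0
  x <- as.vector(x); mean <- rep_len(as.vector(mean), length(x))
  sd <- rep_len(sd, length(x))
  for (i in seq_along(x))
    tot <- tot + log(1 / (sd[i] * sqrt(2 * pi))) -
      (x[i] - mean[i])^2 / (2 * sd[i]^2)
  tot
}
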
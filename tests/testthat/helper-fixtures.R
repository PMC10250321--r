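# Canonical fixtures shared across the suite.

ref_params <- function() sls_params(k1 = 200, k2 = 100, mu = 300)
ref_dp <- 500      # Pa
ref_rp <- 3.5e-6   # m (7 um pipette)

# Hand-evaluated reference values for the creep model at ref conditions:
#   L_max = 2 * 3.5e-6 * 500 / (pi * 200)
#   L(0)  = 2 * 3.5e-6 * 500 / (pi * 300)
#   tau   = 300 * (200 + 100) / (200 * 100)
ref_lmax <- 2 * 3.5e-6 * 500 / (pi * 200)
ref_l0 <- 2 * 3.5e-6 * 500 / (pi * 300)
ref_tau <- 4.5

noiseless <- function() noise_spec(scale = 0)

ref_creep <- function(n_points = 200, t_max = 10 * ref_tau, noise = noiseless()) {
  simulate_creep(ref_params(), ref_dp, ref_rp,
                 n_points = n_points, t_max = t_max, noise = noise)
}

rel_err <- function(est, truth) abs(est - truth) / abs(truth)

params_rel_err <- function(fit, truth) {
  max(rel_err(c(fit$params$k1, fit$params$k2, fit$params$mu),
              c(truth$k1, truth$k2, truth$mu)))
}

# Random valid SLS triplets, log-normal around the reference values.
random_triplets <- function(n, seed) {
  set.seed(seed)
  data.frame(k1 = stats::rlnorm(n, log(200), 0.5),
             k2 = stats::rlnorm(n, log(100), 0.5),
             mu = stats::rlnorm(n, log(300), 0.5))
}
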
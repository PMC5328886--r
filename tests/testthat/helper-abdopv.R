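# Shared fixtures, built in code at test time.

# Frozen solution of the three-anchor system P(0)=5.0, P(7.7)=16.3,
# P(10.4)=49.4 cmH2O, computed independently (scalar root in p after
# eliminating v and k analytically) before the implementation was written.
frozen_default_params <- c(v = 2.816962930929593,
                           k = 1.9962101521747362,
                           p = 4.756138660939587)

# Noise-free points on an exponential PV curve.
make_exp_points <- function(params, n = 12,
                            p_min = params[["p"]] + 0.8, p_max = 50) {
  P <- seq(p_min, p_max, length.out = n)
  list(pressure = P, volume = exp_volume(P, params))
}

# Noise-free points on a Venegas curve.
make_venegas_points <- function(params, n = 12, p_min = 4, p_max = 50) {
  P <- seq(p_min, p_max, length.out = n)
  list(pressure = P, volume = venegas_volume(P, params))
}

# A small deterministic cohort for IO tests.
tiny_cohort <- function(seed = 11, n_animals = 2) {
  simulate_cohort(cohort_config(n_animals = n_animals, seed = seed))
}
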
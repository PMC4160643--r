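# shared fixtures, all built in code

# the reference trolox control curve (dose 0)
ref_control <- function() kinetic_params(100, 68.12, 4.59)

# random valid kinetic triples, sigmoidal regime when alpha_min > 1
random_params <- function(n, alpha_min = 1.2, alpha_max = 12) {
  lapply(seq_len(n), function(i) {
    kinetic_params(K = runif(1, 50, 110),
                   tau = runif(1, 20, 200),
                   alpha = runif(1, alpha_min, alpha_max))
  })
}

noisy_panel <- function(seed, noise_sd = 1.5, ...) {
  simulate_panel(simulation_scenario(noise_sd = noise_sd, seed = seed, ...))
}

noisy_curve <- function(seed, p = ref_control(), times = seq(0, 180, by = 10),
                        noise_sd = 1.5) {
  set.seed(seed)
  list(time = times,
       response = weibull_survival(times, p) + rnorm(length(times), 0, noise_sd))
}
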
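# Shared fixtures: tiny noise-free datasets built in code.

quiet_dataset <- function(design = "exp1", condition = 30,
                          params = model_params(), n = 2, seed = 7) {
  simulate_group(design, condition, params, noise_spec(0, 0),
                 n_participants = n, seed = seed)
}

noisy_dataset <- function(design = "exp1", condition = 30,
                          params = model_params(), n = 6, seed = 7,
                          sigma_motor = 4, sigma_report = 2) {
  simulate_group(design, condition, params,
                 noise_spec(sigma_motor, sigma_report),
                 n_participants = n, seed = seed)
}
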
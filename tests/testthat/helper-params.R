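# Shared fixtures: all built in code, no data files.

melanoma <- function(...) rescue_preset("melanoma_a375", ...)

# Desk-scaled single-path instance: mutation rate raised to 1e-3 and tumor
# shrunk to N = 1000 so that N/N* matches an intermediate operating point
# while a replicate finishes in milliseconds.
scaled_direct <- function(n_init = 1000) {
  rescue_preset("melanoma_a375", v = 1e-3, u = 0, n_init = n_init)
}

# Random valid parameter row for property-style sweeps (rates in
# [1e-3, 1] per day, per-division probabilities in [0, 0.1]).
random_params <- function() {
  suppressWarnings(rescue_params(
    lambda_s = stats::runif(1, 1e-3, 1), mu_s = stats::runif(1, 1e-3, 1),
    lambda_a = stats::runif(1, 1e-3, 1), mu_a = stats::runif(1, 1e-3, 1),
    lambda_m = stats::runif(1, 1e-3, 1), mu_m = stats::runif(1, 1e-3, 1),
    u = stats::runif(1, 0, 0.1), u_pre = 0,
    v = stats::runif(1, 0, 0.1), v_a = stats::runif(1, 0, 0.1),
    c = 0.07, n_init = 1e3))
}
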
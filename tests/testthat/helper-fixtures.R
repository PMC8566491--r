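# shared fixtures: everything is generated in code, no files needed

default_params <- function() oral_parameters()

# exact synthetic flow curve, optionally with multiplicative noise
make_curve <- function(kappa, n, rates = c(0.1, 1, 10, 100), seed = NULL,
                       noise = 0) {
  fl <- power_law_fluid(kappa, n)
  generate_flow_curve(fl, synthetic_spec(seed = if (is.null(seed)) 1 else
    seed, rates = rates, noise_sd_rel = noise))
}

table1_fluids <- function(tab = table1_samples()) {
  lapply(seq_len(nrow(tab)), function(i)
    power_law_fluid(tab$kappa[i], tab$n[i], label = as.character(tab$id[i])))
}

rmse <- function(x) sqrt(mean(x^2))

expect_rel_equal <- function(object, expected, rel_tol) {
  expect_lt(max(abs(object - expected) / abs(expected)), rel_tol)
}
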
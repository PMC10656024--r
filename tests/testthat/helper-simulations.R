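# Shared helpers: small, fast simulation settings used across test files.

fast_sim <- function(params = default_parameters(), ...) {
  simulate_placenta(params, by = 2, ...)
}

fetal_total_at_term <- function(params, t_end = 40) {
  sum(igtransfer:::.fetal_at_weeks(params, t_end, t_end))
}

with_param <- function(params, name, value) {
  params[[name]] <- value
  igtransfer:::.validate_parameters(params)
}
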
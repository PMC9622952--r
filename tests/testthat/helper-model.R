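# shared fixtures built in code

# near-zero constant mortality: limit cases (no deaths) without leaving the
# life-table contract (probabilities strictly positive)
null_mortality_table <- function() gompertz_life_table(1e-15, 0, 63, 93)

# parameter set with every stochastic event switched off
no_event_parameters <- function() {
  p <- default_parameters()
  p$transitions$annual_recurrence_rate <- 0
  p$utilities$state_utility[] <- c(1, 1, 1, 0)
  p$econ$discount_rate <- 0
  p$arms$edaravone$day90 <- c(mrs01 = 0.6, mrs23 = 0.3, mrs45 = 0.1, dead = 0)
  p
}

# degenerate sensitivity ranges (low = base = high) so every fitted
# distribution collapses to a point mass
degenerate_ranges <- function(p) {
  p$ranges$low <- p$ranges$base
  p$ranges$high <- p$ranges$base
  p
}

perturbed_sets <- local({
  cache <- NULL
  function(n = 20L, scale = 0.1) {
    if (is.null(cache))
      cache <<- make_perturbed_parameters(
        fixture_spec(n_parameter_sets = 50L, perturbation_scale = scale))
    cache[seq_len(n)]
  }
})
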
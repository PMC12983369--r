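## Shared fixtures: all inputs are generated in code, no data files needed.

kT300 <- aq_constants$k_B * 300

## two-channel toy table with hand-checkable numbers
two_channel_table <- function() {
  E <- c(5, 10, 40, 100, 1000)
  xsec_table(E,
             cbind(elastic = c(0.05, 0.05, 0.05, 0.05, 0.05),
                   ion = c(0, 0, 1.0, 2.0, 1.0) * 0.01),
             list(xsec_channel("elastic", "elastic", 0, "none"),
                  xsec_channel("ion", "ionisation", 10.9)))
}

## single constant-sigma channel: inverse mfp = 33.43 * 0.01 = 0.3343 / nm
flat_table <- function(sigma = 0.01) {
  E <- 10^seq(-3, 4, length.out = 8)
  xsec_table(E, cbind(elastic = rep(sigma, 8), ion = rep(0, 8)),
             list(xsec_channel("elastic", "elastic", 0, "none"),
                  xsec_channel("ion", "ionisation", 10.9)))
}

## all-zero cross sections: nothing can happen (ballistic limit)
zero_table <- function() {
  E <- c(1, 10, 1e4)
  xsec_table(E, cbind(elastic = c(0, 0, 0), ion = c(0, 0, 0)),
             list(xsec_channel("elastic", "elastic", 0, "none"),
                  xsec_channel("ion", "ionisation", 10.9)))
}

## time-independent screening (for conservation tests)
constant_eps_params <- function(eps = 1.78) {
  dielectric_params(eps_electronic = eps, eps_static = eps,
                    amplitudes = c(0, 0), rise_times = c(10, 1000))
}

## Maxwell-Boltzmann kinetic-energy CDF at temperature T
maxwell_cdf <- function(temperature = 300) {
  kT <- aq_constants$k_B * temperature
  function(E) stats::pgamma(E / kT, shape = 1.5)
}

## The headline ensemble (1 keV, 500 histories) is expensive enough that the
## acceptance checks share one cached copy.
.ensemble_cache <- new.env(parent = emptyenv())
acceptance_ensemble <- function() {
  if (is.null(.ensemble_cache$res)) {
    cfg <- sim_config(E0 = 1000, n_histories = 500, seed = 1234)
    .ensemble_cache$res <- run_simulation(cfg, default_xsec_table(),
                                          dielectric_params())
  }
  .ensemble_cache$res
}
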
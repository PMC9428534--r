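# Shared fixtures: small, fast scenario configurations used across tests.
# Population and carrying-capacity scales are reduced so whole runs fit in
# fractions of a second; all demographic constants stay at their defaults.

small_cfg <- function(...) {
  args <- list(...)
  defaults <- list(burn_in_years = 80L, initial_abundance = 200L,
                   carrying_capacity_kg = 600,
                   pre_fishing_years = 20L, max_fishing_years = 40L,
                   total_experiment_years = 100L,
                   env_forcing = 0.1, fishing_F = 0.2, seed = 1L)
  do.call(scenario_config, utils::modifyList(defaults, args))
}

# geometric mean oracle used against across_generational_fitness()
gm <- function(x) if (any(x == 0)) 0 else exp(mean(log(x)))
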
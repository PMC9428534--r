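# Configuration loading/saving and structured output writing. The
# configuration file is YAML with one section per model component; any
# key left unset falls back to the study defaults, so an empty file (or
# no file) yields the full 36-scenario factorial design.

.default_settings <- function() {
  list(
    genetics = list(noise_sd = 3.5, intercept_cm = 60,
                    slope_cm_per_score = 2, growth_alpha = log(6.6),
                    growth_beta = -1, linf_floor_cm = 1,
                    n_loci = 10L, allele_freq = 0.5),
    life_history = list(m_immature = 0.15, reproductive_cost = 0.1,
                        juvenile_age_cutoff = 3, max_age = 25),
    reproduction = list(cost_slope = 0.00523, egg_to_recruit = 1.13e-6,
                        batch_asymptote = 21.1561,
                        batch_midpoint_cm = 55.014,
                        batch_scale_cm = 10.141),
    fishing = list(min_size_cm = 45, sel_intercept = -12.5,
                   sel_slope = 0.25, stop_fraction = 0.15),
    engine = list(burn_in_years = 5000L, pre_fishing_years = 100L,
                  max_fishing_years = 300L,
                  total_experiment_years = 500L,
                  initial_abundance = 2000L,
                  carrying_capacity_kg = 6000, theta = 1,
                  thin_burn_in = 50L),
    design = list(master_seed = 1L, replicates = 50L,
                  strategies = c("MBS", "SBS"),
                  E_grid = .E_GRID, F_grid = .F_GRID,
                  allow_extrapolation = FALSE))
}

.merge_settings <- function(defaults, user) {
  for (sec in names(user)) {
    if (!sec %in% names(defaults)) {
      stop(sprintf("unknown configuration section `%s`", sec),
           call. = FALSE)
    }
    for (key in names(user[[sec]])) {
      if (!key %in% names(defaults[[sec]])) {
        stop(sprintf("unknown configuration key `%s.%s`", sec, key),
             call. = FALSE)
      }
      defaults[[sec]][[key]] <- user[[sec]][[key]]
    }
  }
  defaults
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration (sections `genetics`, `life_history`,
#' `reproduction`, `fishing`, `engine`, `design`), fills unset keys with
#' the study defaults, validates every parameter, and expands the design
#' section into the factorial design tibble. With `path = NULL` (or an
#' empty file) the full default design of 36 scenarios x 50 replicates is
#' returned.
#'
#' Forcing and fishing rates outside the tested grids (E in 0.05-0.30,
#' F in 0.1-0.3) are rejected unless `design.allow_extrapolation` is set,
#' since the model is only explored within those ranges.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return An object of class `run_config`: a list with the merged
#'   `settings` and the expanded `design` tibble.
#' @examples
#' cfg <- load_config()
#' nrow(dplyr::distinct(cfg$design[, c("strategy", "env_forcing",
#'                                     "fishing_F")]))
#' @export
load_config <- function(path = NULL) {
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) {
      stop(sprintf("configuration file `%s` does not exist", path),
           call. = FALSE)
    }
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
  }
  settings <- .merge_settings(.default_settings(), user)

  # constructor validation of every section
  do.call(expression_params,
          settings$genetics[setdiff(names(settings$genetics),
                                    c("n_loci", "allele_freq"))])
  .check_number(settings$genetics$n_loci, "genetics.n_loci", lower = 1)
  .check_number(settings$genetics$allele_freq, "genetics.allele_freq",
                lower = 0, upper = 1)
  do.call(mortality_params, settings$life_history)
  do.call(spawning_params, c(list(strategy = "MBS"),
                             settings$reproduction))
  do.call(fishing_params, settings$fishing)

  des <- settings$design
  if (!all(des$strategies %in% .STRATEGIES)) {
    stop("design.strategies must be a subset of MBS/SBS", call. = FALSE)
  }
  if (!isTRUE(des$allow_extrapolation)) {
    if (any(des$E_grid < min(.E_GRID) | des$E_grid > max(.E_GRID))) {
      stop("design.E_grid outside the tested forcing range ",
           "[0.05, 0.30]; set design.allow_extrapolation to override",
           call. = FALSE)
    }
    if (any(des$F_grid < min(.F_GRID) | des$F_grid > max(.F_GRID))) {
      stop("design.F_grid outside the tested fishing range ",
           "[0.1, 0.3]; set design.allow_extrapolation to override",
           call. = FALSE)
    }
  }
  design <- make_design(master_seed = des$master_seed,
                        replicates = des$replicates,
                        strategies = des$strategies,
                        E_grid = des$E_grid, F_grid = des$F_grid)
  structure(list(settings = settings, design = design),
            class = "run_config")
}

#' Save a run configuration
#'
#' Writes the merged settings back to YAML so that
#' `load_config(save_config(cfg, path))` round-trips.
#'
#' @param config A `run_config` from [load_config()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(config$settings, path, precision = 15)
  invisible(path)
}

#' Build a scenario configuration from a run configuration
#'
#' Maps one row of the design (strategy, forcing, fishing, seed,
#' replicate) plus the configuration settings onto a
#' [scenario_config()].
#'
#' @param config A `run_config`.
#' @param strategy,env_forcing,fishing_F,seed,replicate_id Cell
#'   coordinates.
#' @return A [scenario_config()] object.
#' @export
as_scenario_config <- function(config, strategy, env_forcing, fishing_F,
                               seed, replicate_id = 1L) {
  s <- config$settings
  scenario_config(
    strategy = strategy, env_forcing = env_forcing, fishing_F = fishing_F,
    burn_in_years = s$engine$burn_in_years,
    pre_fishing_years = s$engine$pre_fishing_years,
    max_fishing_years = s$engine$max_fishing_years,
    total_experiment_years = s$engine$total_experiment_years,
    initial_abundance = s$engine$initial_abundance,
    carrying_capacity_kg = s$engine$carrying_capacity_kg,
    theta = s$engine$theta,
    n_loci = s$genetics$n_loci, allele_freq = s$genetics$allele_freq,
    seed = seed, replicate_id = replicate_id,
    thin_burn_in = s$engine$thin_burn_in,
    genetics = do.call(expression_params,
                       s$genetics[setdiff(names(s$genetics),
                                          c("n_loci", "allele_freq"))]),
    mortality = do.call(mortality_params, s$life_history),
    spawning = do.call(spawning_params,
                       c(list(strategy = strategy,
                              env_forcing = env_forcing),
                         s$reproduction)),
    fishing = do.call(fishing_params,
                      c(list(F = fishing_F), s$fishing)))
}

#' Write experiment outputs to disk
#'
#' Writes the combined records, cohort ledgers and per-run table as CSV
#' plus one records CSV per scenario replicate, and a JSON manifest with
#' the design (including every derived seed) and an MD5 checksum per
#' file, so any single cell can be reproduced and verified in isolation.
#'
#' @param exp The list returned by [run_experiment()].
#' @param out_dir Output directory (created if missing).
#' @param master_seed Master seed recorded in the manifest.
#' @return A tibble inventory (`file`, `md5`), invisibly.
#' @export
write_outputs <- function(exp, out_dir, master_seed = NA_integer_) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  write_csv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
  }
  write_csv(exp$records, "records_all.csv")
  write_csv(exp$ledgers, "ledgers_all.csv")
  write_csv(exp$runs, "runs.csv")
  keys <- dplyr::distinct(exp$records[, c("strategy", "env_forcing",
                                          "fishing_F", "replicate")])
  for (i in seq_len(nrow(keys))) {
    k <- keys[i, ]
    sel <- exp$records$strategy == k$strategy &
      exp$records$env_forcing == k$env_forcing &
      exp$records$fishing_F == k$fishing_F &
      exp$records$replicate == k$replicate
    write_csv(exp$records[sel, ],
              sprintf("records_%s_E%03d_F%02d_rep%03d.csv", k$strategy,
                      round(k$env_forcing * 100), round(k$fishing_F * 10),
                      k$replicate))
  }
  inventory <- tibble::tibble(
    file = basename(files),
    md5 = unname(tools::md5sum(files)))
  manifest <- list(
    package_version = as.character(utils::packageVersion("batchspawner")),
    master_seed = master_seed,
    design = exp$design,
    files = inventory)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(inventory)
}
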
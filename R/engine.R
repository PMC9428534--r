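# The annual cycle and the scenario/replicate engine.
#
# Event order within a year (fixed; results are order-sensitive):
#   (1) density ratio B/K from start-of-year biomass
#   (2) growth of all individuals
#   (3) maturation update
#   (4) spawning and recruitment by all mature fish
#   (5) natural mortality Bernoulli trials
#   (6) harvest (fishing phase only, until the moratorium latches)
#   (7) age increment and maximum-age cull; recruits join at age 0
#   (8) emit the annual record

.record_numeric_cols <- function(max_age) {
  c("year", "exp_year", "abundance", "biomass_kg", "recruits",
    "mature_count", "spawning_females", "failed_seasons",
    "catch_count", "catch_biomass_kg", "deaths_natural", "age_culls",
    "mean_linf_cm", "mean_age", "mean_length_cm",
    "mean_maturation_age", "mean_maturation_length_cm", "extinct",
    paste0("age_", 0:max_age))
}

# Spawning and recruitment for all mature individuals in one season.
# Returns the offspring fragment, per-season tallies and the lifetime
# recruit credits earned by the parents (dam and sire each credited once
# per recruit).
.spawn_all <- function(pop, mat_idx, cfg, year) {
  sp <- cfg$spawning
  gp <- cfg$genetics
  nf <- length(mat_idx)
  len <- pop$length[mat_idx]
  eggs <- fecundity(weight_from_length(len))
  nb <- n_batches(len, sp)

  fem <- rep.int(seq_len(nf), nb)
  bidx <- sequence(nb)
  base <- eggs %/% nb
  rem <- eggs %% nb
  batch_eggs <- base[fem] + (bidx <= rem[fem])
  surv <- stats::runif(length(bidx)) < batch_survival_prob(bidx, sp)

  eggs_surv <- numeric(nf)
  if (any(surv)) {
    agg <- rowsum(batch_eggs[surv], fem[surv])
    eggs_surv[as.integer(rownames(agg))] <- agg[, 1L]
  }
  rec <- stats::rbinom(nf, size = eggs_surv, prob = sp$egg_to_recruit)

  # one sire per female per season, uniform among mature fish other than
  # the dam (selfing only if she is the sole mature individual)
  if (nf > 1L) {
    sire <- mat_idx[sample.int(nf, nf, replace = TRUE)]
    bad <- which(sire == mat_idx)
    while (length(bad)) {
      sire[bad] <- mat_idx[sample.int(nf, length(bad), replace = TRUE)]
      bad <- bad[sire[bad] == mat_idx[bad]]
    }
  } else {
    sire <- mat_idx
  }

  n_rec <- sum(rec)
  dam_of <- rep.int(mat_idx, rec)
  sire_of <- rep.int(sire, rec)
  credit <- tabulate(c(dam_of, sire_of), nbins = pop_size(pop))

  frag <- NULL
  if (n_rec > 0L) {
    G_off <- .mendelian_offspring(pop$G, dam_of, sire_of)
    linf_o <- .express_scores(rowSums(G_off), gp)
    frag <- list(id = pop$next_id + seq_len(n_rec) - 1L,
                 birth_year = rep.int(as.integer(year), n_rec),
                 age = integer(n_rec),
                 linf = linf_o,
                 k = k_from_linf(linf_o, gp),
                 length = numeric(n_rec),
                 mature = logical(n_rec),
                 mat_age = rep(NA_real_, n_rec),
                 mat_length = rep(NA_real_, n_rec),
                 lifetime_recruits = integer(n_rec),
                 G = G_off,
                 next_id = pop$next_id + n_rec)
  }
  list(frag = frag, n_recruits = n_rec, failed = sum(rec == 0L),
       spawning_females = nf, credit = credit)
}

# One annual step over the whole population. `fishing_active` indicates
# that harvest runs this year. Returns the updated population, the
# numeric record vector, and the birth years / lifetime outputs of every
# individual that died this year (for the cohort ledger).
.step_population <- function(pop, cfg, fishing_active, year) {
  N <- pop_size(pop)
  mp <- cfg$mortality
  max_age <- mp$max_age
  cols <- .record_numeric_cols(max_age)
  stats_v <- stats::setNames(numeric(length(cols)), cols)
  stats_v["year"] <- year
  stats_v["exp_year"] <- year - cfg$burn_in_years

  if (N == 0L) {
    stats_v["extinct"] <- 1
    stats_v[c("mean_linf_cm", "mean_age", "mean_length_cm",
              "mean_maturation_age", "mean_maturation_length_cm")] <- NA_real_
    return(list(population = pop, stats = stats_v,
                dead_birth_year = integer(0), dead_output = integer(0),
                biomass_start = 0))
  }

  # (1)-(2) density-dependent growth
  biomass_start <- sum(weight_from_length(pop$length))
  ratio <- biomass_start / cfg$carrying_capacity_kg
  pop$length <- grow(pop$length, pop$linf, pop$k, ratio, cfg$theta)

  # (3) maturation (irreversible)
  m2 <- update_maturation(pop$length, pop$linf, pop$mature)
  newm <- m2 & !pop$mature
  pop$mature <- m2
  if (any(newm)) {
    pop$mat_age[newm] <- pop$age[newm] + 1
    pop$mat_length[newm] <- pop$length[newm]
    stats_v["mean_maturation_age"] <- mean(pop$mat_age[newm])
    stats_v["mean_maturation_length_cm"] <- mean(pop$mat_length[newm])
  } else {
    stats_v[c("mean_maturation_age", "mean_maturation_length_cm")] <- NA_real_
  }

  # (4) spawning and recruitment
  mat_idx <- which(pop$mature)
  frag <- NULL
  if (length(mat_idx)) {
    sp_out <- .spawn_all(pop, mat_idx, cfg, year)
    pop$lifetime_recruits <- pop$lifetime_recruits + sp_out$credit
    frag <- sp_out$frag
    stats_v["recruits"] <- sp_out$n_recruits
    stats_v["failed_seasons"] <- sp_out$failed
    stats_v["spawning_females"] <- sp_out$spawning_females
  }
  stats_v["mature_count"] <- length(mat_idx)

  # (5) natural mortality
  p_surv <- natural_survival_prob(pop$age, pop$mature, mp)
  die_nat <- stats::runif(N) > p_surv

  # (6) harvest among natural survivors
  caught <- logical(N)
  w_now <- weight_from_length(pop$length)
  if (fishing_active) {
    pc <- capture_prob(pop$length, cfg$fishing)
    caught <- !die_nat & (stats::runif(N) < pc)
    stats_v["catch_count"] <- sum(caught)
    stats_v["catch_biomass_kg"] <- sum(w_now[caught])
  }

  # (7) ageing and maximum-age cull
  alive <- !die_nat & !caught
  age_next <- pop$age + 1L
  cull <- alive & age_next > max_age
  keep <- alive & !cull
  stats_v["deaths_natural"] <- sum(die_nat)
  stats_v["age_culls"] <- sum(cull)

  dead <- !keep
  dead_birth_year <- pop$birth_year[dead]
  dead_output <- pop$lifetime_recruits[dead]

  pop$age <- age_next
  pop <- .pop_subset(pop, keep)
  if (!is.null(frag)) pop <- .pop_append(pop, frag)

  # (8) annual record at year end (recruits included at age 0)
  n_end <- pop_size(pop)
  stats_v["abundance"] <- n_end
  if (n_end) {
    stats_v["biomass_kg"] <- sum(weight_from_length(pop$length))
    stats_v["mean_linf_cm"] <- mean(pop$linf)
    stats_v["mean_age"] <- mean(pop$age)
    stats_v["mean_length_cm"] <- mean(pop$length)
    hist <- tabulate(pop$age + 1L, nbins = max_age + 1L)
    stats_v[paste0("age_", 0:max_age)] <- hist
  } else {
    stats_v["extinct"] <- 1
    stats_v[c("mean_linf_cm", "mean_age", "mean_length_cm")] <- NA_real_
  }

  list(population = pop, stats = stats_v,
       dead_birth_year = dead_birth_year, dead_output = dead_output,
       biomass_start = biomass_start)
}

#' One annual step
#'
#' Advances a population by one year under the fixed event order
#' (density-dependent growth, maturation, spawning and recruitment,
#' natural mortality, harvest when `phase = "fishing"`, ageing and
#' maximum-age cull) and emits the annual record.
#'
#' @param pop A population object.
#' @param cfg A [scenario_config()] object.
#' @param phase One of `"burn_in"`, `"pre"`, `"fishing"`, `"post"`;
#'   harvest runs only in the fishing phase.
#' @param year Calendar year stamped on the record.
#' @return A list with the updated `population`, a one-row `record`
#'   tibble, and the `dead_birth_year` / `dead_output` vectors of the
#'   individuals that died this year (used for the cohort ledger).
#' @examples
#' set.seed(1)
#' cfg <- scenario_config(initial_abundance = 100, burn_in_years = 0,
#'                        seed = 1)
#' pop <- initialize_population(cfg)
#' step <- annual_step(pop, cfg, phase = "pre")
#' step$record$abundance
#' @export
annual_step <- function(pop, cfg,
                        phase = c("burn_in", "pre", "fishing", "post"),
                        year = 1L) {
  phase <- match.arg(phase)
  st <- .step_population(pop, cfg, fishing_active = phase == "fishing",
                         year = year)
  rec <- tibble::as_tibble(as.list(st$stats))
  rec$phase <- phase
  list(population = st$population,
       record = rec[, c("year", "exp_year", "phase",
                        setdiff(names(rec), c("year", "exp_year", "phase")))],
       dead_birth_year = st$dead_birth_year,
       dead_output = st$dead_output)
}

#' Run one scenario replicate
#'
#' Seeds the RNG from the configuration, burns the population in for
#' `burn_in_years` under environmental forcing only, then runs the
#' experiment: `pre_fishing_years` of forcing, fishing for at most
#' `max_fishing_years` or until the biomass moratorium latches
#' (permanently), then forcing only until `total_experiment_years`.
#' Burn-in records are thinned to every `thin_burn_in`-th year; all
#' experiment years are recorded.
#'
#' @param cfg A [scenario_config()] object.
#' @param record_burn_in Keep (thinned) burn-in records; if `FALSE` only
#'   the final burn-in year is kept.
#' @return An object of class `scenario_run`: a list with `records` (one
#'   tibble row per recorded year, including the age histogram columns
#'   `age_0` ... `age_25`), `ledger` (the per-birth-year cohort ledger
#'   with cohort size, summed lifetime recruit output of dead members,
#'   death count and a `finalized` flag), `fishing_years`, `extinct` and
#'   the `config`.
#' @examples
#' cfg <- scenario_config(env_forcing = 0.1, fishing_F = 0.2,
#'                        burn_in_years = 30, initial_abundance = 150,
#'                        carrying_capacity_kg = 300, seed = 42)
#' run <- run_scenario(cfg)
#' table(run$records$phase)
#' @export
run_scenario <- function(cfg, record_burn_in = TRUE) {
  stopifnot(inherits(cfg, "scenario_config"))
  set.seed(cfg$seed)
  burn <- cfg$burn_in_years
  total <- cfg$total_experiment_years
  pre <- cfg$pre_fishing_years
  maxf <- cfg$max_fishing_years
  max_age <- cfg$mortality$max_age

  pop <- initialize_population(cfg, start_year = 1L)

  # cohort ledger, indexed by birth year (founders can be born before
  # year 1)
  y0 <- 1L - 10L
  ny <- burn + total - y0 + 1L
  coh_size <- coh_out <- coh_dead <- numeric(ny)
  coh_size <- coh_size + tabulate(pop$birth_year - y0 + 1L, nbins = ny)

  keep_year <- c(
    if (burn > 0) {
      if (record_burn_in) {
        unique(c(which(seq_len(burn) %% cfg$thin_burn_in == 0L), burn))
      } else burn
    },
    burn + seq_len(total))
  rec_mat <- matrix(NA_real_, length(keep_year),
                    length(.record_numeric_cols(max_age)),
                    dimnames = list(NULL, .record_numeric_cols(max_age)))
  rec_phase <- character(length(keep_year))
  row <- 0L

  fishing_latched <- FALSE
  onset_biomass <- NA_real_
  extinct <- FALSE
  fishing_years <- 0L

  for (year in seq_len(burn + total)) {
    ey <- year - burn
    phase <- if (ey <= 0L) "burn_in"
             else if (ey <= pre) "pre"
             else if (ey <= pre + maxf && !fishing_latched) "fishing"
             else "post"

    st <- .step_population(pop, cfg, fishing_active = phase == "fishing",
                           year = year)
    pop <- st$population

    # cohort ledger updates
    if (st$stats[["recruits"]] > 0) {
      coh_size[year - y0 + 1L] <- coh_size[year - y0 + 1L] +
        st$stats[["recruits"]]
    }
    if (length(st$dead_birth_year)) {
      i <- st$dead_birth_year - y0 + 1L
      coh_dead <- coh_dead + tabulate(i, nbins = ny)
      agg <- rowsum(as.numeric(st$dead_output), i)
      ii <- as.integer(rownames(agg))
      coh_out[ii] <- coh_out[ii] + agg[, 1L]
    }

    if (phase == "fishing") {
      fishing_years <- fishing_years + 1L
      if (is.na(onset_biomass)) onset_biomass <- st$biomass_start
      if (onset_biomass > 0 &&
          fishing_should_stop(st$stats[["biomass_kg"]], onset_biomass,
                              cfg$fishing)) {
        fishing_latched <- TRUE
      }
    }
    if (phase == "pre" && ey == pre) onset_biomass <- st$stats[["biomass_kg"]]

    if (year %in% keep_year || st$stats[["extinct"]] == 1) {
      row <- row + 1L
      if (row > nrow(rec_mat)) {
        rec_mat <- rbind(rec_mat, st$stats)
        rec_phase <- c(rec_phase, phase)
      } else {
        rec_mat[row, ] <- st$stats
        rec_phase[row] <- phase
      }
    }
    if (st$stats[["extinct"]] == 1) {
      extinct <- TRUE
      break
    }
  }

  records <- tibble::as_tibble(as.data.frame(rec_mat[seq_len(row), ,
                                                     drop = FALSE]))
  records$phase <- rec_phase[seq_len(row)]
  records <- records[, c("year", "exp_year", "phase",
                         setdiff(names(records),
                                 c("year", "exp_year", "phase")))]

  # finalize cohort ledger: members still alive leave their cohort open
  alive_tab <- if (pop_size(pop)) {
    tabulate(pop$birth_year - y0 + 1L, nbins = ny)
  } else numeric(ny)
  present <- coh_size > 0
  ledger <- tibble::tibble(
    birth_year = (y0:(burn + total))[present],
    cohort_size = coh_size[present],
    total_output = coh_out[present],
    deaths = coh_dead[present],
    finalized = (coh_dead[present] >= coh_size[present]) |
      (alive_tab[present] == 0))

  structure(
    list(records = records, ledger = ledger,
         fishing_years = fishing_years, extinct = extinct, config = cfg),
    class = "scenario_run")
}

#' @export
print.scenario_run <- function(x, ...) {
  cat(sprintf(
    "<scenario_run> %s E=%.2f F=%.2f seed=%d: %d recorded years, %s\n",
    x$config$strategy, x$config$env_forcing, x$config$fishing_F,
    x$config$seed, nrow(x$records),
    if (x$extinct) "EXTINCT" else sprintf("fishing lasted %d yr",
                                          x$fishing_years)))
  invisible(x)
}

#' Derive a per-cell seed from a master seed
#'
#' Stable integer hash of the master seed and the scenario coordinates
#' (strategy, forcing rate, fishing rate, replicate), so any cell of a
#' design can be rerun in isolation and reproduce its in-design output
#' bit for bit. The hash is a 31-bit multiplicative accumulator
#' (`h <- (31 h + x) mod (2^31 - 1)` over the coordinate codes).
#'
#' @param master_seed Integer master seed.
#' @param strategy `"MBS"` or `"SBS"`.
#' @param env_forcing,fishing_F Scenario rates.
#' @param replicate Replicate index.
#' @return An integer seed.
#' @export
derive_seed <- function(master_seed, strategy, env_forcing, fishing_F,
                        replicate) {
  codes <- c(match(strategy, .STRATEGIES),
             round(env_forcing * 100), round(fishing_F * 100), replicate)
  h <- as.double(master_seed) %% 2147483647
  for (x in codes) h <- (h * 31 + x) %% 2147483647
  as.integer(h)
}

#' Build a factorial scenario design
#'
#' Enumerates strategies x forcing rates x fishing rates x replicates
#' (the full default grid is the 36-scenario design with 50 replicates)
#' and derives one reproducible seed per cell from the master seed.
#'
#' @param master_seed Integer master seed.
#' @param replicates Replicates per scenario.
#' @param strategies,E_grid,F_grid Factor levels.
#' @return A tibble with one row per scenario replicate.
#' @examples
#' nrow(make_design(1, replicates = 2))
#' @export
make_design <- function(master_seed = 1L, replicates = 50L,
                        strategies = .STRATEGIES,
                        E_grid = .E_GRID, F_grid = .F_GRID) {
  design <- tidyr::expand_grid(strategy = strategies,
                               env_forcing = E_grid,
                               fishing_F = F_grid,
                               replicate = seq_len(replicates))
  design$seed <- mapply(derive_seed, master_seed, design$strategy,
                        design$env_forcing, design$fishing_F,
                        design$replicate)
  design
}

#' Run a factorial experiment
#'
#' Runs [run_scenario()] for every row of a design and returns the
#' combined tidy records and cohort ledgers, keyed by strategy, forcing
#' rate, fishing rate and replicate. Rerunning with the same design (and
#' hence the same derived seeds) reproduces the table bit for bit, and
#' any single cell rerun standalone matches its in-design output.
#'
#' @param design A design tibble from [make_design()].
#' @param ... Overrides passed to [scenario_config()] (e.g.
#'   `burn_in_years`, `carrying_capacity_kg`).
#' @param record_burn_in Passed to [run_scenario()].
#' @param progress Print one line per completed run.
#' @return A list with `records`, `ledgers`, `runs` (per-run fishing
#'   length and extinction flags) and the `design`.
#' @examples
#' \donttest{
#' des <- make_design(1, replicates = 1, E_grid = 0.2, F_grid = 0.2)
#' exp <- run_experiment(des, burn_in_years = 50,
#'                       initial_abundance = 150,
#'                       carrying_capacity_kg = 300)
#' }
#' @export
run_experiment <- function(design, ..., record_burn_in = FALSE,
                           progress = FALSE) {
  stopifnot(all(c("strategy", "env_forcing", "fishing_F", "replicate",
                  "seed") %in% names(design)))
  overrides <- list(...)
  records <- vector("list", nrow(design))
  ledgers <- vector("list", nrow(design))
  runs <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    d <- design[i, ]
    cfg <- do.call(scenario_config, c(
      list(strategy = d$strategy, env_forcing = d$env_forcing,
           fishing_F = d$fishing_F, seed = d$seed,
           replicate_id = d$replicate),
      overrides))
    run <- run_scenario(cfg, record_burn_in = record_burn_in)
    key <- tibble::tibble(strategy = d$strategy,
                          env_forcing = d$env_forcing,
                          fishing_F = d$fishing_F,
                          replicate = d$replicate, seed = d$seed)
    records[[i]] <- dplyr::bind_cols(key[rep(1L, nrow(run$records)), ],
                                     run$records)
    ledgers[[i]] <- dplyr::bind_cols(key[rep(1L, nrow(run$ledger)), ],
                                     run$ledger)
    runs[[i]] <- dplyr::bind_cols(key,
                                  tibble::tibble(
                                    fishing_years = run$fishing_years,
                                    extinct = run$extinct))
    if (progress) {
      message(sprintf("[%d/%d] %s E=%.2f F=%.2f rep=%d: %s", i,
                      nrow(design), d$strategy, d$env_forcing, d$fishing_F,
                      d$replicate,
                      if (run$extinct) "extinct" else "done"))
    }
  }
  list(records = dplyr::bind_rows(records),
       ledgers = dplyr::bind_rows(ledgers),
       runs = dplyr::bind_rows(runs),
       design = design)
}
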
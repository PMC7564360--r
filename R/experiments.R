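# Multi-generation experiments: maintenance and invasion runs, outcome
# classification, and parameter-grid sweeps.

.outcome_levels <- c("coexistence_at_max_gen", "spillover_fixed", "mfcl_fixed")

.assemble_trajectory <- function(rec, outcome_code, terminal_gen, terminal_p,
                                 extinct, resampled, config, seed, engine) {
  rec <- as.data.frame(rec)
  names(rec) <- c("generation", "p", "n_spov_females", "n_mfcl_females",
                  "surv_spov_females", "surv_mfcl_females",
                  "matings_spov", "matings_mfcl",
                  "males_cannibalized", "male_bg_deaths")
  rec$generation <- as.integer(rec$generation)
  rec$mfcl_mating_pct <- ifelse(rec$n_mfcl_females > 0,
                                100 * rec$matings_mfcl / rec$n_mfcl_females,
                                NA_real_)
  half <- (rec$n_spov_females + rec$n_mfcl_females) / 2
  rec$rel_fitness_spov <- ifelse(half > 0, rec$n_spov_females / half, NA_real_)
  outcome <- .outcome_levels[outcome_code + 1L]
  traj <- list(
    records = rec,
    outcome = outcome,
    terminal_generation = as.integer(terminal_gen),
    terminal_p = terminal_p,
    quasi_equilibrium = outcome != "coexistence_at_max_gen" &&
      terminal_gen >= config$quasi_fraction * config$max_generations,
    extinct = isTRUE(extinct),
    resampled_generations = as.integer(resampled),
    config = config,
    seed = seed,
    engine = engine
  )
  class(traj) <- "spovsim_trajectory"
  traj
}

#' Simulate allele-frequency dynamics across generations
#'
#' Iterates initialization, the within-season daily loop and
#' end-of-season reproduction until the spillover allele fixes or is
#' lost (`p` hits 1 or 0, evaluated on each fresh adult generation) or
#' until `max_generations`. One record per evaluated generation; the
#' terminal generation's season is not simulated, so its within-season
#' statistics are `NA`.
#'
#' If reproduction fails entirely (no surviving mated mother, or an
#' empty offspring pool for one sex), the run ends and is classified by
#' the parental gamete pool's majority allele, with `extinct = TRUE`
#' noted on the trajectory.
#'
#' @param config a `spovsim_config`.
#' @param seed optional integer; when given, `set.seed(seed)` is called
#'   so the trajectory is fully reproducible.
#' @param engine `"cpp"` (compiled, default) or `"r"` (reference
#'   implementation; identical rules and draw protocol, much slower).
#' @param max_generations optional override of the config's cap.
#' @return object of class `spovsim_trajectory`: a `records` data frame
#'   (`generation`, `p`, phenotype counts at maturation and at season
#'   end, matings by phenotype, cannibalized males, background male
#'   deaths, derived `mfcl_mating_pct` and `rel_fitness_spov`), the
#'   terminal `outcome` (`"spillover_fixed"`, `"mfcl_fixed"` or
#'   `"coexistence_at_max_gen"`), `terminal_generation`, `terminal_p`
#'   and a `quasi_equilibrium` flag.
#' @export
run_generations <- function(config, seed = NULL, engine = c("cpp", "r"),
                            max_generations = NULL) {
  engine <- match.arg(engine)
  if (!is.null(max_generations)) {
    config$max_generations <- as.integer(max_generations)
  }
  if (!is.null(seed)) set.seed(seed)
  par <- resolve_engine_params(config)
  if (engine == "cpp") {
    res <- cpp_run_generations(par)
    traj <- .assemble_trajectory(res$records, res$outcome, res$terminal_gen,
                                 res$terminal_p, res$extinct == 1L,
                                 res$resampled, config, seed, engine)
  } else {
    traj <- .run_generations_r(config, par, seed)
  }
  traj
}

# Reference (plain R) generation loop; mirrors the compiled engine draw
# for draw.
.run_generations_r <- function(config, par, seed) {
  pop <- initialize_generation(config)
  rows <- list()
  g <- 0L
  outcome <- 0L
  extinct <- FALSE
  resampled <- 0L
  repeat {
    p <- allele_frequency(pop$females, pop$males,
                          females_only = par$males_in_p == 0L)
    n_sp <- sum(pop$females$spov)
    n_mf <- par$nf - n_sp
    if (p == 0 || p == 1) {
      rows[[g + 1L]] <- c(g, p, n_sp, n_mf, rep(NA_real_, 6))
      outcome <- if (p == 1) 1L else 2L
      break
    }
    if (g >= par$maxgen) {
      rows[[g + 1L]] <- c(g, p, n_sp, n_mf, rep(NA_real_, 6))
      outcome <- 0L
      break
    }
    season <- run_season_r(pop, par)
    sf <- season$females
    rows[[g + 1L]] <- c(
      g, p, n_sp, n_mf,
      sum(sf$alive & sf$spov), sum(sf$alive & !sf$spov),
      season$tallies$matings[["spov"]], season$tallies$matings[["mfcl"]],
      season$tallies$males_cannibalized, season$tallies$male_bg_deaths
    )
    rep_out <- withCallingHandlers(
      build_next_generation(season, config),
      warning = function(w) {
        if (grepl("with replacement", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    )
    if (any(rep_out$resampled)) resampled <- resampled + 1L
    if (rep_out$extinct) {
      extinct <- TRUE
      pp <- rep_out$parental_p
      outcome <- if (!is.na(pp) && pp >= 0.5) 1L else 2L
      g <- g + 1L
      rows[[g + 1L]] <- c(g, if (outcome == 1L) 1 else 0, NA, NA,
                          rep(NA_real_, 6))
      break
    }
    pop <- rep_out$population
    g <- g + 1L
  }
  rec <- do.call(rbind, rows)
  last <- rows[[length(rows)]]
  .assemble_trajectory(rec, outcome, last[1], last[2], extinct, resampled,
                       config, seed, "r")
}

#' @export
print.spovsim_trajectory <- function(x, ...) {
  cat("<spovsim_trajectory>", x$config$spillover_strategy, "vs MFCL,",
      x$config$environment$richness, "environment, different =",
      x$config$different, ", dominance =", x$config$dominance, "\n")
  cat("  outcome:", x$outcome,
      if (x$quasi_equilibrium) "(quasi-equilibrium)" else "",
      "at generation", x$terminal_generation,
      sprintf("(terminal p = %.4g)\n", x$terminal_p))
  pr <- x$records$p
  cat(sprintf("  p range over %d recorded generations: [%.3g, %.3g]\n",
              nrow(x$records), min(pr), max(pr)))
  invisible(x)
}

#' Maintenance and invasion runs
#'
#' `run_maintenance()` starts from 50 percent allele frequency with the
#' canonical genotype composition (thirds of heterozygous,
#' spillover-homozygous and MFCL-homozygous females; males half and
#' half). `run_invasion()` starts from a rare-mutant allele frequency
#' (0.01 emulates a novel spillover mutation in an MFCL population; 0.99
#' a novel MFCL mutation in a spillover population), with genotypes in
#' Hardy-Weinberg proportions.
#'
#' @param config a `spovsim_config`.
#' @param p0 initial spillover-allele frequency for an invasion run.
#' @inheritParams run_generations
#' @return a `spovsim_trajectory`.
#' @export
run_maintenance <- function(config, seed = NULL, engine = c("cpp", "r"),
                            max_generations = NULL) {
  config$initial <- list(type = "thirds", p0 = 0.5)
  run_generations(config, seed = seed, engine = match.arg(engine),
                  max_generations = max_generations)
}

#' @rdname run_maintenance
#' @export
run_invasion <- function(config, p0 = 0.01, seed = NULL,
                         engine = c("cpp", "r"), max_generations = NULL) {
  .check(p0 >= 0 && p0 <= 1, "p0")
  config$initial <- list(type = "hw", p0 = p0)
  run_generations(config, seed = seed, engine = match.arg(engine),
                  max_generations = max_generations)
}

#' Classify a trajectory's terminal outcome
#'
#' Fixation labels follow the terminal allele frequency; a run still
#' polymorphic at the generation cap is `"coexistence_at_max_gen"`. A
#' fixation later than `quasi_fraction` of the cap is flagged as a
#' quasi-equilibrium (the allele pair persisted for a long time before
#' one was lost).
#'
#' @param trajectory a `spovsim_trajectory`.
#' @param quasi_fraction override of the config's quasi-equilibrium
#'   fraction (default 0.5).
#' @return list with `outcome`, `quasi_equilibrium`,
#'   `terminal_generation`, `terminal_p`.
#' @export
classify_outcome <- function(trajectory, quasi_fraction = NULL) {
  stopifnot(inherits(trajectory, "spovsim_trajectory"))
  qf <- quasi_fraction %||% trajectory$config$quasi_fraction
  p <- trajectory$terminal_p
  outcome <- if (p == 1) "spillover_fixed" else if (p == 0) "mfcl_fixed" else
    "coexistence_at_max_gen"
  list(
    outcome = outcome,
    quasi_equilibrium = outcome != "coexistence_at_max_gen" &&
      trajectory$terminal_generation >=
        qf * trajectory$config$max_generations,
    terminal_generation = trajectory$terminal_generation,
    terminal_p = p
  )
}

#' Sweep a parameter grid
#'
#' Runs every combination of environment, juvenile survival
#' differential, dominance and strategy pairing, with any number of
#' replicates per cell. One root seed spawns one sub-seed per run
#' (logged in the output), so the whole sweep is reproducible.
#'
#' @param base_config template `spovsim_config`; grid columns override
#'   its fields cell by cell.
#' @param environments character vector of richness labels.
#' @param differents numeric vector of `different` values.
#' @param dominances character vector of dominance settings.
#' @param strategies character vector of spillover-family strategy names.
#' @param replicates runs per cell.
#' @param seed root seed.
#' @param max_generations optional cap override for the whole sweep.
#' @param initial optional initial-composition override (`"thirds"` or a
#'   numeric `p0`), applied to every cell.
#' @param engine passed to [run_generations()].
#' @return list of class `spovsim_sweep`: `runs` (one row per run:
#'   cell coordinates, sub-seed, outcome, terminal generation and p, and
#'   the run's min/max p) and `summary` (outcome counts per cell).
#' @export
sweep_experiments <- function(base_config = simulation_config(),
                              environments = c("poor", "rich"),
                              differents = c(0.1, 0.3, 0.5, 0.7, 0.9),
                              dominances = base_config$dominance,
                              strategies = base_config$spillover_strategy,
                              replicates = 1L,
                              seed = 1L,
                              max_generations = NULL,
                              initial = NULL,
                              engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  grid <- expand.grid(
    environment = environments, different = differents,
    dominance = dominances, strategy = strategies,
    replicate = seq_len(replicates),
    stringsAsFactors = FALSE
  )
  if (nrow(grid) == 0L) stop("empty sweep grid", call. = FALSE)
  set.seed(seed)
  grid$run_seed <- sample.int(.Machine$integer.max, nrow(grid))

  res <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- base_config
    cfg$environment <- default_environment(grid$environment[i])
    cfg$different <- grid$different[i]
    cfg$dominance <- grid$dominance[i]
    cfg$spillover_strategy <- .canon_strategy(grid$strategy[i])
    cfg$strategies$spov <- default_strategy(cfg$spillover_strategy)
    if (!is.null(initial)) {
      cfg <- do.call(simulation_config, utils::modifyList(
        .config_as_args(cfg), list(initial = initial)))
    }
    traj <- run_generations(cfg, seed = grid$run_seed[i], engine = engine,
                            max_generations = max_generations)
    data.frame(
      outcome = traj$outcome,
      quasi_equilibrium = traj$quasi_equilibrium,
      terminal_generation = traj$terminal_generation,
      terminal_p = traj$terminal_p,
      min_p = min(traj$records$p),
      max_p = max(traj$records$p)
    )
  })
  runs <- cbind(grid, do.call(rbind, res))

  summary <- aggregate(
    cbind(
      n = rep(1L, nrow(runs)),
      spillover_fixed = runs$outcome == "spillover_fixed",
      mfcl_fixed = runs$outcome == "mfcl_fixed",
      coexistence = runs$outcome == "coexistence_at_max_gen"
    ) ~ environment + different + dominance + strategy,
    data = runs, FUN = sum
  )
  out <- list(runs = runs, summary = summary, seed = seed)
  class(out) <- "spovsim_sweep"
  out
}

# Recover simulation_config() arguments from a config (used to rebuild a
# config with one field replaced through the validating constructor).
.config_as_args <- function(cfg) {
  list(
    spillover_strategy = cfg$spillover_strategy,
    environment = cfg$environment,
    different = cfg$different,
    dominance = cfg$dominance,
    initial = cfg$initial,
    n_females = cfg$n_females,
    n_males = cfg$n_males,
    season_length = cfg$season_length,
    max_generations = cfg$max_generations,
    pmate = cfg$pmate,
    cl_value = cfg$cl_value,
    male_meal_gain = cfg$male_meal_gain,
    male_mortality_rate = cfg$male_mortality_rate,
    escape_coeff = cfg$escape_coeff,
    mfcl_attack = cfg$mfcl_attack,
    mfcl_attack_rule = cfg$mfcl_attack_rule,
    encounter_model = cfg$encounter_model,
    juvenile_mode = cfg$juvenile_mode,
    different_males = cfg$different_males,
    count_males_in_p = cfg$count_males_in_p,
    quasi_fraction = cfg$quasi_fraction,
    strategies = cfg$strategies,
    seed = cfg$seed,
    replicates = cfg$replicates
  )
}

#' @export
print.spovsim_sweep <- function(x, ...) {
  cat("<spovsim_sweep>", nrow(x$runs), "runs over",
      nrow(x$summary), "cells (root seed", x$seed, ")\n")
  print(x$summary)
  invisible(x)
}
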
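# Deterministic output formats, run manifests, plotting helper, and the
# seeded micro-fixture generator used as a test oracle.

.trajectory_columns <- c("generation", "p", "n_es_females", "n_mfcl_females",
                         "matings_es", "matings_mfcl", "males_cannibalized",
                         "mfcl_mating_pct", "rel_fitness_es")

#' Write / read a trajectory CSV
#'
#' One row per recorded generation with the columns `generation`, `p`,
#' `n_es_females`, `n_mfcl_females`, `matings_es`, `matings_mfcl`,
#' `males_cannibalized`, `mfcl_mating_pct`, `rel_fitness_es`; floats at
#' six significant digits.
#'
#' @param trajectory a `spovsim_trajectory` (or its `records` frame).
#' @param path output / input file path.
#' @return `write_trajectory()` returns `path` invisibly;
#'   `read_trajectory()` returns the data frame.
#' @export
write_trajectory <- function(trajectory, path) {
  rec <- if (inherits(trajectory, "spovsim_trajectory")) {
    trajectory$records
  } else {
    as.data.frame(trajectory)
  }
  out <- data.frame(
    generation = rec$generation,
    p = signif(rec$p, 6),
    n_es_females = rec$n_spov_females,
    n_mfcl_females = rec$n_mfcl_females,
    matings_es = rec$matings_spov,
    matings_mfcl = rec$matings_mfcl,
    males_cannibalized = rec$males_cannibalized,
    mfcl_mating_pct = signif(rec$mfcl_mating_pct, 6),
    rel_fitness_es = signif(rec$rel_fitness_spov, 6)
  )
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  read.csv(path, colClasses = c(generation = "integer"))
}

#' Run manifest
#'
#' Everything needed to re-run an experiment bit-identically: the fully
#' resolved configuration, the root seed and per-run sub-seeds, the RNG
#' kind, package version and timestamps.
#'
#' @param config a `spovsim_config`.
#' @param seed root seed.
#' @param run_seeds per-replicate sub-seeds (if any).
#' @param outputs named character vector of output file paths.
#' @param path optional JSON path to write the manifest to.
#' @return the manifest list, invisibly if written.
#' @export
run_manifest <- function(config, seed, run_seeds = NULL, outputs = NULL,
                         path = NULL) {
  man <- list(
    package = "spovsim",
    version = as.character(utils::packageVersion("spovsim")),
    rng_kind = paste(RNGkind(), collapse = "/"),
    seed = seed,
    run_seeds = run_seeds,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = as.list(outputs),
    config = jsonlite::fromJSON(jsonlite::toJSON(
      {
        x <- unclass(config)
        x$environment <- unclass(x$environment)
        x$strategies <- lapply(x$strategies, unclass)
        x
      },
      auto_unbox = TRUE, digits = NA, null = "null"
    ))
  )
  if (!is.null(path)) {
    jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    return(invisible(man))
  }
  man
}

#' Deterministic micro scenario plus its expected event trace
#'
#' Builds a miniature configuration (a handful of individuals, a few
#' days) and runs the plain-R reference engine on it under the given
#' seed, returning the scenario, the full event trace and the
#' end-of-season state. The compiled engine must reproduce this trace
#' exactly; the test suite asserts that it does.
#'
#' @param n_males,n_females tiny cohort sizes (at most 5 each).
#' @param days season length (at most 5).
#' @param seed integer seed.
#' @param ... config overrides (e.g. `environment`, `dominance`).
#' @return list with `config`, `seed`, `population` (the initialized
#'   generation), `trace` (event data frame) and `season` (the reference
#'   engine's end state).
#' @export
make_micro_fixture <- function(n_males = 2L, n_females = 2L, days = 3L,
                               seed = 7L, ...) {
  stopifnot(n_males <= 5L, n_females <= 5L, days <= 5L,
            n_males >= 0L, n_females >= 0L, days >= 1L)
  # a one-day-maturing cast so encounters actually happen in a short run
  strategies <- list(
    spov = {
      s <- default_strategy("EARLY-SPOV"); s$fem_mat_mean <- 1; s
    },
    mfcl = {
      s <- default_strategy("MFCL"); s$fem_mat_mean <- 1; s
    }
  )
  cfg <- simulation_config(
    n_females = max(n_females, 1L), n_males = max(n_males, 1L),
    season_length = days, initial = 0.5, strategies = strategies,
    max_generations = 1L, ...
  )
  par <- resolve_engine_params(cfg)
  par$nf <- n_females
  par$nm <- n_males
  set.seed(seed)
  geno <- .initial_genotypes(par)
  pop <- .init_life_history(geno, par)
  # males must mature within the micro season to be interesting
  pop$males$mat <- pmin(pop$males$mat, 1L)
  season <- run_season_r(pop, par, log_events = TRUE)
  list(config = cfg, par = par, seed = seed, population = pop,
       trace = season$events, season = season)
}

#' Plot an allele-frequency trajectory
#'
#' Base-graphics line plot of the spillover-allele frequency across
#' generations, with the TOP/BOTTOM threshold marked.
#'
#' @param x a `spovsim_trajectory`.
#' @param threshold optional horizontal reference line (default 0.85).
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.spovsim_trajectory <- function(x, threshold = 0.85, ...) {
  rec <- x$records
  graphics::plot(rec$generation, rec$p, type = "l", ylim = c(0, 1),
                 xlab = "generation", ylab = "spillover allele frequency p",
                 ...)
  graphics::abline(h = threshold, lty = 3, col = "grey40")
  invisible(x)
}
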
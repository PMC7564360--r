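# Parameterization: environments, strategies, and the full scenario config.
# All numeric defaults are the field-calibrated values for the Iberian
# tarantula life history that the model is built around.

.strategy_names <- c("MFCL", "SPOV", "BCD-SPOV", "EARLY-SPOV", "BCD-EM-SPOV")
.strategy_aliases <- c(
  "EM-SPOV" = "EARLY-SPOV",
  "BCD-EARLY-SPOV" = "BCD-EM-SPOV",
  "BCD-EM-EARLY-SPOV" = "BCD-EM-SPOV"
)

.canon_strategy <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  name <- toupper(name)
  if (name %in% names(.strategy_aliases)) name <- unname(.strategy_aliases[name])
  if (!name %in% .strategy_names) {
    stop("unknown strategy name: ", name, call. = FALSE)
  }
  name
}

#' Default parameterization of one female strategy
#'
#' Returns the printed life-history parameterization for one of the five
#' strategies: `MFCL`, `SPOV`, `BCD-SPOV`, `EARLY-SPOV` (alias `EM-SPOV`)
#' or `BCD-EM-SPOV`. The strategies differ only in maturation time, the
#' size-at-maturation regression, adult intake, background mortality and
#' the egg-sac-volume regression.
#'
#' @param name strategy name (case-insensitive; aliases accepted).
#' @return A list of class `spovsim_strategy` with fields:
#'   `name`; `fem_mat_mean`, `fem_mat_sd` (maturation day since season
#'   onset, days); `cw_coeffs` (intercept, maturation-day slope, carapace
#'   length slope, residual sd of adult carapace width, mm);
#'   `intake_multiplier` (spillover females forage at 1.5x the MFCL rate);
#'   `mortality_rate` (background daily death probability, day^-1, the
#'   rich-environment value for spillover strategies);
#'   `vol_coeffs` (intercept, CW slope, condition slope, residual sd of
#'   egg-sac volume, mm^3); `bcd` (whether fecundity uses realized adult
#'   condition as a covariate).
#' @examples
#' default_strategy("EARLY-SPOV")$fem_mat_mean # 39
#' default_strategy("MFCL")$fem_mat_mean      # 56
#' @export
default_strategy <- function(name) {
  name <- .canon_strategy(name)
  early <- name %in% c("EARLY-SPOV", "BCD-EM-SPOV")
  spov <- name != "MFCL"
  bcd <- name %in% c("MFCL", "BCD-SPOV", "BCD-EM-SPOV")
  vol <- switch(name,
    "MFCL" = c(intercept = -2297.64, cw = 217.88, cond = 123.44, sd = 129.59),
    "SPOV" = ,
    "EARLY-SPOV" = c(intercept = -1156.43, cw = 277.21, cond = 0, sd = 140.33),
    "BCD-SPOV" = ,
    "BCD-EM-SPOV" = c(intercept = -1156.43, cw = 277.21, cond = 123.44, sd = 132.97)
  )
  spec <- list(
    name = name,
    fem_mat_mean = if (early) 39 else 56,
    fem_mat_sd = 0.5,
    cw_coeffs = c(
      intercept = 3.21,
      mat = if (early) 0.047 else 0.024,
      cl = 0.39,
      sd = if (early) 0.5066 else 0.4679
    ),
    intake_multiplier = if (spov) 1.5 else 1.0,
    mortality_rate = if (spov) 0.0036 else 0.0030,
    vol_coeffs = vol,
    bcd = bcd
  )
  class(spec) <- "spovsim_strategy"
  spec
}

#' Default environment specification
#'
#' Two canonical environments are supported. Rich environments have high
#' prey availability (condition-increment scale 0.1482 mm/day), high
#' male-female encounter rates (`maxenc = 3` females per male per day), a
#' 1.2x mortality multiplier on spillover females and a moderate spillover
#' attack probability (`pspov = 0.5`). Poor environments halve the intake
#' scale (0.0741), reduce encounters (`maxenc = 1`), raise the spillover
#' mortality multiplier to 1.5 (daily rate 0.0045 instead of 0.0036) and
#' raise the spillover attack probability to 0.9.
#'
#' @param richness `"poor"` or `"rich"`.
#' @param ... named overrides of individual fields (`maxenc`,
#'   `intake_scale`, `mort_multiplier`, `pspov`), for sensitivity sweeps.
#' @return list of class `spovsim_environment`.
#' @export
default_environment <- function(richness = c("poor", "rich"), ...) {
  richness <- match.arg(richness)
  env <- if (richness == "poor") {
    list(richness = "poor", maxenc = 1L, intake_scale = 0.0741,
         mort_multiplier = 1.5, pspov = 0.9)
  } else {
    list(richness = "rich", maxenc = 3L, intake_scale = 0.1482,
         mort_multiplier = 1.2, pspov = 0.5)
  }
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), c("maxenc", "intake_scale", "mort_multiplier", "pspov"))
    if (length(bad)) stop("unknown environment field(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    env <- modifyList(env, dots)
  }
  env$maxenc <- as.integer(env$maxenc)
  .check(env$maxenc >= 1L, "maxenc")
  .check(env$intake_scale > 0, "intake_scale")
  .check(env$mort_multiplier > 0, "mort_multiplier")
  .check(env$pspov >= 0 && env$pspov <= 1, "pspov")
  class(env) <- "spovsim_environment"
  env
}

.check <- function(ok, field) {
  if (!isTRUE(ok)) stop("invalid value for field '", field, "'", call. = FALSE)
  invisible(TRUE)
}

#' Build a full, validated simulation configuration
#'
#' Assembles every parameter of one simulation scenario, filling in the
#' default parameterization for anything not supplied. The scenario pits
#' one spillover-family strategy against MFCL in one environment.
#'
#' @param spillover_strategy name of the spillover-family strategy to pair
#'   against MFCL (`"SPOV"`, `"BCD-SPOV"`, `"EARLY-SPOV"`, `"BCD-EM-SPOV"`).
#'   `"MFCL"` is also accepted, yielding a selectively neutral control in
#'   which the tracked allele has no phenotypic effect.
#' @param environment `"poor"`, `"rich"`, or a `spovsim_environment`.
#' @param different proportion of spillover-phenotype juveniles surviving
#'   to maturation relative to MFCL juveniles, in (0, 1].
#' @param dominance which allele is dominant in heterozygous females:
#'   `"spillover"` or `"mfcl"`.
#' @param initial initial genetic composition: `"thirds"` (the 50 percent
#'   starting point used for maintenance runs: one third each of
#'   heterozygous, spillover-homozygous and MFCL-homozygous females, males
#'   half and half) or a numeric allele frequency `p0` in `[0, 1]`
#'   (genotypes then drawn from Hardy-Weinberg proportions, as for
#'   invasion runs at 0.01 / 0.99).
#' @param n_females,n_males adults per generation (default 500 each).
#' @param season_length days in the mating season (default 79).
#' @param max_generations generation cap (default 20000).
#' @param pmate daily mating probability for a cohabiting pair that was
#'   not broken up by an attack (default 0.5, i.e. mean cohabitation of
#'   about two days).
#' @param cl_value carapace length covariate of the size regressions (mm),
#'   held constant at 3.5.
#' @param male_meal_gain condition gained by a female from cannibalizing a
#'   male (2.39 mm, capped at her satiation threshold).
#' @param male_mortality_rate background daily male mortality (0.0045).
#' @param escape_coeff coefficient of the male escape curve
#'   `exp(-CW * escape_coeff)` (0.1 per mm).
#' @param mfcl_attack probability that an MFCL female attacks when her
#'   attack condition holds (default 1).
#' @param mfcl_attack_rule `"literal"` (attack iff mated OR not satiated)
#'   or `"mated_only"` (attack iff mated).
#' @param encounter_model `"fixed"` (each searching male draws exactly
#'   `maxenc` distinct females per day) or `"poisson"` (daily count drawn
#'   from Poisson(`maxenc`)).
#' @param juvenile_mode how `different` is applied to spillover-phenotype
#'   daughters: `"weight"` (relative sampling weight; default) or `"cull"`
#'   (Bernoulli thinning before sampling).
#' @param different_males also apply `different` to sons carrying the
#'   spillover allele (default `TRUE`: the juvenile survival differential
#'   acts before maturation, where juveniles of both sexes express the
#'   voracity syndrome; hemizygous sons express their single allele).
#'   Set `FALSE` to confine the differential to daughters, treating males
#'   as fully phenotype-neutral carriers at every stage.
#' @param count_males_in_p count male X copies in the allele frequency
#'   (default `TRUE`: 1500 copies for 500 + 500 adults).
#' @param quasi_fraction fraction of `max_generations` after which a
#'   fixation is additionally flagged as a quasi-equilibrium (default 0.5).
#' @param strategies optional list with elements `spov` and/or `mfcl`
#'   giving full `spovsim_strategy` overrides.
#' @param seed optional integer seed recorded in the config.
#' @param replicates default replicate count for sweep runners.
#' @return list of class `spovsim_config`.
#' @examples
#' cfg <- simulation_config("EARLY-SPOV", environment = "poor",
#'                          different = 0.7, dominance = "spillover")
#' cfg$environment$maxenc # 1
#' @export
simulation_config <- function(spillover_strategy = "EARLY-SPOV",
                              environment = "poor",
                              different = 0.5,
                              dominance = c("spillover", "mfcl"),
                              initial = "thirds",
                              n_females = 500L,
                              n_males = 500L,
                              season_length = 79L,
                              max_generations = 20000L,
                              pmate = 0.5,
                              cl_value = 3.5,
                              male_meal_gain = 2.39,
                              male_mortality_rate = 0.0045,
                              escape_coeff = 0.1,
                              mfcl_attack = 1.0,
                              mfcl_attack_rule = c("literal", "mated_only"),
                              encounter_model = c("fixed", "poisson"),
                              juvenile_mode = c("weight", "cull"),
                              different_males = TRUE,
                              count_males_in_p = TRUE,
                              quasi_fraction = 0.5,
                              strategies = NULL,
                              seed = NULL,
                              replicates = 1L) {
  dominance <- match.arg(dominance)
  mfcl_attack_rule <- match.arg(mfcl_attack_rule)
  encounter_model <- match.arg(encounter_model)
  juvenile_mode <- match.arg(juvenile_mode)

  if (is.character(environment)) {
    environment <- default_environment(environment)
  }
  stopifnot(inherits(environment, "spovsim_environment"))

  spov_name <- .canon_strategy(spillover_strategy)
  strat <- list(spov = default_strategy(spov_name),
                mfcl = default_strategy("MFCL"))
  if (!is.null(strategies)) {
    bad <- setdiff(names(strategies), c("spov", "mfcl"))
    if (length(bad)) stop("unknown strategies element(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    for (nm in names(strategies)) {
      stopifnot(inherits(strategies[[nm]], "spovsim_strategy"))
      strat[[nm]] <- strategies[[nm]]
    }
  }

  if (is.character(initial)) {
    .check(identical(initial, "thirds"), "initial")
    initial <- list(type = "thirds", p0 = 0.5)
  } else if (is.numeric(initial) && length(initial) == 1L) {
    .check(initial >= 0 && initial <= 1, "initial")
    initial <- list(type = "hw", p0 = as.numeric(initial))
  } else if (is.list(initial) && !is.null(initial$type)) {
    .check(initial$type %in% c("thirds", "hw"), "initial")
    if (is.null(initial$p0)) initial$p0 <- 0.5
    .check(initial$p0 >= 0 && initial$p0 <= 1, "initial")
  } else {
    stop("invalid value for field 'initial'", call. = FALSE)
  }

  .check(is.numeric(different) && different > 0 && different <= 1, "different")
  .check(n_females >= 1 && n_males >= 1, "n_females/n_males")
  .check(season_length >= 1, "season_length")
  .check(max_generations >= 0, "max_generations")
  .check(pmate >= 0 && pmate <= 1, "pmate")
  .check(cl_value > 0, "cl_value")
  .check(male_meal_gain >= 0, "male_meal_gain")
  .check(male_mortality_rate >= 0 && male_mortality_rate <= 1, "male_mortality_rate")
  .check(escape_coeff >= 0, "escape_coeff")
  .check(mfcl_attack >= 0 && mfcl_attack <= 1, "mfcl_attack")
  .check(quasi_fraction > 0 && quasi_fraction <= 1, "quasi_fraction")

  cfg <- list(
    spillover_strategy = spov_name,
    strategies = strat,
    environment = environment,
    different = as.numeric(different),
    dominance = dominance,
    initial = initial,
    n_females = as.integer(n_females),
    n_males = as.integer(n_males),
    season_length = as.integer(season_length),
    max_generations = as.integer(max_generations),
    pmate = pmate,
    cl_value = cl_value,
    male_meal_gain = male_meal_gain,
    male_mortality_rate = male_mortality_rate,
    escape_coeff = escape_coeff,
    mfcl_attack = mfcl_attack,
    mfcl_attack_rule = mfcl_attack_rule,
    encounter_model = encounter_model,
    juvenile_mode = juvenile_mode,
    different_males = isTRUE(different_males),
    count_males_in_p = isTRUE(count_males_in_p),
    quasi_fraction = quasi_fraction,
    seed = if (is.null(seed)) NULL else as.integer(seed),
    replicates = as.integer(replicates)
  )
  class(cfg) <- "spovsim_config"
  cfg
}

#' @export
print.spovsim_config <- function(x, ...) {
  cat("<spovsim_config>\n")
  cat("  pair:       ", x$spillover_strategy, "vs MFCL\n")
  cat("  environment:", x$environment$richness,
      sprintf("(maxenc=%d, intake=%.4g, mort.mult=%.2g, pspov=%.2g)\n",
              x$environment$maxenc, x$environment$intake_scale,
              x$environment$mort_multiplier, x$environment$pspov))
  cat("  different:  ", x$different, "  dominance:", x$dominance, "\n")
  cat("  initial:    ", x$initial$type, sprintf("(p0=%.3g)", x$initial$p0), "\n")
  cat("  adults:     ", x$n_females, "females +", x$n_males, "males;",
      x$season_length, "day season; cap", x$max_generations, "generations\n")
  invisible(x)
}

# Names accepted at the top level of a config file / mapping.
.config_keys <- function() setdiff(names(formals(simulation_config)), "strategies")

#' Load a configuration from a file or mapping
#'
#' Reads a scenario from a YAML or JSON file (or an already-parsed list)
#' and returns a fully defaulted, validated [simulation_config()]. The
#' `environment` key may be a richness label or a mapping with a
#' `richness` key plus field overrides. Unknown keys are rejected.
#'
#' @param x path to a `.yaml`/`.yml`/`.json` file, or a named list.
#' @param overrides named list applied on top of the file values (used by
#'   command-line runners for flag overrides).
#' @return `spovsim_config`.
#' @export
load_config <- function(x, overrides = NULL) {
  if (is.character(x) && length(x) == 1L) {
    if (grepl("\\.json$", x, ignore.case = TRUE)) {
      x <- jsonlite::fromJSON(x, simplifyVector = TRUE)
    } else {
      x <- yaml::read_yaml(x)
    }
  }
  stopifnot(is.list(x))
  if (!is.null(overrides)) x <- modifyList(x, overrides)
  # a file previously written by write_config() carries a format marker
  # and a full strategies block; reconstruct it through the same path
  if (identical(x$format, "spovsim_config/1")) {
    return(.config_from_serialized(x))
  }
  bad <- setdiff(names(x), .config_keys())
  if (length(bad)) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(x$environment) && is.list(x$environment)) {
    env_args <- x$environment
    richness <- env_args$richness %||% "poor"
    env_args$richness <- NULL
    x$environment <- do.call(default_environment, c(list(richness), env_args))
  }
  do.call(simulation_config, x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize / restore a configuration
#'
#' `write_config()` stores a config as JSON at full numeric precision so
#' that a round trip through [read_config()] reproduces every field
#' bit-exactly.
#'
#' @param config a `spovsim_config`.
#' @param path output / input file path.
#' @return `write_config()` returns `path` invisibly; `read_config()`
#'   returns a revalidated `spovsim_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "spovsim_config"))
  x <- unclass(config)
  x$environment <- unclass(x$environment)
  # named coefficient vectors become JSON objects so names survive
  x$strategies <- lapply(x$strategies, function(s) {
    s <- unclass(s)
    s$cw_coeffs <- as.list(s$cw_coeffs)
    s$vol_coeffs <- as.list(s$vol_coeffs)
    s
  })
  x$format <- "spovsim_config/1"
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(x$format, "spovsim_config/1")) {
    stop("not a spovsim config file: ", path, call. = FALSE)
  }
  .config_from_serialized(x)
}

# Rebuild a config from its serialized form, restoring the numeric types
# JSON cannot distinguish.
.config_from_serialized <- function(x) {
  x$format <- NULL
  strat <- lapply(x$strategies, function(s) {
    list(
      name = s$name,
      fem_mat_mean = as.numeric(s$fem_mat_mean),
      fem_mat_sd = as.numeric(s$fem_mat_sd),
      cw_coeffs = vapply(s$cw_coeffs, as.numeric, 0)[c("intercept", "mat",
                                                       "cl", "sd")],
      intake_multiplier = as.numeric(s$intake_multiplier),
      mortality_rate = as.numeric(s$mortality_rate),
      vol_coeffs = vapply(s$vol_coeffs, as.numeric, 0)[c("intercept", "cw",
                                                         "cond", "sd")],
      bcd = isTRUE(s$bcd)
    ) |> structure(class = "spovsim_strategy")
  })
  env_args <- x$environment
  env <- do.call(default_environment,
                 c(list(env_args$richness),
                   lapply(env_args[c("maxenc", "intake_scale",
                                     "mort_multiplier", "pspov")],
                          as.numeric)))
  x$environment <- NULL
  x$strategies <- NULL
  x$initial <- list(type = x$initial$type, p0 = as.numeric(x$initial$p0))
  for (nm in c("different", "pmate", "cl_value", "male_meal_gain",
               "male_mortality_rate", "escape_coeff", "mfcl_attack",
               "quasi_fraction")) {
    if (!is.null(x[[nm]])) x[[nm]] <- as.numeric(x[[nm]])
  }
  do.call(simulation_config,
          c(x, list(environment = env, strategies = strat)))
}

# Flatten a config into the plain parameter list both engines consume.
# Phenotype index convention everywhere: 1 = MFCL, 2 = spillover family.
# Effective spillover female mortality is the MFCL base rate times the
# environment's mortality multiplier (0.0036 rich, 0.0045 poor).
resolve_engine_params <- function(config) {
  stopifnot(inherits(config, "spovsim_config"))
  st <- list(config$strategies$mfcl, config$strategies$spov)
  env <- config$environment
  mort_f <- c(config$strategies$mfcl$mortality_rate,
              config$strategies$mfcl$mortality_rate * env$mort_multiplier)
  list(
    nf = config$n_females,
    nm = config$n_males,
    slen = config$season_length,
    maxgen = config$max_generations,
    dom_spov = as.integer(config$dominance == "spillover"),
    different = config$different,
    cull = as.integer(config$juvenile_mode == "cull"),
    different_males = as.integer(config$different_males),
    maxenc = env$maxenc,
    poisson_enc = as.integer(config$encounter_model == "poisson"),
    intake_scale = env$intake_scale,
    pspov = env$pspov,
    mat_mean = vapply(st, `[[`, 0, "fem_mat_mean"),
    mat_sd = vapply(st, `[[`, 0, "fem_mat_sd"),
    cw_int = vapply(st, function(s) s$cw_coeffs[["intercept"]], 0),
    cw_mat = vapply(st, function(s) s$cw_coeffs[["mat"]], 0),
    cw_cl = vapply(st, function(s) s$cw_coeffs[["cl"]], 0),
    cw_sd = vapply(st, function(s) s$cw_coeffs[["sd"]], 0),
    intake_mult = vapply(st, `[[`, 0, "intake_multiplier"),
    mort_f = mort_f,
    vol_int = vapply(st, function(s) s$vol_coeffs[["intercept"]], 0),
    vol_cw = vapply(st, function(s) s$vol_coeffs[["cw"]], 0),
    vol_cond = vapply(st, function(s) s$vol_coeffs[["cond"]], 0),
    vol_sd = vapply(st, function(s) s$vol_coeffs[["sd"]], 0),
    cl = config$cl_value,
    meal = config$male_meal_gain,
    mort_m = config$male_mortality_rate,
    esc = config$escape_coeff,
    pmate = config$pmate,
    mfcl_attack = config$mfcl_attack,
    mated_only = as.integer(config$mfcl_attack_rule == "mated_only"),
    # the spillover slot can hold MFCL itself (neutral control), in which
    # case its females use the state-dependent MFCL attack rule
    spov_uses_mfcl_rule = as.integer(config$spillover_strategy == "MFCL"),
    init_thirds = as.integer(config$initial$type == "thirds"),
    p0 = config$initial$p0,
    males_in_p = as.integer(config$count_males_in_p),
    # universal allometry constants shared with the compiled engine
    cond_int = .cond_coeffs[["intercept"]],
    cond_cw = .cond_coeffs[["cw"]],
    cond_sd = .cond_coeffs[["sd"]],
    sat_int = .sat_coeffs[["intercept"]],
    sat_cw = .sat_coeffs[["cw"]],
    sat_cw2 = .sat_coeffs[["cw2"]],
    mal_mat_mean = .male_mat[["mean"]],
    mal_mat_sd = .male_mat[["sd"]],
    off_int = .offspring_coeffs[["intercept"]],
    off_vol = .offspring_coeffs[["vol"]]
  )
}
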
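# The within-season daily loop: maturation entry, background mortality,
# feeding, male mate search, residency/cohabitation, attack/escape/
# cannibalism and mating. Two engines implement the identical rules and
# the identical random-draw protocol: a compiled one (used for multi-
# generation experiments) and the plain-R reference below (used for
# micro-scale oracle runs and debugging). With the same seed the two
# produce bit-identical event sequences and end states.
#
# Fixed within-day ordering, for each day t = 1..season_length:
#   1. entry      - individuals with maturation day t become active
#   2. mortality  - every mature, alive female (ascending index), then
#                   every mature, alive male, dies with her/his daily
#                   rate; a dying partner dissolves the cohabitation
#   3. feeding    - every mature, alive, unsatiated female gains
#                   U(0,1) * intake_scale * intake_multiplier, capped at
#                   her satiation threshold (satiation is absorbing)
#   4. search     - every mature, alive, non-cohabiting male draws up to
#                   maxenc distinct mature females (partial Fisher-Yates
#                   over the day's candidate list); a female with a
#                   resident male turns the newcomer away; otherwise the
#                   female may attack (one uniform draw per decision,
#                   even when the probability is 0 or 1); an attacked
#                   male escapes with exp(-CW * escape_coeff) (his
#                   searching day ends) or is cannibalized; if no attack
#                   and the female is unmated, the male takes residency
#                   and stops searching; a mated female that does not
#                   attack lets him move on
#   5. cohabit    - each resident pair (ascending female index): attack
#                   decision first; an escape dissolves the cohabitation,
#                   a kill ends the male; otherwise the pair mates with
#                   probability pmate and the male departs, free to
#                   search again the next day
# Pairs formed in step 4 are processed in step 5 of the same day.

.attack_prob_scalar <- function(spov, mated, satiated, par) {
  if (spov && par$spov_uses_mfcl_rule == 0L) {
    par$pspov
  } else if (par$mated_only == 1L) {
    if (mated) par$mfcl_attack else 0
  } else {
    if (mated || !satiated) par$mfcl_attack else 0
  }
}

#' Does a female attack an approaching (or cohabiting) male?
#'
#' Spillover-family females attack with probability `pspov` regardless of
#' their mating and satiation state (the behavioral-syndrome phenotype).
#' MFCL females attack (with probability `mfcl_attack`, default 1) only
#' if they have already mated or are not yet satiated; a satiated virgin
#' MFCL female never attacks, which is what lets cohabitation and mating
#' proceed. One uniform deviate is consumed per decision.
#'
#' @param spov logical: female expresses the spillover phenotype.
#' @param mated,satiated the female's current state flags.
#' @param config a `spovsim_config` (supplies `pspov`, `mfcl_attack`,
#'   and the MFCL attack rule).
#' @return logical, one per input female.
#' @export
attack_decision <- function(spov, mated, satiated, config) {
  par <- resolve_engine_params(config)
  n <- length(spov)
  stopifnot(length(mated) == n, length(satiated) == n)
  out <- logical(n)
  for (i in seq_len(n)) {
    pa <- .attack_prob_scalar(spov[i], mated[i], satiated[i], par)
    out[i] <- runif(1) < pa
  }
  out
}

#' Probability that a male escapes a female attack
#'
#' `exp(-CW * coeff)`: larger females are harder to escape from. Equal
#' to 1 at CW = 0 and strictly decreasing in CW.
#'
#' @param cw female carapace width (mm, vector ok).
#' @param coeff escape coefficient (default 0.1 per mm).
#' @return probability in (0, 1].
#' @examples
#' escape_probability(6.408) # ~0.527
#' @export
escape_probability <- function(cw, coeff = 0.1) {
  stopifnot(all(cw >= 0))
  exp(-cw * coeff)
}

#' Resolve an attack on a male
#'
#' With probability [escape_probability()] the male flees unharmed and
#' his encounter (or cohabitation) ends; otherwise he is cannibalized:
#' the female's kill count increments and, unless she is already
#' satiated, her condition rises by `male_meal_gain` (2.39 mm), capped
#' at her satiation threshold. One uniform deviate is consumed.
#'
#' @param female one-row list/data frame with `cw`, `cond`, `maxcond`,
#'   `satiated`, `kills`.
#' @param config a `spovsim_config`.
#' @return list with `male_escaped`, `male_eaten`, and the updated
#'   `female`.
#' @export
resolve_attack <- function(female, config) {
  pe <- escape_probability(female$cw, config$escape_coeff)
  if (runif(1) < pe) {
    return(list(male_escaped = TRUE, male_eaten = FALSE, female = female))
  }
  female$kills <- female$kills + 1L
  if (!female$satiated) {
    female$cond <- min(female$cond + config$male_meal_gain, female$maxcond)
    if (female$cond >= female$maxcond) female$satiated <- TRUE
  }
  list(male_escaped = FALSE, male_eaten = TRUE, female = female)
}

#' Daily condition increment from foraging
#'
#' Each mature, alive, unsatiated female gains
#' `U(0,1) * intake_scale * intake_multiplier` mm of abdomen width per
#' day; spillover females forage at 1.5 times the MFCL rate, and poor
#' environments halve the scale (0.0741 vs 0.1482 mm/day).
#'
#' @param n number of draws.
#' @param strategy a strategy name or `spovsim_strategy`.
#' @param environment a `spovsim_environment` or richness label.
#' @return condition increments (mm).
#' @export
daily_intake <- function(n, strategy, environment) {
  if (is.character(strategy)) strategy <- default_strategy(strategy)
  if (is.character(environment)) environment <- default_environment(environment)
  runif(n) * environment$intake_scale * strategy$intake_multiplier
}

.event_levels <- c("female_death", "male_death", "encounter", "attack",
                   "escape", "cannibalism", "residency", "mating")

# Plain-R reference season engine. `par` is a resolve_engine_params()
# list; `pop` a population list. Returns the end state, tallies and
# (optionally) the full event log.
run_season_r <- function(pop, par, log_events = FALSE) {
  f <- pop$females
  m <- pop$males
  nf <- nrow(f)
  nm <- nrow(m)
  female_bg <- 0L; male_bg <- 0L; cann <- 0L
  mat_count <- c(0L, 0L) # matings by phenotype index (MFCL, spillover)
  ev_day <- integer(0); ev_code <- integer(0)
  ev_male <- integer(0); ev_female <- integer(0)
  push <- function(day, code, male, female) {
    if (!log_events) return(invisible())
    ev_day[[length(ev_day) + 1L]] <<- day
    ev_code[[length(ev_code) + 1L]] <<- code
    ev_male[[length(ev_male) + 1L]] <<- male
    ev_female[[length(ev_female) + 1L]] <<- female
    invisible()
  }

  for (t in seq_len(par$slen)) {
    ## 2. background mortality: females first, then males
    idx <- which(f$alive & f$mat <= t)
    if (length(idx)) {
      u <- runif(length(idx))
      rate <- par$mort_f[ifelse(f$spov[idx], 2L, 1L)]
      for (k in which(u < rate)) {
        i <- idx[k]
        f$alive[i] <- FALSE
        female_bg <- female_bg + 1L
        r <- f$resident[i]
        if (!is.na(r)) {
          m$cohab[r] <- NA_integer_
          f$resident[i] <- NA_integer_
        }
        push(t, 1L, NA_integer_, i)
      }
    }
    jdx <- which(m$alive & m$mat <= t)
    if (length(jdx)) {
      u <- runif(length(jdx))
      for (k in which(u < par$mort_m)) {
        j <- jdx[k]
        m$alive[j] <- FALSE
        male_bg <- male_bg + 1L
        cf <- m$cohab[j]
        if (!is.na(cf)) {
          f$resident[cf] <- NA_integer_
          m$cohab[j] <- NA_integer_
        }
        push(t, 2L, j, NA_integer_)
      }
    }

    ## 3. feeding
    fidx <- which(f$alive & f$mat <= t & !f$satiated)
    if (length(fidx)) {
      u <- runif(length(fidx))
      mult <- par$intake_mult[ifelse(f$spov[fidx], 2L, 1L)]
      newc <- pmin(f$cond[fidx] + u * par$intake_scale * mult, f$maxcond[fidx])
      f$cond[fidx] <- newc
      f$satiated[fidx] <- newc >= f$maxcond[fidx]
    }

    ## 4. male search: a male visits female burrows; a not-yet-mature
    ## female is simply absent, and that visit is wasted
    cand <- which(f$alive)
    ncand <- length(cand)
    for (j in seq_len(nm)) {
      if (!m$alive[j] || m$mat[j] > t || !is.na(m$cohab[j])) next
      if (ncand == 0L) next
      k <- if (par$poisson_enc == 1L) {
        min(rpois(1L, par$maxenc), ncand)
      } else {
        min(par$maxenc, ncand)
      }
      if (k <= 0L) next
      local <- cand
      for (e in seq_len(k)) {
        remaining <- ncand - e + 1L
        r <- floor(runif(1) * remaining)
        if (r >= remaining) r <- remaining - 1L
        pos <- e + r
        tmp <- local[e]; local[e] <- local[pos]; local[pos] <- tmp
        i <- local[e]
        push(t, 3L, j, i)
        if (f$mat[i] > t) next # nobody home yet
        if (!is.na(f$resident[i])) next # prior residency excludes rivals
        pa <- .attack_prob_scalar(f$spov[i], f$mated[i], f$satiated[i], par)
        if (runif(1) < pa) {
          push(t, 4L, j, i)
          if (runif(1) < exp(-f$cw[i] * par$esc)) {
            push(t, 5L, j, i)
            break # male flees; done searching today
          }
          m$alive[j] <- FALSE
          cann <- cann + 1L
          f$kills[i] <- f$kills[i] + 1L
          if (!f$satiated[i]) {
            f$cond[i] <- min(f$cond[i] + par$meal, f$maxcond[i])
            if (f$cond[i] >= f$maxcond[i]) f$satiated[i] <- TRUE
          }
          push(t, 6L, j, i)
          break
        } else if (!f$mated[i]) {
          f$resident[i] <- j
          m$cohab[j] <- i
          push(t, 7L, j, i)
          break
        }
        # mated female, no attack: male moves on to his next encounter
      }
    }

    ## 5. cohabitation
    for (i in seq_len(nf)) {
      if (!f$alive[i] || is.na(f$resident[i])) next
      j <- f$resident[i]
      pa <- .attack_prob_scalar(f$spov[i], f$mated[i], f$satiated[i], par)
      if (runif(1) < pa) {
        push(t, 4L, j, i)
        if (runif(1) < exp(-f$cw[i] * par$esc)) {
          f$resident[i] <- NA_integer_
          m$cohab[j] <- NA_integer_
          push(t, 5L, j, i)
        } else {
          m$alive[j] <- FALSE
          m$cohab[j] <- NA_integer_
          f$resident[i] <- NA_integer_
          cann <- cann + 1L
          f$kills[i] <- f$kills[i] + 1L
          if (!f$satiated[i]) {
            f$cond[i] <- min(f$cond[i] + par$meal, f$maxcond[i])
            if (f$cond[i] >= f$maxcond[i]) f$satiated[i] <- TRUE
          }
          push(t, 6L, j, i)
        }
      } else if (runif(1) < par$pmate) {
        f$mated[i] <- TRUE
        f$father[i] <- m$a[j]
        m$matings[j] <- m$matings[j] + 1L
        ph <- if (f$spov[i]) 2L else 1L
        mat_count[ph] <- mat_count[ph] + 1L
        f$resident[i] <- NA_integer_
        m$cohab[j] <- NA_integer_
        push(t, 8L, j, i)
      }
    }
  }

  events <- if (log_events) {
    data.frame(
      day = as.integer(ev_day),
      event = .event_levels[as.integer(ev_code)],
      male_id = as.integer(ev_male),
      female_id = as.integer(ev_female)
    )
  } else NULL

  list(
    females = f,
    males = m,
    tallies = list(
      female_bg_deaths = female_bg,
      male_bg_deaths = male_bg,
      males_cannibalized = cann,
      matings = c(mfcl = mat_count[1], spov = mat_count[2])
    ),
    events = events
  )
}

#' Run one mating season
#'
#' Executes the daily within-season loop (see the rules in
#' `attack_decision`, `resolve_attack` and `daily_intake`) on an
#' initialized generation and returns the end-of-season state together
#' with event tallies.
#'
#' @param population a `spovsim_population` from [initialize_generation()].
#' @param config a `spovsim_config`.
#' @param log_events record every encounter, attack, escape,
#'   cannibalism, residency, mating and death as a flat table.
#' @param engine `"cpp"` (compiled, default) or `"r"` (plain-R reference
#'   implementation). Both consume random numbers identically, so the
#'   same seed yields the same season.
#' @return list of class `spovsim_season` with elements `females`,
#'   `males` (end-of-season state), `tallies` (background deaths by sex,
#'   males cannibalized, matings by phenotype) and `events` (data frame
#'   or `NULL`).
#' @export
run_season <- function(population, config, log_events = FALSE,
                       engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  par <- resolve_engine_params(config)
  out <- if (engine == "cpp") {
    run_season_cpp_wrap(population, par, log_events)
  } else {
    run_season_r(population, par, log_events)
  }
  class(out) <- "spovsim_season"
  out
}

# Adapter between the R population representation and the compiled season.
run_season_cpp_wrap <- function(pop, par, log_events) {
  f <- pop$females
  m <- pop$males
  res <- cpp_season(
    f$a1, f$a2, as.integer(f$spov), f$mat, f$cw, f$cond, f$maxcond,
    as.integer(f$satiated), as.integer(f$mated),
    ifelse(is.na(f$father), -1L, f$father),
    ifelse(is.na(f$resident), -1L, f$resident - 1L),
    as.integer(f$alive), f$kills,
    m$a, m$mat, as.integer(m$alive),
    ifelse(is.na(m$cohab), -1L, m$cohab - 1L), m$matings,
    par, as.integer(log_events)
  )
  f$cond <- res$f_cond
  f$satiated <- res$f_satiated == 1L
  f$mated <- res$f_mated == 1L
  f$father <- ifelse(res$f_father < 0L, NA_integer_, res$f_father)
  f$resident <- ifelse(res$f_resident < 0L, NA_integer_, res$f_resident + 1L)
  f$alive <- res$f_alive == 1L
  f$kills <- res$f_kills
  m$alive <- res$m_alive == 1L
  m$cohab <- ifelse(res$m_cohab < 0L, NA_integer_, res$m_cohab + 1L)
  m$matings <- res$m_matings
  events <- if (log_events) {
    data.frame(
      day = res$ev_day,
      event = .event_levels[res$ev_code],
      male_id = ifelse(res$ev_male < 0L, NA_integer_, res$ev_male + 1L),
      female_id = ifelse(res$ev_female < 0L, NA_integer_, res$ev_female + 1L)
    )
  } else NULL
  list(
    females = f,
    males = m,
    tallies = list(
      female_bg_deaths = res$female_bg_deaths,
      male_bg_deaths = res$male_bg_deaths,
      males_cannibalized = res$males_cannibalized,
      matings = c(mfcl = res$matings_mfcl, spov = res$matings_spov)
    ),
    events = events
  )
}
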
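# Within-season rules, micro-oracle trace equality between the compiled
# and reference engines, and season-level bookkeeping invariants.

run_both_engines <- function(cfg, seed, log_events = TRUE) {
  set.seed(seed)
  pop <- initialize_generation(cfg)
  set.seed(seed)
  pop2 <- initialize_generation(cfg)
  stopifnot(identical(pop, pop2))
  set.seed(seed + 1)
  r <- run_season(pop, cfg, log_events = log_events, engine = "r")
  set.seed(seed + 1)
  cpp <- run_season(pop, cfg, log_events = log_events, engine = "cpp")
  list(r = r, cpp = cpp)
}

test_that("attack rule: spillover attacks by pspov regardless of state", {
  cfg <- simulation_config("EARLY-SPOV", environment = "poor") # pspov 0.9
  set.seed(1)
  # mated AND satiated spillover female still attacks ~90% of the time
  hits <- attack_decision(rep(TRUE, 2000), rep(TRUE, 2000), rep(TRUE, 2000), cfg)
  expect_lt(abs(mean(hits) - 0.9), 3 * sqrt(0.9 * 0.1 / 2000))
})

test_that("attack rule: MFCL attacks iff mated or hungry", {
  cfg <- simulation_config("EARLY-SPOV")
  set.seed(2)
  # satiated virgin never attacks: the window in which mating can happen
  expect_false(any(attack_decision(rep(FALSE, 200), rep(FALSE, 200),
                                   rep(TRUE, 200), cfg)))
  # mated (cannibalize later) and hungry virgins always attack
  expect_true(all(attack_decision(rep(FALSE, 200), rep(TRUE, 200),
                                  rep(TRUE, 200), cfg)))
  expect_true(all(attack_decision(rep(FALSE, 200), rep(FALSE, 200),
                                  rep(FALSE, 200), cfg)))
  # the alternative mated-only reading drops the hungry-virgin clause
  cfg2 <- simulation_config("EARLY-SPOV", mfcl_attack_rule = "mated_only")
  expect_false(any(attack_decision(rep(FALSE, 200), rep(FALSE, 200),
                                   rep(FALSE, 200), cfg2)))
})

test_that("escape probability is exp(-CW/10)", {
  expect_equal(escape_probability(0), 1)
  expect_equal(escape_probability(6.408), exp(-0.6408))
  expect_equal(escape_probability(6.408), 0.527, tolerance = 1e-3)
  expect_true(all(diff(escape_probability(seq(0, 12, 0.5))) < 0))
})

test_that("a cannibalized male adds 2.39 mm condition, capped at satiation", {
  cfg <- simulation_config("EARLY-SPOV")
  fem <- list(cw = 6, cond = 5, maxcond = 9, satiated = FALSE, kills = 0L)
  set.seed(1)
  out <- NULL
  repeat { # draw until the male fails to escape
    out <- resolve_attack(fem, cfg)
    if (out$male_eaten) break
  }
  expect_equal(out$female$cond, 5 + 2.39)
  expect_equal(out$female$kills, 1L)
  # gain is capped and satiation absorbs
  fem2 <- list(cw = 6, cond = 8.5, maxcond = 9, satiated = FALSE, kills = 0L)
  repeat {
    out <- resolve_attack(fem2, cfg)
    if (out$male_eaten) break
  }
  expect_equal(out$female$cond, 9)
  expect_true(out$female$satiated)
  # satiated female gains nothing from a kill
  fem3 <- list(cw = 6, cond = 9, maxcond = 9, satiated = TRUE, kills = 0L)
  repeat {
    out <- resolve_attack(fem3, cfg)
    if (out$male_eaten) break
  }
  expect_equal(out$female$cond, 9)
  expect_equal(out$female$kills, 1L)
})

test_that("daily intake scales with strategy and environment", {
  set.seed(3)
  # rich MFCL mean 0.1482/2; poor spillover mean 1.5 * 0.0741/2
  x <- daily_intake(2e4, "MFCL", "rich")
  expect_lt(abs(mean(x) - 0.0741), 4 * 0.1482 / sqrt(12 * 2e4))
  y <- daily_intake(2e4, "EARLY-SPOV", "poor")
  expect_lt(abs(mean(y) - 1.5 * 0.03705), 4 * 0.1482 / sqrt(12 * 2e4))
})

test_that("compiled and reference engines emit identical event traces", {
  # micro scenarios, exhaustively comparable
  for (seed in c(7L, 8L, 9L)) {
    fix <- make_micro_fixture(2L, 2L, 3L, seed = seed)
    set.seed(seed)
    geno <- spovsim:::.initial_genotypes(fix$par)
    pop <- spovsim:::.init_life_history(geno, fix$par)
    pop$males$mat <- pmin(pop$males$mat, 1L)
    res <- spovsim:::run_season_cpp_wrap(pop, fix$par, TRUE)
    expect_identical(res$events, fix$trace)
    expect_identical(res$females, fix$season$females)
    expect_identical(res$males, fix$season$males)
  }
})

test_that("engines agree at full population scale over one season", {
  for (env in c("poor", "rich")) {
    cfg <- simulation_config("EARLY-SPOV", environment = env,
                             dominance = "spillover", n_females = 120L,
                             n_males = 120L, initial = "thirds")
    both <- run_both_engines(cfg, seed = 31L)
    expect_identical(both$r$events, both$cpp$events)
    expect_identical(both$r$females, both$cpp$females)
    expect_identical(both$r$males, both$cpp$males)
    expect_identical(both$r$tallies, both$cpp$tallies)
  }
})

test_that("male bookkeeping conserves and mated females record a father", {
  cfg <- simulation_config("EARLY-SPOV", environment = "rich",
                           n_females = 200L, n_males = 200L)
  set.seed(12)
  pop <- initialize_generation(cfg)
  out <- run_season(pop, cfg)
  tal <- out$tallies
  expect_equal(sum(out$males$alive) + tal$male_bg_deaths +
                 tal$males_cannibalized, 200L)
  expect_equal(tal$males_cannibalized, sum(out$females$kills))
  mated <- out$females$mated
  expect_true(all(!is.na(out$females$father[mated])))
  expect_true(all(is.na(out$females$father[!mated])))
  expect_equal(sum(out$males$matings),
               tal$matings[["mfcl"]] + tal$matings[["spov"]])
  # feeding and meals never push condition past the threshold; only
  # degenerate females (born past it) can sit above, unchanged
  started_below <- pop$females$cond < pop$females$maxcond
  expect_true(all(out$females$cond[started_below] <=
                    out$females$maxcond[started_below] + 1e-12))
  expect_equal(out$females$cond[!started_below],
               pop$females$cond[!started_below])
})

test_that("with pspov = 0 and the mated-only MFCL rule, no cannibalism occurs", {
  cfg <- simulation_config(
    "EARLY-SPOV",
    environment = default_environment("rich", pspov = 0),
    mfcl_attack_rule = "mated_only", mfcl_attack = 0,
    n_females = 150L, n_males = 150L
  )
  set.seed(13)
  pop <- initialize_generation(cfg)
  out <- run_season(pop, cfg)
  expect_equal(out$tallies$males_cannibalized, 0L)
  expect_gt(out$tallies$matings[["mfcl"]] + out$tallies$matings[["spov"]], 0L)
})

test_that("male background mortality matches the closed-form survival curve", {
  # males only: maturation day ~1, 79 days at 0.0045/day
  cfg <- simulation_config("EARLY-SPOV", n_females = 1L, n_males = 250L)
  set.seed(14)
  dead <- replicate(20, {
    pop <- initialize_generation(cfg)
    pop$males$mat <- 1L
    pop$females$alive <- FALSE # nobody to meet: death is background only
    out <- run_season(pop, cfg)
    out$tallies$male_bg_deaths
  })
  expected <- 1 - (1 - 0.0045)^79
  n <- 20 * 250
  expect_lt(abs(sum(dead) / n - expected), 4 * sqrt(expected * (1 - expected) / n))
})

test_that("unsatiated virgin MFCL females block mating until satiation", {
  # all-MFCL population in a poor environment: every approach before
  # satiation is an attack, so no female mates while hungry
  cfg <- simulation_config("MFCL", environment = "poor", different = 1,
                           n_females = 80L, n_males = 80L, initial = "thirds")
  set.seed(15)
  pop <- initialize_generation(cfg)
  out <- run_season(pop, cfg, log_events = TRUE)
  # a hungry virgin always attacks, so she can only ever mate after
  # satiation (by prey or by eating a suitor); satiation is absorbing,
  # hence every mated female must end the season satiated
  expect_true(all(out$females$satiated[out$females$mated]))
  expect_gt(nrow(out$events), 0)
})
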
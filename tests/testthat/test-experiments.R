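test_that("degenerate initial frequencies classify immediately", {
  cfg <- simulation_config("EARLY-SPOV", n_females = 30L, n_males = 30L)
  tr0 <- run_invasion(cfg, p0 = 0, seed = 1)
  expect_equal(tr0$outcome, "mfcl_fixed")
  expect_equal(tr0$terminal_generation, 0L)
  expect_equal(nrow(tr0$records), 1L)
  tr1 <- run_invasion(cfg, p0 = 1, seed = 1)
  expect_equal(tr1$outcome, "spillover_fixed")
  expect_equal(tr1$terminal_generation, 0L)
})

test_that("a seed fully determines a trajectory", {
  cfg <- simulation_config("EARLY-SPOV", environment = "rich",
                           n_females = 80L, n_males = 80L,
                           max_generations = 15L)
  a <- run_maintenance(cfg, seed = 33)
  b <- run_maintenance(cfg, seed = 33)
  expect_identical(a$records, b$records)
  expect_identical(a$outcome, b$outcome)
})

test_that("compiled and reference engines produce identical trajectories", {
  # full cycle: initialization, season, reproduction, resampling
  for (dom in c("spillover", "mfcl")) {
    cfg <- simulation_config("EARLY-SPOV", environment = "rich",
                             dominance = dom, different = 0.7,
                             n_females = 60L, n_males = 60L,
                             max_generations = 4L)
    a <- run_generations(cfg, seed = 44, engine = "cpp")
    b <- run_generations(cfg, seed = 44, engine = "r")
    expect_equal(a$records, b$records, tolerance = 1e-12)
    expect_identical(a$outcome, b$outcome)
    expect_identical(a$terminal_generation, b$terminal_generation)
  }
})

test_that("trajectory p-series stays in [0,1] and ends at the cap or fixation", {
  cfg <- simulation_config("EARLY-SPOV", environment = "poor",
                           n_females = 60L, n_males = 60L)
  tr <- run_maintenance(cfg, seed = 2, max_generations = 50)
  expect_true(all(tr$records$p >= 0 & tr$records$p <= 1))
  expect_lte(tr$terminal_generation, 50L)
  if (tr$outcome == "coexistence_at_max_gen") {
    expect_true(tr$terminal_p > 0 && tr$terminal_p < 1)
  } else {
    expect_true(tr$terminal_p %in% c(0, 1))
  }
  cls <- classify_outcome(tr)
  expect_equal(cls$outcome, tr$outcome)
})

test_that("neutral allele drifts without bias", {
  # both phenotypes parameterized as MFCL, different = 1: pure drift;
  # mean terminal p over replicates stays at p0
  cfg <- neutral_config(nf = 50L, nm = 50L, p0 = 0.5)
  set.seed(55)
  seeds <- sample.int(1e6, 200)
  term <- vapply(seeds, function(s) {
    tr <- run_generations(cfg, seed = s, max_generations = 15)
    tr$terminal_p
  }, 0)
  se <- sd(term) / sqrt(length(term))
  expect_lt(abs(mean(term) - 0.5), 3 * se)
})

test_that("neutral absorption time scales with population size as drift predicts", {
  # classic diffusion result: time to fixation/loss is proportional to
  # population size; doubling N should roughly double the absorption time
  run_absorption <- function(nf, seeds) {
    vapply(seeds, function(s) {
      cfg <- neutral_config(nf = nf, nm = nf, p0 = 0.5)
      tr <- run_generations(cfg, seed = s, max_generations = 3000)
      as.numeric(tr$terminal_generation)
    }, 0)
  }
  set.seed(66)
  seeds <- sample.int(1e6, 25)
  t_small <- run_absorption(16L, seeds)
  t_big <- run_absorption(48L, seeds + 1)
  ratio <- mean(t_big) / mean(t_small)
  expect_gt(ratio, 1.3)
  expect_lt(ratio, 8)
})

test_that("classic spillover never persists against MFCL (spot check)", {
  # the qualitative headline: SPOV without early maturation loses
  for (env in c("poor", "rich")) {
    cfg <- simulation_config("SPOV", environment = env, different = 0.5,
                             dominance = "spillover")
    tr <- run_maintenance(cfg, seed = 3, max_generations = 400)
    expect_equal(tr$outcome, "mfcl_fixed")
    expect_lt(tr$terminal_generation, 100)
  }
})

test_that("sweeps cover the grid and are reproducible", {
  cfg <- simulation_config("EARLY-SPOV", n_females = 40L, n_males = 40L)
  sw <- sweep_experiments(cfg, environments = c("poor", "rich"),
                          differents = c(0.3, 0.9),
                          dominances = "spillover",
                          replicates = 2, seed = 9, max_generations = 10)
  expect_equal(nrow(sw$runs), 8L)
  expect_equal(nrow(sw$summary), 4L)
  expect_equal(sum(sw$summary$n), 8L)
  sw2 <- sweep_experiments(cfg, environments = c("poor", "rich"),
                           differents = c(0.3, 0.9),
                           dominances = "spillover",
                           replicates = 2, seed = 9, max_generations = 10)
  expect_identical(sw$runs, sw2$runs)
  expect_error(sweep_experiments(cfg, environments = character(0)),
               "empty sweep grid")
})

test_that("quasi-equilibrium flag marks late fixations", {
  cfg <- simulation_config("EARLY-SPOV", max_generations = 100L)
  fake <- list(
    records = data.frame(generation = 0:60, p = c(seq(0.5, 1, length.out = 61))),
    outcome = "spillover_fixed", terminal_generation = 60L, terminal_p = 1,
    config = cfg
  )
  class(fake) <- "spovsim_trajectory"
  cls <- classify_outcome(fake)
  expect_true(cls$quasi_equilibrium) # 60 >= 0.5 * 100
  cls2 <- classify_outcome(fake, quasi_fraction = 0.9)
  expect_false(cls2$quasi_equilibrium)
})
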
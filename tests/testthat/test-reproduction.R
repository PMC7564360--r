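test_that("egg-sac volume regressions evaluate to the printed means", {
  expect_equal(eggsac_volume(6.408, 0, "SPOV", sd = 0), 619.93, tolerance = 1e-4)
  expect_equal(eggsac_volume(6.408, 0, "EARLY-SPOV", sd = 0), 619.93,
               tolerance = 1e-4)
  expect_equal(eggsac_volume(5.919, 8.38, "MFCL", sd = 0), 26.419,
               tolerance = 1e-3)
  # the condition-dependent spillover variant gains from adult foraging
  expect_gt(eggsac_volume(6.408, 8, "BCD-EM-SPOV", sd = 0),
            eggsac_volume(6.408, 0, "EARLY-SPOV", sd = 0))
  # negative predictions truncate to zero
  expect_equal(eggsac_volume(4, 5, "MFCL", sd = 0), 0)
})

test_that("offspring number is the rounded linear rule, floored at zero", {
  expect_equal(offspring_number(619.9), 157L)
  expect_equal(offspring_number(0), 58L)
  vols <- seq(0, 1500, by = 7)
  expect_true(all(diff(offspring_number(vols)) >= 0))
})

test_that("weighted next-generation sampling hits the closed-form share", {
  # pool of 100 spillover + 100 MFCL daughters, different = 0.5, quota
  # larger than the pool (with-replacement branch): expected spillover
  # share per draw is exactly 0.5 / (0.5 + 1) = 1/3
  set.seed(21)
  w <- rep(c(0.5, 1), each = 100)
  share <- replicate(500, {
    sel <- spovsim:::.select_weighted(200, w, 500)
    mean(sel$idx <= 100)
  })
  se <- sd(share) / sqrt(500)
  expect_lt(abs(mean(share) - 1 / 3), 3 * se)
  # without replacement, the first-draw inclusion shares still reflect
  # the weights: a small sample from a large pool stays near 1/3
  set.seed(22)
  w2 <- rep(c(0.5, 1), each = 2000)
  share1 <- replicate(300, {
    sel <- spovsim:::.select_weighted(4000, w2, 40)
    mean(sel$idx <= 2000)
  })
  expect_lt(abs(mean(share1) - 1 / 3), 4 * sd(share1) / sqrt(300))
  # neutral weights reduce to uniform sampling
  set.seed(23)
  share0 <- replicate(500, {
    sel <- spovsim:::.select_weighted(200, rep(1, 200), 60)
    mean(sel$idx <= 100)
  })
  expect_lt(abs(mean(share0) - 0.5), 3 * sd(share0) / sqrt(500))
})

test_that("undersized pools are resampled with replacement and flagged", {
  set.seed(23)
  sel <- spovsim:::.select_weighted(10, rep(1, 10), 50)
  expect_true(sel$resampled)
  expect_length(sel$idx, 50)
  expect_true(all(sel$idx %in% 1:10))
})

test_that("a monomorphic parental generation fixes the next one", {
  cfg <- simulation_config("EARLY-SPOV", n_females = 30L, n_males = 30L,
                           initial = 0)
  set.seed(24)
  pop <- initialize_generation(cfg)
  season <- run_season(pop, cfg)
  if (any(season$females$alive & season$females$mated)) {
    nxt <- build_next_generation(season, cfg)
    expect_false(nxt$extinct)
    expect_equal(allele_frequency(nxt$population$females,
                                  nxt$population$males), 0)
    expect_equal(nrow(nxt$population$females), 30L)
    expect_equal(nrow(nxt$population$males), 30L)
  }
})

test_that("reproduction without any surviving mated mother is an extinction", {
  cfg <- simulation_config("EARLY-SPOV", n_females = 5L, n_males = 5L)
  set.seed(25)
  pop <- initialize_generation(cfg)
  season <- list(females = pop$females) # nobody mated
  out <- build_next_generation(season, cfg)
  expect_true(out$extinct)
  expect_null(out$population)
})

test_that("offspring allele frequency is unbiased under neutrality", {
  # symmetric strategies (MFCL vs MFCL), different = 1: the offspring
  # generation's allele frequency estimates the parental gamete frequency
  cfg <- neutral_config(nf = 60L, nm = 60L, p0 = 0.5)
  set.seed(26)
  devs <- replicate(120, {
    pop <- initialize_generation(cfg)
    season <- run_season(pop, cfg)
    f <- season$females
    mothers <- f$alive & f$mated
    if (!any(mothers)) return(NA_real_)
    gamete_p <- (sum(f$a1[mothers]) + sum(f$a2[mothers]) +
                   sum(f$father[mothers])) / (3 * sum(mothers))
    nxt <- suppressWarnings(build_next_generation(season, cfg))
    if (nxt$extinct) return(NA_real_)
    allele_frequency(nxt$population$females, nxt$population$males) - gamete_p
  })
  devs <- devs[!is.na(devs)]
  expect_gt(length(devs), 60)
  expect_lt(abs(mean(devs)), 3 * sd(devs) / sqrt(length(devs)))
})
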
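test_that("position labels split at the threshold with strict TOP", {
  expect_equal(as.character(label_positions(c(0.80, 0.85, 0.90))),
               c("BOTTOM", "BOTTOM", "TOP"))
  expect_true(all(label_positions(rep(0.9, 10)) == "TOP"))
  expect_equal(levels(label_positions(0.5)), c("BOTTOM", "TOP"))
})

test_that("relative fitness and mating percentage follow their definitions", {
  expect_equal(relative_fitness_spillover(450, 50), 1.8)
  expect_equal(relative_fitness_spillover(500, 0), 2)
  expect_equal(relative_fitness_spillover(250, 250), 1)
  expect_true(is.na(relative_fitness_spillover(0, 0)))
  expect_equal(mfcl_mating_percentage(5, 50), 10)
  expect_equal(mfcl_mating_percentage(0, 50), 0)
  expect_true(is.na(mfcl_mating_percentage(0, 0)))
})

# synthetic trajectory records with known structure
make_synth_records <- function(n = 400, top_effect = 0, seed = 1,
                               base_rate = 0.3) {
  set.seed(seed)
  p <- pmin(pmax(0.85 + cumsum(rnorm(n, 0, 0.03)), 0.5), 1)
  n_mfcl <- pmax(round(500 * (1 - p)^2), 5)
  top <- as.integer(p > 0.85)
  rate <- plogis(qlogis(base_rate) + top_effect * top)
  mated <- rbinom(n, n_mfcl, rate)
  data.frame(
    generation = seq_len(n) - 1L, p = p,
    n_spov_females = 500 - n_mfcl, n_mfcl_females = n_mfcl,
    matings_spov = 0L, matings_mfcl = mated,
    males_cannibalized = 0L, male_bg_deaths = 0L
  )
}

test_that("compare_positions recovers a known position effect", {
  rec <- make_synth_records(n = 600, top_effect = 0.5, seed = 2)
  out <- compare_positions(rec, "mfcl_mating")
  expect_false(out$degenerate)
  eff <- coef(out$fit)[["positionTOP"]]
  se <- sqrt(vcov(out$fit)["positionTOP", "positionTOP"])
  expect_lt(abs(eff - 0.5), 3 * se)
  expect_lt(out$p_value, 0.01)
  top <- out$adjusted$mean[out$adjusted$position == "TOP"]
  bot <- out$adjusted$mean[out$adjusted$position == "BOTTOM"]
  expect_gt(top, bot)
})

test_that("compare_positions keeps its nominal type-I error on null data", {
  pvals <- vapply(1:300, function(i) {
    rec <- make_synth_records(n = 250, top_effect = 0, seed = 100 + i)
    # gaussian identity model on the fitness ratio metric
    rec$n_spov_females <- round(250 + rnorm(250, 0, 20))
    rec$n_mfcl_females <- 500 - rec$n_spov_females
    out <- compare_positions(rec, "rel_fitness")
    if (out$degenerate) NA_real_ else out$p_value
  }, 0)
  pvals <- pvals[!is.na(pvals)]
  expect_gt(length(pvals), 200)
  rate <- mean(pvals < 0.05)
  se <- sqrt(0.05 * 0.95 / length(pvals))
  expect_lt(abs(rate - 0.05), 4 * se)
})

test_that("adjusted means equal raw group means when covariates carry no effect", {
  # generation is identical across groups, p varies within each group,
  # and the metric is an exact function of position alone; the fitted
  # covariate slopes are then exactly zero and the covariate-adjusted
  # means must reproduce the raw group means
  rec <- data.frame(
    generation = c(1:100, 1:100),
    p = c(rep(c(0.80, 0.84), 50), rep(c(0.86, 0.90), 50)),
    n_spov_females = c(rep(400L, 100), rep(460L, 100)),
    n_mfcl_females = c(rep(100L, 100), rep(40L, 100)),
    matings_spov = 0L, matings_mfcl = 0L,
    males_cannibalized = 0L, male_bg_deaths = 0L
  )
  out <- compare_positions(rec, "rel_fitness")
  raw <- tapply(relative_fitness_spillover(rec$n_spov_females,
                                           rec$n_mfcl_females),
                label_positions(rec$p), mean)
  expect_equal(sort(out$adjusted$mean), sort(as.numeric(raw)),
               tolerance = 1e-6)
})

test_that("degenerate single-position designs are reported, not dropped", {
  rec <- make_synth_records(n = 100, seed = 5)
  rec$p <- rep(0.95, 100) # all TOP
  out <- compare_positions(rec, "mfcl_mating")
  expect_true(out$degenerate)
  expect_true(is.na(out$lr_statistic))
  expect_match(out$message, "one position")
})
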
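# End-of-season reproduction: fecundity allometries, Mendelian offspring,
# differential juvenile survival ("different") and constant-size
# next-generation sampling.
#
# RNG protocol (matched by the compiled engine):
#   1. one egg-sac-volume normal draw per surviving mated mother
#      (ascending female index);
#   2. one uniform sex draw per offspring, brood-major order;
#   3. one uniform maternal-copy draw per offspring, brood-major order;
#   4. daughter selection: in "cull" mode one uniform survival draw per
#      daughter first; then, if the (surviving) pool has at least
#      n_females members, one exponential key per pooled daughter
#      (divided by her sampling weight; weighted reservoir selection of
#      the n_females smallest keys), otherwise n_females uniform draws
#      for weighted sampling with replacement;
#   5. son selection: same scheme with unit weights (or `different`
#      weights for spillover-allele carriers when `different_males`).

#' Draw an egg-sac volume
#'
#' Normal draw from the strategy's fecundity regression. Plain SPOV and
#' EARLY-SPOV use size only (`-1156.43 + 277.21 CW`); the
#' body-condition-dependent variants add `123.44 * condition`; MFCL uses
#' `-2297.64 + 217.88 CW + 123.44 * condition`. The condition covariate
#' is the female's realized end-of-season condition (at most her
#' satiation threshold), so adult foraging feeds into fecundity for the
#' condition-dependent strategies. Negative draws truncate to 0.
#'
#' @param cw carapace width (mm).
#' @param cond realized condition (mm); ignored by strategies whose
#'   condition slope is 0.
#' @param strategy strategy name or `spovsim_strategy`.
#' @param sd residual sd override.
#' @return egg-sac volume (mm^3), non-negative.
#' @examples
#' eggsac_volume(6.408, 8, "SPOV", sd = 0)        # ~619.9
#' eggsac_volume(5.919, 8.38, "MFCL", sd = 0)     # ~26.4
#' @export
eggsac_volume <- function(cw, cond, strategy, sd = NULL) {
  if (is.character(strategy)) strategy <- default_strategy(strategy)
  vc <- strategy$vol_coeffs
  mu <- vc[["intercept"]] + vc[["cw"]] * cw + vc[["cond"]] * cond
  s <- if (is.null(sd)) vc[["sd"]] else sd
  pmax(rnorm(length(mu), mu, s), 0)
}

#' Offspring number from egg-sac volume
#'
#' `N = 57.54 + 0.16 * vol`, rounded to the nearest integer (half up)
#' and floored at zero.
#'
#' @param vol egg-sac volume (mm^3), non-negative.
#' @return integer offspring counts.
#' @examples
#' offspring_number(619.9) # 157
#' offspring_number(0)     # 58
#' @export
offspring_number <- function(vol) {
  stopifnot(all(vol >= 0))
  as.integer(pmax(round_half_up(.offspring_coeffs[["intercept"]] +
                                  .offspring_coeffs[["vol"]] * vol), 0))
}

# Weighted selection of `n` from a pool. Without replacement via
# exponential keys (smallest n keys win; equivalent to successive
# weighted draws); with replacement via inverse-CDF on the cumulative
# weights when the pool is too small.
.select_weighted <- function(n_pool, w, n) {
  if (n_pool >= n) {
    keys <- rexp(n_pool) / w
    list(idx = order(keys)[seq_len(n)], resampled = FALSE)
  } else {
    cw <- cumsum(w)
    u <- runif(n) * cw[n_pool]
    list(idx = findInterval(u, cw) + 1L, resampled = TRUE)
  }
}

#' Build the next generation from the season's survivors
#'
#' Every female alive and mated at season end produces a brood: an
#' egg-sac volume from her strategy's regression, an offspring count,
#' and Mendelian offspring (each a daughter or son with probability one
#' half, carrying one uniformly chosen maternal X copy, daughters also
#' the recorded paternal allele). Daughters whose phenotype under the
#' configured dominance is spillover-family carry relative juvenile
#' survival `different`; exactly `n_females` daughters and `n_males`
#' sons are then sampled without replacement from the weighted pool
#' (with replacement, and a warning, iff a pool is smaller than the
#' target). Sons are unweighted by default: males are phenotypically
#' identical carriers.
#'
#' @param season a `spovsim_season` (or any list with an end-of-season
#'   `females` data frame).
#' @param config a `spovsim_config`.
#' @return list with `population` (a fresh `spovsim_population`, or
#'   `NULL` on extinction), `extinct`, `resampled` (logical per sex),
#'   and `parental_p` (gamete-pool allele frequency of the mothers and
#'   recorded fathers, for classifying extinctions).
#' @export
build_next_generation <- function(season, config) {
  par <- resolve_engine_params(config)
  f <- season$females
  mothers <- which(f$alive & f$mated)
  if (length(mothers) == 0L) {
    return(list(population = NULL, extinct = TRUE,
                resampled = c(f = FALSE, m = FALSE), parental_p = NA_real_))
  }
  parental_p <- (sum(f$a1[mothers]) + sum(f$a2[mothers]) +
                   sum(f$father[mothers])) / (3 * length(mothers))

  ph <- ifelse(f$spov[mothers], 2L, 1L)
  mu <- par$vol_int[ph] + par$vol_cw[ph] * f$cw[mothers] +
    par$vol_cond[ph] * f$cond[mothers]
  vol <- pmax(rnorm(length(mothers), mu, par$vol_sd[ph]), 0)
  nk <- pmax(round_half_up(par$off_int + par$off_vol * vol), 0)
  total <- sum(nk)
  if (total == 0L) {
    return(list(population = NULL, extinct = TRUE,
                resampled = c(f = FALSE, m = FALSE), parental_p = parental_p))
  }

  midx <- rep.int(mothers, nk) # brood-major offspring order
  is_f <- runif(total) < 0.5
  maternal <- ifelse(runif(total) < 0.5, f$a1[midx], f$a2[midx])

  # daughters
  d_pos <- which(is_f)
  d_a1 <- maternal[d_pos]
  d_a2 <- f$father[midx[d_pos]]
  d_spov <- if (par$dom_spov == 1L) (d_a1 + d_a2) >= 1L else (d_a1 + d_a2) == 2L
  if (par$cull == 1L && length(d_pos)) {
    keep <- runif(length(d_pos)) < ifelse(d_spov, par$different, 1)
    d_a1 <- d_a1[keep]; d_a2 <- d_a2[keep]; d_spov <- d_spov[keep]
  }
  if (length(d_a1) == 0L) {
    return(list(population = NULL, extinct = TRUE,
                resampled = c(f = FALSE, m = FALSE), parental_p = parental_p))
  }
  d_w <- if (par$cull == 1L) rep(1, length(d_a1)) else
    ifelse(d_spov, par$different, 1)
  sel_f <- .select_weighted(length(d_a1), d_w, par$nf)

  # sons
  s_pos <- which(!is_f)
  s_a <- maternal[s_pos]
  if (par$cull == 1L && par$different_males == 1L && length(s_pos)) {
    keep <- runif(length(s_pos)) < ifelse(s_a == 1L, par$different, 1)
    s_a <- s_a[keep]
  }
  if (length(s_a) == 0L) {
    return(list(population = NULL, extinct = TRUE,
                resampled = c(f = FALSE, m = FALSE), parental_p = parental_p))
  }
  s_w <- if (par$cull == 0L && par$different_males == 1L) {
    ifelse(s_a == 1L, par$different, 1)
  } else {
    rep(1, length(s_a))
  }
  sel_m <- .select_weighted(length(s_a), s_w, par$nm)

  if (sel_f$resampled || sel_m$resampled) {
    warning("offspring pool smaller than the adult quota; sampled with replacement",
            call. = FALSE)
  }

  geno <- list(
    f_a1 = as.integer(d_a1[sel_f$idx]),
    f_a2 = as.integer(d_a2[sel_f$idx]),
    m_a = as.integer(s_a[sel_m$idx])
  )
  pop <- initialize_generation(config, genotypes = geno)
  list(population = pop, extinct = FALSE,
       resampled = c(f = sel_f$resampled, m = sel_m$resampled),
       parental_p = parental_p)
}
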
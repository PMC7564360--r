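# Building a generation of adults: genotype composition plus individual
# life-history attributes drawn from the calibrated distributions.
#
# A population is a list with two data frames:
#   females: a1, a2 (allele codes), spov (phenotype flag), mat (maturation
#     day, integer in 1..season_length), cw (carapace width, mm), cond
#     (current condition = abdomen width, mm), maxcond (satiation
#     threshold, mm), satiated, mated, father (allele code or NA),
#     resident (male row index or NA), alive, kills (males cannibalized)
#   males: a (allele code), mat, alive, cohab (female row index or NA),
#     matings

# Universal allometry constants (printed values; mm units).
.cond_coeffs <- c(intercept = 3.54, cw = 0.49, sd = 0.2671)
.sat_coeffs <- c(intercept = -38.98, cw = 11.73, cw2 = -0.63)
.male_mat <- c(mean = 36, sd = 0.5)
.offspring_coeffs <- c(intercept = 57.54, vol = 0.16)

# Round half away from zero on the positive axis; the engines use a daily
# grid, so maturation draws land on integer days.
round_half_up <- function(x) floor(x + 0.5)

#' Female satiation threshold
#'
#' Condition (abdomen width) above which a female stops feeding and is
#' ready to produce an egg sac, a quadratic in carapace width:
#' `-38.98 + 11.73 CW - 0.63 CW^2`. The quadratic peaks at
#' `CW = 11.73 / (2 * 0.63) ~ 9.31` mm and is increasing below that.
#'
#' @param cw carapace width (mm), positive.
#' @return threshold (mm). Errors if the quadratic is non-positive for
#'   any input (a degenerate female; generation initialization instead
#'   marks such females satiated at entry to preserve population size).
#' @examples
#' satiation_threshold(5.919) # ~8.38 mm
#' @export
satiation_threshold <- function(cw) {
  stopifnot(all(cw > 0))
  v <- .sat_coeffs[["intercept"]] + .sat_coeffs[["cw"]] * cw +
    .sat_coeffs[["cw2"]] * cw^2
  if (any(v <= 0)) {
    stop("satiation threshold non-positive at CW = ",
         paste(signif(cw[v <= 0], 4), collapse = ", "), call. = FALSE)
  }
  v
}

# unchecked vectorized form used inside the engines
.sat_threshold_raw <- function(cw) {
  .sat_coeffs[["intercept"]] + .sat_coeffs[["cw"]] * cw +
    .sat_coeffs[["cw2"]] * cw^2
}

#' Draw adult carapace width
#'
#' Normal draw around the strategy's size-at-maturation regression
#' `CW ~ intercept + b_mat * fem_mat + b_cl * CL`; early-maturing
#' spillover variants have the steeper maturation slope (0.047 vs 0.024)
#' and so reach larger sizes despite maturing 17 days earlier.
#'
#' @param fem_mat maturation day (vector ok).
#' @param cl carapace length covariate (mm).
#' @param strategy a strategy name or `spovsim_strategy`.
#' @param sd residual sd override (e.g. 0 for a deterministic mean).
#' @return carapace width draws (mm), truncated below at 0.01.
#' @examples
#' set.seed(1)
#' adult_size(39, 3.5, "EARLY-SPOV", sd = 0) # exactly 6.408
#' @export
adult_size <- function(fem_mat, cl, strategy, sd = NULL) {
  if (is.character(strategy)) strategy <- default_strategy(strategy)
  stopifnot(all(fem_mat >= 1))
  cc <- strategy$cw_coeffs
  mu <- cc[["intercept"]] + cc[["mat"]] * fem_mat + cc[["cl"]] * cl
  s <- if (is.null(sd)) cc[["sd"]] else sd
  pmax(rnorm(length(mu), mu, s), 0.01)
}

#' Draw initial adult condition
#'
#' Condition (abdomen width, mm) at maturation:
#' `N(3.54 + 0.49 CW, 0.2671)`, truncated below at 0.
#'
#' @param cw carapace width (mm, vector ok).
#' @param sd residual sd override.
#' @return condition draws (mm).
#' @examples
#' initial_condition(6, sd = 0) # exactly 6.48
#' @export
initial_condition <- function(cw, sd = NULL) {
  stopifnot(all(cw > 0))
  mu <- .cond_coeffs[["intercept"]] + .cond_coeffs[["cw"]] * cw
  s <- if (is.null(sd)) .cond_coeffs[["sd"]] else sd
  pmax(rnorm(length(mu), mu, s), 0)
}

# Genotypes for generation zero. "thirds" composition splits females into
# heterozygous / spillover-homozygous / MFCL-homozygous thirds (remainder
# assigned in that order) and males half-and-half; "hw" draws each X copy
# independently as the spillover allele with probability p0.
# RNG protocol (hw): female first copies, female second copies, male copies.
.initial_genotypes <- function(par) {
  nf <- par$nf; nm <- par$nm
  if (par$init_thirds == 1L) {
    cnt <- rep(nf %/% 3L, 3L)
    r <- nf %% 3L
    if (r > 0L) cnt[seq_len(r)] <- cnt[seq_len(r)] + 1L
    # order: het, SS, MM
    a1 <- c(rep(1L, cnt[1]), rep(1L, cnt[2]), rep(0L, cnt[3]))
    a2 <- c(rep(0L, cnt[1]), rep(1L, cnt[2]), rep(0L, cnt[3]))
    ns <- nm %/% 2L
    ma <- c(rep(1L, ns), rep(0L, nm - ns))
  } else {
    a1 <- as.integer(runif(nf) < par$p0)
    a2 <- as.integer(runif(nf) < par$p0)
    ma <- as.integer(runif(nm) < par$p0)
  }
  list(f_a1 = a1, f_a2 = a2, m_a = ma)
}

# Life-history draws for a generation whose genotypes are already fixed.
# RNG protocol (matched by the compiled engine): female maturation days,
# female carapace widths, female initial conditions, male maturation days.
.init_life_history <- function(geno, par) {
  nf <- length(geno$f_a1)
  nm <- length(geno$m_a)
  spov <- if (par$dom_spov == 1L) (geno$f_a1 + geno$f_a2) >= 1L else
    (geno$f_a1 + geno$f_a2) == 2L
  ph <- ifelse(spov, 2L, 1L) # phenotype index: 1 MFCL, 2 spillover

  mat <- round_half_up(rnorm(nf, par$mat_mean[ph], par$mat_sd[ph]))
  mat <- pmin(pmax(mat, 1), par$slen)
  cw <- rnorm(nf, par$cw_int[ph] + par$cw_mat[ph] * mat + par$cw_cl[ph] * par$cl,
              par$cw_sd[ph])
  cw <- pmax(cw, 0.01)
  cond <- pmax(rnorm(nf, .cond_coeffs[["intercept"]] + .cond_coeffs[["cw"]] * cw,
                     .cond_coeffs[["sd"]]), 0)
  maxcond <- .sat_threshold_raw(cw)

  mmat <- round_half_up(rnorm(nm, .male_mat[["mean"]], .male_mat[["sd"]]))
  mmat <- pmin(pmax(mmat, 1), par$slen)

  list(
    females = data.frame(
      a1 = geno$f_a1, a2 = geno$f_a2, spov = spov,
      mat = as.integer(mat), cw = cw, cond = cond, maxcond = maxcond,
      satiated = cond >= maxcond, mated = rep(FALSE, nf),
      father = rep(NA_integer_, nf), resident = rep(NA_integer_, nf),
      alive = rep(TRUE, nf), kills = rep(0L, nf)
    ),
    males = data.frame(
      a = geno$m_a, mat = as.integer(mmat), alive = rep(TRUE, nm),
      cohab = rep(NA_integer_, nm), matings = rep(0L, nm)
    )
  )
}

#' Initialize a generation of adults
#'
#' Builds the configured number of adult females and males. Genotypes
#' come from the config's initial composition (or, for later generations,
#' from an explicit `genotypes` list); each female then receives a
#' maturation day (rounded to the nearest day and clamped to the season),
#' a carapace width, an initial condition and a satiation threshold, each
#' drawn from her strategy's distributions. Females whose threshold does
#' not exceed their initial condition are marked satiated at entry.
#'
#' @param config a `spovsim_config`.
#' @param genotypes optional list with `f_a1`, `f_a2`, `m_a` allele-code
#'   vectors overriding the config's initial composition.
#' @return population list (see file header) of class `spovsim_population`.
#' @export
initialize_generation <- function(config, genotypes = NULL) {
  par <- resolve_engine_params(config)
  if (is.null(genotypes)) genotypes <- .initial_genotypes(par)
  stopifnot(length(genotypes$f_a1) == length(genotypes$f_a2))
  pop <- .init_life_history(genotypes, par)
  class(pop) <- "spovsim_population"
  pop
}

#' @export
print.spovsim_population <- function(x, ...) {
  cat("<spovsim_population>", nrow(x$females), "females,",
      nrow(x$males), "males; p =",
      signif(allele_frequency(x$females, x$males), 4), "\n")
  invisible(x)
}
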
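# Post-processing of oscillating trajectories: TOP/BOTTOM position
# labels and covariate-adjusted fitness comparisons that diagnose
# frequency-dependent selection.

#' Label generations by their position in an oscillation
#'
#' A generation is `TOP` when the spillover-allele frequency strictly
#' exceeds the threshold (default 0.85, i.e. the allele close to
#' fixation) and `BOTTOM` otherwise.
#'
#' @param p numeric vector of per-generation allele frequencies, or a
#'   `spovsim_trajectory`.
#' @param threshold frequency cut point (default 0.85; `p == threshold`
#'   is `BOTTOM`).
#' @return factor with levels `BOTTOM`, `TOP`.
#' @examples
#' label_positions(c(0.80, 0.85, 0.90)) # BOTTOM BOTTOM TOP
#' @export
label_positions <- function(p, threshold = 0.85) {
  if (inherits(p, "spovsim_trajectory")) p <- p$records$p
  stopifnot(length(p) >= 1, all(p >= 0 & p <= 1, na.rm = TRUE))
  factor(ifelse(p > threshold, "TOP", "BOTTOM"), levels = c("BOTTOM", "TOP"))
}

#' Relative fitness of the spillover strategy in one generation
#'
#' The number of spillover-phenotype females surviving to maturation
#' divided by the average of the two strategies' counts:
#' `N_spov / ((N_spov + N_mfcl) / 2)`, bounded in `[0, 2]` and equal to
#' 1 when the strategies are at parity.
#'
#' @param n_spov,n_mfcl female counts at maturation (vectors ok).
#' @return ratio; `NA` where both counts are zero.
#' @examples
#' relative_fitness_spillover(450, 50) # 1.8
#' @export
relative_fitness_spillover <- function(n_spov, n_mfcl) {
  half <- (n_spov + n_mfcl) / 2
  ifelse(half > 0, n_spov / half, NA_real_)
}

#' Percentage of MFCL females mating in one generation
#'
#' @param matings_mfcl number of MFCL females that mated.
#' @param n_mfcl number of MFCL females at maturation.
#' @return percentage; `NA` where no MFCL female was present.
#' @export
mfcl_mating_percentage <- function(matings_mfcl, n_mfcl) {
  ifelse(n_mfcl > 0, 100 * matings_mfcl / n_mfcl, NA_real_)
}

#' Covariate-adjusted TOP/BOTTOM comparison of a per-generation metric
#'
#' Fits a generalized linear model of a per-generation fitness metric on
#' the oscillation position (TOP/BOTTOM), with generation number (to
#' absorb temporal trend/autocorrelation) and the spillover-allele
#' frequency itself as covariates. Each data point is one generation.
#' The MFCL mating fraction uses a binomial/logit model on successes out
#' of MFCL females present; the spillover relative-fitness ratio uses a
#' Gaussian identity-link model (`family = "gaussian"` forces the latter
#' for the mating metric too). The position effect is tested with a
#' likelihood-ratio chi-square; adjusted (least-squares) means and
#' standard errors are evaluated at the grand mean of the covariates on
#' the link scale and back-transformed to the response scale.
#'
#' @param trajectory a `spovsim_trajectory`, or a data frame with the
#'   trajectory's record columns.
#' @param metric `"mfcl_mating"` or `"rel_fitness"`.
#' @param threshold TOP/BOTTOM frequency cut point (default 0.85).
#' @param family for `"mfcl_mating"`, `"binomial"` (default) or
#'   `"gaussian"`.
#' @param burn_in number of leading generations to drop (default 0; the
#'   whole trajectory enters the comparison).
#' @return object of class `spovsim_equilibrium`: threshold, metric,
#'   per-position adjusted means and standard errors (percentages for
#'   the mating metric), the likelihood-ratio statistic, its df and
#'   p-value, the per-generation labeled data, and the fitted model. If
#'   only one position label occurs, the object is returned with
#'   `degenerate = TRUE` and `NA` statistics instead of a silent drop.
#' @export
compare_positions <- function(trajectory,
                              metric = c("mfcl_mating", "rel_fitness"),
                              threshold = 0.85,
                              family = c("binomial", "gaussian"),
                              burn_in = 0L) {
  metric <- match.arg(metric)
  family <- match.arg(family)
  rec <- if (inherits(trajectory, "spovsim_trajectory")) {
    trajectory$records
  } else {
    as.data.frame(trajectory)
  }
  stopifnot(nrow(rec) >= 2)
  if (burn_in > 0L) rec <- rec[rec$generation >= burn_in, , drop = FALSE]
  # only generations whose season was simulated carry the metric
  rec <- rec[!is.na(rec$n_mfcl_females) & !is.na(rec$matings_mfcl), , drop = FALSE]
  dat <- data.frame(
    generation = rec$generation,
    p = rec$p,
    position = label_positions(rec$p, threshold),
    n_spov = rec$n_spov_females,
    n_mfcl = rec$n_mfcl_females,
    mated_mfcl = rec$matings_mfcl
  )
  dat$rel_fitness <- relative_fitness_spillover(dat$n_spov, dat$n_mfcl)

  out <- list(threshold = threshold, metric = metric, family = family,
              degenerate = FALSE)
  class(out) <- "spovsim_equilibrium"

  if (metric == "mfcl_mating") {
    dat <- dat[dat$n_mfcl > 0, , drop = FALSE]
  } else {
    dat <- dat[!is.na(dat$rel_fitness), , drop = FALSE]
  }
  out$data <- dat
  if (nlevels(droplevels(dat$position)) < 2L) {
    out$degenerate <- TRUE
    out$message <- "only one position label present; nothing to compare"
    out$adjusted <- data.frame(
      position = c("BOTTOM", "TOP"), mean = NA_real_, se = NA_real_
    )
    out$lr_statistic <- NA_real_
    out$df <- NA_integer_
    out$p_value <- NA_real_
    return(out)
  }

  if (metric == "mfcl_mating" && family == "binomial") {
    fit <- glm(cbind(mated_mfcl, n_mfcl - mated_mfcl) ~
                 position + generation + p,
               family = binomial(), data = dat)
    scale <- 100
  } else if (metric == "mfcl_mating") {
    dat$pct <- 100 * dat$mated_mfcl / dat$n_mfcl
    fit <- glm(pct ~ position + generation + p, family = gaussian(),
               data = dat)
    scale <- 1
  } else {
    fit <- glm(rel_fitness ~ position + generation + p,
               family = gaussian(), data = dat)
    scale <- 1
  }
  fit0 <- update(fit, . ~ . - position)
  lrt <- anova(fit0, fit, test = "LRT")
  emm <- emmeans::emmeans(fit, "position", type = "response")
  emm <- as.data.frame(emm)
  mean_col <- intersect(c("prob", "response", "emmean"), names(emm))[1]
  se_col <- if ("SE" %in% names(emm)) "SE" else "std.error"
  out$adjusted <- data.frame(
    position = as.character(emm$position),
    mean = scale * emm[[mean_col]],
    se = scale * emm[[se_col]]
  )
  out$lr_statistic <- lrt$Deviance[2]
  out$df <- lrt$Df[2]
  out$p_value <- lrt$`Pr(>Chi)`[2]
  out$fit <- fit
  out
}

#' @export
print.spovsim_equilibrium <- function(x, ...) {
  cat("<spovsim_equilibrium> metric:", x$metric,
      sprintf("(threshold %.2f)\n", x$threshold))
  if (isTRUE(x$degenerate)) {
    cat("  degenerate design:", x$message, "\n")
    return(invisible(x))
  }
  for (i in seq_len(nrow(x$adjusted))) {
    cat(sprintf("  %-6s adjusted mean %.4g +/- %.2g\n",
                x$adjusted$position[i], x$adjusted$mean[i], x$adjusted$se[i]))
  }
  cat(sprintf("  LR chi-square(%d) = %.4g, p = %.3g\n",
              x$df, x$lr_statistic, x$p_value))
  invisible(x)
}

#' Full equilibrium report for an oscillating trajectory
#'
#' Convenience wrapper running [compare_positions()] for both metrics
#' and bundling the per-generation labeled table.
#'
#' @inheritParams compare_positions
#' @return list of class `spovsim_equilibrium_report` with elements
#'   `mfcl_mating`, `rel_fitness` and `labels`.
#' @export
equilibrium_report <- function(trajectory, threshold = 0.85, burn_in = 0L) {
  list2 <- list(
    mfcl_mating = compare_positions(trajectory, "mfcl_mating",
                                    threshold = threshold, burn_in = burn_in),
    rel_fitness = compare_positions(trajectory, "rel_fitness",
                                    threshold = threshold, burn_in = burn_in),
    labels = label_positions(trajectory, threshold)
  )
  class(list2) <- "spovsim_equilibrium_report"
  list2
}

#' @export
print.spovsim_equilibrium_report <- function(x, ...) {
  print(x$mfcl_mating)
  print(x$rel_fitness)
  invisible(x)
}
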
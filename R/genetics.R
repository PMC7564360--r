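# Sex-linked one-locus genetics on an XX (female) / X0 (male) system.
# Alleles are coded as integers throughout the engines: 1 = "S" (the
# spillover-family allele), 0 = "M" (the MFCL allele). Females carry an
# unordered pair of X copies, males a single copy (hemizygous carriers
# with no phenotypic effect of their own).

#' Allele codes
#'
#' Convert between the integer allele codes used internally (1 = `S`,
#' the spillover-family allele; 0 = `M`, the MFCL allele) and labels.
#'
#' @param x integer vector of codes, or character vector of labels.
#' @return `allele_label()` returns `"S"`/`"M"`; `allele_code()` returns
#'   1/0 integers.
#' @export
allele_label <- function(x) {
  stopifnot(all(x %in% c(0L, 1L)))
  c("M", "S")[x + 1L]
}

#' @rdname allele_label
#' @export
allele_code <- function(x) {
  stopifnot(all(x %in% c("S", "M")))
  as.integer(x == "S")
}

#' Map a female genotype to her behavioral strategy
#'
#' Homozygous females express their own allele's strategy; heterozygous
#' females express the strategy of whichever allele is configured as
#' dominant. The mapping is order-insensitive in the two alleles.
#'
#' @param allele_1,allele_2 integer allele codes (vectors allowed),
#'   1 = spillover allele, 0 = MFCL allele.
#' @param dominance `"spillover"` or `"mfcl"`.
#' @return logical vector: `TRUE` where the female expresses the
#'   spillover-family phenotype, `FALSE` where she expresses MFCL.
#' @examples
#' female_phenotype(1L, 0L, "spillover") # TRUE  (het, spillover dominant)
#' female_phenotype(1L, 0L, "mfcl")      # FALSE (het, MFCL dominant)
#' female_phenotype(0L, 0L, "spillover") # FALSE (homozygote)
#' @export
female_phenotype <- function(allele_1, allele_2, dominance = c("spillover", "mfcl")) {
  dominance <- match.arg(dominance)
  stopifnot(all(allele_1 %in% 0:1), all(allele_2 %in% 0:1))
  s <- allele_1 + allele_2
  if (dominance == "spillover") s >= 1L else s == 2L
}

#' Draw one offspring from a mated female
#'
#' Mendelian segregation on the XX/X0 system: the offspring is a daughter
#' or a son with probability one half each; a daughter receives one
#' uniformly chosen maternal X copy plus the recorded paternal allele; a
#' son receives only the uniformly chosen maternal copy.
#'
#' Two uniform deviates are consumed per call, in the order (sex,
#' maternal copy); the vectorized engines follow the same protocol.
#'
#' @param mother_a1,mother_a2 maternal allele codes.
#' @param father_allele paternal allele code.
#' @return list with `sex` (`"F"`/`"M"`), `allele_1` (maternal),
#'   `allele_2` (paternal for daughters, `NA` for sons).
#' @export
make_offspring <- function(mother_a1, mother_a2, father_allele) {
  stopifnot(mother_a1 %in% 0:1, mother_a2 %in% 0:1, father_allele %in% 0:1)
  sex <- if (runif(1) < 0.5) "F" else "M"
  maternal <- if (runif(1) < 0.5) mother_a1 else mother_a2
  list(
    sex = sex,
    allele_1 = as.integer(maternal),
    allele_2 = if (sex == "F") as.integer(father_allele) else NA_integer_
  )
}

#' Spillover-allele frequency of an adult population
#'
#' Counts spillover (`S`) allele copies over all X chromosomes: two per
#' female and one per male, 1500 copies for the default 500 + 500 adults.
#' Set `females_only = TRUE` to restrict the denominator to female copies.
#'
#' @param females data frame (or list) with integer columns `a1`, `a2`.
#' @param males data frame (or list) with integer column `a`.
#' @param females_only count female X copies only.
#' @return frequency `p` of the spillover allele, in `[0, 1]`.
#' @examples
#' f <- data.frame(a1 = c(1L, 0L), a2 = c(0L, 0L))
#' m <- data.frame(a = c(1L, 0L))
#' allele_frequency(f, m) # 2/6
#' @export
allele_frequency <- function(females, males, females_only = FALSE) {
  nf <- length(females$a1)
  nm <- length(males$a)
  if (nf + nm == 0L) stop("empty population", call. = FALSE)
  s <- sum(females$a1) + sum(females$a2)
  total <- 2L * nf
  if (!females_only) {
    s <- s + sum(males$a)
    total <- total + nm
  }
  if (total == 0L) stop("no X copies to count", call. = FALSE)
  s / total
}
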
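# Chi-square goodness of fit of phenotype segregation to candidate ratios,
# exact ratio enumeration from the epistasis model, and model ranking.

#' Ratio hypothesis
#'
#' A candidate segregation ratio such as `13:3`, given either as a label to
#' parse or as explicit positive class weights.
#'
#' @param label text label, e.g. `"13:3"`; parsed into weights when
#'   `weights` is missing.
#' @param weights positive numeric class weights.
#' @param classes optional class labels (same length as weights).
#' @return object of class `ratio_hypothesis`.
#' @examples
#' ratio_hypothesis("13:3")
#' @export
ratio_hypothesis <- function(label, weights = NULL, classes = NULL) {
  if (is.null(weights)) {
    weights <- suppressWarnings(as.numeric(strsplit(label, ":")[[1]]))
    if (any(is.na(weights))) stopf("cannot parse ratio label '%s'", label)
  }
  if (!length(weights) || any(!is.finite(weights)) || any(weights <= 0))
    stopf("ratio weights must be positive")
  structure(list(label = as.character(label), weights = as.numeric(weights),
                 classes = classes),
            class = "ratio_hypothesis")
}

#' Built-in segregation ratio library
#'
#' The standard one- and two-locus ratios used for model screening:
#' 3:1, 1:1, 13:3, 9:7, 15:1, 9:3:4, 1:2:1 and 1:1:1:1.
#'
#' @return named list of [ratio_hypothesis()] objects.
#' @export
builtin_ratios <- function() {
  labs <- c("3:1", "1:1", "13:3", "9:7", "15:1", "9:3:4", "1:2:1", "1:1:1:1")
  stats::setNames(lapply(labs, ratio_hypothesis), labs)
}

#' Chi-square goodness of fit to a segregation ratio
#'
#' Pearson's statistic `sum((O - E)^2 / E)` with expected counts
#' `E_i = n * w_i / sum(w)`, no continuity correction, `df = k - 1`, and the
#' upper-tail chi-square probability. This is the plain SAS-style test used
#' for seed-type segregation tables: e.g. 148 non-egusi : 26 egusi against
#' 13:3 gives chi2 = 1.6558, P = 0.1982.
#'
#' @param observed non-negative integer counts per phenotype class (>= 2
#'   classes, total >= 1).
#' @param hypothesis a [ratio_hypothesis()] (or a label string) with the same
#'   number of classes.
#' @return object of class `gof_result`: list with `chi2`, `df`, `p`,
#'   `observed`, `expected`, `label`.
#' @examples
#' chi_square_gof(c(148, 26), "13:3")
#' @export
chi_square_gof <- function(observed, hypothesis) {
  if (is.character(hypothesis)) hypothesis <- ratio_hypothesis(hypothesis)
  if (!inherits(hypothesis, "ratio_hypothesis"))
    stopf("`hypothesis` must be a ratio_hypothesis or a label string")
  observed <- as.numeric(observed)
  if (length(observed) < 2L) stopf("need at least two phenotype classes")
  if (any(is.na(observed)) || any(observed < 0) ||
      any(observed != floor(observed)))
    stopf("observed counts must be non-negative integers")
  n <- sum(observed)
  if (n < 1) stopf("total count must be at least 1")
  w <- hypothesis$weights
  if (length(w) != length(observed))
    stopf("hypothesis '%s' has %d classes but %d were observed",
          hypothesis$label, length(w), length(observed))
  expected <- n * w / sum(w)
  chi2 <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  structure(list(chi2 = chi2, df = df,
                 p = stats::pchisq(chi2, df, lower.tail = FALSE),
                 observed = observed, expected = expected,
                 label = hypothesis$label),
            class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf("ratio %s: chi2 = %.4f, df = %d, P = %.4f\n",
              x$label, x$chi2, x$df, x$p))
  invisible(x)
}

# genotype-class distribution at one locus for a cross, as probabilities
# over 0/1/2 copies of the recessive allele. `alleles`: the two parents'
# alleles at this locus (e.g. c("a", "A")); `recessive`: the lowercase one.
locus_cross_dist <- function(cross, alleles, recessive) {
  rec <- alleles == recessive
  deg <- function(k) { p <- numeric(3); p[k + 1] <- 1; p }
  if (cross == "F1") return(deg(sum(rec)))
  if (!xor(rec[1], rec[2])) return(deg(2 * rec[1]))  # monomorphic locus
  switch(cross,
    F2    = c(0.25, 0.5, 0.25),
    BC1F1 = if (rec[1]) c(0, 0.5, 0.5) else c(0.5, 0.5, 0))
}

# selfing distribution given 0/1/2 copies of the recessive allele
self_dist <- function(k) {
  switch(as.character(k),
         "0" = c(1, 0, 0), "1" = c(0.25, 0.5, 0.25), "2" = c(0, 0, 1))
}

#' Exact phenotype segregation ratio of a cross under an epistasis model
#'
#' Enumerates the unlinked two-locus genotype-class frequencies of the cross
#' (F2 over sixteenths, BC1F1 over halves, selfed BC1F2 over quarters per
#' segregating locus), maps each class through the penetrance table, and
#' returns the phenotype ratio in smallest integer form (non-egusi class
#' first). The two model loci must lie on different chromosomes.
#'
#' @param model an [epistasis_model()].
#' @param cross one of `"F1"`, `"F2"`, `"BC1F1"`, `"BC1F2"`.
#' @param parents list of two [parent_spec()]s (recurrent parent first for
#'   backcrosses).
#' @param bc1_genotype for `cross = "BC1F2"`: the selfed BC1 plant's
#'   genotypes, e.g. `c(main = "Aa", suppressor = "BB")`.
#' @return a [ratio_hypothesis()] with `classes` naming the phenotypes.
#' @examples
#' p <- default_parents()
#' enumerate_ratio(default_epistasis_model(), "F2", list(p$B3, p$X1625))  # 13:3
#' @export
enumerate_ratio <- function(model, cross, parents, bc1_genotype = NULL) {
  cross <- match.arg(cross, c("F1", "F2", "BC1F1", "BC1F2"))
  if (model$main_locus$chrom == model$suppressor_locus$chrom)
    stopf("linked model loci (same chromosome) are not supported for exact enumeration")
  if (!all(vapply(parents, inherits, TRUE, "parent_spec")))
    stopf("`parents` must be parent_spec objects")
  main_alleles <- substr(c(parents[[1]]$main, parents[[2]]$main), 1, 1)
  supp_alleles <- substr(c(parents[[1]]$suppressor, parents[[2]]$suppressor),
                         1, 1)
  if (cross == "BC1F2") {
    if (is.null(bc1_genotype))
      stopf("BC1F2 enumeration needs `bc1_genotype` (the selfed plant)")
    pm <- self_dist(match(bc1_genotype[["main"]], GENO_MAIN) - 1L)
    ps <- self_dist(match(bc1_genotype[["suppressor"]], GENO_SUPP) - 1L)
  } else {
    pm <- locus_cross_dist(cross, main_alleles, "a")
    ps <- locus_cross_dist(cross, supp_alleles, "b")
  }
  joint <- outer(pm, ps)  # rows: 0/1/2 copies of a; cols: 0/1/2 copies of b
  pheno <- matrix(assign_phenotype(rep(GENO_MAIN, 3), rep(GENO_SUPP, each = 3),
                                   model), 3, 3)
  probs <- c(non_egusi = sum(joint[pheno == "non_egusi"]),
             egusi = sum(joint[pheno == "egusi"]))
  probs <- probs[probs > 0]
  num <- round(probs * 16)
  g <- Reduce(gcd2, num)
  num <- num / g
  ratio_hypothesis(paste(num, collapse = ":"), weights = num,
                   classes = names(num))
}

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

#' Rank segregation-ratio hypotheses against observed counts
#'
#' Tests each hypothesis with [chi_square_gof()] and orders them by
#' increasing chi-square (ties broken by label). A hypothesis is compatible
#' when its P value is at least `alpha`.
#'
#' @param observed counts per phenotype class.
#' @param hypotheses list of [ratio_hypothesis()] objects or label strings.
#' @param alpha significance level for compatibility (default 0.05).
#' @return data frame with columns `label`, `chi2`, `df`, `p`, `compatible`,
#'   ordered best first.
#' @examples
#' rank_models(c(148, 26), c("13:3", "3:1", "15:1", "9:7"))
#' @export
rank_models <- function(observed, hypotheses, alpha = 0.05) {
  if (!length(hypotheses)) stopf("need at least one hypothesis")
  if (inherits(hypotheses, "ratio_hypothesis")) hypotheses <- list(hypotheses)
  res <- lapply(hypotheses, function(h) chi_square_gof(observed, h))
  out <- data.frame(
    label = vapply(res, `[[`, "", "label"),
    chi2 = vapply(res, `[[`, 0, "chi2"),
    df = vapply(res, `[[`, 0L, "df"),
    p = vapply(res, `[[`, 0, "p"),
    stringsAsFactors = FALSE)
  out$compatible <- out$p >= alpha
  out <- out[order(out$chi2, out$label), , drop = FALSE]
  rownames(out) <- NULL
  out
}
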
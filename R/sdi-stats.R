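#' Strain distribution indices
#'
#' Scalar summaries of a distribution of local first-principal strain
#' values: the arithmetic mean; the maximum local value; the coefficient
#' of variation (sample standard deviation over mean), used as a
#' heterogeneity index; and the adjusted Fisher-Pearson sample skewness,
#' whose sign encodes the side of the long tail (positive = right-skewed,
#' a long tail of few large strains).
#'
#' @param samples numeric vector of strain values, length at least 3.
#' @return Object of class `sdi_summary` with fields `mean`, `maximum`,
#'   `coefficient_of_variation` (NA with a note when the mean is zero) and
#'   `skewness` (0 by convention for zero-variance samples).
#' @export
compute_sdi <- function(samples) {
  n <- length(samples)
  if (n < 3) stop("need at least 3 samples")
  if (any(!is.finite(samples))) stop("samples must be finite")
  m <- mean(samples)
  s <- sd(samples)
  cv <- if (abs(m) < .Machine$double.eps) NA_real_ else s / m
  skew <- if (s == 0) 0 else {
    g1 <- mean((samples - m)^3) / (mean((samples - m)^2))^(3 / 2)
    g1 * sqrt(n * (n - 1)) / (n - 2)
  }
  structure(list(mean = m, maximum = max(samples),
                 coefficient_of_variation = cv, skewness = skew, n = n),
            class = "sdi_summary")
}

#' @export
print.sdi_summary <- function(x, ...) {
  cat(sprintf("<sdi> n=%d mean=%.4g max=%.4g CV=%.4g skewness=%.4g\n",
              x$n, x$mean, x$maximum, x$coefficient_of_variation, x$skewness))
  invisible(x)
}

#' Compare one strain distribution index between two groups
#'
#' Screens both groups for normality (Shapiro-Wilk at the 5% level) and
#' then applies the more powerful test that the data support: a two-sample
#' Student's t-test when both groups pass the screen, a Wilcoxon rank-sum
#' test otherwise. This substitutes an explicit, reproducible rule for the
#' automatic location-test selection used in the original analysis.
#'
#' @param group_a,group_b numeric vectors of per-specimen index values.
#' @param alpha significance level for the decision reported in `reject`.
#' @return List with `branch` (`"t"` or `"rank"`), `statistic`, `p_value`,
#'   `reject`, `alpha` and the group sizes.
#' @export
compare_groups_sdi <- function(group_a, group_b, alpha = 0.05) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2 || nb < 2) stop("each group needs at least 2 specimens")
  if (sd(group_a) == 0 && sd(group_b) == 0 && mean(group_a) == mean(group_b)) {
    return(list(branch = "degenerate", statistic = NA_real_, p_value = 1,
                reject = FALSE, alpha = alpha, n = c(na, nb)))
  }
  if (sd(group_a) == 0 || sd(group_b) == 0) {
    stop("degenerate group with zero variance")
  }
  normal <- function(x) {
    if (length(x) < 3) return(FALSE)
    shapiro.test(x)$p.value >= 0.05
  }
  if (normal(group_a) && normal(group_b)) {
    ht <- t.test(group_a, group_b, var.equal = TRUE)
    branch <- "t"
  } else {
    ht <- suppressWarnings(wilcox.test(group_a, group_b, exact = TRUE))
    branch <- "rank"
  }
  list(branch = branch, statistic = unname(ht$statistic),
       p_value = ht$p.value, reject = ht$p.value < alpha,
       alpha = alpha, n = c(na, nb))
}

#' Pairwise Mann-Whitney U tests between tissue regions
#'
#' Runs a Mann-Whitney U test for each named region pair and declares
#' significance at `alpha` divided by the number of pairs actually tested
#' (Bonferroni). The default pair list holds the six comparisons of the
#' tissue-type analysis: intact elastin without vs with thrombus
#' attachment, intact vs fragmented elastin, thrombus with vs without
#' RBCs, and the cross-type similarity checks.
#'
#' @param rs a `region_strains`.
#' @param pairs list of 2-element character vectors of region labels.
#' @param alpha family significance level.
#' @return data.frame, one row per tested pair, with the U statistic, raw
#'   p-value, Bonferroni-corrected threshold and decision; pairs missing a
#'   region are skipped with a warning.
#' @export
pairwise_region_tests <- function(rs,
                                  pairs = list(c("A1", "A2"), c("A1", "A3"),
                                               c("A4", "A5"), c("A1", "A4"),
                                               c("A2", "A5"), c("A3", "A5")),
                                  alpha = 0.05) {
  have <- names(rs$samples)[vapply(rs$samples, length, integer(1)) > 0]
  usable <- vapply(pairs, function(p) all(p %in% have), logical(1))
  if (any(!usable)) {
    warning("skipping pairs with missing regions: ",
            paste(vapply(pairs[!usable], paste, "", collapse = "-"), collapse = ", "))
  }
  pairs <- pairs[usable]
  m <- length(pairs)
  if (m == 0) stop("no testable region pairs")
  thr <- alpha / m
  out <- do.call(rbind, lapply(pairs, function(p) {
    a <- rs$samples[[p[1]]]; b <- rs$samples[[p[2]]]
    ht <- suppressWarnings(wilcox.test(a, b))
    data.frame(region_a = p[1], region_b = p[2],
               n_a = length(a), n_b = length(b),
               U = unname(ht$statistic), p_value = ht$p.value,
               corrected_threshold = thr,
               significant = ht$p.value < thr)
  }))
  attr(out, "bonferroni_divisor") <- m
  out
}

#' Linear fit of mean strain against tissue proportion
#'
#' Ordinary least squares of per-specimen mean strain on the area
#' proportion of a tissue type, with the coefficient of determination and
#' the two-sided p-value of the slope.
#'
#' @param proportion,mean_strain numeric vectors, length at least 3.
#' @return List of class `fit_result`: `slope`, `intercept`, `R_squared`,
#'   `p_value`, `n`.
#' @export
fit_mean_strain_vs_proportion <- function(proportion, mean_strain) {
  if (length(proportion) != length(mean_strain) || length(proportion) < 3) {
    stop("need matched vectors of length >= 3")
  }
  if (sd(proportion) == 0) stop("proportion is constant; slope undefined")
  fit <- lm(mean_strain ~ proportion)
  sm <- summary(fit)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 R_squared = sm$r.squared,
                 p_value = sm$coefficients[2, 4],
                 n = length(proportion)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit> slope=%.4g intercept=%.4g R2=%.3f p=%.3g (n=%d)\n",
              x$slope, x$intercept, x$R_squared, x$p_value, x$n))
  invisible(x)
}
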
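# Statistical layer: Pearson correlation with two-tailed significance,
# simple linear regression R^2, pooled-variance two-sample t-test,
# normal-approximation power/sample-size calculation, and correlation tables
# in the style of the study's summary tables. Standard machinery is delegated
# to base R (cor.test, lm, t.test, qnorm); these wrappers fix the exact
# conventions used.

#' Pearson correlation with two-tailed p-value
#'
#' Product-moment correlation; significance from
#' t = r * sqrt((n - 2) / (1 - r^2)) against the t distribution with n - 2
#' degrees of freedom, two-tailed.
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return A list (class \code{correlation_result}) with r, r_squared,
#'   p_two_tailed and n.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("degenerate input: zero variance")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  r <- unname(ct$estimate)
  structure(list(r = r, r_squared = r^2,
                 p_two_tailed = ct$p.value, n = length(x)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (r^2 = %.3f), two-tailed p = %.4g, n = %d\n",
              x$r, x$r_squared, x$p_two_tailed, x$n))
  invisible(x)
}

#' Simple linear regression with R^2
#'
#' Least-squares fit of y on x; for simple regression R^2 equals the squared
#' Pearson correlation.
#'
#' @inheritParams pearson_cor
#' @return A list with slope, intercept, r_squared and the underlying
#'   \code{lm} fit.
#' @export
linear_regression <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("degenerate input: zero variance")
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  list(slope = unname(cf[2L]), intercept = unname(cf[1L]),
       r_squared = summary(fit)$r.squared, fit = fit)
}

#' Pooled-variance two-sample Student's t-test
#'
#' Classical Student's t (equal variances assumed, not Welch), two-tailed.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return A list (class \code{t_test_result}) with t, df, p_two_tailed,
#'   group_means and pooled_sd.
#' @export
two_sample_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop("each group needs n >= 2")
  tt <- stats::t.test(a, b, var.equal = TRUE, alternative = "two.sided")
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / (n1 + n2 - 2)
  structure(list(t = unname(tt$statistic), df = n1 + n2 - 2L,
                 p_two_tailed = tt$p.value,
                 group_means = c(mean(a), mean(b)),
                 pooled_sd = sqrt(sp2)),
            class = "t_test_result")
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("Student's t = %.3f, df = %d, two-tailed p = %.4g\n",
              x$t, x$df, x$p_two_tailed))
  cat(sprintf("  group means %.3f vs %.3f, pooled sd %.3f\n",
              x$group_means[1], x$group_means[2], x$pooled_sd))
  invisible(x)
}

#' Per-group sample size for a two-sample comparison
#'
#' Normal-approximation formula
#' n = ceiling(2 * (z_{1-alpha/2} + z_{power})^2 * (sd / delta)^2).
#' With a between-group difference of 30 (same units as sd 15), 80% power and
#' alpha 0.05 this gives 4 per group. \code{method = "exact"} instead solves
#' the noncentral-t power equation (\code{power.t.test}), which returns a
#' larger n.
#'
#' @param delta Effect difference (> 0), same units as \code{sd}.
#' @param sd Common standard deviation (> 0).
#' @param power Target power in (0, 1).
#' @param alpha Two-sided significance level in (0, 1).
#' @param method \code{"normal"} (default) or \code{"exact"}.
#' @return Integer sample size per group.
#' @export
sample_size_normal <- function(delta, sd, power = 0.80, alpha = 0.05,
                               method = c("normal", "exact")) {
  method <- match.arg(method)
  if (delta <= 0) stop("delta must be > 0")
  if (sd <= 0) stop("sd must be > 0")
  if (power <= 0 || power >= 1) stop("power must be in (0, 1)")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (method == "normal") {
    n <- 2 * (stats::qnorm(1 - alpha / 2) + stats::qnorm(power))^2 * (sd / delta)^2
    return(as.integer(ceiling(n)))
  }
  pt <- stats::power.t.test(delta = delta, sd = sd, power = power,
                            sig.level = alpha, type = "two.sample",
                            alternative = "two.sided")
  as.integer(ceiling(pt$n))
}

#' Correlation table over variable pairs
#'
#' One Pearson test per requested pair, flagged at the 0.05 (*) and 0.01 (**)
#' two-tailed levels. No multiple-testing correction is applied by default,
#' matching the single-test star convention of the study tables; set
#' \code{adjust = "BH"} for Benjamini-Hochberg adjusted flags.
#'
#' @param data A data.frame holding all variables.
#' @param pairs A list of length-2 character vectors (or a 2-column character
#'   matrix) naming the variable pairs.
#' @param adjust \code{"none"} (default) or \code{"BH"}.
#' @return A data.frame with columns var1, var2, n, r, r_squared, p, stars.
#' @export
correlation_table <- function(data, pairs, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (is.matrix(pairs)) pairs <- split(pairs, row(pairs))
  if (length(pairs) == 0L) stop("no variable pairs requested")
  rows <- lapply(pairs, function(p) {
    if (length(p) != 2L) stop("each pair must name two variables")
    if (!all(p %in% names(data))) stop("unknown variable in pair: ",
                                       paste(p, collapse = ", "))
    keep <- stats::complete.cases(data[, p])
    if (sum(keep) < 3L) stop("fewer than 3 complete cases for pair ",
                             paste(p, collapse = "-"))
    res <- pearson_cor(data[keep, p[1]], data[keep, p[2]])
    data.frame(var1 = p[1], var2 = p[2], n = res$n, r = res$r,
               r_squared = res$r_squared, p = res$p_two_tailed,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  p_flag <- if (adjust == "BH") stats::p.adjust(out$p, method = "BH") else out$p
  out$stars <- ifelse(p_flag < 0.01, "**", ifelse(p_flag < 0.05, "*", ""))
  rownames(out) <- NULL
  out
}
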
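new_test_result <- function(method, statistic, p_value, n, note = NA_character_) {
  tibble::tibble(method = method, statistic = unname(statistic),
                 p_value = unname(p_value), n = list(n), alpha = 0.05,
                 note = note)
}

#' Shapiro-Wilk normality screen
#'
#' The study screens every variable (flow rates, flow differences) for
#' normality before falling back on medians and nonparametric tests.
#'
#' @param x Numeric sample, 3 <= n <= 5000, non-constant.
#' @return One-row tibble: method, statistic (W), p_value, n, alpha.
#' @export
test_normality <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3 || length(x) > 5000) {
    stop("Shapiro-Wilk requires 3 <= n <= 5000.")
  }
  if (sd(x) == 0) stop("Sample is constant; normality is undefined.")
  ht <- shapiro.test(x)
  new_test_result("shapiro-wilk", ht$statistic, ht$p.value, length(x))
}

#' Spearman rank correlation
#'
#' @param x,y Equal-length samples, n >= 3.
#' @return One-row tibble with `statistic` = rho (tie-corrected).
#' @export
test_spearman <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  ht <- suppressWarnings(cor.test(x, y, method = "spearman",
                                  exact = FALSE))
  new_test_result("spearman", ht$estimate, ht$p.value, length(x))
}

#' Ordinary least-squares flow calibration fit
#'
#' Fits `y ~ x` with free intercept, as used to compare flow values between
#' acquisition methods (slope near 1 indicates agreement).
#'
#' @param x,y Equal-length samples, n >= 3.
#' @return A `flow_fit` object; see [tidy()] and [glance()] methods, or the
#'   `$slope`, `$intercept`, `$r_squared` elements.
#' @export
linear_fit <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  model <- lm(y ~ x, data = data.frame(x = x, y = y))
  structure(list(model = model,
                 slope = unname(coef(model)[2]),
                 intercept = unname(coef(model)[1]),
                 r_squared = suppressWarnings(summary(model)$r.squared),
                 n = length(x)),
            class = "flow_fit")
}

#' @export
print.flow_fit <- function(x, ...) {
  cat(sprintf("<flow_fit> slope %.4g, intercept %.4g, R^2 %.4g (n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' @rdname linear_fit
#' @param x A `flow_fit` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.flow_fit <- function(x, ...) {
  co <- suppressWarnings(summary(x$model)$coefficients)
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = unname(co[, 1]), std_error = unname(co[, 2]),
                 statistic = unname(co[, 3]), p_value = unname(co[, 4]))
}

#' @rdname linear_fit
#' @exportS3Method generics::glance
glance.flow_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r_squared = x$r_squared, n = x$n)
}

#' Two-sided paired Wilcoxon signed-rank test
#'
#' Compares paired samples, or one sample against a constant (the study
#' tests whether flow differences exceed 5% and 10% of the median flow this
#' way). Identical pairs are degenerate: p = 1 is returned with a warning.
#'
#' @param x Numeric sample.
#' @param y Paired sample of equal length, or a single constant to test `x`
#'   against.
#' @return One-row tibble with `statistic` = V (signed-rank sum).
#' @export
test_paired_wilcoxon <- function(x, y = 0) {
  if (length(y) == 1) y <- rep(y, length(x))
  stopifnot(length(x) == length(y))
  d <- x - y
  if (all(d == 0)) {
    warning("All paired differences are zero; returning p = 1.")
    return(new_test_result("paired wilcoxon", NA_real_, 1, length(x),
                           note = "degenerate: all differences zero"))
  }
  ht <- suppressWarnings(wilcox.test(d, mu = 0, alternative = "two.sided"))
  new_test_result("paired wilcoxon", ht$statistic, ht$p.value, length(x))
}

#' Kruskal-Wallis rank test across groups
#'
#' Used with the CS acceleration factor (or voxel size) as grouping factor.
#'
#' @param groups List of >= 2 numeric samples (total n >= 5).
#' @return One-row tibble with `statistic` = tie-corrected H and chi-square
#'   p-value; `n` holds the per-group sizes.
#' @export
test_kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  sizes <- lengths(groups)
  if (any(sizes < 1) || sum(sizes) < 5) {
    stop("Need >= 2 non-empty groups with total n >= 5.")
  }
  ht <- kruskal.test(groups)
  new_test_result("kruskal-wallis", ht$statistic, ht$p.value, sizes)
}

#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Compares two independent velocity or flow distributions, with tie
#' correction.
#'
#' @param x,y Non-empty numeric samples.
#' @return One-row tibble with `statistic` = W.
#' @export
test_rank_sum <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  ht <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))
  new_test_result("rank-sum", ht$statistic, ht$p.value,
                  c(length(x), length(y)))
}
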
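#' Quadratic dose-response fit with vertex optimum
#'
#' OLS fit of y = c0 + c1 x + c2 x^2 across CO2 treatments, reporting the
#' vertex x_opt = -c1 / (2 c2) as the optimum dose and whether it is a
#' maximum (c2 < 0) or minimum (c2 > 0). Vertices falling outside the
#' observed dose range extended by half its width are flagged
#' `extrapolated` rather than suppressed.
#'
#' @param x Doses (e.g. growth CO2, ppm); >= 4 distinct values.
#' @param y Responses.
#' @return Object of class `quadratic_fit`: list with `coefficients`
#'   (c0, c1, c2), `r2`, `x_opt`, `opt_kind`, `extrapolated`, `n`.
#' @examples
#' x <- c(400, 600, 800, 1000, 1200)
#' fit_quadratic(x, -(x - 900)^2 / 1000 + 25)
#' @export
fit_quadratic <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < 4)
    stop_fit("fit_quadratic: need >= 4 distinct x values")
  fit <- stats::lm(y ~ x + I(x^2))
  co <- unname(stats::coef(fit))
  if (any(!is.finite(co))) stop_fit("fit_quadratic: rank-deficient design")
  sse <- sum(stats::residuals(fit)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sse / sst else 1
  x_opt <- if (abs(co[3]) > 0) -co[2] / (2 * co[3]) else NA_real_
  rng <- range(x); half <- diff(rng) / 2
  structure(list(
    coefficients = c(c0 = co[1], c1 = co[2], c2 = co[3]),
    r2 = r2,
    x_opt = x_opt,
    opt_kind = if (is.na(x_opt)) NA_character_ else
      if (co[3] < 0) "maximum" else "minimum",
    extrapolated = !is.na(x_opt) &&
      (x_opt < rng[1] - half || x_opt > rng[2] + half),
    n = length(x)
  ), class = "quadratic_fit")
}

#' @export
print.quadratic_fit <- function(x, ...) {
  co <- x$coefficients
  cat(sprintf("Quadratic fit (n = %d): y = %.4g + %.4g x + %.4g x^2, R2 = %.3f\n",
              x$n, co[1], co[2], co[3], x$r2))
  if (!is.na(x$x_opt))
    cat(sprintf("  vertex (%s%s): x_opt = %.1f\n", x$opt_kind,
                if (x$extrapolated) ", extrapolated" else "", x$x_opt))
  invisible(x)
}

#' Linear dose-response fit
#'
#' OLS line with slope, intercept, R2 and the two-sided p-value of the
#' slope.
#'
#' @param x Predictor (>= 3 points with non-zero variance).
#' @param y Response.
#' @return Object of class `linear_fit`: list with `slope`, `intercept`,
#'   `r2`, `p_value`, `n`.
#' @export
fit_linear <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop_fit("fit_linear: need >= 3 points")
  if (stats::var(x) == 0) stop_fit("fit_linear: zero variance in x")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  sst <- sum((y - mean(y))^2)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 0,
                 p_value = if (nrow(sm$coefficients) > 1)
                   sm$coefficients[2, 4] else NA_real_,
                 n = length(x)),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("Linear fit (n = %d): y = %.4g + %.4g x, R2 = %.3f, p = %.3g\n",
              x$n, x$intercept, x$slope, x$r2, x$p_value))
  invisible(x)
}

#' One-way fixed-effects ANOVA
#'
#' F = MSB/MSW with (k - 1, N - k) degrees of freedom, via [stats::aov()].
#'
#' @param groups List of numeric vectors, one per treatment group; at
#'   least 2 groups with at least 2 values each.
#' @return Data frame with one row: `term`, `df1`, `df2`, `F`, `p`.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("one_way_anova: need >= 2 groups")
  if (any(vapply(groups, length, 1L) < 2))
    stop("one_way_anova: every group needs >= 2 values")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  tab <- summary(stats::aov(y ~ g))[[1]]
  data.frame(term = "group", df1 = tab$Df[1], df2 = tab$Df[2],
             F = tab$`F value`[1], p = tab$`Pr(>F)`[1],
             stringsAsFactors = FALSE)
}

#' Balanced two-way fixed-effects ANOVA
#'
#' Standard balanced decomposition with interaction, via [stats::aov()].
#' Only balanced complete designs are accepted (the chamber design is
#' balanced); this sidesteps sums-of-squares type ambiguity.
#'
#' @param values Numeric response vector.
#' @param factor_a,factor_b Factors of the same length as `values` (e.g.
#'   CO2 level and leaf surface).
#' @return Data frame with rows for `factor_a`, `factor_b`,
#'   `interaction`; columns `term`, `df1`, `df2`, `F`, `p`.
#' @export
two_way_anova <- function(values, factor_a, factor_b) {
  a <- factor(factor_a); b <- factor(factor_b)
  stopifnot(length(values) == length(a), length(values) == length(b))
  counts <- table(a, b)
  if (any(counts == 0))
    stop("two_way_anova: missing cell(s); design must be complete")
  if (length(unique(as.vector(counts))) != 1)
    stop("two_way_anova: unbalanced design; aggregate to equal replication first")
  if (counts[1] < 2)
    stop("two_way_anova: need >= 2 replicates per cell")
  tab <- summary(stats::aov(values ~ a * b))[[1]]
  df2 <- tab$Df[4]
  data.frame(term = c("factor_a", "factor_b", "interaction"),
             df1 = tab$Df[1:3], df2 = df2,
             F = tab$`F value`[1:3], p = tab$`Pr(>F)`[1:3],
             stringsAsFactors = FALSE)
}
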
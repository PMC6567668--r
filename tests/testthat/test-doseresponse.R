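test_that("quadratic fits recover exact vertices", {
  x <- c(400, 600, 800, 1000, 1200, 1400, 1600)
  f1 <- fit_quadratic(x, (x - 600)^2 + 3)
  expect_equal(f1$x_opt, 600, tolerance = 1e-8)
  expect_equal(f1$opt_kind, "minimum")
  expect_equal(f1$r2, 1, tolerance = 1e-12)
  f2 <- fit_quadratic(x, -x^2 + 1800 * x)
  expect_equal(f2$x_opt, 900, tolerance = 1e-8)
  expect_equal(f2$opt_kind, "maximum")
  expect_error(fit_quadratic(c(1, 1, 2, 2), c(1, 2, 3, 4)),
               class = "soyco2_fit_error")
})

test_that("quadratic vertex is shift-equivariant and scale-invariant in y", {
  set.seed(14)
  x <- seq(400, 1600, by = 200)
  y <- -(x - 900)^2 / 500 + 20 + rnorm(length(x), 0, 0.5)
  f <- fit_quadratic(x, y)
  f_shift <- fit_quadratic(x + 250, y)
  expect_equal(f_shift$x_opt, f$x_opt + 250, tolerance = 1e-6)
  f_scale <- fit_quadratic(x, 7 * y)
  expect_equal(f_scale$x_opt, f$x_opt, tolerance = 1e-6)
  expect_equal(f_scale$r2, f$r2, tolerance = 1e-10)
})

test_that("noisy parabolas yield vertices within 10% of truth", {
  set.seed(22)
  x <- rep(seq(400, 1600, by = 200), each = 5)
  errs <- vapply(1:20, function(i) {
    y <- -(x - 900)^2 / 1000 + 25
    y <- y + rnorm(length(y), 0, 0.05 * diff(range(y)))
    abs(fit_quadratic(x, y)$x_opt - 900) / 900
  }, numeric(1))
  expect_lt(median(errs), 0.10)
})

test_that("extrapolated vertices are flagged, not suppressed", {
  x <- seq(400, 1600, by = 200)
  f <- fit_quadratic(x, -(x - 5000)^2 / 1e4)
  expect_true(f$extrapolated)
  expect_equal(f$x_opt, 5000, tolerance = 1e-6)
})

test_that("linear fits report slope, r2 and slope p-value", {
  x <- 1:10
  f <- suppressWarnings(fit_linear(x, 2 * x + 1))  # exact fit trips summary.lm
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_equal(f$r2, 1, tolerance = 1e-12)
  fc <- suppressWarnings(fit_linear(x, rep(4, 10)))
  expect_equal(fc$slope, 0, tolerance = 1e-12)
  expect_equal(fc$r2, 0)
  expect_error(fit_linear(rep(3, 5), 1:5), class = "soyco2_fit_error")
})

test_that("linear slope CIs cover the truth at the nominal rate", {
  set.seed(33)
  x <- seq(0, 10, length.out = 20)
  cover <- vapply(1:200, function(i) {
    y <- 1 + 2 * x + rnorm(20)
    fit <- lm(y ~ x)
    ci <- confint(fit)[2, ]
    ci[1] <= 2 && 2 <= ci[2]
  }, logical(1))
  expect_gt(mean(cover), 0.90)
  expect_lt(mean(cover), 0.99)
})

test_that("one-way ANOVA matches hand-computed sums of squares", {
  res <- one_way_anova(list(c(1, 2, 3), c(4, 5, 6)))
  # SSB = 13.5 on 1 df, SSW = 4 on 4 df -> F = 13.5 / 1 = 13.5
  expect_equal(res$F, 13.5, tolerance = 1e-12)
  expect_equal(res$df1, 1)
  expect_equal(res$df2, 4)
  res0 <- one_way_anova(list(c(1, 3), c(1, 3), c(3, 1)))
  expect_equal(res0$F, 0, tolerance = 1e-12)
  expect_error(one_way_anova(list(c(1, 2, 3))))
  expect_error(one_way_anova(list(c(1, 2), c(3))))
})

test_that("one-way ANOVA with two groups equals the squared t statistic", {
  set.seed(44)
  for (i in 1:10) {
    a <- rnorm(6); b <- rnorm(8, 0.5)
    f <- one_way_anova(list(a, b))$F
    t2 <- t.test(a, b, var.equal = TRUE)$statistic^2
    expect_equal(f, unname(t2), tolerance = 1e-10)
  }
})

test_that("two-way ANOVA decomposes balanced designs", {
  set.seed(55)
  a <- rep(c("400", "800"), each = 10)
  b <- rep(rep(c("adaxial", "abaxial"), each = 5), 2)
  # additive means + tiny noise: interaction F near zero
  y <- ifelse(a == "800", 2, 0) + ifelse(b == "abaxial", 3, 0) +
    rnorm(20, 0, 1e-6)
  res <- two_way_anova(y, a, b)
  expect_equal(res$term, c("factor_a", "factor_b", "interaction"))
  # additive truth: interaction SS is noise-sized, main effects dominate
  expect_lt(res$F[res$term == "interaction"] / res$F[res$term == "factor_a"],
            1e-6)
  expect_gt(res$F[res$term == "factor_a"], 1e6)

  # interaction effect of ~3 sigma is detected most of the time
  det <- vapply(1:30, function(i) {
    y2 <- ifelse(a == "800" & b == "abaxial", 3, 0) + rnorm(20)
    two_way_anova(y2, a, b)$p[3] < 0.05
  }, logical(1))
  expect_gte(mean(det), 0.8)

  expect_error(two_way_anova(y[-1], a[-1], b[-1]), "unbalanced")
  drop_cell <- !(a == "800" & b == "abaxial")
  expect_error(two_way_anova(y[drop_cell], a[drop_cell], b[drop_cell]),
               "missing cell")
})
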
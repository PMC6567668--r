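test_that("stomatal density is count per area", {
  expect_equal(stomatal_density(0, 0.16), 0)
  expect_equal(stomatal_density(16, 0.16), 100)
  # 30 pooled fields of 0.16 mm2 holding 486 stomata
  expect_equal(stomatal_density(486, 30 * 0.16), 101.25)
  expect_error(stomatal_density(5, 0), class = "soyco2_domain_error")
})

test_that("shape index matches hand evaluations and its circular maximum", {
  r <- 5
  expect_equal(shape_index(pi * r^2, 2 * pi * r), 100 / (2 * sqrt(pi)),
               tolerance = 1e-12)
  expect_equal(round(shape_index(92.6, 40.7), 1), 23.6)
  expect_equal(round(shape_index(133.1, 42.8), 1), 27.0)
  expect_error(shape_index(-1, 10), class = "soyco2_domain_error")
})

test_that("shape index never exceeds the isoperimetric bound", {
  set.seed(5)
  for (i in 1:50) {
    area <- runif(1, 10, 500)
    perim <- sqrt(4 * pi * area) * runif(1, 1, 3)  # isoperimetric-valid
    expect_lte(shape_index(area, perim), 100 / (2 * sqrt(pi)) + 1e-9)
  }
})

test_that("area index follows the literal unit-converted formula", {
  expect_equal(area_index(0, 100), 0)
  expect_equal(area_index(16.8, 92.6), 0.155568)
  expect_equal(round(area_index(101.3, 133.1), 3), 1.348)
  # linear in density and in mean area
  expect_equal(area_index(2 * 16.8, 92.6), 2 * area_index(16.8, 92.6))
  expect_equal(area_index(16.8, 3 * 92.6), 3 * area_index(16.8, 92.6))
  # scale factor surfaces table conventions explicitly
  expect_equal(area_index(16.8, 92.6, scale = 60),
               60 * area_index(16.8, 92.6))
  expect_error(area_index(-1, 50), class = "soyco2_domain_error")
})

test_that("percent change reproduces treatment-table contrasts", {
  expect_equal(percent_change(92.6, 126.4), 37)
  expect_equal(percent_change(16.8, 7.3), -57)
  expect_equal(percent_change(5, 5), 0)
  # half-up rounding, not banker's
  expect_equal(percent_change(100, 136.5), 37)
  expect_equal(percent_change(100, 63.5), -37)  # -36.5 rounds away from zero
  expect_error(percent_change(0, 5), class = "soyco2_domain_error")
})

test_that("percent change has opposite signs under reversal and is unit-free", {
  set.seed(9)
  for (i in 1:20) {
    a <- runif(1, 1, 100); b <- runif(1, 1, 100)
    f <- percent_change(a, b, 6); g <- percent_change(b, a, 6)
    if (abs(a - b) > 1e-6) expect_true(sign(f) == -sign(g))
    expect_equal(percent_change(1000 * a, 1000 * b, 6), f)
  }
})

test_that("adaxial/abaxial ratio divides surface values", {
  expect_equal(round(adaxial_abaxial_ratio(16.8, 101.3), 3), 0.166)
  expect_equal(adaxial_abaxial_ratio(7, 7), 1)
  expect_equal(adaxial_abaxial_ratio(0, 12), 0)
  expect_error(adaxial_abaxial_ratio(1, 0), class = "soyco2_domain_error")
})

test_that("SSI aggregation order changes results by < 10% at CV <= 0.3", {
  set.seed(101)
  sdlog <- sqrt(log(1 + 0.3^2))
  area <- rlnorm(500, log(100) - sdlog^2 / 2, sdlog)
  perim <- 100 * sqrt(area) / 24 * rlnorm(500, 0, 0.05)  # SSI ~ 24%
  mor <- mean(shape_index(area, perim))
  rom <- shape_index(mean(area), mean(perim))
  expect_lt(abs(mor - rom) / rom, 0.10)
})

test_that("field summaries aggregate morphology and counts per surface", {
  morph <- data.frame(
    surface = rep(c("adaxial", "abaxial"), each = 4),
    length_um = c(9, 10, 9, 10, 9.5, 9.5, 9.5, 9.5),
    width_um = rep(2.5, 8),
    area_um2 = c(90, 100, 95, 105, 130, 135, 130, 133),
    perimeter_um = c(40, 42, 41, 40, 43, 42, 43, 44))
  fields <- data.frame(
    surface = c("adaxial", "adaxial", "abaxial"),
    n_stomata = c(3, 2, 16),
    field_area_mm2 = c(0.16, 0.16, 0.16))
  s <- stomatal_field_summary(morph, fields)
  ad <- s[s$surface == "adaxial", ]
  expect_equal(ad$density_mm2, 5 / 0.32)
  expect_equal(ad$area_um2, mean(c(90, 100, 95, 105)))
  expect_equal(ad$ssi_pct, mean(shape_index(c(90, 100, 95, 105), c(40, 42, 41, 40))))
  expect_equal(ad$sai_pct, area_index(5 / 0.32, 97.5))
  expect_equal(nrow(s), 2)
})
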
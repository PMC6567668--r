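test_that("forward model reproduces hand-evaluated limb rates", {
  p <- ref_params()
  # at ci = gamma_star the gross term vanishes: A = -rd on either limb
  at_gamma <- fvcb_assimilation(p, 42.75)
  expect_equal(at_gamma$an, -1.5, tolerance = 1e-12)

  # ci = 300: Ac = 100*257.25/(300 + 404.9*(1+210/278.4)) - 1.5 = 23.96,
  # Aj = 150*257.25/(4*300+8*42.75) - 1.5 = 23.52; RuBP limb is limiting
  km <- 404.9 * (1 + 210 / 278.4)
  ac <- 100 * (300 - 42.75) / (300 + km) - 1.5
  aj <- 150 * (300 - 42.75) / (4 * 300 + 8 * 42.75) - 1.5
  row <- fvcb_assimilation(p, 300)
  expect_equal(row$an, aj, tolerance = 1e-12)
  expect_equal(row$limb, "rubp")
  expect_equal(round(ac, 2), 23.96)
  expect_equal(round(aj, 2), 23.52)

  # saturating ci: A -> j/4 - rd = 36
  expect_equal(fvcb_assimilation(p, 1e8)$an, 36, tolerance = 1e-4)

  expect_error(fvcb_assimilation(p, -5), class = "soyco2_domain_error")
  expect_error(fvcb_params(vcmax = -1, j = 150, rd = 1),
               class = "soyco2_domain_error")
})

test_that("assimilation is monotone in ci above the compensation point", {
  p <- ref_params()
  ci <- seq(45, 2000, by = 5)
  an <- fvcb_assimilation(p, ci)$an
  expect_true(all(diff(an) >= -1e-12))
  # and each limb individually is strictly increasing
  ac <- p$vcmax * (ci - p$gamma_star) / (ci + p$kc * (1 + p$o / p$ko)) - p$rd
  aj <- p$j * (ci - p$gamma_star) / (4 * ci + 8 * p$gamma_star) - p$rd
  expect_true(all(diff(ac) > 0))
  expect_true(all(diff(aj) > 0))
})

test_that("noiseless curves round-trip through fit_aci exactly", {
  for (truth in list(ref_params(), fvcb_params(60, 120, 0.8),
                     fvcb_params(150, 200, 2.5))) {
    crv <- aci_curve(fvcb_assimilation(truth, ref_steps())[, c("ci", "an")])
    fit <- fit_aci(crv)
    expect_lt(abs(fit$params$vcmax - truth$vcmax) / truth$vcmax, 1e-4)
    expect_lt(abs(fit$params$j - truth$j) / truth$j, 1e-4)
    expect_lt(abs(fit$params$rd - truth$rd) / max(truth$rd, 1), 1e-4)
    expect_equal(fit$r2, 1, tolerance = 1e-8)
    expect_gte(sum(fit$limb_labels == "rubisco"), 3)
    expect_gte(sum(fit$limb_labels == "rubp"), 3)
  }
})

test_that("fit_aci honours the measured-rd policy", {
  truth <- ref_params()
  crv <- generate_aci_curve(truth, ref_steps(), noise_sd = 0.3, seed = 7,
                            growth_co2 = 400)
  fit <- fit_aci(crv, rd = "measured")
  expect_equal(fit$params$rd, truth$rd)
  expect_lt(abs(fit$params$vcmax - 100) / 100, 0.05)
})

test_that("fit_aci rejects short curves and missing rd_measured", {
  p <- ref_params()
  short <- aci_curve(fvcb_assimilation(p, c(50, 150, 300, 700, 1500))[, c("ci", "an")])
  expect_error(fit_aci(short), class = "soyco2_fit_error")
  crv <- aci_curve(fvcb_assimilation(p, ref_steps())[, c("ci", "an")])
  expect_error(fit_aci(crv, rd = "measured"), class = "soyco2_fit_error")
})

test_that("median parameter recovery error stays below 5% under noise", {
  truth <- ref_params()
  errs <- t(vapply(1:40, function(i) {
    crv <- generate_aci_curve(truth, ref_steps(), noise_sd = 0.5, seed = 1000 + i)
    fit <- fit_aci(crv)
    c(abs(fit$params$vcmax - 100) / 100, abs(fit$params$j - 150) / 150)
  }, numeric(2)))
  expect_lt(median(errs[, 1]), 0.05)
  expect_lt(median(errs[, 2]), 0.05)
  # errors shrink as noise goes to zero
  errs0 <- vapply(1:10, function(i) {
    crv <- generate_aci_curve(truth, ref_steps(), noise_sd = 0.05, seed = 2000 + i)
    abs(fit_aci(crv)$params$vcmax - 100) / 100
  }, numeric(1))
  expect_lt(median(errs0), median(errs[, 1]))
})

test_that("WUE is An/Tr with a guarded domain", {
  expect_equal(compute_wue(20, 4), 5)
  expect_equal(compute_wue(0, 3), 0)
  expect_equal(compute_wue(23.52, 5.6), 4.2)
  expect_error(compute_wue(10, 0), class = "soyco2_domain_error")
})

test_that("jmax_from_j inverts the non-rectangular hyperbola", {
  expect_equal(jmax_from_j(150, 1500, theta = 0.9, alpha = 0.3), 157.5)
  # theta -> 1 with j = alpha*ppfd/2 returns j itself
  expect_equal(jmax_from_j(225, 1500, theta = 1 - 1e-12, alpha = 0.3), 225,
               tolerance = 1e-6)
  expect_error(jmax_from_j(450, 1500, alpha = 0.3),
               class = "soyco2_domain_error")
})
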
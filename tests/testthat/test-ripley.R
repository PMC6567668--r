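test_that("two-point window example matches the closed form", {
  pp <- point_pattern(c(0.4, 0.6), c(0.5, 0.5), ppwindow(1, 1))
  expect_equal(ripley_k(pp, 0.25, "none")$khat, 1.0)
  # translation: overlap of unit square shifted by 0.2 is 0.8 -> weight 1.25
  expect_equal(ripley_k(pp, 0.25, "translation")$khat, 1.25)
  expect_equal(ripley_k(pp, 0, "none")$khat, 0)
  expect_error(ripley_k(point_pattern(0.5, 0.5, ppwindow(1, 1)), 0.2),
               class = "soyco2_fit_error")
})

test_that("ripley_k equals the brute-force double loop for small n", {
  set.seed(31)
  for (rep in 1:6) {
    n <- sample(3:10, 1)
    w <- ppwindow(runif(1, 50, 400), runif(1, 50, 400))
    pp <- point_pattern(runif(n, 0, w$width), runif(n, 0, w$height), w)
    d <- seq(0, min(w$width, w$height) / 2, length.out = 9)
    for (corr in c("none", "translation")) {
      expect_equal(ripley_k(pp, d, corr)$khat, brute_force_k(pp, d, corr),
                   tolerance = 1e-12)
    }
  }
})

test_that("khat is non-decreasing and distances beyond validity are truncated", {
  set.seed(12)
  pp <- simulate_csr(30, ppwindow(400, 400))
  k <- ripley_k(pp, default_distance_grid())
  expect_true(all(diff(k$khat) >= 0))
  expect_warning(k2 <- ripley_k(pp, c(50, 100, 300)), "truncating")
  expect_equal(k2$d, c(50, 100))
})

test_that("the L-transform has its closed-form anchors", {
  d <- seq(0, 50, by = 5)
  expect_equal(l_transform(pi * d^2, d), rep(0, length(d)))
  expect_equal(l_transform(0, 10), -10)
  expect_equal(l_transform(4 * pi, 1), 1)
  expect_error(l_transform(-1, 1), "negative")
})

test_that("K and L scale covariantly with the coordinates", {
  set.seed(77)
  w <- ppwindow(200, 200)
  pp <- simulate_csr(25, w)
  s <- 3
  pp_s <- point_pattern(pp$x * s, pp$y * s, ppwindow(200 * s, 200 * s))
  d <- seq(2, 80, by = 2)
  k1 <- ripley_k(pp, d, "translation")$khat
  k2 <- ripley_k(pp_s, d * s, "translation")$khat
  expect_equal(k2, s^2 * k1, tolerance = 1e-10)
  expect_equal(l_transform(k2, d * s), s * l_transform(k1, d),
               tolerance = 1e-10)
})

test_that("CSR envelopes bracket zero and demand enough simulations", {
  env <- csr_envelope(50, ppwindow(1, 1), seq(0.02, 0.25, by = 0.02),
                      n_sims = 60, seed = 4)
  expect_true(all(env$envelope_low <= 0))
  expect_true(all(env$envelope_high >= 0))
  expect_error(csr_envelope(50, ppwindow(1, 1), 0.1, n_sims = 10),
               class = "soyco2_domain_error")
  # determinism under seed
  env2 <- csr_envelope(50, ppwindow(1, 1), seq(0.02, 0.25, by = 0.02),
                       n_sims = 60, seed = 4)
  expect_identical(env, env2)
})

test_that("mean L-d under CSR stays near zero (translation correction)", {
  set.seed(88)
  d <- seq(10, 100, by = 10)
  w <- ppwindow(400, 400)
  lsum <- rowMeans(vapply(1:200, function(i) {
    l_transform(ripley_k(simulate_csr(50, w), d)$khat, d)
  }, numeric(length(d))))
  expect_true(all(abs(lsum) <= pmax(0.05 * d, 1)))
})

test_that("scale classification splits regular/random/clustered correctly", {
  d <- seq(2, 20, by = 2)
  env <- data.frame(d = d, envelope_low = -1, envelope_high = 1)
  cls <- classify_scales(rep(0, 10), env, d)
  expect_true(all(cls$labels == "random"))
  expect_length(cls$regular_range, 0)

  lhat <- c(-12, -12, -12, 0, 0, 2, 2, -2, 0, 0)
  cls2 <- classify_scales(lhat, env, d)
  expect_equal(cls2$labels[1:3], rep("regular", 3))
  expect_equal(cls2$labels[6:7], rep("clustered", 2))
  expect_equal(cls2$regular_range, c(2, 6))  # longest contiguous regular run
  expect_error(classify_scales(rep(0, 9), env, d), "grid mismatch")
})

test_that("hard-core patterns are detected as regular at short range", {
  hits <- vapply(1:10, function(i) {
    pat <- simulate_hardcore(40, ppwindow(400, 400), r_min = 30,
                             seed = 500 + i)
    res <- ripley_analysis(pat, seq(0, 100, by = 2), n_sims = 60,
                           seed = 900 + i)
    length(res$regular_range) > 0 && res$regular_range[1] <= 30
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("clustered patterns exceed the upper envelope at small scales", {
  hits <- vapply(1:10, function(i) {
    pat <- simulate_cluster(5e-5, 8, sigma = 10, ppwindow(400, 400),
                            seed = 300 + i)
    if (pat$n < 10) return(NA)
    res <- ripley_analysis(pat, seq(0, 100, by = 4), n_sims = 60,
                           seed = 700 + i)
    any(res$labels == "clustered")
  }, logical(1))
  expect_gte(mean(hits, na.rm = TRUE), 0.9)
})
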
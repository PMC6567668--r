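# Shared fixtures and independent oracles for the test suite.

ref_params <- function() fvcb_params(vcmax = 100, j = 150, rd = 1.5)

ref_steps <- function() default_ci_steps()

# Independent brute-force Ripley K oracle: explicit double loop over
# ordered pairs, no sorting/cumsum tricks. Used to validate ripley_k().
brute_force_k <- function(pattern, distances, correction = "none") {
  w <- pattern$window
  n <- pattern$n
  out <- numeric(length(distances))
  for (di in seq_along(distances)) {
    acc <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      dx <- pattern$x[j] - pattern$x[i]
      dy <- pattern$y[j] - pattern$y[i]
      if (sqrt(dx^2 + dy^2) <= distances[di]) {
        wij <- if (correction == "translation")
          w$area / ((w$width - abs(dx)) * (w$height - abs(dy))) else 1
        acc <- acc + wij
      }
    }
    out[di] <- w$area / (n * (n - 1)) * acc
  }
  out
}

# Small synthetic study used by several files (cheap: 3 treatments x 2 pots)
small_study <- function(seed = 42) {
  generate_study(study_config(
    treatments = c(400, 600, 800, 1000), pots_per_treatment = 2,
    fields_per_surface = 1, seed = seed))
}
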
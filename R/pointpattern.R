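#' Rectangular observation window
#'
#' @param width,height Window dimensions (um), > 0. Origin is (0, 0) at
#'   the lower-left corner. The default 400 x 400 um window has the
#'   0.16 mm2 area of a standard microscope field.
#' @return An object of class `ppwindow`.
#' @export
ppwindow <- function(width = 400, height = 400) {
  if (width <= 0 || height <= 0) stop_domain("ppwindow: dimensions must be > 0")
  structure(list(width = width, height = height, area = width * height),
            class = "ppwindow")
}

#' Planar point pattern
#'
#' Stomatal (x, y) coordinates inside a rectangular window. Exactly
#' coincident points are jittered by at most `jitter` (default 0.01 um)
#' with a warning, since pair distances of zero are undefined for K.
#'
#' @param x,y Coordinates (um), inside the window.
#' @param window A [ppwindow()].
#' @param surface Optional `"adaxial"` or `"abaxial"` tag.
#' @param treatment_co2 Optional growth CO2 (ppm) tag.
#' @param jitter Maximum jitter applied to duplicated coordinates (um).
#' @return An object of class `point_pattern`.
#' @export
point_pattern <- function(x, y, window = ppwindow(), surface = NA_character_,
                          treatment_co2 = NA_real_, jitter = 0.01) {
  stopifnot(inherits(window, "ppwindow"), length(x) == length(y))
  if (length(x) > 0 &&
      (any(x < 0 | x > window$width) || any(y < 0 | y > window$height)))
    stop_domain("point_pattern: points outside the window")
  dup <- duplicated(cbind(x, y))
  if (any(dup)) {
    warning(sprintf("point_pattern: jittering %d duplicated coordinate(s) by <= %g um",
                    sum(dup), jitter))
    x[dup] <- pmin(pmax(x[dup] + stats::runif(sum(dup), -jitter, jitter), 0),
                   window$width)
    y[dup] <- pmin(pmax(y[dup] + stats::runif(sum(dup), -jitter, jitter), 0),
                   window$height)
  }
  structure(list(x = x, y = y, n = length(x), window = window,
                 surface = surface, treatment_co2 = treatment_co2),
            class = "point_pattern")
}

#' @export
print.point_pattern <- function(x, ...) {
  cat(sprintf("Point pattern: %d points in %.0f x %.0f um window", x$n,
              x$window$width, x$window$height))
  if (!is.na(x$surface)) cat(sprintf(" [%s", x$surface)) else cat(" [")
  if (!is.na(x$treatment_co2)) cat(sprintf(", %g ppm", x$treatment_co2))
  cat("]\n")
  invisible(x)
}

#' Simulate complete spatial randomness (CSR)
#'
#' `n` points i.i.d. uniform on the window (a binomial process).
#'
#' @param n Number of points (>= 0).
#' @param window A [ppwindow()].
#' @param seed Optional integer seed for reproducibility.
#' @return A [point_pattern()].
#' @export
simulate_csr <- function(n, window = ppwindow(), seed = NULL) {
  if (n < 0) stop_domain("simulate_csr: n must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  point_pattern(stats::runif(n, 0, window$width),
                stats::runif(n, 0, window$height), window)
}

#' Simulate a hard-core (inhibition) pattern
#'
#' Simple sequential inhibition: points are proposed uniformly and
#' accepted only if at least `r_min` from every accepted point, until `n`
#' points are placed. Generates regular patterns such as stomatal
#' arrangements, which avoid each other at short range.
#'
#' @param n Number of points.
#' @param window A [ppwindow()].
#' @param r_min Minimum permitted pairwise distance (um).
#' @param seed Optional integer seed.
#' @param max_attempts Proposal budget before giving up.
#' @return A [point_pattern()] whose minimum pairwise distance is >= r_min.
#' @export
simulate_hardcore <- function(n, window = ppwindow(), r_min, seed = NULL,
                              max_attempts = 10000 * max(n, 1)) {
  if (n < 0 || r_min < 0) stop_domain("simulate_hardcore: n, r_min must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  xs <- numeric(0); ys <- numeric(0); attempts <- 0L
  while (length(xs) < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop_fit(sprintf(
        "simulate_hardcore: packing failed (%d of %d points after %d attempts)",
        length(xs), n, attempts))
    px <- stats::runif(1, 0, window$width)
    py <- stats::runif(1, 0, window$height)
    if (length(xs) == 0 || all((xs - px)^2 + (ys - py)^2 >= r_min^2)) {
      xs <- c(xs, px); ys <- c(ys, py)
    }
  }
  point_pattern(xs, ys, window)
}

#' Simulate a Thomas cluster process
#'
#' Poisson parents at `parent_intensity`, each with Poisson(`mean_offspring`)
#' children displaced by an isotropic Gaussian of sd `sigma`; children
#' falling outside the window are discarded. A clustered control for
#' pattern classification tests.
#'
#' @param parent_intensity Parents per um2, > 0.
#' @param mean_offspring Mean children per parent, > 0.
#' @param sigma Gaussian displacement sd (um), > 0.
#' @param window A [ppwindow()].
#' @param seed Optional integer seed.
#' @return A [point_pattern()].
#' @export
simulate_cluster <- function(parent_intensity, mean_offspring, sigma,
                             window = ppwindow(), seed = NULL) {
  if (parent_intensity <= 0 || mean_offspring <= 0 || sigma <= 0)
    stop_domain("simulate_cluster: all parameters must be > 0")
  if (!is.null(seed)) set.seed(seed)
  n_parents <- stats::rpois(1, parent_intensity * window$area)
  px <- stats::runif(n_parents, 0, window$width)
  py <- stats::runif(n_parents, 0, window$height)
  kids <- stats::rpois(n_parents, mean_offspring)
  cx <- rep(px, kids) + stats::rnorm(sum(kids), 0, sigma)
  cy <- rep(py, kids) + stats::rnorm(sum(kids), 0, sigma)
  keep <- cx >= 0 & cx <= window$width & cy >= 0 & cy <= window$height
  point_pattern(cx[keep], cy[keep], window)
}
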
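#' Default Ripley distance grid
#'
#' 0 to 200 um in 2 um steps, the scale range over which stomatal
#' patterns are typically analysed.
#' @return Numeric vector of distances (um).
#' @export
default_distance_grid <- function() seq(0, 200, by = 2)

#' Ripley's K-function estimate
#'
#' \deqn{\hat K(d) = \frac{|W|}{n(n-1)} \sum_{i \ne j} w_{ij} 1(d_{ij} \le d)}
#' with `w_ij = 1` (no edge correction) or the translation correction
#' `w_ij = |W| / |W \cap W_{x_j - x_i}|`, where the overlap of the window
#' with its translate by the pair displacement is
#' `(width - |dx|)(height - |dy|)`. Under CSR, K(d) = pi d^2.
#'
#' @param pattern A [point_pattern()] with n >= 2.
#' @param distances Non-negative distance grid (um). Distances beyond half
#'   the shorter window side (where the translation correction loses
#'   validity) are truncated with a warning.
#' @param correction `"translation"` (default) or `"none"`.
#' @return Data frame with columns `d` and `khat` (um2).
#' @export
ripley_k <- function(pattern, distances = default_distance_grid(),
                     correction = c("translation", "none")) {
  stopifnot(inherits(pattern, "point_pattern"))
  correction <- match.arg(correction)
  n <- pattern$n
  if (n < 2) stop_fit("ripley_k: need at least 2 points")
  w <- pattern$window
  dmax_valid <- min(w$width, w$height) / 2
  if (any(distances > dmax_valid)) {
    warning(sprintf("ripley_k: truncating distances beyond %.1f um (half the shorter window side)",
                    dmax_valid))
    distances <- distances[distances <= dmax_valid]
  }
  dx <- outer(pattern$x, pattern$x, "-")
  dy <- outer(pattern$y, pattern$y, "-")
  dij <- sqrt(dx^2 + dy^2)
  off <- upper.tri(dij) | lower.tri(dij)
  wij <- if (correction == "translation") {
    w$area / ((w$width - abs(dx)) * (w$height - abs(dy)))
  } else {
    matrix(1, n, n)
  }
  dvec <- dij[off]; wvec <- wij[off]
  ord <- order(dvec)
  dvec <- dvec[ord]
  cw <- cumsum(wvec[ord])
  idx <- findInterval(distances, dvec)
  sums <- ifelse(idx == 0, 0, cw[pmax(idx, 1)])
  data.frame(d = distances, khat = w$area / (n * (n - 1)) * sums)
}

#' L-transform of Ripley's K
#'
#' The variance-stabilised L(d) - d = sqrt(K(d)/pi) - d. Zero under CSR;
#' negative values indicate regularity (inhibition), positive values
#' clustering.
#'
#' @param khat Non-negative K values.
#' @param distances Matching distance grid.
#' @return Numeric vector of L(d) - d (um).
#' @export
l_transform <- function(khat, distances) {
  if (length(khat) != length(distances))
    stop("l_transform: khat and distances lengths differ")
  if (any(khat < 0)) stop("l_transform: negative khat")
  sqrt(khat / pi) - distances
}

#' Monte Carlo CSR envelope for L(d) - d
#'
#' Simulates `n_sims` binomial (fixed-n) CSR patterns in the window and
#' returns the pointwise empirical alpha/2 and 1 - alpha/2 quantiles of
#' L(d) - d at each grid distance. The envelope conditions on the observed
#' number of points rather than an estimated intensity.
#'
#' @param n Observed number of points (>= 2).
#' @param window A [ppwindow()].
#' @param distances Distance grid (um).
#' @param n_sims Number of CSR replicates (>= 20; 100 gives conventional
#'   95% pointwise bounds).
#' @param alpha Two-sided envelope level (default 0.05).
#' @param seed Optional integer seed; results are deterministic given it.
#' @param correction Edge correction passed to [ripley_k()].
#' @return Data frame with columns `d`, `envelope_low`, `envelope_high`.
#' @export
csr_envelope <- function(n, window = ppwindow(),
                         distances = default_distance_grid(), n_sims = 100,
                         alpha = 0.05, seed = NULL,
                         correction = "translation") {
  if (n < 2) stop_fit("csr_envelope: need n >= 2")
  if (n_sims < 20) stop_domain("csr_envelope: insufficient simulations (need >= 20)")
  if (!is.null(seed)) set.seed(seed)
  distances <- distances[distances <= min(window$width, window$height) / 2]
  sims <- vapply(seq_len(n_sims), function(i) {
    p <- point_pattern(stats::runif(n, 0, window$width),
                       stats::runif(n, 0, window$height), window)
    l_transform(ripley_k(p, distances, correction)$khat, distances)
  }, numeric(length(distances)))
  # Weibull (type 6) quantiles: plotting position k/(n+1), so a fresh CSR
  # pattern exceeds the two-sided envelope with probability ~ alpha, which
  # the default (type 7) estimator understates for tail quantiles at n = 100
  qs <- apply(sims, 1, stats::quantile, probs = c(alpha / 2, 1 - alpha / 2),
              names = FALSE, type = 6)
  data.frame(d = distances, envelope_low = qs[1, ], envelope_high = qs[2, ])
}

#' Classify spatial scales against a CSR envelope
#'
#' Labels each grid distance `regular` (L - d below the lower envelope),
#' `clustered` (above the upper envelope) or `random` (inside), and
#' reports the longest contiguous run of `regular` labels as
#' `regular_range = c(d_min, d_max)` (numeric(0) if none).
#'
#' @param lhat L(d) - d values.
#' @param envelope Data frame from [csr_envelope()] on the same grid.
#' @param distances Distance grid (um).
#' @return List with `labels` (character vector) and `regular_range`.
#' @export
classify_scales <- function(lhat, envelope, distances) {
  if (length(lhat) != length(distances) || nrow(envelope) != length(distances) ||
      any(abs(envelope$d - distances) > 1e-9))
    stop("classify_scales: grid mismatch between lhat, envelope and distances")
  labels <- ifelse(lhat < envelope$envelope_low, "regular",
                   ifelse(lhat > envelope$envelope_high, "clustered", "random"))
  reg <- labels == "regular"
  regular_range <- numeric(0)
  if (any(reg)) {
    runs <- rle(reg)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    ix <- which(runs$values)
    best <- ix[which.max(runs$lengths[ix])]
    regular_range <- c(distances[starts[best]], distances[ends[best]])
  }
  list(labels = labels, regular_range = regular_range)
}

#' Full Ripley analysis of one pattern
#'
#' Convenience wrapper: K, L-transform, CSR envelope and per-scale
#' classification in one call.
#'
#' @param pattern A [point_pattern()].
#' @param distances Distance grid (um).
#' @param n_sims,alpha,seed Envelope options, see [csr_envelope()].
#' @param correction Edge correction, see [ripley_k()].
#' @return An object of class `kfunction_result`: list with `distances`,
#'   `khat`, `lhat`, `envelope_low`, `envelope_high`, `labels`,
#'   `regular_range`, `n`.
#' @export
ripley_analysis <- function(pattern, distances = default_distance_grid(),
                            n_sims = 100, alpha = 0.05, seed = NULL,
                            correction = "translation") {
  k <- ripley_k(pattern, distances, correction)
  lhat <- l_transform(k$khat, k$d)
  env <- csr_envelope(pattern$n, pattern$window, k$d, n_sims, alpha, seed,
                      correction)
  cls <- classify_scales(lhat, env, k$d)
  structure(list(distances = k$d, khat = k$khat, lhat = lhat,
                 envelope_low = env$envelope_low,
                 envelope_high = env$envelope_high,
                 labels = cls$labels, regular_range = cls$regular_range,
                 n = pattern$n),
            class = "kfunction_result")
}

#' @export
print.kfunction_result <- function(x, ...) {
  cat(sprintf("Ripley analysis: n = %d, %d distances up to %.0f um\n",
              x$n, length(x$distances), max(x$distances)))
  tab <- table(factor(x$labels, c("regular", "random", "clustered")))
  cat(sprintf("  scales: %d regular, %d random, %d clustered\n",
              tab[[1]], tab[[2]], tab[[3]]))
  if (length(x$regular_range))
    cat(sprintf("  longest regular run: %.0f-%.0f um\n",
                x$regular_range[1], x$regular_range[2]))
  invisible(x)
}
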
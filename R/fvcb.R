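#' FvCB parameter set
#'
#' Bundles the parameters of the Farquhar--von Caemmerer--Berry (FvCB) model
#' of C3 photosynthesis: the maximum Rubisco carboxylation rate `vcmax`, the
#' electron transport rate `j` at measurement light, day respiration `rd`,
#' and the Rubisco kinetic constants at 25 degC. With infinite mesophyll
#' conductance (Cc = Ci) net assimilation is the minimum of the
#' Rubisco-limited and RuBP-regeneration-limited rates:
#' \deqn{A_c = V_{cmax} (C_i - \Gamma^*) / (C_i + K_c (1 + O/K_o)) - R_d}
#' \deqn{A_j = J (C_i - \Gamma^*) / (4 C_i + 8 \Gamma^*) - R_d}
#'
#' @param vcmax Maximum carboxylation rate (umol m-2 s-1).
#' @param j Electron transport rate (umol e- m-2 s-1).
#' @param rd Day respiration (umol m-2 s-1).
#' @param gamma_star CO2 compensation point without Rd (ubar), 25 degC default.
#' @param kc Michaelis constant for CO2 (ubar).
#' @param ko Michaelis constant for O2 (mbar).
#' @param o Oxygen partial pressure (mbar).
#' @return An object of class `fvcb_params`.
#' @export
fvcb_params <- function(vcmax, j, rd, gamma_star = 42.75, kc = 404.9,
                        ko = 278.4, o = 210) {
  vals <- c(vcmax = vcmax, j = j, rd = rd, gamma_star = gamma_star,
            kc = kc, ko = ko, o = o)
  if (any(!is.finite(vals))) stop_domain("fvcb_params: non-finite parameter")
  if (any(vals[c("vcmax", "j", "gamma_star", "kc", "ko", "o")] <= 0))
    stop_domain("fvcb_params: vcmax, j and kinetic constants must be > 0")
  if (rd < 0) stop_domain("fvcb_params: rd must be >= 0")
  structure(as.list(vals), class = "fvcb_params")
}

#' @export
print.fvcb_params <- function(x, ...) {
  cat(sprintf(
    "FvCB parameters: Vcmax = %.2f, J = %.2f, Rd = %.2f umol m-2 s-1\n",
    x$vcmax, x$j, x$rd))
  cat(sprintf("  kinetics (25 degC): Gamma* = %.2f ubar, Kc = %.1f ubar, Ko = %.1f mbar, O = %.0f mbar\n",
              x$gamma_star, x$kc, x$ko, x$o))
  invisible(x)
}

# Effective Michaelis-Menten constant Km = Kc (1 + O/Ko), ubar
fvcb_km <- function(params) params$kc * (1 + params$o / params$ko)

# Per-limb gross carboxylation efficiency terms (assimilation = coef * rate - rd)
fvcb_xc <- function(ci, params) (ci - params$gamma_star) / (ci + fvcb_km(params))
fvcb_xj <- function(ci, params) (ci - params$gamma_star) / (4 * ci + 8 * params$gamma_star)

#' Forward FvCB assimilation
#'
#' Evaluates the FvCB model at intercellular CO2 `ci`, returning the
#' minimum of the Rubisco-limited and RuBP-regeneration-limited rates and
#' which limb is limiting (ties go to the Rubisco limb).
#'
#' @param params An [fvcb_params()] object.
#' @param ci Intercellular CO2 (ubar), vectorised, all > 0.
#' @return A data frame with columns `ci`, `an` (net assimilation,
#'   umol m-2 s-1) and `limb` (`"rubisco"` or `"rubp"`).
#' @examples
#' p <- fvcb_params(vcmax = 100, j = 150, rd = 1.5)
#' fvcb_assimilation(p, c(100, 300, 1200))
#' @export
fvcb_assimilation <- function(params, ci) {
  stopifnot(inherits(params, "fvcb_params"))
  if (any(!is.finite(ci)) || any(ci <= 0))
    stop_domain("fvcb_assimilation: ci must be finite and > 0")
  ac <- params$vcmax * fvcb_xc(ci, params) - params$rd
  aj <- params$j * fvcb_xj(ci, params) - params$rd
  limb <- ifelse(ac <= aj, "rubisco", "rubp")
  data.frame(ci = ci, an = pmin(ac, aj), limb = limb,
             stringsAsFactors = FALSE)
}

#' Leaf water-use efficiency
#'
#' WUE = An / Tr, the assimilation gained per unit water transpired.
#'
#' @param an Net assimilation (umol CO2 m-2 s-1).
#' @param tr Transpiration (mmol H2O m-2 s-1), must be > 0.
#' @return WUE in umol CO2 / mmol H2O.
#' @export
compute_wue <- function(an, tr) {
  if (any(!is.finite(tr)) || any(tr <= 0))
    stop_domain("compute_wue: tr must be > 0")
  an / tr
}

#' Light saturation correction for J
#'
#' Converts an electron transport rate `j` realised at photon flux `ppfd`
#' into the light-saturated maximum `jmax` by inverting the
#' non-rectangular hyperbola light response with curvature `theta` and
#' effective quantum yield `alpha`. Curves measured at saturating light
#' normally report `j` directly as Jmax; this correction is opt-in.
#'
#' @param j Electron transport rate (umol m-2 s-1).
#' @param ppfd Photon flux density (umol m-2 s-1).
#' @param theta Curvature of the hyperbola, in (0, 1).
#' @param alpha Effective quantum yield (e- per photon).
#' @return jmax (umol m-2 s-1).
#' @export
jmax_from_j <- function(j, ppfd, theta = 0.9, alpha = 0.3) {
  if (theta <= 0 || theta >= 1) stop_domain("jmax_from_j: theta must be in (0, 1)")
  i2 <- alpha * ppfd
  if (any(i2 <= j))
    stop_domain("jmax_from_j: alpha * ppfd must exceed j (light insufficient)")
  j * (i2 - theta * j) / (i2 - j)
}

#' Construct an A-Ci curve
#'
#' An ordered set of gas-exchange points for one leaf, as produced by a
#' LI-6400-style cuvette CO2 ladder. Points are sorted by `ci`; at least
#' six points are required for limb-partition fitting.
#'
#' @param df Data frame with at least columns `ci` (> 0) and `an`; optional
#'   `gs`, `tr`, `ppfd`, `tleaf`, `vpd`.
#' @param growth_co2 Growth CO2 treatment (ppm).
#' @param leaf_id,pot_id Identifiers.
#' @param rd_measured Optional dark respiration measurement (umol m-2 s-1).
#' @return An object of class `aci_curve` (a data frame with metadata
#'   attributes).
#' @export
aci_curve <- function(df, growth_co2 = NA_real_, leaf_id = "leaf1",
                      pot_id = "pot1", rd_measured = NULL) {
  stopifnot(is.data.frame(df), all(c("ci", "an") %in% names(df)))
  if (any(!is.finite(df$ci)) || any(df$ci <= 0))
    stop_domain("aci_curve: ci must be finite and > 0")
  if ("ppfd" %in% names(df) && any(df$ppfd < 0, na.rm = TRUE))
    stop_domain("aci_curve: ppfd must be >= 0")
  df <- df[order(df$ci), , drop = FALSE]
  if (anyDuplicated(df$ci))
    stop_domain("aci_curve: duplicate ci values")
  rownames(df) <- NULL
  structure(df, growth_co2 = growth_co2, leaf_id = leaf_id, pot_id = pot_id,
            rd_measured = rd_measured, class = c("aci_curve", "data.frame"))
}

#' @export
print.aci_curve <- function(x, ...) {
  cat(sprintf("A-Ci curve: leaf %s, pot %s, growth CO2 %s ppm, %d points (Ci %.0f-%.0f)\n",
              attr(x, "leaf_id"), attr(x, "pot_id"),
              format(attr(x, "growth_co2")), nrow(x), min(x$ci), max(x$ci)))
  print(as.data.frame(x), ...)
  invisible(x)
}

# Exact least-squares solve for (vcmax, j, rd) given a limb assignment.
# Conditional on the partition the model is linear:
#   an_i = vcmax * xc_i * [i in rubisco] + j * xj_i * [i in rubp] - rd
# rd is bounded to [rd_lo, rd_hi]; if the unconstrained solution violates a
# bound, refit with rd pinned to that bound (the active-set solution).
fit_partition <- function(ci, an, is_rubisco, params0, rd_policy, rd_fixed,
                          rd_bounds = c(0, 10)) {
  xc <- fvcb_xc(ci, params0) * is_rubisco
  xj <- fvcb_xj(ci, params0) * (!is_rubisco)
  solve_ls <- function(rd = NULL) {
    if (is.null(rd)) {
      X <- cbind(xc = xc, xj = xj, nrd = -1)
      co <- tryCatch(qr.coef(qr(X), an), error = function(e) NULL)
      if (is.null(co) || any(!is.finite(co))) return(NULL)
      list(vcmax = co[[1]], j = co[[2]], rd = co[[3]])
    } else {
      X <- cbind(xc = xc, xj = xj)
      co <- tryCatch(qr.coef(qr(X), an + rd), error = function(e) NULL)
      if (is.null(co) || any(!is.finite(co))) return(NULL)
      list(vcmax = co[[1]], j = co[[2]], rd = rd)
    }
  }
  sol <- if (rd_policy == "measured") solve_ls(rd_fixed) else {
    s <- solve_ls()
    if (!is.null(s) && (s$rd < rd_bounds[1] || s$rd > rd_bounds[2])) {
      lo <- solve_ls(rd_bounds[1]); hi <- solve_ls(rd_bounds[2])
      sse_of <- function(z) if (is.null(z)) Inf else
        sum((z$vcmax * xc + z$j * xj - z$rd - an)^2)
      if (sse_of(lo) <= sse_of(hi)) lo else hi
    } else s
  }
  if (is.null(sol) || sol$vcmax <= 0 || sol$j <= 0) return(NULL)
  pred <- sol$vcmax * xc + sol$j * xj - sol$rd
  sol$sse <- sum((an - pred)^2)
  sol$pred <- pred
  sol
}

#' Fit the FvCB model to an A-Ci curve
#'
#' Estimates Vcmax, J and Rd by exhaustive enumeration of the limb
#' transition: for every candidate transition between consecutive observed
#' Ci values with at least three points on each side, the Rubisco-limited
#' limb is assigned below and the RuBP-regeneration limb above, and
#' (Vcmax, J, Rd) are estimated by exact least squares (the model is linear
#' in the parameters once the partition is fixed). The partition with the
#' smallest residual sum of squares wins; ties break toward the lower
#' transition Ci. With curves measured at saturating light the fitted J is
#' reported as Jmax.
#'
#' @param curve An [aci_curve()].
#' @param kinetics Kinetic constants as an [fvcb_params()]-style list;
#'   only `gamma_star`, `kc`, `ko`, `o` are used. Default: standard 25 degC
#'   values.
#' @param rd Either `"fit"` (estimate Rd jointly, bounded to
#'   `rd_bounds`) or `"measured"` (fix Rd to the curve's `rd_measured`).
#' @param rd_bounds Bounds for fitted Rd (umol m-2 s-1).
#' @param min_points_per_limb Minimum points assigned to each limb.
#' @return An object of class `fvcb_fit`: a list with `params`
#'   ([fvcb_params()]), `transition_ci`, `limb_labels`, `sse`, `r2`,
#'   `n_points`, `fitted`, `residuals`.
#' @examples
#' p <- fvcb_params(100, 150, 1.5)
#' steps <- c(50, 100, 150, 200, 300, 400, 600, 800, 1000, 1200, 1400, 1600)
#' crv <- aci_curve(fvcb_assimilation(p, steps)[, c("ci", "an")])
#' fit_aci(crv)
#' @export
fit_aci <- function(curve, kinetics = NULL, rd = c("fit", "measured"),
                    rd_bounds = c(0, 10), min_points_per_limb = 3) {
  stopifnot(inherits(curve, "aci_curve"))
  rd <- match.arg(rd)
  n <- nrow(curve)
  if (n < 6) stop_fit("fit_aci: insufficient points (need >= 6)")
  rd_fixed <- attr(curve, "rd_measured")
  if (rd == "measured" && is.null(rd_fixed))
    stop_fit("fit_aci: rd = 'measured' but curve has no rd_measured")
  kin <- kinetics %||% list()
  params0 <- fvcb_params(vcmax = 1, j = 1, rd = 0,
                         gamma_star = kin$gamma_star %||% 42.75,
                         kc = kin$kc %||% 404.9,
                         ko = kin$ko %||% 278.4,
                         o = kin$o %||% 210)
  ci <- curve$ci; an <- curve$an
  cuts <- seq(min_points_per_limb, n - min_points_per_limb)
  if (length(cuts) == 0) stop_fit("fit_aci: no admissible limb partition")
  best <- NULL; best_cut <- NA_integer_
  for (k in cuts) {
    sol <- fit_partition(ci, an, seq_len(n) <= k, params0, rd, rd_fixed, rd_bounds)
    if (!is.null(sol) && (is.null(best) || sol$sse < best$sse - 1e-12)) {
      best <- sol; best_cut <- k
    }
  }
  if (is.null(best))
    stop_fit("fit_aci: no partition produced an admissible least-squares fit",
             diagnostics = list(n_points = n))
  sst <- sum((an - mean(an))^2)
  r2 <- if (sst > 0) max(0, min(1, 1 - best$sse / sst)) else 1
  labels <- ifelse(seq_len(n) <= best_cut, "rubisco", "rubp")
  structure(list(
    params = fvcb_params(best$vcmax, best$j, max(best$rd, 0),
                         params0$gamma_star, params0$kc, params0$ko, params0$o),
    transition_ci = mean(ci[best_cut + c(0, 1)]),
    limb_labels = labels,
    sse = best$sse, r2 = r2, n_points = n,
    fitted = best$pred, residuals = an - best$pred,
    growth_co2 = attr(curve, "growth_co2"),
    leaf_id = attr(curve, "leaf_id"), pot_id = attr(curve, "pot_id")
  ), class = "fvcb_fit")
}

#' @export
print.fvcb_fit <- function(x, ...) {
  cat(sprintf("FvCB fit (%d points): Vcmax = %.2f, Jmax = %.2f, Rd = %.2f\n",
              x$n_points, x$params$vcmax, x$params$j, x$params$rd))
  cat(sprintf("  transition Ci = %.1f ubar, SSE = %.4g, R2 = %.4f\n",
              x$transition_ci, x$sse, x$r2))
  invisible(x)
}

#' @export
coef.fvcb_fit <- function(object, ...) {
  c(vcmax = object$params$vcmax, jmax = object$params$j, rd = object$params$rd)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
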
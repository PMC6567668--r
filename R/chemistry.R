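#' Tissue carbon-to-nitrogen ratio
#'
#' @param c Carbon concentration (mg g-1 DW).
#' @param n Nitrogen concentration (mg g-1 DW), > 0.
#' @return C/N (dimensionless). Tables conventionally print 2 decimals.
#' @export
cn_ratio <- function(c, n) {
  if (any(n <= 0)) stop_domain("cn_ratio: n must be > 0")
  c / n
}

#' Total non-structural carbohydrates
#'
#' TNC = soluble sugar + starch.
#'
#' @param soluble_sugar,starch Concentrations (mg g-1 DW), >= 0.
#' @return TNC (mg g-1 DW).
#' @export
total_nonstructural_carbohydrate <- function(soluble_sugar, starch) {
  if (any(soluble_sugar < 0) || any(starch < 0))
    stop_domain("total_nonstructural_carbohydrate: inputs must be >= 0")
  soluble_sugar + starch
}

#' Treatment summary of tissue chemistry
#'
#' Mean and SD of C, N, C/N, soluble sugar, starch and TNC per
#' (tissue, treatment) cell. Derived quantities (C/N, TNC) are computed
#' per sample first, then averaged. Cells with a single sample get
#' `NA` SDs; empty cells are simply absent.
#'
#' @param samples Data frame with columns `tissue`, `treatment_co2_ppm`,
#'   `c_mg_g`, `n_mg_g`, `soluble_sugar_mg_g`, `starch_mg_g` (and
#'   optionally `pot_id`).
#' @return Data frame with one row per (tissue, treatment), columns
#'   `tissue`, `treatment_co2_ppm`, `n_samples`, then `<trait>_mean` and
#'   `<trait>_sd` for c, n, cn, soluble_sugar, starch, tnc.
#' @export
chemistry_treatment_summary <- function(samples) {
  req <- c("tissue", "treatment_co2_ppm", "c_mg_g", "n_mg_g",
           "soluble_sugar_mg_g", "starch_mg_g")
  stopifnot(all(req %in% names(samples)))
  samples$cn <- cn_ratio(samples$c_mg_g, samples$n_mg_g)
  samples$tnc <- total_nonstructural_carbohydrate(samples$soluble_sugar_mg_g,
                                                  samples$starch_mg_g)
  traits <- c(c = "c_mg_g", n = "n_mg_g", cn = "cn",
              soluble_sugar = "soluble_sugar_mg_g", starch = "starch_mg_g",
              tnc = "tnc")
  key <- interaction(samples$tissue, samples$treatment_co2_ppm, drop = TRUE)
  rows <- lapply(split(samples, key), function(d) {
    out <- data.frame(tissue = d$tissue[1],
                      treatment_co2_ppm = d$treatment_co2_ppm[1],
                      n_samples = nrow(d), stringsAsFactors = FALSE)
    for (nm in names(traits)) {
      v <- d[[traits[[nm]]]]
      out[[paste0(nm, "_mean")]] <- mean(v)
      out[[paste0(nm, "_sd")]] <- if (length(v) > 1) stats::sd(v) else NA_real_
    }
    out
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$tissue, out$treatment_co2_ppm), , drop = FALSE]
  rownames(out) <- NULL
  out
}
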
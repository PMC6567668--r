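#' Stomatal density
#'
#' Number of stomata per unit leaf area.
#'
#' @param n_stomata Count of stomata (>= 0).
#' @param field_area Observed field area (mm2), > 0. Microscope fields
#'   default to 0.16 mm2 elsewhere in the package.
#' @return Density in stomata mm-2.
#' @export
stomatal_density <- function(n_stomata, field_area) {
  if (any(field_area <= 0)) stop_domain("stomatal_density: field_area must be > 0")
  if (any(n_stomata < 0)) stop_domain("stomatal_density: n_stomata must be >= 0")
  n_stomata / field_area
}

#' Stomatal shape index (SSI)
#'
#' SSI = 100 * sqrt(area) / perimeter (%). By the isoperimetric
#' inequality the maximum is 100 / (2 sqrt(pi)) ~ 28.21%, attained by a
#' circle; elongated stomata score lower.
#'
#' @param area Stomatal area (um2), > 0.
#' @param perimeter Stomatal perimeter (um), > 0.
#' @return SSI in percent.
#' @export
shape_index <- function(area, perimeter) {
  if (any(area <= 0) || any(perimeter <= 0))
    stop_domain("shape_index: area and perimeter must be > 0")
  100 * sqrt(area) / perimeter
}

#' Stomatal area index (SAI)
#'
#' Total stomatal area per unit leaf area: density x mean stomatal area,
#' expressed in percent. The literal unit-consistent form converts um2 to
#' mm2 (factor 1e-6) before the x100: `density * area * 1e-4`. Some
#' published tables report values tens of times larger than this literal
#' form (an unstated per-field normalisation); the optional `scale` factor
#' lets callers reproduce such conventions explicitly rather than silently.
#'
#' @param density Stomatal density (mm-2), >= 0.
#' @param mean_stoma_area Mean area per stoma (um2), > 0.
#' @param scale Extra multiplicative factor (default 1 = literal formula).
#' @return SAI in percent.
#' @export
area_index <- function(density, mean_stoma_area, scale = 1) {
  if (any(density < 0)) stop_domain("area_index: density must be >= 0")
  if (any(mean_stoma_area <= 0)) stop_domain("area_index: mean_stoma_area must be > 0")
  if (any(scale <= 0)) stop_domain("area_index: scale must be > 0")
  density * mean_stoma_area * 1e-6 * 100 * scale
}

#' Signed percent change
#'
#' 100 * (treatment - baseline) / baseline, rounded half away from zero so
#' that e.g. a 36.5% increase prints as 37%.
#'
#' @param baseline Reference value, non-zero.
#' @param treatment Comparison value.
#' @param ndigits Decimals to keep (default 0).
#' @return Signed percent change.
#' @examples
#' percent_change(92.6, 126.4)  # +37
#' percent_change(16.8, 7.3)    # -57
#' @export
percent_change <- function(baseline, treatment, ndigits = 0) {
  if (any(baseline == 0)) stop_domain("percent_change: baseline must be non-zero")
  round_half_up(100 * (treatment - baseline) / baseline, ndigits)
}

#' Adaxial/abaxial ratio
#'
#' Ratio of an upper-surface trait value to the lower-surface value.
#'
#' @param adaxial Adaxial (upper surface) value.
#' @param abaxial Abaxial (lower surface) value, > 0.
#' @return adaxial / abaxial.
#' @export
adaxial_abaxial_ratio <- function(adaxial, abaxial) {
  if (any(abaxial <= 0)) stop_domain("adaxial_abaxial_ratio: abaxial must be > 0")
  adaxial / abaxial
}

#' Summarise stomatal morphology and fields per surface
#'
#' Aggregates per-stoma morphology and per-field counts into the
#' surface-level descriptors used in treatment tables: density, mean
#' length/width/area/perimeter, SSI and SAI. SSI and SAI are computed both
#' as mean-of-ratios (per-stoma, the default reported variant) and
#' ratio-of-means; both are returned. SAI is linear in per-stoma area, so
#' the two aggregation orders coincide and a single column is returned.
#'
#' @param morphology Data frame with columns `surface`, `length_um`,
#'   `width_um`, `area_um2`, `perimeter_um`.
#' @param fields Data frame with columns `surface`, `n_stomata`,
#'   `field_area_mm2`.
#' @param sai_scale Passed to [area_index()].
#' @return Data frame, one row per surface, with columns `surface`,
#'   `n_stomata`, `total_field_area_mm2`, `density_mm2`, `length_um`,
#'   `width_um`, `area_um2`, `perimeter_um`, `ssi_pct`,
#'   `ssi_ratio_of_means_pct`, `sai_pct`.
#' @export
stomatal_field_summary <- function(morphology, fields, sai_scale = 1) {
  stopifnot(all(c("surface", "length_um", "width_um", "area_um2",
                  "perimeter_um") %in% names(morphology)),
            all(c("surface", "n_stomata", "field_area_mm2") %in% names(fields)))
  surfaces <- sort(unique(c(morphology$surface, fields$surface)))
  out <- lapply(surfaces, function(s) {
    m <- morphology[morphology$surface == s, , drop = FALSE]
    f <- fields[fields$surface == s, , drop = FALSE]
    dens <- stomatal_density(sum(f$n_stomata), sum(f$field_area_mm2))
    mean_area <- mean(m$area_um2)
    data.frame(
      surface = s,
      n_stomata = sum(f$n_stomata),
      total_field_area_mm2 = sum(f$field_area_mm2),
      density_mm2 = dens,
      length_um = mean(m$length_um),
      width_um = mean(m$width_um),
      area_um2 = mean_area,
      perimeter_um = mean(m$perimeter_um),
      ssi_pct = mean(shape_index(m$area_um2, m$perimeter_um)),
      ssi_ratio_of_means_pct = shape_index(mean_area, mean(m$perimeter_um)),
      sai_pct = area_index(dens, mean_area, scale = sai_scale),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
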
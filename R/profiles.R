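# Default treatment-level trait profiles for the synthetic study generator:
# per-CO2 means and SDs of stomatal, anatomical and tissue-chemistry traits
# of soybean grown at 400-1600 ppm. These are the generator's anchors; real
# studies supply their own measured tables.

co2_levels <- function() c(400, 600, 800, 1000, 1200, 1400, 1600)

profile_block <- function(trait, mean, sd, ...) {
  data.frame(..., trait = trait, co2 = co2_levels(), mean = mean, sd = sd,
             stringsAsFactors = FALSE)
}

#' Default stomatal trait profiles
#'
#' Per-surface, per-CO2 means and SDs of stomatal length, width, area,
#' perimeter (um-scale, per stoma), density (mm-2), shape index and area
#' index (%), used as the synthetic generator's defaults for soybean.
#'
#' @return Long data frame with columns `surface`, `trait`, `co2`,
#'   `mean`, `sd`.
#' @export
stomatal_trait_profiles <- function() {
  ad <- rbind(
    profile_block("length_um",    c(9.4, 9.7, 9.6, 9.6, 9.0, 9.50, 9.8),
                  c(1.3, 1.6, 0.6, 0.8, 2.0, 0.5, 1.6)),
    profile_block("width_um",     c(2.2, 1.8, 2.6, 1.7, 2.7, 2.4, 2.5),
                  c(0.9, 0.4, 0.5, 0.2, 0.5, 0.5, 0.7)),
    profile_block("area_um2",     c(92.6, 88.7, 105.4, 83.3, 126.4, 100.3, 103.9),
                  c(16.2, 9.6, 5.2, 9.0, 24.1, 17.2, 11.0)),
    profile_block("perimeter_um", c(40.7, 45.0, 41.0, 37.9, 46.2, 40.5, 41.2),
                  c(0.5, 1.0, 0.1, 0.2, 0.4, 0.3, 0.27)),
    profile_block("density_mm2",  c(16.8, 7.3, 6.6, 17.8, 10.4, 11.4, 8.7),
                  c(8.9, 4.9, 4.7, 5.3, 6.4, 6.3, 3.5)),
    profile_block("ssi_pct",      c(24.0, 20.4, 25.0, 24.1, 24.3, 24.6, 24.7),
                  c(1.3, 4.7, 0.2, 0.2, 2.4, 0.6, 0.7)),
    profile_block("sai_pct",      c(9.4, 3.9, 4.2, 9.0, 7.9, 6.9, 5.4),
                  c(1.7, 0.4, 0.3, 1.0, 1.5, 1.2, 0.6)))
  ab <- rbind(
    profile_block("length_um",    c(9.6, 9.8, 9.5, 10.2, 8.9, 9.4, 9.2),
                  c(1.7, 0.6, 0.8, 0.7, 0.6, 0.2, 0.1)),
    profile_block("width_um",     c(3.1, 3.1, 3.2, 2.9, 3.0, 3.1, 2.8),
                  c(0.9, 0.3, 0.3, 0.4, 0.4, 0.2, 0.1)),
    profile_block("area_um2",     c(133.1, 123.9, 108.9, 102.3, 109.3, 113.9, 110.1),
                  c(0.5, 16.5, 13.8, 6.1, 7.5, 9.2, 17.8)),
    profile_block("perimeter_um", c(42.8, 44.6, 41.1, 40.7, 40.7, 42.6, 41.8),
                  c(5.5, 2.8, 3.1, 1.4, 2.0, 1.7, 3.3)),
    profile_block("density_mm2",  c(101.3, 128.3, 95.7, 92, 104.8, 84.2, 111.4),
                  c(20.1, 18, 10.8, 17.0, 9.7, 9.2, 17.8)),
    profile_block("ssi_pct",      c(25.3, 24.9, 25.2, 24.9, 25.1, 25.0, 25.1),
                  c(0.1, 0.1, 0.4, 0.1, 0.5, 0.4, 0.1)),
    profile_block("sai_pct",      c(81.9, 96.3, 63.2, 57.1, 69.5, 58.2, 74.8),
                  c(0.3, 12.8, 8.0, 3.4, 4.8, 4.72, 12.1)))
  rbind(cbind(surface = "adaxial", ad, stringsAsFactors = FALSE),
        cbind(surface = "abaxial", ab, stringsAsFactors = FALSE))
}

#' Default leaf anatomy trait profiles
#'
#' Palisade and spongy mesophyll cell dimensions, the palisade/spongy
#' ratio and leaf thickness per CO2 treatment (means and SDs), used as
#' generator defaults.
#'
#' @return Long data frame with columns `layer`, `trait`, `co2`, `mean`,
#'   `sd`.
#' @export
anatomy_trait_profiles <- function() {
  pal <- rbind(
    profile_block("cell_length_um",    c(35.69, 39.14, 38.59, 42.03, 33.38, 29.76, 41.15),
                  c(3.04, 3.43, 3.45, 5.23, 6.24, 4.47, 7.35)),
    profile_block("cell_width_um",     c(9.35, 8.93, 7.90, 9.00, 7.25, 10.40, 8.13),
                  c(1.76, 1.78, 1.22, 1.50, 1.29, 1.18, 2.00)),
    profile_block("cell_area_um2",     c(303.3, 348.7, 275.0, 328.0, 213.1, 232.1, 303.5),
                  c(39.6, 39.4, 76.2, 80.9, 46.3, 60.5, 88.9)),
    profile_block("cell_perimeter_um", c(83.0, 95.1, 80.6, 99.3, 71.4, 67.6, 100.9),
                  c(6.4, 12.6, 9.9, 12.7, 9.4, 10.2, 19.3)))
  spo <- rbind(
    profile_block("cell_length_um",    c(20.72, 24.85, 22.61, 27.36, 19.87, 20.15, 20.07),
                  c(2.43, 4.00, 5.45, 7.75, 3.11, 2.87, 5.11)),
    profile_block("cell_width_um",     c(11.91, 12.04, 9.39, 10.54, 8.28, 12.68, 8.46),
                  c(3.13, 3.75, 5.44, 3.71, 2.14, 2.15, 2.40)),
    profile_block("cell_area_um2",     c(207.8, 265.3, 192.0, 258.9, 150.0, 215.6, 177.2),
                  c(57.6, 88.4, 64.5, 24.5, 43.8, 53.0, 67.7)),
    profile_block("cell_perimeter_um", c(86.2, 76.88, 60.6, 71.4, 55.5, 55.6, 63.1),
                  c(13.2, 13.8, 13.3, 21.7, 12.0, 13.7, 15.5)))
  leaf <- rbind(
    profile_block("palisade_spongy_ratio", c(1.88, 2.52, 2.59, 2.77, 2.13, 1.90, 1.75),
                  c(0.68, 0.23, 0.64, 0.54, 0.60, 0.49, 0.25)),
    profile_block("leaf_thickness_um", c(103.5, 126.9, 121.5, 125.4, 108.7, 108.0, 106.9),
                  c(11.0, 9.9, 9.9, 12.7, 14.1, 12.2, 11.1)))
  rbind(cbind(layer = "palisade", pal, stringsAsFactors = FALSE),
        cbind(layer = "spongy", spo, stringsAsFactors = FALSE),
        cbind(layer = "leaf", leaf, stringsAsFactors = FALSE))
}

#' Default tissue chemistry trait profiles
#'
#' Carbon, nitrogen (mg g-1 DW), soluble sugar and starch (mg g-1 DW)
#' of leaf, stem and root per CO2 treatment, used as generator defaults.
#' C/N and TNC are derived, not stored.
#'
#' @return Long data frame with columns `tissue`, `trait`, `co2`, `mean`,
#'   `sd`.
#' @export
chemistry_trait_profiles <- function() {
  leaf <- rbind(
    profile_block("c_mg_g", c(403.6, 386.14, 390.54, 373.66, 393.30, 392.07, 395.71),
                  c(0.33, 0.23, 0.24, 12.73, 0.70, 0.50, 0.37)),
    profile_block("n_mg_g", c(32.04, 30.56, 33.56, 31.61, 34.04, 32.61, 30.83),
                  c(0.12, 0.22, 0.16, 1.00, 0.12, 0.07, 0.2)),
    profile_block("soluble_sugar_mg_g", c(65.5, 30.5, 72.6, 59.0, 27.4, 29.7, 22.6),
                  c(3.9, 5.0, 13.8, 13.3, 1.7, 7.6, 2.7)),
    profile_block("starch_mg_g", c(17.9, 26.0, 14.9, 27.5, 16.9, 15.8, 19.4),
                  c(7.8, 5.3, 2.0, 4.4, 5.0, 1.7, 1.9)))
  stem <- rbind(
    profile_block("c_mg_g", c(375.71, 358.33, 348.84, 347.86, 335.51, 339.93, 359.40),
                  c(0.66, 0.47, 0.17, 0.20, 0.05, 1.01, 0.30)),
    profile_block("n_mg_g", c(26.47, 32.58, 43.24, 45.85, 37.51, 42.24, 36.94),
                  c(0.14, 0.19, 0.25, 0.41, 0.10, 0.12, 0.20)),
    profile_block("soluble_sugar_mg_g", c(51.1, 59.7, 55.8, 64.5, 54.2, 47.2, 53.3),
                  c(6.4, 4.9, 4.3, 7.4, 3.5, 1.2, 5.1)),
    profile_block("starch_mg_g", c(16.2, 20.2, 20.2, 11.7, 23.2, 16.2, 10.9),
                  c(5.8, 2.7, 4.1, 0.3, 4.1, 0.7, 3.9)))
  root <- rbind(
    profile_block("c_mg_g", c(352.38, 347.81, 350.68, 354.78, 376.80, 378.59, 371.19),
                  c(0.13, 0.42, 0.18, 0.52, 0.62, 2.97, 8.64)),
    profile_block("n_mg_g", c(26.08, 34.40, 38.35, 37.70, 36.79, 37.57, 33.59),
                  c(0.29, 0.19, 0.09, 0.10, 0.25, 0.33, 3.33)),
    profile_block("soluble_sugar_mg_g", c(58.4, 96.9, 61.2, 40.1, 63.4, 65.2, 52.1),
                  c(5.0, 5.7, 5.3, 2.5, 2.0, 3.3, 5.0)),
    profile_block("starch_mg_g", c(26.8, 17.2, 25.6, 18.1, 18.4, 20.16, 13.3),
                  c(3.3, 9.6, 2.3, 2.3, 1.1, 0.96, 1.5)))
  rbind(cbind(tissue = "leaf", leaf, stringsAsFactors = FALSE),
        cbind(tissue = "stem", stem, stringsAsFactors = FALSE),
        cbind(tissue = "root", root, stringsAsFactors = FALSE))
}

# Lookup helper: mean (and sd) for one profile cell
profile_lookup <- function(profiles, co2, trait, ...) {
  sel <- profiles$trait == trait & profiles$co2 == co2
  extra <- list(...)
  for (nm in names(extra)) sel <- sel & profiles[[nm]] == extra[[nm]]
  row <- profiles[sel, , drop = FALSE]
  if (nrow(row) != 1) stop("profile_lookup: no unique profile cell for ", trait)
  row
}
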
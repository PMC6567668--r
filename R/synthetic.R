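#' Default cuvette CO2 ladder
#'
#' The 12-step cuvette CO2 sequence used for A-Ci curves (ppm).
#' @return Numeric vector.
#' @export
default_ci_steps <- function() {
  c(50, 100, 150, 200, 300, 400, 600, 800, 1000, 1200, 1400, 1600)
}

#' Synthetic study configuration
#'
#' Describes the growth-chamber design the generator emulates: 7 CO2
#' treatments (400-1600 ppm by 200) x 5 pots, a 12-step cuvette ladder per
#' leaf, adaxial/abaxial stomatal fields of 0.16 mm2 with
#' treatment-dependent density and hard-core regularity, and anatomy and
#' chemistry drawn around the default trait profiles.
#'
#' The FvCB truth follows quadratic dose-response profiles: Vcmax peaks at
#' `vcmax_peak_co2` (default 600 ppm) and Jmax declines from
#' `jmax_peak_co2` (default 400 ppm), so the fitted parameters exhibit the
#' interior optima the dose-response stage is meant to recover.
#'
#' @param treatments Growth CO2 levels (ppm).
#' @param pots_per_treatment Pots (replicate leaves) per chamber.
#' @param ci_steps Cuvette CO2 ladder (treated 1:1 as Ci, ubar).
#' @param an_noise_sd Gaussian noise sd on assimilation (umol m-2 s-1).
#' @param pot_cv Between-pot coefficient of variation on FvCB truth.
#' @param vcmax_peak,vcmax_peak_co2,vcmax_curv Vertex value, vertex CO2 and
#'   curvature of the Vcmax profile (umol m-2 s-1, ppm, umol m-2 s-1 ppm-2).
#' @param jmax_peak,jmax_peak_co2,jmax_curv Same for Jmax.
#' @param rd_peak,rd_peak_co2,rd_curv Same for dark respiration.
#' @param fields_per_surface Stomatal microscope fields per surface per pot.
#' @param window Field window, a [ppwindow()] (default 400 x 400 um =
#'   0.16 mm2).
#' @param hardcore_r Named vector of inhibition radii (um) for the
#'   adaxial and abaxial surfaces.
#' @param seed Integer master seed; every stage derives a substream from it.
#' @return Object of class `study_config` (a list).
#' @export
study_config <- function(treatments = co2_levels(), pots_per_treatment = 5,
                         ci_steps = default_ci_steps(), an_noise_sd = 0.5,
                         pot_cv = 0.05,
                         vcmax_peak = 110, vcmax_peak_co2 = 600, vcmax_curv = 5e-5,
                         jmax_peak = 180, jmax_peak_co2 = 400, jmax_curv = 5e-5,
                         rd_peak = 2.2, rd_peak_co2 = 900, rd_curv = 1e-6,
                         fields_per_surface = 3, window = ppwindow(400, 400),
                         hardcore_r = c(adaxial = 30, abaxial = 20),
                         seed = 1) {
  if (length(treatments) < 2) stop_domain("study_config: need >= 2 treatments")
  if (an_noise_sd < 0 || pot_cv < 0) stop_domain("study_config: sds must be >= 0")
  structure(as.list(environment()), class = "study_config")
}

# Quadratic trait profile evaluated at a CO2 level, floored at 10% of peak
quad_profile <- function(co2, peak, peak_co2, curv) {
  pmax(peak - curv * (co2 - peak_co2)^2, 0.1 * peak)
}

#' FvCB truth at a CO2 treatment level
#'
#' Evaluates the configured quadratic Vcmax/Jmax/Rd dose-response profiles.
#'
#' @param config A [study_config()].
#' @param co2 Growth CO2 (ppm).
#' @return An [fvcb_params()] object.
#' @export
fvcb_truth_at <- function(config, co2) {
  fvcb_params(
    vcmax = quad_profile(co2, config$vcmax_peak, config$vcmax_peak_co2, config$vcmax_curv),
    j = quad_profile(co2, config$jmax_peak, config$jmax_peak_co2, config$jmax_curv),
    rd = quad_profile(co2, config$rd_peak, config$rd_peak_co2, config$rd_curv))
}

#' Generate a noisy A-Ci curve from known truth
#'
#' Forward FvCB model at the cuvette ladder plus i.i.d. Gaussian noise on
#' assimilation; `noise_sd = 0` reproduces the forward model exactly.
#'
#' @param truth An [fvcb_params()] object.
#' @param ci_steps Ci ladder (ubar).
#' @param noise_sd Gaussian noise sd (umol m-2 s-1).
#' @param seed Optional integer seed.
#' @param growth_co2,leaf_id,pot_id Metadata passed to [aci_curve()].
#' @return An [aci_curve()].
#' @export
generate_aci_curve <- function(truth, ci_steps = default_ci_steps(),
                               noise_sd = 0.5, seed = NULL,
                               growth_co2 = NA_real_, leaf_id = "leaf1",
                               pot_id = "pot1") {
  if (noise_sd < 0) stop_domain("generate_aci_curve: noise_sd must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  fwd <- fvcb_assimilation(truth, ci_steps)
  fwd$an <- fwd$an + stats::rnorm(length(ci_steps), 0, noise_sd)
  aci_curve(fwd[, c("ci", "an")], growth_co2 = growth_co2,
            leaf_id = leaf_id, pot_id = pot_id, rd_measured = truth$rd)
}

# meanlog/sdlog of a lognormal with given mean and sd
lnorm_pars <- function(m, s) {
  sdlog <- sqrt(log(1 + (s / m)^2))
  list(meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

rnorm_pos <- function(n, mean, sd, floor = 1e-3) pmax(stats::rnorm(n, mean, sd), floor)

#' Generate a complete synthetic study
#'
#' Builds every table the analysis chain consumes, deterministically from
#' the config seed: per-pot A-Ci curves (FvCB forward model + noise),
#' adaxial/abaxial stomatal coordinate fields (hard-core inhibition with
#' treatment-dependent counts; falls back to CSR with a warning if packing
#' fails), per-stoma morphology (lognormal areas with shape-index-consistent
#' perimeters), per-pot anatomy, and per-pot tissue chemistry - plus the
#' generating truth for recovery tests.
#'
#' @param config A [study_config()].
#' @return Object of class `synthetic_study`: list with data frames
#'   `gas_exchange`, `stomatal_coords`, `windows`, `stomatal_fields`,
#'   `morphology`, `anatomy`, `chemistry`, and a `truth` list.
#' @export
generate_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  stoma_prof <- stomatal_trait_profiles()
  anat_prof <- anatomy_trait_profiles()
  chem_prof <- chemistry_trait_profiles()
  win <- config$window
  area_mm2 <- win$area / 1e6

  gas <- list(); coords <- list(); fields <- list(); morph <- list()
  anat <- list(); chem <- list(); truth_rows <- list()
  fid <- 0L

  set.seed(substream_seed(config$seed, "truth"))
  for (co2 in config$treatments) {
    base <- fvcb_truth_at(config, co2)
    for (p in seq_len(config$pots_per_treatment)) {
      pot_id <- sprintf("co2%04d_pot%d", co2, p)
      mult <- pmax(stats::rnorm(3, 1, config$pot_cv), 0.5)
      truth_rows[[pot_id]] <- list(
        pot_id = pot_id, co2 = co2,
        vcmax = base$vcmax * mult[1], jmax = base$j * mult[2],
        rd = base$rd * mult[3])
    }
  }

  for (co2 in config$treatments) {
    for (p in seq_len(config$pots_per_treatment)) {
      pot_id <- sprintf("co2%04d_pot%d", co2, p)
      tr <- truth_rows[[pot_id]]
      params <- fvcb_params(tr$vcmax, tr$jmax, tr$rd)

      # gas exchange: forward FvCB + noise, with plausible gs/tr companions
      set.seed(substream_seed(config$seed, paste0("aci_", pot_id)))
      crv <- generate_aci_curve(params, config$ci_steps, config$an_noise_sd,
                                seed = NULL, growth_co2 = co2,
                                leaf_id = "leaf1", pot_id = pot_id)
      gs <- pmax(0.08 + 0.5 * exp(-crv$ci / 600) +
                   stats::rnorm(nrow(crv), 0, 0.01), 0.01)
      gas[[pot_id]] <- data.frame(
        pot_id = pot_id, leaf_id = "leaf1", growth_co2_ppm = co2,
        ci_umol_mol = crv$ci, an_umol_m2_s = crv$an,
        gs_mol_m2_s = gs, tr_mmol_m2_s = 8 * gs,
        ppfd_umol_m2_s = 1500, tleaf_c = 25, vpd_kpa = 1.2,
        stringsAsFactors = FALSE)

      for (surf in c("adaxial", "abaxial")) {
        dens <- profile_lookup(stoma_prof, co2, "density_mm2", surface = surf)$mean
        r_hc <- config$hardcore_r[[surf]]
        set.seed(substream_seed(config$seed, paste0("pp_", pot_id, "_", surf)))
        for (f in seq_len(config$fields_per_surface)) {
          fid <- fid + 1L
          field_id <- sprintf("F%05d", fid)
          n_pts <- max(stats::rpois(1, dens * area_mm2), 2L)
          pat <- tryCatch(
            simulate_hardcore(n_pts, win, r_hc),
            soyco2_fit_error = function(e) {
              warning(sprintf("generate_study: hard-core packing failed for %s (%s); using CSR",
                              field_id, surf))
              simulate_csr(n_pts, win)
            })
          coords[[field_id]] <- data.frame(
            field_id = field_id, surface = surf, treatment_co2_ppm = co2,
            pot_id = pot_id, x_um = pat$x, y_um = pat$y,
            stringsAsFactors = FALSE)
          fields[[field_id]] <- data.frame(
            field_id = field_id, surface = surf, treatment_co2_ppm = co2,
            pot_id = pot_id, n_stomata = pat$n, field_area_mm2 = area_mm2,
            stringsAsFactors = FALSE)

          # per-stoma morphology: lognormal sizes, SSI-consistent perimeters
          ar <- profile_lookup(stoma_prof, co2, "area_um2", surface = surf)
          ln <- profile_lookup(stoma_prof, co2, "length_um", surface = surf)
          wd <- profile_lookup(stoma_prof, co2, "width_um", surface = surf)
          ssi <- profile_lookup(stoma_prof, co2, "ssi_pct", surface = surf)
          lp_a <- lnorm_pars(ar$mean, ar$sd)
          areas <- stats::rlnorm(pat$n, lp_a$meanlog, lp_a$sdlog)
          ssis <- pmin(pmax(stats::rnorm(pat$n, ssi$mean, ssi$sd), 5), 28.2)
          morph[[field_id]] <- data.frame(
            pot_id = pot_id, surface = surf, field_id = field_id,
            treatment_co2_ppm = co2,
            length_um = rnorm_pos(pat$n, ln$mean, ln$sd, 1),
            width_um = rnorm_pos(pat$n, wd$mean, wd$sd, 0.3),
            area_um2 = areas,
            perimeter_um = 100 * sqrt(areas) / ssis,
            stringsAsFactors = FALSE)
        }
      }

      set.seed(substream_seed(config$seed, paste0("anat_", pot_id)))
      arow <- data.frame(pot_id = pot_id, treatment_co2_ppm = co2,
                         stringsAsFactors = FALSE)
      for (i in seq_len(nrow(anat_prof))) {
        pr <- anat_prof[i, ]
        if (pr$co2 != co2) next
        nm <- if (pr$layer == "leaf") pr$trait else paste0(pr$layer, "_", pr$trait)
        arow[[nm]] <- rnorm_pos(1, pr$mean, pr$sd, 0.1)
      }
      anat[[pot_id]] <- arow

      set.seed(substream_seed(config$seed, paste0("chem_", pot_id)))
      for (tis in c("leaf", "stem", "root")) {
        draw <- function(trait) {
          pr <- profile_lookup(chem_prof, co2, trait, tissue = tis)
          rnorm_pos(1, pr$mean, pr$sd, 0.1)
        }
        chem[[paste0(pot_id, "_", tis)]] <- data.frame(
          pot_id = pot_id, tissue = tis, treatment_co2_ppm = co2,
          c_mg_g = draw("c_mg_g"), n_mg_g = draw("n_mg_g"),
          soluble_sugar_mg_g = draw("soluble_sugar_mg_g"),
          starch_mg_g = draw("starch_mg_g"), stringsAsFactors = FALSE)
      }
    }
  }

  structure(list(
    config = config,
    gas_exchange = do.call(rbind, c(gas, list(make.row.names = FALSE))),
    stomatal_coords = do.call(rbind, c(coords, list(make.row.names = FALSE))),
    windows = data.frame(field_id = names(fields),
                         width_um = win$width, height_um = win$height,
                         stringsAsFactors = FALSE),
    stomatal_fields = do.call(rbind, c(fields, list(make.row.names = FALSE))),
    morphology = do.call(rbind, c(morph, list(make.row.names = FALSE))),
    anatomy = do.call(rbind, c(anat, list(make.row.names = FALSE))),
    chemistry = do.call(rbind, c(chem, list(make.row.names = FALSE))),
    truth = list(fvcb = do.call(rbind, lapply(truth_rows, as.data.frame)),
                 config_seed = config$seed)
  ), class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("Synthetic study: %d treatments x %d pots\n",
              length(x$config$treatments), x$config$pots_per_treatment))
  cat(sprintf("  %d gas-exchange rows, %d stomatal fields (%d coordinates)\n",
              nrow(x$gas_exchange), nrow(x$stomatal_fields),
              nrow(x$stomatal_coords)))
  cat(sprintf("  %d anatomy rows, %d chemistry rows\n",
              nrow(x$anatomy), nrow(x$chemistry)))
  invisible(x)
}
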
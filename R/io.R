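GAS_EXCHANGE_COLUMNS <- c("pot_id", "leaf_id", "growth_co2_ppm", "ci_umol_mol",
                          "an_umol_m2_s", "gs_mol_m2_s", "tr_mmol_m2_s",
                          "ppfd_umol_m2_s", "tleaf_c", "vpd_kpa")

read_checked_csv <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("schema error in ", basename(path), ": missing column(s) ",
         paste(missing, collapse = ", "))
  df
}

#' Read gas-exchange curves from CSV
#'
#' One row per cuvette step; curves are grouped by (pot_id, leaf_id) and
#' sorted by Ci, so row order in the file does not matter.
#'
#' @param path CSV with header columns `pot_id,leaf_id,growth_co2_ppm,
#'   ci_umol_mol,an_umol_m2_s,gs_mol_m2_s,tr_mmol_m2_s,ppfd_umol_m2_s,
#'   tleaf_c,vpd_kpa`.
#' @return Named list of [aci_curve()] objects, keyed `pot_id/leaf_id`.
#' @export
read_gas_exchange <- function(path) {
  df <- read_checked_csv(path, GAS_EXCHANGE_COLUMNS)
  num_cols <- setdiff(GAS_EXCHANGE_COLUMNS, c("pot_id", "leaf_id"))
  for (cl in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    if (any(is.na(v) & !is.na(df[[cl]])))
      stop("parse error in ", basename(path), ", column ", cl, ", row(s) ",
           paste(which(is.na(v) & !is.na(df[[cl]])), collapse = ", "))
    df[[cl]] <- v
  }
  out <- lapply(split(df, paste(df$pot_id, df$leaf_id, sep = "/")), function(d) {
    aci_curve(data.frame(ci = d$ci_umol_mol, an = d$an_umol_m2_s,
                         gs = d$gs_mol_m2_s, tr = d$tr_mmol_m2_s,
                         ppfd = d$ppfd_umol_m2_s, tleaf = d$tleaf_c,
                         vpd = d$vpd_kpa),
              growth_co2 = d$growth_co2_ppm[1],
              leaf_id = d$leaf_id[1], pot_id = d$pot_id[1])
  })
  out
}

#' Write a synthetic study to CSV files
#'
#' Writes `gas_exchange.csv`, `stomatal_coords.csv`, `windows.csv`,
#' `stomatal_fields.csv`, `morphology.csv`, `anatomy.csv`,
#' `chemistry.csv` and `truth.json` under `dir`.
#'
#' @param study A [generate_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- c("gas_exchange", "stomatal_coords", "windows", "stomatal_fields",
            "morphology", "anatomy", "chemistry")
  for (nm in tabs)
    utils::write.csv(study[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  jsonlite::write_json(study$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a study directory written by [write_study()]
#'
#' @param dir Directory containing the study CSVs.
#' @return A list with the same table elements as a `synthetic_study`
#'   (without `config`/`truth`).
#' @export
read_study <- function(dir) {
  list(
    gas_exchange = read_checked_csv(file.path(dir, "gas_exchange.csv"),
                                    GAS_EXCHANGE_COLUMNS),
    stomatal_coords = read_checked_csv(
      file.path(dir, "stomatal_coords.csv"),
      c("field_id", "surface", "treatment_co2_ppm", "x_um", "y_um")),
    windows = read_checked_csv(file.path(dir, "windows.csv"),
                               c("field_id", "width_um", "height_um")),
    stomatal_fields = read_checked_csv(
      file.path(dir, "stomatal_fields.csv"),
      c("field_id", "surface", "n_stomata", "field_area_mm2")),
    morphology = read_checked_csv(
      file.path(dir, "morphology.csv"),
      c("pot_id", "surface", "field_id", "length_um", "width_um",
        "area_um2", "perimeter_um")),
    anatomy = read_checked_csv(file.path(dir, "anatomy.csv"),
                               c("pot_id", "treatment_co2_ppm")),
    chemistry = read_checked_csv(
      file.path(dir, "chemistry.csv"),
      c("pot_id", "tissue", "treatment_co2_ppm", "c_mg_g", "n_mg_g",
        "soluble_sugar_mg_g", "starch_mg_g")))
}

# Per-treatment x surface stomatal table assembled from a study's
# morphology + field tables (pooled over pots)
stomatal_treatment_table <- function(study) {
  key <- interaction(study$stomatal_fields$treatment_co2_ppm,
                     study$stomatal_fields$surface, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(study$stomatal_fields)), key), function(ix) {
    f <- study$stomatal_fields[ix, ]
    co2 <- f$treatment_co2_ppm[1]; surf <- f$surface[1]
    m <- study$morphology[study$morphology$field_id %in% f$field_id, ]
    s <- stomatal_field_summary(m, f)
    cbind(data.frame(treatment_co2_ppm = co2), s)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$surface, out$treatment_co2_ppm), ]
}

#' Run the full analysis pipeline on a study
#'
#' Orchestrates the analysis chain on a synthetic (or equivalently shaped
#' real) study: FvCB fits per leaf; quadratic dose-response of the fitted
#' Vcmax, Jmax and Vcmax/Jmax ratio against growth CO2; per-surface
#' stomatal treatment tables with percent changes against the lowest CO2
#' level; Ripley's K / envelope classification per stomatal field; and
#' tissue chemistry summaries. Deterministic given `seed`.
#'
#' @param study A `synthetic_study` (or [read_study()] output coerced via
#'   [generate_study()]-compatible tables).
#' @param seed Integer seed for the Monte Carlo envelopes.
#' @param n_sims CSR replicates per envelope (default 100).
#' @param alpha Envelope level (default 0.05 = 95% bounds).
#' @param distances Ripley distance grid (um).
#' @param max_ripley_fields Cap on the number of fields analysed per
#'   (treatment, surface); `Inf` analyses all.
#' @return Object of class `study_report`: list with elements `fvcb`
#'   (per-leaf coefficient table), `dose_response` (list of
#'   [fit_quadratic()] objects for vcmax, jmax, ratio), `stomata`
#'   (treatment table), `stomata_change` (percent-change vs baseline),
#'   `ripley` (per-field classification table), `chemistry` (summary
#'   table), and `seed`.
#' @export
run_pipeline <- function(study, seed = 1, n_sims = 100, alpha = 0.05,
                         distances = default_distance_grid(),
                         max_ripley_fields = 2) {
  ge <- study$gas_exchange
  curves <- lapply(split(ge, paste(ge$pot_id, ge$leaf_id, sep = "/")),
                   function(d) aci_curve(
                     data.frame(ci = d$ci_umol_mol, an = d$an_umol_m2_s),
                     growth_co2 = d$growth_co2_ppm[1],
                     leaf_id = d$leaf_id[1], pot_id = d$pot_id[1]))
  fits <- lapply(curves, fit_aci)
  fvcb_tab <- do.call(rbind, lapply(fits, function(f) data.frame(
    pot_id = f$pot_id, leaf_id = f$leaf_id, growth_co2_ppm = f$growth_co2,
    vcmax = f$params$vcmax, jmax = f$params$j, rd = f$params$rd,
    transition_ci = f$transition_ci, sse = f$sse, r2 = f$r2,
    stringsAsFactors = FALSE)))
  rownames(fvcb_tab) <- NULL

  dose <- list(
    vcmax = fit_quadratic(fvcb_tab$growth_co2_ppm, fvcb_tab$vcmax),
    jmax = fit_quadratic(fvcb_tab$growth_co2_ppm, fvcb_tab$jmax),
    vcmax_jmax_ratio = fit_quadratic(fvcb_tab$growth_co2_ppm,
                                     fvcb_tab$vcmax / fvcb_tab$jmax))

  stoma <- stomatal_treatment_table(study)
  base_co2 <- min(stoma$treatment_co2_ppm)
  change <- do.call(rbind, lapply(split(stoma, stoma$surface), function(d) {
    b <- d[d$treatment_co2_ppm == base_co2, ]
    d2 <- d[d$treatment_co2_ppm != base_co2, ]
    data.frame(surface = d2$surface, treatment_co2_ppm = d2$treatment_co2_ppm,
               density_change_pct = percent_change(b$density_mm2, d2$density_mm2),
               area_change_pct = percent_change(b$area_um2, d2$area_um2),
               sai_change_pct = percent_change(b$sai_pct, d2$sai_pct),
               stringsAsFactors = FALSE)
  }))
  rownames(change) <- NULL

  # Ripley classification per field (optionally capped per treatment x surface)
  sf <- study$stomatal_fields
  key <- interaction(sf$treatment_co2_ppm, sf$surface, drop = TRUE)
  keep <- unlist(lapply(split(seq_len(nrow(sf)), key), function(ix)
    utils::head(ix, max_ripley_fields)))
  rip <- list()
  for (i in keep) {
    f <- sf[i, ]
    cc <- study$stomatal_coords[study$stomatal_coords$field_id == f$field_id, ]
    if (nrow(cc) < 2) next
    wrow <- study$windows[study$windows$field_id == f$field_id, ]
    pat <- point_pattern(cc$x_um, cc$y_um,
                         ppwindow(wrow$width_um, wrow$height_um),
                         surface = f$surface, treatment_co2 = f$treatment_co2_ppm)
    res <- ripley_analysis(pat, distances, n_sims, alpha,
                           seed = substream_seed(seed, paste0("rip_", f$field_id)))
    rip[[f$field_id]] <- data.frame(
      field_id = f$field_id, surface = f$surface,
      treatment_co2_ppm = f$treatment_co2_ppm, n = res$n,
      n_regular_scales = sum(res$labels == "regular"),
      n_clustered_scales = sum(res$labels == "clustered"),
      regular_min_um = if (length(res$regular_range)) res$regular_range[1] else NA_real_,
      regular_max_um = if (length(res$regular_range)) res$regular_range[2] else NA_real_,
      stringsAsFactors = FALSE)
  }
  ripley_tab <- do.call(rbind, c(rip, list(make.row.names = FALSE)))

  chem <- chemistry_treatment_summary(study$chemistry)

  structure(list(fvcb = fvcb_tab, dose_response = dose, stomata = stoma,
                 stomata_change = change, ripley = ripley_tab,
                 chemistry = chem, seed = seed),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("Study report: %d leaves fitted across %d CO2 levels\n",
              nrow(x$fvcb), length(unique(x$fvcb$growth_co2_ppm))))
  dv <- x$dose_response$vcmax
  cat(sprintf("  Vcmax dose-response: R2 = %.3f, optimum (%s) at %.1f ppm\n",
              dv$r2, dv$opt_kind, dv$x_opt))
  cat(sprintf("  %d stomatal fields classified, %d chemistry cells summarised\n",
              nrow(x$ripley), nrow(x$chemistry)))
  invisible(x)
}

#' Write a study report to JSON
#'
#' Machine-readable dump of every table and fit in the report; a rerun
#' with the same study and seed reproduces it byte for byte.
#'
#' @param report A [run_pipeline()] result.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "study_report"))
  payload <- list(
    fvcb = report$fvcb,
    dose_response = lapply(report$dose_response, function(q) list(
      c0 = unname(q$coefficients[1]), c1 = unname(q$coefficients[2]),
      c2 = unname(q$coefficients[3]), r2 = q$r2, x_opt = q$x_opt,
      opt_kind = q$opt_kind, extrapolated = q$extrapolated, n = q$n)),
    stomata = report$stomata,
    stomata_change = report$stomata_change,
    ripley = report$ripley,
    chemistry = report$chemistry,
    seed = report$seed)
  jsonlite::write_json(payload, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}
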
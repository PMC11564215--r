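read_bundle_dir <- function(dir) {
  files <- c("samples", "site_properties", "standards", "plate_reads",
             "extracts", "slurry", "irms")
  out <- lapply(files, function(f) {
    p <- file.path(dir, paste0(f, ".csv"))
    if (!file.exists(p)) stop("missing bundle file: ", p)
    tibble::as_tibble(read.csv(p, stringsAsFactors = FALSE,
                               fileEncoding = "UTF-8"))
  })
  names(out) <- files
  out
}

#' Run the full estimation pipeline on a study bundle
#'
#' From raw measurement tables to per-sample results: fits the fluorometric
#' standard curves and converts plate reads to amino-acid pools
#' (ammonium-corrected, soil DW basis); converts extract concentrations to
#' ammonium and nitrate pools; fits slurry time courses to protein
#' depolymerisation rates; estimates gross production, net rates and gross
#' consumption of both inorganic pools by isotope pool dilution; and
#' derives turnover times of the three plant-available N pools.
#'
#' @param bundle A list of tables as returned by [simulate_study()], or a
#'   directory containing the CSV bundle.
#' @param config An [analysis_config()].
#' @return List of tibbles: `samples`, `pools` (ug N g^-1 DW),
#'   `depolymerisation`, `rates` (long: sample x pool), `turnover`, and
#'   `responses` — one row per sample with all response variables in the
#'   units of the configuration (`per_hour` by default), ready for
#'   [fit_mixed_anova()].
#' @export
analyse_study <- function(bundle, config = analysis_config()) {
  if (is.character(bundle)) bundle <- read_bundle_dir(bundle)
  samples <- read_sample_table(bundle$samples)

  # --- pools of plant-available N -----------------------------------------
  std <- bundle$standards
  leu_curve <- fit_standard_curve(std$conc_uM[std$analyte == "leucine"],
                                  std$fluorescence[std$analyte == "leucine"],
                                  "leucine")
  nh4_curve <- fit_standard_curve(std$conc_uM[std$analyte == "ammonium"],
                                  std$fluorescence[std$analyte == "ammonium"],
                                  "ammonium")
  aa <- amino_acid_concentration(bundle$plate_reads, leu_curve, nh4_curve)
  aa <- dplyr::inner_join(aa, samples[, c("sample_id", "moisture_frac")],
                          by = "sample_id")
  aa$aa_ugN_per_gDW <- extract_to_soil_basis(
    um_to_ugN_per_mL(aa$aa_uM), config$extraction_ratio, aa$moisture_frac)

  ex <- dplyr::inner_join(bundle$extracts,
                          samples[, c("sample_id", "moisture_frac")],
                          by = "sample_id")
  ex$ugN_per_gDW <- extract_to_soil_basis(
    ex$conc_ugN_per_mL, config$extraction_ratio, ex$moisture_frac)
  exw <- tidyr::pivot_wider(ex[, c("sample_id", "analyte", "ugN_per_gDW")],
                            names_from = "analyte",
                            values_from = "ugN_per_gDW")
  pools <- dplyr::inner_join(
    aa[, c("sample_id", "aa_ugN_per_gDW", "qc_floored")], exw,
    by = "sample_id")
  names(pools)[names(pools) == "ammonium"] <- "nh4_ugN_per_gDW"
  names(pools)[names(pools) == "nitrate"] <- "no3_ugN_per_gDW"
  pools$total_ugN_per_gDW <- pools$aa_ugN_per_gDW + pools$nh4_ugN_per_gDW +
    pools$no3_ugN_per_gDW

  # --- protein depolymerisation -------------------------------------------
  sl <- dplyr::inner_join(bundle$slurry,
                          samples[, c("sample_id", "moisture_frac")],
                          by = "sample_id")
  depoly <- dplyr::bind_rows(lapply(split(sl, sl$sample_id), function(d) {
    d <- d[order(d$time_h), ]
    r <- depolymerisation_rate(d$time_h, d$conc_ugN_per_mL,
                               moisture_frac = d$moisture_frac[1])
    tibble::tibble(sample_id = d$sample_id[1],
                   depoly_ugN_gDW_h = r$rate_ugN_gDW_h,
                   qc_negative = r$qc_negative)
  }))

  # --- gross rates by pool dilution ---------------------------------------
  obs <- assemble_assay_observations(bundle$irms, config)
  rates <- gross_rates(obs)

  # --- turnover times ------------------------------------------------------
  rw <- tidyr::pivot_wider(
    rates[, c("sample_id", "pool", "gross_production", "net_rate",
              "gross_consumption")],
    names_from = "pool",
    values_from = c("gross_production", "net_rate", "gross_consumption"))
  resp <- Reduce(function(x, y) dplyr::inner_join(x, y, by = "sample_id"),
                 list(samples, pools[, c("sample_id", "aa_ugN_per_gDW",
                                         "nh4_ugN_per_gDW",
                                         "no3_ugN_per_gDW")],
                      depoly[, c("sample_id", "depoly_ugN_gDW_h")], rw))

  tau <- dplyr::bind_rows(
    dplyr::bind_cols(sample_id = resp$sample_id,
                     turnover_time(resp$aa_ugN_per_gDW,
                                   resp$depoly_ugN_gDW_h,
                                   NA_real_, "amino_acids")),
    dplyr::bind_cols(sample_id = resp$sample_id,
                     turnover_time(resp$nh4_ugN_per_gDW,
                                   resp$gross_production_ammonium,
                                   resp$gross_consumption_ammonium,
                                   "ammonium")),
    dplyr::bind_cols(sample_id = resp$sample_id,
                     turnover_time(resp$no3_ugN_per_gDW,
                                   resp$gross_production_nitrate,
                                   resp$gross_consumption_nitrate,
                                   "nitrate"))
  )

  tw <- tidyr::pivot_wider(tau[, c("sample_id", "pool", "turnover_h")],
                           names_from = "pool", values_from = "turnover_h",
                           names_prefix = "turnover_")
  responses <- dplyr::inner_join(resp, tw, by = "sample_id")
  responses <- dplyr::rename(
    responses,
    free_amino_acids = "aa_ugN_per_gDW",
    ammonium = "nh4_ugN_per_gDW",
    nitrate = "no3_ugN_per_gDW",
    depolymerisation = "depoly_ugN_gDW_h",
    gross_mineralisation = "gross_production_ammonium",
    net_mineralisation = "net_rate_ammonium",
    gross_nh4_consumption = "gross_consumption_ammonium",
    gross_nitrification = "gross_production_nitrate",
    net_nitrification = "net_rate_nitrate",
    gross_no3_consumption = "gross_consumption_nitrate",
    turnover_amino_acids = "turnover_amino_acids",
    turnover_ammonium = "turnover_ammonium",
    turnover_nitrate = "turnover_nitrate")
  if (config$output_units == "per_day") {
    for (cc in c("depolymerisation", "gross_mineralisation",
                 "net_mineralisation", "gross_nh4_consumption",
                 "gross_nitrification", "net_nitrification",
                 "gross_no3_consumption")) {
      responses[[cc]] <- per_hour_to_per_day(responses[[cc]])
    }
  }

  list(samples = samples, pools = pools, depolymerisation = depoly,
       rates = rates, turnover = tau, responses = responses)
}

#' Mixed-model ANOVA over all pipeline responses
#'
#' Fits [fit_mixed_anova()] for each response of an [analyse_study()]
#' result and assembles a summary table in the layout of a per-response
#' ANOVA summary (one row per fixed term, plus the fit's marginal and
#' conditional R2).
#'
#' @param responses The `responses` tibble from [analyse_study()].
#' @param which Character vector of response names (default: all responses
#'   named in [default_transform_map()] present in the table).
#' @param group `"species"` or `"pft"`.
#' @param transforms Named transform map (default
#'   [default_transform_map()]).
#' @return Tibble: `response`, `term`, `F`, `df1`, `df2`, `p`, `r2m`,
#'   `r2c`, `transform`.
#' @export
study_anova <- function(responses, which = NULL, group = "species",
                        transforms = default_transform_map()) {
  if (is.null(which)) {
    which <- intersect(names(default_transform_map()), names(responses))
  }
  out <- lapply(which, function(rv) {
    tr <- unname(transforms[rv])
    if (is.na(tr)) tr <- "none"
    keep <- !is.na(responses[[rv]])
    fit <- fit_mixed_anova(responses[keep, ], rv, group = group,
                           transform = tr)
    dplyr::mutate(fit$anova, response = rv, r2m = fit$r2_marginal,
                  r2c = fit$r2_conditional, transform = tr,
                  .before = 1)
  })
  dplyr::bind_rows(out)
}

#' Per-area fluxes from per-mass rates
#'
#' Scales species-mean rates (ug N g^-1 DW h^-1) to ground-area fluxes
#' (g N m^-2 day^-1) with the species' organic-horizon bulk density and
#' depth, and summarises per plant functional type.
#'
#' @param responses The `responses` tibble from [analyse_study()] (rates on
#'   the per-hour scale).
#' @param rate Name of the rate column (default `"depolymerisation"`).
#' @param site_properties Site property table (default packaged).
#' @return List: `by_species` tibble (`species`, `rate_ugN_gDW_day`,
#'   `flux_gN_m2_day`), `by_pft` tibble of PFT mean fluxes.
#' @export
area_fluxes <- function(responses, rate = "depolymerisation",
                        site_properties = default_site_properties()) {
  stopifnot(rate %in% names(responses))
  sp_mean <- dplyr::summarise(
    dplyr::group_by(responses, .data$species),
    rate_ugN_gDW_day = per_hour_to_per_day(mean(.data[[rate]],
                                                na.rm = TRUE)),
    .groups = "drop")
  sp_mean <- dplyr::inner_join(
    sp_mean, site_properties[, c("species", "bulk_density_g_cm3",
                                 "horizon_depth_cm")], by = "species")
  sp_mean$flux_gN_m2_day <- scale_to_area(sp_mean$rate_ugN_gDW_day,
                                          sp_mean$bulk_density_g_cm3,
                                          sp_mean$horizon_depth_cm)
  sp_mean$pft <- unname(species_pft_map()[sp_mean$species])
  by_pft <- dplyr::summarise(
    dplyr::group_by(sp_mean, .data$pft),
    flux_gN_m2_day = mean(.data$flux_gN_m2_day), .groups = "drop")
  list(by_species = sp_mean, by_pft = by_pft)
}
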
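#' Fit a fluorometric standard curve
#'
#' Ordinary least-squares line of fluorescence (RFU) on standard
#' concentration (uM), for leucine (amino-acid) or ammonium standards read
#' with the OPAME reagent. Ammonium forms fluorescent derivatives with the
#' reagent too, so its curve is needed to correct sample fluorescence.
#'
#' @param conc_uM Standard concentrations, uM (>= 2 distinct values).
#' @param fluorescence Fluorescence reads, RFU, same length.
#' @param analyte `"leucine"` or `"ammonium"`.
#' @return A `"standard_curve"` list: `analyte`, `slope` (RFU per uM),
#'   `intercept` (RFU), `r2`, and `valid` (`FALSE` when the slope is not
#'   positive).
#' @export
#' @examples
#' fit_standard_curve(c(0, 10, 20), c(50, 1050, 2050), "leucine")
fit_standard_curve <- function(conc_uM, fluorescence,
                               analyte = c("leucine", "ammonium")) {
  analyte <- match.arg(analyte)
  stopifnot(length(conc_uM) == length(fluorescence), length(conc_uM) >= 2)
  if (length(unique(conc_uM)) < 2) {
    stop("standard concentrations are all identical; cannot fit a curve")
  }
  fit <- lm(fluorescence ~ conc_uM)
  ss_tot <- sum((fluorescence - mean(fluorescence))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - sum(fit$residuals^2) / ss_tot
  slope <- unname(coef(fit)[2])
  structure(list(analyte = analyte,
                 slope = slope,
                 intercept = unname(coef(fit)[1]),
                 r2 = r2,
                 valid = slope > 0),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("%s standard curve: RFU = %.4g + %.4g * uM (r2 = %.4f)%s\n",
              x$analyte, x$intercept, x$slope, x$r2,
              if (x$valid) "" else " [INVALID: slope <= 0]"))
  invisible(x)
}

#' Amino-acid concentration from corrected fluorescence
#'
#' Converts raw OPAME fluorescence to uM leucine equivalents: the buffer
#' blank (background) is subtracted, then the fluorescence contributed by
#' ammonium in the same solution (ammonium-curve slope times the measured
#' ammonium concentration; any ammonium-curve intercept is treated as
#' reagent background already captured by the blank), and the remainder is
#' divided by the leucine-curve slope. Negative results are floored to 0
#' and flagged.
#'
#' `aa_from_fluorescence()` is the vectorised numeric kernel;
#' `amino_acid_concentration()` applies it to a table of plate reads.
#'
#' @param raw_fluorescence,background_fluorescence Sample and buffer-blank
#'   reads, RFU.
#' @param nh4_conc_uM Ammonium concentration in the measured solution, uM.
#' @param leu_slope,nh4_slope Standard-curve slopes, RFU per uM.
#' @return `aa_from_fluorescence`: numeric uM vector with attribute
#'   `"floored"` (logical). `amino_acid_concentration`: tibble with
#'   `sample_id`, `aa_uM`, `qc_floored`.
#' @export
#' @examples
#' aa_from_fluorescence(1250, 50, 5, leu_slope = 100, nh4_slope = 30) # 10.5
aa_from_fluorescence <- function(raw_fluorescence, background_fluorescence,
                                 nh4_conc_uM, leu_slope, nh4_slope) {
  if (any(leu_slope <= 0)) stop("leucine standard-curve slope must be > 0")
  aa <- (raw_fluorescence - background_fluorescence -
           nh4_slope * nh4_conc_uM) / leu_slope
  floored <- aa < 0
  aa[floored] <- 0
  attr(aa, "floored") <- floored
  aa
}

#' @rdname aa_from_fluorescence
#' @param reads Data frame of plate reads with columns `sample_id`,
#'   `raw_fluorescence`, `background_fluorescence`, `nh4_conc_uM`.
#' @param leu_curve,nh4_curve `"standard_curve"` objects for leucine and
#'   ammonium.
#' @export
amino_acid_concentration <- function(reads, leu_curve, nh4_curve) {
  stopifnot(inherits(leu_curve, "standard_curve"),
            inherits(nh4_curve, "standard_curve"))
  if (!leu_curve$valid) stop("invalid leucine standard curve (slope <= 0)")
  aa <- aa_from_fluorescence(reads$raw_fluorescence,
                             reads$background_fluorescence,
                             reads$nh4_conc_uM,
                             leu_curve$slope, nh4_curve$slope)
  tibble::tibble(sample_id = reads$sample_id,
                 aa_uM = as.numeric(aa),
                 qc_floored = attr(aa, "floored"))
}

#' Convert uM (leucine equivalents) to ug N per mL
#'
#' Assumes one N atom per molecule by default (leucine has one).
#'
#' @param conc_uM Concentration in uM.
#' @param n_atoms N atoms per molecule (default 1).
#' @return ug N mL^-1.
#' @export
um_to_ugN_per_mL <- function(conc_uM, n_atoms = 1) {
  conc_uM * n_atoms * UG_N_PER_UMOL / 1000
}

#' @rdname um_to_ugN_per_mL
#' @param conc_ugN_per_mL Concentration in ug N mL^-1.
#' @export
ugN_per_mL_to_um <- function(conc_ugN_per_mL, n_atoms = 1) {
  conc_ugN_per_mL * 1000 / (n_atoms * UG_N_PER_UMOL)
}

#' Extract concentration to soil dry-weight basis
#'
#' A salt extraction at ratio r (mL extractant per g fresh soil, density 1
#' assumed) dilutes the soil pool; the soil-basis concentration is
#' `conc * r / (1 - moisture_frac)` ug N per g DW.
#'
#' @param conc_ugN_per_mL Concentration in the extract, ug N mL^-1.
#' @param extraction_ratio mL extractant per g fresh soil (default 10).
#' @param moisture_frac Gravimetric moisture of the extracted soil,
#'   fraction of FW.
#' @return ug N g^-1 DW.
#' @export
#' @examples
#' extract_to_soil_basis(0.1, 10, 0.75) # 4 ug N / g DW
extract_to_soil_basis <- function(conc_ugN_per_mL, extraction_ratio = 10,
                                  moisture_frac = 0) {
  if (any(extraction_ratio <= 0)) stop("extraction_ratio must be > 0")
  if (any(moisture_frac < 0 | moisture_frac >= 1)) {
    stop("moisture_frac must be in [0, 1)")
  }
  conc_ugN_per_mL * extraction_ratio / (1 - moisture_frac)
}

#' @rdname extract_to_soil_basis
#' @param conc_ugN_per_gDW Soil-basis concentration, ug N g^-1 DW.
#' @export
soil_to_extract_basis <- function(conc_ugN_per_gDW, extraction_ratio = 10,
                                  moisture_frac = 0) {
  if (any(extraction_ratio <= 0)) stop("extraction_ratio must be > 0")
  conc_ugN_per_gDW * (1 - moisture_frac) / extraction_ratio
}

#' Protein depolymerisation rate from a slurry time course
#'
#' Toluene added to a soil slurry blocks microbial uptake of enzymatic
#' reaction products, so free amino acids accumulate linearly at the gross
#' depolymerisation rate. The rate is the OLS slope of slurry amino-acid
#' concentration (ug N mL^-1) on time (h), scaled from the slurry volume to
#' soil dry weight. A negative slope is reported as-is with a QC flag.
#'
#' @param times_h Sampling times, hours, strictly increasing, >= 2 points
#'   (default protocol: 0.25, 4 and 6 h).
#' @param conc_ugN_per_mL Amino-acid concentration in the slurry at each
#'   time, ug N mL^-1. If the measured values still carry the 1:1 TCA stop
#'   dilution, set `apply_tca_factor = TRUE`.
#' @param soil_fw_g Fresh soil in the slurry, g (default 4).
#' @param water_mL Slurry water volume, mL (default 40; the 400 uL of
#'   toluene is ignored, a ~1% volume effect).
#' @param moisture_frac Gravimetric moisture of the soil, fraction of FW.
#' @param tca_dilution_factor Dilution of the subsample by the TCA stop
#'   solution (default 2 for 1:1 mixing).
#' @param apply_tca_factor Multiply concentrations by
#'   `tca_dilution_factor` before fitting (default `FALSE`: concentrations
#'   are already on the slurry basis).
#' @param method `"ols"` (slope through all timepoints, default) or
#'   `"baseline"` (difference between last and first timepoint, using the
#'   first point as the t0 baseline).
#' @return List: `rate_ugN_gDW_h`, `slope_ugN_mL_h`, `qc_negative`.
#' @export
#' @examples
#' depolymerisation_rate(c(0.25, 4, 6), c(0.5, 2.0, 2.8),
#'                       soil_fw_g = 4, moisture_frac = 0.75) # 16 ug N/gDW/h
depolymerisation_rate <- function(times_h, conc_ugN_per_mL,
                                  soil_fw_g = 4, water_mL = 40,
                                  moisture_frac = 0,
                                  tca_dilution_factor = 2,
                                  apply_tca_factor = FALSE,
                                  method = c("ols", "baseline")) {
  method <- match.arg(method)
  stopifnot(length(times_h) == length(conc_ugN_per_mL), length(times_h) >= 2)
  if (any(diff(times_h) <= 0)) stop("times_h must be strictly increasing")
  conc <- if (apply_tca_factor) conc_ugN_per_mL * tca_dilution_factor else
    conc_ugN_per_mL
  slope <- if (method == "ols") {
    unname(coef(lm(conc ~ times_h))[2])
  } else {
    n <- length(conc)
    (conc[n] - conc[1]) / (times_h[n] - times_h[1])
  }
  dw <- fresh_to_dry(soil_fw_g, moisture_frac)
  rate <- slope * water_mL / dw
  list(rate_ugN_gDW_h = rate,
       slope_ugN_mL_h = slope,
       qc_negative = rate < 0)
}
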
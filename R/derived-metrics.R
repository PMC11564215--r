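#' Turnover time of a plant-available N pool
#'
#' Turnover (residence) time is the pool size divided by its mean
#' throughput: for ammonium and nitrate the mean of the gross production
#' and gross consumption rate; for the free amino-acid pool the production
#' (depolymerisation) rate alone, since amino-acid consumption is not
#' measured. When consumption is negative (a QC condition of the
#' pool-dilution estimator) the calculation falls back to production only,
#' flagged.
#'
#' @param pool_size Pool size, ug N g^-1 DW.
#' @param production Gross production rate, ug N g^-1 DW h^-1.
#' @param consumption Gross consumption rate, same units; `NA` allowed only
#'   for the amino-acid pool.
#' @param pool `"amino_acids"`, `"ammonium"` or `"nitrate"` (vectorised).
#' @return Tibble with `pool`, `turnover_h`, `method`
#'   (`"production_only"` or `"mean_prod_cons"`) and `qc` flag
#'   (`"NONPOSITIVE_RATE"`, `"NEGATIVE_CONSUMPTION_FALLBACK"` or `""`).
#' @export
#' @examples
#' turnover_time(12, 1.0, 1.4, "ammonium") # 10 h
turnover_time <- function(pool_size, production, consumption = NA_real_,
                          pool = c("amino_acids", "ammonium", "nitrate")) {
  if (length(pool) %in% c(1L, 3L) && all(pool %in% c("amino_acids",
                                                     "ammonium", "nitrate"))
      && length(pool) != length(pool_size)) {
    pool <- rep(pool[1], length(pool_size))
  }
  stopifnot(length(pool) == length(pool_size),
            all(pool %in% c("amino_acids", "ammonium", "nitrate")))
  consumption <- rep_len(consumption, length(pool_size))
  if (any(pool != "amino_acids" & is.na(consumption) & !is.na(production))) {
    stop("consumption may be missing only for the amino-acid pool")
  }
  denom <- ifelse(pool == "amino_acids", production,
                  (production + consumption) / 2)
  method <- ifelse(pool == "amino_acids", "production_only",
                   "mean_prod_cons")
  qc <- rep("", length(pool_size))
  fallback <- pool != "amino_acids" & !is.na(consumption) & consumption < 0
  denom[fallback] <- production[fallback]
  method[fallback] <- "production_only"
  qc[fallback] <- "NEGATIVE_CONSUMPTION_FALLBACK"
  bad <- is.na(denom) | denom <= 0
  tau <- pool_size / denom
  tau[bad] <- NA_real_
  qc[bad] <- "NONPOSITIVE_RATE"
  tibble::tibble(pool = pool, turnover_h = tau, method = method, qc = qc)
}

#' Scale a mass-specific rate to an areal flux
#'
#' Converts a rate per g soil DW to a flux per m^2 ground, assuming the
#' whole organic horizon cycles at the measured rate: soil mass per m^2 is
#' bulk density (g DW cm^-3) x horizon depth (cm) x 1e4 cm^2 m^-2.
#'
#' @param rate_ugN_gDW_day Rate, ug N g^-1 DW day^-1.
#' @param bulk_density_g_cm3 Bulk density, g DW cm^-3.
#' @param horizon_depth_cm Organic horizon depth, cm.
#' @return Flux, g N m^-2 day^-1
#'   (`rate * bulk_density * depth / 100`).
#' @export
#' @examples
#' scale_to_area(100, 0.1, 10) # 1 g N m-2 day-1
scale_to_area <- function(rate_ugN_gDW_day, bulk_density_g_cm3,
                          horizon_depth_cm) {
  if (any(bulk_density_g_cm3 <= 0) || any(horizon_depth_cm <= 0)) {
    stop("bulk density and horizon depth must be positive")
  }
  rate_ugN_gDW_day * 1e-6 * bulk_density_g_cm3 * horizon_depth_cm * 1e4
}

#' Seasonal change summary (early vs late growing season)
#'
#' Per group (species or PFT), the percent drop of the group mean from
#' early to late season on the untransformed scale, and the late-season
#' mean as a percent of the early-season mean.
#'
#' @param data Data frame with a `season` column (`"early"`/`"late"`).
#' @param value Name of the measurement column.
#' @param group Name of the grouping column (e.g. `"species"` or `"pft"`).
#' @return Tibble with `group`, `mean_early`, `mean_late`, `pct_drop`
#'   (`100 (early - late)/early`) and `late_pct_of_early`.
#' @export
seasonal_change <- function(data, value, group) {
  stopifnot(all(c("season", value, group) %in% names(data)))
  agg <- tapply(data[[value]],
                list(data[[group]], data$season),
                mean, na.rm = TRUE)
  if (!all(c("early", "late") %in% colnames(agg))) {
    stop("both seasons must be present")
  }
  e <- agg[, "early"]; l <- agg[, "late"]
  if (any(is.na(e)) || any(is.na(l))) {
    stop("both seasons must be present in every group")
  }
  if (any(e <= 0)) stop("early-season mean must be > 0")
  tibble::tibble(
    group = rownames(agg),
    mean_early = unname(e),
    mean_late = unname(l),
    pct_drop = unname(100 * (e - l) / e),
    late_pct_of_early = unname(100 * l / e)
  )
}
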
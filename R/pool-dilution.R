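#' Atom percent excess
#'
#' APE is the sample 15N atom percent minus the background
#' (natural-abundance) atom percent. Samples at or below background are
#' floored to 0 and flagged as unlabelled via the `"qc_unlabelled"`
#' attribute.
#'
#' @param atom_pct_sample Sample 15N abundance, atom %.
#' @param background_atom_pct Background 15N abundance, atom % (in (0,100)).
#' @return Numeric APE (atom %), attribute `"qc_unlabelled"` logical.
#' @export
#' @examples
#' ape(15.3663, 0.3663) # 15
ape <- function(atom_pct_sample, background_atom_pct = 0.3663) {
  if (any(background_atom_pct <= 0 | background_atom_pct >= 100)) {
    stop("background_atom_pct must be in (0, 100)")
  }
  out <- atom_pct_sample - background_atom_pct
  flagged <- out <= 0
  out[flagged] <- 0
  attr(out, "qc_unlabelled") <- flagged
  out
}

#' 15N label addition per gram soil dry weight
#'
#' Mass of N added by a tracer solution, expressed per g soil DW:
#' `volume_uL * conc_mM / 1000` umol N times 14.0067 ug N per umol, divided
#' by the dry weight of the amended fresh soil.
#'
#' @param volume_uL Label solution volume, uL.
#' @param conc_mM Label concentration, mmol N L^-1.
#' @param soil_fw_g Fresh soil amended, g.
#' @param moisture_frac Gravimetric moisture, fraction of FW.
#' @return ug N g^-1 DW.
#' @export
#' @examples
#' label_addition_per_gDW(500, 0.13, 2, 0.75) # ~1.82
label_addition_per_gDW <- function(volume_uL, conc_mM, soil_fw_g,
                                   moisture_frac) {
  stopifnot(volume_uL >= 0, conc_mM >= 0, soil_fw_g > 0)
  ug_n <- volume_uL * conc_mM / 1000 * UG_N_PER_UMOL
  ug_n / fresh_to_dry(soil_fw_g, moisture_frac)
}

#' Isotopic enrichment of a pool after label addition
#'
#' Mass-weighted mean atom percent of the mixed pool formed by adding a
#' highly enriched label to a pool at background abundance.
#'
#' @param pool_before Pool size before addition, ug N g^-1 DW (>= 0).
#' @param label_added Label N added, ug N g^-1 DW.
#' @param label_atom_pct Label enrichment, atom %.
#' @param background_atom_pct Pool abundance before addition, atom %.
#' @return Atom % of the mixed pool.
#' @export
#' @examples
#' initial_enrichment(1.8, 1.8, 99, 0.3663) # 49.683
initial_enrichment <- function(pool_before, label_added,
                               label_atom_pct = 99,
                               background_atom_pct = 0.3663) {
  if (any(pool_before < 0)) stop("pool_before must be >= 0")
  total <- pool_before + label_added
  if (any(total == 0)) stop("pool_before + label_added must be > 0")
  (pool_before * background_atom_pct + label_added * label_atom_pct) / total
}

#' Gross rates from 15N pool dilution (Kirkham-Bartholomew)
#'
#' Estimates gross production, net rate and gross consumption of an
#' inorganic N pool (ammonium or nitrate) from its size and 15N enrichment
#' at the start and end of an incubation. Production of unlabelled N
#' dilutes the tracer, so with `A0`, `At` the pool sizes (ug N g^-1 DW),
#' `APE0`, `APEt` the atom percent excesses and `t` the interval (h):
#'
#' \deqn{net = (A_t - A_0)/t}
#' \deqn{gross = (A_t - A_0)/t \cdot \ln(APE_0/APE_t) / \ln(A_t/A_0)}
#' \deqn{consumption = gross - net}
#'
#' When `|At - A0| < eps * A0` the removable singularity is handled by the
#' analytic limit `gross = A0 ln(APE0/APEt)/t` (flag `NEAR_ZERO_NET_LIMIT`).
#' The same equations serve the nitrate pool (gross nitrification and
#' nitrate consumption). Rows with rising APE (impossible under dilution)
#' get `APE_INCREASE` and missing production/consumption; negative
#' consumption (net exceeding gross) is reported as-is with
#' `NEGATIVE_CONSUMPTION`.
#'
#' @param obs Data frame with columns `A0`, `At`, `atom_pct_0`,
#'   `atom_pct_t`, `background_atom_pct`, `t_h`, and optionally
#'   `sample_id` and `pool` (`"ammonium"`/`"nitrate"`), one row per assay
#'   observation.
#' @param eps Relative threshold for the near-zero-net limit branch
#'   (default 1e-6).
#' @return Tibble with `sample_id`, `pool`, `gross_production`, `net_rate`,
#'   `gross_consumption` (ug N g^-1 DW h^-1) and `flags`
#'   (comma-separated).
#' @export
#' @examples
#' gross_rates(data.frame(A0 = 10, At = 20, atom_pct_0 = 15.3663,
#'                        atom_pct_t = 4.1163, background_atom_pct = 0.3663,
#'                        t_h = 20))
gross_rates <- function(obs, eps = 1e-6) {
  need <- c("A0", "At", "atom_pct_0", "atom_pct_t", "background_atom_pct",
            "t_h")
  missing <- setdiff(need, names(obs))
  if (length(missing) > 0) {
    stop("obs is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (any(obs$A0 <= 0)) stop("A0 must be > 0")
  if (any(obs$At <= 0)) stop("At must be > 0")
  if (any(obs$t_h <= 0)) stop("t must be > 0")

  ape0 <- as.numeric(ape(obs$atom_pct_0, obs$background_atom_pct))
  apet <- as.numeric(ape(obs$atom_pct_t, obs$background_atom_pct))
  if (any(ape0 <= 0)) stop("APE at timepoint 0 must be > 0 (labelled pool)")
  if (any(apet <= 0)) stop("APE at time t must be > 0")

  n <- nrow(obs)
  net <- (obs$At - obs$A0) / obs$t_h
  gross <- rep(NA_real_, n)
  flags <- vector("list", n)

  increase <- apet > ape0
  limit <- !increase & abs(obs$At - obs$A0) < eps * obs$A0
  regular <- !increase & !limit

  lr <- log(ape0 / apet)
  gross[regular] <- net[regular] * lr[regular] /
    log(obs$At[regular] / obs$A0[regular])
  gross[limit] <- obs$A0[limit] * lr[limit] / obs$t_h[limit]

  cons <- gross - net
  for (i in seq_len(n)) {
    f <- character(0)
    if (increase[i]) f <- c(f, "APE_INCREASE")
    if (limit[i]) f <- c(f, "NEAR_ZERO_NET_LIMIT")
    if (!is.na(cons[i]) && cons[i] < 0) f <- c(f, "NEGATIVE_CONSUMPTION")
    flags[[i]] <- f
  }

  tibble::tibble(
    sample_id = if ("sample_id" %in% names(obs)) obs$sample_id else
      as.character(seq_len(n)),
    pool = if ("pool" %in% names(obs)) obs$pool else "ammonium",
    gross_production = gross,
    net_rate = net,
    gross_consumption = cons,
    flags = vapply(flags, paste, character(1), collapse = ",")
  )
}

#' Assemble assay observations from an IRMS table
#'
#' Pairs the timepoint-0 and timepoint-t rows of an IRMS export
#' (`sample_id, pool, timepoint, pool_ugN_per_gDW, atom_pct_15N`, optional
#' `replicate`), averaging duplicate assay subsamples per sample and pool,
#' and attaches the incubation interval and 15N background from the
#' configuration.
#'
#' @param irms Data frame or CSV path of IRMS results. `timepoint` must be
#'   `0` or `"t"`.
#' @param config An [analysis_config()].
#' @return Observation tibble suitable for [gross_rates()].
#' @export
assemble_assay_observations <- function(irms, config = analysis_config()) {
  df <- if (is.data.frame(irms)) as.data.frame(irms) else {
    read.csv(irms, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  }
  need <- c("sample_id", "pool", "timepoint", "pool_ugN_per_gDW",
            "atom_pct_15N")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("irms table is missing column(s): ", paste(missing, collapse = ", "))
  }
  df$timepoint <- as.character(df$timepoint)
  if (!all(df$timepoint %in% c("0", "t"))) {
    stop("timepoint must be 0 or t")
  }
  agg <- dplyr::summarise(
    dplyr::group_by(df, .data$sample_id, .data$pool, .data$timepoint),
    pool_ugN_per_gDW = mean(.data$pool_ugN_per_gDW),
    atom_pct_15N = mean(.data$atom_pct_15N),
    .groups = "drop"
  )
  wide <- tidyr::pivot_wider(
    agg, names_from = "timepoint",
    values_from = c("pool_ugN_per_gDW", "atom_pct_15N")
  )
  tibble::tibble(
    sample_id = wide$sample_id,
    pool = wide$pool,
    A0 = wide$pool_ugN_per_gDW_0,
    At = wide$pool_ugN_per_gDW_t,
    atom_pct_0 = wide$atom_pct_15N_0,
    atom_pct_t = wide$atom_pct_15N_t,
    background_atom_pct = config$background_atom_pct,
    t_h = config$t_hours
  )
}
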
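#' Species to plant-functional-type map
#'
#' The six target species of the field design: three dwarf shrubs
#' (*Empetrum hermaphroditum*, *Arctostaphylos alpinus*, *Betula nana*) and
#' three mosses (*Hylocomium splendens*, *Aulacomnium turgidum*,
#' *Tomentypnum nitens*). The map is total over these species and partitions
#' them 3/3 into the two plant functional types (PFTs).
#'
#' @return Named character vector mapping species name to `"shrub"` or
#'   `"moss"`.
#' @export
#' @examples
#' species_pft_map()
species_pft_map <- function() {
  c(
    "Empetrum hermaphroditum" = "shrub",
    "Arctostaphylos alpinus"  = "shrub",
    "Betula nana"             = "shrub",
    "Hylocomium splendens"    = "moss",
    "Aulacomnium turgidum"    = "moss",
    "Tomentypnum nitens"      = "moss"
  )
}

#' Dry weight from fresh weight and gravimetric moisture
#'
#' @param fresh_weight_g Fresh weight in grams.
#' @param moisture_frac Gravimetric moisture as a fraction of fresh weight,
#'   in `[0, 1)`.
#' @return Dry weight in grams: `fresh_weight_g * (1 - moisture_frac)`.
#' @export
#' @examples
#' fresh_to_dry(2, 0.75) # 0.5 g DW
fresh_to_dry <- function(fresh_weight_g, moisture_frac) {
  stopifnot(is.numeric(fresh_weight_g), is.numeric(moisture_frac))
  if (any(moisture_frac < 0 | moisture_frac >= 1)) {
    stop("moisture_frac must be in [0, 1)")
  }
  fresh_weight_g * (1 - moisture_frac)
}

sample_table_columns <- c(
  "sample_id", "block", "species", "season", "location_id",
  "fresh_weight_g", "moisture_frac"
)

validate_sample_table <- function(df) {
  missing <- setdiff(sample_table_columns, names(df))
  if (length(missing) > 0) {
    stop("sample table is missing column(s): ", paste(missing, collapse = ", "))
  }
  map <- species_pft_map()
  unknown <- setdiff(unique(df$species), names(map))
  if (length(unknown) > 0) {
    stop("unmapped species: ", paste(unknown, collapse = ", "))
  }
  if (any(!df$season %in% c("early", "late"))) {
    stop("season must be 'early' or 'late'")
  }
  if (any(df$moisture_frac <= 0 | df$moisture_frac >= 1)) {
    stop("moisture_frac outside (0, 1)")
  }
  if (any(df$fresh_weight_g <= 0)) stop("fresh_weight_g must be positive")
  # one sampling location belongs to one block and is revisited at most once
  loc <- unique(df[, c("location_id", "block")])
  if (anyDuplicated(loc$location_id) > 0) {
    stop("location_id assigned to more than one block")
  }
  n_seas <- tapply(df$season, df$location_id, function(s) length(unique(s)))
  if (any(tapply(df$season, df$location_id, length) > 2)) {
    stop("a location_id appears more than twice (max one sample per season)")
  }
  invisible(df)
}

#' Read a field sample table
#'
#' Reads `samples.csv` (columns `sample_id, block, species, season,
#' location_id, fresh_weight_g, moisture_frac`), validates it against the
#' fixed design (known species, seasons `early`/`late`, moisture in (0,1),
#' sampling locations nested in blocks and revisited at most once across
#' seasons) and derives the plant functional type from the species.
#'
#' @param path Path to a CSV file, or a data frame with the same columns.
#' @return A tibble of validated samples with an added `pft` column.
#' @export
read_sample_table <- function(path) {
  df <- if (is.data.frame(path)) as.data.frame(path) else {
    read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  }
  validate_sample_table(df)
  df$pft <- unname(species_pft_map()[df$species])
  df$block <- as.character(df$block)
  tibble::as_tibble(df[, c(sample_table_columns[1:5], "pft",
                           sample_table_columns[6:7])])
}

#' Write a field sample table
#'
#' @param samples Tibble as returned by [read_sample_table()] (the derived
#'   `pft` column is dropped on write).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(samples, path) {
  validate_sample_table(samples)
  write.csv(samples[, sample_table_columns], path, row.names = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

site_property_columns <- c(
  "species", "c_pct", "n_pct", "cn_ratio", "moisture_pct_fw", "ph",
  "bulk_density_g_cm3", "horizon_depth_cm"
)

#' Read per-species site (soil) properties
#'
#' One row per species: organic-horizon C and N content (% of DW), C:N
#' ratio, soil moisture (% of FW), pH, bulk density (g DW cm^-3) and organic
#' horizon depth (cm). Optional `*_se` columns carry standard errors of the
#' means and are kept if present.
#'
#' @param path CSV path or data frame. The packaged summary table of the
#'   study sites is at `system.file("extdata", "site_properties.csv",
#'   package = "tundraN")`.
#' @return Tibble with one row per species.
#' @export
read_site_properties <- function(path) {
  df <- if (is.data.frame(path)) as.data.frame(path) else {
    read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  }
  missing <- setdiff(site_property_columns, names(df))
  if (length(missing) > 0) {
    stop("site property table is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$species) > 0) stop("duplicate species rows")
  num <- df[, setdiff(site_property_columns, "species")]
  if (any(!vapply(num, is.numeric, logical(1))) || any(as.matrix(num) <= 0)) {
    stop("all site properties must be strictly positive numbers")
  }
  # C:N is reported rounded; tolerate up to 10% discrepancy with C/N
  rel <- abs(df$cn_ratio - df$c_pct / df$n_pct) / df$cn_ratio
  if (any(rel > 0.10)) {
    warning("cn_ratio deviates >10% from c_pct/n_pct for: ",
            paste(df$species[rel > 0.10], collapse = ", "))
  }
  tibble::as_tibble(df)
}

#' Packaged site-property table
#'
#' Convenience accessor for the site-property summary shipped with the
#' package (per-species means and standard errors, n = 5 blocks).
#'
#' @return Tibble, see [read_site_properties()].
#' @export
default_site_properties <- function() {
  read_site_properties(system.file("extdata", "site_properties.csv",
                                   package = "tundraN", mustWork = TRUE))
}

#' Analysis configuration
#'
#' Bundles the assay and inference constants used across the pipeline.
#'
#' @param t_hours Pool-dilution incubation interval between the two
#'   extractions, hours. Default 20 (extractions 4 h and 24 h after label
#'   addition, with 4 h taken as timepoint 0 of the assay).
#' @param background_atom_pct Background (natural-abundance) 15N atom
#'   percent subtracted when forming atom percent excess. Default 0.3663
#'   atom %. The value is configurable and echoed in outputs.
#' @param label_volume_uL,label_conc_mM,label_atom_pct 15N label addition:
#'   volume (uL), concentration (mM) and isotopic enrichment (atom %).
#'   Defaults 500 uL of 0.13 mM at 99 atom %.
#' @param assay_soil_fw_g Fresh soil per assay subsample, grams (default 2).
#' @param extraction_ratio Salt-extraction ratio, mL extractant per g fresh
#'   soil (default 10, i.e. 1:10 w/w).
#' @param transforms Named character vector mapping response names to
#'   `"none"`, `"sqrt"` or `"log"` for the ANOVA layer; defaults to
#'   [default_transform_map()].
#' @param posthoc_threshold Interaction p-value below which post-hoc
#'   contrasts are conditioned on season and species (default 0.05).
#' @param output_units `"per_hour"` (internal unit, ug N g-1 DW h-1) or
#'   `"per_day"` for reported rates.
#' @return A list with class `"n_analysis_config"`.
#' @export
analysis_config <- function(t_hours = 20,
                            background_atom_pct = 0.3663,
                            label_volume_uL = 500,
                            label_conc_mM = 0.13,
                            label_atom_pct = 99,
                            assay_soil_fw_g = 2,
                            extraction_ratio = 10,
                            transforms = default_transform_map(),
                            posthoc_threshold = 0.05,
                            output_units = c("per_hour", "per_day")) {
  output_units <- match.arg(output_units)
  stopifnot(t_hours > 0,
            background_atom_pct > 0, background_atom_pct < 1,
            label_atom_pct > background_atom_pct, label_atom_pct <= 100,
            posthoc_threshold > 0, posthoc_threshold < 1,
            extraction_ratio > 0, assay_soil_fw_g > 0)
  structure(list(
    t_hours = t_hours,
    background_atom_pct = background_atom_pct,
    label_volume_uL = label_volume_uL,
    label_conc_mM = label_conc_mM,
    label_atom_pct = label_atom_pct,
    assay_soil_fw_g = assay_soil_fw_g,
    extraction_ratio = extraction_ratio,
    transforms = transforms,
    posthoc_threshold = posthoc_threshold,
    output_units = output_units
  ), class = "n_analysis_config")
}

#' @export
print.n_analysis_config <- function(x, ...) {
  cat("N-cycling analysis configuration\n")
  cat("  incubation interval t:", x$t_hours, "h\n")
  cat("  background 15N:", x$background_atom_pct, "atom %\n")
  cat("  label:", x$label_volume_uL, "uL of", x$label_conc_mM, "mM at",
      x$label_atom_pct, "atom % on", x$assay_soil_fw_g, "g FW\n")
  cat("  extraction ratio:", x$extraction_ratio, "mL g-1 FW\n")
  cat("  reported rate units:", x$output_units, "\n")
  invisible(x)
}

#' Read/write an analysis configuration as YAML
#'
#' @param path YAML file path.
#' @return For `read_analysis_config`, an `"n_analysis_config"` object.
#' @export
read_analysis_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$transforms <- unlist(x$transforms)
  do.call(analysis_config, x)
}

#' @rdname read_analysis_config
#' @param config An `"n_analysis_config"` object.
#' @export
write_analysis_config <- function(config, path) {
  stopifnot(inherits(config, "n_analysis_config"))
  x <- unclass(config)
  x$transforms <- as.list(x$transforms)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Rate unit conversion
#'
#' Internal rates are ug N g-1 DW h-1; reporting may use per-day.
#'
#' @param rate Numeric rate(s) in ug N g-1 DW h-1.
#' @return Rate in ug N g-1 DW day-1.
#' @export
per_hour_to_per_day <- function(rate) rate * 24
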
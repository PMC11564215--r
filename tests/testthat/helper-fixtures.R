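# Small in-code fixtures shared across test files.

# Full-design sample table (5 blocks x 6 species x 2 seasons).
make_design_samples <- function(blocks = 5) {
  sp <- names(tundraN::species_pft_map())
  code <- c("Ehe", "Aal", "Bna", "Hsp", "Atu", "Tni")
  d <- expand.grid(block = seq_len(blocks), species = sp,
                   season = c("early", "late"), stringsAsFactors = FALSE)
  d$location_id <- sprintf("B%d_%s", d$block, code[match(d$species, sp)])
  d$sample_id <- paste0(d$location_id, "_", d$season)
  d$fresh_weight_g <- 20
  d$moisture_frac <- 0.75
  d[, c("sample_id", "block", "species", "season", "location_id",
        "fresh_weight_g", "moisture_frac")]
}

packaged_site_properties_path <- function() {
  system.file("extdata", "site_properties.csv", package = "tundraN",
              mustWork = TRUE)
}

# Assay observations generated by the closed-form forward model for given
# true rates, on the estimator's input scale.
obs_from_truth <- function(m, c, A0, ape0 = 15, bg = 0.3663, t_h = 20) {
  # choose a label/pool split that realises the requested APE0 exactly
  frac <- ape0 / (99 - bg)
  tundraN::simulate_assay_closed_form(
    m, c, pool_before = A0 * (1 - frac), label_added = A0 * frac,
    label_atom_pct = 99, background_atom_pct = bg, t_h = t_h)
}
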
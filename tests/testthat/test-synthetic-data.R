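test_that("closed form reproduces the worked dilution example", {
  # m = 1, c = 0.5, post-label pool 10 at APE0 = 15, t = 20 h
  cf <- obs_from_truth(1, 0.5, 10)
  expect_equal(cf$A0, 10)
  expect_equal(cf$atom_pct_0 - 0.3663, 15)
  expect_equal(cf$At, 20)
  expect_equal(cf$atom_pct_t - 0.3663, 3.75, tolerance = 1e-12)
})

test_that("balanced rates keep the total pool constant", {
  cf <- obs_from_truth(0.7, 0.7, 10)
  expect_equal(cf$At, cf$A0)
  # and the excess decays exponentially
  expect_equal(cf$atom_pct_t - 0.3663,
               15 * exp(-0.7 * 20 / 10), tolerance = 1e-12)
})

test_that("pure dilution (c = 0) gives APEt = APE0 * A0/At", {
  cf <- obs_from_truth(0.9, 0, 10)
  expect_equal(cf$atom_pct_t - 0.3663, 15 * cf$A0 / cf$At,
               tolerance = 1e-12)
})

test_that("closed form matches the RK4 oracle on a random grid", {
  set.seed(51)
  n <- 40
  m <- runif(n, 0, 2)
  c <- runif(n, 0, 2)
  A0 <- runif(n, 1, 50)
  t_h <- runif(n, 1, 48)
  keep <- A0 + (m - c) * t_h > 0.05 * A0
  m <- m[keep]; c <- c[keep]; A0 <- A0[keep]; t_h <- t_h[keep]
  for (i in seq_along(m)) {
    cf <- obs_from_truth(m[i], c[i], A0[i], t_h = t_h[i])
    H0 <- cf$A0 * (cf$atom_pct_0 - 0.3663) / 100
    o <- ode_oracle(m[i], c[i], cf$A0, H0, t_h[i], steps = 4000)
    expect_equal(o$A, cf$At, tolerance = 1e-9)
    Ht <- cf$At * (cf$atom_pct_t - 0.3663) / 100
    expect_equal(o$H, Ht, tolerance = 1e-9)
  }
})

test_that("RK4 oracle identity and exhaustion cases", {
  o <- ode_oracle(0, 0, 10, 1.5, 20, steps = 100)
  expect_equal(o$A, 10)
  expect_equal(o$H, 1.5)
  expect_error(ode_oracle(0, 1, 5, 1, 20, steps = 200), "exhausted")
  expect_error(simulate_assay_closed_form(0, 1, 5, 0.5, t_h = 20),
               "exhausts")
})

test_that("estimator recovers the time-average of a declining rate", {
  # production declining linearly to half its initial value over the assay
  m0 <- 1; cc <- 0.5; T <- 20
  o <- ode_oracle(function(t) m0 * (1 - 0.5 * t / T), cc,
                  A0 = 12, H0 = 12 * 0.15, t_h = T, steps = 5000)
  obs <- data.frame(A0 = 12, At = o$A, atom_pct_0 = 15.3663,
                    atom_pct_t = 0.3663 + 100 * o$H / o$A,
                    background_atom_pct = 0.3663, t_h = T)
  r <- gross_rates(obs)
  expect_lt(abs(r$gross_production - 0.75 * m0) / (0.75 * m0), 0.10)
})

test_that("default truth table encodes the intended field contrasts", {
  tt <- default_truth_table()
  expect_equal(nrow(tt), 12)
  wide <- merge(tt[tt$season == "early", ], tt[tt$season == "late", ],
                by = "species", suffixes = c("_e", "_l"))
  # depolymerisation roughly one order of magnitude above mineralisation
  ratio <- tt$depoly / tt$gross_min
  expect_true(all(ratio[tt$season == "early"] >= 5))
  # mosses decline steeply, the evergreen shrub stays flat
  moss <- wide$species %in% c("Hylocomium splendens",
                              "Aulacomnium turgidum", "Tomentypnum nitens")
  expect_true(all(1 - wide$gross_min_l[moss] / wide$gross_min_e[moss] >=
                    0.70))
  ever <- wide$species == "Empetrum hermaphroditum"
  expect_equal(wide$gross_min_l[ever], wide$gross_min_e[ever])
  expect_true(all(as.matrix(tt[, -(1:2)]) > 0))
})

test_that("simulated studies have the design arithmetic and determinism", {
  cfg <- simulation_config()
  b1 <- simulate_study(cfg, seed = 9)
  expect_equal(nrow(b1$samples), 60)
  # 60 samples x 2 pools x 2 timepoints x 2 duplicates
  expect_equal(nrow(b1$irms), 480)
  expect_equal(nrow(b1$slurry), 180)
  b2 <- simulate_study(cfg, seed = 9)
  expect_identical(b1, b2)
  b3 <- simulate_study(cfg, seed = 10)
  expect_false(identical(b1$irms, b3$irms))
})

test_that("written bundles are byte-identical under the same seed", {
  cfg <- simulation_config()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_study(cfg, seed = 3, dir = d1)
  simulate_study(cfg, seed = 3, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  expect_true(file.exists(file.path(d1, "manifest.yaml")))
})

test_that("noise-free simulation is inverted exactly by the pipeline", {
  cfg <- simulation_config(noise = zero_noise())
  b <- simulate_study(cfg, seed = 2)
  res <- analyse_study(b, cfg$analysis)
  m <- merge(res$responses, b$sample_truth[, c(
    "sample_id", "gross_min", "nh4_cons", "gross_nit", "no3_cons",
    "depoly", "pool_aa", "pool_nh4", "pool_no3")], by = "sample_id")
  expect_equal(m$free_amino_acids, m$pool_aa, tolerance = 1e-10)
  expect_equal(m$ammonium, m$pool_nh4, tolerance = 1e-10)
  expect_equal(m$nitrate, m$pool_no3, tolerance = 1e-10)
  expect_equal(m$depolymerisation, m$depoly, tolerance = 1e-10)
  expect_equal(m$gross_mineralisation, m$gross_min, tolerance = 1e-10)
  expect_equal(m$gross_nh4_consumption, m$nh4_cons, tolerance = 1e-10)
  expect_equal(m$gross_nitrification, m$gross_nit, tolerance = 1e-10)
  expect_equal(m$gross_no3_consumption, m$no3_cons, tolerance = 1e-10)
  # turnover follows from exact pools and rates
  expect_equal(m$turnover_amino_acids, m$pool_aa / m$depoly,
               tolerance = 1e-10)
  expect_equal(m$turnover_ammonium,
               m$pool_nh4 / ((m$gross_min + m$nh4_cons) / 2),
               tolerance = 1e-10)
})

test_that("configured seasonal declines are reproduced by the summaries", {
  cfg <- simulation_config(noise = zero_noise())
  b <- simulate_study(cfg, seed = 4)
  res <- analyse_study(b, cfg$analysis)
  r <- res$responses
  moss <- r[r$pft == "moss", ]
  sc <- seasonal_change(moss, "ammonium", "pft")
  expect_equal(sc$pct_drop, 60, tolerance = 1e-6)
  eh <- r[r$species == "Empetrum hermaphroditum", ]
  expect_equal(seasonal_change(eh, "ammonium", "species")$pct_drop, 75,
               tolerance = 1e-6)
  expect_equal(seasonal_change(eh, "nitrate", "species")$late_pct_of_early,
               10, tolerance = 1e-6)
  scm <- seasonal_change(moss, "gross_mineralisation", "pft")
  expect_gt(scm$pct_drop, 70)
})

test_that("parameter recovery is exact without noise", {
  cfg <- simulation_config(noise = zero_noise())
  rep1 <- parameter_recovery_report(cfg, n_reps = 1, seed = 1)
  expect_lt(max(abs(rep1$rel_bias)), 1e-9)
  expect_lt(max(rep1$rel_rmse), 1e-9)
})

test_that("noise model and config validate their inputs", {
  expect_error(noise_model(sd_block = -1), ">= 0")
  tt <- default_truth_table()
  tt$gross_min[1] <- -1
  expect_error(simulation_config(truth = tt), "nonnegative")
})
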
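test_that("atom percent excess subtracts background and flags unlabelled", {
  expect_equal(as.numeric(ape(15.3663, 0.3663)), 15)
  expect_equal(as.numeric(ape(99, 0.3663)), 98.6337)
  z <- ape(0.3663, 0.3663)
  expect_equal(as.numeric(z), 0)
  expect_true(attr(z, "qc_unlabelled"))
  expect_error(ape(5, 0), "background")
  expect_error(ape(5, 100), "background")
})

test_that("label addition per g DW matches the assay protocol", {
  expect_equal(label_addition_per_gDW(500, 0.13, 2, 0.75),
               0.5 * 0.13 * 14.0067 / 1000 * 1000 / 0.5) # 1.8209
  expect_equal(round(label_addition_per_gDW(500, 0.13, 2, 0.75), 1), 1.8)
  expect_equal(label_addition_per_gDW(0, 0.13, 2, 0.75), 0)
  expect_equal(label_addition_per_gDW(500, 0.13, 2, 0.760),
               0.910436 / 0.48, tolerance = 1e-5)
})

test_that("initial enrichment is the mass-weighted mean atom percent", {
  expect_equal(initial_enrichment(0, 1.8, 99, 0.3663), 99)
  expect_equal(initial_enrichment(1.8, 1.8, 99, 0.3663), (0.3663 + 99) / 2)
  expect_equal(round(initial_enrichment(1.8, 1.8, 99, 0.3663), 3), 49.683)
  expect_equal(initial_enrichment(5, 0, 99, 0.3663), 0.3663)
  expect_error(initial_enrichment(0, 0), "> 0")
})

test_that("gross rates reproduce the closed-form worked example", {
  # m = 1, c = 0.5, A0 = 10, APE0 = 15, t = 20 h  ->  At = 20, APEt = 3.75
  obs <- data.frame(A0 = 10, At = 20, atom_pct_0 = 15.3663,
                    atom_pct_t = 4.1163, background_atom_pct = 0.3663,
                    t_h = 20)
  r <- gross_rates(obs)
  expect_equal(r$gross_production, 1.0)
  expect_equal(r$net_rate, 0.5)
  expect_equal(r$gross_consumption, 0.5)
  expect_equal(r$flags, "")
})

test_that("near-zero-net limit branch recovers m = c", {
  obs <- data.frame(A0 = 10, At = 10, atom_pct_0 = 15.3663,
                    atom_pct_t = 7.8663, background_atom_pct = 0.3663,
                    t_h = 20)
  r <- gross_rates(obs)
  expect_equal(r$gross_production, 10 * log(2) / 20)
  expect_equal(r$net_rate, 0)
  expect_equal(r$gross_consumption, 10 * log(2) / 20)
  expect_match(r$flags, "NEAR_ZERO_NET_LIMIT")
})

test_that("no dilution and no pool change means all rates are zero", {
  obs <- data.frame(A0 = 10, At = 10, atom_pct_0 = 15.3663,
                    atom_pct_t = 15.3663, background_atom_pct = 0.3663,
                    t_h = 20)
  r <- gross_rates(obs)
  expect_equal(r$gross_production, 0)
  expect_equal(r$net_rate, 0)
  expect_equal(r$gross_consumption, 0)
})

test_that("rising APE yields missing production with a flag", {
  obs <- data.frame(A0 = 10, At = 12, atom_pct_0 = 5,
                    atom_pct_t = 7, background_atom_pct = 0.3663, t_h = 20)
  r <- gross_rates(obs)
  expect_true(is.na(r$gross_production))
  expect_equal(r$net_rate, 0.1)
  expect_match(r$flags, "APE_INCREASE")
})

test_that("negative consumption is reported, not clipped", {
  # strong net increase with little dilution -> net > gross
  cf <- obs_from_truth(m = 1, c = 0.1, A0 = 10)
  names(cf)[names(cf) == "t_h"] <- "t_h"
  r <- gross_rates(as.data.frame(cf))
  expect_equal(r$gross_production, 1, tolerance = 1e-10)
  expect_equal(r$gross_consumption, 0.1, tolerance = 1e-9)
  cf2 <- within(as.data.frame(cf), atom_pct_t <- atom_pct_0 -
                  0.2 * (atom_pct_0 - 0.3663))
  r2 <- gross_rates(cf2)
  expect_true(r2$gross_consumption < 0)
  expect_match(r2$flags, "NEGATIVE_CONSUMPTION")
})

test_that("estimator inverts the constant-rate forward model exactly", {
  set.seed(101)
  n <- 200
  m <- runif(n, 0.01, 2)
  c <- runif(n, 0, 2)
  A0 <- runif(n, 1, 50)
  t_h <- runif(n, 1, 48)
  # keep the pool from exhausting
  keep <- A0 + (m - c) * t_h > 0.05 * A0
  cf <- obs_from_truth(m[keep], c[keep], A0[keep], t_h = t_h[keep])
  r <- gross_rates(as.data.frame(cf))
  expect_lt(max(abs(r$gross_production - m[keep]) / m[keep]), 1e-8)
  expect_lt(max(abs(r$gross_consumption - c[keep]) /
                  pmax(c[keep], 1e-3)), 1e-8)
  expect_lt(max(abs(r$net_rate - (m[keep] - c[keep]))), 1e-8)
})

test_that("gross rates are invariant to rescaling atom percent excess", {
  cf <- as.data.frame(obs_from_truth(0.8, 0.5, 12))
  r1 <- gross_rates(cf)
  cf2 <- cf
  cf2$atom_pct_0 <- 0.3663 + 0.5 * (cf$atom_pct_0 - 0.3663)
  cf2$atom_pct_t <- 0.3663 + 0.5 * (cf$atom_pct_t - 0.3663)
  r2 <- gross_rates(cf2)
  expect_equal(r2$gross_production, r1$gross_production)
  expect_equal(r2$gross_consumption, r1$gross_consumption)
})

test_that("ammonium and nitrate flow through the same estimator", {
  cf <- as.data.frame(obs_from_truth(c(0.6, 0.6), c(0.4, 0.4), c(8, 8)))
  cf$pool <- c("ammonium", "nitrate")
  cf$sample_id <- c("s1", "s1")
  r <- gross_rates(cf)
  expect_equal(r$gross_production[1], r$gross_production[2])
  expect_equal(r$gross_consumption[1], r$gross_consumption[2])
})

test_that("gross_rates validates its inputs", {
  base <- data.frame(A0 = 10, At = 12, atom_pct_0 = 15, atom_pct_t = 10,
                     background_atom_pct = 0.3663, t_h = 20)
  bad <- base; bad$A0 <- -1
  expect_error(gross_rates(bad), "A0")
  bad <- base; bad$t_h <- 0
  expect_error(gross_rates(bad), "t")
  bad <- base; bad$atom_pct_t <- 0.3663
  expect_error(gross_rates(bad), "APE")
})

test_that("duplicate IRMS subsamples are averaged per observation", {
  cfg <- analysis_config()
  irms <- data.frame(
    sample_id = "s1", pool = "ammonium",
    timepoint = rep(c("0", "t"), each = 2),
    replicate = rep(1:2, 2),
    pool_ugN_per_gDW = c(10, 12, 19, 21),
    atom_pct_15N = c(15, 16, 4, 5))
  obs <- assemble_assay_observations(irms, cfg)
  expect_equal(nrow(obs), 1)
  expect_equal(obs$A0, 11)
  expect_equal(obs$At, 20)
  expect_equal(obs$atom_pct_0, 15.5)
  expect_equal(obs$t_h, cfg$t_hours)
  expect_equal(obs$background_atom_pct, cfg$background_atom_pct)
})
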
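test_that("response transforms and their inverses", {
  expect_equal(transform_response(c(0, 1, 4, 9), "sqrt"), c(0, 1, 2, 3))
  expect_equal(transform_response(c(1, 2), "none"), c(1, 2))
  expect_equal(transform_response(exp(1:3), "log"), 1:3)
  expect_error(transform_response(c(1, 0, 2), "log"), "row\\(s\\): 2")
  expect_error(transform_response(c(-1, 2), "sqrt"), "row\\(s\\): 1")
  x <- runif(10, 0.1, 5)
  for (tr in c("none", "sqrt", "log")) {
    expect_equal(inverse_transform(transform_response(x, tr), tr), x)
  }
})

test_that("zero random variance reduces to classical fixed-effects ANOVA", {
  d <- data.frame(y = c(1, 2, 3, 4, 5, 6),
                  species = rep(c("a", "b"), each = 3),
                  block = c("1", "2", "3", "3", "2", "1"),
                  location_id = paste0("L", 1:6))
  # one-way layout: compare against the classical oracle on the same data
  fit <- fit_mixed_anova(d, "y", group = "species", transform = "none",
                         include_season = FALSE)
  fs <- fit$anova[fit$anova$term == "species", ]
  expect_equal(fs$F, 13.5, tolerance = 1e-6)
  expect_equal(fs$df1, 1)
  expect_equal(fs$df2, 4, tolerance = 1e-6)
})

test_that("mixed ANOVA matches aov on balanced data with null random terms", {
  set.seed(5)
  d <- expand.grid(block = factor(1:4), species = c("a", "b", "c"),
                   season = c("early", "late"),
                   stringsAsFactors = FALSE)
  d$location_id <- paste0(d$block, d$species)
  # fixed effects only; block labels carry no signal
  eff <- c(a = 0, b = 1, c = 2)
  d$y <- eff[d$species] + (d$season == "late") * 0.5 + rnorm(nrow(d), 0, 1)
  fit <- fit_mixed_anova(d, "y", transform = "none")
  if (all(vapply(lme4::VarCorr(fit$model),
                 function(x) x[1, 1], numeric(1)) < 1e-8)) {
    cl <- anova(lm(y ~ season * species, data = d))
    expect_equal(fit$anova$F[fit$anova$term == "season"],
                 cl$`F value`[rownames(cl) == "season"], tolerance = 1e-6)
    expect_equal(fit$anova$F[fit$anova$term == "species"],
                 cl$`F value`[rownames(cl) == "species"], tolerance = 1e-6)
  }
  expect_true(fit$r2_marginal <= fit$r2_conditional)
  expect_true(fit$r2_conditional <= 1)
})

test_that("constant response gives zero F", {
  d <- make_design_samples()
  d$y <- 7
  fit <- fit_mixed_anova(d, "y", transform = "none")
  expect_equal(fit$anova$F, c(0, 0, 0))
})

test_that("R2m/R2c are invariant to affine rescaling of the response", {
  set.seed(11)
  d <- make_design_samples()
  d$y <- 1 + (d$season == "late") + as.integer(factor(d$species)) / 2 +
    rnorm(60, 0, 0.5)
  f1 <- fit_mixed_anova(d, "y", transform = "none")
  d$y2 <- 100 + 7 * d$y
  f2 <- fit_mixed_anova(d, "y2", transform = "none")
  expect_equal(f1$r2_marginal, f2$r2_marginal, tolerance = 1e-6)
  expect_equal(f1$r2_conditional, f2$r2_conditional, tolerance = 1e-6)
  expect_gte(f1$r2_conditional, f1$r2_marginal)
})

test_that("variance partition matches the fitted components", {
  set.seed(12)
  d <- make_design_samples()
  blk <- rnorm(5, 0, 1)
  d$y <- 2 * (d$season == "late") + blk[as.integer(d$block)] +
    rnorm(60, 0, 1)
  fit <- fit_mixed_anova(d, "y", transform = "none")
  vf <- var(as.vector(model.matrix(fit$model) %*% lme4::fixef(fit$model)))
  vr <- sum(vapply(lme4::VarCorr(fit$model), function(x) x[1, 1],
                   numeric(1)))
  ve <- sigma(fit$model)^2
  expect_equal(fit$r2_marginal, vf / (vf + vr + ve))
  expect_equal(fit$r2_conditional, (vf + vr) / (vf + vr + ve))
})

test_that("two-level factor Tukey p equals the unadjusted p", {
  set.seed(21)
  d <- make_design_samples()
  d <- d[d$species %in% c("Betula nana", "Empetrum hermaphroditum"), ]
  d$y <- rnorm(nrow(d)) + (d$species == "Betula nana")
  fit <- fit_mixed_anova(d, "y", transform = "none")
  ps <- posthoc_contrasts(fit, condition_on = "none")
  em <- emmeans::emmeans(fit$model, ~ .g)
  raw <- summary(emmeans::contrast(em, "pairwise", adjust = "none"))
  expect_equal(ps$contrasts$p_adjusted, raw$p.value, tolerance = 1e-10)
})

test_that("adjusted p-values never fall below unadjusted ones", {
  set.seed(22)
  d <- make_design_samples()
  d$y <- rnorm(60) + as.integer(factor(d$species)) / 4
  fit <- fit_mixed_anova(d, "y", transform = "none")
  ps <- posthoc_contrasts(fit, condition_on = "none")
  em <- emmeans::emmeans(fit$model, ~ .g)
  raw <- summary(emmeans::contrast(em, "pairwise", adjust = "none"))
  expect_true(all(ps$contrasts$p_adjusted >= raw$p.value - 1e-12))
})

test_that("a far-shifted group lands in its own letter class", {
  set.seed(23)
  d <- make_design_samples()
  d$y <- rnorm(60, 0, 0.1)
  d$y[d$species == "Aulacomnium turgidum"] <- 50
  fit <- fit_mixed_anova(d, "y", transform = "none")
  ps <- posthoc_contrasts(fit, condition_on = "none")
  let <- ps$letters
  at <- let$letters[let$level == "Aulacomnium turgidum"]
  others <- let$letters[let$level != "Aulacomnium turgidum"]
  expect_false(any(grepl(at, others, fixed = TRUE)))
  expect_equal(length(unique(others)), 1)
})

test_that("significant interaction switches to conditioned contrasts", {
  set.seed(24)
  d <- make_design_samples()
  # strong species x season interaction
  d$y <- rnorm(60, 0, 0.2) +
    ifelse(d$species == "Betula nana" & d$season == "late", 10, 0)
  fit <- fit_mixed_anova(d, "y", transform = "none")
  ps <- posthoc_contrasts(fit)
  expect_equal(ps$conditioning, "interaction")
  expect_true(all(grepl("^season=", ps$contrasts$stratum)))
  ps2 <- posthoc_contrasts(fit, factor = "season")
  expect_true(all(grepl("^species=", ps2$contrasts$stratum)))
})

test_that("compact letters encode the significance partition", {
  g <- c("g1", "g2", "g3")
  none <- matrix(FALSE, 3, 3)
  expect_equal(unname(compact_letters(g, none)), c("a", "a", "a"))
  all_sig <- !diag(3)
  expect_equal(unname(compact_letters(g, all_sig)), c("a", "b", "c"))
  # chain: 1 vs 3 differ, 2 overlaps both
  chain <- matrix(FALSE, 3, 3)
  chain[1, 3] <- chain[3, 1] <- TRUE
  expect_equal(unname(compact_letters(g, chain)), c("a", "ab", "b"))
})

test_that("pearson correlations: exact, null, and error cases", {
  x <- 1:20
  out <- pearson_correlations(data.frame(x = x, y = 2 * x, z = -x),
                              list(c("x", "y"), c("x", "z")))
  expect_equal(out$r, c(1, -1))
  set.seed(31)
  n <- 2000
  d <- data.frame(x = rnorm(n), y = rnorm(n))
  r0 <- pearson_correlations(d, c("x", "y"))
  expect_lt(abs(r0$r), 3 / sqrt(n))
  expect_error(pearson_correlations(data.frame(x = c(1, 1, 1), y = 1:3),
                                    c("x", "y")), "zero variance")
  expect_error(pearson_correlations(data.frame(x = 1:2, y = 1:2),
                                    c("x", "y")), "3 complete")
})
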
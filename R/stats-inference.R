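#' Default response-transformation map
#'
#' Variance-stabilising transforms applied before the mixed-effect ANOVA,
#' one per response: pools of amino acids and ammonium, protein
#' depolymerisation and the ammonium/nitrate turnover times are
#' log-transformed; nitrate pools, gross mineralisation, gross
#' consumption, gross nitrification and amino-acid turnover are
#' square-root transformed; net rates (which can be negative) are left
#' untransformed.
#'
#' @return Named character vector over the pipeline's response names.
#' @export
default_transform_map <- function() {
  c(
    free_amino_acids     = "log",
    ammonium             = "log",
    nitrate              = "sqrt",
    depolymerisation     = "log",
    gross_mineralisation = "sqrt",
    net_mineralisation   = "none",
    gross_nh4_consumption = "sqrt",
    gross_nitrification  = "sqrt",
    net_nitrification    = "none",
    gross_no3_consumption = "sqrt",
    turnover_amino_acids = "sqrt",
    turnover_ammonium    = "log",
    turnover_nitrate     = "log"
  )
}

#' Transform a response variable
#'
#' @param values Numeric vector.
#' @param transform `"none"`, `"sqrt"` or `"log"`.
#' @return Transformed values. `inverse_transform` maps fitted values back
#'   to the original scale.
#' @export
#' @examples
#' transform_response(c(0, 1, 4, 9), "sqrt")
transform_response <- function(values, transform = c("none", "sqrt", "log")) {
  transform <- match.arg(transform)
  if (transform == "none") return(values)
  ok <- !is.na(values)
  if (transform == "sqrt" && any(values[ok] < 0)) {
    stop("sqrt transform requires nonnegative values; offending row(s): ",
         paste(which(values < 0 & ok), collapse = ", "))
  }
  if (transform == "log" && any(values[ok] <= 0)) {
    stop("log transform requires positive values; offending row(s): ",
         paste(which(values <= 0 & ok), collapse = ", "))
  }
  switch(transform, sqrt = sqrt(values), log = log(values))
}

#' @rdname transform_response
#' @export
inverse_transform <- function(values, transform = c("none", "sqrt", "log")) {
  transform <- match.arg(transform)
  switch(transform, none = values, sqrt = values^2, log = exp(values))
}

# Nakagawa-Schielzeth variance partition for a Gaussian mixed model:
# R2m = var(fixed)/(var(fixed)+sum(var(random))+var(resid)),
# R2c adds the random-effect variances to the numerator.
r2_nakagawa <- function(model) {
  vf <- var(as.vector(model.matrix(model) %*% lme4::fixef(model)))
  vr <- sum(vapply(lme4::VarCorr(model), function(x) x[1, 1], numeric(1)))
  ve <- sigma(model)^2
  tot <- vf + vr + ve
  list(r2_marginal = vf / tot, r2_conditional = (vf + vr) / tot)
}

#' Nested mixed-effect ANOVA
#'
#' Fits the study's inference model by REML: a response against season,
#' a grouping factor (plant species, or plant functional type) and their
#' interaction as fixed effects, with block and sampling location nested
#' within block as random intercepts — the location term carries the
#' repeated-measures correlation between the two seasonal samples of one
#' spot. For PFT models, species is added as a further random intercept.
#' Fixed terms are tested with type III F tests and Satterthwaite
#' denominator degrees of freedom; explained variance is summarised by
#' marginal R2 (fixed effects) and conditional R2 (fixed plus random).
#'
#' @param data Tidy table with columns `block`, `location_id`, `season`,
#'   the grouping factor and the response.
#' @param response Name of the response column.
#' @param group Fixed grouping factor: `"species"` (default) or `"pft"`.
#' @param transform `"none"`, `"sqrt"` or `"log"`; defaults to the entry
#'   of [default_transform_map()] if `response` is listed there, else
#'   `"none"`.
#' @param species_random Add a species random intercept (default: `TRUE`
#'   when `group = "pft"`).
#' @param ddf Denominator-df method, `"Satterthwaite"` (default) or
#'   `"Kenward-Roger"`.
#' @param include_season Keep season (and the interaction) in the fixed
#'   part (default `TRUE`); `FALSE` fits a one-way layout in the grouping
#'   factor, used for diagnostics against classical ANOVA.
#' @return A `"mixed_anova"` list: `model` (the lmerTest fit), `anova`
#'   (tibble of term, F, df1, df2, p), `r2_marginal`, `r2_conditional`,
#'   `response`, `group`, `transform`, `singular`.
#' @export
fit_mixed_anova <- function(data, response, group = "species",
                            transform = NULL, species_random = NULL,
                            ddf = c("Satterthwaite", "Kenward-Roger"),
                            include_season = TRUE) {
  ddf <- match.arg(ddf)
  stopifnot(response %in% names(data), group %in% names(data),
            all(c("block", "location_id") %in% names(data)))
  if (include_season && !"season" %in% names(data)) {
    stop("data must contain a season column")
  }
  if (is.null(transform)) {
    transform <- unname(default_transform_map()[response])
    if (is.na(transform)) transform <- "none"
  }
  if (is.null(species_random)) species_random <- identical(group, "pft")
  if (length(unique(data[[group]])) < 2 ||
      (include_season && length(unique(data$season)) < 2)) {
    stop("each fixed factor needs at least 2 levels")
  }

  d <- as.data.frame(data)
  d$.y <- transform_response(d[[response]], transform)
  d$.g <- factor(d[[group]])
  if (include_season) d$season <- factor(d$season)
  d$block <- factor(d$block)
  d$location_id <- factor(d$location_id)

  if (var(d$.y, na.rm = TRUE) == 0) {
    # degenerate: no variation anywhere, all F are 0 by convention
    ng <- nlevels(d$.g)
    terms <- if (include_season) {
      c("season", group, paste0("season:", group))
    } else group
    return(structure(list(
      model = NULL,
      anova = tibble::tibble(term = terms,
                             F = 0,
                             df1 = if (include_season) {
                               c(1, ng - 1, ng - 1)
                             } else ng - 1,
                             df2 = NA_real_, p = 1),
      r2_marginal = 0, r2_conditional = 0,
      response = response, group = group, transform = transform,
      singular = TRUE), class = "mixed_anova"))
  }

  rand <- "(1 | block)"
  # the location term carries the repeated-measures correlation; with no
  # repeated visits it is confounded with the residual and is dropped
  if (nlevels(d$location_id) < nrow(d)) {
    rand <- paste(rand, "+ (1 | location_id)")
  }
  if (species_random) rand <- paste(rand, "+ (1 | species)")
  fixed <- if (include_season) "season * .g" else ".g"
  form <- stats::as.formula(paste(".y ~", fixed, "+", rand))

  model <- withCallingHandlers(
    suppressMessages(lmerTest::lmer(
      form, data = d, REML = TRUE,
      control = lme4::lmerControl(check.conv.singular = "ignore",
                                  calc.derivs = FALSE))),
    warning = function(w) invokeRestart("muffleWarning"))
  singular <- lme4::isSingular(model)

  at <- as.data.frame(anova(model, type = 3, ddf = ddf))
  terms <- rownames(at)
  terms <- gsub("\\.g", group, terms)
  r2 <- r2_nakagawa(model)

  structure(list(
    model = model,
    anova = tibble::tibble(
      term = terms,
      F = at$`F value`,
      df1 = at$NumDF,
      df2 = at$DenDF,
      p = at$`Pr(>F)`
    ),
    r2_marginal = r2$r2_marginal,
    r2_conditional = r2$r2_conditional,
    response = response,
    group = group,
    transform = transform,
    singular = singular
  ), class = "mixed_anova")
}

#' @export
print.mixed_anova <- function(x, ...) {
  cat(sprintf("Mixed-effect ANOVA: %s (%s-transformed), fixed: season x %s\n",
              x$response, x$transform, x$group))
  print(as.data.frame(x$anova), digits = 4)
  cat(sprintf("R2 marginal = %.3f, conditional = %.3f%s\n",
              x$r2_marginal, x$r2_conditional,
              if (x$singular) "  [singular fit]" else ""))
  invisible(x)
}

#' Compact letter display from a significance matrix
#'
#' Insert-and-absorb algorithm: groups not sharing a letter are
#' significantly different. Ties are broken by the supplied group order
#' (alphabetical by default in [posthoc_contrasts()]).
#'
#' @param groups Character vector of group names, in display order.
#' @param sig Logical matrix (`groups x groups`), `TRUE` where the pair is
#'   significantly different.
#' @return Named character vector of letter strings.
#' @export
compact_letters <- function(groups, sig) {
  n <- length(groups)
  stopifnot(is.matrix(sig), nrow(sig) == n, ncol(sig) == n)
  cols <- list(rep(TRUE, n))
  pairs <- which(sig & upper.tri(sig), arr.ind = TRUE)
  if (nrow(pairs) > 0) {
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      newcols <- list()
      for (col in cols) {
        if (col[i] && col[j]) {
          a <- col; a[i] <- FALSE
          b <- col; b[j] <- FALSE
          newcols <- c(newcols, list(a, b))
        } else {
          newcols <- c(newcols, list(col))
        }
      }
      # absorb columns contained in another column
      keep <- rep(TRUE, length(newcols))
      for (a in seq_along(newcols)) {
        for (b in seq_along(newcols)) {
          if (a != b && keep[a] && keep[b] &&
              all(!newcols[[a]] | newcols[[b]]) &&
              !identical(newcols[[a]], newcols[[b]])) {
            keep[a] <- FALSE
          }
        }
      }
      # drop exact duplicates
      cols <- unique(newcols[keep])
    }
  }
  ord <- order(vapply(cols, function(col) which(col)[1], integer(1)))
  cols <- cols[ord]
  letters_out <- vapply(seq_len(n), function(i) {
    paste0(letters[which(vapply(cols, `[`, logical(1), i))], collapse = "")
  }, character(1))
  stats::setNames(letters_out, groups)
}

#' Tukey and interaction-conditioned post-hoc contrasts
#'
#' Tukey-adjusted pairwise comparisons of estimated marginal means for a
#' fixed factor of a [fit_mixed_anova()] model. With
#' `condition_on = "auto"` (default), the season-by-group interaction
#' p-value decides: below the threshold, group contrasts are estimated
#' within each season and season contrasts within each group; otherwise
#' contrasts are pooled over both seasons. Compact letter groupings are
#' recomputed per conditioning stratum.
#'
#' @param fit A `"mixed_anova"` object.
#' @param factor Factor to compare: the model's grouping factor (default)
#'   or `"season"`.
#' @param condition_on `"auto"`, `"none"` or `"interaction"`.
#' @param threshold Interaction p-value threshold (default 0.05).
#' @param alpha Significance level for the letter display (default 0.05).
#' @return A `"contrast_set"` list: `contrasts` (tibble with `stratum`,
#'   `contrast`, `estimate`, `se`, `df`, `t`, `p_adjusted`),
#'   `letters` (tibble with `stratum`, `level`, `letters`),
#'   `conditioning`, `interaction_p`.
#' @export
posthoc_contrasts <- function(fit, factor = NULL,
                              condition_on = c("auto", "none",
                                               "interaction"),
                              threshold = 0.05, alpha = 0.05) {
  condition_on <- match.arg(condition_on)
  stopifnot(inherits(fit, "mixed_anova"))
  if (is.null(factor)) factor <- fit$group
  if (!factor %in% c(fit$group, "season")) {
    stop("factor must be 'season' or the model grouping factor '",
         fit$group, "'")
  }
  int_p <- fit$anova$p[grepl(":", fit$anova$term)]
  use_conditional <- switch(condition_on,
    auto = length(int_p) == 1 && !is.na(int_p) && int_p < threshold,
    interaction = TRUE,
    none = FALSE)

  spec_var <- if (factor == fit$group) ".g" else "season"
  by_var <- if (use_conditional) setdiff(c(".g", "season"), spec_var) else
    NULL
  em <- emmeans::emmeans(fit$model, specs = spec_var, by = by_var)
  prs <- summary(emmeans::contrast(em, method = "pairwise",
                                   adjust = "tukey"))
  prs <- as.data.frame(prs)
  stratum <- if (is.null(by_var)) "overall" else {
    nm <- if (by_var == ".g") fit$group else by_var
    paste0(nm, "=", prs[[by_var]])
  }
  contrasts <- tibble::tibble(
    stratum = stratum,
    contrast = as.character(prs$contrast),
    estimate = prs$estimate,
    se = prs$SE,
    df = prs$df,
    t = prs$t.ratio,
    p_adjusted = prs$p.value
  )

  # compact letters per stratum from the adjusted p-values
  lets <- lapply(split(contrasts, contrasts$stratum), function(cc) {
    lv <- sort(unique(unlist(strsplit(cc$contrast, " - "))))
    sig <- matrix(FALSE, length(lv), length(lv),
                  dimnames = list(lv, lv))
    for (r in seq_len(nrow(cc))) {
      ab <- strsplit(cc$contrast[r], " - ")[[1]]
      sig[ab[1], ab[2]] <- sig[ab[2], ab[1]] <- cc$p_adjusted[r] < alpha
    }
    cl <- compact_letters(lv, sig)
    tibble::tibble(stratum = cc$stratum[1], level = lv,
                   letters = unname(cl))
  })
  structure(list(
    contrasts = contrasts,
    letters = dplyr::bind_rows(lets),
    conditioning = if (use_conditional) "interaction" else "overall",
    interaction_p = if (length(int_p) == 1) int_p else NA_real_
  ), class = "contrast_set")
}

#' @export
print.contrast_set <- function(x, ...) {
  cat("Tukey-adjusted contrasts (conditioning:", x$conditioning, ")\n")
  print(as.data.frame(x$contrasts), digits = 4)
  invisible(x)
}

#' Pearson correlations between soil variables
#'
#' @param data Data frame of measurements.
#' @param pairs List of length-2 character vectors (variable pairs).
#' @return Tibble with `var1`, `var2`, `r`, `p` (two-sided), `n`.
#' @export
pearson_correlations <- function(data, pairs) {
  if (is.character(pairs)) pairs <- list(pairs)
  rows <- lapply(pairs, function(pr) {
    stopifnot(length(pr) == 2, all(pr %in% names(data)))
    x <- data[[pr[1]]]; y <- data[[pr[2]]]
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 3) stop("need at least 3 complete pairs for ",
                          pr[1], " vs ", pr[2])
    if (sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      stop("zero variance in ", pr[1], " or ", pr[2])
    }
    ct <- cor.test(x[ok], y[ok], method = "pearson")
    tibble::tibble(var1 = pr[1], var2 = pr[2],
                   r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
  })
  dplyr::bind_rows(rows)
}

#' Type-I error calibration of the seasonal term
#'
#' Simulates the nested design under the null of no fixed effects (block,
#' location and residual variation only), fits the mixed ANOVA, and
#' returns the rejection rate of the season term at `alpha`.
#'
#' @param n_reps Number of simulated datasets.
#' @param blocks,n_species Reduced design size (default 4 blocks, 2
#'   species, both seasons).
#' @param sd_block,sd_location,sd_resid Standard deviations of the random
#'   components on the response scale.
#' @param alpha Nominal level (default 0.05).
#' @param seed Random seed.
#' @return List: `rejection_rate`, `p_values`, `mc_se` (binomial
#'   Monte-Carlo standard error at the nominal level).
#' @export
type1_error_calibration <- function(n_reps = 1000, blocks = 4,
                                    n_species = 2, sd_block = 0.5,
                                    sd_location = 0.5, sd_resid = 1,
                                    alpha = 0.05, seed = 1) {
  set.seed(seed)
  design <- expand.grid(block = factor(seq_len(blocks)),
                        species = factor(paste0("sp", seq_len(n_species))),
                        season = factor(c("early", "late")))
  design$location_id <- interaction(design$block, design$species)
  p_values <- vapply(seq_len(n_reps), function(i) {
    b <- rnorm(blocks, 0, sd_block)[design$block]
    l <- rnorm(nlevels(design$location_id), 0, sd_location)[
      as.integer(design$location_id)]
    design$y <- b + l + rnorm(nrow(design), 0, sd_resid)
    fit <- fit_mixed_anova(design, "y", group = "species",
                           transform = "none")
    fit$anova$p[fit$anova$term == "season"]
  }, numeric(1))
  list(rejection_rate = mean(p_values < alpha),
       p_values = p_values,
       mc_se = sqrt(alpha * (1 - alpha) / n_reps))
}
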
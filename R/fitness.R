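# Natural-selection fitness regressions and the effect-size report.

#' Per-pair fitness-component table from an experiment
#'
#' Collects, for every breeding pair, the mean parental standard length and
#' the four fitness components used by the natural-selection analysis:
#' total fecundity (with collection days), hatch counts, number of progeny
#' reaching 75 dph, and number of progeny kept as breeders.
#'
#' @param experiment a `medaka_experiment`.
#' @return data frame with one row per breeding pair.
#' @export
pair_fitness_table <- function(experiment) {
  cl <- experiment$tables$clutches
  fish <- experiment$tables$fish
  per_pair <- function(flag) {
    counts <- tapply(flag, fish$family_id, sum)
    out <- as.integer(counts[cl$pair_id])
    out[is.na(out)] <- 0L
    out
  }
  data.frame(
    pair_id = cl$pair_id, line = cl$line, generation = cl$generation,
    parent_sdl = cl$parent_sdl,
    days_collected = cl$days_collected,
    n_eggs = cl$n_eggs, n_hatched = cl$n_hatched,
    n_progeny_75 = per_pair(fish$alive_75),
    n_kept = per_pair(fish$breeder),
    stringsAsFactors = FALSE
  )
}

#' Quadratic fitness regression on mean parental length
#'
#' Fits the stated likelihood family with linear and quadratic
#' mean-parental-length terms (centered): a zero-inflated Poisson for the
#' count components (with observation-level overdispersion for fecundity
#' only) and a Binomial for hatch rate.
#'
#' @param component one of `"fecundity"`, `"hatch_rate"`,
#'   `"progeny_75dph"`, `"progeny_kept"`.
#' @param pairs a [pair_fitness_table()] (or data frame with the same
#'   columns).
#' @param seed,chains,n_adapt,n_iter passed to [fit_model()].
#' @return list of class `fitness_regression`: `component`, `family`,
#'   `linear` and `quadratic` summaries (estimate, CI, MCMC p-value),
#'   `center`, and the fitted `samples`.
#' @export
fitness_regression <- function(component = c("fecundity", "hatch_rate",
                                             "progeny_75dph",
                                             "progeny_kept"),
                               pairs, seed = 1, chains = 3,
                               n_adapt = 500, n_iter = 2000) {
  component <- match.arg(component)
  pairs <- as.data.frame(pairs)
  if (stats::var(pairs$parent_sdl) < 1e-12) {
    stop("singular design: all mean parental lengths are equal")
  }
  x <- pairs$parent_sdl - mean(pairs$parent_sdl)
  if (component == "hatch_rate") {
    d <- pairs[pairs$n_eggs > 0, ]
    x <- d$parent_sdl - mean(pairs$parent_sdl)
    code <- paste0(
      "model {\n",
      "  for (i in 1:N) {\n",
      "    y[i] ~ dbin(p[i], size[i])\n",
      "    logit(p[i]) <- b0 + b1 * x[i] + b2 * x2[i]\n",
      "  }\n",
      "  b0 ~ ", .prior_fixed, "\n  b1 ~ ", .prior_fixed,
      "\n  b2 ~ ", .prior_fixed, "\n",
      "}")
    spec <- model_spec(
      name = paste0("fitness_", component), code = code,
      data = list(y = d$n_hatched, size = d$n_eggs, x = x, x2 = x^2,
                  N = nrow(d)),
      params = c("b0", "b1", "b2"), family = "binomial")
  } else {
    y <- switch(component, fecundity = pairs$n_eggs,
                progeny_75dph = pairs$n_progeny_75,
                progeny_kept = pairs$n_kept)
    offs <- if (component == "fecundity") log(pairs$days_collected)
            else rep(0, nrow(pairs))
    overdisp <- component == "fecundity"
    code <- paste0(
      "model {\n",
      "  for (i in 1:N) {\n",
      "    z[i] ~ dbern(q[i])\n",
      "    y[i] ~ dpois(z[i] * lambda[i] + 1.0E-10)\n",
      "    q[i] <- 1 - pzero[i]\n",
      if (overdisp) paste0(
        # hierarchically centered overdispersion: the latent log rate is
        # drawn around the linear predictor, which mixes far better than
        # an additive observation-level offset
        "    log(lambda[i]) <- theta[i]\n",
        "    theta[i] ~ dnorm(offs[i] + b0 + b1 * x[i] + b2 * x2[i], tauE)\n")
      else "    log(lambda[i]) <- offs[i] + b0 + b1 * x[i] + b2 * x2[i]\n",
      "    logit(pzero[i]) <- g0 + d1 * x[i] + d2 * x2[i]\n",
      "  }\n",
      "  b0 ~ ", .prior_fixed, "\n  b1 ~ ", .prior_fixed,
      "\n  b2 ~ ", .prior_fixed, "\n",
      "  g0 ~ ", .prior_fixed, "\n  d1 ~ ", .prior_fixed,
      "\n  d2 ~ ", .prior_fixed, "\n",
      if (overdisp) paste0(
        "  tauE <- pow(sigmaE, -2)\n  sigmaE ~ ", .prior_sd, "\n") else "",
      "}")
    spec <- model_spec(
      name = paste0("fitness_", component), code = code,
      data = list(y = y, offs = offs, x = x, x2 = x^2, N = length(y)),
      params = c("b0", "b1", "b2", "g0", "d1", "d2",
                 if (overdisp) "sigmaE"),
      family = "zip",
      inits = function(chain) list(z = rep(1L, length(y))))
  }
  fit <- fit_model(spec, chains = chains, n_adapt = n_adapt,
                   n_iter = n_iter, seed = seed,
                   on_nonconvergence = "warn")
  d <- as_draws(fit)
  summarize <- function(nm) {
    v <- d[, nm]
    list(estimate = mean(v), sd = stats::sd(v),
         lower = stats::quantile(v, 0.025, names = FALSE),
         upper = stats::quantile(v, 0.975, names = FALSE),
         mcmc_p = mcmc_p_value(v))
  }
  structure(list(
    component = component,
    family = if (component == "hatch_rate") "binomial"
             else "zero-inflated-poisson",
    linear = summarize("b1"), quadratic = summarize("b2"),
    center = mean(pairs$parent_sdl), samples = fit
  ), class = "fitness_regression")
}

#' Predicted fitness over a grid of parental lengths
#'
#' Figure-style output: posterior mean and 95% credible band of the
#' expected fitness component over a grid of mean parental lengths.
#'
#' @param res a [fitness_regression()] result.
#' @param lengths grid of parental standard lengths (mm).
#' @return data frame with `length`, `mean`, `lower`, `upper`.
#' @export
fitness_prediction_grid <- function(res, lengths) {
  d <- as_draws(res$samples)
  x <- lengths - res$center
  pred <- vapply(seq_along(x), function(i) {
    eta <- d[, "b0"] + d[, "b1"] * x[i] + d[, "b2"] * x[i]^2
    mu <- if (res$family == "binomial") stats::plogis(eta) else {
      q <- if ("g0" %in% colnames(d)) {
        1 - stats::plogis(d[, "g0"] + d[, "d1"] * x[i] +
                            d[, "d2"] * x[i]^2)
      } else 1
      q * exp(eta)
    }
    c(mean(mu), stats::quantile(mu, c(0.025, 0.975), names = FALSE))
  }, numeric(3))
  data.frame(length = lengths, mean = pred[1, ], lower = pred[2, ],
             upper = pred[3, ])
}

#' Bonferroni-corrected significance cutoff
#'
#' @param n_tests number of tests in the family (the effect-size report
#'   tests 14 traits x 2 lines = 28 corrected effects).
#' @param nominal family-wise error rate.
#' @return per-test alpha.
#' @export
bonferroni_alpha <- function(n_tests = 28, nominal = 0.05) {
  stopifnot(n_tests >= 1)
  nominal / n_tests
}

.trait_defs <- list(
  sdl_75 = "Standard body length at 75 dph (mm)",
  maturity = "Maturity probability (logit)",
  surv_egg_0 = "Egg-to-larvae survival (logit)",
  surv_0_15 = "Larvae-to-15 dph survival (logit)",
  surv_15_60 = "15-to-60 dph survival (logit)",
  surv_60_75 = "60-to-75 dph survival (logit)",
  fertility = "Fertility (logit)",
  fecundity = "Nonzero fecundity (log)",
  egg_size = "Egg size (perimeter mm)",
  incubation = "Mean incubation time (days)",
  sdl_hatch = "Standard body length at hatch (mm)",
  lhb = "Pituitary LHb (ln ratio)",
  fshb = "Pituitary FSHb (ln ratio)",
  gh = "Pituitary GH (ln ratio)"
)

#' Raw line-contrast effect sizes
#'
#' Simple line-mean contrasts against the Control line, on each trait's
#' reporting scale: plain mean differences for lengths, egg size,
#' incubation and ln hormone ratios; differences of logits of pooled
#' proportions for maturity, survival stages and fertility; difference of
#' log mean daily fecundity among fertile pairs.
#'
#' @param tables experiment tables.
#' @param lines lines to contrast against Control.
#' @return data frame `trait`, `line`, `raw`.
#' @export
raw_effect_table <- function(tables, lines = c("Small", "Large")) {
  fish <- tables$fish
  cl <- tables$clutches
  sv <- tables$survival
  hm <- tables$hormones
  mean_of <- function(df, col, line, filter = TRUE) {
    v <- df[[col]][df$line == line & filter]
    mean(v, na.rm = TRUE)
  }
  logit_prop <- function(num, den) stats::qlogis(sum(num) / sum(den))
  rows <- list()
  for (line in lines) {
    vals <- c(
      sdl_75 = mean_of(fish, "length_75", line) -
        mean_of(fish, "length_75", "Control"),
      maturity = stats::qlogis(mean(fish$mature_75[fish$line == line &
                                                     fish$alive_75])) -
        stats::qlogis(mean(fish$mature_75[fish$line == "Control" &
                                            fish$alive_75])),
      surv_egg_0 = .surv_logit(sv, "egg-0", line) -
        .surv_logit(sv, "egg-0", "Control"),
      surv_0_15 = .surv_logit(sv, "0-15", line) -
        .surv_logit(sv, "0-15", "Control"),
      surv_15_60 = .surv_logit(sv, "15-60", line) -
        .surv_logit(sv, "15-60", "Control"),
      surv_60_75 = .surv_logit(sv, "60-75", line) -
        .surv_logit(sv, "60-75", "Control"),
      fertility = stats::qlogis(mean(cl$n_eggs[cl$line == line] > 0)) -
        stats::qlogis(mean(cl$n_eggs[cl$line == "Control"] > 0)),
      fecundity = .log_daily_fec(cl, line) - .log_daily_fec(cl, "Control"),
      egg_size = mean_of(cl, "mean_egg_perimeter_mm", line) -
        mean_of(cl, "mean_egg_perimeter_mm", "Control"),
      incubation = mean_of(cl, "incubation_days", line) -
        mean_of(cl, "incubation_days", "Control"),
      sdl_hatch = mean_of(fish, "length_0", line) -
        mean_of(fish, "length_0", "Control"),
      lhb = if (is.null(hm)) NA_real_ else
        mean_of(hm, "ln_ratio_lhb", line) -
          mean_of(hm, "ln_ratio_lhb", "Control"),
      fshb = if (is.null(hm)) NA_real_ else
        mean_of(hm, "ln_ratio_fshb", line) -
          mean_of(hm, "ln_ratio_fshb", "Control"),
      gh = if (is.null(hm)) NA_real_ else
        mean_of(hm, "ln_ratio_gh", line) -
          mean_of(hm, "ln_ratio_gh", "Control")
    )
    rows[[line]] <- data.frame(trait = names(vals), line = line,
                               raw = unname(vals),
                               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.surv_logit <- function(sv, stage, line) {
  s <- sv[sv$stage == stage & sv$line == line, ]
  stats::qlogis(sum(s$n_end) / sum(s$n_start))
}

.log_daily_fec <- function(cl, line) {
  s <- cl[cl$line == line & cl$n_eggs > 0, ]
  log(mean(s$n_eggs / s$days_collected))
}

#' Effect-size report for all traits and selected lines
#'
#' Combines raw line contrasts ([raw_effect_table()]) with corrected
#' effects: the posterior means of the line coefficients of the fitted
#' trait models (contrasts against Control at reference/centered
#' covariates; effects are common across sexes since the models carry no
#' line-by-sex interactions). Significance is flagged at the
#' Bonferroni-corrected cutoff for the whole 28-test family. The fertility
#' effect is reported on the fertility (not infertility) logit scale, so a
#' positive value means more fertile pairs.
#'
#' @param fits named list of fitted models: `m1`, `m2`, `m3` (itself a
#'   named list by transition), `m4`, `m5`, `m6`, `m7`, `m8`. Missing
#'   entries produce explicit gaps (`NA`) in the table.
#' @param tables experiment tables (for the raw contrasts).
#' @param lines lines to report.
#' @param n_tests,nominal Bonferroni family (defaults 28 tests at 0.05).
#' @return data frame with one row per trait and line: `raw`, `corrected`,
#'   `mcmc_p`, `significant`, and the cutoff `alpha`.
#' @export
effect_size_table <- function(fits, tables, lines = c("Small", "Large"),
                              n_tests = 28, nominal = 0.05) {
  alpha <- bonferroni_alpha(n_tests, nominal)
  raw <- raw_effect_table(tables, lines)
  grab <- function(fit, line, part = "beta", gene = NULL) {
    if (is.null(fit)) return(list(est = NA_real_, p = NA_real_))
    dr <- tryCatch(coef_draws(fit, paste0("line", line), part = part,
                              gene = gene),
                   error = function(e) NULL)
    if (is.null(dr)) return(list(est = NA_real_, p = NA_real_))
    list(est = mean(dr), p = mcmc_p_value(dr))
  }
  corrected <- lapply(lines, function(line) {
    fert <- grab(fits$m4, line, part = "gamma")
    vals <- list(
      sdl_75 = grab(fits$m1, line),
      maturity = grab(fits$m2, line),
      surv_egg_0 = grab(fits$m3[["egg-0"]], line),
      surv_0_15 = grab(fits$m3[["0-15"]], line),
      surv_15_60 = grab(fits$m3[["15-60"]], line),
      surv_60_75 = grab(fits$m3[["60-75"]], line),
      # zero part models infertility; report on the fertility scale
      fertility = list(est = -fert$est, p = fert$p),
      fecundity = grab(fits$m4, line),
      egg_size = grab(fits$m5, line),
      incubation = grab(fits$m6, line),
      sdl_hatch = grab(fits$m7, line),
      lhb = grab(fits$m8, line, gene = "lhb"),
      fshb = grab(fits$m8, line, gene = "fshb"),
      gh = grab(fits$m8, line, gene = "gh")
    )
    data.frame(trait = names(vals), line = line,
               corrected = vapply(vals, function(v) v$est, numeric(1)),
               mcmc_p = vapply(vals, function(v) v$p, numeric(1)),
               stringsAsFactors = FALSE)
  })
  corrected <- do.call(rbind, corrected)
  out <- merge(raw, corrected, by = c("trait", "line"), sort = FALSE)
  out$significant <- !is.na(out$mcmc_p) & out$mcmc_p < alpha
  out$alpha <- alpha
  out$trait_label <- unlist(.trait_defs[out$trait])
  out[order(match(out$trait, names(.trait_defs)), out$line), ]
}
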
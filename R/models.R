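# Builders for the experiment's eight Bayesian trait models. All fixed
# effects are passed to JAGS through a design matrix built with treatment
# contrasts (reference levels: Control line, female sex), so every model
# shares the same parameter layout: beta[k] for fixed effects (named in
# spec$terms$coef), aG[g] for the generation random intercept, sigma-type
# scale parameters, and optional observation-level overdispersion.

.prior_fixed <- "dnorm(0, 1.0E-4)"      # weakly informative, sd 100
.prior_sd <- "dt(0, 0.04, 1) T(0,)"     # half-Cauchy, scale 5

.require_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop("table '", what, "' is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
}

.line_factor <- function(x) {
  levs <- c("Control", setdiff(unique(x), "Control"))
  factor(x, levels = levs)
}

.sex_factor <- function(x) {
  factor(x, levels = c("F", intersect(c("M", "I"), unique(x))))
}

.gen_index <- function(generation, generations = NULL) {
  if (is.null(generations)) generations <- sort(unique(generation))
  idx <- match(generation, generations)
  list(idx = idx, levels = generations, n = length(generations))
}

# center continuous covariates, remembering the centers
.centered <- function(df, cols) {
  centers <- vapply(cols, function(cl) mean(df[[cl]], na.rm = TRUE),
                    numeric(1))
  for (cl in cols) df[[paste0(cl, "_c")]] <- df[[cl]] - centers[[cl]]
  list(df = df, centers = centers)
}

# shared JAGS fragments ------------------------------------------------------

.code_fixed_and_ranef <- function(overdisp = FALSE) {
  paste0(
    "  for (k in 1:K) { beta[k] ~ ", .prior_fixed, " }\n",
    "  for (g in 1:NG) { aG[g] ~ dnorm(0, tauG) }\n",
    "  tauG <- pow(sigmaG, -2)\n",
    "  sigmaG ~ ", .prior_sd, "\n",
    if (overdisp) paste0(
      "  for (i in 1:N) { eps[i] ~ dnorm(0, tauE) }\n",
      "  tauE <- pow(sigmaE, -2)\n",
      "  sigmaE ~ ", .prior_sd, "\n") else "")
}

#' Build one of the Gaussian trait models
#'
#' Models 1 (standard length at 75 dph), 5 (individual egg perimeter),
#' 6 (incubation time) and 7 (standard length at hatch) share a normal
#' likelihood with a generation random intercept and model-specific fixed
#' effects:
#' * Model 1: line + sex + age (continuous, dph) + inbreeding.
#' * Model 5: line + mother length + mother and father inbreeding.
#' * Model 6: line + mother length + mother and father inbreeding.
#' * Model 7: line + mean parental length + own inbreeding.
#'
#' Continuous covariates are centered; factors use treatment contrasts with
#' Control line and female sex as reference levels, so line coefficients
#' are contrasts against the Control line.
#'
#' @param model_id 1, 5, 6 or 7.
#' @param tables the `tables` element of a `medaka_experiment` (or a list
#'   with the same layout).
#' @param generations generations to pool (default: all present).
#' @return a [model_spec()].
#' @export
build_gaussian_model <- function(model_id, tables, generations = NULL) {
  stopifnot(model_id %in% c(1, 5, 6, 7))
  if (model_id == 1) {
    .require_cols(tables$fish,
                  c("length_75", "line", "generation", "sex", "age_75",
                    "inbreeding"), "fish")
    d <- tables$fish[!is.na(tables$fish$length_75), ]
    center_cols <- c("age_75", "inbreeding")
    form <- ~ line + sex + age_75_c + inbreeding_c
    y <- d$length_75
    name <- "model1_length75"
  } else if (model_id == 5) {
    .require_cols(tables$eggs,
                  c("perimeter_mm", "line", "generation", "mother_sdl",
                    "mo_inb", "fa_inb"), "eggs")
    d <- tables$eggs[!is.na(tables$eggs$perimeter_mm), ]
    center_cols <- c("mother_sdl", "mo_inb", "fa_inb")
    form <- ~ line + mother_sdl_c + mo_inb_c + fa_inb_c
    y <- d$perimeter_mm
    name <- "model5_eggsize"
  } else if (model_id == 6) {
    .require_cols(tables$clutches,
                  c("incubation_days", "line", "generation", "mother_sdl",
                    "mo_inb", "fa_inb"), "clutches")
    d <- tables$clutches[!is.na(tables$clutches$incubation_days), ]
    center_cols <- c("mother_sdl", "mo_inb", "fa_inb")
    form <- ~ line + mother_sdl_c + mo_inb_c + fa_inb_c
    y <- d$incubation_days
    name <- "model6_incubation"
  } else {
    .require_cols(tables$fish,
                  c("length_0", "line", "generation", "parent_sdl",
                    "inbreeding"), "fish")
    d <- tables$fish[!is.na(tables$fish$length_0), ]
    center_cols <- c("parent_sdl", "inbreeding")
    form <- ~ line + parent_sdl_c + inbreeding_c
    y <- d$length_0
    name <- "model7_hatchlength"
  }
  if (!is.null(generations)) d <- d[d$generation %in% generations, ]
  cc <- .centered(d, center_cols)
  d <- cc$df
  d$line <- .line_factor(d$line)
  if (model_id == 1) d$sex <- .sex_factor(d$sex)
  X <- stats::model.matrix(form, d)
  y <- switch(as.character(model_id),
              "1" = d$length_75, "5" = d$perimeter_mm,
              "6" = d$incubation_days, "7" = d$length_0)
  gi <- .gen_index(d$generation)
  code <- paste0(
    "model {\n",
    "  for (i in 1:N) {\n",
    "    y[i] ~ dnorm(mu[i], tau)\n",
    "    mu[i] <- inprod(X[i,], beta) + aG[gen[i]]\n",
    "  }\n",
    .code_fixed_and_ranef(),
    "  tau <- pow(sigma, -2)\n",
    "  sigma ~ ", .prior_sd, "\n",
    "}")
  model_spec(
    name = name, code = code,
    data = list(y = as.numeric(y), X = X, N = nrow(X), K = ncol(X),
                gen = gi$idx, NG = gi$n),
    params = c("beta", "aG", "sigma", "sigmaG"),
    family = "normal",
    terms = list(coef = colnames(X), centers = cc$centers,
                 generations = gi$levels, model_id = model_id,
                 symbols = switch(as.character(model_id),
                   "1" = c("alphaG", "alphaL", "alphaS", "Age", "Inb",
                           "sigma", "sigmaG"),
                   "5" = c("alphaG", "alphaL", "Mo.sdl", "Mo.inb", "Fa.inb",
                           "sigma", "sigmaG"),
                   "6" = c("alphaG", "alphaL", "Mo.sdl", "Mo.inb", "Fa.inb",
                           "sigma", "sigmaG"),
                   "7" = c("alphaG", "alphaL", "Parent.sdl", "Inb",
                           "sigma", "sigmaG"))),
    ppp = .ppp_gaussian()
  )
}

.ppp_gaussian <- function() {
  list(
    observed = function(data) data$y,
    mean_var = function(draw, data) {
      beta <- draw[sprintf("beta[%d]", seq_len(data$K))]
      aG <- draw[sprintf("aG[%d]", seq_len(data$NG))]
      mu <- as.numeric(data$X %*% beta) + aG[data$gen]
      list(mean = mu, var = rep(draw[["sigma"]]^2, data$N))
    },
    simulate = function(draw, data) {
      beta <- draw[sprintf("beta[%d]", seq_len(data$K))]
      aG <- draw[sprintf("aG[%d]", seq_len(data$NG))]
      mu <- as.numeric(data$X %*% beta) + aG[data$gen]
      stats::rnorm(data$N, mu, draw[["sigma"]])
    }
  )
}

#' Build the maturity ogive model
#'
#' Bernoulli-logit model of maturity status at 75 dph with line-specific
#' length and age slopes, a common inbreeding slope, and a generation
#' random intercept. Length and age are centered (centers stored in the
#' spec) so the line intercept contrasts are evaluated at an average-aged,
#' average-length fish.
#'
#' @param tables experiment tables (uses the fish table, fish alive at
#'   75 dph).
#' @param generations generations to pool.
#' @return a [model_spec()]; a separation warning is attached when a line
#'   is entirely mature or entirely immature.
#' @export
build_ogive_model <- function(tables, generations = NULL) {
  .require_cols(tables$fish,
                c("mature_75", "length_75", "age_75", "line", "generation",
                  "inbreeding"), "fish")
  d <- tables$fish[!is.na(tables$fish$length_75), ]
  if (!is.null(generations)) d <- d[d$generation %in% generations, ]
  cc <- .centered(d, c("length_75", "age_75", "inbreeding"))
  d <- cc$df
  d$line <- .line_factor(d$line)
  sep <- tapply(d$mature_75, d$line, function(m) all(m == 1) || all(m == 0))
  if (any(sep)) {
    warning("complete separation: line(s) ",
            paste(names(sep)[sep], collapse = ", "),
            " are entirely mature or entirely immature")
  }
  X <- stats::model.matrix(~ line + length_75_c:line + age_75_c:line +
                             inbreeding_c, d)
  gi <- .gen_index(d$generation)
  code <- paste0(
    "model {\n",
    "  for (i in 1:N) {\n",
    "    y[i] ~ dbern(p[i])\n",
    "    logit(p[i]) <- inprod(X[i,], beta) + aG[gen[i]]\n",
    "  }\n",
    .code_fixed_and_ranef(),
    "}")
  model_spec(
    name = "model2_ogive", code = code,
    data = list(y = as.numeric(d$mature_75), X = X, N = nrow(X),
                K = ncol(X), gen = gi$idx, NG = gi$n),
    params = c("beta", "aG", "sigmaG"),
    family = "bernoulli",
    terms = list(coef = colnames(X), centers = cc$centers,
                 generations = gi$levels, model_id = 2,
                 lines = levels(d$line),
                 symbols = c("alphaG", "alphaL", "beta1L_Sdl", "beta2L_Age",
                             "Inb", "sigmaG")),
    ppp = list(
      observed = function(data) data$y,
      mean_var = function(draw, data) {
        p <- stats::plogis(.eta(draw, data))
        list(mean = p, var = p * (1 - p))
      },
      simulate = function(draw, data) {
        stats::rbinom(data$N, 1, stats::plogis(.eta(draw, data)))
      }
    )
  )
}

# linear predictor X beta + aG[gen] from a pooled draw
.eta <- function(draw, data) {
  beta <- draw[sprintf("beta[%d]", seq_len(data$K))]
  aG <- draw[sprintf("aG[%d]", seq_len(data$NG))]
  as.numeric(data$X %*% beta) + aG[data$gen]
}

#' Build a stage-survival model
#'
#' Binomial-logit model of family counts surviving one developmental
#' transition, with line effects, mother/father inbreeding slopes and an
#' observation-level Gaussian overdispersion term (no generation random
#' effect, following the survival model's structure).
#'
#' @param transition one of `"egg-0"`, `"0-15"`, `"15-60"`, `"60-75"`.
#' @param tables experiment tables (uses the survival table).
#' @param generations generations to pool.
#' @return a [model_spec()].
#' @export
build_survival_model <- function(transition = c("egg-0", "0-15", "15-60",
                                                "60-75"),
                                 tables, generations = NULL) {
  transition <- match.arg(transition)
  .require_cols(tables$survival,
                c("stage", "n_start", "n_end", "line", "mo_inb", "fa_inb"),
                "survival")
  d <- tables$survival[tables$survival$stage == transition, ]
  if (!is.null(generations) && "generation" %in% names(d)) {
    d <- d[d$generation %in% generations, ]
  }
  if (any(d$n_end > d$n_start)) {
    stop("survival data error: n_end exceeds n_start for ",
         sum(d$n_end > d$n_start), " families")
  }
  if (any(d$n_start == 0)) {
    warning("excluding ", sum(d$n_start == 0),
            " families with n_start = 0")
    d <- d[d$n_start > 0, ]
  }
  cc <- .centered(d, c("mo_inb", "fa_inb"))
  d <- cc$df
  d$line <- .line_factor(d$line)
  X <- stats::model.matrix(~ line + mo_inb_c + fa_inb_c, d)
  # non-centered overdispersion: the fixed effects (the quantities the
  # report tests) mix several-fold better than under hierarchical
  # centering, at the cost of slower mixing of the nuisance sd
  code <- paste0(
    "model {\n",
    "  for (i in 1:N) {\n",
    "    n_end[i] ~ dbin(p[i], n_start[i])\n",
    "    logit(p[i]) <- inprod(X[i,], beta) + eps[i]\n",
    "  }\n",
    "  for (k in 1:K) { beta[k] ~ ", .prior_fixed, " }\n",
    "  for (i in 1:N) { eps[i] ~ dnorm(0, tauE) }\n",
    "  tauE <- pow(sigmaE, -2)\n",
    "  sigmaE ~ ", .prior_sd, "\n",
    "}")
  model_spec(
    name = paste0("model3_survival_", gsub("-", "_", transition)),
    code = code,
    data = list(n_end = d$n_end, n_start = d$n_start, X = X, N = nrow(X),
                K = ncol(X)),
    params = c("beta", "sigmaE"),
    family = "binomial",
    terms = list(coef = colnames(X), centers = cc$centers,
                 transition = transition, model_id = 3,
                 symbols = c("alphaL", "Mo.inb", "Fa.inb", "epsilon",
                             "sigmaE")),
    ppp = list(
      observed = function(data) data$n_end,
      mean_var = function(draw, data) {
        beta <- draw[sprintf("beta[%d]", seq_len(data$K))]
        p <- stats::plogis(as.numeric(data$X %*% beta))
        list(mean = data$n_start * p, var = data$n_start * p * (1 - p))
      },
      simulate = function(draw, data) {
        beta <- draw[sprintf("beta[%d]", seq_len(data$K))]
        eta <- as.numeric(data$X %*% beta) +
          stats::rnorm(data$N, 0, draw[["sigmaE"]])
        stats::rbinom(data$N, data$n_start, stats::plogis(eta))
      }
    )
  )
}

#' Build the zero-inflated Poisson fecundity model
#'
#' Two-part model of total clutch sizes per breeding pair: a logit-scale
#' zero part (probability a pair is infertile) and a log-link Poisson count
#' part with the natural log of the number of collection days as offset,
#' quadratic mean-parental-length terms, generation random intercepts in
#' both parts, and observation-level overdispersion in the count part.
#'
#' The default construction is the standard mixture (a structural zero with
#' probability pi, otherwise Poisson); `construction = "deflated"` instead
#' uses a Poisson with literally deflated mean `(1 - pi) * lambda`.
#'
#' @param tables experiment tables (uses the clutches table).
#' @param generations generations to pool.
#' @param construction `"mixture"` (default) or `"deflated"`.
#' @return a [model_spec()].
#' @export
build_zip_fecundity_model <- function(tables, generations = NULL,
                                      construction = c("mixture",
                                                       "deflated")) {
  construction <- match.arg(construction)
  .require_cols(tables$clutches,
                c("n_eggs", "days_collected", "line", "generation",
                  "mo_inb", "fa_inb", "parent_sdl"), "clutches")
  d <- tables$clutches
  if (!is.null(generations)) d <- d[d$generation %in% generations, ]
  if (any(d$days_collected <= 0)) stop("collection days must be positive")
  cc <- .centered(d, c("mo_inb", "fa_inb", "parent_sdl"))
  d <- cc$df
  d$line <- .line_factor(d$line)
  X <- stats::model.matrix(~ line + mo_inb_c + fa_inb_c + parent_sdl_c +
                             I(parent_sdl_c^2), d)
  gi <- .gen_index(d$generation)
  lik <- if (construction == "mixture") paste0(
    "    z[i] ~ dbern(q[i])\n",
    "    y[i] ~ dpois(z[i] * lambda[i] + 1.0E-10)\n")
  else paste0(
    "    y[i] ~ dpois(q[i] * lambda[i] + 1.0E-10)\n")
  code <- paste0(
    "model {\n",
    "  for (i in 1:N) {\n",
    lik,
    "    q[i] <- 1 - pzero[i]\n",
    # hierarchically centered overdispersion for good Gibbs mixing
    "    log(lambda[i]) <- theta[i]\n",
    "    theta[i] ~ dnorm(offs[i] + inprod(X[i,], beta) + aG[gen[i]],",
    " tauE)\n",
    "    logit(pzero[i]) <- inprod(X[i,], gamma) + gG[gen[i]]\n",
    "  }\n",
    "  for (k in 1:K) { beta[k] ~ ", .prior_fixed, " }\n",
    "  for (k in 1:K) { gamma[k] ~ ", .prior_fixed, " }\n",
    "  for (g in 1:NG) { aG[g] ~ dnorm(0, tauG) }\n",
    "  for (g in 1:NG) { gG[g] ~ dnorm(0, tauGG) }\n",
    "  tauG <- pow(sigmaG, -2)\n  sigmaG ~ ", .prior_sd, "\n",
    "  tauGG <- pow(sigmaGG, -2)\n  sigmaGG ~ ", .prior_sd, "\n",
    "  tauE <- pow(sigmaE, -2)\n  sigmaE ~ ", .prior_sd, "\n",
    "}")
  inits <- if (construction == "mixture") {
    function(chain) list(z = rep(1L, nrow(d)))
  } else NULL
  model_spec(
    name = paste0("model4_fecundity_", construction), code = code,
    data = list(y = d$n_eggs, offs = log(d$days_collected), X = X,
                N = nrow(X), K = ncol(X), gen = gi$idx, NG = gi$n),
    params = c("beta", "gamma", "aG", "gG", "sigmaG", "sigmaGG", "sigmaE"),
    family = "zip",
    terms = list(coef = colnames(X), centers = cc$centers,
                 generations = gi$levels, model_id = 4,
                 construction = construction,
                 symbols = c("alphaG", "alphaL", "Mo.inb", "Fa.inb",
                             "Parent.sdl", "Parent.sdl2", "gammaG",
                             "gammaL", "offset", "pi", "lambda",
                             "epsilon", "sigmaE", "sigmaG", "sigmaGG")),
    inits = inits,
    ppp = list(
      observed = function(data) data$y,
      mean_var = function(draw, data) {
        beta <- draw[sprintf("beta[%d]", seq_len(data$K))]
        gam <- draw[sprintf("gamma[%d]", seq_len(data$K))]
        aG <- draw[sprintf("aG[%d]", seq_len(data$NG))]
        gG <- draw[sprintf("gG[%d]", seq_len(data$NG))]
        lam <- exp(data$offs + as.numeric(data$X %*% beta) + aG[data$gen])
        pz <- stats::plogis(as.numeric(data$X %*% gam) + gG[data$gen])
        list(mean = (1 - pz) * lam,
             var = (1 - pz) * lam * (1 + pz * lam))
      },
      simulate = function(draw, data) {
        beta <- draw[sprintf("beta[%d]", seq_len(data$K))]
        gam <- draw[sprintf("gamma[%d]", seq_len(data$K))]
        aG <- draw[sprintf("aG[%d]", seq_len(data$NG))]
        gG <- draw[sprintf("gG[%d]", seq_len(data$NG))]
        eps <- stats::rnorm(data$N, 0, draw[["sigmaE"]])
        lam <- exp(data$offs + as.numeric(data$X %*% beta) +
                     aG[data$gen] + eps)
        pz <- stats::plogis(as.numeric(data$X %*% gam) + gG[data$gen])
        z <- stats::rbinom(data$N, 1, 1 - pz)
        stats::rpois(data$N, z * lam)
      }
    )
  )
}

#' Build the multivariate hormone model
#'
#' Trivariate normal model of per-fish ln hormone/actin ratios (LHb, FSHb,
#' GH) with per-gene fixed effects (line, sex, inbreeding, length),
#' per-gene generation random intercepts, and a line-specific residual
#' covariance matrix under an inverse-Wishart prior (scale matrix
#' `diag(rho)`, `rho = 3` degrees of freedom).
#'
#' @param tables experiment tables (uses the hormones table; rows with a
#'   missing measurement are excluded with a report).
#' @param generations generations to pool.
#' @return a [model_spec()].
#' @export
build_hormone_model <- function(tables, generations = NULL) {
  .require_cols(tables$hormones,
                c("ln_ratio_lhb", "ln_ratio_fshb", "ln_ratio_gh", "line",
                  "sex", "length", "inbreeding", "generation"), "hormones")
  d <- tables$hormones
  if (!is.null(generations)) d <- d[d$generation %in% generations, ]
  Y <- as.matrix(d[, c("ln_ratio_lhb", "ln_ratio_fshb", "ln_ratio_gh")])
  keep <- stats::complete.cases(Y)
  if (any(!keep)) {
    message("excluding ", sum(!keep), " fish with missing measurements")
    d <- d[keep, ]
    Y <- Y[keep, , drop = FALSE]
  }
  cc <- .centered(d, c("length", "inbreeding"))
  d <- cc$df
  d$line <- .line_factor(d$line)
  d$sex <- .sex_factor(d$sex)
  X <- stats::model.matrix(~ line + sex + inbreeding_c + length_c, d)
  gi <- .gen_index(d$generation)
  nl <- nlevels(d$line)
  code <- paste0(
    "model {\n",
    "  for (i in 1:N) {\n",
    "    Y[i, 1:3] ~ dmnorm(mu[i, 1:3], Omega[lineid[i], 1:3, 1:3])\n",
    "    for (j in 1:3) {\n",
    "      mu[i, j] <- inprod(X[i,], beta[j, ]) + aG[j, gen[i]]\n",
    "    }\n",
    "  }\n",
    "  for (j in 1:3) {\n",
    "    for (k in 1:K) { beta[j, k] ~ ", .prior_fixed, " }\n",
    "    for (g in 1:NG) { aG[j, g] ~ dnorm(0, tauG[j]) }\n",
    "    tauG[j] <- pow(sigmaG[j], -2)\n",
    "    sigmaG[j] ~ ", .prior_sd, "\n",
    "  }\n",
    "  for (l in 1:NL) {\n",
    "    Omega[l, 1:3, 1:3] ~ dwish(R[1:3, 1:3], rho)\n",
    "    Sigma[l, 1:3, 1:3] <- inverse(Omega[l, 1:3, 1:3])\n",
    "  }\n",
    "}")
  model_spec(
    name = "model8_hormones", code = code,
    data = list(Y = Y, X = X, N = nrow(X), K = ncol(X),
                gen = gi$idx, NG = gi$n,
                lineid = as.integer(d$line), NL = nl,
                R = diag(3) * 3, rho = 3),
    params = c("beta", "aG", "sigmaG", "Sigma"),
    family = "mvnormal",
    terms = list(coef = colnames(X), centers = cc$centers,
                 generations = gi$levels, model_id = 8,
                 genes = c("lhb", "fshb", "gh"),
                 lines = levels(d$line),
                 symbols = c("alphaG", "alphaL", "alphaS", "Inb", "Sdl",
                             "SigmaL", "R", "rho", "sigmaG")),
    ppp = list(
      observed = function(data) data$Y,
      mean_var = function(draw, data) {
        mu <- .mvn_mu(draw, data)
        v <- t(vapply(seq_len(data$N), function(i) {
          l <- data$lineid[i]
          c(draw[[sprintf("Sigma[%d,1,1]", l)]],
            draw[[sprintf("Sigma[%d,2,2]", l)]],
            draw[[sprintf("Sigma[%d,3,3]", l)]])
        }, numeric(3)))
        list(mean = mu, var = v)
      },
      simulate = function(draw, data) {
        mu <- .mvn_mu(draw, data)
        out <- mu
        for (l in seq_len(data$NL)) {
          S <- matrix(NA_real_, 3, 3)
          for (a in 1:3) for (b in 1:3) {
            S[a, b] <- draw[[sprintf("Sigma[%d,%d,%d]", l, a, b)]]
          }
          rows <- which(data$lineid == l)
          z <- matrix(stats::rnorm(3 * length(rows)), length(rows), 3)
          out[rows, ] <- mu[rows, ] + z %*% chol(S)
        }
        out
      }
    )
  )
}

.mvn_mu <- function(draw, data) {
  mu <- matrix(NA_real_, data$N, 3)
  for (j in 1:3) {
    beta <- draw[sprintf("beta[%d,%d]", j, seq_len(data$K))]
    aG <- draw[sprintf("aG[%d,%d]", j, seq_len(data$NG))]
    mu[, j] <- as.numeric(data$X %*% beta) + aG[data$gen]
  }
  mu
}

#' Posterior draws of one fixed-effect coefficient
#'
#' @param samples a fitted `posterior_samples` whose spec was produced by
#'   one of the `build_*_model` constructors.
#' @param coef coefficient name as it appears in `spec$terms$coef`
#'   (e.g. `"lineLarge"`).
#' @param part `"beta"` (count/mean part) or `"gamma"` (zero part of the
#'   fecundity model).
#' @param gene for the hormone model, one of `"lhb"`, `"fshb"`, `"gh"`.
#' @return numeric vector of pooled posterior draws.
#' @export
coef_draws <- function(samples, coef, part = "beta", gene = NULL) {
  spec <- samples$spec
  k <- match(coef, spec$terms$coef)
  if (is.na(k)) {
    stop("coefficient '", coef, "' not in spec; available: ",
         paste(spec$terms$coef, collapse = ", "))
  }
  d <- as_draws(samples)
  nm <- if (!is.null(gene)) {
    j <- match(gene, spec$terms$genes)
    if (is.na(j)) stop("unknown gene '", gene, "'")
    sprintf("%s[%d,%d]", part, j, k)
  } else {
    sprintf("%s[%d]", part, k)
  }
  if (!nm %in% colnames(d)) stop("parameter ", nm, " was not monitored")
  d[, nm]
}
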
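#' Declarative Bayesian model specification
#'
#' A model spec couples a JAGS model definition with its data, the
#' parameters to monitor, and optional closures used for posterior
#' predictive checking. Specs for the experiment's eight trait models are
#' built by the `build_*_model` constructors; custom specs can be created
#' directly.
#'
#' @param name short identifier.
#' @param code JAGS model code (character scalar).
#' @param data named list of data passed to the sampler.
#' @param params character vector of parameters to monitor.
#' @param family likelihood family label (`"normal"`, `"bernoulli"`,
#'   `"binomial"`, `"zip"`, `"mvnormal"`, ...).
#' @param terms named list describing the linear-predictor terms (used for
#'   reporting and coverage audits).
#' @param inits optional function `(chain) -> list` of parameter initial
#'   values (RNG seeds are added automatically).
#' @param ppp optional list of closures for [posterior_predictive_p()]:
#'   `observed(data)` returning the response, `simulate(draw, data)`
#'   returning one replicate response, and `mean_var(draw, data)` returning
#'   `list(mean =, var =)` for Pearson residuals.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(name, code, data, params, family = "normal",
                       terms = list(), inits = NULL, ppp = NULL) {
  stopifnot(is.character(code), length(code) == 1, is.list(data),
            is.character(params))
  structure(list(name = name, code = code, data = data, params = params,
                 family = family, terms = terms, inits = inits, ppp = ppp),
            class = "model_spec")
}

#' Fit a model spec by MCMC
#'
#' Runs JAGS with independent chains, discards the adaptation/burn-in
#' phase, thins the retained draws, and computes the Gelman-Rubin statistic
#' for every monitored scalar parameter. Draws are reproducible given
#' `seed` (chain RNGs are seeded deterministically from it).
#'
#' @param spec a [model_spec()].
#' @param chains number of independent chains (default 3).
#' @param n_adapt adaptation + burn-in iterations.
#' @param n_iter post-burn-in iterations per chain (before thinning).
#' @param thin thinning period (default 5).
#' @param seed integer seed.
#' @param rhat_max convergence threshold on the potential scale reduction
#'   factor.
#' @param on_nonconvergence `"error"` (default) raises a diagnostic error
#'   naming the offending parameters, `"warn"` downgrades it to a warning,
#'   `"none"` skips the check.
#' @param quiet suppress JAGS progress output.
#' @return object of class `posterior_samples`: list with `mcmc` (a
#'   [coda::mcmc.list]), `params`, `rhat`, `spec`, `seed`, `thin`.
#' @export
fit_model <- function(spec, chains = 3, n_adapt = 500, n_iter = 2500,
                      thin = 5, seed = 1,
                      rhat_max = 1.1,
                      on_nonconvergence = c("error", "warn", "none"),
                      quiet = TRUE) {
  stopifnot(inherits(spec, "model_spec"), chains >= 1)
  on_nonconvergence <- match.arg(on_nonconvergence)
  try(rjags::load.module("glm", quiet = TRUE), silent = TRUE)
  inits <- lapply(seq_len(chains), function(ch) {
    ini <- if (is.null(spec$inits)) list() else spec$inits(ch)
    ini$.RNG.name <- "base::Mersenne-Twister"
    ini$.RNG.seed <- (abs(seed) %% 1000000L) * 1000L + ch
    ini
  })
  jm <- rjags::jags.model(textConnection(spec$code), data = spec$data,
                          n.chains = chains, inits = inits,
                          n.adapt = n_adapt, quiet = quiet)
  samp <- rjags::coda.samples(jm, variable.names = spec$params,
                              n.iter = n_iter, thin = thin,
                              progress.bar = "none")
  out <- structure(list(mcmc = samp,
                        params = coda::varnames(samp),
                        rhat = NULL, spec = spec, seed = seed, thin = thin),
                   class = "posterior_samples")
  if (chains >= 2) {
    out$rhat <- gelman_rubin(out)
    bad <- names(out$rhat)[is.finite(out$rhat) & out$rhat > rhat_max]
    if (length(bad) > 0 && on_nonconvergence != "none") {
      msg <- paste0("MCMC did not converge (Rhat > ", rhat_max, ") for: ",
                    paste(sprintf("%s (%.3f)", bad, out$rhat[bad]),
                          collapse = ", "))
      if (on_nonconvergence == "error") {
        stop(errorCondition(msg, class = "mcmc_convergence_error",
                            parameters = bad))
      }
      warning(msg, call. = FALSE)
    }
  }
  out
}

#' Gelman-Rubin potential scale reduction factors
#'
#' @param samples a `posterior_samples` object (or a [coda::mcmc.list])
#'   with at least two chains.
#' @return named numeric vector of point-estimate PSRF values, one per
#'   monitored scalar parameter.
#' @export
gelman_rubin <- function(samples) {
  m <- if (inherits(samples, "posterior_samples")) samples$mcmc else samples
  if (coda::nchain(m) < 2) {
    stop("Gelman-Rubin diagnostic requires at least 2 chains")
  }
  # drop parameters without variation (e.g. structural zeros) to keep
  # gelman.diag well-defined; they trivially 'converged'
  keep <- apply(as.matrix(m), 2, stats::var) > 0
  psrf <- rep(1, coda::nvar(m))
  names(psrf) <- coda::varnames(m)
  if (any(keep)) {
    gd <- coda::gelman.diag(m[, names(psrf)[keep], drop = FALSE],
                            autoburnin = FALSE, multivariate = FALSE)
    psrf[names(psrf)[keep]] <- gd$psrf[, "Point est."]
  }
  psrf
}

#' Matrix of pooled posterior draws
#'
#' @param samples a `posterior_samples` object.
#' @return numeric matrix, rows = draws pooled across chains, columns =
#'   parameters.
#' @export
as_draws <- function(samples) {
  # bind chains directly (each mcmc object is a plain matrix underneath);
  # this keeps parameter names without relying on S3 dispatch to coda's
  # as.matrix method, e.g. on fits deserialized in a fresh session
  do.call(rbind, lapply(samples$mcmc, function(ch) {
    m <- unclass(ch)
    attr(m, "mcpar") <- NULL
    m
  }))
}

#' MCMC p-value of a posterior sample
#'
#' Twice the proportion of draws whose sign is opposite to the sign of the
#' posterior mean, capped at 1 (a Bayesian analogue of a two-sided t test).
#' Zeros never count as opposite-signed. A degenerate all-zero sample is
#' defined as p = 1 (with a warning).
#'
#' @param draws numeric vector of posterior draws for a scalar parameter.
#' @return p-value in `[0, 1]`.
#' @export
mcmc_p_value <- function(draws) {
  draws <- as.numeric(draws)
  if (length(draws) == 0) stop("empty posterior sample")
  m <- mean(draws)
  if (all(draws == 0)) {
    warning("all posterior draws are exactly zero; p-value defined as 1")
    return(1)
  }
  opposite <- if (m > 0) draws < 0 else if (m < 0) draws > 0
              else draws != 0   # mean exactly 0: all nonzero mass is opposite
  min(1, 2 * mean(opposite))
}

#' Posterior predictive (Bayesian) p-value
#'
#' For each retained posterior draw, simulates a replicate dataset from the
#' fitted likelihood and compares the discrepancy (sum of squared Pearson
#' residuals) of the replicate with that of the observed data. The reported
#' p-value is the proportion of draws for which the replicate discrepancy
#' is at least as large as the observed one; values near 0.5 indicate a
#' well-fitting model.
#'
#' @param samples a `posterior_samples` object whose spec carries `ppp`
#'   closures (see [model_spec()]).
#' @param seed integer seed (replicates are reproducible given the seed).
#' @param n_sims number of posterior draws to use (default: up to 200,
#'   evenly spaced through the pooled sample).
#' @return p-value in `[0, 1]`.
#' @export
posterior_predictive_p <- function(samples, seed = 1, n_sims = 200) {
  spec <- samples$spec
  if (is.null(spec$ppp)) {
    stop("model spec '", spec$name, "' does not define a simulable ",
         "likelihood for posterior predictive checking")
  }
  set.seed(seed)
  draws <- as_draws(samples)
  idx <- unique(round(seq(1, nrow(draws), length.out = min(n_sims,
                                                           nrow(draws)))))
  y_obs <- spec$ppp$observed(spec$data)
  exceed <- logical(length(idx))
  for (i in seq_along(idx)) {
    draw <- draws[idx[i], ]
    mv <- spec$ppp$mean_var(draw, spec$data)
    v <- pmax(mv$var, 1e-12)
    d_obs <- sum((y_obs - mv$mean)^2 / v, na.rm = TRUE)
    y_rep <- spec$ppp$simulate(draw, spec$data)
    d_rep <- sum((y_rep - mv$mean)^2 / v, na.rm = TRUE)
    exceed[i] <- d_rep >= d_obs
  }
  mean(exceed)
}

#' Posterior summary table
#'
#' @param samples a `posterior_samples` object.
#' @param params optional subset of parameter names.
#' @return data frame with posterior mean, sd, quantiles, Rhat and the
#'   MCMC p-value per parameter.
#' @export
posterior_summary <- function(samples, params = NULL) {
  d <- as_draws(samples)
  if (!is.null(params)) d <- d[, params, drop = FALSE]
  suppressWarnings(
    data.frame(
      parameter = colnames(d),
      mean = colMeans(d),
      sd = apply(d, 2, stats::sd),
      q2.5 = apply(d, 2, stats::quantile, 0.025),
      median = apply(d, 2, stats::median),
      q97.5 = apply(d, 2, stats::quantile, 0.975),
      rhat = if (is.null(samples$rhat)) NA_real_
             else unname(samples$rhat[colnames(d)]),
      mcmc_p = apply(d, 2, function(x) {
        if (all(x == 0)) NA_real_ else mcmc_p_value(x)
      }),
      row.names = NULL
    )
  )
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat("Posterior samples for model '", x$spec$name, "'\n", sep = "")
  cat("  chains:", coda::nchain(x$mcmc),
      " draws/chain:", coda::niter(x$mcmc),
      " thin:", x$thin, "\n")
  if (!is.null(x$rhat)) {
    cat(sprintf("  max Rhat: %.3f\n", max(x$rhat, na.rm = TRUE)))
  }
  invisible(x)
}
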
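# Minimal hand-built model specs used to exercise the MCMC machinery
# against closed-form and simulation oracles.

# Normal likelihood with known variance and a flat-ish prior on the mean;
# conjugate, so the posterior for mu is available in closed form.
normal_mean_spec <- function(y, sigma, prior_sd = 100) {
  code <- "model {
    for (i in 1:N) { y[i] ~ dnorm(mu, tau) }
    mu ~ dnorm(0, prior_prec)
  }"
  model_spec(
    name = "normal_mean", code = code,
    data = list(y = y, N = length(y), tau = 1 / sigma^2,
                prior_prec = 1 / prior_sd^2),
    params = "mu", family = "normal",
    ppp = list(
      observed = function(data) data$y,
      mean_var = function(draw, data) {
        list(mean = rep(draw[["mu"]], data$N), var = rep(1 / data$tau, data$N))
      },
      simulate = function(draw, data) {
        rnorm(data$N, draw[["mu"]], sqrt(1 / data$tau))
      }
    )
  )
}

logistic_spec <- function(y, x) {
  code <- "model {
    for (i in 1:N) {
      y[i] ~ dbern(p[i])
      logit(p[i]) <- b0 + b1 * x[i]
    }
    b0 ~ dnorm(0, 1.0E-4)
    b1 ~ dnorm(0, 1.0E-4)
  }"
  model_spec(name = "logistic", code = code,
             data = list(y = y, x = x, N = length(y)),
             params = c("b0", "b1"), family = "bernoulli")
}

# Fabricate a posterior_samples object from plain draw matrices (one per
# chain); used to test diagnostics without running a sampler.
fake_samples <- function(chain_list, name = "fake") {
  ml <- coda::mcmc.list(lapply(chain_list, coda::mcmc))
  structure(list(mcmc = ml, params = coda::varnames(ml), rhat = NULL,
                 spec = model_spec(name, "model{}", list(), "x"),
                 seed = NA, thin = 1),
            class = "posterior_samples")
}
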
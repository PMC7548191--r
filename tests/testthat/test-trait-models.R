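test_that("Gaussian trait models recover simulation truth within 3 posterior sd", {
  cases <- list(
    list(id = 1, sim = sim_m1_data,
         check = c(lineLarge = "lineLarge", lineSmall = "lineSmall")),
    list(id = 5, sim = sim_m5_data,
         check = c(lineSmall = "lineSmall", b_mosdl = "mother_sdl_c")),
    list(id = 6, sim = sim_m6_data,
         check = c(lineSmall = "lineSmall", b_moinb = "mo_inb_c")),
    list(id = 7, sim = sim_m7_data,
         check = c(lineLarge = "lineLarge", b_inb = "inbreeding_c"))
  )
  for (case in cases) {
    sim <- case$sim(seed = 42)
    spec <- build_gaussian_model(case$id, sim$tables)
    fit <- quick_fit(spec, seed = 1)
    for (tr_name in names(case$check)) {
      draws <- coef_draws(fit, case$check[[tr_name]])
      expect_lt(abs(mean(draws) - sim$truth[[tr_name]]), 3 * sd(draws),
                label = sprintf("model %d, %s", case$id, tr_name))
    }
  }
})

test_that("a configured Large-line growth shift is recovered from a full experiment", {
  # +1.2 mm generative Large-line shift, heritability off and random rules
  # so nothing else can move line means
  cfg <- simulation_config(n_generations = 5, seed = 8)
  arch <- trait_architecture(
    h2_length = 0,
    line_effects = list(Large = list(growth_span = 1.2 /
                                       (1 - exp(-0.02 * 75)))))
  rules <- list(Control = selection_rule("random"),
                Small = selection_rule("random"),
                Large = selection_rule("random"))
  ex <- run_experiment(cfg, arch, rules)
  fish <- ex$tables$fish[!is.na(ex$tables$fish$length_75), ]
  set.seed(3)
  fish <- fish[sample(nrow(fish), min(900, nrow(fish))), ]
  fit <- quick_fit(build_gaussian_model(1, list(fish = fish)), seed = 2)
  draws <- coef_draws(fit, "lineLarge")
  expect_lt(abs(mean(draws) - 1.2), 3 * sd(draws))
  # and the Small line stays at zero
  ds <- coef_draws(fit, "lineSmall")
  expect_lt(abs(mean(ds)), 3 * sd(ds))
})

test_that("the ogive model recovers line-specific slopes", {
  sim <- sim_m2_data(n = 3000, seed = 5)
  spec <- build_ogive_model(sim$tables)
  fit <- quick_fit(spec, seed = 1)
  for (line in LINES3) {
    dl <- coef_draws(fit, sprintf("line%s:length_75_c", line))
    expect_lt(abs(mean(dl) - sim$truth[[paste0("len_", line)]]), 3 * sd(dl))
    # positive configured length slope: overwhelming posterior mass above 0
    expect_gt(mean(dl > 0), 0.99)
    da <- coef_draws(fit, sprintf("line%s:age_75_c", line))
    expect_lt(abs(mean(da) - sim$truth[[paste0("age_", line)]]), 3 * sd(da))
  }
})

test_that("complete separation in a line raises a warning", {
  sim <- sim_m2_data(n = 200, seed = 2)
  sim$tables$fish$mature_75 <- 0
  expect_warning(build_ogive_model(sim$tables), "separation")
})

test_that("survival models recover intercept and overdispersion", {
  truth <- c(b0 = qlogis(0.9), lineSmall = 0, lineLarge = 0,
             b_mo = 0, b_fa = 0, sigmaE = 1.0)
  sim <- sim_m3_data(n = 150, seed = 9, truth = truth)
  fit <- quick_fit(build_survival_model("0-15", sim$tables), seed = 1)
  s <- posterior_summary(fit)
  b0 <- s[s$parameter == "beta[1]", ]
  expect_lt(abs(b0$mean - qlogis(0.9)), 3 * b0$sd)
  expect_true(plogis(b0$mean) > 0.8 && plogis(b0$mean) < 0.96)
  se <- s[s$parameter == "sigmaE", ]
  expect_lt(abs(se$mean - 1.0), 3 * se$sd)
})

test_that("survival data errors are caught", {
  sim <- sim_m3_data(n = 50, seed = 3)
  bad <- sim$tables
  bad$survival$n_end[1] <- bad$survival$n_start[1] + 5
  expect_error(build_survival_model("0-15", bad), "n_end exceeds")
  zero <- sim$tables
  zero$survival$n_start[1:3] <- 0
  zero$survival$n_end[1:3] <- 0
  expect_warning(build_survival_model("0-15", zero), "excluding 3")
})

test_that("the ZIP fecundity model recovers infertility rate and daily rate", {
  sim <- sim_m4_data(n = 300, seed = 11)
  spec <- build_zip_fecundity_model(sim$tables)
  fit <- quick_fit(spec, seed = 1, n_iter = 1500)
  d <- as_draws(fit)
  pz <- plogis(d[, "gamma[1]"])
  qs <- quantile(pz, c(0.025, 0.975))
  expect_true(qs[1] <= 0.3 && 0.3 <= qs[2])
  lam <- exp(d[, "beta[1]"])
  ql <- quantile(lam, c(0.025, 0.975))
  expect_true(ql[1] <= 12 && 12 <= ql[2])
})

test_that("the collection-day offset leaves daily-rate parameters unchanged", {
  truth <- c(b0 = log(10), lineSmall = 0, lineLarge = 0, b_sdl = 0,
             b_sdl2 = 0, g0 = qlogis(0.15), gline = 0,
             sigmaE = 0.15, sigmaG = 0.1)
  sim <- sim_m4_data(n = 250, seed = 21, truth = truth, days = 4:5)
  sim2 <- sim_m4_data(n = 250, seed = 21, truth = truth, days = 8:10)
  # doubled exposure at the same daily rate doubles the expected totals
  expect_equal(mean(sim2$tables$clutches$n_eggs) /
                 mean(sim$tables$clutches$n_eggs), 2, tolerance = 0.15)
  fit1 <- quick_fit(build_zip_fecundity_model(sim$tables), seed = 1)
  fit2 <- quick_fit(build_zip_fecundity_model(sim2$tables), seed = 1)
  b1 <- as_draws(fit1)[, "beta[1]"]
  b2 <- as_draws(fit2)[, "beta[1]"]
  # same daily-rate parameter despite doubled exposure
  expect_lt(abs(mean(b1) - mean(b2)),
            3 * sqrt(var(b1) + var(b2)))
  expect_lt(abs(mean(b1) - truth[["b0"]]), 3 * sd(b1))
  expect_lt(abs(mean(b2) - truth[["b0"]]), 3 * sd(b2))
})

test_that("with no zero counts the zero-part intercept collapses to negative", {
  truth <- c(b0 = log(15), lineSmall = 0, lineLarge = 0, b_sdl = 0,
             b_sdl2 = 0, g0 = -50, gline = 0, sigmaE = 0.1, sigmaG = 0.1)
  sim <- sim_m4_data(n = 150, seed = 31, truth = truth)
  expect_true(all(sim$tables$clutches$n_eggs > 0))
  fit <- quick_fit(build_zip_fecundity_model(sim$tables), seed = 1)
  g0 <- as_draws(fit)[, "gamma[1]"]
  expect_lt(quantile(g0, 0.975), 0)
  expect_lt(mean(plogis(g0)), 0.05)
})

test_that("nonpositive collection days are rejected", {
  sim <- sim_m4_data(n = 30, seed = 1)
  sim$tables$clutches$days_collected[1] <- 0
  expect_error(build_zip_fecundity_model(sim$tables), "positive")
})

test_that("the hormone model recovers residual correlations and line shifts", {
  sim <- sim_m8_data(n = 250, seed = 6, resid_cor = 0.7)
  spec <- build_hormone_model(sim$tables)
  fit <- quick_fit(spec, seed = 1)
  d <- as_draws(fit)
  # residual correlations across the three gene pairs, Control line
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    r <- d[, sprintf("Sigma[1,%d,%d]", pair[1], pair[2])] /
      sqrt(d[, sprintf("Sigma[1,%d,%d]", pair[1], pair[1])] *
             d[, sprintf("Sigma[1,%d,%d]", pair[2], pair[2])])
    expect_lt(abs(mean(r) - 0.7), 0.1)
  }
  # configured Small-line GH shift of +0.44: sign recovered decisively
  gh_small <- coef_draws(fit, "lineSmall", gene = "gh")
  expect_gt(mean(gh_small > 0), 0.9)
  # every posterior covariance draw is positive definite
  idx <- seq(1, nrow(d), length.out = 50)
  for (i in round(idx)) {
    for (l in 1:3) {
      S <- matrix(NA_real_, 3, 3)
      for (a in 1:3) for (b in 1:3) {
        S[a, b] <- d[i, sprintf("Sigma[%d,%d,%d]", l, a, b)]
      }
      expect_true(all(eigen(S, symmetric = TRUE,
                            only.values = TRUE)$values > 0))
    }
  }
})

test_that("builders name missing columns and unknown coefficients", {
  sim <- sim_m1_data(n = 30, seed = 1)
  broken <- sim$tables
  broken$fish$inbreeding <- NULL
  expect_error(build_gaussian_model(1, broken), "inbreeding")
  spec <- build_gaussian_model(1, sim$tables)
  fit <- quick_fit(spec, seed = 1, n_adapt = 200, n_iter = 300)
  expect_error(coef_draws(fit, "nonexistent"), "not in spec")
})

test_that("every printed model symbol is consumed by exactly one spec", {
  expected <- list(
    model1_length75 = c("alphaG", "alphaL", "alphaS", "Age", "Inb",
                        "sigma", "sigmaG"),
    model2_ogive = c("alphaG", "alphaL", "beta1L_Sdl", "beta2L_Age",
                     "Inb", "sigmaG"),
    model3_survival_0_15 = c("alphaL", "Mo.inb", "Fa.inb", "epsilon",
                             "sigmaE"),
    model4_fecundity_mixture = c("alphaG", "alphaL", "Mo.inb", "Fa.inb",
                                 "Parent.sdl", "Parent.sdl2", "gammaG",
                                 "gammaL", "offset", "pi", "lambda",
                                 "epsilon", "sigmaE", "sigmaG", "sigmaGG"),
    model5_eggsize = c("alphaG", "alphaL", "Mo.sdl", "Mo.inb", "Fa.inb",
                       "sigma", "sigmaG"),
    model6_incubation = c("alphaG", "alphaL", "Mo.sdl", "Mo.inb", "Fa.inb",
                          "sigma", "sigmaG"),
    model7_hatchlength = c("alphaG", "alphaL", "Parent.sdl", "Inb",
                           "sigma", "sigmaG"),
    model8_hormones = c("alphaG", "alphaL", "alphaS", "Inb", "Sdl",
                        "SigmaL", "R", "rho", "sigmaG")
  )
  specs <- list(
    build_gaussian_model(1, sim_m1_data(50, 1)$tables),
    build_ogive_model(sim_m2_data(50, 1)$tables),
    build_survival_model("0-15", sim_m3_data(50, 1)$tables),
    build_zip_fecundity_model(sim_m4_data(50, 1)$tables),
    build_gaussian_model(5, sim_m5_data(50, 1)$tables),
    build_gaussian_model(6, sim_m6_data(50, 1)$tables),
    build_gaussian_model(7, sim_m7_data(50, 1)$tables),
    build_hormone_model(sim_m8_data(50, 1)$tables)
  )
  got <- lapply(specs, function(s) sort(s$terms$symbols))
  names(got) <- vapply(specs, function(s) s$name, character(1))
  for (nm in names(expected)) {
    expect_identical(got[[nm]], sort(expected[[nm]]), label = nm)
  }
})
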
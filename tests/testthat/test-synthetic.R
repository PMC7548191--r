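arch0 <- trait_architecture()

test_that("growth follows the von Bertalanffy curve", {
  # hatch length exact at age 0 without noise or genetics
  expect_equal(simulate_growth(arch0, 0, age = 0, env_sd = 0), 4.5)
  # strictly increasing in age without noise
  lens <- simulate_growth(arch0, 0, age = 0:100, env_sd = 0)
  expect_true(all(diff(lens) > 0))
  # asymptote: within a millimetre millionth once age >> 1/k
  far <- simulate_growth(arch0, 0, age = 20 / arch0$growth_rate_k,
                         env_sd = 0)
  expect_lt(abs(far - (arch0$hatch_length_mean + arch0$L_inf_mean)), 1e-6)
  expect_error(simulate_growth(arch0, 0, age = -1, env_sd = 0),
               "non-negative")
})

test_that("clutch counts have Poisson moments when overdispersion is off", {
  arch <- trait_architecture(fecundity_zero_prob = 0,
                             fecundity_daily_rate = 10,
                             fecundity_overdispersion_sd = 0)
  set.seed(101)
  totals <- replicate(10000, {
    sum(stats::rpois(5, 10))   # oracle: direct Poisson sum
  })
  set.seed(202)
  sim <- replicate(10000, {
    simulate_reproduction(arch, mother_length = 20, days = 5)$n_eggs
  })
  # Poisson(50): mean 50, variance 50; 10,000 reps give se(mean) ~ 0.07
  expect_equal(mean(sim), 50, tolerance = 3 * sqrt(50 / 10000) / 50)
  expect_equal(var(sim), 50, tolerance = 0.1)
  expect_equal(mean(sim), mean(totals), tolerance = 0.01)
})

test_that("all clutches are empty when the infertility probability is 1", {
  arch <- trait_architecture(fecundity_zero_prob = 1)
  for (i in 1:5) {
    cl <- simulate_reproduction(arch, 20, days = 4, seed = i)
    expect_true(cl$infertile)
    expect_equal(cl$n_eggs, 0L)
  }
})

test_that("egg-perimeter mother-length slope is recovered by least squares", {
  arch <- trait_architecture(egg_perimeter_slope = 0.02,
                             fecundity_zero_prob = 0)
  set.seed(7)
  mother_len <- runif(400, 17, 24)
  eggs <- lapply(seq_along(mother_len), function(i) {
    cl <- simulate_reproduction(arch, mother_len[i], days = 4)
    data.frame(len = mother_len[i], pm = cl$perimeters)
  })
  eggs <- do.call(rbind, eggs)
  expect_gt(nrow(eggs), 5000)
  fit <- summary(lm(pm ~ len, data = eggs))$coefficients
  expect_lt(abs(fit["len", "Estimate"] - 0.02), 3 * fit["len", "Std. Error"])
})

test_that("hormone draws honour the configured covariance and line shifts", {
  fish <- data.frame(id = sprintf("h%05d", 1:10000),
                     line = rep(c("Control", "Small"), each = 5000),
                     sex = "F", length = 20, inbreeding = 0)
  # diagonal covariance: near-zero cross correlations
  arch_d <- trait_architecture(
    hormone_cov_by_line = list(Control = diag(3) * 0.5,
                               Small = diag(3) * 0.5,
                               Large = diag(3) * 0.5))
  h <- simulate_hormones(arch_d, fish, seed = 5)
  hc <- h[h$line == "Control", ]
  cors <- cor(hc[, c("ln_ratio_lhb", "ln_ratio_fshb", "ln_ratio_gh")])
  expect_true(all(abs(cors[upper.tri(cors)]) < 0.05))

  # configured Small-line GH shift of +0.44 recovered within 3 se
  gh_c <- h$ln_ratio_gh[h$line == "Control"]
  gh_s <- h$ln_ratio_gh[h$line == "Small"]
  shift <- arch0$hormone_mean_by_line$Small["gh"] -
    arch0$hormone_mean_by_line$Control["gh"]
  expect_equal(unname(shift), 0.44)
  se <- sqrt(var(gh_c) / 5000 + var(gh_s) / 5000)
  expect_lt(abs((mean(gh_s) - mean(gh_c)) - 0.44), 3 * se)

  # degenerate covariance limit: all fish equal the line mean
  tiny <- diag(3) * 1e-20
  arch_z <- trait_architecture(
    hormone_cov_by_line = list(Control = tiny, Small = tiny, Large = tiny))
  hz <- simulate_hormones(arch_z, fish[1:50, ], seed = 1)
  expect_equal(hz$ln_ratio_lhb,
               rep(unname(arch_z$hormone_mean_by_line$Control["lhb"]), 50),
               tolerance = 1e-8)

  # non-positive-definite covariance is rejected
  bad <- matrix(1, 3, 3)
  arch_b <- arch0
  arch_b$hormone_cov_by_line <- list(Control = bad)
  expect_error(simulate_hormones(arch_b, fish[1:2, ], seed = 1),
               "positive definite")
})

test_that("the same seed reproduces the experiment byte for byte", {
  cfg <- simulation_config(n_generations = 3, seed = 77)
  e1 <- run_experiment(cfg)
  e2 <- run_experiment(cfg)
  expect_identical(e1$tables, e2$tables)
  expect_identical(e1$differentials, e2$differentials)
})

test_that("the emitted pedigree passes pedigree validation and matches stored F", {
  ex <- run_experiment(simulation_config(n_generations = 4, seed = 12))
  ped <- ex$pedigree
  expect_s3_class(ped, "pedigree")
  # fish-table inbreeding equals pedigree-derived 2k-1 for a no-prephase run
  ex0 <- run_experiment(simulation_config(n_generations = 4, seed = 12,
                                          prephase = FALSE))
  ki <- kinship_and_inbreeding(ex0$pedigree)
  fish <- ex0$tables$fish
  expect_equal(fish$inbreeding,
               ki$inbreeding[match(fish$id, ki$id)], tolerance = 1e-12)
})

test_that("without heritability and selection no line trends in mean length", {
  cfg <- simulation_config(n_generations = 5, seed = 31)
  arch <- trait_architecture(h2_length = 0)
  rules <- list(Control = selection_rule("random"),
                Small = selection_rule("random"),
                Large = selection_rule("random"))
  ex <- run_experiment(cfg, arch, rules)
  fish <- ex$tables$fish[!is.na(ex$tables$fish$length_75), ]
  m <- aggregate(length_75 ~ line + generation, fish, mean)
  # per-line regression of generation-mean length on generation:
  # slope CI must cover 0 (no genetic response possible)
  for (line in c("Small", "Large")) {
    d <- m[m$line == line, ]
    fit <- summary(lm(length_75 ~ generation, d))$coefficients
    ci <- fit["generation", "Estimate"] +
      c(-1, 1) * qt(0.975, nrow(d) - 2) * fit["generation", "Std. Error"]
    expect_true(ci[1] <= 0 && ci[2] >= 0)
  }
})

test_that("selection response tracks the breeder's equation", {
  # R = h^2 * S, using the simulator's own realized differentials
  cfg <- simulation_config(n_generations = 7, seed = 91)
  arch <- trait_architecture(h2_length = 0.3)
  ex <- run_experiment(cfg, arch)
  fish <- ex$tables$fish[!is.na(ex$tables$fish$length_75), ]
  m <- aggregate(length_75 ~ line + generation, fish, mean)
  for (line in c("Large", "Small")) {
    d <- ex$differentials[ex$differentials$line == line, ]
    cum_S <- sum(d$delta_length[d$generation < max(m$generation)])
    response <- m$length_75[m$line == line & m$generation == max(m$generation)] -
      m$length_75[m$line == line & m$generation == 2]
    predicted <- arch$h2_length * cum_S
    # one realization of a 6-generation experiment: generous band
    expect_lt(abs(response - predicted), max(0.75, 0.6 * abs(predicted)))
    if (line == "Large") expect_gt(response, 0)
    if (line == "Small") expect_lt(response, 0)
  }
})

test_that("default maturation parameters give ~86% maturity at 75 dph", {
  ex <- run_experiment(simulation_config(n_generations = 3, seed = 55))
  fish <- ex$tables$fish
  frac <- mean(fish$mature_75[fish$alive_75 & fish$line == "Control"])
  expect_equal(frac, 0.86, tolerance = 0.05)
})
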
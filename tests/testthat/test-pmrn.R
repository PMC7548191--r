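test_that("maturation probability follows the increment formula", {
  expect_equal(as.numeric(maturation_probability(0.2, 0.2)), 0)
  expect_equal(as.numeric(maturation_probability(0.5, 0)), 0.5)
  expect_equal(as.numeric(maturation_probability(0.64, 0.4)), 0.4)
  expect_error(maturation_probability(1, 0.9999), "undefined")
  # non-monotone ogive: clipped to [0, 1] and counted
  m <- maturation_probability(c(0.3, 0.2), c(0.4, 0.1))
  expect_equal(as.numeric(m), c(0, 1 / 9))
  expect_equal(attr(m, "clipped"), 1L)
})

test_that("growth trajectories coincide for a noise-free cohort and order otherwise", {
  ages <- c(0, 15, 60, 75)
  ideal <- data.frame(age = rep(ages, each = 50),
                      length = rep(4.5 + 20 * (1 - exp(-0.02 * ages)),
                                   each = 50))
  tr <- growth_trajectories(ideal)
  grid <- seq(0, 87, by = 3)
  expect_equal(tr$q0.1$fn(grid), tr$q0.5$fn(grid), tolerance = 1e-6)
  expect_equal(tr$q0.5$fn(grid), tr$q0.9$fn(grid), tolerance = 1e-6)

  # noisy cohort: slow <= median <= fast everywhere
  set.seed(4)
  noisy <- data.frame(
    age = rep(ages, each = 300),
    length = rep(4.5 + 20 * (1 - exp(-0.02 * ages)), each = 300) +
      rnorm(1200, 0, rep(c(0.2, 0.4, 1.0, 1.3), each = 300)))
  trn <- growth_trajectories(noisy)
  expect_true(all(trn$q0.1$fn(grid) <= trn$q0.5$fn(grid) + 1e-9))
  expect_true(all(trn$q0.5$fn(grid) <= trn$q0.9$fn(grid) + 1e-9))

  # median trajectory tracks the observed per-age medians
  med <- tapply(noisy$length, noisy$age, median)
  expect_true(all(abs(trn$q0.5$fn(ages) - med) < 0.2))

  expect_error(growth_trajectories(ideal[ideal$age < 20, ]), "3 distinct")
})

test_that("a constant-hazard ogive crosses at ln(0.5)/ln(1 - m0) increments", {
  m0 <- 0.1
  h <- 87 / 200
  ogive <- function(age, length) 1 - (1 - m0)^(age / h)
  traj <- function(age) 5 + 0.2 * age
  pt <- pmrn_point(traj, ogive, n_increments = 200, age_range = c(0, 87))
  t_star <- log(0.5) / log(1 - m0)   # 6.5788 increments
  expect_false(pt$absent)
  expect_equal(pt$a50 / h, t_star, tolerance = 0.02)
  expect_equal(pt$s50, traj(pt$a50))
})

test_that("an ogive of zero never crosses and reports absence", {
  pt <- pmrn_point(function(age) 5 + 0.2 * age,
                   function(age, length) rep(0, length(age)))
  expect_true(pt$absent)
  expect_true(is.na(pt$a50))
})

test_that("crossings agree with a fine-grid brute-force evaluation", {
  ogive <- function(age, length) plogis(-14 + 0.45 * length + 0.05 * age)
  traj <- function(age) 4.5 + 20 * (1 - exp(-0.025 * age))
  coarse <- pmrn_point(traj, ogive, n_increments = 200)
  # brute force: cumulative product on 20,000 increments, no interpolation
  ages <- seq(0, 87, length.out = 20001)
  o <- pmin(ogive(ages, traj(ages)), 1 - 1e-9)
  m <- (o[-1] - o[-length(o)]) / (1 - o[-length(o)])
  m <- pmin(1, pmax(0, m))
  cum <- 1 - cumprod(1 - m)
  a50_fine <- ages[which(cum >= 0.5)[1] + 1]
  one_increment <- 87 / 200
  expect_lt(abs(coarse$a50 - a50_fine), one_increment)

  # resolution invariance: 200 vs 2,000 increments
  fine <- pmrn_point(traj, ogive, n_increments = 2000)
  expect_lt(abs(coarse$a50 - fine$a50), one_increment)
})

test_that("cumulative maturation is nondecreasing along any trajectory", {
  set.seed(12)
  for (r in 1:10) {
    b <- runif(1, 0.2, 0.6); c0 <- runif(1, -16, -10)
    ogive <- function(age, length) plogis(c0 + b * length + 0.03 * age)
    traj <- function(age) 4.5 + runif(1, 15, 22) * (1 - exp(-0.02 * age))
    ages <- seq(0, 87, length.out = 201)
    o <- pmin(ogive(ages, traj(ages)), 1 - 1e-9)
    m <- maturation_probability(o[-1], o[-length(o)])
    cum <- 1 - cumprod(1 - m)
    expect_true(all(diff(cum) >= -1e-12))
  }
})

test_that("with a length-only ogive all trajectories cross at the same length", {
  ogive <- function(age, length) plogis(-9 + 0.6 * length)
  trajs <- list(
    slow = function(age) 4 + 16 * (1 - exp(-0.018 * age)),
    med = function(age) 4.5 + 20 * (1 - exp(-0.022 * age)),
    fast = function(age) 5 + 24 * (1 - exp(-0.028 * age))
  )
  s50 <- vapply(trajs, function(tr) {
    pmrn_point(tr, ogive, n_increments = 2000)$s50
  }, numeric(1))
  expect_lt(max(s50) - min(s50), 0.05)
})

test_that("pmrn_curve propagates posterior uncertainty", {
  # structural spec from a tiny synthetic fit, draws fabricated directly
  sim <- sim_m2_data(n = 80, seed = 3)
  spec <- build_ogive_model(sim$tables)
  K <- length(spec$terms$coef)
  base <- c(2.35, 0.4, -1.2, 0.1, 0.55, 0.5, 0.6, 0.045, 0.05, 0.055)[seq_len(K)]
  names(base) <- sprintf("beta[%d]", seq_len(K))
  make_fit <- function(sd_scale, n = 200) {
    set.seed(99)
    d <- sapply(seq_len(K), function(k) rnorm(n, base[k], 0.05 * sd_scale))
    colnames(d) <- names(base)
    f <- fake_samples(list(d))
    f$spec <- spec
    f
  }
  trajs <- growth_trajectories(data.frame(
    age = rep(c(0, 15, 60, 75), each = 30),
    length = rep(c(4.5, 9.8, 18.9, 20.5), each = 30) + rnorm(120, 0, 0.4)))

  # single draw: bounds collapse onto the point estimate
  one <- make_fit(1)
  one$mcmc <- coda::mcmc.list(coda::mcmc(as_draws(one)[1, , drop = FALSE]))
  c1 <- pmrn_curve(one, trajs["q0.5"], line = "Control")
  expect_equal(c1$a50_lo, c1$a50)
  expect_equal(c1$a50_hi, c1$a50)

  # inflating the posterior sd widens the envelope
  narrow <- pmrn_curve(make_fit(1), trajs["q0.5"], line = "Control")
  wide <- pmrn_curve(make_fit(10), trajs["q0.5"], line = "Control")
  expect_gt(wide$a50_hi - wide$a50_lo, narrow$a50_hi - narrow$a50_lo)
})

test_that("an upward-shifted maturation threshold lifts the PMRN", {
  # Large line simulated with a lower ogive intercept (maturation requires
  # more length at equal age): its s50 must exceed the Control s50
  sim <- sim_m2_data(n = 80, seed = 3)
  spec <- build_ogive_model(sim$tables)
  K <- length(spec$terms$coef)
  stopifnot(K == 10)
  beta <- c(2.35, 0.1, -1.2, 0.1, 0.55, 0.55, 0.55, 0.05, 0.05, 0.05)
  names(beta) <- sprintf("beta[%d]", seq_len(K))
  i_large <- grep("lineLarge$", spec$terms$coef)
  expect_equal(beta[[i_large]], -1.2)
  d <- matrix(rep(beta, each = 50), nrow = 50,
              dimnames = list(NULL, names(beta)))
  d <- d + rnorm(length(d), 0, 0.02)
  f <- fake_samples(list(d))
  f$spec <- spec
  traj <- list(q0.5 = function(age) 4.5 + 20.6 * (1 - exp(-0.02 * age)))
  ctrl <- pmrn_curve(f, traj, line = "Control")
  lrg <- pmrn_curve(f, traj, line = "Large")
  expect_gt(lrg$s50, ctrl$s50)
  expect_gt(lrg$a50, ctrl$a50)
})
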
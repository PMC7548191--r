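# Direct model-scale simulators: each draws data straight from one trait
# model's likelihood with known ("true") parameter values, returning the
# table layout the corresponding builder expects plus the truth vector
# named by coefficient. Used for parameter-recovery checks.

LINES3 <- c("Control", "Small", "Large")

# common frame of line / generation / inbreeding covariates
.cov_frame <- function(n, n_gen = 5) {
  data.frame(
    line = sample(LINES3, n, replace = TRUE),
    generation = sample(seq_len(n_gen), n, replace = TRUE),
    inbreeding = pmax(0, rnorm(n, 0.06, 0.04)),
    mo_inb = pmax(0, rnorm(n, 0.06, 0.04)),
    fa_inb = pmax(0, rnorm(n, 0.06, 0.04)),
    stringsAsFactors = FALSE
  )
}

sim_m1_data <- function(n = 400, seed = 1,
                        truth = c(b0 = 20.5, lineSmall = -0.02,
                                  lineLarge = 1.2, sexM = 0.3, sexI = -1.5,
                                  b_age = 0.08, b_inb = 1.0,
                                  sigma = 1.0, sigmaG = 0.4)) {
  set.seed(seed)
  d <- .cov_frame(n)
  d$sex <- sample(c("F", "M", "I"), n, replace = TRUE, prob = c(.45, .45, .1))
  d$age_75 <- sample(68:84, n, replace = TRUE)
  aG <- rnorm(5, 0, truth[["sigmaG"]])
  mu <- truth[["b0"]] + aG[d$generation] +
    (d$line == "Small") * truth[["lineSmall"]] +
    (d$line == "Large") * truth[["lineLarge"]] +
    (d$sex == "M") * truth[["sexM"]] + (d$sex == "I") * truth[["sexI"]] +
    truth[["b_age"]] * (d$age_75 - mean(d$age_75)) +
    truth[["b_inb"]] * (d$inbreeding - mean(d$inbreeding))
  d$length_75 <- rnorm(n, mu, truth[["sigma"]])
  list(tables = list(fish = d), truth = truth)
}

sim_m2_data <- function(n = 600, seed = 1,
                        truth = c(b0 = 1.2, lineSmall = 0.3,
                                  lineLarge = -0.9,
                                  len_Control = 0.8, len_Small = 0.7,
                                  len_Large = 0.9,
                                  age_Control = 0.05, age_Small = 0.04,
                                  age_Large = 0.06,
                                  b_inb = -1.0, sigmaG = 0.4)) {
  set.seed(seed)
  d <- .cov_frame(n)
  d$age_75 <- sample(68:84, n, replace = TRUE)
  d$length_75 <- rnorm(n, 20.5, 1.5)
  aG <- rnorm(5, 0, truth[["sigmaG"]])
  len_c <- d$length_75 - mean(d$length_75)
  age_c <- d$age_75 - mean(d$age_75)
  len_slope <- truth[paste0("len_", d$line)]
  age_slope <- truth[paste0("age_", d$line)]
  eta <- truth[["b0"]] + aG[d$generation] +
    (d$line == "Small") * truth[["lineSmall"]] +
    (d$line == "Large") * truth[["lineLarge"]] +
    len_slope * len_c + age_slope * age_c +
    truth[["b_inb"]] * (d$inbreeding - mean(d$inbreeding))
  d$mature_75 <- rbinom(n, 1, plogis(eta))
  list(tables = list(fish = d), truth = truth)
}

sim_m3_data <- function(n = 150, seed = 1,
                        truth = c(b0 = 2.2, lineSmall = -0.3,
                                  lineLarge = 0.3, b_mo = -2, b_fa = -1,
                                  sigmaE = 0.5)) {
  set.seed(seed)
  d <- .cov_frame(n)
  d$stage <- "0-15"
  d$n_start <- sample(15:40, n, replace = TRUE)
  eta <- truth[["b0"]] +
    (d$line == "Small") * truth[["lineSmall"]] +
    (d$line == "Large") * truth[["lineLarge"]] +
    truth[["b_mo"]] * (d$mo_inb - mean(d$mo_inb)) +
    truth[["b_fa"]] * (d$fa_inb - mean(d$fa_inb)) +
    rnorm(n, 0, truth[["sigmaE"]])
  d$n_end <- rbinom(n, d$n_start, plogis(eta))
  list(tables = list(survival = d), truth = truth)
}

sim_m4_data <- function(n = 250, seed = 1,
                        truth = c(b0 = log(12), lineSmall = -0.2,
                                  lineLarge = 0.2, b_sdl = 0.05,
                                  b_sdl2 = -0.01,
                                  g0 = qlogis(0.3), gline = 0,
                                  sigmaE = 0.3, sigmaG = 0.3),
                        days = 4:5) {
  set.seed(seed)
  d <- .cov_frame(n)
  d$parent_sdl <- rnorm(n, 20, 1.2)
  d$days_collected <- sample(days, n, replace = TRUE)
  aG <- rnorm(5, 0, truth[["sigmaG"]])
  sdl_c <- d$parent_sdl - mean(d$parent_sdl)
  log_lam <- log(d$days_collected) + truth[["b0"]] + aG[d$generation] +
    (d$line == "Small") * truth[["lineSmall"]] +
    (d$line == "Large") * truth[["lineLarge"]] +
    truth[["b_sdl"]] * sdl_c + truth[["b_sdl2"]] * sdl_c^2 +
    rnorm(n, 0, truth[["sigmaE"]])
  pzero <- plogis(truth[["g0"]] + truth[["gline"]] *
                    (d$line != "Control"))
  z <- rbinom(n, 1, 1 - pzero)
  d$n_eggs <- rpois(n, z * exp(log_lam))
  list(tables = list(clutches = d), truth = truth)
}

sim_m5_data <- function(n = 400, seed = 1,
                        truth = c(b0 = 3.5, lineSmall = 0.08,
                                  lineLarge = 0.03, b_mosdl = 0.02,
                                  b_moinb = 0.3, b_fainb = -0.2,
                                  sigma = 0.15, sigmaG = 0.05)) {
  set.seed(seed)
  d <- .cov_frame(n)
  d$mother_sdl <- rnorm(n, 20, 1.2)
  aG <- rnorm(5, 0, truth[["sigmaG"]])
  mu <- truth[["b0"]] + aG[d$generation] +
    (d$line == "Small") * truth[["lineSmall"]] +
    (d$line == "Large") * truth[["lineLarge"]] +
    truth[["b_mosdl"]] * (d$mother_sdl - mean(d$mother_sdl)) +
    truth[["b_moinb"]] * (d$mo_inb - mean(d$mo_inb)) +
    truth[["b_fainb"]] * (d$fa_inb - mean(d$fa_inb))
  d$perimeter_mm <- rnorm(n, mu, truth[["sigma"]])
  list(tables = list(eggs = d), truth = truth)
}

sim_m6_data <- function(n = 300, seed = 1,
                        truth = c(b0 = 8, lineSmall = 0.18,
                                  lineLarge = 0.12, b_mosdl = -0.1,
                                  b_moinb = 1.0, b_fainb = 0.5,
                                  sigma = 1.0, sigmaG = 0.3)) {
  set.seed(seed)
  d <- .cov_frame(n)
  d$mother_sdl <- rnorm(n, 20, 1.2)
  aG <- rnorm(5, 0, truth[["sigmaG"]])
  mu <- truth[["b0"]] + aG[d$generation] +
    (d$line == "Small") * truth[["lineSmall"]] +
    (d$line == "Large") * truth[["lineLarge"]] +
    truth[["b_mosdl"]] * (d$mother_sdl - mean(d$mother_sdl)) +
    truth[["b_moinb"]] * (d$mo_inb - mean(d$mo_inb)) +
    truth[["b_fainb"]] * (d$fa_inb - mean(d$fa_inb))
  d$incubation_days <- rnorm(n, mu, truth[["sigma"]])
  list(tables = list(clutches = d), truth = truth)
}

sim_m7_data <- function(n = 400, seed = 1,
                        truth = c(b0 = 4.5, lineSmall = -0.07,
                                  lineLarge = -0.12, b_psdl = 0.02,
                                  b_inb = 0.5, sigma = 0.25,
                                  sigmaG = 0.08)) {
  set.seed(seed)
  d <- .cov_frame(n)
  d$parent_sdl <- rnorm(n, 20, 1.2)
  aG <- rnorm(5, 0, truth[["sigmaG"]])
  mu <- truth[["b0"]] + aG[d$generation] +
    (d$line == "Small") * truth[["lineSmall"]] +
    (d$line == "Large") * truth[["lineLarge"]] +
    truth[["b_psdl"]] * (d$parent_sdl - mean(d$parent_sdl)) +
    truth[["b_inb"]] * (d$inbreeding - mean(d$inbreeding))
  d$length_0 <- rnorm(n, mu, truth[["sigma"]])
  list(tables = list(fish = d), truth = truth)
}

sim_m8_data <- function(n = 180, seed = 1, resid_cor = 0.6,
                        truth = c(lhb_Small = 0.2, fshb_Small = 0.28,
                                  gh_Small = 0.44, lhb_Large = -0.26,
                                  fshb_Large = -0.3, gh_Large = 0.2,
                                  sexM = 0.3, b_inb = 0.5, b_sdl = 0.05,
                                  sd_res = 0.8, sigmaG = 0.2)) {
  set.seed(seed)
  d <- .cov_frame(n)
  d$id <- sprintf("hf%04d", seq_len(n))
  d$sex <- sample(c("F", "M"), n, replace = TRUE)
  d$length <- rnorm(n, 12, 1)
  S <- truth[["sd_res"]]^2 * (diag(3) * (1 - resid_cor) + resid_cor)
  arch <- trait_architecture(
    hormone_mean_by_line = list(
      Control = c(lhb = -1.5, fshb = -2.0, gh = 1.0),
      Small = c(lhb = -1.5 + truth[["lhb_Small"]],
                fshb = -2.0 + truth[["fshb_Small"]],
                gh = 1.0 + truth[["gh_Small"]]),
      Large = c(lhb = -1.5 + truth[["lhb_Large"]],
                fshb = -2.0 + truth[["fshb_Large"]],
                gh = 1.0 + truth[["gh_Large"]])),
    hormone_cov_by_line = list(Control = S, Small = S, Large = S),
    hormone_sex_shift = rep(truth[["sexM"]], 3),
    hormone_inb_slope = rep(truth[["b_inb"]], 3),
    hormone_length_slope = rep(truth[["b_sdl"]], 3),
    reference_length = 12)
  h <- simulate_hormones(arch, d)
  aG <- rnorm(5, 0, truth[["sigmaG"]])
  for (cl in c("ln_ratio_lhb", "ln_ratio_fshb", "ln_ratio_gh")) {
    h[[cl]] <- h[[cl]] + aG[d$generation]
  }
  h$generation <- d$generation
  list(tables = list(hormones = h), truth = truth, resid_cor = resid_cor)
}

# fit one model spec quickly with test-appropriate chain lengths
quick_fit <- function(spec, seed = 1, n_adapt = 400, n_iter = 1200,
                      ...) {
  fit_model(spec, seed = seed, n_adapt = n_adapt, n_iter = n_iter,
            on_nonconvergence = "none", ...)
}
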
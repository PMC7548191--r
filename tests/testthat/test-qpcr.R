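# 7-point calibrator series (10-fold dilutions), noiseless by default
make_calibrator <- function(intercept = 22, slope = -1 / log10(2),
                            volumes = 10^seq(-3, 3)) {
  data.frame(volume = volumes, cq = intercept + slope * log10(volumes))
}

make_curves <- function() {
  list(lhb = fit_standard_curve(make_calibrator(24)),
       fshb = fit_standard_curve(make_calibrator(26)),
       gh = fit_standard_curve(make_calibrator(20)),
       actb = fit_standard_curve(make_calibrator(18)))
}

test_that("a perfect-doubling calibrator gives slope -3.3219 and E = 1", {
  curve <- fit_standard_curve(make_calibrator())
  expect_equal(curve$slope, -1 / log10(2), tolerance = 1e-10)
  expect_equal(curve$slope, -3.3219, tolerance = 1e-4)
  expect_equal(curve$efficiency, 1, tolerance = 1e-10)
  expect_equal(curve$n_points, 7)
  expect_equal(curve$r_squared, 1)
})

test_that("quantification round-trips every calibrator point exactly", {
  cal <- make_calibrator(intercept = 25, slope = -3.1)
  curve <- fit_standard_curve(cal)
  expect_equal(quantify(curve, cal$cq), cal$volume, tolerance = 1e-12)
})

test_that("degenerate calibrators are rejected", {
  expect_error(fit_standard_curve(data.frame(volume = c(1, 10),
                                             cq = c(20, 17))),
               "3 distinct")
  expect_error(fit_standard_curve(data.frame(volume = c(-1, 1, 10),
                                             cq = c(23, 20, 17))),
               "positive")
  expect_error(fit_standard_curve(data.frame(volume = c(1, 10, 100),
                                             cq = c(17, 20, 23))),
               "slope")
})

test_that("ln ratios follow expression ratios", {
  curves <- make_curves()
  # gene at exactly the actin expression: ratio 1, ln ratio 0
  s1 <- data.frame(fish_id = "f1",
                   cq_lhb = curves$lhb$intercept,
                   cq_fshb = curves$fshb$intercept,
                   cq_gh = curves$gh$intercept,
                   cq_actb = curves$actb$intercept)
  r1 <- relative_expression(s1, curves)
  expect_equal(r1$ln_ratio_lhb, 0, tolerance = 1e-12)
  expect_equal(r1$ln_ratio_gh, 0, tolerance = 1e-12)

  # gene expression exactly twice actin: ln ratio = ln 2
  s2 <- s1
  s2$cq_gh <- curves$gh$intercept + curves$gh$slope * log10(2)
  r2 <- relative_expression(s2, curves)
  expect_equal(r2$ln_ratio_gh, log(2), tolerance = 1e-12)

  # scaling both expressions by a constant leaves the ratio unchanged
  s3 <- s1
  for (cl in c("cq_lhb", "cq_fshb", "cq_gh", "cq_actb")) {
    s3[[cl]] <- s3[[cl]] + curves$lhb$slope * log10(37)
  }
  # identical slopes across curves in this fixture, so a common Cq shift
  # is a common expression scaling
  r3 <- relative_expression(s3, curves)
  expect_equal(r3$ln_ratio_lhb, r1$ln_ratio_lhb, tolerance = 1e-10)
})

test_that("simulated hormone profiles round-trip through Cq exactly", {
  curves <- make_curves()
  fish <- data.frame(id = sprintf("f%02d", 1:40),
                     line = sample(c("Control", "Small", "Large"), 40,
                                   replace = TRUE),
                     sex = "F", length = rnorm(40, 12), inbreeding = 0.05)
  h <- simulate_hormones(trait_architecture(), fish, seed = 10)
  cq <- hormones_to_cq(h, curves, cq_noise_sd = 0, seed = 11)
  back <- relative_expression(cq, curves)
  expect_equal(back$ln_ratio_lhb, h$ln_ratio_lhb, tolerance = 1e-9)
  expect_equal(back$ln_ratio_fshb, h$ln_ratio_fshb, tolerance = 1e-9)
  expect_equal(back$ln_ratio_gh, h$ln_ratio_gh, tolerance = 1e-9)
})

test_that("duplicates are averaged on the Cq scale", {
  curves <- make_curves()
  s <- data.frame(fish_id = c("f1", "f1"),
                  cq_lhb = c(24, 26), cq_fshb = c(26, 26),
                  cq_gh = c(20, 20), cq_actb = c(18, 18))
  r <- relative_expression(s, curves)
  expect_equal(nrow(r), 1)
  # mean Cq 25 corresponds to lhb expression at Cq 25, not mean expression
  expected <- log(quantify(curves$lhb, 25) / quantify(curves$actb, 18))
  expect_equal(r$ln_ratio_lhb, expected, tolerance = 1e-12)
})

test_that("inter-run shifts are removed by the run calibrator", {
  curves <- make_curves()
  base <- data.frame(fish_id = "f1", run_id = "run1",
                     cq_lhb = 25, cq_fshb = 27, cq_gh = 21, cq_actb = 19)
  shifted <- base
  shifted$run_id <- "run2"
  shift <- 0.8   # run-wide technical offset
  for (cl in c("cq_lhb", "cq_fshb", "cq_gh", "cq_actb")) {
    shifted[[cl]] <- shifted[[cl]] + shift
  }
  rc <- rbind(
    data.frame(run_id = "run1", gene = c("lhb", "fshb", "gh", "actb"),
               cq = c(24, 26, 20, 18), blank_cq = 40),
    data.frame(run_id = "run2", gene = c("lhb", "fshb", "gh", "actb"),
               cq = c(24, 26, 20, 18) + shift, blank_cq = 40)
  )
  r1 <- relative_expression(base, curves, run_calibrator = rc)
  r2 <- relative_expression(shifted, curves, run_calibrator = rc)
  expect_equal(r2$ln_ratio_lhb, r1$ln_ratio_lhb, tolerance = 1e-10)
  expect_equal(r2$ln_ratio_gh, r1$ln_ratio_gh, tolerance = 1e-10)
})

test_that("missing actin and contaminated blanks are reported", {
  curves <- make_curves()
  s <- data.frame(fish_id = "f1", cq_lhb = 25, cq_fshb = 27, cq_gh = 21,
                  cq_actb = NA)
  expect_error(relative_expression(s, curves), "unusable")

  s2 <- data.frame(fish_id = "f1", run_id = "run1", cq_lhb = 25,
                   cq_fshb = 27, cq_gh = 21, cq_actb = 19)
  rc <- data.frame(run_id = "run1", gene = c("lhb", "fshb", "gh", "actb"),
                   cq = c(24, 26, 20, 18), blank_cq = 28)
  expect_warning(relative_expression(s2, curves, run_calibrator = rc),
                 "blank")
})
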
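#' Maturation probability of one growth increment
#'
#' Converts consecutive maturity-ogive predictions into the conditional
#' probability of *maturing* during the increment:
#' `m = (o_curr - o_prev) / (1 - o_prev)`. When the ogive is non-monotone
#' along a trajectory the raw value can leave `[0, 1]`; it is clipped, and
#' the number of clipped increments is reported via the `"clipped"`
#' attribute.
#'
#' @param o_curr maturity probability at the end of the increment.
#' @param o_prev maturity probability at the start (must be < 1; values
#'   within 1e-3 of 1 are rejected as numerically unusable).
#' @return maturation probability in `[0, 1]` (vectorized), with attribute
#'   `clipped` counting clipped entries.
#' @export
maturation_probability <- function(o_curr, o_prev) {
  if (any(o_prev >= 1 - 1e-3)) {
    stop("ogive at increment start is (numerically) 1; ",
         "maturation probability undefined")
  }
  m <- (o_curr - o_prev) / (1 - o_prev)
  clipped <- sum(m < 0 | m > 1)
  m <- pmin(1, pmax(0, m))
  attr(m, "clipped") <- clipped
  m
}

#' Fit slow, median and fast growth trajectories
#'
#' Computes per-age length quantiles from a length-at-age table and fits a
#' saturating (von Bertalanffy) curve through each quantile, yielding
#' smooth trajectories usable over the full PMRN age range.
#'
#' @param length_at_age data frame with columns `age` (dph) and `length`
#'   (mm); at least 3 distinct ages are required.
#' @param quantiles growth quantiles to track (default slow/median/fast =
#'   0.1, 0.5, 0.9).
#' @param age_range ages over which the trajectories must extrapolate.
#' @return named list of `growth_trajectory` objects, each with `fn(age)`,
#'   `params` and `quantile`.
#' @export
growth_trajectories <- function(length_at_age,
                                quantiles = c(0.1, 0.5, 0.9),
                                age_range = c(0, 87)) {
  d <- as.data.frame(length_at_age)
  stopifnot(all(c("age", "length") %in% names(d)))
  d <- d[!is.na(d$length), ]
  ages <- sort(unique(d$age))
  if (length(ages) < 3) {
    stop("need lengths observed at >= 3 distinct ages, got ", length(ages))
  }
  out <- lapply(quantiles, function(q) {
    pts <- data.frame(
      age = ages,
      length = vapply(ages, function(a) {
        stats::quantile(d$length[d$age == a], q, names = FALSE)
      }, numeric(1))
    )
    fit <- minpack.lm::nlsLM(
      length ~ l0 + (linf - l0) * (1 - exp(-k * age)),
      data = pts,
      start = list(l0 = min(pts$length), linf = max(pts$length) * 1.2,
                   k = 0.02),
      lower = c(l0 = 0, linf = 0, k = 1e-4),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    p <- as.list(stats::coef(fit))
    structure(
      list(fn = function(age) {
        p$l0 + (p$linf - p$l0) * (1 - exp(-p$k * age))
      },
      params = unlist(p), quantile = q, age_range = age_range),
      class = "growth_trajectory")
  })
  names(out) <- paste0("q", quantiles)
  out
}

# evaluate a trajectory (object, function, or data frame) at given ages
.traj_length <- function(traj, age) {
  if (inherits(traj, "growth_trajectory")) return(traj$fn(age))
  if (is.function(traj)) return(traj(age))
  stats::approx(traj$age, traj$length, xout = age, rule = 2)$y
}

#' Age and length at 50% cumulative maturation along one trajectory
#'
#' Evaluates a maturity ogive at `n_increments` equal age steps along a
#' growth trajectory, forms per-increment maturation probabilities,
#' accumulates `1 - prod(1 - m)`, and returns the first crossing of 0.5
#' with linear interpolation between the bracketing increments. A
#' trajectory that never crosses yields `absent = TRUE` (not an error).
#'
#' @param traj a `growth_trajectory` (or any function age -> length, or a
#'   data frame with `age`/`length` columns).
#' @param ogive function `(age, length) -> maturity probability`.
#' @param n_increments number of growth increments (default 200).
#' @param age_range ages spanned by the increments (default 0 to 87 dph).
#' @return list with `a50`, `s50`, `absent`, `clipped_fraction`.
#' @export
pmrn_point <- function(traj, ogive, n_increments = 200,
                       age_range = c(0, 87)) {
  ages <- seq(age_range[1], age_range[2], length.out = n_increments + 1)
  lens <- .traj_length(traj, ages)
  o <- ogive(ages, lens)
  # cap just below the undefined-ogive guard: once the ogive saturates the
  # cumulative curve is long past 0.5, so the crossing is unaffected
  o <- pmin(pmax(o, 0), 1 - 2e-3)
  m <- maturation_probability(o[-1], o[-length(o)])
  cum <- 1 - cumprod(1 - m)
  hit <- which(cum >= 0.5)
  if (length(hit) == 0) {
    return(list(a50 = NA_real_, s50 = NA_real_, absent = TRUE,
                clipped_fraction = attr(m, "clipped") / length(m)))
  }
  t2 <- hit[1]                      # increment index whose end crosses 0.5
  c2 <- cum[t2]
  c1 <- if (t2 == 1) 0 else cum[t2 - 1]
  a1 <- ages[t2]; a2 <- ages[t2 + 1]
  frac <- if (c2 > c1) (0.5 - c1) / (c2 - c1) else 0
  a50 <- a1 + frac * (a2 - a1)
  list(a50 = a50, s50 = .traj_length(traj, a50), absent = FALSE,
       clipped_fraction = attr(m, "clipped") / length(m))
}

# ogive closure for one posterior draw of the maturity model, evaluated at
# the generation-typical level (random intercept 0) and mean inbreeding
.ogive_fun <- function(spec, draw, line) {
  coefs <- spec$terms$coef
  centers <- spec$terms$centers
  beta <- draw[sprintf("beta[%d]", seq_along(coefs))]
  names(beta) <- coefs
  function(age, length) {
    eta <- 0
    for (nm in coefs) {
      parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
      val <- 1
      for (p in parts) {
        val <- val * switch(
          p,
          "(Intercept)" = 1,
          "length_75_c" = length - centers[["length_75"]],
          "age_75_c" = age - centers[["age_75"]],
          "inbreeding_c" = 0,
          # factor dummy, e.g. "lineLarge"
          as.numeric(paste0("line", line) == p))
      }
      eta <- eta + beta[[nm]] * val
    }
    stats::plogis(eta)
  }
}

#' PMRN curve with credible envelope from a fitted maturity model
#'
#' Propagates the full posterior of the maturity ogive: for every retained
#' MCMC draw and every growth trajectory, computes the 50% crossing point,
#' then summarizes crossings as the posterior median with a 95% credible
#' envelope. Draws whose crossing is absent are counted; a trajectory with
#' more than 50% absent crossings is flagged unreliable.
#'
#' @param samples fitted `posterior_samples` of the maturity ogive model.
#' @param trajectories list of growth trajectories (see
#'   [growth_trajectories()]).
#' @param line line label for which the ogive is evaluated.
#' @param n_increments,age_range passed to [pmrn_point()].
#' @param n_draws maximum posterior draws to propagate (default 400,
#'   evenly spaced through the pooled sample).
#' @return data frame with one row per trajectory: point estimates
#'   (`a50`, `s50`), credible bounds, the proportion of absent crossings
#'   and a reliability flag.
#' @export
pmrn_curve <- function(samples, trajectories, line, n_increments = 200,
                       age_range = c(0, 87), n_draws = 400) {
  spec <- samples$spec
  if (is.null(spec$terms$model_id) || spec$terms$model_id != 2) {
    stop("pmrn_curve requires a fitted maturity ogive model")
  }
  draws <- as_draws(samples)
  idx <- unique(round(seq(1, nrow(draws),
                          length.out = min(n_draws, nrow(draws)))))
  rows <- lapply(seq_along(trajectories), function(ti) {
    traj <- trajectories[[ti]]
    a <- s <- rep(NA_real_, length(idx))
    for (i in seq_along(idx)) {
      og <- .ogive_fun(spec, draws[idx[i], ], line)
      pt <- pmrn_point(traj, og, n_increments, age_range)
      if (!pt$absent) {
        a[i] <- pt$a50
        s[i] <- pt$s50
      }
    }
    absent <- mean(is.na(a))
    data.frame(
      trajectory = names(trajectories)[ti],
      line = line,
      a50 = stats::median(a, na.rm = TRUE),
      a50_lo = stats::quantile(a, 0.025, na.rm = TRUE, names = FALSE),
      a50_hi = stats::quantile(a, 0.975, na.rm = TRUE, names = FALSE),
      s50 = stats::median(s, na.rm = TRUE),
      s50_lo = stats::quantile(s, 0.025, na.rm = TRUE, names = FALSE),
      s50_hi = stats::quantile(s, 0.975, na.rm = TRUE, names = FALSE),
      prop_absent = absent,
      unreliable = absent > 0.5,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Long length-at-age table from a fish table
#'
#' Reshapes the wide per-fish length columns (`length_0`, `length_15`,
#' `length_60`, `length_75`) into the long `age`/`length` format used by
#' [growth_trajectories()]; the 75 dph measurement uses the realized
#' phenotyping age of each fish.
#'
#' @param fish fish table of a `medaka_experiment`.
#' @return data frame with columns `age`, `length`.
#' @export
length_at_age_table <- function(fish) {
  ages <- c(0, 15, 60)
  out <- do.call(rbind, lapply(ages, function(a) {
    data.frame(age = a, length = fish[[paste0("length_", a)]])
  }))
  out <- rbind(out, data.frame(age = fish$age_75, length = fish$length_75))
  out[!is.na(out$length), ]
}
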
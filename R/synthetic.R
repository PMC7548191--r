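#' Von Bertalanffy mean standard length at age
#'
#' @param arch a [trait_architecture()].
#' @param age age in days posthatch.
#' @return mean standard length (mm): `hatch + L_inf * (1 - exp(-k * age))`.
#' @export
vb_mean_length <- function(arch, age) {
  arch$hatch_length_mean +
    arch$L_inf_mean * (1 - exp(-arch$growth_rate_k * age))
}

#' Simulate standard length at a given age
#'
#' Draws a standard length from the von Bertalanffy mean curve shifted by a
#' breeding value, with Gaussian environmental noise. With `env_sd = 0` and
#' `breeding_value = 0` the hatch length is returned exactly at age 0 and
#' the length approaches `hatch + L_inf` as age grows.
#'
#' @param arch a [trait_architecture()].
#' @param breeding_value additive-genetic shift (mm).
#' @param age age in days posthatch (vectorized).
#' @param env_sd environmental standard deviation (mm).
#' @param seed optional integer seed.
#' @return numeric vector of standard lengths (mm).
#' @export
simulate_growth <- function(arch, breeding_value = 0, age, env_sd = NULL,
                            seed = NULL) {
  if (any(age < 0)) stop("age must be non-negative")
  if (is.null(env_sd)) env_sd <- arch$sigma_e
  if (!is.null(seed)) set.seed(seed)
  vb_mean_length(arch, age) + breeding_value +
    stats::rnorm(length(age), 0, env_sd)
}

#' Simulate one clutch record for a breeding pair
#'
#' With probability `fecundity_zero_prob` the pair is infertile and all
#' counts are zero. Otherwise daily egg counts are Poisson around a family
#' rate with log-normal overdispersion and a log-linear mother-length
#' effect; egg perimeters are Gaussian with a mother-length slope;
#' incubation time is Gaussian; hatched larvae are Binomial with the
#' egg-stage survival probability.
#'
#' @param arch a [trait_architecture()].
#' @param mother_length mother standard length (mm).
#' @param days number of egg-collection days (>= 1).
#' @param seed optional integer seed.
#' @param line line label used for optional generative line shifts.
#' @return list with `infertile`, `days`, `eggs_per_day`, `n_eggs`,
#'   `perimeters`, `mean_perimeter`, `incubation_days`, `n_hatched`.
#' @export
simulate_reproduction <- function(arch, mother_length, days, seed = NULL,
                                  line = "Control") {
  stopifnot(days >= 1)
  if (!is.null(seed)) set.seed(seed)
  out <- list(infertile = FALSE, days = days,
              eggs_per_day = rep(0L, days), n_eggs = 0L,
              perimeters = numeric(0), mean_perimeter = NA_real_,
              incubation_days = NA_real_, n_hatched = 0L)
  if (stats::runif(1) < arch$fecundity_zero_prob) {
    out$infertile <- TRUE
    return(out)
  }
  log_rate <- log(arch$fecundity_daily_rate) +
    arch$fecundity_length_slope * (mother_length - arch$reference_length) +
    .line_shift(arch, line, "fecundity_log_rate") +
    stats::rnorm(1, 0, arch$fecundity_overdispersion_sd)
  out$eggs_per_day <- stats::rpois(days, exp(log_rate))
  out$n_eggs <- sum(out$eggs_per_day)
  if (out$n_eggs > 0) {
    pm_mean <- arch$egg_perimeter_mean +
      arch$egg_perimeter_slope * (mother_length - arch$reference_length) +
      .line_shift(arch, line, "egg_perimeter")
    out$perimeters <- stats::rnorm(out$n_eggs, pm_mean, arch$egg_perimeter_sd)
    out$mean_perimeter <- mean(out$perimeters)
    out$incubation_days <- stats::rnorm(1, arch$incubation_mean +
                                          .line_shift(arch, line, "incubation"),
                                        arch$incubation_sd)
    out$n_hatched <- stats::rbinom(1, out$n_eggs,
                                   stats::plogis(arch$survival_logits["egg_0"]))
  }
  out
}

#' Simulate pituitary ln hormone/actin ratios for a set of fish
#'
#' Draws, per fish, a trivariate (LHb, FSHb, GH) ln gene/actin ratio vector
#' from the line-specific multivariate normal, with the mean shifted by sex,
#' inbreeding, and standard length.
#'
#' @param arch a [trait_architecture()].
#' @param fish data frame with columns `id`, `line`, `sex`, `length`,
#'   `inbreeding`.
#' @param seed optional integer seed.
#' @return data frame with columns `fish_id`, `line`, `sex`, `length`,
#'   `inbreeding`, `ln_ratio_lhb`, `ln_ratio_fshb`, `ln_ratio_gh`.
#' @export
simulate_hormones <- function(arch, fish, seed = NULL) {
  fish <- as.data.frame(fish)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(fish)
  y <- matrix(NA_real_, n, 3)
  for (line in unique(fish$line)) {
    sel <- which(fish$line == line)
    mu_line <- arch$hormone_mean_by_line[[line]]
    if (is.null(mu_line)) stop("no hormone means configured for line ", line)
    S <- arch$hormone_cov_by_line[[line]]
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev <= 0)) stop("hormone covariance for line ", line,
                           " is not positive definite")
    R <- chol(S)
    mu <- matrix(mu_line, length(sel), 3, byrow = TRUE)
    mu <- mu + outer(as.numeric(fish$sex[sel] == "M"), arch$hormone_sex_shift)
    mu <- mu + outer(fish$inbreeding[sel], arch$hormone_inb_slope)
    mu <- mu + outer(fish$length[sel] - arch$reference_length,
                     arch$hormone_length_slope)
    z <- matrix(stats::rnorm(length(sel) * 3), length(sel), 3)
    y[sel, ] <- mu + z %*% R
  }
  data.frame(fish_id = fish$id, line = fish$line, sex = fish$sex,
             length = fish$length, inbreeding = fish$inbreeding,
             ln_ratio_lhb = y[, 1], ln_ratio_fshb = y[, 2],
             ln_ratio_gh = y[, 3], stringsAsFactors = FALSE)
}

# Relatedness among selection-line founders induced by the shared
# pre-selection laboratory phase: a base of unrelated adults, two
# random-mating pair generations, then founders drawn from the final pool.
# Returns the kinship-source relationship matrix among all founders
# (one block of 2 * n_pairs_per_line per line), with the diagonal reset to
# 1 so that founders themselves are treated as non-inbred.
.prephase_founder_relationship <- function(config) {
  n_base <- config$n_base_adults
  rows <- list()
  # wild-caught founding stock, assumed unrelated
  wild_ids <- sprintf("wild_%03d", seq_len(config$n_wild_founders))
  rows[[length(rows) + 1]] <- data.frame(
    id = wild_ids, sire_id = NA_character_, dam_id = NA_character_,
    sex = rep(c("M", "F"), length.out = config$n_wild_founders),
    line = "base", generation = -4L, stringsAsFactors = FALSE)
  # pond generations: mass spawning modelled as random parentage
  prev_m <- wild_ids[seq(1, length(wild_ids), 2)]
  prev_f <- wild_ids[seq(2, length(wild_ids), 2)]
  for (pg in seq_len(config$n_pond_generations)) {
    ids <- sprintf("pond%d_%03d", pg, seq_len(config$pond_cohort_size))
    rows[[length(rows) + 1]] <- data.frame(
      id = ids,
      sire_id = sample(prev_m, length(ids), replace = TRUE),
      dam_id = sample(prev_f, length(ids), replace = TRUE),
      sex = rep(c("M", "F"), length.out = length(ids)),
      line = "base", generation = -4L + pg, stringsAsFactors = FALSE)
    prev_m <- ids[seq(1, length(ids), 2)]
    prev_f <- ids[seq(2, length(ids), 2)]
  }
  # adults transferred to the laboratory
  base_ids <- sprintf("base_%03d", seq_len(n_base))
  rows[[length(rows) + 1]] <- data.frame(
    id = base_ids,
    sire_id = sample(prev_m, n_base, replace = TRUE),
    dam_id = sample(prev_f, n_base, replace = TRUE),
    sex = rep(c("M", "F"), length.out = n_base),
    line = "base", generation = -2L, stringsAsFactors = FALSE)
  males <- base_ids[seq(1, n_base, 2)]
  females <- base_ids[seq(2, n_base, 2)]
  # generation -1: group mating in the base, enough fish for n_pairs_pre[1]
  # pairs; each fish gets random base parents
  n_m1 <- 2 * config$n_pairs_pre[1]
  ids_m1 <- sprintf("pre1_%03d", seq_len(n_m1))
  rows[[length(rows) + 1]] <- data.frame(
    id = ids_m1,
    sire_id = sample(males, n_m1, replace = TRUE),
    dam_id = sample(females, n_m1, replace = TRUE),
    sex = rep(c("M", "F"), length.out = n_m1),
    line = "base", generation = -1L,
    stringsAsFactors = FALSE)
  # generation 0: offspring of the n_pairs_pre[1] pairs (pair i is fish
  # 2i-1 x 2i), assigned to families at random
  n_0 <- 2 * config$n_pairs_pre[2]
  fam1 <- sample(config$n_pairs_pre[1], n_0, replace = TRUE)
  ids_0 <- sprintf("pre2_%03d", seq_len(n_0))
  rows[[length(rows) + 1]] <- data.frame(id = ids_0,
                          sire_id = ids_m1[2 * fam1 - 1],
                          dam_id = ids_m1[2 * fam1],
                          sex = rep(c("M", "F"), length.out = n_0),
                          line = "base", generation = 0L,
                          stringsAsFactors = FALSE)
  # founders: drawn from the generation-0 families, shared pool across lines
  n_founders <- 6 * config$n_pairs_per_line
  fam0 <- sample(config$n_pairs_pre[2], n_founders, replace = TRUE)
  f_ids <- sprintf("f1pool_%03d", seq_len(n_founders))
  rows[[length(rows) + 1]] <- data.frame(id = f_ids,
                          sire_id = ids_0[2 * fam0 - 1],
                          dam_id = ids_0[2 * fam0],
                          sex = rep(c("M", "F"), length.out = n_founders),
                          line = "base", generation = 1L,
                          stringsAsFactors = FALSE)
  ped <- pedigree(do.call(rbind, rows))
  A <- additive_relationship(ped)[f_ids, f_ids]
  diag(A) <- 1   # founders assumed non-inbred
  list(A = A, family = fam0)
}

# Daily maturation hazard on the logit scale, given ages and lengths.
.maturation_hazard <- function(arch, age, length, line = "Control") {
  stats::plogis(arch$maturation_intercept +
                  .line_shift(arch, line, "maturation_intercept") +
                  arch$maturation_age_slope * age +
                  arch$maturation_length_slope * length)
}

# Simulate, for n fish with given growth parameters, the day of maturation
# (NA if not matured by max_age). Lengths follow the individual curves.
.simulate_maturation_day <- function(arch, hatch_len, span_dev, max_age,
                                     line = "Control") {
  n <- length(hatch_len)
  g <- 1 - exp(-arch$growth_rate_k * seq_len(max_age))
  g75 <- 1 - exp(-arch$growth_rate_k * 75)
  day_mat <- rep(NA_integer_, n)
  alive <- seq_len(n)
  # length of fish i at day d: hatch_i + (L_inf + shift) * g[d] + dev_i * g[d]/g75
  span <- arch$L_inf_mean + .line_shift(arch, line, "growth_span")
  for (d in seq_len(max_age)) {
    if (length(alive) == 0) break
    len_d <- hatch_len[alive] + span * g[d] + span_dev[alive] * g[d] / g75
    m <- .maturation_hazard(arch, d, len_d, line)
    hit <- stats::runif(length(alive)) < m
    day_mat[alive[hit]] <- d
    alive <- alive[!hit]
  }
  day_mat
}

#' Run a full synthetic bidirectional size-selection experiment
#'
#' Iterates, for each line and generation: breeding-pair reproduction,
#' family aquaria stocking, density thinning at 15 dph, stage-wise survival,
#' growth and maturation, family-stage selection at 60 dph, individual-stage
#' selection of mature breeders at 75 dph, and sib-mating-aware pairing that
#' minimizes the median offspring inbreeding coefficient. Emits the complete
#' measurement tables, the realized pedigree, per-episode selection
#' differentials and the mean-inbreeding trajectory. Fully reproducible
#' given `config$seed`.
#'
#' @param config a [simulation_config()].
#' @param arch a [trait_architecture()].
#' @param rules named list of [selection_rule()]s, one per line; defaults to
#'   the classic Control/Small/Large design.
#' @return object of class `medaka_experiment`: a list with `tables`
#'   (`fish`, `clutches`, `eggs`, `survival`, `hormones`), `pedigree`,
#'   `differentials`, `mean_inbreeding`, `shortfalls`, `config`, `arch`.
#' @export
run_experiment <- function(config = simulation_config(),
                           arch = trait_architecture(),
                           rules = list(
                             Control = selection_rule("random"),
                             Small = selection_rule("smallest"),
                             Large = selection_rule("largest")
                           )) {
  set.seed(config$seed)
  lines <- names(rules)
  g75 <- 1 - exp(-arch$growth_rate_k * 75)
  prephase <- if (config$prephase) .prephase_founder_relationship(config)
              else NULL

  fish_rows <- list(); clutch_rows <- list(); egg_rows <- list()
  surv_rows <- list(); horm_rows <- list(); ped_rows <- list()
  diff_rows <- list(); meanF_rows <- list(); shortfalls <- list()

  for (li in seq_along(lines)) {
    line <- lines[li]
    rule <- rules[[line]]
    lid <- substr(line, 1, 1)
    # founder breeders (F1): non-inbred; related through the pre-selection
    # phase when config$prephase is on
    n_f1 <- 2 * config$n_pairs_per_line
    f1_ids <- sprintf("%s1_%03d", lid, seq_len(n_f1))
    f1_sex <- rep(c("M", "F"), config$n_pairs_per_line)
    f1_bv <- stats::rnorm(n_f1, 0, arch$sigma_a)
    f1_len75 <- vb_mean_length(arch, 75) + f1_bv +
      stats::rnorm(n_f1, 0, arch$sigma_e)
    # breeder bookkeeping: additive relationship among breeders only
    if (is.null(prephase)) {
      A <- diag(n_f1)
      f1_family <- NULL
    } else {
      block <- ((li - 1) * n_f1 + 1):(li * n_f1)
      A <- prephase$A[block, block]
      f1_family <- prephase$family[block]
    }
    dimnames(A) <- list(f1_ids, f1_ids)
    br_sire <- stats::setNames(rep(NA_character_, n_f1), f1_ids)
    br_dam <- br_sire
    br_gen <- stats::setNames(rep(1L, n_f1), f1_ids)
    br_F <- stats::setNames(rep(0, n_f1), f1_ids)
    br_len <- stats::setNames(f1_len75, f1_ids)
    br_bv <- stats::setNames(f1_bv, f1_ids)
    if (is.null(prephase)) {
      pairs <- data.frame(male = f1_ids[f1_sex == "M"],
                          female = f1_ids[f1_sex == "F"],
                          stringsAsFactors = FALSE)
    } else {
      # founders carry pre-phase relatedness: pair them like later
      # generations (no full-sib matings, minimal median offspring
      # inbreeding); pseudo-parent rows expose the founders' families
      fams <- sort(unique(f1_family))
      pseudo <- data.frame(
        id = c(sprintf("pp%d_s", fams), sprintf("pp%d_d", fams)),
        sire_id = NA_character_, dam_id = NA_character_,
        sex = rep(c("M", "F"), each = length(fams)),
        line = line, generation = 0L, stringsAsFactors = FALSE)
      f1_ped <- pedigree(rbind(pseudo, data.frame(
        id = f1_ids,
        sire_id = sprintf("pp%d_s", f1_family),
        dam_id = sprintf("pp%d_d", f1_family),
        sex = f1_sex, line = line, generation = 1L,
        stringsAsFactors = FALSE)))
      plan <- propose_pairs(data.frame(id = f1_ids, sex = f1_sex),
                            f1_ped, n_pairs = config$n_pairs_per_line,
                            n_resamples = config$pairing_resamples, A = A)
      pairs <- plan$pairs[, c("male", "female")]
    }
    for (i in seq_len(n_f1)) {
      ped_rows[[length(ped_rows) + 1]] <- data.frame(
        id = f1_ids[i], sire_id = NA_character_, dam_id = NA_character_,
        sex = f1_sex[i], line = line, generation = 1L,
        stringsAsFactors = FALSE)
    }
    meanF_rows[[length(meanF_rows) + 1]] <- data.frame(
      line = line, generation = 1L, mean_inbreeding = 0,
      n = n_f1, stringsAsFactors = FALSE)

    for (gen in 2:config$n_generations) {
      # --- reproduction: one clutch per pair
      fam <- list()
      for (p in seq_len(nrow(pairs))) {
        m_id <- pairs$male[p]; f_id <- pairs$female[p]
        pair_id <- sprintf("%s%d_P%02d", lid, gen, p)
        days <- sample(config$egg_collection_days, 1)
        cl <- simulate_reproduction(arch, mother_length = br_len[f_id],
                                    days = days, line = line)
        parent_sdl <- (br_len[m_id] + br_len[f_id]) / 2
        off_F <- 0.5 * A[m_id, f_id]
        clutch_rows[[length(clutch_rows) + 1]] <- data.frame(
          pair_id = pair_id, line = line, generation = gen,
          sire_id = m_id, dam_id = f_id,
          mother_sdl = unname(br_len[f_id]), parent_sdl = unname(parent_sdl),
          mo_inb = unname(br_F[f_id]), fa_inb = unname(br_F[m_id]),
          days_collected = days, n_eggs = cl$n_eggs,
          mean_egg_perimeter_mm = cl$mean_perimeter,
          incubation_days = cl$incubation_days, n_hatched = cl$n_hatched,
          infertile = cl$infertile, stringsAsFactors = FALSE)
        if (cl$n_eggs > 0) {
          egg_rows[[length(egg_rows) + 1]] <- data.frame(
            pair_id = pair_id, line = line, generation = gen,
            mother_sdl = unname(br_len[f_id]), mo_inb = unname(br_F[f_id]),
            fa_inb = unname(br_F[m_id]),
            perimeter_mm = cl$perimeters, stringsAsFactors = FALSE)
          surv_rows[[length(surv_rows) + 1]] <- data.frame(
            family_id = pair_id, line = line, generation = gen,
            stage = "egg-0", n_start = cl$n_eggs, n_end = cl$n_hatched,
            mo_inb = unname(br_F[f_id]), fa_inb = unname(br_F[m_id]),
            stringsAsFactors = FALSE)
        }
        if (cl$n_hatched > 0) {
          fam[[pair_id]] <- list(pair_id = pair_id, sire = m_id, dam = f_id,
                                 n_hatched = cl$n_hatched,
                                 parent_sdl = unname(parent_sdl),
                                 off_F = unname(off_F),
                                 mo_inb = unname(br_F[f_id]),
                                 fa_inb = unname(br_F[m_id]))
        }
      }
      if (length(fam) == 0) {
        stop("experiment failure: line ", line, " produced no offspring at ",
             "generation ", gen)
      }

      # --- stock family aquaria, create fish
      gen_fish <- list()
      for (fm in fam) {
        target <- max(1L, round(stats::rnorm(1, config$larvae_per_family_mean,
                                             config$larvae_per_family_sd)))
        n_stock <- min(fm$n_hatched, target)
        mid_bv <- 0.5 * (br_bv[fm$sire] + br_bv[fm$dam])
        bv <- stats::rnorm(n_stock, mid_bv, arch$sigma_a / sqrt(2))
        e_dev <- stats::rnorm(n_stock, 0, arch$sigma_e)
        hatch_len <- arch$hatch_length_mean +
          .line_shift(arch, line, "hatch_length") +
          arch$hatch_parent_slope * (fm$parent_sdl - arch$reference_length) +
          arch$hatch_inb_slope * fm$off_F +
          stats::rnorm(n_stock, 0, arch$hatch_length_sd)
        ids <- sprintf("%s_%03d", fm$pair_id, seq_len(n_stock))
        # whole sibling families share a phenotyping age near 75 dph
        pheno_age <- max(65, min(87, round(stats::rnorm(1, 75, 4))))
        gen_fish[[fm$pair_id]] <- data.frame(
          id = ids, family_id = fm$pair_id, sire_id = fm$sire,
          dam_id = fm$dam, line = line, generation = gen,
          inbreeding = fm$off_F, mo_inb = fm$mo_inb, fa_inb = fm$fa_inb,
          parent_sdl = fm$parent_sdl, pheno_age = pheno_age,
          bv = bv, span_dev = bv + e_dev, hatch_len = hatch_len,
          n_stocked = n_stock, stringsAsFactors = FALSE)
      }

      # --- survival and thinning
      od <- function() stats::rnorm(1, 0, arch$survival_overdispersion_sd)
      for (pid in names(gen_fish)) {
        f <- gen_fish[[pid]]
        n0 <- nrow(f)
        p15 <- stats::plogis(arch$survival_logits["d0_15"] + od())
        alive15 <- stats::runif(n0) < p15
        surv_rows[[length(surv_rows) + 1]] <- data.frame(
          family_id = pid, line = line, generation = gen, stage = "0-15",
          n_start = n0, n_end = sum(alive15),
          mo_inb = f$mo_inb[1], fa_inb = f$fa_inb[1],
          stringsAsFactors = FALSE)
        f <- f[alive15, , drop = FALSE]
        # density thinning: overflow above the cap removed at random
        if (nrow(f) > config$thin_to_at_15dph) {
          keep <- sample(nrow(f), config$thin_to_at_15dph)
          f <- f[sort(keep), , drop = FALSE]
        }
        n15 <- nrow(f)
        p60 <- stats::plogis(arch$survival_logits["d15_60"] + od())
        alive60 <- stats::runif(n15) < p60
        surv_rows[[length(surv_rows) + 1]] <- data.frame(
          family_id = pid, line = line, generation = gen, stage = "15-60",
          n_start = n15, n_end = sum(alive60),
          mo_inb = f$mo_inb[1], fa_inb = f$fa_inb[1],
          stringsAsFactors = FALSE)
        f <- f[alive60, , drop = FALSE]
        n60 <- nrow(f)
        p75 <- stats::plogis(arch$survival_logits["d60_75"] + od())
        alive75 <- stats::runif(n60) < p75
        surv_rows[[length(surv_rows) + 1]] <- data.frame(
          family_id = pid, line = line, generation = gen, stage = "60-75",
          n_start = n60, n_end = sum(alive75),
          mo_inb = f$mo_inb[1], fa_inb = f$fa_inb[1],
          stringsAsFactors = FALSE)
        f$alive60 <- TRUE
        f$alive75 <- alive75
        gen_fish[[pid]] <- f
      }
      gen_fish <- gen_fish[vapply(gen_fish, nrow, integer(1)) > 0]
      if (length(gen_fish) == 0) {
        stop("experiment failure: line ", line,
             " lost all families by 60 dph at generation ", gen)
      }

      # --- growth, maturation, phenotyping
      all_f <- do.call(rbind, gen_fish)
      rownames(all_f) <- NULL
      span <- arch$L_inf_mean + .line_shift(arch, line, "growth_span")
      len_at <- function(age) {
        gfrac <- 1 - exp(-arch$growth_rate_k * age)
        all_f$hatch_len + span * gfrac + all_f$span_dev * gfrac / g75
      }
      all_f$length_0 <- all_f$hatch_len
      all_f$length_15 <- len_at(15)
      all_f$length_60 <- ifelse(all_f$alive60, len_at(60), NA_real_)
      all_f$length_75 <- ifelse(all_f$alive75, len_at(all_f$pheno_age),
                                NA_real_)
      day_mat <- .simulate_maturation_day(arch, all_f$hatch_len,
                                          all_f$span_dev,
                                          max_age = max(all_f$pheno_age),
                                          line = line)
      all_f$maturation_day <- day_mat
      all_f$mature_75 <- !is.na(day_mat) & day_mat <= all_f$pheno_age
      all_f$sex <- ifelse(all_f$mature_75,
                          sample(c("M", "F"), nrow(all_f), replace = TRUE),
                          "I")
      all_f$age_75 <- all_f$pheno_age

      # --- hormone sampling at 40 dph
      pool <- which(all_f$alive60)
      n_h <- min(config$n_hormone_fish, length(pool))
      if (n_h > 0) {
        hsel <- sample(pool, n_h)
        hfish <- data.frame(id = all_f$id[hsel], line = line,
                            sex = all_f$sex[hsel],
                            length = all_f$hatch_len[hsel] +
                              (span + all_f$span_dev[hsel] / g75) *
                              (1 - exp(-arch$growth_rate_k * 40)),
                            inbreeding = all_f$inbreeding[hsel],
                            stringsAsFactors = FALSE)
        h <- simulate_hormones(arch, hfish)
        h$generation <- gen
        horm_rows[[length(horm_rows) + 1]] <- h
      }

      # --- family-stage selection at 60 dph
      alive60_f <- all_f[all_f$alive60 & !is.na(all_f$length_60), ]
      fam_lengths <- split(alive60_f$length_60, alive60_f$family_id)
      kept_fams <- tryCatch(
        family_selection(fam_lengths, rule),
        error = function(e) {
          # fall back to every eligible family when fewer than requested
          sizes <- vapply(fam_lengths, length, integer(1))
          el <- names(fam_lengths)[sizes >= rule$min_family_size]
          if (length(el) < 2) {
            stop("experiment failure: line ", line, " has ", length(el),
                 " eligible families at generation ", gen, call. = FALSE)
          }
          el
        })

      # --- individual-stage selection at 75 dph
      breeders <- character(0)
      for (pid in kept_fams) {
        fam75 <- all_f[all_f$family_id == pid & all_f$alive75, ]
        members <- data.frame(id = fam75$id, sex = fam75$sex,
                              mature = fam75$mature_75,
                              length = fam75$length_75,
                              stringsAsFactors = FALSE)
        got <- tryCatch(individual_selection(members, rule),
                        error = function(e) {
          shortfalls[[length(shortfalls) + 1]] <<- data.frame(
            line = line, generation = gen, family_id = pid,
            message = conditionMessage(e), stringsAsFactors = FALSE)
          # take whatever mature fish are available
          mm <- members[as.logical(members$mature), ]
          unlist(lapply(c("M", "F"), function(sx) {
            pool <- mm[mm$sex == sx, ]
            n_keep <- min(nrow(pool),
                          if (sx == "M") rule$males_kept else rule$females_kept)
            if (n_keep == 0) return(character(0))
            if (rule$direction == "random") return(sample(pool$id, n_keep))
            ord <- if (rule$direction == "largest") order(-pool$length, pool$id)
                   else order(pool$length, pool$id)
            pool$id[ord][seq_len(n_keep)]
          }))
        })
        breeders <- c(breeders, got)
      }
      cohort75 <- all_f[all_f$alive75, ]
      sel <- selection_differential(
        data.frame(id = cohort75$id, mature = cohort75$mature_75,
                   length = cohort75$length_75),
        data.frame(id = breeders,
                   mature = cohort75$mature_75[match(breeders, cohort75$id)],
                   length = cohort75$length_75[match(breeders, cohort75$id)]))
      diff_rows[[length(diff_rows) + 1]] <- data.frame(
        line = line, generation = gen,
        delta_length = sel$delta_length, delta_maturity = sel$delta_maturity,
        n_before = sel$n_before, n_after = sel$n_after,
        stringsAsFactors = FALSE)

      # --- extend breeder relationship matrix and form next pairs
      bi <- match(breeders, all_f$id)
      n_m <- sum(all_f$sex[bi] == "M"); n_f <- sum(all_f$sex[bi] == "F")
      n_pairs_next <- min(config$n_pairs_per_line, n_m, n_f)
      if (gen < config$n_generations && n_pairs_next < 2) {
        stop("experiment failure: line ", line, " has too few breeders (",
             n_m, "M/", n_f, "F) at generation ", gen)
      }
      for (b in bi) {
        id <- all_f$id[b]; s <- all_f$sire_id[b]; d <- all_f$dam_id[b]
        old <- rownames(A)
        arow <- 0.5 * (A[s, ] + A[d, ])
        A <- rbind(cbind(A, arow), c(arow, 1 + 0.5 * A[s, d]))
        rownames(A) <- colnames(A) <- c(old, id)
        br_sire[id] <- s; br_dam[id] <- d
        br_gen[id] <- gen
        br_F[id] <- all_f$inbreeding[b]
        br_len[id] <- all_f$length_75[b]
        br_bv[id] <- all_f$bv[b]
      }
      if (gen < config$n_generations) {
        cand <- data.frame(id = all_f$id[bi], sex = all_f$sex[bi],
                           stringsAsFactors = FALSE)
        # breeder-only pedigree for pairing (relationship matrix passed in)
        ids_A <- rownames(A)
        sexes <- rep("I", length(ids_A))
        sexes[match(cand$id, ids_A)] <- cand$sex
        br_ped <- pedigree(data.frame(
          id = ids_A,
          sire_id = unname(br_sire[ids_A]),
          dam_id = unname(br_dam[ids_A]),
          sex = sexes, line = line,
          generation = unname(br_gen[ids_A]),
          stringsAsFactors = FALSE))
        plan <- propose_pairs(cand, br_ped, n_pairs = n_pairs_next,
                              n_resamples = config$pairing_resamples,
                              A = A)
        pairs <- plan$pairs[, c("male", "female")]
      }

      # --- record fish and pedigree rows
      fish_rows[[length(fish_rows) + 1]] <- data.frame(
        id = all_f$id, sire_id = all_f$sire_id, dam_id = all_f$dam_id,
        family_id = all_f$family_id, line = line, generation = gen,
        sex = all_f$sex, inbreeding = all_f$inbreeding,
        mo_inb = all_f$mo_inb, fa_inb = all_f$fa_inb,
        parent_sdl = all_f$parent_sdl,
        length_0 = all_f$length_0, length_15 = all_f$length_15,
        length_60 = all_f$length_60, length_75 = all_f$length_75,
        mature_75 = as.integer(all_f$mature_75),
        maturation_day = all_f$maturation_day,
        age_75 = all_f$age_75, alive_75 = all_f$alive75,
        kept_family = all_f$family_id %in% kept_fams,
        breeder = all_f$id %in% breeders,
        stringsAsFactors = FALSE)
      ped_rows[[length(ped_rows) + 1]] <- data.frame(
        id = all_f$id, sire_id = all_f$sire_id, dam_id = all_f$dam_id,
        sex = all_f$sex, line = line, generation = gen,
        stringsAsFactors = FALSE)
      meanF_rows[[length(meanF_rows) + 1]] <- data.frame(
        line = line, generation = gen,
        mean_inbreeding = mean(all_f$inbreeding), n = nrow(all_f),
        stringsAsFactors = FALSE)
    }
  }

  fish <- do.call(rbind, fish_rows)
  structure(list(
    tables = list(
      fish = fish,
      clutches = do.call(rbind, clutch_rows),
      eggs = do.call(rbind, egg_rows),
      survival = do.call(rbind, surv_rows),
      hormones = if (length(horm_rows)) do.call(rbind, horm_rows) else NULL
    ),
    pedigree = pedigree(do.call(rbind, ped_rows)),
    differentials = do.call(rbind, diff_rows),
    mean_inbreeding = do.call(rbind, meanF_rows),
    shortfalls = if (length(shortfalls)) do.call(rbind, shortfalls)
                 else NULL,
    config = config, arch = arch
  ), class = "medaka_experiment")
}

#' @export
print.medaka_experiment <- function(x, ...) {
  cat("Synthetic size-selection experiment\n")
  cat("  lines:", paste(unique(x$tables$fish$line), collapse = ", "), "\n")
  cat("  generations:", max(x$tables$fish$generation), "\n")
  cat("  fish:", nrow(x$tables$fish),
      " clutches:", nrow(x$tables$clutches), "\n")
  fF <- x$mean_inbreeding[x$mean_inbreeding$generation ==
                            max(x$mean_inbreeding$generation), ]
  cat(sprintf("  mean inbreeding at final generation: %.3f\n",
              mean(fF$mean_inbreeding)))
  invisible(x)
}
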
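#' Trait architecture of the generative experiment model
#'
#' Bundles every generative parameter the simulator needs: growth-curve
#' parameters, the heritability of standard length, the maturation hazard,
#' stage-wise survival, zero-inflated fecundity, egg traits, incubation and
#' pituitary hormone expression. Defaults are calibrated to the medaka
#' selection experiment the package models: Control-line standard length of
#' about 20.5 mm and about 86% maturity at 75 dph, family aquaria of about
#' 15-20 fish, and hormone line shifts matching the reported corrected
#' effect sizes.
#'
#' @param h2_length narrow-sense heritability of standard length at 75 dph.
#' @param length_p_sd phenotypic standard deviation (mm) of standard length
#'   at 75 dph; split into additive-genetic and environmental parts by
#'   `h2_length`.
#' @param L_inf_mean asymptotic growth span above hatch length (mm) of the
#'   von Bertalanffy mean curve.
#' @param growth_rate_k von Bertalanffy rate (1/day).
#' @param hatch_length_mean mean standard length at hatch (mm).
#' @param hatch_length_sd residual sd of hatch length (mm).
#' @param hatch_parent_slope change in hatch length per mm of mean parental
#'   length.
#' @param hatch_inb_slope change in hatch length per unit inbreeding
#'   coefficient.
#' @param maturation_intercept,maturation_age_slope,maturation_length_slope
#'   logit-scale coefficients of the daily maturation hazard
#'   `logit(m) = intercept + age_slope * age + length_slope * length`.
#' @param survival_logits named logits of daily-independent stage survival
#'   probabilities for stages `egg_0`, `d0_15`, `d15_60`, `d60_75` (whole
#'   stage, not per day).
#' @param survival_overdispersion_sd family-level logit-scale sd of stage
#'   survival.
#' @param fecundity_zero_prob probability a breeding pair is infertile
#'   (structural zero).
#' @param fecundity_daily_rate expected eggs per day for a fertile pair at
#'   the reference mother length.
#' @param fecundity_overdispersion_sd log-scale family overdispersion sd.
#' @param fecundity_length_slope log-scale change in daily rate per mm of
#'   mother length above the reference.
#' @param reference_length reference standard length (mm) at which length
#'   slopes are anchored.
#' @param egg_perimeter_mean mean egg perimeter (mm) at the reference
#'   mother length.
#' @param egg_perimeter_slope change in egg perimeter per mm mother length.
#' @param egg_perimeter_sd residual sd of egg perimeter (mm).
#' @param incubation_mean,incubation_sd incubation time (days).
#' @param hormone_mean_by_line list of per-line 3-vectors of mean ln
#'   gene/actin ratios (LHb, FSHb, GH).
#' @param hormone_cov_by_line list of per-line 3x3 positive-definite
#'   residual covariance matrices.
#' @param hormone_sex_shift 3-vector added for males (females are the
#'   reference).
#' @param hormone_inb_slope,hormone_length_slope 3-vectors of inbreeding and
#'   length effects on the ln ratios.
#' @param line_effects optional named list `line -> list(trait = shift)`
#'   of additive generative shifts; supported traits are `growth_span`,
#'   `maturation_intercept`, `hatch_length`, `egg_perimeter`, `incubation`
#'   and `fecundity_log_rate`.
#' @return object of class `trait_architecture`.
#' @export
trait_architecture <- function(
  h2_length = 0.3,
  length_p_sd = 1.5,
  L_inf_mean = 20.6,
  growth_rate_k = 0.02,
  hatch_length_mean = 4.5,
  hatch_length_sd = 0.25,
  hatch_parent_slope = 0.02,
  hatch_inb_slope = 0.5,
  maturation_intercept = -14.7,
  maturation_age_slope = 0.063,
  maturation_length_slope = 0.42,
  survival_logits = c(egg_0 = 1.4, d0_15 = 2.2, d15_60 = 2.6, d60_75 = 3.0),
  survival_overdispersion_sd = 0.3,
  fecundity_zero_prob = 0.1,
  fecundity_daily_rate = 12,
  fecundity_overdispersion_sd = 0.3,
  fecundity_length_slope = 0.05,
  reference_length = 20,
  egg_perimeter_mean = 3.5,
  egg_perimeter_slope = 0.02,
  egg_perimeter_sd = 0.15,
  incubation_mean = 8,
  incubation_sd = 1,
  hormone_mean_by_line = list(
    Control = c(lhb = -1.5, fshb = -2.0, gh = 1.0),
    Small = c(lhb = -1.3, fshb = -1.72, gh = 1.44),
    Large = c(lhb = -1.76, fshb = -2.3, gh = 1.2)
  ),
  hormone_cov_by_line = NULL,
  hormone_sex_shift = c(0.3, 0.3, 0.2),
  hormone_inb_slope = c(0, 0, 0),
  hormone_length_slope = c(0.05, 0.05, 0.05),
  line_effects = list()
) {
  if (is.null(hormone_cov_by_line)) {
    base_cov <- 0.64 * (diag(3) * 0.4 + 0.6)
    dimnames(base_cov) <- list(c("lhb", "fshb", "gh"), c("lhb", "fshb", "gh"))
    hormone_cov_by_line <- list(Control = base_cov, Small = base_cov,
                                Large = base_cov)
  }
  stopifnot(
    h2_length >= 0, h2_length <= 1, length_p_sd >= 0,
    growth_rate_k > 0, hatch_length_sd >= 0,
    fecundity_zero_prob >= 0, fecundity_zero_prob <= 1,
    fecundity_daily_rate > 0, fecundity_overdispersion_sd >= 0,
    egg_perimeter_sd >= 0, incubation_sd >= 0,
    survival_overdispersion_sd >= 0
  )
  for (m in hormone_cov_by_line) {
    if (!isTRUE(all(eigen(m, symmetric = TRUE,
                          only.values = TRUE)$values > 0))) {
      stop("hormone covariance matrices must be positive definite")
    }
  }
  arch <- list(
    h2_length = h2_length, length_p_sd = length_p_sd,
    sigma_a = sqrt(h2_length) * length_p_sd,
    sigma_e = sqrt(1 - h2_length) * length_p_sd,
    L_inf_mean = L_inf_mean, growth_rate_k = growth_rate_k,
    hatch_length_mean = hatch_length_mean, hatch_length_sd = hatch_length_sd,
    hatch_parent_slope = hatch_parent_slope,
    hatch_inb_slope = hatch_inb_slope,
    maturation_intercept = maturation_intercept,
    maturation_age_slope = maturation_age_slope,
    maturation_length_slope = maturation_length_slope,
    survival_logits = survival_logits,
    survival_overdispersion_sd = survival_overdispersion_sd,
    fecundity_zero_prob = fecundity_zero_prob,
    fecundity_daily_rate = fecundity_daily_rate,
    fecundity_overdispersion_sd = fecundity_overdispersion_sd,
    fecundity_length_slope = fecundity_length_slope,
    reference_length = reference_length,
    egg_perimeter_mean = egg_perimeter_mean,
    egg_perimeter_slope = egg_perimeter_slope,
    egg_perimeter_sd = egg_perimeter_sd,
    incubation_mean = incubation_mean, incubation_sd = incubation_sd,
    hormone_mean_by_line = hormone_mean_by_line,
    hormone_cov_by_line = hormone_cov_by_line,
    hormone_sex_shift = hormone_sex_shift,
    hormone_inb_slope = hormone_inb_slope,
    hormone_length_slope = hormone_length_slope,
    line_effects = line_effects
  )
  class(arch) <- "trait_architecture"
  arch
}

# line-specific generative shift for a trait, 0 when unset
.line_shift <- function(arch, line, trait) {
  le <- arch$line_effects[[line]]
  if (is.null(le) || is.null(le[[trait]])) 0 else le[[trait]]
}

#' Configuration of one simulated selection experiment
#'
#' @param n_generations number of generations including the founder
#'   generation F1 (default 7, i.e. six selection episodes F1-F6).
#' @param n_pairs_per_line breeding pairs per line per generation.
#' @param families_kept families retained at the 60 dph family stage.
#' @param min_family_size minimum family size at 60 dph.
#' @param larvae_per_family_mean,larvae_per_family_sd initial stocking
#'   density of family aquaria (larvae per aquarium).
#' @param thin_to_at_15dph density cap applied at 15 dph (overflow removed
#'   at random).
#' @param egg_collection_days days of egg collection per pair (4 or 5,
#'   drawn uniformly per clutch).
#' @param phenotyping_ages ages (dph) at which standard length is measured.
#' @param n_hormone_fish fish sampled per line and generation for pituitary
#'   expression (sampled at 40 dph).
#' @param prephase simulate the pre-experiment history (wild founding
#'   stock, pond mass-spawning generations, transferred base adults, two
#'   random-mating laboratory pair generations) and start the selection
#'   lines from founders drawn from that shared pool. Founders are then
#'   related to one another, as in the real experiment, but their own
#'   inbreeding is reset to zero (founders assumed non-inbred).
#' @param n_wild_founders wild-caught breeders founding the stock.
#' @param n_pond_generations pond generations between the wild stock and
#'   the laboratory transfer.
#' @param pond_cohort_size fish per pond cohort.
#' @param n_base_adults adults transferred to the laboratory.
#' @param n_pairs_pre breeding pairs in the two pre-selection laboratory
#'   generations.
#' @param pairing_resamples candidate pairings drawn when minimizing the
#'   median offspring inbreeding.
#' @param seed integer seed making the whole experiment reproducible.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_generations = 7, n_pairs_per_line = 20,
                              families_kept = 10, min_family_size = 10,
                              larvae_per_family_mean = 19.6,
                              larvae_per_family_sd = 1.6,
                              thin_to_at_15dph = 17,
                              egg_collection_days = c(4, 5),
                              phenotyping_ages = c(0, 15, 60, 75),
                              n_hormone_fish = 12,
                              prephase = TRUE,
                              n_wild_founders = 100,
                              n_pond_generations = 2,
                              pond_cohort_size = 300,
                              n_base_adults = 60,
                              n_pairs_pre = c(54, 56),
                              pairing_resamples = 100,
                              seed = 1) {
  stopifnot(n_generations >= 2, n_pairs_per_line >= 2, families_kept >= 1,
            all(diff(phenotyping_ages) > 0), all(egg_collection_days >= 1))
  structure(
    list(n_generations = n_generations, n_pairs_per_line = n_pairs_per_line,
         families_kept = families_kept, min_family_size = min_family_size,
         larvae_per_family_mean = larvae_per_family_mean,
         larvae_per_family_sd = larvae_per_family_sd,
         thin_to_at_15dph = thin_to_at_15dph,
         egg_collection_days = egg_collection_days,
         phenotyping_ages = phenotyping_ages,
         n_hormone_fish = n_hormone_fish,
         prephase = prephase,
         n_wild_founders = n_wild_founders,
         n_pond_generations = n_pond_generations,
         pond_cohort_size = pond_cohort_size,
         n_base_adults = n_base_adults,
         n_pairs_pre = n_pairs_pre,
         pairing_resamples = pairing_resamples,
         seed = seed),
    class = "simulation_config"
  )
}
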
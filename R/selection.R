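#' Selection rule for one experimental line
#'
#' Describes the two-stage truncation selection applied each generation:
#' at the family stage, undersized families are discarded and a fixed number
#' of families is kept by mean standard length (extreme ends) or at random;
#' at the individual stage, a fixed number of mature males and females per
#' family is kept by individual length (or at random).
#'
#' @param direction `"random"` (Control line), `"smallest"` (Small line) or
#'   `"largest"` (Large line).
#' @param families_kept number of families retained at the family stage.
#' @param min_family_size families smaller than this at 60 dph are discarded
#'   before ranking.
#' @param males_kept,females_kept mature breeders kept per family.
#' @return object of class `selection_rule`.
#' @export
selection_rule <- function(direction = c("random", "smallest", "largest"),
                           families_kept = 10, min_family_size = 10,
                           males_kept = 2, females_kept = 2) {
  direction <- match.arg(direction)
  stopifnot(families_kept >= 1, min_family_size >= 0,
            males_kept >= 1, females_kept >= 1)
  structure(
    list(direction = direction, families_kept = families_kept,
         min_family_size = min_family_size,
         males_kept = males_kept, females_kept = females_kept),
    class = "selection_rule"
  )
}

#' Family-stage selection at 60 dph
#'
#' Discards families below the rule's minimum size, then keeps
#' `families_kept` families with the largest or smallest mean standard
#' length (or a seeded uniform random subset for `"random"`).
#'
#' @param families named list mapping family id to the numeric vector of its
#'   members' standard lengths (mm) at 60 dph.
#' @param rule a [selection_rule()].
#' @param seed integer seed used for the `"random"` direction.
#' @return character vector of kept family ids.
#' @export
family_selection <- function(families, rule, seed = NULL) {
  stopifnot(inherits(rule, "selection_rule"))
  sizes <- vapply(families, length, integer(1))
  eligible <- names(families)[sizes >= rule$min_family_size]
  if (length(eligible) < rule$families_kept) {
    stop("only ", length(eligible), " families of size >= ",
         rule$min_family_size, " but ", rule$families_kept, " required")
  }
  if (rule$direction == "random") {
    if (!is.null(seed)) set.seed(seed)
    return(sort(sample(eligible, rule$families_kept)))
  }
  means <- vapply(families[eligible], mean, numeric(1))
  ord <- order(means, eligible,
               decreasing = (rule$direction == "largest"))
  sort(eligible[ord][seq_len(rule$families_kept)])
}

#' Individual-stage selection at 75 dph
#'
#' Within one family, keeps the required number of mature males and mature
#' females most extreme in the rule's direction (uniform random for
#' `"random"`). Ties in length are broken by ascending id, so the result is
#' deterministic for directional rules.
#'
#' @param members data frame with columns `id`, `sex` (`"I"`/`"M"`/`"F"`),
#'   `mature` (logical or 0/1) and `length` (mm).
#' @param rule a [selection_rule()].
#' @param seed seed for the `"random"` direction.
#' @return character vector of breeder ids (`males_kept + females_kept`
#'   when feasible).
#' @export
individual_selection <- function(members, rule, seed = NULL) {
  stopifnot(inherits(rule, "selection_rule"))
  members <- as.data.frame(members)
  mature <- members[as.logical(members$mature), , drop = FALSE]
  pick <- function(sex, n_keep) {
    pool <- mature[mature$sex == sex, , drop = FALSE]
    if (nrow(pool) < n_keep) {
      stop("family shortfall: ", nrow(pool), " mature ",
           if (sex == "M") "males" else "females", " but ", n_keep,
           " required", call. = FALSE)
    }
    if (rule$direction == "random") {
      return(sample(pool$id, n_keep))
    }
    ord <- if (rule$direction == "largest") {
      order(-pool$length, pool$id)   # ties resolved to the lower id
    } else {
      order(pool$length, pool$id)
    }
    pool$id[ord][seq_len(n_keep)]
  }
  if (rule$direction == "random" && !is.null(seed)) set.seed(seed)
  c(pick("M", rule$males_kept), pick("F", rule$females_kept))
}

#' Resultant selection differential of one selection episode
#'
#' The length differential is the mean standard length of the kept subset
#' minus the mean of the full cohort before selection; the maturity
#' differential is the difference in proportion mature.
#'
#' @param before data frame with columns `id`, `mature`, `length` for the
#'   cohort before selection.
#' @param after the kept subset (same columns); must be a subset of
#'   `before` by id.
#' @return list with `delta_length` (mm), `delta_maturity` (proportion),
#'   `n_before`, `n_after`.
#' @export
selection_differential <- function(before, after) {
  before <- as.data.frame(before)
  after <- as.data.frame(after)
  if (nrow(after) == 0) stop("empty after-selection set")
  if (!all(after$id %in% before$id)) {
    stop("after-selection set is not a subset of the before-selection cohort")
  }
  list(
    delta_length = mean(after$length) - mean(before$length),
    delta_maturity = mean(as.logical(after$mature)) -
      mean(as.logical(before$mature)),
    n_before = nrow(before),
    n_after = nrow(after)
  )
}

#' Diagnostic for unintended selection at the family-discard step
#'
#' Discarding families below a minimum size can itself select on family
#' traits. This fits an overdispersed (quasibinomial) logistic regression of
#' the discard indicator on a family covariate and reports the slope
#' p-value, mirroring the experiment's own checks on fecundity, early
#' survival and body length.
#'
#' @param discarded logical vector, one entry per family.
#' @param covariate numeric family-level covariate (e.g. fecundity, mean
#'   length, egg-to-15-dph survival).
#' @return list with `estimate` and `p_value` for the covariate slope.
#' @export
family_discard_diagnostic <- function(discarded, covariate) {
  stopifnot(length(discarded) == length(covariate))
  fit <- stats::glm(discarded ~ covariate, family = stats::quasibinomial())
  s <- summary(fit)$coefficients
  list(estimate = unname(s["covariate", "Estimate"]),
       p_value = unname(s["covariate", "Pr(>|t|)"]))
}
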
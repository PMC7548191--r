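#' Construct and validate a pedigree
#'
#' A pedigree is a data frame of individuals with parent links. Founders have
#' both parents missing (`NA` or `""`); all other individuals have both
#' parents present and previously listed. Validation enforces acyclicity,
#' resolvable parent references, and both-or-neither parents.
#'
#' @param x data frame with columns `id`, `sire_id`, `dam_id`, `sex`
#'   (one of `"I"`, `"M"`, `"F"`), `line`, `generation` (integer).
#' @return An object of class `pedigree` (a validated data frame, ordered so
#'   parents precede offspring).
#' @examples
#' ped <- pedigree(data.frame(
#'   id = c("a", "b", "c"), sire_id = c(NA, NA, "a"), dam_id = c(NA, NA, "b"),
#'   sex = c("M", "F", "I"), line = "Control", generation = c(0, 0, 1)
#' ))
#' @export
pedigree <- function(x) {
  stopifnot(is.data.frame(x))
  required <- c("id", "sire_id", "dam_id", "sex", "line", "generation")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop("pedigree is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  for (col in c("id", "sire_id", "dam_id", "sex", "line")) {
    x[[col]] <- as.character(x[[col]])
    x[[col]][!is.na(x[[col]]) & x[[col]] == ""] <- NA_character_
  }
  if (anyNA(x$id)) stop("pedigree ids must be non-missing")
  if (anyDuplicated(x$id)) {
    stop("duplicated pedigree ids: ",
         paste(unique(x$id[duplicated(x$id)]), collapse = ", "))
  }
  if (!all(x$sex %in% c("I", "M", "F"))) {
    stop("sex must be one of 'I', 'M', 'F'")
  }
  one_parent <- xor(is.na(x$sire_id), is.na(x$dam_id))
  if (any(one_parent)) {
    stop("individuals with exactly one known parent: ",
         paste(x$id[one_parent], collapse = ", "))
  }
  known <- c(x$sire_id, x$dam_id)
  known <- known[!is.na(known)]
  unknown <- setdiff(known, x$id)
  if (length(unknown) > 0) {
    stop("parent ids not present in pedigree: ",
         paste(unique(unknown), collapse = ", "))
  }
  x <- x[order(x$generation), , drop = FALSE]
  ord <- .topological_order(x)   # errors on cycles
  x <- x[ord, , drop = FALSE]
  rownames(x) <- NULL
  class(x) <- c("pedigree", "data.frame")
  x
}

# Kahn topological sort over parent->offspring edges; cycle => structural error
.topological_order <- function(x) {
  n <- nrow(x)
  idx <- seq_len(n)
  names(idx) <- x$id
  sire <- ifelse(is.na(x$sire_id), NA_integer_, idx[x$sire_id])
  dam <- ifelse(is.na(x$dam_id), NA_integer_, idx[x$dam_id])
  indeg <- (!is.na(sire)) + (!is.na(dam))
  children <- vector("list", n)
  for (i in idx) {
    if (!is.na(sire[i])) children[[sire[i]]] <- c(children[[sire[i]]], i)
    if (!is.na(dam[i])) children[[dam[i]]] <- c(children[[dam[i]]], i)
  }
  queue <- idx[indeg == 0]
  out <- integer(0)
  while (length(queue) > 0) {
    i <- queue[[1]]
    queue <- queue[-1]
    out <- c(out, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) < n) {
    stop("pedigree contains a cycle (an individual is its own ancestor)")
  }
  out
}

#' Additive relationship matrix of a pedigree
#'
#' Computes Wright's numerator relationship matrix A by the recursive tabular
#' method over a topological order: for individual i with parents s, d,
#' `A[i, j] = 0.5 * (A[s, j] + A[d, j])` for earlier j and
#' `A[i, i] = 1 + 0.5 * A[s, d]`; founders are treated as unrelated and
#' non-inbred. Kinship coefficients are `A / 2`.
#'
#' @param ped a [pedigree()].
#' @return numeric matrix with dimnames equal to the pedigree ids.
#' @export
additive_relationship <- function(ped) {
  if (!inherits(ped, "pedigree")) ped <- pedigree(ped)
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$id
  sire <- ifelse(is.na(ped$sire_id), NA_integer_, idx[ped$sire_id])
  dam <- ifelse(is.na(ped$dam_id), NA_integer_, idx[ped$dam_id])
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in idx) {
    if (is.na(sire[i])) {
      A[i, i] <- 1
    } else {
      s <- sire[i]; d <- dam[i]
      if (i > 1L) {
        prev <- seq_len(i - 1L)
        row <- 0.5 * (A[s, prev] + A[d, prev])
        A[i, prev] <- row
        A[prev, i] <- row
      }
      A[i, i] <- 1 + 0.5 * A[s, d]
    }
  }
  A
}

#' Kinship matrix of a pedigree
#'
#' @param ped a [pedigree()].
#' @return symmetric matrix of kinship coefficients (self-kinship on the
#'   diagonal, at least 0.5).
#' @export
kinship_matrix <- function(ped) {
  additive_relationship(ped) / 2
}

#' Per-individual self-kinship and inbreeding coefficients
#'
#' The inbreeding coefficient of an individual is `F = 2 * k - 1`, where `k`
#' is its kinship coefficient with itself; equivalently F is the kinship of
#' its two parents. Founders have `F = 0`.
#'
#' @param ped a [pedigree()].
#' @return data frame with columns `id`, `kinship_self` (in `[0.5, 1]`) and
#'   `inbreeding` (in `[0, 1]`).
#' @export
kinship_and_inbreeding <- function(ped) {
  if (!inherits(ped, "pedigree")) ped <- pedigree(ped)
  A <- additive_relationship(ped)
  k_self <- diag(A) / 2
  data.frame(
    id = ped$id,
    kinship_self = k_self,
    inbreeding = 2 * k_self - 1,
    stringsAsFactors = FALSE
  )
}

#' Propose breeding pairs minimizing the median offspring inbreeding
#'
#' Draws `n_resamples` random male-female pairings that avoid full-sib
#' matings (optionally also half-sib matings) and returns the pairing whose
#' hypothetical offspring have the smallest median inbreeding coefficient.
#' The offspring inbreeding of a pair is the kinship coefficient between its
#' two members, read from the pedigree relationship matrix.
#'
#' @param candidates data frame with columns `id` and `sex` (`"M"`/`"F"`),
#'   all ids resolvable in `ped`; or a character vector of ids whose sexes
#'   are taken from the pedigree.
#' @param ped a [pedigree()] containing all candidates.
#' @param n_pairs number of pairs to form.
#' @param n_resamples number of random candidate pairings to draw.
#' @param seed integer seed; the result is deterministic given the seed.
#' @param exclude_half_sibs also forbid half-sib matings (default `FALSE`).
#' @param A optional precomputed [additive_relationship()] matrix for `ped`.
#' @return list with elements `pairs` (data frame `male`, `female`,
#'   `offspring_f`), `median_f`, and `n_valid_sampled`.
#' @export
propose_pairs <- function(candidates, ped, n_pairs,
                          n_resamples = 200, seed = NULL,
                          exclude_half_sibs = FALSE, A = NULL) {
  if (!inherits(ped, "pedigree")) ped <- pedigree(ped)
  if (is.character(candidates)) {
    candidates <- data.frame(id = candidates,
                             sex = ped$sex[match(candidates, ped$id)],
                             stringsAsFactors = FALSE)
  }
  if (!all(candidates$id %in% ped$id)) {
    stop("candidate ids not found in pedigree: ",
         paste(setdiff(candidates$id, ped$id), collapse = ", "))
  }
  males <- candidates$id[candidates$sex == "M"]
  females <- candidates$id[candidates$sex == "F"]
  if (length(males) < n_pairs || length(females) < n_pairs) {
    stop("need at least ", n_pairs, " males and ", n_pairs, " females; got ",
         length(males), " males, ", length(females), " females")
  }
  if (is.null(A)) A <- additive_relationship(ped)
  pr <- ped[match(c(males, females), ped$id), c("id", "sire_id", "dam_id")]
  fam_key <- function(ids) {
    i <- match(ids, pr$id)
    ifelse(is.na(pr$sire_id[i]), paste0("founder:", ids),
           paste(pr$sire_id[i], pr$dam_id[i], sep = "/"))
  }
  male_fam <- fam_key(males)
  female_fam <- fam_key(females)
  male_parents <- pr[match(males, pr$id), c("sire_id", "dam_id")]
  female_parents <- pr[match(females, pr$id), c("sire_id", "dam_id")]

  # allowed[i, j]: male i may be paired with female j
  allowed <- outer(seq_along(males), seq_along(females),
                   Vectorize(function(i, j) {
    if (startsWith(male_fam[i], "founder:") ||
        startsWith(female_fam[j], "founder:")) return(TRUE)
    shared <- (male_parents$sire_id[i] == female_parents$sire_id[j]) +
      (male_parents$dam_id[i] == female_parents$dam_id[j])
    if (exclude_half_sibs) shared == 0 else shared < 2
  }))

  # feasibility: a full matching of size n_pairs must exist in the
  # bipartite graph of allowed matings
  g <- igraph::graph_from_biadjacency_matrix(allowed)
  match_size <- igraph::max_bipartite_match(g)$matching_size
  if (match_size < n_pairs) {
    blocking <- unique(male_fam[rowSums(allowed) == 0])
    stop("no full-sib-free pairing of ", n_pairs, " pairs exists; ",
         "blocking families: ",
         if (length(blocking) > 0) paste(blocking, collapse = ", ")
         else "cross-family constraints")
  }

  if (!is.null(seed)) set.seed(seed)
  kin <- A[males, females, drop = FALSE] / 2
  best <- NULL
  best_median <- Inf
  n_valid <- 0L
  for (r in seq_len(n_resamples)) {
    sel_m <- if (length(males) > n_pairs) sample(seq_along(males), n_pairs)
             else sample(seq_along(males))
    assignment <- .random_assignment(sel_m, allowed, n_pairs,
                                     n_females = length(females))
    if (is.null(assignment)) next
    n_valid <- n_valid + 1L
    f_vals <- kin[cbind(assignment$m, assignment$f)]
    med <- stats::median(f_vals)
    if (med < best_median) {
      best_median <- med
      best <- data.frame(male = males[assignment$m],
                         female = females[assignment$f],
                         offspring_f = f_vals,
                         stringsAsFactors = FALSE)
    }
  }
  if (is.null(best)) {
    stop("no valid pairing found in ", n_resamples,
         " resamples although one exists; increase n_resamples")
  }
  list(pairs = best, median_f = best_median, n_valid_sampled = n_valid)
}

# Randomized greedy assignment of females to an ordered male subset,
# respecting the allowed matrix; NULL if the draw dead-ends.
.random_assignment <- function(male_order, allowed, n_pairs, n_females) {
  free <- rep(TRUE, n_females)
  m_out <- integer(n_pairs)
  f_out <- integer(n_pairs)
  for (k in seq_len(n_pairs)) {
    i <- male_order[k]
    opts <- which(free & allowed[i, ])
    if (length(opts) == 0) return(NULL)
    j <- if (length(opts) == 1) opts else sample(opts, 1)
    free[j] <- FALSE
    m_out[k] <- i
    f_out[k] <- j
  }
  list(m = m_out, f = f_out)
}

#' Inbreeding effective population size from a mean-inbreeding trajectory
#'
#' Uses the inbreeding effective number: the per-generation rate of
#' inbreeding is `dF_t = (F_t - F_{t-1}) / (1 - F_{t-1})` and
#' `Ne = 1 / (2 * mean(dF))`.
#'
#' @param mean_F_by_generation numeric vector of mean inbreeding
#'   coefficients, one per generation, in chronological order.
#' @return list with `Ne` (may be `Inf` when mean `dF <= 0`), `delta_F`
#'   (per-step rates) and `mean_delta_F`.
#' @export
effective_size <- function(mean_F_by_generation) {
  f <- as.numeric(mean_F_by_generation)
  if (length(f) < 2) stop("need at least 2 generations of mean inbreeding")
  if (any(f < 0 | f >= 1)) stop("mean inbreeding must be in [0, 1)")
  dF <- diff(f) / (1 - f[-length(f)])
  m <- mean(dF)
  list(
    Ne = if (m <= 0) Inf else 1 / (2 * m),
    delta_F = dF,
    mean_delta_F = m
  )
}
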
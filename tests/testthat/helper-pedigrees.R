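# Small pedigree builders used across test files.

ped_row <- function(id, sire = NA, dam = NA, sex = "I",
                    line = "Control", generation = 0) {
  data.frame(id = id, sire_id = sire, dam_id = dam, sex = sex,
             line = line, generation = generation,
             stringsAsFactors = FALSE)
}

# n unrelated founder families, each with one male and one female offspring
founder_families <- function(n_fam) {
  rows <- list()
  for (f in seq_len(n_fam)) {
    s <- sprintf("s%d", f); d <- sprintf("d%d", f)
    rows[[length(rows) + 1]] <- ped_row(s, sex = "M")
    rows[[length(rows) + 1]] <- ped_row(d, sex = "F")
    rows[[length(rows) + 1]] <-
      ped_row(sprintf("m%d", f), s, d, sex = "M", generation = 1)
    rows[[length(rows) + 1]] <-
      ped_row(sprintf("f%d", f), s, d, sex = "F", generation = 1)
  }
  pedigree(do.call(rbind, rows))
}

# Exhaustive enumeration of all full-sib-free pairings of the given males
# and females; returns the minimal achievable median offspring inbreeding.
# Independent brute-force oracle for propose_pairs.
min_median_offspring_f <- function(males, females, ped) {
  A <- additive_relationship(ped)
  pr <- as.data.frame(ped)
  full_sibs <- function(a, b) {
    ia <- match(a, pr$id); ib <- match(b, pr$id)
    if (is.na(pr$sire_id[ia]) || is.na(pr$sire_id[ib])) return(FALSE)
    pr$sire_id[ia] == pr$sire_id[ib] && pr$dam_id[ia] == pr$dam_id[ib]
  }
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  best <- Inf
  for (p in perms(females)) {
    ok <- TRUE
    for (i in seq_along(males)) {
      if (full_sibs(males[i], p[i])) { ok <- FALSE; break }
    }
    if (!ok) next
    fvals <- A[cbind(males, p)] / 2
    best <- min(best, stats::median(fvals))
  }
  best
}
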
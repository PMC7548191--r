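# CSV interfaces for experiment tables and pedigrees. All outputs are
# plain CSV; a sidecar metadata file records the seed and configuration.

#' Write all experiment tables to a directory
#'
#' Emits `fish.csv`, `clutches.csv`, `eggs.csv`, `survival.csv`,
#' `hormones.csv`, `pedigree.csv`, `differentials.csv`,
#' `mean_inbreeding.csv` and a `run_metadata.txt` sidecar (seed,
#' configuration, package version).
#'
#' @param experiment a `medaka_experiment`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_experiment_tables <- function(experiment, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    if (!is.null(df)) {
      utils::write.csv(df, file.path(dir, paste0(name, ".csv")),
                       row.names = FALSE)
    }
  }
  w(experiment$tables$fish, "fish")
  w(experiment$tables$clutches, "clutches")
  w(experiment$tables$eggs, "eggs")
  w(experiment$tables$survival, "survival")
  w(experiment$tables$hormones, "hormones")
  w(as.data.frame(experiment$pedigree), "pedigree")
  w(experiment$differentials, "differentials")
  w(experiment$mean_inbreeding, "mean_inbreeding")
  cfg <- experiment$config
  meta <- c(
    sprintf("seed: %d", cfg$seed),
    sprintf("package_version: %s",
            as.character(utils::packageVersion("medakasel"))),
    sprintf("n_generations: %d", cfg$n_generations),
    sprintf("n_pairs_per_line: %d", cfg$n_pairs_per_line),
    sprintf("families_kept: %d", cfg$families_kept),
    sprintf("prephase: %s", cfg$prephase),
    sprintf("config_hash: %s",
            paste(utils::head(abs(utils::head(
              as.integer(charToRaw(paste(deparse(cfg), collapse = ""))),
              64)), 8), collapse = ""))
  )
  writeLines(meta, file.path(dir, "run_metadata.txt"))
  invisible(dir)
}

#' Read experiment tables from a directory
#'
#' @param dir directory written by [write_experiment_tables()].
#' @return list with `tables` (fish, clutches, eggs, survival, hormones)
#'   and, when present, `pedigree`, `differentials`, `mean_inbreeding`.
#' @export
read_experiment_tables <- function(dir) {
  r <- function(name) {
    path <- file.path(dir, paste0(name, ".csv"))
    if (!file.exists(path)) return(NULL)
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  out <- list(tables = list(
    fish = r("fish"), clutches = r("clutches"), eggs = r("eggs"),
    survival = r("survival"), hormones = r("hormones")
  ))
  ped <- r("pedigree")
  if (!is.null(ped)) out$pedigree <- pedigree(ped)
  out$differentials <- r("differentials")
  out$mean_inbreeding <- r("mean_inbreeding")
  out
}

#' Read a pedigree CSV
#'
#' Expected columns: `id`, `sire_id`, `dam_id`, `sex`, `line`,
#' `generation`; empty strings or NA mark founders.
#'
#' @param path CSV file path.
#' @return a validated [pedigree()].
#' @export
read_pedigree_csv <- function(path) {
  pedigree(utils::read.csv(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", "")))
}

#' Write a pedigree CSV with kinship and inbreeding columns
#'
#' Writes the pedigree with two derived columns appended:
#' `kinship_self` and `inbreeding` (computed as `2 * kinship_self - 1`).
#'
#' @param ped a [pedigree()].
#' @param path output CSV path.
#' @return the inbreeding table, invisibly.
#' @export
write_pedigree_csv <- function(ped, path) {
  ki <- kinship_and_inbreeding(ped)
  out <- cbind(as.data.frame(ped),
               kinship_self = ki$kinship_self[match(ped$id, ki$id)],
               inbreeding = ki$inbreeding[match(ped$id, ki$id)])
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(out)
}
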
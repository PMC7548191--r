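#!/usr/bin/env Rscript
# Final report: the 14-trait x 2-line effect-size table (raw line
# contrasts and covariate-corrected model effects, Bonferroni cutoff
# 0.05/28) and the natural-selection fitness regressions on mean parental
# length with prediction grids.

library(medakasel)

run <- read_experiment_tables("results/tables")
fits <- readRDS("results/fits.rds")
seed <- as.integer(Sys.getenv("MEDAKASEL_SEED", "1"))

tab <- effect_size_table(fits, run$tables)
cat(sprintf("Effect-size report (alpha = %.4g):\n", tab$alpha[1]))
print(tab[, c("trait_label", "line", "raw", "corrected", "mcmc_p",
              "significant")],
      row.names = FALSE, digits = 3)
write.csv(tab, "results/effect_sizes.csv", row.names = FALSE)

# reconstruct the experiment object columns pair_fitness_table needs
ex_like <- list(tables = run$tables)
class(ex_like) <- "medaka_experiment"
pairs <- pair_fitness_table(ex_like)
grid_lengths <- seq(floor(min(pairs$parent_sdl)),
                    ceiling(max(pairs$parent_sdl)), by = 0.25)
for (component in c("fecundity", "hatch_rate", "progeny_75dph",
                    "progeny_kept")) {
  res <- fitness_regression(component, pairs, seed = seed)
  cat(sprintf(
    "%-14s linear %+.3f [%+.3f, %+.3f]  quadratic %+.4f [%+.4f, %+.4f]\n",
    component, res$linear$estimate, res$linear$lower, res$linear$upper,
    res$quadratic$estimate, res$quadratic$lower, res$quadratic$upper))
  grid <- fitness_prediction_grid(res, grid_lengths)
  write.csv(grid, sprintf("results/fitness_%s.csv", component),
            row.names = FALSE)
}
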
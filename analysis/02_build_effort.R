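#!/usr/bin/env Rscript
# Rebuild the reporting-effort layer from the raw toponym match table written
# by 01_simulate.R: per-article weight normalisation, summation to the grid,
# then Poisson boosted-tree smoothing/imputation on socioeconomic covariates.
# Demonstrates the effort pipeline on its own inputs and writes the raw and
# smoothed layers under results/effort/.
suppressMessages(library(eidhotspots))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[[1]]) else 1L

world_dir <- file.path("results", "world")
if (!dir.exists(world_dir)) stop("run analysis/01_simulate.R first")

config <- synth_config(seed = seed)
world <- gen_world(config)  # regenerate for the grid and covariates
matches <- read_match_table(file.path(world_dir, "matches.csv"))

raw <- aggregate_matches(matches, world$grid)
eff <- smooth_effort(raw, world$predictors,
                     covariate_names = c("human_population", "urban", "gens"),
                     seed = seed)
print(eff)

out <- file.path("results", "effort")
dir.create(out, recursive = TRUE, showWarnings = FALSE)
write_layers_csv(list(eff$raw, eff$smoothed), world$grid,
                 file.path(out, "effort_layers.csv"))

land <- world$grid$land_mask
message(sprintf("raw mass %.1f over %d articles; smoothed > 0 on all %d land cells: %s",
                sum(raw$values), length(unique(matches$article_id)),
                sum(land), all(eff$smoothed$values[land] > 0)))
message(sprintf("zero raw cells imputed: %d of %d land cells",
                sum(raw$values[land] == 0), sum(land)))
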
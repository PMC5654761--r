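#!/usr/bin/env Rscript
# The reporting-bias algebra on the fitted ensemble: the response map
# (risk relative to effort), the observed risk index (response x effort),
# and the bias-corrected risk index (observed x population / effort =
# response x population). Renders standard-deviation-scaled heat maps and
# compares both indices against the generative true risk. Requires
# 03_fit_ensemble.R to have written results/ensemble/response.csv.
suppressMessages(library(eidhotspots))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[[1]]) else 1L

world <- gen_world(synth_config(seed = seed))
resp_path <- file.path("results", "ensemble", "response.csv")
if (!file.exists(resp_path)) stop("run analysis/03_fit_ensemble.R first")
response <- read_layers_csv(resp_path, world$grid)[[1]]

effort <- world$effort$smoothed
population <- get_layer(world$predictors, "human_population", 2000L)
observed <- observed_index(response, effort)
bias <- reporting_bias(effort, population)
corrected <- corrected_index(observed, population, effort,
                             floor = world$effort$floor)

out <- file.path("results", "maps")
dir.create(out, recursive = TRUE, showWarnings = FALSE)
for (m in list(response, observed, bias, corrected))
  render_map(m, world$grid,
             png_path = file.path(out, paste0(m$name, ".png")),
             csv_path = file.path(out, paste0(m$name, "_scaled.csv")))
write_layers_csv(list(observed, bias, corrected), world$grid,
                 file.path(out, "risk_indices.csv"))

ok <- !is.na(corrected$values)
tv <- world$true_risk$values
sp <- function(x) cor(x[ok], tv[ok], method = "spearman")
message(sprintf("Spearman vs true risk: response %.2f, observed %.2f, corrected %.2f",
                sp(response$values), sp(observed$values),
                sp(corrected$values)))
message(sprintf("bias correction identity |corrected - response*population| max: %.2e",
                max(abs(corrected$values[ok] -
                          response$values[ok] * population$values[ok]))))
message("maps written to ", out)
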
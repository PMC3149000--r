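#!/usr/bin/env Rscript
# Regenerates the text fixtures shipped under inst/extdata/:
#   - the default network and composition files (documented, machine-readable)
#   - 4 synthetic cultivation scenarios (1 A-stat + 3 D-stat) with fixed seeds
# Run from the repository root: Rscript scripts/make-fixtures.R

devtools::load_all(".", quiet = TRUE)

dir.create("inst/extdata", showWarnings = FALSE, recursive = TRUE)

write_network(build_default_network(), "inst/extdata/network_default.tsv")
write_composition_table(default_composition_table(),
                        "inst/extdata/composition_default.tsv")

round_series <- function(s) {
  num <- vapply(s, is.numeric, TRUE)
  s[num] <- lapply(s[num], signif, digits = 7)
  s
}

astat <- generate_scenario(scenario_config("astat", seed = 101L))
write_timeseries(round_series(astat$series), "inst/extdata/astat_synthetic.tsv")

dstat_cfg <- data.frame(D = c(0.10, 0.30, 0.45), cap = c(0.9, 0.5, 0.2),
                        seed = c(201L, 202L, 203L))
for (i in seq_len(nrow(dstat_cfg))) {
  sc <- generate_scenario(scenario_config(
    "dstat", dilution_rate = dstat_cfg$D[i],
    coutilisation_capability = dstat_cfg$cap[i], seed = dstat_cfg$seed[i]))
  write_timeseries(round_series(sc$series),
                   sprintf("inst/extdata/dstat_D%03d_synthetic.tsv",
                           round(100 * dstat_cfg$D[i])))
}
cat("fixtures written to inst/extdata/\n")
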
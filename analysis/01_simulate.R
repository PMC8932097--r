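#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# Emulates the study sample: 83 regions with monthly climate over
# 1981-2019, a region-year outcome panel over 2014-2019 generated from
# the time-varying-coefficient model (truth = the reported coefficient
# paths), and individual 8-item survey responses. 200 respondents per
# region-year keep this demonstration run light; the generator default
# (800, matching the survey's ~411k total interviews) is used in the
# tests.

library(fiesclim)

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20260929 %% 100000L

climate <- simulate_climate(climate_gen_params(seed = seed))
panel <- simulate_panel(climate, panel_gen_params(seed = seed + 1L))
responses <- simulate_fies_responses(panel, respondents_per_region = 200L,
                                     seed = seed + 2L)

write_table_csv(climate, file.path(out, "climate.csv"))
write_table_csv(attr(climate, "regions"), file.path(out, "regions.csv"))
write_table_csv(panel, file.path(out, "panel_true.csv"))
write_table_csv(responses, file.path(out, "responses.csv"))

an <- annual_temperature_anomaly(climate)
m_anom <- mean(an$anomaly[an$year %in% 2014:2019])
message(sprintf("simulated %d regions x %d months of climate", 83L, 39L * 12L))
message(sprintf("mean 2014-2019 temperature anomaly: %.3f degC (study sample: 0.56)",
                m_anom))
message(sprintf("true prevalence ranges: msfi %.1f-%.1f%%, sfi %.1f-%.1f%%",
                min(panel$msfi), max(panel$msfi), min(panel$sfi), max(panel$sfi)))
message(sprintf("%d survey respondents written", nrow(responses)))
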
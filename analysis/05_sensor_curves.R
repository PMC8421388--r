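#!/usr/bin/env Rscript

# Stage 5: equilibrium sensor curves and the stimulation:death statistic.
#
# Evaluates Hill-model dose-response curves for the example sensor registry
# (placeholder Kd/Hill values; see the registry file) and computes the
# stimulation:death response ratio for a physiological Ca2+ transient versus
# a catastrophic rise to extracellular levels: near 0 for a death indicator,
# near 1 for an activity indicator.

suppressMessages(library(gedipipe))

out_dir <- file.path("results", "sensors")
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
registry <- read_sensor_registry(system.file("extdata",
                                             "sensors_example.yaml",
                                             package = "gedipipe"))
ca_grid <- 10^seq(-9, -1, length.out = 161)
curves <- do.call(rbind, lapply(registry, function(s)
  data.frame(sensor = s$name, ca_molar = ca_grid,
             relative_fluorescence = response_curve(s, ca_grid))))
write.csv(curves, file.path(out_dir, "response_curves.csv"),
          row.names = FALSE)
cat("Response curves on", length(ca_grid), "concentrations for",
    length(registry), "sensors ->", file.path(out_dir, "response_curves.csv"),
    "\n")

base_ca <- 5e-8
stim_ca <- c(base_ca, base_ca, 1e-6, 1e-6, base_ca)     # transient to 1 uM
death_ca <- c(base_ca, base_ca, 5e-4, 1.5e-3, 2e-3)     # rise to ~2 mM
ratios <- vapply(registry, function(s) {
  offset <- 0.05
  stim <- fluorescence_trace(1:5, offset + hill_fluorescence(s, stim_ca),
                             baseline_window = 1:2)
  death <- fluorescence_trace(1:5, offset + hill_fluorescence(s, death_ca),
                              baseline_window = 1:2)
  stim_death_ratio(stim, death)
}, numeric(1))
tab <- data.frame(sensor = names(ratios), stim_death_ratio = ratios)
write.csv(tab, file.path(out_dir, "stim_death_ratios.csv"),
          row.names = FALSE)
cat("Stimulation:death response ratios:\n")
print(tab, row.names = FALSE)
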
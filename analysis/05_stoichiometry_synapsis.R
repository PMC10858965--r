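#!/usr/bin/env Rscript
# Synapsis-aligned Lig4 stoichiometry and the pre-synapsis dissociation
# statistic from the default three-color simulation: step-normalized Cy7
# traces aligned at detected synapsis (t = 0), median over Cy7-present
# trajectories per one-second bin.

suppressMessages(library(nhejfret))
dir.create("results", showWarnings = FALSE)
n_mol <- 2500

sch <- scheme_three_color()
truth <- simulate_state_paths(kinetic_preset("wt"), sch, n_mol, seed = 81)
ts <- render_trajectories(truth, photophysics_model(), sch, seed = 82)
r <- analyze_three_color(ts)

al <- r$alignment
trace <- data.frame(time_to_synapsis = al$time, median_stoichiometry = al$median,
                    n_present = al$n)
write.csv(trace, "results/stoichiometry_alignment.csv", row.names = FALSE)

message(sprintf("aligned synapsis events: %d", al$n_events))
message(sprintf("median stoichiometry, -10..-5 s window : %.2f", r$stoich_presyn_median))
message(sprintf("median stoichiometry at t = 0          : %.2f", r$stoich_t0_median))
message(sprintf("synapsis events with a Cy7 down-step in the prior 10 s: %.1f%% [%.1f, %.1f]",
                r$dissociation$percent, r$dissociation$ci95[1], r$dissociation$ci95[2]))
write_results(list(n_events = al$n_events,
                   stoich_presyn_median = r$stoich_presyn_median,
                   stoich_t0_median = r$stoich_t0_median,
                   dissociation = r$dissociation),
              "results/stoichiometry_summary.json")
message("wrote results/stoichiometry_alignment.csv, results/stoichiometry_summary.json")
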
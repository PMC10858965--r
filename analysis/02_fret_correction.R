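#!/usr/bin/env Rscript
# Demultiplex and correct the three-color container from 01, compute
# apparent FRET efficiencies, and summarize the corrected signal levels of
# the structural states (unsynapsed baseline vs synapsed high-FRET).

suppressMessages(library(nhejfret))
ts <- read_trajectory_set("results/trajectories_three_color")

rows <- list()
for (i in seq_along(ts$molecules)) {
  st <- demultiplex(ts$molecules[[i]], ts$scheme)
  masks <- masks_from_truth(ts$truth[[i]], st)
  corr <- correct_intensities(st, ts$photo$crosstalk, masks = masks)
  syn <- ts$truth[[i]]$synapsis_time
  tvec <- rowMeans(st$times)
  e35 <- corr$efficiencies$E35
  pre <- is.finite(e35) & (is.na(syn) | tvec < syn)
  post <- is.finite(e35) & !is.na(syn) & tvec > syn
  rows[[i]] <- data.frame(molecule = i, synapsed = !is.na(syn),
                          mean_e35_pre = mean(e35[pre]),
                          mean_e35_post = if (any(post)) mean(e35[post]) else NA,
                          n_valid_cycles = sum(is.finite(e35)))
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/fret_correction_summary.csv", row.names = FALSE)
message("per-molecule corrected E35 summary:")
print(tab, digits = 3)
message(sprintf("pooled pre-synapsis E35 = %.3f; post-synapsis E35 = %.3f",
                mean(tab$mean_e35_pre, na.rm = TRUE),
                mean(tab$mean_e35_post, na.rm = TRUE)))
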
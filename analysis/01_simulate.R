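#!/usr/bin/env Rscript
# Simulate one synthetic "subject" under the full condition matrix:
# C1000 (8 directions, 1 s ISI, jittered), Cr (key-press control, 2 s ISI),
# C300 / C175 (5-direction BCI conditions) and C300s (single-speaker
# control, no spatial cue -> attention components absent).
#
# Continuous signals go to scratch/ as EDF+ with tab-separated marker
# tables; summary counts go to results/simulation_counts.tsv.

suppressMessages(library(audiobci))

dir.create("scratch/data", recursive = TRUE, showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

seed0 <- 20260925L
conditions <- c("C1000", "C300", "C175", "C300s")
counts <- list()

for (i in seq_along(conditions)) {
  cond <- conditions[i]
  cfg <- condition_preset(cond, seed = seed0 + i)
  seq_ <- generate_sequence(cond, n_trials = cfg$n_trials, seed = cfg$seed)
  rec <- simulate_recording(seq_, config_templates(cfg), config_noise(cfg),
                            seed = cfg$seed + 1L)
  write_edf(rec, sprintf("scratch/data/%s.edf", cond))
  write_markers(seq_, sprintf("scratch/data/%s_markers.tsv", cond))
  write_config(cfg, sprintf("scratch/data/%s_config.yaml", cond))
  counts[[cond]] <- data.frame(
    condition = cond, trials = cfg$n_trials,
    subtrials = nrow(seq_),
    minutes = round(ncol(rec$signal) / rec$rate / 60, 1),
    min_gap = min_direction_gap(seq_))
  message(sprintf("%-6s %4d trials, %5d subtrials, %5.1f min of signal",
                  cond, cfg$n_trials, nrow(seq_), counts[[cond]]$minutes))
  rm(rec); gc(verbose = FALSE)
}

# key-press condition: behaviour only, no EEG needed. Seven simulated
# subjects, as the behavioural tables pool subjects before normalizing
# false-alarm rates.
n_subjects <- 7L
tot_sub <- 0L; tot_press <- 0L
for (vp in seq_len(n_subjects)) {
  cfg_cr <- condition_preset("Cr", seed = seed0 + 10L * vp)
  seq_cr <- generate_sequence("Cr", n_trials = cfg_cr$n_trials, seed = cfg_cr$seed)
  resp <- simulate_key_responses(seq_cr, seed = cfg_cr$seed + 1L)
  write_markers(seq_cr, sprintf("scratch/data/Cr_markers_s%d.tsv", vp))
  write.table(resp, sprintf("scratch/data/Cr_responses_s%d.tsv", vp),
              sep = "\t", quote = FALSE, row.names = FALSE)
  tot_sub <- tot_sub + nrow(seq_cr); tot_press <- tot_press + nrow(resp)
}
counts$Cr <- data.frame(condition = "Cr", trials = n_subjects * 8L,
                        subtrials = tot_sub, minutes = NA, min_gap = NA)
message(sprintf("Cr     %d simulated subjects, %5d subtrials, %d key presses",
                n_subjects, tot_sub, tot_press))

tab <- do.call(rbind, counts)
write.table(tab, "results/simulation_counts.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("C300 spans ", tab["C300", "subtrials"], " subtrials; C175 ",
        tab["C175", "subtrials"], "; C300s ", tab["C300s", "subtrials"],
        "; C1000 ", tab["C1000", "subtrials"], ".")
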
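#!/usr/bin/env Rscript
# Turn classifier scores into the study's endpoint tables:
#  - selection-accuracy curves P(k) over iteration counts k,
#  - information-transfer rates with max-ITR under 70% / 90% constraints,
#  - key-press behavioural scores (overall, per direction) and the
#    neighbour-vs-other false-alarm normalization.
#
# Outputs: results/selection_itr_<cond>.tsv, results/itr_summary.tsv,
# results/key_response_scores.tsv, results/key_response_by_direction.tsv,
# results/neighbor_fa_rates.tsv.

suppressMessages(library(audiobci))

conditions <- c("C1000", "C300", "C175", "C300s")
fmt_cell <- function(m) if (is.na(m$k)) "- (-)" else
  sprintf("%.2f (%d)", m$bits_per_minute, m$k)
rows <- list()

for (cond in conditions) {
  cv <- readRDS(sprintf("scratch/data/%s_cv.rds", cond))
  cfg <- read_config(sprintf("scratch/data/%s_config.yaml", cond))
  tsc <- trial_scores(cv, n_directions = cfg$n_directions)
  curve <- selection_curve(tsc, max_k = cfg$n_per_direction)
  itr <- itr_report(curve, N = cfg$n_directions, isi_ms = cfg$isi_ms)
  write.table(itr$series, sprintf("results/selection_itr_%s.tsv", cond),
              sep = "\t", quote = FALSE, row.names = FALSE)
  best_k <- which.max(curve$accuracy)
  thresh70 <- which(curve$accuracy >= 0.7)[1]
  rows[[cond]] <- data.frame(
    condition = cond,
    max_selection_pct = round_half_up(100 * max(curve$accuracy), 2),
    k_at_max = best_k,
    k_reaching_70pct = ifelse(is.na(thresh70), "-", thresh70),
    max_itr_70 = fmt_cell(itr$max_itr_70),
    max_itr_90 = fmt_cell(itr$max_itr_90))
  message(sprintf("%-6s max selection %6.2f%% (k=%d); max ITR 70%%: %s; 90%%: %s",
                  cond, 100 * max(curve$accuracy), best_k,
                  fmt_cell(itr$max_itr_70), fmt_cell(itr$max_itr_90)))
}
write.table(do.call(rbind, rows), "results/itr_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# behavioural control condition: score each simulated subject, then pool
per_subject <- list(); per_dir <- list(); confusions <- list(); n_targets <- 0L
for (vp in 1:7) {
  seq_cr <- read_markers(sprintf("scratch/data/Cr_markers_s%d.tsv", vp))
  resp <- read.delim(sprintf("scratch/data/Cr_responses_s%d.tsv", vp))
  ks <- score_key_responses(seq_cr, resp)
  per_subject[[vp]] <- cbind(subject = sprintf("S%d", vp), ks$counts)
  per_dir[[vp]] <- ks$per_direction
  confusions[[vp]] <- ks$confusions
  n_targets <- n_targets + ks$n_targets
}
subj_tab <- do.call(rbind, per_subject)
write.table(subj_tab, "results/key_response_scores.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
dir_tab <- do.call(rbind, per_dir)
dir_pool <- aggregate(cbind(hits, false_alarms, misses) ~ direction, dir_tab, sum)
dir_pool$error_pct <- round_half_up(
  key_response_error(dir_pool$hits, dir_pool$false_alarms, dir_pool$misses), 1)
write.table(dir_pool, "results/key_response_by_direction.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
conf_pool <- do.call(rbind, confusions)
ks <- list(counts = data.frame(
  hits = sum(subj_tab$hits), false_alarms = sum(subj_tab$false_alarms),
  misses = sum(subj_tab$misses),
  error_pct = key_response_error(sum(subj_tab$hits), sum(subj_tab$false_alarms),
                                 sum(subj_tab$misses))))
nb <- neighbor_fa_rates(conf_pool, n_directions = 8, n_targets = n_targets)
write.table(data.frame(p_neighbor_pct = round_half_up(nb$p_neighbor_pct, 2),
                       p_other_pct = round_half_up(nb$p_other_pct, 2),
                       n_neighbor = nb$n_neighbor, n_other = nb$n_other,
                       n_targets = nb$n_targets),
            "results/neighbor_fa_rates.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("Key response: %d hits, %d FA, %d misses -> error %.1f%%; FA rate %.2f%% on neighbours vs %.2f%% elsewhere",
                ks$counts$hits, ks$counts$false_alarms, ks$counts$misses,
                ks$counts$error_pct, nb$p_neighbor_pct, nb$p_other_pct))
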
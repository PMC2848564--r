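#' Condition presets
#'
#' The full parameter matrix of the five experimental conditions, one
#' structured configuration per condition:
#' \tabular{lccccc}{
#'   \tab directions \tab reps/direction \tab trials \tab ISI (ms) \tab jitter \cr
#'   C1000 \tab 8 \tab 10 \tab 32 \tab 1000 \tab 25/14.4 ms \cr
#'   Cr    \tab 8 \tab 10 \tab 8  \tab 2000 \tab 25/14.4 ms \cr
#'   C300  \tab 5 \tab 15 \tab 50 \tab 300  \tab none \cr
#'   C175  \tab 5 \tab 15 \tab 40 \tab 175  \tab none \cr
#'   C300s \tab 5 \tab 15 \tab 20 \tab 300  \tab none \cr
#' }
#' C300 therefore spans 3750 subtrials, C175 3000, C300s 1500 and C1000
#' 2560. The single-speaker control C300s is emulated with
#' `attention_scale = 0`: without the spatial cue the attended direction
#' leaves no reliable class difference in the ERP for a typical subject.
#' ERP signal-to-noise is not a published quantity; the template amplitudes
#' follow the measured grand-average peaks and the noise level is a free
#' parameter of the generator.
#'
#' @param condition preset name.
#' @param ... overrides for any preset field (e.g. `n_trials`, `noise`).
#' @return list of class `condition_config`.
#' @examples
#' cfg <- condition_preset("C300", n_trials = 10)
#' @export
condition_preset <- function(condition = c("C1000", "Cr", "C300", "C175", "C300s"),
                             ...) {
  condition <- match.arg(condition)
  base <- switch(condition,
    C1000 = list(n_directions = 8L, n_per_direction = 10L, n_trials = 32L,
                 isi_ms = 1000, jitter_mean = 25, jitter_sd = 14.4,
                 attention_scale = 1),
    Cr    = list(n_directions = 8L, n_per_direction = 10L, n_trials = 8L,
                 isi_ms = 2000, jitter_mean = 25, jitter_sd = 14.4,
                 attention_scale = 1),
    C300  = list(n_directions = 5L, n_per_direction = 15L, n_trials = 50L,
                 isi_ms = 300, jitter_mean = 0, jitter_sd = 0,
                 attention_scale = 1),
    C175  = list(n_directions = 5L, n_per_direction = 15L, n_trials = 40L,
                 isi_ms = 175, jitter_mean = 0, jitter_sd = 0,
                 attention_scale = 1),
    C300s = list(n_directions = 5L, n_per_direction = 15L, n_trials = 20L,
                 isi_ms = 300, jitter_mean = 0, jitter_sd = 0,
                 attention_scale = 0)
  )
  cfg <- c(list(condition = condition), base,
           list(threshold_uv = 70, cv_folds = 10L, n_pos = 10L, n_neg = 10L,
                p300_amplitude = 10, p300_latency = 430,
                n2_amplitude = -5, n2_latency = 200,
                evoked_amplitude = 3,
                noise_background_sd = 18, noise_ar_coef = 0.97,
                noise_line_amplitude = 5, noise_blink_rate = 4,
                noise_blink_amplitude = 120,
                seed = 1L))
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  .validate_config(cfg)
  structure(cfg, class = "condition_config")
}

.preset_invariants <- list(
  C1000 = list(n_directions = 8L, n_per_direction = 10L, isi_ms = 1000),
  Cr    = list(n_directions = 8L, n_per_direction = 10L, isi_ms = 2000),
  C300  = list(n_directions = 5L, n_per_direction = 15L, isi_ms = 300),
  C175  = list(n_directions = 5L, n_per_direction = 15L, isi_ms = 175),
  C300s = list(n_directions = 5L, n_per_direction = 15L, isi_ms = 300)
)

.validate_config <- function(cfg) {
  stopifnot(cfg$n_trials >= 1, cfg$isi_ms > 0, cfg$threshold_uv > 0,
            cfg$cv_folds >= 2, cfg$jitter_sd >= 0)
  inv <- .preset_invariants[[cfg$condition]]
  for (f in names(inv)) {
    if (!isTRUE(all.equal(cfg[[f]], inv[[f]], check.attributes = FALSE))) {
      warning("config field ", f, " = ", cfg[[f]],
              " deviates from the ", cfg$condition, " condition value ", inv[[f]])
    }
  }
  invisible(cfg)
}

#' Serialize / load a condition configuration (YAML)
#'
#' @param config a [condition_preset()] list.
#' @param path file path.
#' @return the path, or the restored `condition_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  int_fields <- c("n_directions", "n_per_direction", "n_trials", "cv_folds",
                  "n_pos", "n_neg", "seed")
  for (f in int_fields) cfg[[f]] <- as.integer(cfg[[f]])
  .validate_config(cfg)
  structure(cfg, class = "condition_config")
}

#' Templates and noise model implied by a configuration
#' @param config a `condition_config`.
#' @return an [erp_templates()] / [noise_spec()] object.
#' @export
config_templates <- function(config) {
  erp_templates(p300_amplitude = config$p300_amplitude,
                p300_latency = config$p300_latency,
                n2_amplitude = config$n2_amplitude,
                n2_latency = config$n2_latency,
                evoked_amplitude = config$evoked_amplitude,
                attention_scale = config$attention_scale,
                jitter_mean = config$jitter_mean,
                jitter_sd = config$jitter_sd)
}

#' @rdname config_templates
#' @export
config_noise <- function(config) {
  noise_spec(background_sd = config$noise_background_sd,
             ar_coef = config$noise_ar_coef,
             line_amplitude = config$noise_line_amplitude,
             blink_rate = config$noise_blink_rate,
             blink_amplitude = config$noise_blink_amplitude)
}

#' Run the full offline pipeline for one condition
#'
#' simulate -> preprocess -> decode -> evaluate, deterministic given
#' `config$seed`. For the decoding conditions the result carries the
#' cross-validation summary, the selection curve and the ITR report; for
#' the key-press condition (`Cr`) it carries the behavioural score tables
#' instead.
#'
#' @param config a [condition_preset()].
#' @param out_dir optional directory; when given, report tables are written
#'   as tab-separated files (`markers.tsv`, `rejection.tsv`, `cv_scores.tsv`,
#'   `selection_itr.tsv` or `key_responses.tsv`).
#' @param montage channel table.
#' @return list of class `pipeline_result` with elements `config`,
#'   `sequence`, `rejection`, and either (`cv`, `curve`, `itr`) or
#'   (`responses`, `key_scores`).
#' @export
run_pipeline <- function(config, out_dir = NULL, montage = default_montage()) {
  seed <- config$seed
  seq_ <- generate_sequence(config$condition, n_trials = config$n_trials,
                            n_directions = config$n_directions,
                            n_per_direction = config$n_per_direction,
                            isi_ms = config$isi_ms, seed = seed)
  out <- list(config = config, sequence = seq_)

  if (config$condition == "Cr") {
    out$responses <- simulate_key_responses(seq_, seed = seed + 1L)
    out$key_scores <- score_key_responses(seq_, out$responses)
    out$neighbor_rates <- neighbor_fa_rates(
      out$key_scores$confusions, n_directions = config$n_directions,
      n_targets = out$key_scores$n_targets)
  } else {
    rec <- simulate_recording(seq_, config_templates(config),
                              config_noise(config), montage = montage,
                              seed = seed + 1L)
    ep <- preprocess(rec, threshold_uv = config$threshold_uv)
    out$rejection <- ep$rejection
    out$cv <- crossvalidate(ep, k = config$cv_folds,
                            n_pos = config$n_pos, n_neg = config$n_neg)
    tsc <- trial_scores(out$cv, n_directions = config$n_directions)
    out$curve <- selection_curve(tsc, max_k = config$n_per_direction)
    out$itr <- itr_report(out$curve, N = config$n_directions,
                          isi_ms = config$isi_ms)
  }

  if (!is.null(out_dir)) .write_pipeline_tables(out, out_dir)
  class(out) <- "pipeline_result"
  out
}

.write_pipeline_tables <- function(out, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  w(as.data.frame(out$sequence), "markers.tsv")
  if (!is.null(out$cv)) {
    w(data.frame(condition = out$config$condition,
                 n_rejected = out$rejection$n_rejected,
                 n_total = out$rejection$n_total,
                 pct = out$rejection$pct), "rejection.tsv")
    w(out$cv$scores, "cv_scores.tsv")
    w(out$itr$series, "selection_itr.tsv")
  }
  if (!is.null(out$key_scores)) {
    w(out$key_scores$counts, "key_responses.tsv")
    w(out$key_scores$per_direction, "key_responses_by_direction.tsv")
  }
  invisible(out_dir)
}
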
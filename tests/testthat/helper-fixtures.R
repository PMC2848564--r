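# Shared fixtures: all synthetic, built in code.

# Small montage (>= 20 selectable channels not required everywhere; tests
# that exercise 10+10 selection use the full default_montage()).
tiny_montage <- function() {
  data.frame(
    label = c("F1", "F2", "C1", "C2", "P1", "P2", "EOG1"),
    role = c("frontal", "frontal", "central", "central", "parietal",
             "parietal", "ocular")
  )
}

quiet_noise <- function() {
  noise_spec(background_sd = 0, line_amplitude = 0, blink_rate = 0)
}

# Deterministic epoch set built directly (no simulation): n_trials trials of
# one iteration block each, direction-major order, at 100 Hz with the
# standard 95-sample window. `signal_fun(is_target)` returns a channel x 95
# matrix added on top of iid noise.
make_epochs <- function(n_trials = 10, n_directions = 5, n_iterations = 6,
                        montage = tiny_montage(), noise_sd = 1,
                        signal_fun = NULL, seed = 42) {
  set.seed(seed)
  n_ch <- nrow(montage)
  rows <- list()
  data <- list()
  for (tr in seq_len(n_trials)) {
    target <- sample.int(n_directions, 1)
    for (it in seq_len(n_iterations)) {
      for (d in sample.int(n_directions)) {
        ep <- matrix(rnorm(n_ch * 95, 0, noise_sd), n_ch, 95)
        if (!is.null(signal_fun)) ep <- ep + signal_fun(d == target)
        rows[[length(rows) + 1L]] <- data.frame(
          onset_ms = length(rows) * 300, direction = d,
          target_direction = target, is_target = d == target,
          trial_id = tr, iteration_id = it, condition = "C300")
        data[[length(data) + 1L]] <- ep
      }
    }
  }
  info <- do.call(rbind, rows)
  arr <- array(NA_real_, c(length(data), n_ch, 95))
  for (i in seq_along(data)) arr[i, , ] <- data[[i]]
  structure(list(data = arr, info = info, channels = montage,
                 times_ms = seq(-15, 79) * 10, rate = 100, n_baseline = 15,
                 artifact = logical(length(data)),
                 incomplete = logical(length(data))),
            class = "bci_epochs")
}

# Exhaustive pair-count oracle for the signed ROC index: counts wins minus
# losses over all cross-class pairs, ties as zero.
roc_index_pairs <- function(a, b) {
  s <- 0
  for (x in a) for (y in b) s <- s + sign(x - y)
  s / (length(a) * length(b))
}
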
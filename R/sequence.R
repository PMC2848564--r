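#' Condition tags
#'
#' The five experimental conditions of the paradigm:
#' \describe{
#'   \item{C1000}{8-direction oddball, 1000 ms inter-stimulus interval (ISI),
#'     onset latency jitter, mental counting task.}
#'   \item{Cr}{as C1000 but with a 2000 ms ISI and an overt key-press
#'     response to every target stimulus.}
#'   \item{C300}{5-direction BCI condition, 300 ms ISI.}
#'   \item{C175}{5-direction BCI condition, 175 ms ISI.}
#'   \item{C300s}{single-speaker control at 300 ms ISI: spatial information
#'     removed, so attention-dependent ERP components are absent in the
#'     simulation.}
#' }
#' @keywords internal
#' @name conditions
NULL

.bci_conditions <- c("C300", "C175", "C300s")
.all_conditions <- c("C1000", "Cr", .bci_conditions)

#' Generate a constrained pseudo-random stimulus sequence
#'
#' Builds the stimulus stream for one recording session of an auditory
#' oddball condition. Stimuli are organised in iterations: consecutive
#' blocks in which every direction occurs exactly once, in pseudo-random
#' order. For the BCI conditions (`C300`, `C175`, `C300s`) the order is
#' additionally constrained so that at least two other directions separate
#' two presentations of the same direction (a positional gap of at least 3),
#' which limits the overlap of target response windows at short ISIs.
#'
#' Each trial is a block of `n_per_direction` iterations sharing one attended
#' target direction, drawn uniformly per trial.
#'
#' Block orders are drawn by rejection sampling over random permutations
#' (checking the boundary with the previous block); after `max_retries`
#' failed draws a deterministic repair picks the first valid rotation of the
#' sorted direction list. In practice the rejection step succeeds within a
#' handful of draws.
#'
#' @param condition one of `"C1000"`, `"Cr"`, `"C300"`, `"C175"`, `"C300s"`.
#' @param n_trials number of trials (one target selection each).
#' @param n_directions number of speaker directions (5 for the BCI
#'   conditions, 8 for `C1000`/`Cr`).
#' @param n_per_direction stimulus repetitions per direction within a trial
#'   (the number of iterations).
#' @param isi_ms onset-to-onset inter-stimulus interval in ms.
#' @param trial_gap_ms extra silent gap between trials in ms.
#' @param start_ms recording lead-in before the first stimulus in ms (keeps
#'   the first epoch's baseline inside the recording).
#' @param seed integer seed; the sequence is reproducible given the seed.
#' @param max_retries rejection-sampling cap per iteration block.
#'
#' @return A `data.frame` of class `bci_sequence` with one row per stimulus:
#'   `onset_ms`, `direction`, `target_direction`, `is_target`, `trial_id`,
#'   `iteration_id`, `condition`; attributes `n_directions` and `isi_ms`.
#' @examples
#' s <- generate_sequence("C300", n_trials = 2, seed = 1)
#' nrow(s)            # 2 trials x 75 subtrials
#' table(s$direction) # each direction 15x per trial
#' @export
generate_sequence <- function(condition = c("C1000", "Cr", "C300", "C175", "C300s"),
                              n_trials,
                              n_directions = if (condition %in% .bci_conditions) 5L else 8L,
                              n_per_direction = if (condition %in% .bci_conditions) 15L else 10L,
                              isi_ms = switch(condition,
                                C1000 = 1000, Cr = 2000, C300 = 300,
                                C175 = 175, C300s = 300),
                              trial_gap_ms = 2000,
                              start_ms = 1000,
                              seed = NULL,
                              max_retries = 10000L) {
  condition <- match.arg(condition)
  stopifnot(n_trials >= 1, n_per_direction >= 1, isi_ms > 0)
  min_gap <- if (condition %in% .bci_conditions) 3L else 1L
  if (min_gap > 1L && n_directions < 4L) {
    stop("minimum-separation constraint is not satisfiable in a non-degenerate ",
         "way with fewer than 4 directions")
  }
  if (n_directions < 2L) stop("need at least 2 directions")
  if (!is.null(seed)) set.seed(seed)

  rows <- vector("list", n_trials)
  onset0 <- start_ms
  for (tr in seq_len(n_trials)) {
    target <- sample.int(n_directions, 1L)
    dirs <- integer(0)
    iters <- integer(0)
    for (it in seq_len(n_per_direction)) {
      tail_prev <- utils::tail(dirs, min_gap - 1L)
      blk <- .draw_block(n_directions, tail_prev, min_gap, max_retries)
      dirs <- c(dirs, blk)
      iters <- c(iters, rep.int(it, n_directions))
    }
    n_sub <- length(dirs)
    onsets <- onset0 + (seq_len(n_sub) - 1L) * isi_ms
    rows[[tr]] <- data.frame(
      onset_ms = onsets,
      direction = dirs,
      target_direction = target,
      is_target = dirs == target,
      trial_id = tr,
      iteration_id = iters,
      condition = condition
    )
    onset0 <- onsets[n_sub] + isi_ms + trial_gap_ms
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_directions") <- as.integer(n_directions)
  attr(out, "isi_ms") <- isi_ms
  class(out) <- c("bci_sequence", "data.frame")
  out
}

# One iteration block: permutation of 1..D respecting the positional gap
# with the tail of the previous block. For min_gap = 3 the only possible
# violations sit at the block boundary (a block has no repeats internally).
.draw_block <- function(D, tail_prev, min_gap, max_retries) {
  if (min_gap <= 1L || length(tail_prev) == 0L) {
    return(sample.int(D))
  }
  for (i in seq_len(max_retries)) {
    blk <- sample.int(D)
    if (.boundary_ok(blk, tail_prev, min_gap)) return(blk)
  }
  # deterministic repair: first valid rotation of the identity permutation
  base <- seq_len(D)
  for (r in 0:(D - 1L)) {
    blk <- c(base[(r + 1L):D], base[seq_len(r)])
    if (.boundary_ok(blk, tail_prev, min_gap)) return(blk)
  }
  stop("could not construct an iteration block satisfying the separation constraint")
}

.boundary_ok <- function(blk, tail_prev, min_gap) {
  k <- length(tail_prev)
  for (i in seq_len(min(min_gap - 1L, length(blk)))) {
    for (j in seq_len(k)) {
      # positional distance between tail_prev[j] and blk[i] is i + k - j
      if (i + k - j < min_gap && blk[i] == tail_prev[j]) return(FALSE)
    }
  }
  TRUE
}

#' Check the direction-separation constraint of a stimulus sequence
#'
#' Scans the direction stream of each trial and returns the minimal
#' positional gap between two presentations of the same direction.
#'
#' @param sequence a [generate_sequence()] result.
#' @return integer: the smallest index difference between equal directions
#'   within a trial.
#' @export
min_direction_gap <- function(sequence) {
  gaps <- vapply(split(sequence$direction, sequence$trial_id), function(d) {
    idx <- split(seq_along(d), d)
    g <- vapply(idx, function(i) if (length(i) > 1L) min(diff(i)) else length(d), 1)
    min(g)
  }, 1)
  as.integer(min(gaps))
}

#' Simulate overt key-press responses for the behavioural control condition
#'
#' For condition `Cr` subjects press a key after every attended target
#' stimulus. The sensitivity model gives a hit probability for targets, a
#' confusion (false-alarm) probability for non-targets directly neighbouring
#' the target on the circular speaker layout, a confusion probability for the
#' remaining non-targets, and a reaction-time distribution (normal, truncated
#' at 0) for the latency of each press relative to stimulus onset.
#'
#' @param sequence a [generate_sequence()] result (condition `Cr`).
#' @param model list with `p_hit`, `p_neighbor`, `p_other` (probabilities)
#'   and `rt_mean`, `rt_sd` (ms).
#' @param seed integer seed.
#' @return `data.frame` with one row per key press: `time_ms`,
#'   `stimulus_index` (row of `sequence` that elicited it), `direction`.
#' @export
simulate_key_responses <- function(sequence,
                                   model = key_response_model(),
                                   seed = NULL) {
  p <- c(model$p_hit, model$p_neighbor, model$p_other)
  if (any(p < 0 | p > 1)) stop("response probabilities must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  D <- attr(sequence, "n_directions")
  dist <- .circular_distance(sequence$direction, sequence$target_direction, D)
  prob <- ifelse(sequence$is_target, model$p_hit,
                 ifelse(dist == 1L, model$p_neighbor, model$p_other))
  press <- stats::runif(nrow(sequence)) < prob
  idx <- which(press)
  rt <- .rtruncnorm_pos(length(idx), model$rt_mean, model$rt_sd)
  data.frame(
    time_ms = sequence$onset_ms[idx] + rt,
    stimulus_index = idx,
    direction = sequence$direction[idx]
  )
}

#' Default key-press sensitivity model
#'
#' Hit and confusion probabilities in the range reported for attentive
#' healthy listeners: near-perfect target detection, confusions concentrated
#' on the two direct neighbours of the attended direction, reaction times
#' around 460 +/- 140 ms.
#'
#' @param p_hit probability of responding to a target.
#' @param p_neighbor false-alarm probability for a direct neighbour.
#' @param p_other false-alarm probability for the remaining directions.
#' @param rt_mean,rt_sd reaction-time mean and SD in ms.
#' @return list usable by [simulate_key_responses()].
#' @export
key_response_model <- function(p_hit = 0.97, p_neighbor = 0.0122,
                               p_other = 0.0066, rt_mean = 460, rt_sd = 140) {
  list(p_hit = p_hit, p_neighbor = p_neighbor, p_other = p_other,
       rt_mean = rt_mean, rt_sd = rt_sd)
}

.circular_distance <- function(a, b, D) {
  d <- abs(a - b) %% D
  pmin(d, D - d)
}

.rtruncnorm_pos <- function(n, mean, sd) {
  if (n == 0L) return(numeric(0))
  if (sd <= 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < 0)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < 0]
  }
  x
}
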
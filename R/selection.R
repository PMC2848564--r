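#' Per-trial direction x iteration score matrices
#'
#' Rearranges cross-validated subtrial scores into one matrix per trial
#' (rows = directions, columns = iterations) with `NA` where a subtrial was
#' rejected or unscored. These are the inputs of the multi-class selection
#' rule.
#'
#' @param cv a `cv_result` (or its `scores` data.frame).
#' @param n_directions number of directions; taken from the data if `NULL`.
#' @return named list (one element per trial): list(`scores` matrix,
#'   `target` true direction).
#' @export
trial_scores <- function(cv, n_directions = NULL) {
  df <- if (inherits(cv, "cv_result")) cv$scores else cv
  if (is.null(n_directions)) n_directions <- max(df$direction)
  df$score[df$masked] <- NA_real_
  lapply(split(df, df$trial_id), function(tr) {
    n_it <- max(tr$iteration_id)
    m <- matrix(NA_real_, n_directions, n_it)
    m[cbind(tr$direction, tr$iteration_id)] <- tr$score
    list(scores = m, target = tr$target_direction[1])
  })
}

#' Multi-class target selection from averaged classifier scores
#'
#' Averages, per direction, the valid classifier scores among the first `k`
#' iterations and designates the direction with the most negative mean as
#' the attended target. Directions whose subtrials were all rejected within
#' the first `k` iterations are excluded from the argmin; if every direction
#' is empty the trial is unselectable (`NA`, counted as an error downstream,
#' with its time still counted for the transfer rate). Ties resolve to the
#' lowest direction index.
#'
#' @param scores direction x iteration matrix (`NA` = missing subtrial).
#' @param k number of iterations to average (columns `1..k`).
#' @return selected direction index, or `NA_integer_`.
#' @export
select_target <- function(scores, k) {
  stopifnot(k >= 1)
  k <- min(k, ncol(scores))
  m <- rowMeans(scores[, seq_len(k), drop = FALSE], na.rm = TRUE)
  m[is.nan(m)] <- NA_real_
  if (all(is.na(m))) return(NA_integer_)
  which.min(m)
}

#' Selection-accuracy curve over iteration counts
#'
#' `P(k)` is the fraction of trials whose selected direction equals the true
#' target when averaging over the first `k` iterations, for
#' `k = 1..max_iterations`. Unselectable trials count as errors.
#'
#' @param trials a [trial_scores()] list.
#' @param max_k largest iteration count; defaults to the available columns.
#' @return `data.frame` of class `selection_curve`: `k`, `accuracy` in
#'   `[0, 1]`, `n_trials`.
#' @export
selection_curve <- function(trials, max_k = NULL) {
  stopifnot(length(trials) >= 1)
  if (is.null(max_k)) max_k <- max(vapply(trials, function(t) ncol(t$scores), 1L))
  acc <- vapply(seq_len(max_k), function(k) {
    ok <- vapply(trials, function(t) {
      sel <- select_target(t$scores, k)
      !is.na(sel) && sel == t$target
    }, TRUE)
    mean(ok)
  }, 1)
  structure(data.frame(k = seq_len(max_k), accuracy = acc,
                       n_trials = length(trials)),
            class = c("selection_curve", "data.frame"))
}

#' Information per selection (bits)
#'
#' Wolpaw's per-selection information content of an `N`-class selection with
#' accuracy `P`, with errors spread uniformly over the `N - 1` wrong
#' classes:
#' `R = log2 N + P log2 P + (1 - P) log2((1 - P)/(N - 1))`,
#' using the convention `0 log2 0 = 0`. `R` ranges from 0 (chance,
#' `P = 1/N`) to `log2 N` (`P = 1`).
#'
#' @param N number of classes (`>= 2`).
#' @param P selection accuracy in `[0, 1]` (vectorized).
#' @return bits per selection.
#' @examples
#' itr_bits_per_selection(5, 1)    # log2(5)
#' itr_bits_per_selection(5, 0.2)  # 0
#' @export
itr_bits_per_selection <- function(N, P) {
  if (N < 2) stop("N must be at least 2")
  stopifnot(all(P >= 0 & P <= 1))
  xlx <- function(p) ifelse(p > 0, p * log2(p), 0)
  log2(N) + xlx(P) + ifelse(P < 1, (1 - P) * log2((1 - P) / (N - 1)), 0)
}

#' Information transfer rate (bits/minute)
#'
#' One selection takes `k` iterations of `N` stimuli at the given ISI:
#' `T = k * N * isi_ms` (no inter-trial pause or stimulus-duration term),
#' so the speed is `V = 60000 / T` selections/minute and `B = R * V`.
#'
#' @param R bits per selection (see [itr_bits_per_selection()]).
#' @param k iterations averaged per selection.
#' @param N number of classes/directions.
#' @param isi_ms inter-stimulus interval in ms.
#' @return bits per minute (vectorized over `R` and `k`).
#' @examples
#' itr_bits_per_minute(itr_bits_per_selection(5, 0.9), k = 15, N = 5,
#'                     isi_ms = 300)  # ~4.41
#' @export
itr_bits_per_minute <- function(R, k, N, isi_ms) {
  stopifnot(all(k > 0), N > 0, isi_ms > 0)
  V <- 60000 / (k * N * isi_ms)
  R * V
}

#' Maximum ITR under a selection-accuracy constraint
#'
#' Maximizes the bits/minute over the iteration counts whose selection
#' accuracy reaches the threshold (70% for a usable, 90% for a reliable
#' interface). If no iteration count qualifies the result is absent
#' (`NA`). Ties resolve to the smaller iteration count.
#'
#' @param curve a [selection_curve()].
#' @param threshold accuracy constraint in `[0, 1]`.
#' @param N,isi_ms condition parameters for the timing model.
#' @return list: `bits_per_minute`, `k`, `accuracy` (all `NA` if the
#'   constraint is never met).
#' @export
max_itr_thresholded <- function(curve, threshold = 0.7, N, isi_ms) {
  ok <- which(curve$accuracy >= threshold - 1e-12)
  if (length(ok) == 0L) {
    return(list(bits_per_minute = NA_real_, k = NA_integer_, accuracy = NA_real_))
  }
  B <- itr_bits_per_minute(itr_bits_per_selection(N, curve$accuracy[ok]),
                           curve$k[ok], N, isi_ms)
  i <- which.max(B)
  list(bits_per_minute = B[i], k = curve$k[ok][i], accuracy = curve$accuracy[ok][i])
}

#' Selection-curve / ITR report
#'
#' @param curve a [selection_curve()].
#' @param N,isi_ms condition parameters.
#' @return list of class `itr_report`: `series` (per k: accuracy, bits per
#'   selection `R`, selections/minute `V`, bits/minute `B`), `max_itr_70`,
#'   `max_itr_90`.
#' @export
itr_report <- function(curve, N, isi_ms) {
  R <- itr_bits_per_selection(N, curve$accuracy)
  B <- itr_bits_per_minute(R, curve$k, N, isi_ms)
  series <- data.frame(k = curve$k, accuracy = curve$accuracy, R = R,
                       V = 60000 / (curve$k * N * isi_ms), B = B)
  structure(list(series = series,
                 max_itr_70 = max_itr_thresholded(curve, 0.70, N, isi_ms),
                 max_itr_90 = max_itr_thresholded(curve, 0.90, N, isi_ms),
                 N = N, isi_ms = isi_ms),
            class = "itr_report")
}

#' @export
print.itr_report <- function(x, ...) {
  fmt <- function(m) if (is.na(m$k)) "- (-)" else
    sprintf("%.2f (%d)", m$bits_per_minute, m$k)
  cat(sprintf("<itr_report> N=%d, ISI=%g ms; max ITR 70%%: %s; max ITR 90%%: %s bits/min\n",
              x$N, x$isi_ms, fmt(x$max_itr_70), fmt(x$max_itr_90)))
  invisible(x)
}

#' Key-response error score
#'
#' Percentage error of the overt response task, excluding true negatives
#' (correctly unanswered non-targets), whose large number would mask the
#' error size: `error = (FA + misses) / (hits + FA + misses) * 100`.
#'
#' @param hits,false_alarms,misses counts (vectorized).
#' @return error percentage.
#' @examples
#' key_response_error(72, 3, 0)   # 4
#' key_response_error(88, 17, 8)  # ~22.1
#' @export
key_response_error <- function(hits, false_alarms, misses) {
  100 * (false_alarms + misses) / (hits + false_alarms + misses)
}

#' Score key-press responses against the stimulus stream
#'
#' Assigns each key press to a stimulus whose onset precedes it by a lag
#' inside `window_ms`; among unconsumed candidate stimuli the earliest is
#' taken (each stimulus elicits at most one response). A press on a target
#' is a hit, on a non-target a false alarm attributed to that stimulus'
#' direction; unanswered targets are misses. Presses with no candidate
#' stimulus are tallied separately as strays. At the 2000 ms ISI of the
#' control condition the response windows of consecutive stimuli do not
#' overlap, so the assignment rule is unambiguous in practice.
#'
#' @param sequence a [generate_sequence()] result (condition `Cr`).
#' @param responses data.frame with `time_ms` (from
#'   [simulate_key_responses()] or real data).
#' @param window_ms accepted response lag `c(min, max)` in ms post-onset.
#' @return list of class `key_response_result`: `counts` (hits,
#'   false_alarms, misses, strays, error_pct, rt_mean_ms, rt_sd_ms),
#'   `per_direction` (the same split by target direction of the trial),
#'   `confusions` (data.frame target_direction x response_direction counts
#'   for false alarms), `n_targets`.
#' @export
score_key_responses <- function(sequence, responses, window_ms = c(150, 1500)) {
  n_stim <- nrow(sequence)
  consumed <- logical(n_stim)
  hit_rt <- numeric(0)
  fa <- data.frame(target_direction = integer(0), response_direction = integer(0))
  strays <- 0L
  for (t in sort(responses$time_ms)) {
    lag <- t - sequence$onset_ms
    cand <- which(lag >= window_ms[1] & lag <= window_ms[2] & !consumed)
    if (length(cand) == 0L) {
      strays <- strays + 1L
      next
    }
    i <- cand[1]  # earliest unconsumed stimulus in the window
    consumed[i] <- TRUE
    if (sequence$is_target[i]) {
      hit_rt <- c(hit_rt, lag[i])
    } else {
      fa <- rbind(fa, data.frame(target_direction = sequence$target_direction[i],
                                 response_direction = sequence$direction[i]))
    }
  }
  hits_i <- which(sequence$is_target & consumed)
  miss_i <- which(sequence$is_target & !consumed)
  counts <- data.frame(
    hits = length(hits_i),
    false_alarms = nrow(fa),
    misses = length(miss_i),
    strays = strays,
    error_pct = key_response_error(length(hits_i), nrow(fa), length(miss_i)),
    rt_mean_ms = if (length(hit_rt)) mean(hit_rt) else NA_real_,
    rt_sd_ms = if (length(hit_rt) > 1) stats::sd(hit_rt) else NA_real_
  )
  # per attended-direction breakdown
  dirs <- sort(unique(sequence$target_direction))
  per_dir <- do.call(rbind, lapply(dirs, function(d) {
    tgt <- sequence$target_direction == d
    h <- sum(sequence$is_target & consumed & tgt)
    m <- sum(sequence$is_target & !consumed & tgt)
    f <- sum(fa$target_direction == d)
    data.frame(direction = d, hits = h, false_alarms = f, misses = m,
               error_pct = key_response_error(h, f, m))
  }))
  structure(list(counts = counts, per_direction = per_dir, confusions = fa,
                 n_targets = sum(sequence$is_target)),
            class = "key_response_result")
}

#' Neighbour vs. other false-alarm rates
#'
#' Normalizes false-alarm counts by the number of opportunities on the
#' circular speaker layout: each target presentation offers 2 direct
#' neighbours and `N - 3` other non-target directions.
#'
#' @param confusions data.frame with `target_direction` and
#'   `response_direction` (false alarms only), as produced by
#'   [score_key_responses()]; alternatively pass precomputed counts via
#'   `n_neighbor`/`n_other`.
#' @param n_directions number of directions on the circle.
#' @param n_targets total number of target presentations.
#' @param n_neighbor,n_other optional explicit false-alarm counts
#'   (override `confusions`).
#' @return list: `p_neighbor_pct`, `p_other_pct`, counts.
#' @examples
#' neighbor_fa_rates(n_neighbor = 14, n_other = 19, n_directions = 8,
#'                   n_targets = 576)  # 1.22% / 0.66%
#' @export
neighbor_fa_rates <- function(confusions = NULL, n_directions = 8, n_targets,
                              n_neighbor = NULL, n_other = NULL) {
  if (is.null(n_neighbor) || is.null(n_other)) {
    d <- .circular_distance(confusions$response_direction,
                            confusions$target_direction, n_directions)
    n_neighbor <- sum(d == 1)
    n_other <- sum(d > 1)
  }
  list(
    p_neighbor_pct = 100 * n_neighbor / (n_targets * 2),
    p_other_pct = 100 * n_other / (n_targets * (n_directions - 3)),
    n_neighbor = n_neighbor, n_other = n_other, n_targets = n_targets
  )
}
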
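#' Signed ROC separability index
#'
#' Twice the signed area between the ROC curve of two one-dimensional
#' samples and the no-discrimination diagonal. Equals the rank-biserial
#' correlation `2U/(n1*n2) - 1`, with `U` the Mann-Whitney statistic
#' counting tied pairs as one half; ties trace diagonal ROC segments. The
#' index is `+1` iff every value of class 1 strictly exceeds every value of
#' class 2, `-1` in the reversed case, and `0` for perfectly mixed samples.
#' Unlike Fisher score or t-statistics it makes no Gaussian assumption and
#' is invariant under strictly increasing transforms.
#'
#' @param values_class1,values_class2 numeric vectors (non-empty).
#' @return scalar in `[-1, 1]`; positive means class 1 tends to be larger.
#' @examples
#' roc_index(c(3, 4), c(1, 2))  # 1
#' roc_index(5, 5)              # 0
#' @export
roc_index <- function(values_class1, values_class2) {
  n1 <- length(values_class1)
  n2 <- length(values_class2)
  if (n1 == 0L || n2 == 0L) stop("both classes must be non-empty")
  r <- rank(c(values_class1, values_class2))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  2 * u / (n1 * n2) - 1
}

#' ROC separability map over channels and time points
#'
#' Applies [roc_index()] per (channel, sample) across the unmasked epochs,
#' with target epochs as class 1: positive values mean the target class is
#' more positive at that channel and latency.
#'
#' @param epochs a `bci_epochs` object with `is_target` labels.
#' @param use logical epoch filter; defaults to the unmasked epochs.
#' @return matrix (channels x samples) of class `bci_rocmap`, all entries in
#'   `[-1, 1]`, with `channels`, `times_ms` and `n_baseline` attributes.
#' @export
channelwise_roc <- function(epochs, use = !epochs$artifact) {
  tgt <- epochs$info$is_target & use
  ntg <- !epochs$info$is_target & use
  n1 <- sum(tgt)
  n2 <- sum(ntg)
  if (n1 == 0L || n2 == 0L) {
    stop("both target and non-target epochs are required after masking")
  }
  n_ch <- dim(epochs$data)[2]
  nt <- dim(epochs$data)[3]
  out <- matrix(NA_real_, n_ch, nt)
  keep <- tgt | ntg
  is1 <- tgt[keep]
  for (ch in seq_len(n_ch)) {
    m <- epochs$data[keep, ch, , drop = TRUE]
    r <- apply(m, 2, rank)
    u <- colSums(r[is1, , drop = FALSE]) - n1 * (n1 + 1) / 2
    out[ch, ] <- 2 * u / (n1 * n2) - 1
  }
  structure(out,
            channels = epochs$channels,
            times_ms = epochs$times_ms,
            n_baseline = epochs$n_baseline,
            class = c("bci_rocmap", "matrix", "array"))
}

#' Select discriminative channels from a ROC map
#'
#' Picks the `n_pos` channels with the highest positive ROC peak and the
#' `n_neg` channels with the lowest negative ROC peak, searching the full
#' post-baseline window. A channel may qualify for both lists (set
#' `disjoint = TRUE` to forbid this); ocular channels are excluded from
#' selection by default since they monitor artifacts, not brain signals.
#' Ties break deterministically by channel index. With fewer than
#' `n_pos + n_neg` eligible channels all of them are returned with a
#' warning.
#'
#' @param rocmap a [channelwise_roc()] result.
#' @param n_pos,n_neg number of channels per list.
#' @param exclude_roles channel roles never selected.
#' @param disjoint forbid a channel from appearing in both lists.
#' @return list with `positive`, `negative` (label vectors ordered by peak
#'   magnitude) and `channels` (their concatenation, positive list first).
#' @export
select_channels <- function(rocmap, n_pos = 10, n_neg = 10,
                            exclude_roles = "ocular", disjoint = FALSE) {
  ch_tab <- attr(rocmap, "channels")
  post <- seq_len(ncol(rocmap)) > attr(rocmap, "n_baseline")
  eligible <- which(!(ch_tab$role %in% exclude_roles))
  if (length(eligible) < n_pos + n_neg) {
    warning("fewer than ", n_pos + n_neg, " eligible channels; selecting all")
  }
  vals <- rocmap[eligible, post, drop = FALSE]
  pk_max <- apply(vals, 1, max)
  pk_min <- apply(vals, 1, min)
  ord_pos <- eligible[order(-pk_max, eligible)]
  pos <- utils::head(ord_pos, min(n_pos, length(eligible)))
  ord_neg <- eligible[order(pk_min, eligible)]
  if (disjoint) ord_neg <- setdiff(ord_neg, pos)
  neg <- utils::head(ord_neg, min(n_neg, length(ord_neg)))
  list(positive = ch_tab$label[pos],
       negative = ch_tab$label[neg],
       channels = c(ch_tab$label[pos], ch_tab$label[neg]))
}

#' Characterize an ERP peak on full-rate data
#'
#' Latency and amplitude measurement of the attention-dependent components:
#' the channel is chosen as the one with the extremal ROC value inside the
#' search window (maximal for the positive component, minimal for the
#' negative one), then the peak is the extremum of the target-class average
#' on that channel within the window, on the non-decimated (1 kHz) epochs.
#' Two equal extrema resolve to the earlier latency; channels tied on the
#' ROC value (possible only in degenerate, noise-free data) resolve to the
#' one with the strongest target response in the window.
#'
#' @param epochs_1khz `bci_epochs` cut from the 1 kHz recording.
#' @param rocmap ROC map computed on the same epochs.
#' @param window_ms search window, e.g. `c(300, 650)` for the parietal
#'   positivity or `c(100, 300)` for the early negativity.
#' @param sign `"positive"` or `"negative"` component.
#' @return `data.frame` with `channel`, `latency_ms`, `amplitude_uv`.
#' @export
characterize_peak <- function(epochs_1khz, rocmap = channelwise_roc(epochs_1khz),
                              window_ms = c(300, 650),
                              sign = c("positive", "negative")) {
  sign <- match.arg(sign)
  times <- attr(rocmap, "times_ms")
  win <- times >= window_ms[1] & times <= window_ms[2]
  if (!any(win)) stop("search window lies outside the epoch span")
  vals <- rocmap[, win, drop = FALSE]
  use <- epochs_1khz$info$is_target & !epochs_1khz$artifact
  peak_roc <- if (sign == "positive") apply(vals, 1, max) else -apply(vals, 1, min)
  cand <- which(peak_roc > max(peak_roc) - 1e-12)
  if (length(cand) > 1L) {
    # ROC ties (degenerate, e.g. noise-free data): take the channel with the
    # strongest target-class response in the window
    amp <- vapply(cand, function(ch) {
      a <- apply(epochs_1khz$data[use, ch, win, drop = FALSE], 3, mean, na.rm = TRUE)
      if (sign == "positive") max(a) else -min(a)
    }, 1)
    ch <- cand[which.max(amp)]
  } else {
    ch <- cand
  }
  avg <- apply(epochs_1khz$data[use, ch, , drop = FALSE], 3, mean, na.rm = TRUE)
  avg_win <- avg[win]
  t_win <- epochs_1khz$times_ms[win]
  i <- if (sign == "positive") which.max(avg_win) else which.min(avg_win)
  data.frame(channel = epochs_1khz$channels$label[ch],
             latency_ms = t_win[i],
             amplitude_uv = avg_win[i])
}

#' Write a ROC map as a tab-separated table
#'
#' @param rocmap a [channelwise_roc()] result.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_rocmap <- function(rocmap, path) {
  df <- data.frame(channel = attr(rocmap, "channels")$label,
                   as.data.frame(unclass(rocmap)[, , drop = FALSE]))
  names(df)[-1] <- sprintf("t%g", attr(rocmap, "times_ms"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
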
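#' Low-pass filter specification
#'
#' Chebyshev type II low-pass design used throughout the pipeline: order 8,
#' 30 Hz pass-band edge, 42 Hz stop-band edge, 50 dB stop-band attenuation.
#' The digital filter is designed from the stop-band edge and attenuation
#' (the defining parameters of a Chebyshev II response); the resulting
#' pass-band droop at 30 Hz is below ~1.2 dB. In `causal` mode the filter is
#' applied forward only, as required for portability to an online setting
#' (at the cost of a group delay); `zero-phase` mode applies it forward and
#' backward and is meant for ERP visualisation and peak measurement.
#'
#' @param order filter order.
#' @param pass_hz pass-band edge in Hz (documentation/validation only).
#' @param stop_hz stop-band edge in Hz.
#' @param atten_db minimum stop-band attenuation in dB.
#' @param mode `"causal"` or `"zero-phase"`.
#' @return list of class `filter_spec`.
#' @export
filter_spec <- function(order = 8, pass_hz = 30, stop_hz = 42, atten_db = 50,
                        mode = c("causal", "zero-phase")) {
  mode <- match.arg(mode)
  stopifnot(pass_hz < stop_hz, order >= 1, atten_db > 0)
  structure(list(order = order, pass_hz = pass_hz, stop_hz = stop_hz,
                 atten_db = atten_db, mode = mode),
            class = "filter_spec")
}

.design_filter <- function(spec, rate) {
  nyq <- rate / 2
  if (spec$stop_hz >= nyq) {
    stop("filter stop-band edge (", spec$stop_hz, " Hz) must lie below the Nyquist ",
         "frequency (", nyq, " Hz)")
  }
  signal::cheby2(spec$order, spec$atten_db, spec$stop_hz / nyq)
}

#' Apply the low-pass filter to a continuous recording
#'
#' @param recording a `bci_recording`.
#' @param spec a [filter_spec()].
#' @return the recording with filtered signal (same shape and rate).
#' @export
apply_lowpass <- function(recording, spec = filter_spec()) {
  flt <- .design_filter(spec, recording$rate)
  sig <- recording$signal
  for (ch in seq_len(nrow(sig))) {
    sig[ch, ] <- if (spec$mode == "zero-phase") {
      signal::filtfilt(flt, sig[ch, ])
    } else {
      signal::filter(flt, sig[ch, ])
    }
  }
  recording$signal <- sig
  recording
}

#' Downsample a filtered recording by an integer factor
#'
#' Keeps every `factor`-th sample. No further anti-alias stage is applied:
#' the 42 Hz stop-band edge of the standard filter lies below the 50 Hz
#' Nyquist frequency of the 100 Hz output rate. Marker onsets are stored in
#' ms and therefore unchanged.
#'
#' @param recording a `bci_recording` (already low-pass filtered).
#' @param factor integer decimation factor (10: 1 kHz to 100 Hz).
#' @return the decimated recording.
#' @export
downsample <- function(recording, factor = 10) {
  if (factor != round(factor) || factor < 1) stop("factor must be a positive integer")
  recording$signal <- recording$signal[, seq(1, ncol(recording$signal), by = factor),
                                       drop = FALSE]
  recording$rate <- recording$rate / factor
  recording
}

#' Cut stimulus-locked epochs with baseline correction
#'
#' Epochs the continuous signal into the half-open window
#' `[tmin_ms, tmax_ms)` relative to each marker onset and subtracts, per
#' epoch and channel, the mean of the baseline samples (the first
#' `baseline_ms` of the window). At 100 Hz the default window yields 95
#' samples: 15 baseline plus 80 post-onset, the onset sample being the first
#' post-baseline sample. Epochs whose window exceeds the recording bounds
#' are kept but flagged (`incomplete`) and pre-masked as artifacts rather
#' than silently dropped.
#'
#' @param recording a `bci_recording` at any rate.
#' @param markers marker table; defaults to `recording$markers`.
#' @param tmin_ms,tmax_ms epoch window in ms relative to onset.
#' @param baseline_ms baseline span at the start of the window.
#' @return object of class `bci_epochs`: `data` (epoch x channel x sample
#'   array, uV), `info` (marker rows), `channels`, `times_ms`, `rate`,
#'   `n_baseline`, logical vectors `artifact` and `incomplete`.
#' @export
extract_epochs <- function(recording, markers = recording$markers,
                           tmin_ms = -150, tmax_ms = 800, baseline_ms = 150) {
  rate <- recording$rate
  period <- 1000 / rate
  nb <- round(baseline_ms / period)
  npost <- round(tmax_ms / period)
  ntot <- round((tmax_ms - tmin_ms) / period)
  stopifnot(nb + npost == ntot, nb >= 1)
  n_ch <- nrow(recording$signal)
  n_samp <- ncol(recording$signal)
  n_ep <- nrow(markers)

  data <- array(NA_real_, dim = c(n_ep, n_ch, ntot))
  incomplete <- logical(n_ep)
  onset_idx <- floor(markers$onset_ms / period) + 1L
  rel <- seq(-nb, npost - 1L)
  for (i in seq_len(n_ep)) {
    idx <- onset_idx[i] + rel
    if (idx[1] < 1L || idx[ntot] > n_samp) {
      incomplete[i] <- TRUE
      next
    }
    ep <- recording$signal[, idx, drop = FALSE]
    ep <- ep - rowMeans(ep[, seq_len(nb), drop = FALSE])
    data[i, , ] <- ep
  }
  structure(list(data = data,
                 info = as.data.frame(markers),
                 channels = recording$channels,
                 times_ms = rel * period,
                 rate = rate,
                 n_baseline = nb,
                 artifact = incomplete,
                 incomplete = incomplete),
            class = "bci_epochs")
}

#' @export
print.bci_epochs <- function(x, ...) {
  cat(sprintf("<bci_epochs> %d epochs x %d channels x %d samples @ %g Hz; %d masked\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$rate,
              sum(x$artifact)))
  invisible(x)
}

#' Threshold-based ocular artifact rejection
#'
#' Marks a subtrial as artifact iff, after removing a least-squares linear
#' trend from its ocular-channel epoch, any sample deviates from the
#' (detrended) baseline mean by more than `threshold_uv` on any ocular
#' channel. Detrending prevents slow drifts from reaching the threshold;
#' only ocular channels are examined because the threshold is defined there
#' (the method targets eye artifacts). Masked subtrials stay in the epoch
#' set so that selection and ITR accounting keep the full timeline.
#'
#' @param epochs a `bci_epochs` object.
#' @param ocular_channels channel labels to scan; defaults to all channels
#'   with role `"ocular"`.
#' @param threshold_uv rejection threshold in uV.
#' @return `epochs` with an updated `artifact` mask and a `rejection`
#'   element: list(`n_total`, `n_rejected`, `pct`).
#' @export
reject_artifacts <- function(epochs, ocular_channels = NULL, threshold_uv = 70) {
  if (is.null(ocular_channels)) {
    ocular_channels <- epochs$channels$label[epochs$channels$role == "ocular"]
  }
  ch_idx <- match(ocular_channels, epochs$channels$label)
  if (length(ch_idx) == 0L || anyNA(ch_idx)) {
    stop("no ocular channels found for artifact rejection")
  }
  n_ep <- dim(epochs$data)[1]
  nb <- epochs$n_baseline
  nt <- dim(epochs$data)[3]
  tt <- seq_len(nt)
  mask <- epochs$artifact
  for (i in seq_len(n_ep)) {
    if (epochs$incomplete[i]) next
    for (ch in ch_idx) {
      x <- epochs$data[i, ch, ]
      x <- stats::.lm.fit(cbind(1, tt), x)$residuals
      if (max(abs(x - mean(x[seq_len(nb)]))) > threshold_uv) {
        mask[i] <- TRUE
        break
      }
    }
  }
  epochs$artifact <- mask
  epochs$rejection <- list(n_total = n_ep, n_rejected = sum(mask),
                           pct = rejection_pct(sum(mask), n_ep))
  epochs
}

#' Rejection percentage, rounded half-up to two decimals
#'
#' @param n_rejected,n_total counts of rejected and total subtrials.
#' @return percentage in `[0, 100]`.
#' @examples
#' rejection_pct(1497, 2560) # 58.48
#' @export
rejection_pct <- function(n_rejected, n_total) {
  round_half_up(100 * n_rejected / n_total, 2)
}

#' Rejection report over conditions
#'
#' @param epoch_sets named list of `bci_epochs` after [reject_artifacts()].
#' @return `data.frame` with `condition`, `n_rejected`, `n_total`, `pct`.
#' @export
rejection_report <- function(epoch_sets) {
  out <- data.frame(
    condition = names(epoch_sets),
    n_rejected = vapply(epoch_sets, function(e) e$rejection$n_rejected, 1L),
    n_total = vapply(epoch_sets, function(e) e$rejection$n_total, 1L)
  )
  out$pct <- rejection_pct(out$n_rejected, out$n_total)
  rownames(out) <- NULL
  out
}

#' Standard preprocessing chain
#'
#' Filter (causally by default), downsample to 100 Hz, epoch, baseline
#' correct and reject ocular artifacts in the order the analysis assumes:
#' the filter runs on the continuous recording before epoching, which avoids
#' epoch-edge transients.
#'
#' @param recording a 1 kHz `bci_recording`.
#' @param spec a [filter_spec()].
#' @param factor decimation factor.
#' @param threshold_uv artifact rejection threshold.
#' @return a `bci_epochs` object at 100 Hz with rejection applied.
#' @export
preprocess <- function(recording, spec = filter_spec(), factor = 10,
                       threshold_uv = 70) {
  rec <- apply_lowpass(recording, spec)
  rec <- downsample(rec, factor)
  ep <- extract_epochs(rec)
  reject_artifacts(ep, threshold_uv = threshold_uv)
}

#' Round half-up
#'
#' Base `round()` rounds half to even; reported percentages follow the
#' conventional half-up rule of the printed tables.
#'
#' @param x numeric vector (non-negative use intended).
#' @param digits decimal places.
#' @return rounded values.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
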
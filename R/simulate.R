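#' Default electrode montage
#'
#' A named 1-D channel list with spatial role tags; no geometric coordinates
#' are used anywhere in the pipeline. 31 EEG channels (10 frontal, 8 central,
#' 10 parietal, 3 occipital) plus two ocular (EOG) channels for artifact
#' monitoring.
#'
#' @return `data.frame` with columns `label` and
#'   `role` (`frontal`/`central`/`parietal`/`occipital`/`ocular`).
#' @export
default_montage <- function() {
  data.frame(
    label = c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "FC3", "FCz", "FC4",
              "T7", "C3", "Cz", "C4", "T8", "CP3", "CPz", "CP4",
              "P7", "P3", "P1", "Pz", "P2", "P4", "P8", "PO3", "POz", "PO4",
              "O1", "Oz", "O2",
              "EOGh", "EOGv"),
    role = c(rep("frontal", 10), rep("central", 8), rep("parietal", 10),
             rep("occipital", 3), rep("ocular", 2))
  )
}

#' Event-related potential template set
#'
#' Parameterizes the per-stimulus EEG response as a sum of Gaussian bump
#' components, each with a peak amplitude (uV), peak latency (ms), temporal
#' width (Gaussian SD, ms) and a gain per channel role. Three physiological
#' components are modelled:
#' \itemize{
#'   \item a stimulus-evoked N1--P2 complex common to targets and
#'     non-targets (fronto-central, ~100/180 ms), driving the rhythmic
#'     deflections that overlap at short ISIs;
#'   \item an attention-dependent parietal positivity (P300) present only
#'     for attended targets, peaking inside 300--650 ms;
#'   \item an attention-dependent fronto-temporal negativity (N2) present
#'     only for targets, peaking inside 100--300 ms.
#' }
#' `attention_scale` multiplies the two target-only components; setting it
#' to 0 emulates the single-speaker control condition in which the class
#' difference vanishes. Latency jitter (mean/SD, ms; normal truncated at 0)
#' shifts each stimulus response relative to its marker.
#'
#' @param p300_amplitude,p300_latency,p300_width P300 peak (uV), latency and
#'   width (ms); defaults follow the grand-average parietal response of
#'   attentive listeners (~10 uV around 430 ms).
#' @param n2_amplitude,n2_latency,n2_width early negativity parameters.
#' @param evoked_amplitude amplitude (uV) of the class-independent evoked
#'   complex.
#' @param attention_scale multiplier on the target-only components.
#' @param jitter_mean,jitter_sd onset latency jitter in ms.
#' @param support_ms temporal support of one response.
#' @return list of class `erp_templates`.
#' @export
erp_templates <- function(p300_amplitude = 10, p300_latency = 430, p300_width = 80,
                          n2_amplitude = -5, n2_latency = 200, n2_width = 45,
                          evoked_amplitude = 3,
                          attention_scale = 1,
                          jitter_mean = 0, jitter_sd = 0,
                          support_ms = 800) {
  stopifnot(jitter_sd >= 0, support_ms > 0)
  g <- function(frontal = 0, central = 0, parietal = 0, occipital = 0, ocular = 0) {
    c(frontal = frontal, central = central, parietal = parietal,
      occipital = occipital, ocular = ocular)
  }
  comps <- list(
    list(name = "N1", class = "both", amp = -evoked_amplitude, lat = 100,
         width = 25, gains = g(frontal = 0.7, central = 1, parietal = 0.4)),
    list(name = "P2", class = "both", amp = evoked_amplitude, lat = 180,
         width = 35, gains = g(frontal = 0.6, central = 1, parietal = 0.5)),
    list(name = "N2", class = "target", amp = n2_amplitude * attention_scale,
         lat = n2_latency, width = n2_width,
         gains = g(frontal = 1, central = 0.2)),
    list(name = "P300", class = "target", amp = p300_amplitude * attention_scale,
         lat = p300_latency, width = p300_width,
         gains = g(frontal = 0.1, central = 0.4, parietal = 1, occipital = 0.6))
  )
  structure(list(components = comps, jitter_mean = jitter_mean,
                 jitter_sd = jitter_sd, support_ms = support_ms),
            class = "erp_templates")
}

#' Evaluate a template as a channel x sample matrix
#'
#' @param templates an [erp_templates()] object.
#' @param montage channel table as from [default_montage()].
#' @param class `"target"` or `"nontarget"`.
#' @param rate sampling rate in Hz.
#' @param latency_shift_ms extra latency added to every component (jitter).
#' @return matrix (channels x samples) in uV covering `[0, support_ms)`.
#' @export
template_matrix <- function(templates, montage, class = c("target", "nontarget"),
                            rate = 1000, latency_shift_ms = 0) {
  class <- match.arg(class)
  t_ms <- (seq_len(round(templates$support_ms * rate / 1000)) - 1) * 1000 / rate
  out <- matrix(0, nrow(montage), length(t_ms))
  for (cmp in templates$components) {
    if (cmp$class == "target" && class != "target") next
    wave <- cmp$amp * exp(-0.5 * ((t_ms - cmp$lat - latency_shift_ms) / cmp$width)^2)
    gains <- cmp$gains[montage$role]
    out <- out + outer(unname(gains), wave)
  }
  out
}

#' Noise and artifact model
#'
#' Background EEG noise is a per-channel AR(1) process (autoregressive
#' coefficient `ar_coef`) scaled to `background_sd` uV, plus a sinusoidal
#' mains component at `line_freq` Hz. Ocular blinks occur as a Poisson
#' process at `blink_rate` events/minute; each blink is a raised-cosine
#' deflection of `blink_amplitude` uV and `blink_duration_ms` duration on
#' the ocular channels, with a 15% leak onto frontal channels.
#'
#' @param background_sd background noise SD in uV.
#' @param ar_coef AR(1) coefficient in `[0, 1)` (spectral shape).
#' @param line_freq,line_amplitude mains frequency (Hz) and amplitude (uV).
#' @param blink_rate blinks per minute.
#' @param blink_amplitude blink peak in uV (set below 70 to exercise the
#'   rejection threshold from the other side).
#' @param blink_duration_ms blink duration in ms.
#' @return list of class `noise_spec`.
#' @export
noise_spec <- function(background_sd = 18, ar_coef = 0.97,
                       line_freq = 50, line_amplitude = 5,
                       blink_rate = 4, blink_amplitude = 120,
                       blink_duration_ms = 250) {
  stopifnot(background_sd >= 0, line_amplitude >= 0, blink_amplitude >= 0,
            blink_rate >= 0, ar_coef >= 0, ar_coef < 1)
  structure(list(background_sd = background_sd, ar_coef = ar_coef,
                 line_freq = line_freq, line_amplitude = line_amplitude,
                 blink_rate = blink_rate, blink_amplitude = blink_amplitude,
                 blink_duration_ms = blink_duration_ms),
            class = "noise_spec")
}

#' Simulate a continuous multi-channel EEG recording
#'
#' Superimposes one ERP template instance per stimulus (the target template
#' iff the stimulus direction equals the trial's attended direction, shifted
#' by a per-stimulus latency jitter draw) on background noise. Overlapping
#' responses at short ISIs sum linearly. Ocular channels additionally
#' receive blink artifacts.
#'
#' @param sequence a [generate_sequence()] result.
#' @param templates an [erp_templates()] object.
#' @param noise a [noise_spec()] object.
#' @param montage channel table; see [default_montage()].
#' @param rate sampling rate in Hz (1000 by default).
#' @param pad_ms silence appended after the last response.
#' @param seed integer seed; the signal is bit-identical per seed.
#' @return list of class `bci_recording`: `signal` (channels x samples, uV),
#'   `rate`, `channels` (montage), `markers` (the sequence).
#' @export
simulate_recording <- function(sequence, templates = erp_templates(),
                               noise = noise_spec(),
                               montage = default_montage(),
                               rate = 1000, pad_ms = 1000, seed = NULL) {
  stopifnot(inherits(templates, "erp_templates"), inherits(noise, "noise_spec"))
  if (!is.null(seed)) set.seed(seed)
  n_ch <- nrow(montage)
  dur_ms <- max(sequence$onset_ms) + templates$support_ms +
    3 * templates$jitter_sd + templates$jitter_mean + pad_ms
  n <- ceiling(dur_ms * rate / 1000)

  sig <- .background_noise(noise, n_ch, n, rate)

  # per-stimulus jitter (truncated normal, >= 0)
  jit <- if (templates$jitter_sd > 0 || templates$jitter_mean > 0) {
    .rtruncnorm_pos(nrow(sequence), templates$jitter_mean, templates$jitter_sd)
  } else {
    rep(0, nrow(sequence))
  }

  # cache jitter-free templates; jittered ones are evaluated on demand
  tmpl <- list(target = template_matrix(templates, montage, "target", rate),
               nontarget = template_matrix(templates, montage, "nontarget", rate))
  L <- ncol(tmpl$target)
  for (i in seq_len(nrow(sequence))) {
    cls <- if (sequence$is_target[i]) "target" else "nontarget"
    m <- if (jit[i] == 0) tmpl[[cls]] else
      template_matrix(templates, montage, cls, rate, latency_shift_ms = jit[i])
    i0 <- floor(sequence$onset_ms[i] * rate / 1000) + 1L
    idx <- i0:min(i0 + L - 1L, n)
    sig[, idx] <- sig[, idx] + m[, seq_along(idx), drop = FALSE]
  }

  sig <- sig + .blinks(noise, montage, n, rate)

  structure(list(signal = sig, rate = rate, channels = montage,
                 markers = sequence),
            class = "bci_recording")
}

.background_noise <- function(noise, n_ch, n, rate) {
  sig <- matrix(0, n_ch, n)
  if (noise$background_sd > 0) {
    innov_sd <- noise$background_sd * sqrt(1 - noise$ar_coef^2)
    for (ch in seq_len(n_ch)) {
      e <- stats::rnorm(n, 0, innov_sd)
      sig[ch, ] <- stats::filter(e, noise$ar_coef, method = "recursive")
    }
  }
  if (noise$line_amplitude > 0) {
    t_s <- (seq_len(n) - 1) / rate
    for (ch in seq_len(n_ch)) {
      sig[ch, ] <- sig[ch, ] +
        noise$line_amplitude * sin(2 * pi * noise$line_freq * t_s +
                                   stats::runif(1, 0, 2 * pi))
    }
  }
  sig
}

.blinks <- function(noise, montage, n, rate) {
  out <- matrix(0, nrow(montage), n)
  if (noise$blink_rate <= 0 || noise$blink_amplitude <= 0) return(out)
  dur_min <- n / rate / 60
  n_blinks <- stats::rpois(1, noise$blink_rate * dur_min)
  if (n_blinks == 0) return(out)
  L <- round(noise$blink_duration_ms * rate / 1000)
  wave <- noise$blink_amplitude * 0.5 * (1 - cos(2 * pi * seq_len(L) / (L + 1)))
  ocular <- montage$role == "ocular"
  frontal <- montage$role == "frontal"
  starts <- sort(sample.int(max(n - L, 1L), n_blinks, replace = TRUE))
  for (s in starts) {
    idx <- s:min(s + L - 1L, n)
    w <- wave[seq_along(idx)]
    out[ocular, idx] <- out[ocular, idx] + rep(w, each = sum(ocular))
    out[frontal, idx] <- out[frontal, idx] + rep(0.15 * w, each = sum(frontal))
  }
  out
}

#' @export
print.bci_recording <- function(x, ...) {
  cat(sprintf("<bci_recording> %d channels x %d samples @ %g Hz (%.1f s), %d markers\n",
              nrow(x$signal), ncol(x$signal), x$rate,
              ncol(x$signal) / x$rate, nrow(x$markers)))
  invisible(x)
}
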
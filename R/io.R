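#' Write a recording as an EDF+ file
#'
#' Serializes the continuous signal in European Data Format (EDF+C): 16-bit
#' samples with per-channel physical scaling, one-second data records, and
#' an "EDF Annotations" channel holding the record time-keeping annotations
#' plus one annotation per stimulus marker (`stim <direction>`). The signal
#' is zero-padded to a whole number of records (the marker table carries
#' the exact event timing, so trailing padding is harmless). Quantization
#' error is bounded by the channel's physical range divided by 2^16 - 2.
#'
#' No EDF handling package exists in this R installation, so the fixed-
#' layout format is read and written directly.
#'
#' @param recording a `bci_recording`.
#' @param path output file path.
#' @param patient,recording_id free-text header fields.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path, patient = "X X X X",
                      recording_id = "Startdate 01-JAN-2026 X X X") {
  sig <- recording$signal
  rate <- recording$rate
  if (rate != round(rate)) stop("EDF writer requires an integer sampling rate")
  n_ch <- nrow(sig)
  n_rec <- ceiling(ncol(sig) / rate)
  if (ncol(sig) < n_rec * rate) {
    sig <- cbind(sig, matrix(0, n_ch, n_rec * rate - ncol(sig)))
  }
  phys_max <- pmax(apply(abs(sig), 1, max), 1)
  dig_max <- 32767

  # annotation TALs per record; every TAL is NUL-terminated at write time
  tals <- lapply(seq_len(n_rec) - 1L, function(r) {
    s <- sprintf("+%d\x14\x14", r)
    mk <- recording$markers
    if (!is.null(mk)) {
      in_rec <- which(mk$onset_ms / 1000 >= r & mk$onset_ms / 1000 < r + 1)
      for (i in in_rec) {
        s <- c(s, sprintf("+%.4f\x14stim %d\x14", mk$onset_ms[i] / 1000,
                          mk$direction[i]))
      }
    }
    s
  })
  tal_raw <- lapply(tals, function(pieces) {
    do.call(c, lapply(pieces, function(p) c(charToRaw(p), as.raw(0))))
  })
  ann_bytes <- max(vapply(tal_raw, length, 1L)) + 1
  ann_ns <- ceiling(ann_bytes / 2)

  con <- file(path, "wb")
  on.exit(close(con))
  wf <- function(x, width) {
    s <- formatC(as.character(x), width = -width)
    s <- substr(s, 1, width)
    writeChar(paste(s, collapse = ""), con, nchars = sum(nchar(s)), eos = NULL)
  }
  ns_total <- n_ch + 1L
  wf("0", 8); wf(patient, 80); wf(recording_id, 80)
  wf("01.01.26", 8); wf("00.00.00", 8)
  wf(256 * (ns_total + 1), 8); wf("EDF+C", 44)
  wf(n_rec, 8); wf("1", 8); wf(ns_total, 4)
  labels <- c(recording$channels$label, "EDF Annotations")
  for (l in labels) wf(l, 16)
  for (i in seq_len(ns_total)) wf("", 80)                      # transducer
  wf_each <- function(vals, width) for (v in vals) wf(v, width)
  wf_each(c(rep("uV", n_ch), ""), 8)                           # dimension
  wf_each(c(sprintf("%.7g", -phys_max), "-1"), 8)              # phys min
  wf_each(c(sprintf("%.7g", phys_max), "1"), 8)                # phys max
  wf_each(c(rep(-dig_max, n_ch), -32768), 8)                   # dig min
  wf_each(rep(dig_max, ns_total), 8)                           # dig max
  for (i in seq_len(ns_total)) wf("", 80)                      # prefilter
  wf_each(c(rep(rate, n_ch), ann_ns), 8)                       # samples/record
  for (i in seq_len(ns_total)) wf("", 32)                      # reserved

  dig <- round(sweep(sig, 1, dig_max / phys_max, "*"))
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * rate + 1L):(r * rate)
    writeBin(as.integer(t(dig[, idx])), con, size = 2, endian = "little")
    tal <- tal_raw[[r]]
    writeBin(c(tal, raw(2 * ann_ns - length(tal))), con)
  }
  invisible(path)
}

#' Read an EDF/EDF+ file written by [write_edf()]
#'
#' Parses the fixed-layout header, rescales the 16-bit samples to physical
#' units and collects `stim` annotations.
#'
#' @param path EDF file path.
#' @param montage optional channel table supplying roles; matched by label.
#' @return a `bci_recording` (markers reduced to onset/direction when only
#'   annotations are available; pair with [read_markers()] for full labels).
#' @export
read_edf <- function(path, montage = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rs <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  rs(8); rs(80); rs(80); rs(8); rs(8)
  rs(8); reserved <- rs(44)
  n_rec <- as.integer(rs(8))
  rec_dur <- as.numeric(rs(8))
  ns <- as.integer(rs(4))
  labels <- vapply(seq_len(ns), function(i) rs(16), "")
  for (i in seq_len(ns)) rs(80)
  dims <- vapply(seq_len(ns), function(i) rs(8), "")
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rs(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rs(8), ""))
  dmin_ <- as.numeric(vapply(seq_len(ns), function(i) rs(8), ""))
  dmax_ <- as.numeric(vapply(seq_len(ns), function(i) rs(8), ""))
  for (i in seq_len(ns)) rs(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rs(8), ""))
  for (i in seq_len(ns)) rs(32)

  is_ann <- labels == "EDF Annotations"
  sig_idx <- which(!is_ann)
  out <- matrix(0, length(sig_idx), n_rec * spr[sig_idx[1]])
  ann_raw <- list()
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      if (is_ann[s]) {
        ann_raw[[length(ann_raw) + 1L]] <- readBin(con, "raw", n = 2 * spr[s])
      } else {
        v <- readBin(con, "integer", n = spr[s], size = 2, endian = "little")
        j <- match(s, sig_idx)
        scale <- (pmax_[s] - pmin_[s]) / (dmax_[s] - dmin_[s])
        out[j, ((r - 1L) * spr[s] + 1L):(r * spr[s])] <-
          pmin_[s] + (v - dmin_[s]) * scale
      }
    }
  }
  markers <- .parse_stim_annotations(ann_raw)
  channels <- if (!is.null(montage)) {
    montage[match(labels[sig_idx], montage$label), , drop = FALSE]
  } else {
    data.frame(label = labels[sig_idx], role = NA_character_)
  }
  rownames(channels) <- NULL
  structure(list(signal = out, rate = spr[sig_idx[1]] / rec_dur,
                 channels = channels, markers = markers),
            class = "bci_recording")
}

.parse_stim_annotations <- function(ann_raw) {
  bytes <- do.call(c, ann_raw)
  if (is.null(bytes) || length(bytes) == 0L) return(NULL)
  nul <- bytes == as.raw(0)
  grp <- cumsum(nul)
  tals <- vapply(split(bytes[!nul], grp[!nul]), rawToChar, "")
  onset <- numeric(0)
  direction <- integer(0)
  for (tal in tals) {
    parts <- unlist(strsplit(tal, "\x14", fixed = TRUE))
    if (length(parts) >= 2 && grepl("^stim ", parts[2])) {
      onset <- c(onset, 1000 * as.numeric(parts[1]))
      direction <- c(direction, as.integer(sub("^stim ", "", parts[2])))
    }
  }
  if (length(onset) == 0L) return(NULL)
  data.frame(onset_ms = onset, direction = direction)
}

#' Write / read the stimulus marker table
#'
#' Tab-separated dialect with columns `onset_ms`, `direction`,
#' `target_direction`, `is_target`, `trial_id`, `iteration_id`,
#' `condition`; the companion of the EDF signal file.
#'
#' @param sequence a [generate_sequence()] result.
#' @param path file path.
#' @return the path ([write_markers()]) or a `bci_sequence`
#'   ([read_markers()]).
#' @export
write_markers <- function(sequence, path) {
  utils::write.table(as.data.frame(sequence), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_markers
#' @export
read_markers <- function(path) {
  df <- utils::read.delim(path)
  df$is_target <- as.logical(df$is_target)
  attr(df, "n_directions") <- max(df$direction)
  isi <- diff(df$onset_ms[df$trial_id == df$trial_id[1]])
  attr(df, "isi_ms") <- if (length(isi)) stats::median(isi) else NA_real_
  class(df) <- c("bci_sequence", "data.frame")
  df
}
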
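# Continuous-recording preprocessing: zero-phase band-pass filtering,
# regression-based blink correction, epoching, threshold rejection, averaging.

new_subject_erp <- function(data, times_ms, fs, subject, condition, n_trials,
                            reference = "CZ") {
  structure(list(data = data, times_ms = times_ms, fs = fs, subject = subject,
                 condition = condition, n_trials = n_trials,
                 reference = reference),
            class = "subject_erp")
}

#' @export
print.subject_erp <- function(x, ...) {
  cat(sprintf("<subject_erp: subject %s, condition %s, %d x %d, ref %s, %d trials>\n",
              x$subject, x$condition, nrow(x$data), ncol(x$data), x$reference,
              x$n_trials))
  invisible(x)
}

#' Zero-phase band-pass filter a continuous recording
#'
#' Butterworth cascade applied forward and backward (`signal::filtfilt`) for
#' zero phase shift: a 2nd-order high-pass (12 dB/octave single-pass slope)
#' at `low_hz` and an 8th-order low-pass (48 dB/octave) at `high_hz`. Edge
#' transients are controlled by odd reflection padding before the
#' bidirectional pass.
#'
#' @param recording An `eeg_recording`.
#' @param low_hz,high_hz Band edges in Hz (defaults 0.1 and 30).
#' @return The filtered `eeg_recording`.
#' @export
bandpass_zero_phase <- function(recording, low_hz = 0.1, high_hz = 30) {
  fs <- recording$fs
  n <- ncol(recording$data)
  pad <- min(n - 1L, as.integer(round(3 * fs / low_hz / 10)), 30000L)
  if (n < 10L * fs / high_hz || n < 3L)
    stopf("signal too short to filter (%d samples)", n)
  hp <- signal::butter(2, low_hz / (fs / 2), type = "high")
  lp <- signal::butter(8, high_hz / (fs / 2), type = "low")
  filt1 <- function(x) {
    # odd reflection padding at both ends
    left <- 2 * x[1] - x[(pad + 1L):2L]
    right <- 2 * x[n] - x[(n - 1L):(n - pad)]
    y <- c(left, x, right)
    y <- signal::filtfilt(lp, y)
    y <- signal::filtfilt(hp, y)
    y[(pad + 1L):(pad + n)]
  }
  recording$data <- t(apply(recording$data, 1, filt1))
  recording
}

# Blink sample mask: samples where |VEOG| exceeds `threshold_uv`, dilated by
# `dilate_ms` on both sides.
blink_mask <- function(veog, fs, threshold_uv = 100, dilate_ms = 200) {
  hits <- abs(veog) > threshold_uv
  if (!any(hits)) return(hits)
  d <- round(dilate_ms * fs / 1000)
  idx <- which(hits)
  mask <- logical(length(veog))
  for (i in idx) mask[max(1L, i - d):min(length(veog), i + d)] <- TRUE
  mask
}

#' Regression-based ocular artifact correction
#'
#' Implements the classic EOG regression correction: for each EEG channel a
#' propagation coefficient `b_i` is estimated by least squares of the
#' event-related-activity-subtracted EEG on the (equally corrected) VEOG over
#' blink segments, and `b_i * VEOG` is subtracted from the whole channel.
#' Blink segments are detected on VEOG by an amplitude threshold and dilated
#' by 200 ms. With no detected blinks the recording is returned unchanged
#' with a warning.
#'
#' @param recording An `eeg_recording` with a `VEOG` channel.
#' @param threshold_uv Blink detection threshold on VEOG (uV).
#' @return The corrected `eeg_recording`, with the estimated coefficients in
#'   attribute `blink_coef_hat`.
#' @export
correct_blinks <- function(recording, threshold_uv = 100) {
  if (!"VEOG" %in% rownames(recording$data))
    stopf("no VEOG channel in recording")
  veog <- recording$data["VEOG", ]
  mask <- blink_mask(veog, recording$fs, threshold_uv)
  if (!any(mask)) {
    warnf("no blinks detected; returning recording unchanged")
    attr(recording, "blink_coef_hat") <-
      setNames(rep(0, sum(rownames(recording$data) != "VEOG")),
               rownames(recording$data)[rownames(recording$data) != "VEOG"])
    return(recording)
  }
  eeg_rows <- which(rownames(recording$data) != "VEOG")
  # subtract average event-related activity before estimating propagation
  resid <- recording$data
  if (nrow(recording$events) > 0L) {
    ep_len <- round(recording$fs * 1.0) + 1L
    for (cid in unique(recording$events$condition_id)) {
      on <- recording$events$sample[recording$events$condition_id == cid]
      on <- on[on + ep_len - 1L <= ncol(resid)]
      if (length(on) < 2L) next
      era <- matrix(0, nrow(resid), ep_len)
      for (s in on) era <- era + recording$data[, s:(s + ep_len - 1L)]
      era <- era / length(on)
      for (s in on) resid[, s:(s + ep_len - 1L)] <-
          resid[, s:(s + ep_len - 1L)] - era
    }
  }
  v <- resid["VEOG", mask]
  v <- v - mean(v)
  b <- as.numeric(resid[eeg_rows, mask, drop = FALSE] %*% v -
                    rowMeans(resid[eeg_rows, mask, drop = FALSE]) * sum(v)) /
    sum(v^2)
  names(b) <- rownames(recording$data)[eeg_rows]
  recording$data[eeg_rows, ] <- recording$data[eeg_rows, ] -
    b %o% recording$data["VEOG", ]
  attr(recording, "blink_coef_hat") <- b
  recording
}

#' Cut a continuous recording into stimulus-locked epochs
#'
#' One epoch per event, covering `tmin`..`tmax` seconds around stimulus
#' onset (defaults -0.1..1.0 s, i.e. 1101 samples at 1 kHz). The mean over
#' the baseline interval (`tmin`..0) is subtracted per channel and epoch.
#'
#' @param recording An `eeg_recording`.
#' @param tmin,tmax Epoch window in seconds relative to stimulus onset.
#' @return An `epoch_set`: list with `data` (trials x channels x samples
#'   array), `times_ms`, `fs`, `channels`, `montage`, `trials` (tibble with
#'   `trial`, `condition_id`, `retained`), and planted-truth bookkeeping
#'   carried over from the recording.
#' @export
epoch_recording <- function(recording, tmin = -0.1, tmax = 1.0) {
  fs <- recording$fs
  pre <- round(-tmin * fs); post <- round(tmax * fs)
  len <- pre + post + 1L
  ev <- recording$events
  if (any(ev$sample - pre < 1L) || any(ev$sample + post > ncol(recording$data)))
    stopf("truncated epoch: event window extends beyond the recording")
  data <- array(0, dim = c(nrow(ev), nrow(recording$data), len),
                dimnames = list(NULL, rownames(recording$data), NULL))
  for (k in seq_len(nrow(ev))) {
    ep <- recording$data[, (ev$sample[k] - pre):(ev$sample[k] + post)]
    ep <- ep - rowMeans(ep[, seq_len(pre + 1L), drop = FALSE])
    data[k, , ] <- ep
  }
  structure(list(
    data = data, times_ms = seq(tmin * 1000, tmax * 1000, by = 1000 / fs),
    fs = fs, channels = rownames(recording$data), montage = recording$montage,
    trials = tibble::tibble(trial = ev$trial, condition_id = ev$condition_id,
                            retained = TRUE),
    truth = recording$truth
  ), class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set: %d trials (%d retained) x %d channels x %d samples>\n",
              dim(x$data)[1], sum(x$trials$retained), dim(x$data)[2],
              dim(x$data)[3]))
  invisible(x)
}

#' Flag epochs exceeding an absolute amplitude threshold
#'
#' Any epoch whose absolute value exceeds `threshold_uv` on any EEG channel
#' at any sample is flagged as rejected (the EOG channel is excluded from the
#' test). Epochs are assumed baseline-corrected.
#'
#' @param epochs An `epoch_set`.
#' @param threshold_uv Rejection threshold in uV (default 75).
#' @return The `epoch_set` with its `retained` flags updated.
#' @export
reject_artifacts <- function(epochs, threshold_uv = 75) {
  eeg_idx <- which(epochs$channels != "VEOG")
  peak <- apply(abs(epochs$data[, eeg_idx, , drop = FALSE]), 1, max)
  epochs$trials$retained <- peak <= threshold_uv
  if (!any(epochs$trials$retained)) warnf("all epochs rejected")
  epochs
}

#' Average retained epochs into per-condition subject ERPs
#'
#' Arithmetic mean over retained trials for each condition. The EOG channel
#' is dropped from the output; the reference state is inherited from
#' acquisition (`"CZ"`).
#'
#' @param epochs An `epoch_set`.
#' @param subject Subject identifier stored in the outputs.
#' @return A named list of `subject_erp` objects, one per condition.
#' @export
average_erp <- function(epochs, subject = 1L) {
  keep <- epochs$trials$retained
  eeg_idx <- which(epochs$channels != "VEOG")
  conds <- unique(epochs$trials$condition_id)
  out <- lapply(conds, function(cid) {
    sel <- keep & epochs$trials$condition_id == cid
    if (!any(sel)) stopf("empty cell: no retained trials for condition %s", cid)
    m <- apply(epochs$data[sel, eeg_idx, , drop = FALSE], c(2, 3), mean)
    rownames(m) <- epochs$channels[eeg_idx]
    new_subject_erp(m, epochs$times_ms, epochs$fs, subject = subject,
                    condition = cid, n_trials = sum(sel), reference = "CZ")
  })
  names(out) <- conds
  out
}

#' Re-reference a subject ERP to the common average
#'
#' Subtracts the instantaneous mean over all EEG channels; idempotent, and
#' leaves global field power unchanged.
#'
#' @param erp A `subject_erp`.
#' @return The re-referenced `subject_erp` (`reference = "average"`).
#' @export
rereference_average <- function(erp) {
  erp$data <- sweep(erp$data, 2, colMeans(erp$data))
  erp$reference <- "average"
  erp
}

#' Grand-average ERPs across subjects
#'
#' Each subject ERP is re-referenced to the common average before averaging.
#'
#' @param erps A list of `subject_erp` objects for the same condition.
#' @return A `subject_erp` with `subject = "grand"` and an `n_subjects`
#'   attribute.
#' @export
grand_average <- function(erps) {
  if (length(erps) < 2L) stopf("need >= 2 subjects for a grand average")
  mats <- lapply(erps, function(e) rereference_average(e)$data)
  g <- Reduce(`+`, mats) / length(mats)
  out <- new_subject_erp(g, erps[[1]]$times_ms, erps[[1]]$fs,
                         subject = "grand", condition = erps[[1]]$condition,
                         n_trials = NA_integer_, reference = "average")
  attr(out, "n_subjects") <- length(erps)
  out
}
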
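# File interchange: minimal EDF for continuous recordings (events in a CSV
# sidecar), CSV/JSON for tabular results.

#' Write a continuous recording to EDF
#'
#' Minimal European Data Format writer: 16-bit samples, one-second data
#' records, physical range taken from the data. Event markers are written to
#' a CSV sidecar (`<path>.events.csv`) with columns `sample`, `trial`,
#' `condition_id`, since the package does not use EDF+ annotation channels.
#'
#' @param recording An `eeg_recording`.
#' @param path Output file path (`.edf`).
#' @return `path`, invisibly.
#' @export
write_recording_edf <- function(recording, path) {
  X <- recording$data
  fs <- recording$fs
  K <- nrow(X)
  rec_len <- fs                       # samples per channel per 1 s record
  n_rec <- ceiling(ncol(X) / rec_len)
  pad <- n_rec * rec_len - ncol(X)
  if (pad > 0) X <- cbind(X, matrix(0, K, pad))
  pmin <- floor(apply(X, 1, min)); pmax <- ceiling(apply(X, 1, max))
  same <- pmax <= pmin
  pmax[same] <- pmin[same] + 1
  dmin <- -32768; dmax <- 32767

  fixed <- function(s, width) {
    s <- substr(paste0(s, strrep(" ", width)), 1, width)
    charToRaw(s)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  header <- c(
    fixed("0", 8), fixed("simulated", 80), fixed("synthetic EEG", 80),
    fixed("01.01.26", 8), fixed("00.00.00", 8),
    fixed(as.character(256 * (K + 1)), 8), fixed("", 44),
    fixed(as.character(n_rec), 8), fixed("1", 8), fixed(as.character(K), 4)
  )
  writeBin(unlist(header), con)
  field <- function(vals, width) unlist(lapply(vals, fixed, width = width))
  writeBin(field(rownames(X), 16), con)                      # label
  writeBin(field(rep("AgAgCl", K), 80), con)                 # transducer
  writeBin(field(rep("uV", K), 8), con)                      # dimension
  writeBin(field(format(pmin, trim = TRUE), 8), con)
  writeBin(field(format(pmax, trim = TRUE), 8), con)
  writeBin(field(rep(dmin, K), 8), con)
  writeBin(field(rep(dmax, K), 8), con)
  writeBin(field(rep("", K), 80), con)                       # prefiltering
  writeBin(field(rep(rec_len, K), 8), con)
  writeBin(field(rep("", K), 32), con)                       # reserved

  scale <- (dmax - dmin) / (pmax - pmin)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * rec_len + 1):(r * rec_len)
    dig <- round((X[, idx, drop = FALSE] - pmin) * scale + dmin)
    writeBin(as.integer(t(dig)), con, size = 2, endian = "little")
  }
  readr::write_csv(recording$events, paste0(path, ".events.csv"),
                   progress = FALSE)
  invisible(path)
}

#' Read a recording written by [write_recording_edf()]
#'
#' @param path Path to the `.edf` file; the `.events.csv` sidecar is read
#'   when present.
#' @param montage Montage to attach (labels must cover the EDF channels).
#' @return An `eeg_recording`.
#' @export
read_recording_edf <- function(path, montage = make_montage()) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width, n = 1) {
    vapply(seq_len(n), function(i)
      trimws(rawToChar(readBin(con, "raw", width))), character(1))
  }
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                   # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  K <- as.integer(rd(4))
  labels <- rd(16, K)
  rd(80, K); rd(8, K)
  pmin <- as.numeric(rd(8, K)); pmax <- as.numeric(rd(8, K))
  dmin <- as.numeric(rd(8, K)); dmax <- as.numeric(rd(8, K))
  rd(80, K)
  rec_len <- as.integer(rd(8, K))
  rd(32, K)
  X <- matrix(0, K, n_rec * rec_len[1], dimnames = list(labels, NULL))
  scale <- (pmax - pmin) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    dig <- readBin(con, "integer", K * rec_len[1], size = 2, signed = TRUE,
                   endian = "little")
    dig <- matrix(dig, rec_len[1], K)
    X[, ((r - 1) * rec_len[1] + 1):(r * rec_len[1])] <-
      t(dig - dmin) * scale + pmin
  }
  events_path <- paste0(path, ".events.csv")
  events <- if (file.exists(events_path))
    readr::read_csv(events_path, show_col_types = FALSE, progress = FALSE)
  else tibble::tibble(sample = integer(), trial = integer(),
                      condition_id = character())
  structure(list(data = X, fs = rec_len[1] / rec_dur, montage = montage,
                 events = events, truth = NULL),
            class = "eeg_recording")
}

#' Write a subject or grand-average ERP as CSV plus JSON metadata
#'
#' The CSV holds the channels x time matrix (one row per channel, first
#' column `channel`, remaining columns the time points in ms); the JSON
#' sidecar records reference state, trial count, subject and condition.
#'
#' @param erp A `subject_erp`.
#' @param path Output `.csv` path (the sidecar gets `.json` appended).
#' @return `path`, invisibly.
#' @export
write_erp_csv <- function(erp, path) {
  df <- tibble::as_tibble(erp$data, .name_repair = ~ as.character(erp$times_ms))
  df <- dplyr::bind_cols(tibble::tibble(channel = rownames(erp$data)), df)
  readr::write_csv(df, path, progress = FALSE)
  meta <- list(subject = erp$subject, condition = erp$condition,
               reference = erp$reference, n_trials = erp$n_trials,
               fs = erp$fs)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read an ERP written by [write_erp_csv()]
#'
#' @param path Path to the `.csv`.
#' @return A `subject_erp`.
#' @export
read_erp_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  m <- as.matrix(df[, -1])
  rownames(m) <- df$channel
  times <- as.numeric(colnames(df)[-1])
  colnames(m) <- NULL
  new_subject_erp(m, times, meta$fs, subject = meta$subject,
                  condition = meta$condition, n_trials = meta$n_trials,
                  reference = meta$reference)
}

#' Serialize a stimulus layout to a tidy tibble / CSV
#'
#' @param layout A `stimulus_layout`.
#' @param path Optional output CSV path.
#' @return The tidy tibble (one row per element, with shape metadata
#'   columns), invisibly when written.
#' @export
layout_to_table <- function(layout, path = NULL) {
  sh <- attr(layout, "shape")
  out <- dplyr::mutate(tibble::as_tibble(layout),
                       shape_kind = sh$kind,
                       circumradius_deg = sh$circumradius_deg,
                       orientation_rad = sh$orientation_rad,
                       condition = attr(layout, "condition") %||% NA_character_)
  if (!is.null(path)) {
    readr::write_csv(out, path, progress = FALSE)
    return(invisible(out))
  }
  out
}

#' Write a rendered stimulus to PNG with a luminance sidecar
#'
#' Grayscale PNG (8-bit) with a JSON sidecar recording the linear mapping
#' from pixel value back to cd/m^2, so the rendered luminances are
#' recoverable to quantization accuracy.
#'
#' @param img A `luminance_image` from [render_stimulus()].
#' @param path Output `.png` path.
#' @return `path`, invisibly.
#' @export
write_stimulus_png <- function(img, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stopf("the 'png' package is required for PNG output")
  disp <- attr(img, "display")
  lo <- 0
  hi <- disp$background_cd * 2
  m <- unclass(img)
  attr(m, "display") <- NULL
  png::writePNG((m - lo) / (hi - lo), path)
  jsonlite::write_json(list(cd_per_unit = hi - lo, offset_cd = lo,
                            background_cd = disp$background_cd),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
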
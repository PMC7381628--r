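#' Standard 64-channel montage with a vertical EOG channel
#'
#' Builds the electrode montage used throughout the package: 64 scalp
#' electrodes laid out according to the extended 10-20 system (with `Cz` as
#' the nominal online reference) plus one vertical EOG channel (`VEOG`)
#' placed below the left eye. Positions are unit vectors on a spherical head
#' model with the x axis pointing to the right ear, y to the nasion and z to
#' the vertex.
#'
#' Each scalp position is parameterised by a sagittal angle (degrees forward
#' of the vertex along the midline) given by the row letter (Fp = 72, AF = 54,
#' F = 36, FC = 18, C = 0, CP = -18, P = -36, PO = -54, O = -72) and a lateral
#' angle given by the electrode number (1/2 = 18, 3/4 = 36, 5/6 = 54,
#' 7/8 = 72 degrees; odd numbers left, even right).
#'
#' @return A tibble with columns `channel`, `x`, `y`, `z` and `type`
#'   (`"eeg"` or `"eog"`); 65 rows. All position vectors have unit norm.
#' @examples
#' m <- make_montage()
#' all(c("P7", "PO5", "PO7", "P8", "PO6", "PO8", "FC1", "FC3", "C1", "C3", "Cz")
#'     %in% m$channel)
#' @export
make_montage <- function() {
  rows <- list(
    Fp = list(72, c("Fp1", "Fpz", "Fp2")),
    AF = list(54, c("AF7", "AF3", "AFz", "AF4", "AF8")),
    F  = list(36, c("F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8")),
    FC = list(18, c("FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8")),
    C  = list(0,  c("T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8")),
    CP = list(-18, c("TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8")),
    P  = list(-36, c("P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8")),
    PO = list(-54, c("PO7", "PO5", "PO3", "POz", "PO4", "PO6", "PO8")),
    O  = list(-72, c("O1", "Oz", "O2"))
  )
  lateral_deg <- function(label) {
    if (grepl("z$", label)) return(0)
    k <- as.integer(sub("^[A-Za-z]+", "", label))
    side <- if (k %% 2L == 1L) -1 else 1
    side * c(18, 18, 36, 36, 54, 54, 72, 72)[k]
  }
  tabs <- purrr::map(rows, function(r) {
    a <- r[[1]] * pi / 180
    b <- purrr::map_dbl(r[[2]], lateral_deg) * pi / 180
    tibble::tibble(
      channel = r[[2]],
      x = cos(a) * sin(b),
      y = sin(a) + 0 * b,
      z = cos(a) * cos(b),
      type = "eeg"
    )
  })
  scalp <- dplyr::bind_rows(tabs)
  scalp <- dplyr::bind_rows(
    scalp,
    tibble::tibble(channel = "Iz", x = 0, y = sin(-pi / 2), z = cos(pi / 2),
                   type = "eeg")
  )
  # VEOG sits below and in front of the left eye, off the scalp proper.
  a <- 100 * pi / 180; b <- -15 * pi / 180
  veog <- tibble::tibble(channel = "VEOG", x = cos(a) * sin(b), y = sin(a),
                         z = cos(a) * cos(b), type = "eog")
  out <- dplyr::bind_rows(scalp, veog)
  stopifnot(!anyDuplicated(out$channel), nrow(out) == 65L)
  class(out) <- c("numerp_montage", class(out))
  out
}

# EEG channel labels of a montage, in montage order.
eeg_channels <- function(montage) montage$channel[montage$type == "eeg"]

# Pairwise great-circle (angular) distance matrix between montage positions.
montage_distances <- function(montage, channels = eeg_channels(montage)) {
  m <- montage[match(channels, montage$channel), ]
  P <- as.matrix(m[, c("x", "y", "z")])
  G <- tcrossprod(P)
  G[G > 1] <- 1; G[G < -1] <- -1
  D <- acos(G)
  dimnames(D) <- list(channels, channels)
  D
}

# Angular distance of each montage position to a single unit vector.
angles_to_point <- function(montage, point, channels = eeg_channels(montage)) {
  m <- montage[match(channels, montage$channel), ]
  P <- as.matrix(m[, c("x", "y", "z")])
  d <- drop(P %*% (point / sqrt(sum(point^2))))
  d[d > 1] <- 1; d[d < -1] <- -1
  stats::setNames(acos(d), channels)
}
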
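#' Analysis windows and electrode sets of the three ERP components
#'
#' N1 (160-220 ms) and N2 (250-400 ms) are quantified over the posterior
#' electrode pairs P7/PO5/PO7 (left) and P8/PO6/PO8 (right); the left
#' mid-frontal numerosity effect (LMF, 400-650 ms) over FC1, FC3, C1, C3.
#' Window endpoints are inclusive on both sides.
#'
#' @return A tibble with columns `component`, `t_start`, `t_end` (ms) and a
#'   list-column `electrodes`; rows N1, N2, LMF.
#' @export
component_windows <- function() {
  tibble::tibble(
    component = c("N1", "N2", "LMF"),
    t_start = c(160, 250, 400),
    t_end = c(220, 400, 650),
    electrodes = list(c("P7", "PO5", "PO7", "P8", "PO6", "PO8"),
                      c("P7", "PO5", "PO7", "P8", "PO6", "PO8"),
                      c("FC1", "FC3", "C1", "C3")),
    hemisphere_split = c(TRUE, TRUE, FALSE)
  )
}

# Gaussian bump on the sphere around a unit vector `centre`.
sphere_bump <- function(montage, centre, width) {
  a <- angles_to_point(montage, centre)
  exp(-(a / width)^2 / 2)
}

#' Re-express a map (or channels x time matrix) against the common average
#'
#' Subtracts the instantaneous mean across channels, making the topography
#' reference-free.
#'
#' @param x A numeric vector (one map) or channels x time matrix.
#' @return The average-referenced input.
#' @export
average_reference <- function(x) {
  if (is.matrix(x)) sweep(x, 2, colMeans(x)) else x - mean(x)
}

# Scale an average-referenced map to unit global field power.
unit_gfp <- function(v) v / sqrt(mean((v - mean(v))^2))

#' Generator template maps for the three evoked components
#'
#' Builds one average-referenced, unit-GFP scalp map per component on the 64
#' EEG channels of `montage`: a bilateral lateral-posterior map for N1 (bumps
#' near P7/P8), an occipital midline map for N2 (bump near Oz), and a left
#' fronto-central map for the LMF (bump at the centroid of FC1/FC3/C1/C3).
#' The widths keep all pairwise spatial correlations below 0.5, so the three
#' generators are distinguishable topographic states.
#'
#' @param montage A [make_montage()] tibble.
#' @param width Angular width (radians) of the LMF bump; the posterior bumps
#'   use slightly narrower fixed widths.
#' @return A 64 x 3 matrix (rownames = channels, colnames = N1/N2/LMF), each
#'   column average-referenced with unit GFP.
#' @export
make_templates <- function(montage = make_montage(), width = 0.55) {
  ch <- eeg_channels(montage)
  pos <- function(lab) {
    m <- montage[match(lab, montage$channel), c("x", "y", "z")]
    v <- colMeans(as.matrix(m))
    v / sqrt(sum(v^2))
  }
  n1 <- sphere_bump(montage, pos("P7"), 0.45) +
        sphere_bump(montage, pos("P8"), 0.45)
  n2 <- sphere_bump(montage, pos("Oz"), 0.5)
  lmf <- sphere_bump(montage, pos(c("FC1", "FC3", "C1", "C3")), width)
  tm <- cbind(N1 = n1, N2 = n2, LMF = lmf)
  tm <- apply(tm, 2, function(v) unit_gfp(average_reference(v)))
  rownames(tm) <- ch
  tm
}

# Component waveforms on a millisecond time axis (0..1000), unit peak.
component_waveform <- function(component, t_ms,
                               params = waveform_params()) {
  p <- params[[component]]
  if (p$shape == "gaussian") {
    exp(-((t_ms - p$center) / p$sd)^2 / 2)
  } else { # raised-cosine ramps around a plateau
    w <- numeric(length(t_ms))
    up <- t_ms > p$on & t_ms < p$on + p$ramp
    w[up] <- 0.5 * (1 - cos(pi * (t_ms[up] - p$on) / p$ramp))
    w[t_ms >= p$on + p$ramp & t_ms <= p$off - p$ramp] <- 1
    dn <- t_ms > p$off - p$ramp & t_ms < p$off
    w[dn] <- 0.5 * (1 - cos(pi * (p$off - t_ms[dn]) / p$ramp))
    w
  }
}

waveform_params <- function() {
  list(N1 = list(shape = "gaussian", center = 190, sd = 15),
       N2 = list(shape = "gaussian", center = 310, sd = 30),
       LMF = list(shape = "plateau", on = 400, off = 650, ramp = 40))
}

# Default per-condition component amplitudes (uV, in mean-window units).
# Orderings planted as simulation truth: N2 larger (less negative) for shape
# than random and for different than same polarity; LMF ordered 3 > 4 > 5 = 6.
default_amplitudes <- function(experiment) {
  conds <- condition_set(experiment)
  lmf_by_n <- c(`3` = 3.0, `4` = 2.1, `5` = 1.2, `6` = 1.2)
  n2 <- if (experiment == 3L) {
    ifelse(conds$polarity_scheme == "mixed", -3.0, -4.5)
  } else {
    ifelse(conds$configuration == "shape", -3.0, -4.5)
  }
  tidyr::crossing(condition_id = conds$condition_id,
                  component = c("N1", "N2", "LMF")) |>
    dplyr::left_join(conds, by = "condition_id") |>
    dplyr::mutate(amplitude = dplyr::case_when(
      .data$component == "N1" ~ -2.5,
      .data$component == "N2" ~ n2[match(.data$condition_id, conds$condition_id)],
      TRUE ~ unname(lmf_by_n[as.character(.data$n_elements)])
    )) |>
    dplyr::select("condition_id", "component", "amplitude")
}

# Default behavioural generator parameters per condition: Bernoulli accuracy
# and shifted-lognormal RTs. Accuracy falls and RT rises with numerosity;
# shape-like configurations are easier than random; same- vs different-
# polarity stimuli differ only marginally.
default_behavior_params <- function(experiment) {
  conds <- condition_set(experiment)
  acc_base <- c(`3` = 0.98, `4` = 0.95, `5` = 0.88, `6` = 0.82)
  rt_base <- c(`3` = 450, `4` = 490, `5` = 560, `6` = 600)
  acc <- acc_base[as.character(conds$n_elements)]
  rt <- rt_base[as.character(conds$n_elements)]
  if (experiment == 3L) {
    harder <- conds$polarity_scheme == "mixed"
    acc <- acc - ifelse(harder, 0.014, 0)
    rt <- rt + ifelse(harder, 7, 0)
  } else {
    harder <- conds$configuration == "random"
    acc <- acc - ifelse(harder, 0.06, 0)
    rt <- rt + ifelse(harder, 60, 0)
  }
  tibble::tibble(condition_id = conds$condition_id,
                 p_correct = pmin(pmax(unname(acc), 0), 1),
                 rt_shift_ms = 200,
                 rt_meanlog = log(unname(rt) - 200),
                 rt_sdlog = 0.22)
}

#' Noise and artifact specification for the synthetic recording
#'
#' @param sd Marginal noise standard deviation per EEG channel (uV).
#' @param ar AR(1) coefficient of the temporal noise model.
#' @param spatial_range Angular range (radians) of the exponential spatial
#'   correlation between electrodes.
#' @param blink_rate Blink rate (events per second) on the VEOG channel.
#' @param blink_amp_uv Peak blink amplitude on VEOG (uV).
#' @param artifact_rate Probability that a trial carries a gross-amplitude
#'   artifact (a 150 uV burst on one channel).
#' @param artifact_amp_uv Peak amplitude of planted gross artifacts (uV).
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(sd = 10, ar = 0.97, spatial_range = 0.8,
                       blink_rate = 0.1, blink_amp_uv = 250,
                       artifact_rate = 0.03, artifact_amp_uv = 150) {
  structure(list(sd = sd, ar = ar, spatial_range = spatial_range,
                 blink_rate = blink_rate, blink_amp_uv = blink_amp_uv,
                 artifact_rate = artifact_rate,
                 artifact_amp_uv = artifact_amp_uv),
            class = "noise_spec")
}

#' Ground truth for a simulated experiment
#'
#' Bundles everything the synthetic-data generator needs and everything the
#' recovery diagnostics compare against: the component template maps, the
#' per-condition component amplitude table (in mean-window uV), component
#' waveform parameters, blink propagation coefficients per channel, the
#' behavioural generator parameters and the noise specification.
#'
#' Blink propagation decays exponentially with angular distance from the
#' frontal pole, emulating volume conduction of the ocular dipole.
#'
#' @param experiment 1, 2 or 3.
#' @param montage A [make_montage()] tibble.
#' @param amplitudes Optional replacement amplitude table
#'   (`condition_id`, `component`, `amplitude`).
#' @param behavior Optional replacement behavioural parameter table.
#' @param noise A [noise_spec()].
#' @param subject_sd Between-subject SD (uV) of per-component amplitude
#'   deviations (shared across conditions within a subject).
#' @return A list of class `numerp_ground_truth`.
#' @export
make_ground_truth <- function(experiment = 1, montage = make_montage(),
                              amplitudes = NULL, behavior = NULL,
                              noise = noise_spec(),
                              subject_sd = c(N1 = 0.4, N2 = 0.4, LMF = 0.25)) {
  experiment <- as.integer(experiment)
  templates <- make_templates(montage)
  frontal_pole <- c(0, 1, 0.1); frontal_pole <- frontal_pole / sqrt(sum(frontal_pole^2))
  bcoef <- 0.25 * exp(-angles_to_point(montage, frontal_pole) / 0.9)
  structure(list(
    experiment = experiment,
    montage = montage,
    templates = templates,
    amplitudes = amplitudes %||% default_amplitudes(experiment),
    waveforms = waveform_params(),
    blink_coef = bcoef,
    behavior = behavior %||% default_behavior_params(experiment),
    noise = noise,
    subject_sd = subject_sd
  ), class = "numerp_ground_truth")
}

#' @export
print.numerp_ground_truth <- function(x, ...) {
  cat(sprintf("<numerp_ground_truth: experiment %d, %d conditions, %d channels>\n",
              x$experiment, length(unique(x$amplitudes$condition_id)),
              ncol(x$templates) * 0 + nrow(x$templates)))
  invisible(x)
}

# Scale factor turning a unit template (x) waveform into the requested
# mean-window amplitude: amplitude / (mean template value over the analysis
# electrodes x mean waveform value over the analysis window).
component_scale <- function(component, amplitude, ground_truth, fs = 1000) {
  win <- component_windows()
  w <- win[win$component == component, ]
  t_ms <- seq(0, 1000, by = 1000 / fs)
  in_win <- t_ms >= w$t_start & t_ms <= w$t_end
  wave <- component_waveform(component, t_ms, ground_truth$waveforms)
  tmpl_mean <- mean(ground_truth$templates[w$electrodes[[1]], component])
  amplitude / (tmpl_mean * mean(wave[in_win]))
}

#' Noise-free evoked epoch for one condition
#'
#' Sums the three component generators: each is the outer product of its
#' template map with its windowed waveform, scaled so that the mean amplitude
#' over the component's own analysis window and electrode set equals the
#' ground-truth amplitude table entry.
#'
#' @param condition_id A condition id present in the ground-truth amplitude
#'   table.
#' @param ground_truth A [make_ground_truth()] object.
#' @param fs Sampling rate (Hz).
#' @param subject_dev Optional named numeric of per-component amplitude
#'   deviations (uV) added to the table entries (between-subject variation).
#' @return A channels x samples matrix (uV) covering 0..1000 ms post-onset.
#' @export
evoked_signal <- function(condition_id, ground_truth, fs = 1000,
                          subject_dev = c(N1 = 0, N2 = 0, LMF = 0)) {
  t_ms <- seq(0, 1000, by = 1000 / fs)
  K <- nrow(ground_truth$templates)
  out <- matrix(0, K, length(t_ms),
                dimnames = list(rownames(ground_truth$templates), NULL))
  amps <- ground_truth$amplitudes[
    ground_truth$amplitudes$condition_id == condition_id, ]
  if (nrow(amps) == 0L) stopf("condition '%s' not in amplitude table", condition_id)
  for (i in seq_len(nrow(amps))) {
    comp <- amps$component[i]
    dev <- if (comp %in% names(subject_dev)) subject_dev[[comp]] else 0
    amp <- amps$amplitude[i] + dev
    if (is.na(amp) || amp == 0) next
    s <- component_scale(comp, amp, ground_truth, fs)
    wave <- component_waveform(comp, t_ms, ground_truth$waveforms)
    out <- out + s * tcrossprod(ground_truth$templates[, comp], wave)
  }
  attr(out, "times_ms") <- t_ms
  out
}

#' Synthetic scalp-map series built from planted templates
#'
#' Builds a map series in which each planted template is active in its own
#' contiguous window with a smooth (half-sine) strength envelope, plus iid
#' channel noise: the standard construction for testing microstate
#' segmentation recovery.
#'
#' @param templates Channels x q matrix of average-referenced template maps.
#' @param samples_per_state Number of time points per template window.
#' @param peak_uv Peak field strength (GFP) of each state, in uV.
#' @param noise_sd SD of iid channel noise added to every sample (uV).
#' @param seed Integer seed.
#' @return A channels x (q * samples_per_state) matrix with attribute
#'   `truth_labels` (the planted template index per time point).
#' @export
simulate_map_series <- function(templates, samples_per_state = 150,
                                peak_uv = 5, noise_sd = 0.5, seed = 1L) {
  q <- ncol(templates)
  env <- sin(pi * (seq_len(samples_per_state) - 0.5) / samples_per_state)
  X <- do.call(cbind, lapply(seq_len(q), function(m)
    tcrossprod(templates[, m], peak_uv * env)))
  X <- X + withr::with_seed(seed, matrix(rnorm(length(X), 0, noise_sd),
                                         nrow(X), ncol(X)))
  attr(X, "truth_labels") <- rep(seq_len(q), each = samples_per_state)
  X
}
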
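# Synthetic continuous EEG, behavioural tables, and the fast epoch-level
# simulation path.

# Spatially correlated AR(1) noise: K x n matrix with unit AR(1) processes in
# time (marginal sd `sd`) mixed by the Cholesky factor of an exponential
# spatial correlation over great-circle electrode distance.
simulate_noise <- function(montage, n, spec, seed = 1L,
                           channels = eeg_channels(montage)) {
  K <- length(channels)
  if (spec$sd == 0) return(matrix(0, K, n, dimnames = list(channels, NULL)))
  D <- montage_distances(montage, channels)
  C <- exp(-D / spec$spatial_range)
  L <- chol(C + diag(1e-9, K))
  withr::with_seed(seed, {
    innov_sd <- spec$sd * sqrt(1 - spec$ar^2)
    Z <- matrix(rnorm(K * n, 0, innov_sd), n, K)
    Z[1, ] <- rnorm(K, 0, spec$sd) # stationary start
    X <- if (spec$ar != 0)
      t(as.matrix(stats::filter(Z, spec$ar, method = "recursive")))
    else t(Z)
    X <- crossprod(L, X)
    rownames(X) <- channels
    X
  })
}

# Stereotyped biphasic blink waveform (unit peak) sampled at `fs`;
# 400 ms long: a 250 ms positive lobe followed by a 150 ms negative dip.
blink_waveform <- function(fs = 1000) {
  n1 <- round(0.25 * fs); n2 <- round(0.15 * fs)
  c(sin(pi * seq_len(n1) / n1), -0.25 * sin(pi * seq_len(n2) / n2))
}

#' Simulate a continuous EEG recording for one scheduled session
#'
#' Concatenates trials at a 1,100 ms inter-trial interval (100 ms stimulus +
#' 1,000 ms blank, plus up to 100 ms uniform jitter): each trial contributes
#' its condition's noise-free evoked epoch, on top of temporally
#' autocorrelated, spatially correlated background noise. Eye blinks are
#' added on the VEOG channel at a Poisson rate and propagated to every EEG
#' channel with the ground-truth propagation coefficients; a configurable
#' fraction of trials additionally carries a gross-amplitude artifact burst
#' on one random channel.
#'
#' @param schedule A [build_schedule()] tibble.
#' @param ground_truth A [make_ground_truth()] object.
#' @param noise A [noise_spec()]; defaults to the one stored in
#'   `ground_truth`.
#' @param seed Integer seed.
#' @param fs Sampling rate (Hz).
#' @param subject_dev Named per-component amplitude deviations (uV) for this
#'   subject.
#' @return An `eeg_recording`: list with `data` (65 x samples matrix, uV;
#'   rownames = channels, VEOG last), `fs`, `events` (tibble `sample`,
#'   `trial`, `condition_id`), `montage`, and planted ground-truth bookkeeping
#'   in `truth` (`blink_coef`, `artifact_trials`, `blink_samples`).
#' @export
simulate_recording <- function(schedule, ground_truth,
                               noise = ground_truth$noise, seed = 1L,
                               fs = 1000,
                               subject_dev = c(N1 = 0, N2 = 0, LMF = 0)) {
  if (nrow(schedule) == 0L) stopf("empty schedule")
  montage <- ground_truth$montage
  ch_eeg <- eeg_channels(montage)
  n_trials <- nrow(schedule)
  iti <- round(1.1 * fs)
  seeds <- derive_seeds(seed, 4L)
  jitter <- withr::with_seed(seeds[1], sample.int(round(0.1 * fs), n_trials,
                                                  replace = TRUE))
  onsets <- round(0.5 * fs) + cumsum(c(0L, rep(iti, n_trials - 1L))) + cumsum(jitter)
  n <- max(onsets) + round(1.1 * fs)

  X <- simulate_noise(montage, n, noise, seed = seeds[2])
  veog <- if (noise$sd > 0)
    withr::with_seed(seeds[2] + 1L, rnorm(n, 0, noise$sd / 2)) else numeric(n)

  # evoked responses (one template epoch per condition, reused across trials)
  epochs <- lapply(unique(schedule$condition_id), function(cid)
    evoked_signal(cid, ground_truth, fs = fs, subject_dev = subject_dev))
  names(epochs) <- unique(schedule$condition_id)
  ep_len <- ncol(epochs[[1]])
  for (k in seq_len(n_trials)) {
    idx <- onsets[k]:(onsets[k] + ep_len - 1L)
    X[, idx] <- X[, idx] + epochs[[schedule$condition_id[k]]]
  }

  # blinks: Poisson process on VEOG, propagated with the planted coefficients
  bw <- blink_waveform(fs)
  blink_samples <- integer(0)
  if (noise$blink_rate > 0) {
    blink_on <- withr::with_seed(seeds[3], {
      nb <- rpois(1, noise$blink_rate * n / fs)
      if (nb > 0) sort(sample.int(n - length(bw), nb)) else integer(0)
    })
    amps <- withr::with_seed(seeds[3] + 1L,
                             noise$blink_amp_uv * runif(length(blink_on), 0.8, 1.2))
    for (j in seq_along(blink_on)) {
      idx <- blink_on[j]:(blink_on[j] + length(bw) - 1L)
      veog[idx] <- veog[idx] + amps[j] * bw
      X[, idx] <- X[, idx] + ground_truth$blink_coef %o% (amps[j] * bw)
      blink_samples <- c(blink_samples, idx)
    }
  }

  # gross artifacts: per-trial Bernoulli, one channel, 100 ms half-sine burst
  artifact_trials <- integer(0)
  if (noise$artifact_rate > 0) {
    hit <- withr::with_seed(seeds[4], runif(n_trials) < noise$artifact_rate)
    artifact_trials <- which(hit)
    burst <- noise$artifact_amp_uv * sin(pi * seq_len(round(0.1 * fs)) / round(0.1 * fs))
    info <- withr::with_seed(seeds[4] + 1L, list(
      ch = sample.int(length(ch_eeg), length(artifact_trials), replace = TRUE),
      lat = sample(round(0.1 * fs):round(0.9 * fs), length(artifact_trials),
                   replace = TRUE)))
    for (j in seq_along(artifact_trials)) {
      s0 <- onsets[artifact_trials[j]] + info$lat[j]
      idx <- s0:(s0 + length(burst) - 1L)
      X[info$ch[j], idx] <- X[info$ch[j], idx] + burst
    }
  }

  data <- rbind(X, VEOG = veog)
  structure(list(
    data = data, fs = fs, montage = montage,
    events = tibble::tibble(sample = onsets, trial = schedule$trial,
                            condition_id = schedule$condition_id),
    truth = list(blink_coef = ground_truth$blink_coef,
                 artifact_trials = artifact_trials,
                 blink_samples = unique(blink_samples))
  ), class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording: %d channels x %d samples @ %g Hz, %d events>\n",
              nrow(x$data), ncol(x$data), x$fs, nrow(x$events)))
  invisible(x)
}

#' Simulate a behavioural response table
#'
#' Correctness is Bernoulli with the condition's planted accuracy; incorrect
#' reports are drawn uniformly from the other response options (3-6).
#' Reaction times are shifted lognormal with condition-dependent location.
#'
#' @param schedule A [build_schedule()] tibble.
#' @param ground_truth A [make_ground_truth()] object.
#' @param seed Integer seed.
#' @param subject Subject identifier stored in the output.
#' @return A tibble: `subject`, `trial`, `condition_id`, `configuration`,
#'   `polarity_scheme`, `n_elements`, `reported_number`, `correct`, `rt_ms`.
#' @export
simulate_behavior <- function(schedule, ground_truth, seed = 1L, subject = 1L) {
  if (nrow(schedule) == 0L) stopf("empty schedule")
  par <- ground_truth$behavior[
    match(schedule$condition_id, ground_truth$behavior$condition_id), ]
  withr::with_seed(seed, {
    correct <- rbinom(nrow(schedule), 1L, par$p_correct) == 1L
    reported <- schedule$n_elements
    wrong <- which(!correct)
    reported[wrong] <- vapply(schedule$n_elements[wrong], function(nn)
      sample(setdiff(3:6, nn), 1L), integer(1))
    rt <- par$rt_shift_ms + rlnorm(nrow(schedule), par$rt_meanlog, par$rt_sdlog)
  })
  tibble::tibble(subject = subject, trial = schedule$trial,
                 condition_id = schedule$condition_id,
                 configuration = schedule$configuration,
                 polarity_scheme = schedule$polarity_scheme,
                 n_elements = schedule$n_elements,
                 reported_number = reported, correct = correct, rt_ms = rt)
}

#' Simulate per-subject average ERPs directly (epoch-level path)
#'
#' Fast alternative to the full continuous-recording chain: for each subject
#' and condition it returns the planted evoked epoch (with per-subject
#' amplitude deviations) plus residual averaged noise with standard deviation
#' `noise$sd / sqrt(trials_per_condition)` (spatially and temporally
#' correlated as in the continuous model). Epochs cover -100..1000 ms; the
#' baseline interval carries noise only.
#'
#' @param experiment 1, 2 or 3.
#' @param ground_truth A [make_ground_truth()] object.
#' @param subjects Number of subjects.
#' @param trials_per_condition Trials averaged per condition (sets the
#'   residual noise level).
#' @param seed Integer seed.
#' @param fs Sampling rate (Hz).
#' @return An `erp_study`: list with `erps[[subject]][[condition_id]]`
#'   (channels x 1101 matrices, CZ-reference state), `times_ms`, `fs`,
#'   `montage`, `subject_dev` (the planted per-subject deviations).
#' @export
simulate_subject_erps <- function(experiment, ground_truth = NULL,
                                  subjects = 19, trials_per_condition = 100,
                                  seed = 1L, fs = 1000) {
  gt <- ground_truth %||% make_ground_truth(experiment)
  conds <- condition_set(experiment)
  montage <- gt$montage
  ch <- eeg_channels(montage)
  t_ms <- seq(-100, 1000, by = 1000 / fs)
  n_pre <- sum(t_ms < 0)
  noise_sd <- gt$noise$sd / sqrt(trials_per_condition)
  spec_avg <- gt$noise; spec_avg$sd <- noise_sd
  seeds <- derive_seeds(seed, subjects)
  erps <- lapply(seq_len(subjects), function(s) {
    dev_seed <- derive_seeds(seeds[s], 2L)
    dev <- withr::with_seed(dev_seed[1],
      stats::setNames(rnorm(length(gt$subject_sd), 0, gt$subject_sd),
                      names(gt$subject_sd)))
    cond_seeds <- derive_seeds(dev_seed[2], nrow(conds))
    out <- lapply(seq_len(nrow(conds)), function(ci) {
      ev <- evoked_signal(conds$condition_id[ci], gt, fs = fs, subject_dev = dev)
      noise <- simulate_noise(montage, length(t_ms), spec_avg,
                              seed = cond_seeds[ci])
      ep <- noise
      ep[, (n_pre + 1):length(t_ms)] <- ep[, (n_pre + 1):length(t_ms)] + ev
      # baseline correction, as the preprocessing chain would apply
      ep <- ep - rowMeans(ep[, seq_len(n_pre + 1), drop = FALSE])
      new_subject_erp(ep, t_ms, fs, subject = s,
                      condition = conds$condition_id[ci],
                      n_trials = trials_per_condition, reference = "CZ")
    })
    names(out) <- conds$condition_id
    out
  })
  structure(list(erps = erps, times_ms = t_ms, fs = fs, montage = montage,
                 experiment = as.integer(experiment)),
            class = "erp_study")
}
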
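# Shared fixtures, all built in code.

# A recording object wrapping an arbitrary channels x samples matrix.
make_rec <- function(data, fs = 1000, events = NULL) {
  structure(list(
    data = data, fs = fs, montage = make_montage(),
    events = events %||% tibble::tibble(sample = integer(), trial = integer(),
                                        condition_id = character()),
    truth = NULL
  ), class = "eeg_recording")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Ground truth with all stochastic nuisance switched off.
gt_quiet <- function(experiment = 1, ...) {
  make_ground_truth(experiment,
                    noise = noise_spec(sd = 0, blink_rate = 0,
                                       artifact_rate = 0),
                    subject_sd = c(N1 = 0, N2 = 0, LMF = 0), ...)
}

# Ground truth where only one component is planted.
gt_single_component <- function(component, experiment = 1) {
  gt <- gt_quiet(experiment)
  gt$amplitudes$amplitude[gt$amplitudes$component != component] <- 0
  gt
}

# Orthonormal zero-mean maps on K channels (columns), for planted-template
# constructions independent of the head model.
orthogonal_maps <- function(K, q) {
  C <- stats::contr.helmert(K)[, seq_len(q), drop = FALSE]
  apply(C, 2, function(v) (v - mean(v)) / sqrt(sum((v - mean(v))^2)))
}

# Subject x channel x time array filled from a generator function f(s).
subject_array <- function(S, K, Tn, f) {
  out <- array(0, dim = c(S, K, Tn))
  for (s in seq_len(S)) out[s, , ] <- f(s)
  out
}

expect_all_true <- function(x) expect_true(all(x))
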
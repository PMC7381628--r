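# Reference-free topographic measures and the randomization TANOVA.

#' Global field power
#'
#' Spatial root-mean-square of the average-referenced map:
#' `sqrt(mean((u - mean(u))^2))`. For a channels x time matrix, one value per
#' time point.
#'
#' @param x A numeric map (one value per channel) or a channels x time matrix.
#' @return A scalar, or a vector over time for matrix input.
#' @export
gfp <- function(x) {
  if (is.matrix(x)) {
    xc <- sweep(x, 2, colMeans(x))
    sqrt(colMeans(xc^2))
  } else {
    sqrt(mean((x - mean(x))^2))
  }
}

#' Spatial correlation between two scalp maps
#'
#' Pearson correlation across channels of the average-referenced maps;
#' polarity-sensitive (a map and its inverse correlate at -1).
#'
#' @param u,v Numeric maps (one value per channel).
#' @return Correlation in `[-1, 1]`.
#' @export
spatial_correlation <- function(u, v) {
  if (gfp(u) == 0 || gfp(v) == 0) stopf("zero-GFP map")
  stats::cor(u - mean(u), v - mean(v))
}

#' Global map dissimilarity (DISS)
#'
#' Root-mean-square difference between the two GFP-normalized,
#' average-referenced maps: a strength-independent index of configuration
#' divergence in `[0, 2]`, algebraically equal to `sqrt(2 * (1 - r))` with
#' `r` the spatial correlation.
#'
#' @param u,v Numeric maps (one value per channel).
#' @return DISS in `[0, 2]`.
#' @export
diss <- function(u, v) {
  gu <- gfp(u); gv <- gfp(v)
  if (gu == 0 || gv == 0) stopf("zero-GFP map")
  uc <- (u - mean(u)) / gu
  vc <- (v - mean(v)) / gv
  sqrt(mean((uc - vc)^2))
}

# Column-wise DISS between two channels x time matrices (no error on
# zero-GFP columns; returns NA there).
diss_series <- function(U, V) {
  Uc <- sweep(U, 2, colMeans(U)); Vc <- sweep(V, 2, colMeans(V))
  gu <- sqrt(colMeans(Uc^2)); gv <- sqrt(colMeans(Vc^2))
  out <- sqrt(colMeans((sweep(Uc, 2, gu, "/") - sweep(Vc, 2, gv, "/"))^2))
  out[gu == 0 | gv == 0] <- NA_real_
  out
}

# All 2^S - 1 non-identity sign patterns for S subjects (logical matrix).
all_sign_patterns <- function(S) {
  M <- 2^S - 1L
  out <- matrix(FALSE, M, S)
  for (s in seq_len(S)) out[, s] <- bitwAnd(seq_len(M), bitwShiftL(1L, s - 1L)) > 0L
  out
}

#' Point-wise randomization test on topographic dissimilarity (TANOVA)
#'
#' At every time point the observed statistic is the DISS between the grand
#' averages of two within-subject conditions. The null distribution is built
#' by randomly exchanging the two condition labels within each subject (fair
#' coin per subject), recomputing the grand averages and their DISS, `M`
#' times; `p = (1 + #{null >= observed}) / (M + 1)`. Consecutive significant
#' time points (`p < alpha`) are merged into windows and windows shorter than
#' `min_duration_ms` are discarded.
#'
#' With `exhaustive = TRUE` all `2^S - 1` non-identity sign patterns are
#' enumerated instead of Monte-Carlo sampling, which yields the exact
#' permutation p value (the identity pattern is the observed statistic and
#' contributes the `+1`).
#'
#' @param x,y Subject x channel x time arrays (same dimensions), one map
#'   series per subject and condition. Subjects must be matched across `x`
#'   and `y`.
#' @param M Number of random permutations (ignored when `exhaustive`).
#' @param alpha Significance level.
#' @param min_duration_ms Minimum duration of a reported window.
#' @param fs Sampling rate in Hz (to convert the duration criterion and to
#'   label time); default 1000.
#' @param times_ms Optional time axis (length = number of time points).
#' @param seed Integer seed for the sign patterns.
#' @param exhaustive Enumerate all sign patterns (requires a small number of
#'   subjects).
#' @return A `tanova_result`: tibble with columns `time_ms`, `diss`, `p`,
#'   `significant`, and attributes `windows` (tibble `start_ms`, `end_ms`),
#'   `M`, `alpha`.
#' @export
tanova <- function(x, y, M = 5000, alpha = 0.05, min_duration_ms = 10,
                   fs = 1000, times_ms = NULL, seed = 1L,
                   exhaustive = FALSE) {
  stopifnot(length(dim(x)) == 3L, all(dim(x) == dim(y)))
  S <- dim(x)[1]; K <- dim(x)[2]; Tn <- dim(x)[3]
  if (S < 2L) stopf("need >= 2 subjects")
  if (exhaustive && S > 20L) stopf("exhaustive enumeration limited to 20 subjects")
  signs <- if (exhaustive) all_sign_patterns(S) else
    withr::with_seed(seed, matrix(runif(M * S) < 0.5, M, S))
  M <- nrow(signs)
  Wflip <- matrix(as.numeric(signs), M, S)

  times_ms <- times_ms %||% ((seq_len(Tn) - 1L) * 1000 / fs)
  obs <- numeric(Tn); pvals <- numeric(Tn)
  for (t in seq_len(Tn)) {
    Xt <- x[, , t, drop = FALSE]; dim(Xt) <- c(S, K)
    Yt <- y[, , t, drop = FALSE]; dim(Yt) <- c(S, K)
    ga1 <- colMeans(Xt); ga2 <- colMeans(Yt)
    obs[t] <- diss(ga1, ga2)
    D <- Yt - Xt
    # permuted grand averages: flip adds D to group 1, removes it from 2
    P <- (Wflip %*% D) / S
    G1 <- matrix(ga1, M, K, byrow = TRUE) + P
    G2 <- matrix(ga2, M, K, byrow = TRUE) - P
    d_null <- diss_rows(G1, G2)
    # exact ties (e.g. the all-flip pattern, which only swaps the two grand
    # averages) must count as >= regardless of floating-point summation order
    pvals[t] <- (1 + sum(d_null >= obs[t] - 1e-10)) / (M + 1)
  }
  sig <- pvals < alpha
  min_samples <- max(1L, ceiling(min_duration_ms * fs / 1000))
  runs <- logical_runs(sig)
  runs <- runs[runs$length >= min_samples, , drop = FALSE]
  keep <- rep(FALSE, Tn)
  for (i in seq_len(nrow(runs))) keep[runs$start[i]:runs$end[i]] <- TRUE
  out <- tibble::tibble(time_ms = times_ms, diss = obs, p = pvals,
                        significant = keep)
  attr(out, "windows") <- tibble::tibble(
    start_ms = times_ms[runs$start], end_ms = times_ms[runs$end])
  attr(out, "M") <- M
  attr(out, "alpha") <- alpha
  class(out) <- c("tanova_result", class(out))
  out
}

# Row-wise DISS between two M x K matrices of maps.
diss_rows <- function(U, V) {
  Uc <- U - rowMeans(U); Vc <- V - rowMeans(V)
  gu <- sqrt(rowMeans(Uc^2)); gv <- sqrt(rowMeans(Vc^2))
  sqrt(rowMeans((Uc / gu - Vc / gv)^2))
}

#' Average matched conditions into one map series per subject and group
#'
#' Reduces a multi-condition contrast (e.g. low {3,4} vs. high {5,6}
#' numerosity) to a two-group within-subject design by averaging each
#' subject's ERPs within group, as required by [tanova()].
#'
#' @param study An `erp_study` or nested list `erps[[subject]][[condition]]`.
#' @param conditions Character vector of condition ids to average.
#' @param window_ms Optional `c(start, end)` restriction of the time axis.
#' @return A subject x channel x time array (common-average referenced).
#' @export
condition_group_array <- function(study, conditions, window_ms = NULL) {
  erps <- if (inherits(study, "erp_study")) study$erps else study
  first <- rereference_average(erps[[1]][[conditions[1]]])
  sel <- if (is.null(window_ms)) rep(TRUE, length(first$times_ms))
         else first$times_ms >= window_ms[1] & first$times_ms <= window_ms[2]
  K <- nrow(first$data); Tn <- sum(sel); S <- length(erps)
  out <- array(0, dim = c(S, K, Tn),
               dimnames = list(NULL, rownames(first$data), NULL))
  for (s in seq_len(S)) {
    acc <- 0
    for (cid in conditions)
      acc <- acc + rereference_average(erps[[s]][[cid]])$data[, sel]
    out[s, , ] <- acc / length(conditions)
  }
  attr(out, "times_ms") <- first$times_ms[sel]
  out
}

#' @export
tidy.tanova_result <- function(x, ...) {
  out <- x; class(out) <- class(tibble::tibble()); tibble::as_tibble(out)
}

#' @export
glance.tanova_result <- function(x, ...) {
  w <- attr(x, "windows")
  tibble::tibble(n_windows = nrow(w), M = attr(x, "M"),
                 alpha = attr(x, "alpha"), min_p = min(x$p))
}
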
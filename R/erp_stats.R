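# Component mean amplitudes and within-subject statistics.

#' Component mean amplitude of a subject ERP
#'
#' Arithmetic mean of the ERP over the samples inside the component window
#' (endpoints inclusive), per listed electrode. The ERP is expected to be
#' common-average referenced for topographic comparability.
#'
#' @param erp A `subject_erp`.
#' @param window One row of [component_windows()] (or a compatible list with
#'   `component`, `t_start`, `t_end`, `electrodes`).
#' @return A tibble: `subject`, `condition_id`, `component`, `electrode`,
#'   `hemisphere`, `amplitude` (uV).
#' @export
mean_amplitude <- function(erp, window) {
  electrodes <- if (is.list(window$electrodes)) window$electrodes[[1]] else window$electrodes
  missing <- setdiff(electrodes, rownames(erp$data))
  if (length(missing) > 0L)
    stopf("missing electrode(s): %s", paste(missing, collapse = ", "))
  sel <- erp$times_ms >= window$t_start & erp$times_ms <= window$t_end
  if (!any(sel)) stopf("window outside the epoch")
  amps <- rowMeans(erp$data[electrodes, sel, drop = FALSE])
  hemi <- ifelse(grepl("[1357]$", electrodes), "left",
                 ifelse(grepl("[2468]$", electrodes), "right", "midline"))
  tibble::tibble(subject = erp$subject, condition_id = erp$condition,
                 component = window$component, electrode = electrodes,
                 hemisphere = hemi, amplitude = unname(amps))
}

#' Component amplitude table for a whole study
#'
#' Applies [mean_amplitude()] to every subject x condition ERP of an
#' `erp_study` (or a nested list `erps[[subject]][[condition]]`) for every
#' component window, after common-average re-referencing.
#'
#' @param study An `erp_study` or nested list of `subject_erp` objects.
#' @param windows A [component_windows()]-shaped tibble.
#' @return A tidy tibble, one row per subject x condition x component x
#'   electrode.
#' @export
amplitude_table <- function(study, windows = component_windows()) {
  erps <- if (inherits(study, "erp_study")) study$erps else study
  purrr::map_dfr(erps, function(subj)
    purrr::map_dfr(subj, function(e) {
      er <- rereference_average(e)
      purrr::map_dfr(seq_len(nrow(windows)), function(i)
        mean_amplitude(er, windows[i, ]))
    }))
}

# Normalized Helmert contrasts (orthonormal rows) for a k-level factor.
orthonormal_contrasts <- function(k) {
  C <- t(stats::contr.helmert(k))
  C / sqrt(rowSums(C^2))
}

#' Repeated-measures ANOVA for fully within-subject designs
#'
#' Classical univariate repeated-measures ANOVA via orthonormal-contrast
#' projection: for each effect (main effects and all interactions of the
#' `within` factors) the subject x cell matrix is projected onto the
#' effect's orthonormal contrast space; the F statistic is the ratio of the
#' effect mean square to the effect-by-subject mean square. The
#' Greenhouse-Geisser epsilon is estimated from the covariance of the
#' contrast scores as `(tr V)^2 / (d * tr(V^2))` and applied to the degrees
#' of freedom of effects with more than one numerator df; partial eta squared
#' is `SS_effect / (SS_effect + SS_error)`.
#'
#' @param data A data frame with one row per subject x cell.
#' @param dv Name of the dependent-variable column.
#' @param within Character vector of within-subject factor column names.
#' @param subject Name of the subject identifier column.
#' @return A tibble of class `anova_result`: one row per effect with columns
#'   `effect`, `df1`, `df2`, `statistic` (F), `gg_epsilon`, `p_uncorrected`,
#'   `p` (GG-corrected where applied), `pes` (partial eta squared), `n`.
#' @examples
#' d <- tidyr::crossing(subject = 1:8, a = c("x", "y"))
#' d$y <- rnorm(nrow(d)) + (d$a == "x")
#' rm_anova(d, "y", within = "a")
#' @export
rm_anova <- function(data, dv, within, subject = "subject") {
  data <- dplyr::ungroup(tibble::as_tibble(data))
  for (f in c(within, subject)) if (!f %in% names(data)) stopf("missing column '%s'", f)
  data[[subject]] <- factor(data[[subject]])
  levs <- lapply(within, function(f) {
    v <- data[[f]]
    if (is.factor(v)) levels(droplevels(v)) else sort(unique(v))
  })
  names(levs) <- within
  k <- vapply(levs, length, integer(1))
  cells <- rev(expand.grid(rev(levs), stringsAsFactors = FALSE))
  names(cells) <- within
  m <- nrow(cells)
  key <- function(df) do.call(paste, c(df[within], sep = "\r"))
  data$..cell <- match(key(data), key(cells))
  if (anyNA(data$..cell)) stopf("unexpected factor combination in data")
  counts <- table(data[[subject]], data$..cell)
  if (any(counts == 0L)) stopf("missing cell: design must be complete")
  if (any(counts > 1L)) stopf("unbalanced design: more than one row per subject x cell")
  subj_levels <- levels(data[[subject]])
  n <- length(subj_levels)
  if (n < 2L) stopf("need >= 2 subjects")
  Y <- matrix(NA_real_, n, m)
  Y[cbind(match(data[[subject]], subj_levels), data$..cell)] <- data[[dv]]

  effects <- unlist(lapply(seq_along(within), function(r)
    utils::combn(within, r, simplify = FALSE)), recursive = FALSE)
  res <- purrr::map_dfr(effects, function(eff) {
    # Kronecker product over factors, first factor slowest (matches cells)
    C <- Reduce(kronecker, lapply(within, function(f)
      if (f %in% eff) orthonormal_contrasts(k[[f]])
      else matrix(1 / sqrt(k[[f]]), 1, k[[f]])))
    d <- nrow(C)
    Z <- Y %*% t(C)
    mz <- colMeans(Z)
    ss_eff <- n * sum(mz^2)
    Zc <- sweep(Z, 2, mz)
    ss_err <- sum(Zc^2)
    Fval <- (ss_eff / d) / (ss_err / (d * (n - 1)))
    V <- crossprod(Zc) / (n - 1)
    eps <- if (d == 1L) 1 else sum(diag(V))^2 / (d * sum(V * V))
    p_unc <- pf(Fval, d, d * (n - 1), lower.tail = FALSE)
    p_gg <- pf(Fval, eps * d, eps * d * (n - 1), lower.tail = FALSE)
    tibble::tibble(effect = paste(eff, collapse = ":"),
                   df1 = d, df2 = d * (n - 1), statistic = Fval,
                   gg_epsilon = eps, p_uncorrected = p_unc,
                   p = if (d > 1L) p_gg else p_unc,
                   pes = ss_eff / (ss_eff + ss_err), n = n)
  })
  class(res) <- c("anova_result", class(res))
  res
}

#' Bonferroni-corrected pairwise paired comparisons
#'
#' All pairwise paired t-tests between the levels of `factor` (averaging over
#' any other cells within subject x level first); p values are multiplied by
#' the number of comparisons and clipped at 1.
#'
#' @inheritParams rm_anova
#' @param factor Name of the factor column to compare.
#' @return A tibble: `level1`, `level2`, `mean_diff`, `statistic` (t), `df`,
#'   `p`, `p_adj`.
#' @export
bonferroni_posthoc <- function(data, dv, factor, subject = "subject") {
  agg <- data |>
    dplyr::group_by(.data[[subject]], .data[[factor]]) |>
    dplyr::summarise(..v = mean(.data[[dv]]), .groups = "drop")
  levs <- if (is.factor(agg[[factor]])) levels(droplevels(agg[[factor]]))
          else sort(unique(agg[[factor]]))
  if (length(levs) < 2L) stopf("factor needs >= 2 levels")
  pairs <- utils::combn(levs, 2, simplify = FALSE)
  m <- length(pairs)
  wide <- tidyr::pivot_wider(agg, names_from = dplyr::all_of(factor),
                             values_from = "..v")
  res <- purrr::map_dfr(pairs, function(pr) {
    x <- wide[[as.character(pr[1])]]; y <- wide[[as.character(pr[2])]]
    tt <- stats::t.test(x, y, paired = TRUE)
    tibble::tibble(level1 = as.character(pr[1]), level2 = as.character(pr[2]),
                   mean_diff = mean(x - y), statistic = unname(tt$statistic),
                   df = unname(tt$parameter), p = tt$p.value,
                   p_adj = min(1, tt$p.value * m))
  })
  attr(res, "n_comparisons") <- m
  res
}

#' Behavioural accuracy and reaction-time ANOVAs
#'
#' Aggregates the trial-level behaviour table to per-subject, per-condition
#' accuracy (proportion correct) and mean RT, then runs [rm_anova()] on each.
#' By default all trials enter the RT aggregate; set `correct_only = TRUE`
#' to restrict RTs to correct trials.
#'
#' @param behavior A [simulate_behavior()]-shaped tibble (may contain several
#'   subjects).
#' @param within Within-subject factors (default depends on the experiment
#'   columns present: configuration or polarity crossed with numerosity).
#' @param correct_only Use only correct trials for the RT aggregate.
#' @return A list of class `behavior_stats`: `cells` (per-subject cell
#'   means), `accuracy` and `rt` (both `anova_result` tibbles).
#' @export
behavior_stats <- function(behavior, within = NULL, correct_only = FALSE) {
  if (length(unique(behavior$subject)) < 2L)
    stopf("need >= 2 subjects for behavioural ANOVAs")
  if (is.null(within)) {
    within <- if (dplyr::n_distinct(behavior$polarity_scheme) > 1L)
      c("polarity_scheme", "n_elements") else c("configuration", "n_elements")
  }
  cells <- behavior |>
    dplyr::group_by(.data$subject, dplyr::across(dplyr::all_of(within))) |>
    dplyr::summarise(
      accuracy = mean(.data$correct),
      rt_ms = if (correct_only) mean(.data$rt_ms[.data$correct])
              else mean(.data$rt_ms),
      .groups = "drop")
  structure(list(
    cells = cells,
    accuracy = rm_anova(cells, "accuracy", within = within),
    rt = rm_anova(cells, "rt_ms", within = within)
  ), class = "behavior_stats")
}

#' @export
print.behavior_stats <- function(x, ...) {
  cat("Accuracy ANOVA:\n"); print(x$accuracy)
  cat("RT ANOVA:\n"); print(x$rt)
  invisible(x)
}

#' @export
tidy.anova_result <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.anova_result <- function(x, ...) {
  tibble::tibble(n_effects = nrow(x), n = x$n[1],
                 min_p = min(x$p), sig_effects = sum(x$p < 0.05))
}
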
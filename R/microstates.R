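# Microstate segmentation by atomize-and-agglomerate hierarchical clustering
# (AAHC), cross-validation model selection, and GEV back-fitting.

# Internal AAHC engine. V: K x T matrix of unit-L2-norm, average-referenced
# maps; g2: squared L2 norms of the original maps. Polarity-sensitive: maps
# and their inverses are treated as different states. Returns snapshots of
# (templates, labels) at every cluster count in q_range.
aahc_engine <- function(V, g2, q_range) {
  K <- nrow(V); Tn <- ncol(V)
  stopifnot(max(q_range) <= Tn)
  label <- seq_len(Tn)              # cluster id per time point
  members <- as.list(seq_len(Tn))
  Ssum <- V                         # K x Tn: per-cluster sums of member maps
  num <- g2                         # per-cluster GEV numerator (Inf = dead)
  # live templates are kept packed in the first C columns of Apack
  Apack <- V
  pack2cluster <- seq_len(Tn)
  cluster2pack <- seq_len(Tn)
  snapshots <- vector("list", max(q_range))

  recompute <- function(c) {
    mem <- members[[c]]
    a <- Ssum[, c]
    a <- a / sqrt(sum(a^2))
    Apack[, cluster2pack[c]] <<- a
    pr <- crossprod(V[, mem, drop = FALSE], a)  # (v_t' a); |v|=1
    num[c] <<- sum(g2[mem] * pr^2)
  }

  C <- Tn
  repeat {
    if (C %in% q_range) {
      snapshots[[C]] <- list(templates = Apack[, seq_len(C), drop = FALSE],
                             labels = cluster2pack[label])
    }
    if (C <= min(q_range)) break
    worst <- which.min(num)
    mem <- members[[worst]]
    members[[worst]] <- integer(0)
    num[worst] <- Inf
    # drop the dead template from the packed set (swap in the last column)
    p <- cluster2pack[worst]
    if (p != C) {
      Apack[, p] <- Apack[, C]
      moved <- pack2cluster[C]
      pack2cluster[p] <- moved
      cluster2pack[moved] <- p
    }
    C <- C - 1L
    # reassign each member to the best-correlated surviving template
    W <- crossprod(V[, mem, drop = FALSE], Apack[, seq_len(C), drop = FALSE])
    dest <- pack2cluster[max.col(W, ties.method = "first")]
    for (d in unique(dest)) {
      take <- mem[dest == d]
      members[[d]] <- c(members[[d]], take)
      Ssum[, d] <- Ssum[, d] + rowSums(V[, take, drop = FALSE])
      label[take] <- d
    }
    for (d in unique(dest)) recompute(d)
  }
  snapshots
}

# Relabel segments shorter than min_samples to the better-correlated flanking
# template, independently within each block (condition). Iterative until
# stable or the iteration cap.
smooth_labels <- function(labels, V, templates, min_samples, blocks) {
  if (min_samples <= 1L) return(labels)
  for (b in unique(blocks)) {
    idx <- which(blocks == b)
    lab <- labels[idx]
    r <- rle(lab)
    nr <- length(r$lengths)
    if (nr <= 1L) next
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    val <- r$values; len <- r$lengths
    prv <- c(0L, seq_len(nr - 1L)); nxt <- c(seq_len(nr)[-1L], 0L)
    alive <- rep(TRUE, nr)
    # merge each too-short segment, whole, into the better-correlated
    # flanking segment; every merge removes at least one run, so this
    # terminates with no short runs (or a single run) per block
    repeat {
      short <- which(alive & len < min_samples)
      if (length(short) == 0L) break
      i <- short[which.min(len[short])]
      if (prv[i] == 0L && nxt[i] == 0L) break  # single run left
      span <- starts[i]:ends[i]
      Vs <- V[, idx[span], drop = FALSE]
      score <- function(j) if (j == 0L) -Inf
               else sum(crossprod(Vs, templates[, val[j]]))
      w <- if (score(nxt[i]) > score(prv[i])) nxt[i] else prv[i]
      lab[span] <- val[w]
      # grow the winner over the dissolved run
      starts[w] <- min(starts[w], starts[i]); ends[w] <- max(ends[w], ends[i])
      len[w] <- ends[w] - starts[w] + 1L
      alive[i] <- FALSE
      o <- if (w == prv[i]) nxt[i] else prv[i]     # run on the far side
      if (w == prv[i]) { nxt[w] <- o; if (o > 0L) prv[o] <- w }
      else { prv[w] <- o; if (o > 0L) nxt[o] <- w }
      # coalesce if the winner now touches a run with the same template
      if (o > 0L && val[o] == val[w]) {
        starts[w] <- min(starts[w], starts[o]); ends[w] <- max(ends[w], ends[o])
        len[w] <- ends[w] - starts[w] + 1L
        alive[o] <- FALSE
        oo <- if (o == nxt[w]) nxt[o] else prv[o]
        if (o == nxt[w]) { nxt[w] <- oo; if (oo > 0L) prv[oo] <- w }
        else { prv[w] <- oo; if (oo > 0L) nxt[oo] <- w }
      }
    }
    labels[idx] <- lab
  }
  labels
}

#' Cross-validation criterion for a microstate model
#'
#' Residual variance of the labelled map series under unit-norm templates,
#' penalized for the number of templates:
#' `sigma2 = sum_t (u_t'u_t - (a_{L_t}'u_t)^2) / (T (K - 1))` and
#' `CV = sigma2 * ((K - 1) / (K - 1 - q))^2`.
#'
#' @param series Channels x time matrix of average-referenced maps.
#' @param templates Channels x q matrix of template maps (any scale; they are
#'   normalized to unit L2 norm internally).
#' @param labels Integer template assignment per time point (NA time points
#'   are skipped).
#' @return A list with `sigma2`, `cv`, `q`.
#' @export
cv_criterion <- function(series, templates, labels) {
  K <- nrow(series); q <- ncol(templates)
  if (q >= K - 1L) stopf("q must be smaller than K - 1")
  A <- apply(templates, 2, function(a) a / sqrt(sum(a^2)))
  keep <- !is.na(labels)
  U <- series[, keep, drop = FALSE]
  lab <- labels[keep]
  Tn <- ncol(U)
  u2 <- colSums(U^2)
  proj <- colSums(U * A[, lab, drop = FALSE])
  sigma2 <- max(0, sum(u2 - proj^2) / (Tn * (K - 1)))
  list(sigma2 = sigma2, cv = sigma2 * ((K - 1) / (K - 1 - q))^2, q = q)
}

#' Segment a grand-average map series into microstates (AAHC)
#'
#' Atomize-and-agglomerate hierarchical clustering of the concatenated
#' grand-average ERPs of all conditions: every time-point map starts as its
#' own cluster; the cluster contributing least global explained variance is
#' repeatedly dissolved and its members reassigned to the cluster with the
#' highest polarity-sensitive spatial correlation. Templates (normalized
#' means of member maps) and labels are recorded at every candidate map
#' count, segments shorter than `min_segment_ms` are relabelled to the
#' better-correlated neighbour, and the optimal map count `q_star` minimizes
#' the cross-validation criterion.
#'
#' @param series Either a channels x time matrix, or a named list of
#'   channels x time matrices (one per condition, concatenated internally).
#'   Maps must be average-referenced; zero-GFP time points are dropped.
#' @param q_range Candidate map counts (default 1..12).
#' @param min_segment_ms Minimum accepted segment duration (ms).
#' @param fs Sampling rate in Hz.
#' @return A `microstate_segmentation`: list with `templates` (list by q,
#'   channels x q, unit L2 norm), `labels` (list by q, per retained time
#'   point), `criteria` (tibble `q`, `sigma2`, `cv`), `q_star`, `blocks`
#'   (condition id per retained time point), `series` (the retained maps),
#'   `channels`.
#' @export
segment_microstates <- function(series, q_range = 1:12, min_segment_ms = 10,
                                fs = 1000) {
  if (is.list(series)) {
    blocks <- rep(names(series) %||% seq_along(series),
                  vapply(series, ncol, integer(1)))
    X <- do.call(cbind, series)
  } else {
    blocks <- rep("series", ncol(series))
    X <- series
  }
  X <- average_reference(X)
  g <- sqrt(colSums(X^2))
  keep <- g > 1e-12
  if (!any(keep)) stopf("degenerate input: all maps have zero GFP")
  X <- X[, keep, drop = FALSE]; blocks <- blocks[keep]; g <- g[keep]
  K <- nrow(X); Tn <- ncol(X)
  q_range <- q_range[q_range < K - 1L & q_range <= Tn]
  V <- sweep(X, 2, g, "/")
  min_samples <- max(1L, ceiling(min_segment_ms * fs / 1000))

  snaps <- aahc_engine(V, g^2, q_range)
  crit <- purrr::map_dfr(sort(q_range), function(q) {
    sn <- snaps[[q]]
    lab <- smooth_labels(sn$labels, V, sn$templates, min_samples, blocks)
    snaps[[q]]$labels <<- lab
    cv <- cv_criterion(X, sn$templates, lab)
    tibble::tibble(q = q, sigma2 = cv$sigma2, cv = cv$cv)
  })
  # smallest q within numerical tolerance of the CV minimum (exact fits tie
  # at zero residual for every q at or above the true map count)
  cv_min <- min(crit$cv)
  tol <- max(1e-12 * mean(colSums(X^2)) / (K - 1), 1e-9 * abs(cv_min))
  q_star <- min(crit$q[crit$cv <= cv_min + tol])
  structure(list(
    templates = stats::setNames(lapply(sort(q_range), function(q)
      snaps[[q]]$templates), paste0("q", sort(q_range))),
    labels = stats::setNames(lapply(sort(q_range), function(q)
      snaps[[q]]$labels), paste0("q", sort(q_range))),
    criteria = crit, q_star = q_star, blocks = blocks, series = X,
    channels = rownames(X), fs = fs, min_segment_ms = min_segment_ms
  ), class = "microstate_segmentation")
}

#' @export
print.microstate_segmentation <- function(x, ...) {
  cat(sprintf("<microstate_segmentation: %d maps x %d time points, q* = %d>\n",
              nrow(x$series), ncol(x$series), x$q_star))
  print(x$criteria)
  invisible(x)
}

#' Templates of the selected (or given) microstate map count
#'
#' @param seg A `microstate_segmentation`.
#' @param q Map count (defaults to the CV-selected `q_star`).
#' @return A channels x q matrix of unit-norm template maps.
#' @export
segmentation_templates <- function(seg, q = seg$q_star) {
  tm <- seg$templates[[paste0("q", q)]]
  if (is.null(tm)) stopf("no snapshot recorded for q = %d", q)
  rownames(tm) <- seg$channels
  colnames(tm) <- paste0("map", seq_len(ncol(tm)))
  tm
}

#' Back-fit microstate templates to an individual ERP
#'
#' Each time point in the analysis window is assigned (winner-take-all) to
#' the template with the highest polarity-sensitive spatial correlation; ties
#' break to the lowest template index. The global explained variance of
#' template `m` is `GEV_m = sum_{t: L_t = m} (GFP_t r_t)^2 / sum_t GFP_t^2`
#' with sums over the window. Zero-GFP time points are skipped with a
#' warning.
#'
#' @param erp A `subject_erp` (will be common-average re-referenced).
#' @param templates Channels x q template matrix (rows matched to the ERP's
#'   channels by name when both are named).
#' @param window One row of [component_windows()] or `NULL` for the full
#'   epoch.
#' @return A list of class `microstate_fit`: `labels` (per window time
#'   point), `gev` (tibble `subject`, `condition_id`, `component`,
#'   `template`, `gev`), `times_ms`.
#' @export
backfit_microstates <- function(erp, templates, window = NULL) {
  e <- rereference_average(erp)
  if (!is.null(rownames(templates)) && !is.null(rownames(e$data)))
    templates <- templates[rownames(e$data), , drop = FALSE]
  sel <- if (is.null(window)) rep(TRUE, length(e$times_ms))
         else e$times_ms >= window$t_start & e$times_ms <= window$t_end
  U <- average_reference(e$data[, sel, drop = FALSE])
  K <- nrow(U)
  A <- apply(templates, 2, function(a) {
    a <- a - mean(a); a / sqrt(sum(a^2))
  })
  gfp_t <- sqrt(colMeans(U^2))
  nz <- gfp_t > 1e-12
  if (any(!nz)) warnf("skipping %d zero-GFP time point(s)", sum(!nz))
  # polarity-sensitive correlation = cosine of average-referenced maps
  normU <- sqrt(colSums(U^2))
  R <- crossprod(A, U)                        # q x T, = r * |u|
  Rcor <- sweep(R, 2, pmax(normU, 1e-300), "/")
  labels <- rep(NA_integer_, ncol(U))
  labels[nz] <- apply(Rcor[, nz, drop = FALSE], 2, which.max)
  r_win <- Rcor[cbind(labels[nz], which(nz))]
  denom <- sum(gfp_t[nz]^2)
  gev <- vapply(seq_len(ncol(A)), function(m) {
    sel_m <- labels[nz] == m
    sum((gfp_t[nz][sel_m] * r_win[sel_m])^2) / denom
  }, numeric(1))
  structure(list(
    labels = labels,
    gev = tibble::tibble(subject = erp$subject, condition_id = erp$condition,
                         component = if (is.null(window)) "full" else window$component,
                         template = colnames(templates) %||%
                           paste0("map", seq_len(ncol(A))),
                         gev = gev),
    times_ms = e$times_ms[sel]
  ), class = "microstate_fit")
}

#' GEV table for a whole study
#'
#' Back-fits the templates to every subject x condition ERP for every
#' component window and stacks the per-template GEV rows.
#'
#' @param study An `erp_study` or nested list `erps[[subject]][[condition]]`.
#' @param templates Channels x q template matrix.
#' @param windows A [component_windows()]-shaped tibble.
#' @return A tidy tibble: `subject`, `condition_id`, `component`, `template`,
#'   `gev`.
#' @export
gev_table <- function(study, templates, windows = component_windows()) {
  erps <- if (inherits(study, "erp_study")) study$erps else study
  purrr::map_dfr(erps, function(subj)
    purrr::map_dfr(subj, function(e)
      purrr::map_dfr(seq_len(nrow(windows)), function(i)
        backfit_microstates(e, templates, windows[i, ])$gev)))
}

#' Repeated-measures ANOVA on global explained variance
#'
#' Thin delegation to [rm_anova()] on a [gev_table()]-shaped tibble,
#' typically with the microstate template as an additional within factor.
#'
#' @param fit A tibble with columns `subject`, `gev` and the factor columns.
#' @param within Within-subject factor column names.
#' @param subject Subject column name.
#' @return An `anova_result` tibble.
#' @export
microstate_anova <- function(fit, within, subject = "subject") {
  rm_anova(fit, "gev", within = within, subject = subject)
}

#' @export
tidy.microstate_segmentation <- function(x, ...) x$criteria

#' @export
glance.microstate_segmentation <- function(x, ...) {
  tibble::tibble(q_star = x$q_star, n_timepoints = ncol(x$series),
                 n_channels = nrow(x$series),
                 cv_min = min(x$criteria$cv))
}
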
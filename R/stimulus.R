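#' Gaussian-blob element specification
#'
#' The stimulus elements are truncated Gaussian luminance blobs. The defaults
#' follow the study conditions: standard deviation 0.08 degrees of visual
#' angle, a size factor of 5 (the blob extends to `size_factor * sigma_deg`
#' = 0.4 deg from its centre) and a Weber contrast of 0.90 against the
#' mid-grey background.
#'
#' @param sigma_deg Gaussian standard deviation in degrees of visual angle.
#' @param size_factor Unitless multiple of `sigma_deg` giving the truncation
#'   radius (the element "size").
#' @param contrast Weber contrast in (0, 1].
#' @return A list of class `element_spec` with an additional computed field
#'   `size_deg = size_factor * sigma_deg`.
#' @export
element_spec <- function(sigma_deg = 0.08, size_factor = 5, contrast = 0.90) {
  if (!(sigma_deg > 0)) stopf("sigma_deg must be > 0")
  if (!(contrast > 0 && contrast <= 1)) stopf("contrast must be in (0, 1]")
  size <- size_factor * sigma_deg
  if (!(size > 0)) stopf("size_factor * sigma_deg must be > 0")
  structure(list(sigma_deg = sigma_deg, size_factor = size_factor,
                 contrast = contrast, size_deg = size),
            class = "element_spec")
}

SHAPE_KINDS <- c(triangle = 3L, square = 4L, pentagon = 5L, hexagon = 6L)

#' Regular-polygon shape specification
#'
#' Virtual shapes are regular polygons inscribed in the 8-deg-diameter
#' stimulus area, i.e. with a default circumradius of 4 degrees.
#'
#' @param kind One of `"triangle"`, `"square"`, `"pentagon"`, `"hexagon"`.
#' @param circumradius_deg Circumradius in degrees of visual angle.
#' @param orientation_rad Rotation in radians; at 0 the first vertex points up.
#' @return A list of class `shape_spec` with fields `kind`, `n_vertices`,
#'   `circumradius_deg`, `orientation_rad`.
#' @export
shape_spec <- function(kind = c("triangle", "square", "pentagon", "hexagon"),
                       circumradius_deg = 4, orientation_rad = 0) {
  kind <- match.arg(kind)
  if (!(circumradius_deg > 0)) stopf("circumradius_deg must be > 0")
  orientation_rad <- orientation_rad %% (2 * pi)
  structure(list(kind = kind, n_vertices = SHAPE_KINDS[[kind]],
                 circumradius_deg = circumradius_deg,
                 orientation_rad = orientation_rad),
            class = "shape_spec")
}

#' Vertices of a regular polygon
#'
#' Returns the `n_vertices` equally spaced points on the circle of radius
#' `circumradius_deg`, rotated by `orientation_rad`; with zero orientation the
#' first vertex sits at the top of the circle (polar angle pi/2).
#'
#' @param shape A [shape_spec()].
#' @return A tibble with columns `x_deg`, `y_deg`, one row per vertex.
#' @examples
#' polygon_vertices(shape_spec("triangle"))
#' @export
polygon_vertices <- function(shape) {
  n <- shape$n_vertices
  ang <- pi / 2 + shape$orientation_rad + 2 * pi * (seq_len(n) - 1L) / n
  tibble::tibble(x_deg = shape$circumradius_deg * cos(ang),
                 y_deg = shape$circumradius_deg * sin(ang))
}

# --- layout container ---------------------------------------------------------

new_layout <- function(centres, on_vertex, shape, element,
                       polarity = rep("white", nrow(centres)),
                       condition = NULL) {
  out <- tibble::tibble(element = seq_len(nrow(centres)),
                        x_deg = centres$x_deg, y_deg = centres$y_deg,
                        polarity = polarity, on_vertex = on_vertex)
  attr(out, "shape") <- shape
  attr(out, "element_spec") <- element
  attr(out, "condition") <- condition
  class(out) <- c("stimulus_layout", class(out))
  out
}

#' @export
print.stimulus_layout <- function(x, ...) {
  sh <- attr(x, "shape")
  cat(sprintf("<stimulus_layout: %d element(s), %s, orientation %.3f rad>\n",
              nrow(x), sh$kind, sh$orientation_rad))
  NextMethod()
}

layout_min_distance <- function(layout) {
  if (nrow(layout) < 2L) return(Inf)
  min(stats::dist(cbind(layout$x_deg, layout$y_deg)))
}

# Minimum allowed pairwise centre distance: twice the element size.
min_separation <- function(element) 2 * element$size_deg

check_layout <- function(layout, area_radius_deg = 4) {
  el <- attr(layout, "element_spec")
  r <- sqrt(layout$x_deg^2 + layout$y_deg^2)
  if (any(r > area_radius_deg + 1e-9))
    stopf("layout extends beyond the %g-deg-diameter area", 2 * area_radius_deg)
  if (layout_min_distance(layout) < min_separation(el) - 1e-12)
    stopf("layout violates the minimum-distance constraint")
  invisible(layout)
}

# --- placement ----------------------------------------------------------------

#' Place elements on the vertices of a shape
#'
#' In the vertex-matched design (Experiment 1) all `n` elements coincide with
#' the `n` polygon vertices. In the triangle-sampling design (Experiments 2
#' and 3) three elements sit on the triangle vertices and any remainder is
#' placed uniformly at random inside the closed triangle via
#' [place_random_within()].
#'
#' @param shape A [shape_spec()].
#' @param n Number of elements (3-6).
#' @param element An [element_spec()].
#' @param seed Integer seed for the random remainder (ignored when
#'   `n == shape$n_vertices`).
#' @param max_attempts Rejection-sampling budget before an
#'   infeasible-geometry error.
#' @return A `stimulus_layout` tibble.
#' @export
place_on_vertices <- function(shape, n, element = element_spec(), seed = 1L,
                              max_attempts = 10000L) {
  verts <- polygon_vertices(shape)
  if (n == shape$n_vertices) {
    lay <- new_layout(verts, on_vertex = rep(TRUE, n), shape, element)
    return(check_layout(lay))
  }
  if (shape$kind != "triangle" || n < shape$n_vertices)
    stopf("n != n_vertices is only supported for triangles sampled by extra elements")
  extra <- place_random_within(shape, n - shape$n_vertices, seed = seed,
                               element = element, existing = verts,
                               max_attempts = max_attempts)
  centres <- dplyr::bind_rows(verts, extra[, c("x_deg", "y_deg")])
  lay <- new_layout(centres,
                    on_vertex = c(rep(TRUE, shape$n_vertices),
                                  rep(FALSE, n - shape$n_vertices)),
                    shape, element)
  check_layout(lay)
}

#' Place elements randomly on the contour of a shape, avoiding vertices
#'
#' Samples element centres uniformly (by arc length) on the polygon boundary,
#' excluding an exclusion zone of one minimum separation (`2 * size_deg`)
#' around every vertex, and enforcing the pairwise minimum-distance
#' constraint by rejection sampling.
#'
#' @inheritParams place_on_vertices
#' @return A `stimulus_layout` tibble whose centres all lie on polygon edges.
#' @export
place_random_on_contour <- function(shape, n, element = element_spec(),
                                    seed = 1L, max_attempts = 10000L) {
  verts <- as.matrix(polygon_vertices(shape))
  nv <- nrow(verts)
  nxt <- c(2:nv, 1L)
  edge_len <- sqrt(rowSums((verts[nxt, , drop = FALSE] - verts)^2))
  excl <- min_separation(element)
  usable <- edge_len - 2 * excl
  if (any(usable <= 0) || n * min_separation(element) > sum(usable) + n * 1e-12)
    stopf("infeasible geometry: contour too short for %d elements", n)
  withr::with_seed(seed, {
    for (attempt in seq_len(max_attempts)) {
      e <- sample.int(nv, n, replace = TRUE, prob = usable / sum(usable))
      t <- runif(n, min = excl, max = edge_len[e] - excl)
      P <- verts[e, , drop = FALSE] +
        (verts[nxt[e], , drop = FALSE] - verts[e, , drop = FALSE]) *
        (t / edge_len[e])
      if (n < 2L || min(stats::dist(P)) >= min_separation(element)) {
        lay <- new_layout(tibble::tibble(x_deg = P[, 1], y_deg = P[, 2]),
                          on_vertex = rep(FALSE, n), shape, element)
        return(check_layout(lay))
      }
    }
  })
  stopf("infeasible geometry: no valid contour layout in %d attempts", max_attempts)
}

# Uniform point in a triangle given its three vertices (rows of V).
runif_triangle <- function(n, V) {
  r1 <- sqrt(runif(n)); r2 <- runif(n)
  cbind((1 - r1) * V[1, 1] + r1 * (1 - r2) * V[2, 1] + r1 * r2 * V[3, 1],
        (1 - r1) * V[1, 2] + r1 * (1 - r2) * V[2, 2] + r1 * r2 * V[3, 2])
}

#' Place elements uniformly inside a closed triangle
#'
#' Samples `n` centres uniformly over the closed triangle (interior and
#' boundary) with rejection sampling against the pairwise minimum-distance
#' constraint, including distances to any already-placed elements passed in
#' `existing` (e.g. the vertex elements).
#'
#' @inheritParams place_on_vertices
#' @param existing Optional data frame of already placed centres
#'   (`x_deg`, `y_deg`) that the new points must also keep clear of.
#' @return A `stimulus_layout` tibble (empty when `n == 0`).
#' @export
place_random_within <- function(shape, n, element = element_spec(), seed = 1L,
                                existing = NULL, max_attempts = 10000L) {
  if (shape$kind != "triangle")
    stopf("place_random_within() is defined for triangles")
  if (n == 0L)
    return(new_layout(tibble::tibble(x_deg = double(), y_deg = double()),
                      on_vertex = logical(), shape, element))
  V <- as.matrix(polygon_vertices(shape))
  E <- if (!is.null(existing)) cbind(existing$x_deg, existing$y_deg) else NULL
  sep <- min_separation(element)
  withr::with_seed(seed, {
    for (attempt in seq_len(max_attempts)) {
      P <- runif_triangle(n, V)
      ok <- (n < 2L || min(stats::dist(P)) >= sep)
      if (ok && !is.null(E)) {
        dmin <- min(sqrt(outer(P[, 1], E[, 1], "-")^2 +
                         outer(P[, 2], E[, 2], "-")^2))
        ok <- dmin >= sep
      }
      if (ok) {
        lay <- new_layout(tibble::tibble(x_deg = P[, 1], y_deg = P[, 2]),
                          on_vertex = rep(FALSE, n), shape, element)
        return(check_layout(lay))
      }
    }
  })
  stopf("infeasible geometry: no valid interior layout in %d attempts", max_attempts)
}

#' Assign luminance polarities to a layout
#'
#' @param layout A `stimulus_layout`.
#' @param scheme `"all_white"`, `"all_black"`, `"same"` (a fair coin picks
#'   all-white or all-black for the whole layout) or `"mixed"` (independent
#'   fair coins per element, resampled until both polarities are present).
#' @param seed Integer seed.
#' @return The layout with its `polarity` column filled in.
#' @export
assign_polarity <- function(layout, scheme = c("all_white", "all_black",
                                               "same", "mixed"), seed = 1L) {
  scheme <- match.arg(scheme)
  n <- nrow(layout)
  pol <- withr::with_seed(seed, switch(scheme,
    all_white = rep("white", n),
    all_black = rep("black", n),
    same = rep(sample(c("white", "black"), 1L), n),
    mixed = {
      repeat {
        p <- sample(c("white", "black"), n, replace = TRUE)
        if (length(unique(p)) == 2L) break
      }
      p
    }
  ))
  layout$polarity <- pol
  layout
}

# --- conditions and schedules -------------------------------------------------

#' Condition set of an experiment
#'
#' Each experiment has eight conditions. Experiment 1 crosses the four shapes
#' (triangle, square, pentagon, hexagon; element count matched to vertex
#' count) with spatial configuration (on-vertices "shape" vs. on-contour
#' "random"). Experiment 2 uses only the triangle, sampled by 3-6 elements
#' (three on the vertices, the rest inside), against matched random-contour
#' conditions. Experiment 3 uses the triangle-sampling stimuli with 3-6
#' elements crossed with luminance polarity (same vs. different).
#'
#' @param experiment 1, 2 or 3.
#' @return A tibble with columns `condition_id`, `experiment`,
#'   `configuration`, `n_elements`, `shape_kind`, `polarity_scheme`.
#' @export
condition_set <- function(experiment) {
  experiment <- as.integer(experiment)
  if (!experiment %in% 1:3) stopf("experiment must be 1, 2 or 3")
  n <- 3:6
  if (experiment == 1L) {
    tibble::tibble(
      condition_id = c(paste0("S", n), paste0("R", n)),
      experiment = experiment,
      configuration = rep(c("shape", "random"), each = 4L),
      n_elements = rep(n, 2L),
      shape_kind = rep(names(SHAPE_KINDS), 2L),
      polarity_scheme = "all_white"
    )
  } else if (experiment == 2L) {
    tibble::tibble(
      condition_id = c(paste0("S", n), paste0("R", n)),
      experiment = experiment,
      configuration = rep(c("shape", "random"), each = 4L),
      n_elements = rep(n, 2L),
      shape_kind = "triangle",
      polarity_scheme = "all_white"
    )
  } else {
    tibble::tibble(
      condition_id = c(paste0("S", n), paste0("D", n)),
      experiment = experiment,
      configuration = "shape",
      n_elements = rep(n, 2L),
      shape_kind = "triangle",
      polarity_scheme = rep(c("same", "mixed"), each = 4L)
    )
  }
}

#' Build a randomized, balanced trial schedule
#'
#' Every condition appears exactly `reps` times in a seeded random order
#' (the default `reps = 100` gives the full 800-trial session). The virtual
#' shape orientation is drawn uniformly in `[0, 2*pi)` per trial and each
#' trial gets its own derived layout seed so layouts are independently
#' reproducible.
#'
#' @param experiment 1, 2 or 3.
#' @param reps Presentations per condition.
#' @param seed Master seed for the permutation, orientations and per-trial
#'   layout seeds.
#' @return A tibble of class `trial_schedule`: one row per trial with columns
#'   `trial`, the condition columns of [condition_set()], `orientation_rad`
#'   and `layout_seed`.
#' @export
build_schedule <- function(experiment, reps = 100L, seed = 1L) {
  if (reps < 1L) stopf("reps must be >= 1")
  conds <- condition_set(experiment)
  n_trials <- nrow(conds) * reps
  sched <- withr::with_seed(seed, {
    idx <- sample(rep(seq_len(nrow(conds)), each = reps))
    tibble::tibble(
      trial = seq_len(n_trials),
      conds[idx, ],
      orientation_rad = runif(n_trials, 0, 2 * pi),
      layout_seed = sample.int(.Machine$integer.max - 1L, n_trials)
    )
  })
  class(sched) <- c("trial_schedule", class(sched))
  sched
}

#' Generate the stimulus layout for one scheduled trial
#'
#' Dispatches on the trial's configuration: `"shape"` places elements on the
#' polygon vertices (plus interior elements for the triangle-sampling
#' designs) and `"random"` places them on the shape contour away from the
#' vertices; then assigns polarities according to the condition's scheme.
#'
#' @param trial A single row of a [build_schedule()] tibble (or any list with
#'   the same fields).
#' @param element An [element_spec()].
#' @return A `stimulus_layout` tibble.
#' @export
generate_layout <- function(trial, element = element_spec()) {
  shape <- shape_spec(trial$shape_kind, orientation_rad = trial$orientation_rad)
  seed <- trial$layout_seed
  lay <- if (trial$configuration == "shape") {
    place_on_vertices(shape, trial$n_elements, element, seed = seed)
  } else {
    place_random_on_contour(shape, trial$n_elements, element, seed = seed)
  }
  lay <- assign_polarity(lay, trial$polarity_scheme, seed = seed + 1)
  attr(lay, "condition") <- trial$condition_id
  lay
}

# --- rendering ----------------------------------------------------------------

#' Display geometry
#'
#' @param width_px,height_px Resolution in pixels.
#' @param width_cm,height_cm Physical screen size in cm.
#' @param distance_cm Viewing distance in cm.
#' @param background_cd Background luminance in cd/m^2.
#' @return A list of class `display_geometry`.
#' @export
display_geometry <- function(width_px = 1024L, height_px = 768L,
                             width_cm = 36, height_cm = 27,
                             distance_cm = 100, background_cd = 65.5) {
  structure(list(width_px = width_px, height_px = height_px,
                 width_cm = width_cm, height_cm = height_cm,
                 distance_cm = distance_cm, background_cd = background_cd),
            class = "display_geometry")
}

#' Render a layout to a luminance image
#'
#' Draws each element as a truncated Gaussian luminance increment (white) or
#' decrement (black) on the mid-grey background:
#' `L(r) = L_bg * (1 +/- contrast * exp(-r^2 / (2 sigma^2)))` for
#' `r <= size_factor * sigma`, zero modulation beyond the truncation radius.
#' Degrees of visual angle are converted to screen position via the viewing
#' distance (`cm = distance * tan(deg)`), with the origin at screen centre
#' and y increasing upward.
#'
#' @param layout A `stimulus_layout`.
#' @param display A [display_geometry()].
#' @return A `height_px` x `width_px` matrix of luminances in cd/m^2 (row 1 =
#'   top of the screen) with attribute `display`.
#' @export
render_stimulus <- function(layout, display = display_geometry()) {
  deg2px_x <- function(deg) display$distance_cm * tan(deg * pi / 180) *
    display$width_px / display$width_cm
  half_w_deg <- atan(display$width_cm / 2 / display$distance_cm) * 180 / pi
  half_h_deg <- atan(display$height_cm / 2 / display$distance_cm) * 180 / pi
  if (4 > half_w_deg || 4 > half_h_deg)
    stopf("stimulus area (8 deg) exceeds the display")
  el <- attr(layout, "element_spec")
  px_per_cm <- display$width_px / display$width_cm
  img <- matrix(display$background_cd, display$height_px, display$width_px)
  cx0 <- (display$width_px + 1) / 2; cy0 <- (display$height_px + 1) / 2
  for (i in seq_len(nrow(layout))) {
    # pixel position of the element centre
    px <- cx0 + display$distance_cm * tan(layout$x_deg[i] * pi / 180) * px_per_cm
    py <- cy0 - display$distance_cm * tan(layout$y_deg[i] * pi / 180) * px_per_cm
    rad_px <- ceiling(display$distance_cm * tan(el$size_deg * pi / 180) * px_per_cm) + 1L
    xs <- max(1L, floor(px - rad_px)):min(display$width_px, ceiling(px + rad_px))
    ys <- max(1L, floor(py - rad_px)):min(display$height_px, ceiling(py + rad_px))
    # per-pixel visual angle offsets from the element centre
    xdeg <- atan((xs - cx0) / px_per_cm / display$distance_cm) * 180 / pi
    ydeg <- -atan((ys - cy0) / px_per_cm / display$distance_cm) * 180 / pi
    dx <- xdeg - layout$x_deg[i]
    dy <- ydeg - layout$y_deg[i]
    r2 <- outer(dy^2, dx^2, "+")
    prof <- exp(-r2 / (2 * el$sigma_deg^2))
    prof[sqrt(r2) > el$size_deg] <- 0
    sign <- if (layout$polarity[i] == "white") 1 else -1
    img[ys, xs] <- img[ys, xs] +
      sign * el$contrast * display$background_cd * prof
  }
  attr(img, "display") <- display
  class(img) <- c("luminance_image", class(img))
  img
}
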
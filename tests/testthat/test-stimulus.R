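test_that("polygon vertices follow the stated geometry", {
  tri <- polygon_vertices(shape_spec("triangle", circumradius_deg = 4))
  ang <- sort((atan2(tri$y_deg, tri$x_deg) * 180 / pi) %% 360)
  expect_equal(ang, c(90, 210, 330))
  expect_equal(sqrt(tri$x_deg^2 + tri$y_deg^2), rep(4, 3))

  sq <- polygon_vertices(shape_spec("square", circumradius_deg = 2.5))
  sides <- sqrt(rowSums((sq[c(2:4, 1), ] - sq)^2))
  expect_equal(sides, rep(2.5 * sqrt(2), 4))

  hex <- polygon_vertices(shape_spec("hexagon", circumradius_deg = 4))
  sides <- sqrt(rowSums((hex[c(2:6, 1), ] - hex)^2))
  expect_equal(sides, rep(4, 6))

  # orientation rotates the whole vertex set
  rot <- polygon_vertices(shape_spec("triangle", orientation_rad = pi / 7))
  ang2 <- (atan2(rot$y_deg, rot$x_deg)) %% (2 * pi)
  expect_equal(sort((ang2 - pi / 7) %% (2 * pi)),
               sort((atan2(tri$y_deg, tri$x_deg)) %% (2 * pi)),
               tolerance = 1e-12)
})

test_that("vertex placement reproduces polygon vertices exactly", {
  for (kind in c("triangle", "square", "pentagon", "hexagon")) {
    sh <- shape_spec(kind, orientation_rad = 0.3)
    lay <- place_on_vertices(sh, sh$n_vertices)
    verts <- polygon_vertices(sh)
    expect_identical(lay$x_deg, verts$x_deg)
    expect_identical(lay$y_deg, verts$y_deg)
    expect_all_true(lay$on_vertex)
  }
})

test_that("triangle sampling puts 3 on vertices and the rest strictly inside", {
  sh <- shape_spec("triangle", orientation_rad = 1.1)
  lay <- place_on_vertices(sh, 6, seed = 7)
  expect_equal(nrow(lay), 6)
  expect_equal(sum(lay$on_vertex), 3)
  verts <- polygon_vertices(sh)
  expect_equal(lay$x_deg[1:3], verts$x_deg)
  # interior points are inside the closed triangle (sign test on half-planes)
  V <- as.matrix(verts)
  inside <- function(p) {
    s <- sapply(1:3, function(i) {
      a <- V[i, ]; b <- V[i %% 3 + 1, ]
      (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
    })
    all(s >= -1e-9) || all(s <= 1e-9)
  }
  for (i in 4:6) expect_true(inside(c(lay$x_deg[i], lay$y_deg[i])))
  # degenerate remainder: 3 elements = plain vertex condition
  expect_identical(place_on_vertices(sh, 3, seed = 1)[, c("x_deg", "y_deg")],
                   place_on_vertices(sh, 3, seed = 99)[, c("x_deg", "y_deg")])
})

test_that("contour placement stays on edges, off vertices, and is reproducible", {
  sh <- shape_spec("triangle", orientation_rad = 0.4)
  verts <- as.matrix(polygon_vertices(sh))
  seg_dist <- function(p, a, b) {
    t <- pmin(1, pmax(0, sum((p - a) * (b - a)) / sum((b - a)^2)))
    sqrt(sum((a + t * (b - a) - p)^2))
  }
  for (seed in 1:5) {
    lay <- place_random_on_contour(sh, 6, seed = seed)
    for (i in seq_len(nrow(lay))) {
      p <- c(lay$x_deg[i], lay$y_deg[i])
      d <- min(sapply(1:3, function(j)
        seg_dist(p, verts[j, ], verts[j %% 3 + 1, ])))
      expect_lt(d, 1e-9)
      dv <- min(sqrt(colSums((t(verts) - p)^2)))
      expect_gte(dv, 2 * element_spec()$size_deg - 1e-12)
    }
  }
  expect_identical(place_random_on_contour(sh, 5, seed = 11),
                   place_random_on_contour(sh, 5, seed = 11))
})

test_that("infeasible geometries raise errors", {
  tiny <- shape_spec("triangle", circumradius_deg = 0.5)
  expect_error(place_random_on_contour(tiny, 6), "infeasible")
  # interior too crowded for many separated elements
  small <- shape_spec("triangle", circumradius_deg = 1)
  expect_error(place_random_within(small, 12, max_attempts = 200),
               "infeasible")
})

test_that("interior placement is empty for n = 0 and uniform by symmetry", {
  sh <- shape_spec("triangle")
  expect_equal(nrow(place_random_within(sh, 0)), 0)
  # with orientation 0 the triangle is symmetric about x = 0: left/right
  # counts must match a fair coin, as under the unconstrained uniform oracle
  n_draws <- 4000
  lefts <- vapply(seq_len(n_draws), function(s) {
    lay <- place_random_within(sh, 3, seed = s)
    sum(lay$x_deg < 0)
  }, numeric(1))
  se <- stats::sd(lefts) / sqrt(n_draws)
  expect_lt(abs(mean(lefts) - 1.5), 3 * se)
})

test_that("polarity assignment follows the scheme", {
  sh <- shape_spec("hexagon")
  lay <- place_on_vertices(sh, 6)
  expect_all_true(assign_polarity(lay, "all_white", 1)$polarity == "white")
  expect_all_true(assign_polarity(lay, "all_black", 1)$polarity == "black")
  for (s in 1:30) {
    p <- assign_polarity(lay, "mixed", s)$polarity
    expect_setequal(unique(p), c("white", "black"))
    sm <- assign_polarity(lay, "same", s)$polarity
    expect_length(unique(sm), 1)
  }
  # conditional-on-nonuniform mean white count for n = 6 is 3 (enumeration
  # of the 62 admissible vectors is symmetric); Monte-Carlo check
  whites <- vapply(1:4000, function(s)
    sum(assign_polarity(lay, "mixed", s)$polarity == "white"), numeric(1))
  se <- stats::sd(whites) / sqrt(length(whites))
  expect_lt(abs(mean(whites) - 3), 3 * se)
})

test_that("condition sets define the eight cells of each experiment", {
  for (e in 1:3) {
    cs <- condition_set(e)
    expect_equal(nrow(cs), 8)
    expect_false(anyDuplicated(cs$condition_id) > 0)
  }
  cs1 <- condition_set(1)
  expect_equal(cs1$n_elements[cs1$configuration == "shape"], 3:6)
  expect_equal(unname(c(triangle = 3, square = 4, pentagon = 5,
                        hexagon = 6)[cs1$shape_kind]), cs1$n_elements)
  expect_all_true(condition_set(2)$shape_kind == "triangle")
  cs3 <- condition_set(3)
  expect_setequal(unique(cs3$polarity_scheme), c("same", "mixed"))
})

test_that("schedules are balanced, randomized and reproducible", {
  sched <- build_schedule(2, reps = 7, seed = 3)
  expect_equal(nrow(sched), 56)
  expect_all_true(table(sched$condition_id) == 7)
  expect_all_true(sched$orientation_rad >= 0 & sched$orientation_rad < 2 * pi)
  expect_identical(build_schedule(2, reps = 7, seed = 3), sched)
  expect_false(identical(build_schedule(2, reps = 7, seed = 4)$condition_id,
                         sched$condition_id))
  r1 <- build_schedule(1, reps = 1, seed = 2)
  expect_equal(sort(r1$condition_id), sort(condition_set(1)$condition_id))
})

test_that("generated layouts respect the minimum-distance and area invariants", {
  sched <- build_schedule(1, reps = 4, seed = 9)
  el <- element_spec()
  for (k in seq_len(nrow(sched))) {
    lay <- generate_layout(sched[k, ])
    expect_equal(nrow(lay), sched$n_elements[k])
    if (nrow(lay) > 1)
      expect_gte(min(stats::dist(cbind(lay$x_deg, lay$y_deg))),
                 2 * el$size_deg - 1e-12)
    expect_all_true(sqrt(lay$x_deg^2 + lay$y_deg^2) <= 4 + 1e-9)
  }
})

test_that("rendering places truncated Gaussian blobs on the background", {
  # odd-plus-one resolutions put a pixel exactly at the screen centre
  disp <- display_geometry(width_px = 513L, height_px = 385L,
                           width_cm = 36, height_cm = 27)
  sh <- shape_spec("triangle")
  el <- element_spec()
  empty <- numerp:::new_layout(tibble::tibble(x_deg = double(),
                                              y_deg = double()),
                               logical(), sh, el)
  img0 <- render_stimulus(empty, disp)
  expect_all_true(img0 == 65.5)

  one <- numerp:::new_layout(tibble::tibble(x_deg = 0, y_deg = 0), FALSE,
                             sh, el)
  img_w <- render_stimulus(assign_polarity(one, "all_white", 1), disp)
  expect_equal(max(img_w), 65.5 * (1 + 0.90), tolerance = 1e-9)
  expect_equal(min(img_w), 65.5)
  img_b <- render_stimulus(assign_polarity(one, "all_black", 1), disp)
  expect_equal(min(img_b), 65.5 * (1 - 0.90), tolerance = 1e-9)
  # truncation: no modulation beyond size_factor * sigma
  xs_deg <- atan(((1:513) - 257) / (513 / 36) / 100) * 180 / pi
  far <- abs(xs_deg) > el$size_deg + 0.02
  expect_all_true(img_w[193, far] == 65.5)
  # stimulus area must fit the display
  expect_error(render_stimulus(one, display_geometry(width_cm = 10)),
               "exceeds")
})
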
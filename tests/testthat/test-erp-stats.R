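test_that("mean amplitude averages the window per electrode", {
  w <- component_windows()
  ch64 <- make_montage()$channel[1:64]
  erp <- numerp:::new_subject_erp(
    matrix(5, 64, 1101, dimnames = list(ch64, NULL)),
    seq(-100, 1000), 1000, subject = 1, condition = "S3", n_trials = 10)
  rows <- mean_amplitude(erp, w[1, ])
  expect_equal(nrow(rows), 6)
  expect_all_true(rows$amplitude == 5)
  expect_setequal(rows$electrode, w$electrodes[[1]])
  expect_setequal(unique(rows$hemisphere), c("left", "right"))

  # symmetric positive/negative half-windows cancel
  x <- matrix(0, 64, 1101, dimnames = dimnames(erp$data))
  sel <- seq(-100, 1000) >= 160 & seq(-100, 1000) <= 220
  half <- sum(sel) / 2
  x[, which(sel)] <- rep(c(1, -1), c(ceiling(half), sum(sel) - ceiling(half)))
  erp2 <- numerp:::new_subject_erp(x, seq(-100, 1000), 1000, 1, "S3", 10)
  expect_lt(abs(mean_amplitude(erp2, w[1, ])$amplitude[1]), 0.02)

  erp3 <- erp; rownames(erp3$data)[rownames(erp3$data) == "P7"] <- "XX"
  expect_error(mean_amplitude(erp3, w[1, ]), "missing electrode")
})

test_that("rm_anova equals the paired t-test on two-level designs", {
  for (seed in 1:5) {
    set.seed(seed)
    d <- tidyr::crossing(subject = factor(1:9), a = c("x", "y"))
    d$y <- rnorm(18) + (d$a == "x") * 0.4
    r <- rm_anova(d, "y", within = "a")
    tt <- t.test(d$y[d$a == "x"], d$y[d$a == "y"], paired = TRUE)
    expect_equal(r$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(r$p, tt$p.value, tolerance = 1e-10)
    expect_equal(r$gg_epsilon, 1)
  }
})

test_that("rm_anova matches the aov cell-means oracle on random 2x3 designs", {
  for (seed in 1:6) {
    set.seed(100 + seed)
    d <- tidyr::crossing(subject = factor(1:5), A = c("a1", "a2"),
                         B = c("b1", "b2", "b3"))
    d$y <- rnorm(nrow(d)) + as.numeric(d$subject) / 4 +
      (d$A == "a1") * rnorm(1) + (d$B == "b2") * rnorm(1)
    r <- rm_anova(d, "y", within = c("A", "B"))
    a <- summary(stats::aov(y ~ A * B + Error(subject / (A * B)), data = d))
    f_or <- c(a[["Error: subject:A"]][[1]]["A", "F value"],
              a[["Error: subject:B"]][[1]]["B", "F value"],
              a[["Error: subject:A:B"]][[1]]["A:B", "F value"])
    expect_equal(r$statistic, f_or, tolerance = 1e-8)
    expect_all_true(r$gg_epsilon >= 1 / r$df1 - 1e-12)
    expect_all_true(r$gg_epsilon <= 1 + 1e-12)
    expect_all_true(r$pes >= 0 & r$pes <= 1)
  }
})

test_that("GG epsilon is 1 for spherical contrast covariance by construction", {
  set.seed(42)
  n <- 10; k <- 4
  C <- numerp:::orthonormal_contrasts(k)
  Z <- matrix(rnorm(n * (k - 1)), n, k - 1)
  Z <- sweep(Z, 2, colMeans(Z))
  Z <- qr.Q(qr(Z))[, 1:(k - 1)]        # orthonormal, so cov(Z) is spherical
  Z <- sweep(Z, 2, colMeans(Z))
  Y <- Z %*% C + rnorm(n)              # subject offsets live in the mean space
  d <- tidyr::crossing(subject = 1:n, A = 1:k)
  d <- dplyr::arrange(d, subject, A)
  d$y <- as.vector(t(Y))
  r <- rm_anova(d, "y", within = "A")
  expect_equal(r$gg_epsilon, 1, tolerance = 1e-8)
})

test_that("flat condition means give F of zero despite subject effects", {
  d <- tidyr::crossing(subject = factor(1:8), A = c("a", "b", "c"))
  d <- dplyr::arrange(d, subject, A)
  # per-cell deviations that cancel exactly across subjects: every condition
  # mean is identical, the error term is not
  D <- outer(c(1, -1, 0.5, -0.5, rep(0, 4)), c(1, 0, -1))
  d$y <- as.numeric(d$subject) * 2 + as.vector(t(D))
  r <- rm_anova(d, "y", within = "A")
  expect_lt(r$statistic, 1e-20)
  expect_lt(r$pes, 1e-20)
})

test_that("rm_anova rejects malformed designs", {
  d <- tidyr::crossing(subject = factor(1:4), A = c("a", "b"))
  d$y <- rnorm(8)
  expect_error(rm_anova(d[-1, ], "y", within = "A"), "missing cell")
  expect_error(rm_anova(rbind(d, d[1, ]), "y", within = "A"), "unbalanced")
  expect_error(rm_anova(d[d$subject == "1", ], "y", within = "A"),
               ">= 2 subjects")
})

test_that("Bonferroni post-hocs count comparisons and clip at 1", {
  set.seed(3)
  d <- tidyr::crossing(subject = factor(1:8), A = factor(1:4))
  d$y <- rnorm(32)
  ph <- bonferroni_posthoc(d, "y", "A")
  expect_equal(nrow(ph), 6)
  expect_equal(attr(ph, "n_comparisons"), 6)
  expect_all_true(ph$p_adj >= ph$p)
  expect_all_true(ph$p_adj <= 1)
  expect_all_true(ph$p_adj == pmin(1, ph$p * 6))
})

test_that("Bonferroni post-hoc type-I rate stays below alpha under the null", {
  hits <- vapply(1:400, function(s) {
    set.seed(s)
    d <- tidyr::crossing(subject = factor(1:10), A = factor(1:3))
    d$y <- rnorm(30)
    any(bonferroni_posthoc(d, "y", "A")$p_adj < 0.05)
  }, logical(1))
  # familywise error should be at most ~alpha; allow 3 SE above 0.05
  expect_lt(mean(hits), 0.05 + 3 * sqrt(0.05 * 0.95 / 400))
})

test_that("behaviour statistics recover planted effects with power", {
  gt <- make_ground_truth(1)
  one_sim <- function(seed) {
    seeds <- numerp:::derive_seeds(seed, 19)
    beh <- purrr::map_dfr(1:19, function(s)
      simulate_behavior(build_schedule(1, reps = 25, seed = seeds[s]), gt,
                        seed = seeds[s] + 1L, subject = s))
    bs <- behavior_stats(beh)
    c(rt = bs$rt$p[bs$rt$effect == "configuration"] < 0.05,
      acc = bs$accuracy$p[bs$accuracy$effect == "configuration"] < 0.05)
  }
  res <- vapply(1:30, one_sim, logical(2))
  expect_gte(mean(res["rt", ]), 0.95)
  expect_gte(mean(res["acc", ]), 0.95)
})

test_that("behaviour statistics handle degenerate inputs", {
  gt <- make_ground_truth(1)
  gt$behavior$p_correct <- 1
  beh <- purrr::map_dfr(1:3, function(s)
    simulate_behavior(build_schedule(1, reps = 2, seed = s), gt,
                      seed = s, subject = s))
  bs <- behavior_stats(beh)
  expect_all_true(bs$cells$accuracy == 1)
  expect_all_true(bs$accuracy$statistic < 1e-12 | is.nan(bs$accuracy$statistic))
  expect_error(behavior_stats(beh[beh$subject == 1, ]), ">= 2 subjects")
})

test_that("anova tidiers return well-formed tibbles", {
  d <- tidyr::crossing(subject = factor(1:5), A = c("a", "b"))
  d$y <- rnorm(10)
  r <- rm_anova(d, "y", within = "A")
  expect_s3_class(tidy(r), "tbl_df")
  g <- glance(r)
  expect_equal(g$n_effects, 1)
  expect_equal(g$n, 5)
})

test_that("LMF post-hocs separate 3 from 4 but not 5 from 6 at study scale", {
  gt <- make_ground_truth(1)
  st <- simulate_subject_erps(1, gt, subjects = 19,
                              trials_per_condition = 100, seed = 12, fs = 500)
  at <- amplitude_table(st) |>
    dplyr::left_join(condition_set(1), by = "condition_id")
  lmf <- at[at$component == "LMF", ] |>
    dplyr::group_by(.data$subject, .data$n_elements) |>
    dplyr::summarise(amplitude = mean(.data$amplitude), .groups = "drop")
  lm_means <- tapply(lmf$amplitude, lmf$n_elements, mean)
  expect_true(lm_means["3"] > lm_means["4"])
  expect_true(lm_means["4"] > lm_means["5"])
  ph <- bonferroni_posthoc(lmf, "amplitude", "n_elements")
  expect_lt(ph$p_adj[ph$level1 == "3" & ph$level2 == "4"], 0.05)
  expect_gt(ph$p_adj[ph$level1 == "5" & ph$level2 == "6"], 0.05)
})
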
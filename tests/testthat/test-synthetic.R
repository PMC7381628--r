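test_that("evoked signal reproduces the planted amplitude table exactly", {
  w <- component_windows()
  # all-zero amplitudes give an all-zero epoch
  gt0 <- gt_quiet()
  gt0$amplitudes$amplitude <- 0
  expect_all_true(evoked_signal("S3", gt0) == 0)

  # single-component plants equal their table entries in their own windows
  for (comp in c("N1", "N2", "LMF")) {
    gt <- gt_single_component(comp)
    wi <- w[w$component == comp, ]
    for (cid in c("S3", "R5")) {
      ev <- evoked_signal(cid, gt)
      t_ms <- attr(ev, "times_ms")
      sel <- t_ms >= wi$t_start & t_ms <= wi$t_end
      planted <- gt$amplitudes$amplitude[
        gt$amplitudes$condition_id == cid & gt$amplitudes$component == comp]
      expect_equal(mean(ev[wi$electrodes[[1]], sel]), planted,
                   tolerance = 1e-9)
    }
  }

  # planted N2 configuration contrast has the configured size
  gtn2 <- gt_single_component("N2")
  wi <- w[w$component == "N2", ]
  evS <- evoked_signal("S4", gtn2); evR <- evoked_signal("R4", gtn2)
  sel <- attr(evS, "times_ms") >= wi$t_start & attr(evS, "times_ms") <= wi$t_end
  expect_equal(mean(evS[wi$electrodes[[1]], sel]) -
                 mean(evR[wi$electrodes[[1]], sel]), 1.5, tolerance = 1e-9)
  expect_error(evoked_signal("nope", gtn2), "not in amplitude table")
})

test_that("zero-noise recordings cut back into the planted evoked epochs", {
  gt <- gt_quiet()
  sched <- build_schedule(1, reps = 2, seed = 1)
  rec <- simulate_recording(sched, gt, seed = 2)
  ep <- epoch_recording(rec)
  expect_equal(dim(ep$data)[3], 1101)
  post <- ep$times_ms >= 0
  eeg <- which(ep$channels != "VEOG")
  for (k in c(1, 9)) {
    ev <- evoked_signal(sched$condition_id[k], gt)
    expect_equal(max(abs(ep$data[k, eeg, post] - ev)), 0, tolerance = 1e-12)
  }
})

test_that("recordings are reproducible from the seed", {
  gt <- make_ground_truth(1, noise = noise_spec(sd = 4))
  sched <- build_schedule(1, reps = 1, seed = 5)
  r1 <- simulate_recording(sched, gt, seed = 9)
  r2 <- simulate_recording(sched, gt, seed = 9)
  expect_identical(r1$data, r2$data)
  r3 <- simulate_recording(sched, gt, seed = 10)
  expect_false(identical(r1$data, r3$data))
})

test_that("planted gross artifacts appear at the configured rate", {
  gt <- make_ground_truth(1, noise = noise_spec(sd = 4, blink_rate = 0,
                                                artifact_rate = 0.05))
  sched <- build_schedule(1, reps = 50, seed = 2)  # 400 trials
  rec <- simulate_recording(sched, gt, seed = 3)
  phat <- length(rec$truth$artifact_trials) / nrow(sched)
  se <- sqrt(0.05 * 0.95 / nrow(sched))
  expect_lt(abs(phat - 0.05), 3 * se)
  # planted artifacts actually exceed the rejection threshold after epoching
  ep <- reject_artifacts(epoch_recording(rec))
  expect_all_true(!ep$trials$retained[rec$truth$artifact_trials])
})

test_that("blink propagation is planted as configured and recoverable", {
  gt <- make_ground_truth(1, noise = noise_spec(sd = 0.5, ar = 0,
                                                blink_rate = 0.5,
                                                artifact_rate = 0))
  sched <- build_schedule(1, reps = 10, seed = 1)
  rec <- simulate_recording(sched, gt, seed = 4)
  expect_gt(length(rec$truth$blink_samples), 0)
  # direct least-squares oracle over the true blink samples
  mask <- rec$truth$blink_samples
  v <- rec$data["VEOG", mask]
  ch <- "Fp1"
  b_hat <- stats::coef(stats::lm(rec$data[ch, mask] ~ v))[2]
  expect_equal(unname(b_hat), unname(gt$blink_coef[ch]), tolerance = 0.02)
})

test_that("behaviour simulation matches its planted parameters", {
  gt <- make_ground_truth(1)
  # perfect accuracy plant
  gt1 <- gt
  gt1$behavior$p_correct <- 1
  sched <- build_schedule(1, reps = 5, seed = 1)
  beh <- simulate_behavior(sched, gt1, seed = 2)
  expect_all_true(beh$correct)
  expect_all_true(beh$reported_number == beh$n_elements)
  expect_all_true(beh$rt_ms > 0)

  # accuracy within 3 SE of the plant at large n
  big <- build_schedule(1, reps = 1250, seed = 3)  # 1250 trials/condition
  beh2 <- simulate_behavior(big, gt, seed = 4)
  cells <- dplyr::summarise(dplyr::group_by(beh2, condition_id),
                            acc = mean(correct), med = stats::median(rt_ms),
                            n = dplyr::n())
  cells <- dplyr::left_join(cells, gt$behavior, by = "condition_id")
  se <- sqrt(cells$p_correct * (1 - cells$p_correct) / cells$n)
  expect_all_true(abs(cells$acc - cells$p_correct) < 3 * se)
  # planted orderings: accuracy falls and median RT rises with numerosity
  cs <- dplyr::left_join(cells, condition_set(1), by = "condition_id")
  for (cfg in c("shape", "random")) {
    sub <- dplyr::arrange(cs[cs$configuration == cfg, ], n_elements)
    expect_all_true(diff(sub$acc) < 0.02)      # non-increasing up to MC noise
    expect_all_true(diff(sub$med) > -5)
  }
  # shape easier than matched random
  wide <- tidyr::pivot_wider(cs[, c("configuration", "n_elements", "acc", "med")],
                             names_from = "configuration",
                             values_from = c("acc", "med"))
  expect_all_true(wide$acc_shape > wide$acc_random)
  expect_all_true(wide$med_shape < wide$med_random)
  # incorrect reports never equal the true numerosity
  expect_all_true(beh2$reported_number[!beh2$correct] !=
                    beh2$n_elements[!beh2$correct])
})

test_that("epoch-level simulation matches its planted evoked signals", {
  st <- simulate_subject_erps(1, gt_quiet(), subjects = 2,
                              trials_per_condition = 4, seed = 1)
  ev <- evoked_signal("S5", gt_quiet())
  post <- st$times_ms >= 0
  expect_equal(max(abs(st$erps[[1]][["S5"]]$data[, post] - ev)), 0,
               tolerance = 1e-12)
  expect_all_true(abs(st$erps[[2]][["S5"]]$data[, !post]) < 1e-12)
})

test_that("synthetic map series carries its planted labels", {
  tm <- orthogonal_maps(16, 3)
  X <- simulate_map_series(tm, samples_per_state = 20, peak_uv = 4,
                           noise_sd = 0, seed = 1)
  expect_equal(dim(X), c(16, 60))
  expect_equal(attr(X, "truth_labels"), rep(1:3, each = 20))
  # each segment is exactly proportional to its template
  expect_equal(abs(cor(X[, 10], tm[, 1])), 1, tolerance = 1e-12)
  expect_equal(abs(cor(X[, 30], tm[, 2])), 1, tolerance = 1e-12)
})
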
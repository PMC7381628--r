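# End-to-end orchestration: simulate -> preprocess -> ERP statistics ->
# TANOVA -> microstates -> report.

#' Pipeline configuration
#'
#' Bundles every analysis parameter with the study defaults: 0.1-30 Hz
#' zero-phase band-pass, +/-75 uV rejection threshold, the N1/N2/LMF windows
#' and electrode sets, a 10 ms TANOVA/microstate duration criterion, and
#' candidate microstate counts 1..12.
#'
#' @param experiment 1, 2 or 3.
#' @param subjects Number of simulated subjects (19 as in the analysed
#'   samples of the first two experiments).
#' @param trials_per_condition Trials per condition (100 in the full design).
#' @param seed Master seed; all stage seeds are derived from it.
#' @param sim_mode `"erp"` simulates subject-average ERPs directly;
#'   `"continuous"` simulates continuous recordings and runs the full
#'   preprocessing chain (filtering, blink correction, epoching, rejection).
#' @param filter Apply the band-pass filter (continuous mode only).
#' @param low_hz,high_hz Band-pass edges (Hz).
#' @param reject_uv Epoch rejection threshold (uV).
#' @param tanova_M Permutation count for the TANOVA.
#' @param alpha Significance level.
#' @param min_duration_ms Duration criterion for TANOVA windows and
#'   microstate segments.
#' @param q_range Candidate microstate map counts.
#' @param segment_decim Temporal decimation factor for the segmentation
#'   input (1 = native rate; e.g. 4 segments every 4th sample).
#' @param noise A [noise_spec()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(experiment = 1, subjects = 19,
                            trials_per_condition = 100, seed = 1L,
                            sim_mode = c("erp", "continuous"),
                            filter = TRUE, low_hz = 0.1, high_hz = 30,
                            reject_uv = 75, tanova_M = 1000, alpha = 0.05,
                            min_duration_ms = 10, q_range = 1:12,
                            segment_decim = 1L, noise = noise_spec()) {
  structure(list(experiment = as.integer(experiment), subjects = subjects,
                 trials_per_condition = trials_per_condition, seed = seed,
                 sim_mode = match.arg(sim_mode), filter = filter,
                 low_hz = low_hz, high_hz = high_hz, reject_uv = reject_uv,
                 tanova_M = tanova_M, alpha = alpha,
                 min_duration_ms = min_duration_ms, q_range = q_range,
                 segment_decim = as.integer(segment_decim),
                 noise = noise, windows = component_windows()),
            class = "pipeline_config")
}

# Simulate, preprocess and average one subject through the continuous chain.
process_continuous_subject <- function(s, cfg, gt, seed) {
  sub_seeds <- derive_seeds(seed, 3L)
  sched <- build_schedule(cfg$experiment, reps = cfg$trials_per_condition,
                          seed = sub_seeds[1])
  dev <- withr::with_seed(sub_seeds[2],
    stats::setNames(rnorm(length(gt$subject_sd), 0, gt$subject_sd),
                    names(gt$subject_sd)))
  rec <- simulate_recording(sched, gt, noise = cfg$noise, seed = sub_seeds[3],
                            subject_dev = dev)
  if (cfg$filter) rec <- bandpass_zero_phase(rec, cfg$low_hz, cfg$high_hz)
  rec <- correct_blinks(rec)
  ep <- epoch_recording(rec)
  ep <- reject_artifacts(ep, cfg$reject_uv)
  list(erps = average_erp(ep, subject = s),
       n_rejected = sum(!ep$trials$retained),
       behavior_schedule = sched)
}

#' Run the full analysis pipeline on simulated data
#'
#' Simulates the configured experiment, computes per-subject and
#' grand-average ERPs, the behavioural and component mean-amplitude
#' repeated-measures ANOVAs, the two planned TANOVA contrasts
#' (configuration/polarity, and low {3,4} vs. high {5,6} numerosity), and
#' the microstate segmentation with GEV back-fitting and ANOVA. Identical
#' configurations and seeds give identical reports.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `run_report` with elements `config`,
#'   `ground_truth`, `behavior` (trial table), `behavior_stats`,
#'   `amplitudes`, `component_anovas` (list per component), `tanova`
#'   (list of two `tanova_result`s), `segmentation`, `gev`, `gev_anova`,
#'   `grand_averages`, `study`, `n_rejected`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cfg <- config
  gt <- make_ground_truth(cfg$experiment, noise = cfg$noise)
  seeds <- derive_seeds(cfg$seed, cfg$subjects + 2L)
  conds <- condition_set(cfg$experiment)

  # --- simulation + (optional) preprocessing ---
  if (cfg$sim_mode == "continuous") {
    per_subj <- lapply(seq_len(cfg$subjects), function(s)
      process_continuous_subject(s, cfg, gt, seeds[s]))
    erps <- lapply(per_subj, `[[`, "erps")
    study <- structure(list(erps = erps,
                            times_ms = erps[[1]][[1]]$times_ms,
                            fs = erps[[1]][[1]]$fs, montage = gt$montage,
                            experiment = cfg$experiment),
                       class = "erp_study")
    n_rejected <- vapply(per_subj, `[[`, numeric(1), "n_rejected")
    schedules <- lapply(per_subj, `[[`, "behavior_schedule")
  } else {
    study <- simulate_subject_erps(cfg$experiment, gt,
                                   subjects = cfg$subjects,
                                   trials_per_condition = cfg$trials_per_condition,
                                   seed = seeds[1])
    n_rejected <- rep(0, cfg$subjects)
    schedules <- lapply(seq_len(cfg$subjects), function(s)
      build_schedule(cfg$experiment, reps = cfg$trials_per_condition,
                     seed = seeds[s]))
  }

  behavior <- purrr::map_dfr(seq_len(cfg$subjects), function(s)
    simulate_behavior(schedules[[s]], gt, seed = seeds[s] + 1L, subject = s))
  beh_stats <- behavior_stats(behavior)

  # --- component amplitudes and ANOVAs ---
  amps <- amplitude_table(study, cfg$windows) |>
    dplyr::left_join(conds, by = "condition_id")
  fac2 <- if (cfg$experiment == 3L) "polarity_scheme" else "configuration"
  component_anovas <- lapply(stats::setNames(cfg$windows$component,
                                             cfg$windows$component),
    function(comp) {
      d <- amps[amps$component == comp, ] |>
        dplyr::group_by(.data$subject, .data$condition_id, .data$n_elements,
                        .data[[fac2]]) |>
        dplyr::summarise(amplitude = mean(.data$amplitude), .groups = "drop")
      rm_anova(d, "amplitude", within = c(fac2, "n_elements"))
    })

  # --- grand averages ---
  grand <- lapply(stats::setNames(conds$condition_id, conds$condition_id),
    function(cid) grand_average(lapply(study$erps, `[[`, cid)))

  # --- TANOVA contrasts ---
  groups1 <- if (cfg$experiment == 3L)
    list(conds$condition_id[conds$polarity_scheme != "mixed"],
         conds$condition_id[conds$polarity_scheme == "mixed"])
  else
    list(conds$condition_id[conds$configuration == "shape"],
         conds$condition_id[conds$configuration == "random"])
  low_high <- list(conds$condition_id[conds$n_elements %in% 3:4],
                   conds$condition_id[conds$n_elements %in% 5:6])
  post <- c(0, 1000)
  tanova_res <- list(
    condition = tanova(
      condition_group_array(study, groups1[[1]], post),
      condition_group_array(study, groups1[[2]], post),
      M = cfg$tanova_M, alpha = cfg$alpha,
      min_duration_ms = cfg$min_duration_ms, fs = study$fs,
      seed = seeds[cfg$subjects + 1L]),
    numerosity = tanova(
      condition_group_array(study, low_high[[1]], post),
      condition_group_array(study, low_high[[2]], post),
      M = cfg$tanova_M, alpha = cfg$alpha,
      min_duration_ms = cfg$min_duration_ms, fs = study$fs,
      seed = seeds[cfg$subjects + 2L])
  )

  # --- microstates: segment post-stimulus grand averages, back-fit, ANOVA ---
  post_sel <- which(grand[[1]]$times_ms >= 0)
  post_sel <- post_sel[seq(1, length(post_sel), by = cfg$segment_decim)]
  seg_input <- lapply(grand, function(g) g$data[, post_sel])
  seg <- segment_microstates(seg_input, q_range = cfg$q_range,
                             min_segment_ms = cfg$min_duration_ms,
                             fs = study$fs / cfg$segment_decim)
  templates <- segmentation_templates(seg)
  gev <- gev_table(study, templates, cfg$windows) |>
    dplyr::left_join(conds, by = "condition_id")
  gev_anova <- lapply(stats::setNames(cfg$windows$component,
                                      cfg$windows$component),
    function(comp) {
      d <- gev[gev$component == comp, ]
      microstate_anova(d, within = c("template", fac2, "n_elements"))
    })

  structure(list(config = cfg, ground_truth = gt, behavior = behavior,
                 behavior_stats = beh_stats, amplitudes = amps,
                 component_anovas = component_anovas, tanova = tanova_res,
                 segmentation = seg, templates = templates, gev = gev,
                 gev_anova = gev_anova, grand_averages = grand,
                 study = study, n_rejected = n_rejected),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report: experiment %d, %d subjects, sim mode '%s'>\n",
              x$config$experiment, x$config$subjects, x$config$sim_mode))
  cat(sprintf("  microstates: q* = %d; TANOVA windows: %d (condition), %d (numerosity)\n",
              x$segmentation$q_star,
              nrow(attr(x$tanova$condition, "windows")),
              nrow(attr(x$tanova$numerosity, "windows"))))
  invisible(x)
}

#' Ground-truth recovery diagnostics for a simulated run
#'
#' Compares a [run_pipeline()] report against the generator's ground truth:
#' recovered-template spatial correlations, planted effect directions (N2
#' larger for shape than random, LMF ordered 3 > 4 > 5 with 5 and 6
#' equivalent, polarity affecting N2 only in Experiment 3), and the 5-vs-6
#' Bonferroni null.
#'
#' @param report A `run_report`.
#' @param ground_truth The matching [make_ground_truth()] (defaults to the
#'   one stored in the report).
#' @param alpha Significance level for the direction tests.
#' @return A tibble of class `recovery_diagnostics`: `check`, `value`,
#'   `pass`.
#' @export
validate_recovery <- function(report, ground_truth = report$ground_truth,
                              alpha = 0.05) {
  if (is.null(ground_truth)) stopf("missing ground truth")
  gt <- ground_truth
  cfg <- report$config
  fac2 <- if (cfg$experiment == 3L) "polarity_scheme" else "configuration"

  # template recovery: best |spatial correlation| per planted generator map
  tmpl_cor <- vapply(colnames(gt$templates), function(comp)
    max(abs(stats::cor(gt$templates[, comp],
                       report$templates[rownames(gt$templates), ]))),
    numeric(1))

  n2 <- report$amplitudes[report$amplitudes$component == "N2", ]
  n2_means <- tapply(n2$amplitude, n2[[fac2]], mean)
  n2_diff <- if (cfg$experiment == 3L) {
    unname(n2_means["mixed"] - n2_means["same"])
  } else {
    unname(n2_means["shape"] - n2_means["random"])
  }

  lmf <- report$amplitudes[report$amplitudes$component == "LMF", ] |>
    dplyr::group_by(.data$subject, .data$n_elements) |>
    dplyr::summarise(amplitude = mean(.data$amplitude), .groups = "drop")
  lmf_means <- tapply(lmf$amplitude, lmf$n_elements, mean)
  ph <- bonferroni_posthoc(lmf, "amplitude", "n_elements")
  p56 <- ph$p_adj[ph$level1 == "5" & ph$level2 == "6"]
  p34 <- ph$p_adj[ph$level1 == "3" & ph$level2 == "4"]

  checks <- tibble::tibble(
    check = c("template_correlation_min",
              if (cfg$experiment == 3L) "n2_mixed_minus_same" else "n2_shape_minus_random",
              "lmf_3_gt_4", "lmf_4_gt_5", "lmf_5_vs_6_nonsig", "lmf_3_vs_4_sig"),
    value = c(min(tmpl_cor), n2_diff,
              unname(lmf_means["3"] - lmf_means["4"]),
              unname(lmf_means["4"] - lmf_means["5"]),
              p56, p34),
    pass = c(min(tmpl_cor) > 0.9, n2_diff > 0,
             lmf_means["3"] > lmf_means["4"],
             lmf_means["4"] > lmf_means["5"],
             p56 > alpha, p34 < alpha)
  )
  if (cfg$experiment == 3L) {
    checks <- dplyr::bind_rows(checks, tibble::tibble(
      check = c("polarity_affects_n2", "polarity_spares_lmf"),
      value = c(report$component_anovas$N2$p[
                  report$component_anovas$N2$effect == "polarity_scheme"],
                report$component_anovas$LMF$p[
                  report$component_anovas$LMF$effect == "polarity_scheme"]),
      pass = c(checks$value[2] > 0 &&
                 report$component_anovas$N2$p[
                   report$component_anovas$N2$effect == "polarity_scheme"] < alpha,
               report$component_anovas$LMF$p[
                 report$component_anovas$LMF$effect == "polarity_scheme"] > alpha)
    ))
  }
  class(checks) <- c("recovery_diagnostics", class(checks))
  checks
}
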
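test_that("simulation is deterministic given (seed, embryo_id)", {
  cfg <- simulation_config(seed = 7L)
  a <- simulate_embryo(cfg, "e1")
  b <- simulate_embryo(cfg, "e1")
  expect_identical(a, b)
  expect_false(identical(as.data.frame(a)$x,
                         as.data.frame(simulate_embryo(cfg, "e2"))$x))

  pre <- make_preset("wt", seed = 3L)
  expect_identical(simulate_cohort(pre), simulate_cohort(pre))
})

test_that("zero-noise drift integrates exactly through the pipeline", {
  cfg <- simulation_config(noise_sigma = 0, z_noise_sigma = 0,
                           coherent_fraction = 0, medial_drift = 0.5,
                           imaging_drift = c(0, 0), n_timepoints = 31L,
                           dt = 4)
  kin <- pipeline_kinematics(simulate_embryo(cfg, "e1"))
  # 0.5 um/min over 120 min = 60 um medial displacement for every cell
  expect_equal(kin$velocity_ml, rep(0.5, nrow(kin)), tolerance = 1e-12)
  expect_equal(kin$velocity_ml * kin$duration, rep(60, nrow(kin)),
               tolerance = 1e-9)
})

test_that("drift correction cancels pure imaging drift by construction", {
  cfg <- simulation_config(noise_sigma = 0, z_noise_sigma = 0,
                           coherent_fraction = 0, medial_drift = 0,
                           ap_drift = 0, reference_retraction = 0,
                           imaging_drift = c(1, 0))
  raw <- simulate_embryo(cfg, "e1")
  # raw tracks translate at 4 um/step in x
  cells <- raw[raw$cell_class == "cardiomyocyte", ]
  one <- cells[cells$track_id == cells$track_id[1L], ]
  one <- one[order(one$t_index), ]
  expect_equal(diff(one$x), rep(4, nrow(one) - 1L), tolerance = 1e-12)
  # after correction all cells are stationary
  corrected <- drift_correct(raw)
  for (tid in unique(corrected$track_id)) {
    tr <- corrected[corrected$track_id == tid, ]
    expect_equal(diff(tr$x[order(tr$t_index)]), rep(0, nrow(tr) - 1L),
                 tolerance = 1e-10)
    expect_equal(diff(tr$y[order(tr$t_index)]), rep(0, nrow(tr) - 1L),
                 tolerance = 1e-10)
  }
})

test_that("fully coherent movement preserves medial-lateral rank order", {
  cfg <- simulation_config(noise_sigma = 0.5, coherent_fraction = 1,
                           z_noise_sigma = 0, seed = 11L)
  tracks <- simulate_embryo(cfg, "e1")
  aligned <- align_sides(drift_correct(tracks))
  left <- aligned[aligned$side == "left", ]
  wide <- stats::reshape(
    as.data.frame(left)[, c("track_id", "t_index", "xm")],
    idvar = "track_id", timevar = "t_index", direction = "wide")
  ranks <- apply(wide[, -1L], 2L, rank)
  for (j in seq_len(ncol(ranks))) {
    expect_identical(ranks[, j], ranks[, 1L])
  }
})

test_that("cohort presets reproduce the published cohort structure", {
  wt <- make_preset("wt")
  expect_equal(nrow(wt$embryos), 8L)
  expect_equal(wt$total_cells, 168L)
  expect_true(all(wt$embryos$medial_drift > 0))
  w <- wt$embryos$n_left + wt$embryos$n_right
  expect_equal(sum(w * wt$embryos$medial_drift) / sum(w),
               wt$target_ml_velocity)

  mut <- make_preset("ref_mutant")
  expect_equal(nrow(mut$embryos), 6L)
  expect_equal(mut$total_cells, 137L)
  expect_equal(sum(mut$embryos$phenotype == "mild"), 2L)
  expect_equal(sum(mut$embryos$phenotype == "severe"), 4L)
  expect_true(all(mut$embryos$medial_drift[mut$embryos$phenotype ==
                                             "severe"] <= 0))

  # closed-form calibration, solved independently: 46 mild cells at the
  # wild-type drift and 91 severe cells at d must average 0.016, so
  # d = (137 * 0.016 - 46 * 0.19) / 91
  expect_equal(unique(mut$embryos$medial_drift[mut$embryos$phenotype ==
                                                 "severe"]),
               (137 * 0.016 - 46 * 0.19) / 91, tolerance = 1e-12)
  wm <- mut$embryos$n_left + mut$embryos$n_right
  expect_equal(sum(wm * mut$embryos$medial_drift) / sum(wm), 0.016,
               tolerance = 1e-12)

  expect_error(make_preset("nonsense"))
})

test_that("cohort simulation yields the preset track counts", {
  wt <- simulate_cohort(make_preset("wt"))
  cm <- wt[wt$cell_class == "cardiomyocyte", ]
  expect_equal(length(unique(paste(cm$embryo_id, cm$track_id))), 168L)
  expect_equal(length(unique(wt$embryo_id[wt$cell_class == "reference"])),
               8L)

  mut <- simulate_cohort(make_preset("ref_mutant"))
  cmm <- mut[mut$cell_class == "cardiomyocyte", ]
  expect_equal(length(unique(paste(cmm$embryo_id, cmm$track_id))), 137L)
})

test_that("zero-noise cohort recovers the calibration target exactly", {
  pre <- make_preset("wt", seed = 2L)
  pre$config$noise_sigma <- 0
  pre$config$z_noise_sigma <- 0
  kin <- pipeline_kinematics(simulate_cohort(pre))
  expect_equal(mean(kin$velocity_ml), pre$target_ml_velocity,
               tolerance = 1e-10)
})

test_that("noisy cohorts recover the calibration target within 3 SE", {
  for (preset_name in c("wt", "ref_mutant")) {
    means <- vapply(1:5, function(s) {
      kin <- pipeline_kinematics(simulate_cohort(make_preset(preset_name,
                                                             seed = s)))
      mean(kin$velocity_ml)
    }, numeric(1L))
    target <- make_preset(preset_name)$target_ml_velocity
    se <- stats::sd(means) / sqrt(length(means))
    expect_lt(abs(mean(means) - target), 3 * se + 1e-12)
  }
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(dt = 0), "dt")
  expect_error(simulation_config(n_timepoints = 1), "n_timepoints")
  expect_error(simulation_config(noise_sigma = -1), "sigma")
  expect_error(simulation_config(coherent_fraction = 1.2),
               "coherent_fraction")
})
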
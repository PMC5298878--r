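kin_row <- function(embryo_id, velocity_ml, direction = NA_real_,
                    group = "wt") {
  data.frame(embryo_id = embryo_id, group = group,
             track_id = paste0("t", seq_along(velocity_ml)),
             duration = 120, path_length = 30, displacement = 20,
             speed = 0.25, efficiency = 2 / 3,
             velocity_ml = velocity_ml, velocity_ap = 0.05,
             direction = direction, stringsAsFactors = FALSE)
}

test_that("embryo summaries average cells within each embryo", {
  kin <- rbind(kin_row("e1", c(0.2, 0.2, 0.2)),
               kin_row("e2", c(0.1, -0.1)),
               kin_row("e3", c(0.3, 0.5)))
  s <- summarize_embryos(kin)
  expect_equal(nrow(s), 3L)
  expect_equal(s$mean_velocity_ml[s$embryo_id == "e1"], 0.2)
  expect_equal(s$mean_velocity_ml[s$embryo_id == "e2"], 0)
  expect_equal(s$fraction_non_medial[s$embryo_id == "e2"], 0.5)
  expect_equal(s$n_cells, c(3L, 2L, 2L))
  # undefined values are excluded per metric
  kin2 <- kin_row("e1", c(0.1, 0.2), direction = c(10, NA))
  expect_equal(summarize_embryos(kin2)$mean_direction, 10)
})

test_that("direction histogram places angles in 18-degree bins", {
  h <- direction_histogram(data.frame(direction = c(0, 0, 0)))
  expect_equal(h$counts, c(3L, rep(0L, 9L)))
  expect_equal(length(h$counts), 10L)
  expect_equal(h$bin_edges, seq(0, 180, by = 18))

  # 180 degrees falls in the last bin, not out of range
  h180 <- direction_histogram(data.frame(direction = 180))
  expect_equal(h180$counts[10L], 1L)
  expect_equal(sum(h180$counts), 1L)

  h4 <- direction_histogram(data.frame(direction = c(10, 30, 100, 170)))
  expect_equal(h4$counts, c(1L, 1L, 0L, 0L, 0L, 1L, 0L, 0L, 0L, 1L))
})

test_that("histogram counts conserve the number of directed cells", {
  set.seed(31)
  for (rep in 1:10) {
    dirs <- runif(sample(5:200, 1L), 0, 180)
    dirs[sample(length(dirs), 2L)] <- NA
    h <- direction_histogram(data.frame(direction = dirs))
    expect_equal(sum(h$counts), sum(!is.na(dirs)))
  }
})

test_that("pooled t-test matches the closed-form evaluation", {
  cmp <- compare_groups(1:3, 4:6)
  # independent oracle: pooled variance formula evaluated directly
  sp2 <- (2 * var(1:3) + 2 * var(4:6)) / 4
  t_oracle <- (mean(1:3) - mean(4:6)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  p_oracle <- 2 * pt(t_oracle, df = 4)
  expect_equal(cmp$t_statistic, t_oracle, tolerance = 1e-12)
  expect_equal(cmp$t_statistic, -3.674235, tolerance = 1e-6)
  expect_equal(cmp$p_value, p_oracle, tolerance = 1e-12)
  expect_equal(cmp$p_value, 0.02131164, tolerance = 1e-6)
  expect_equal(cmp$df, 4)

  # swapping groups negates t, p unchanged
  rev <- compare_groups(4:6, 1:3)
  expect_equal(rev$t_statistic, -cmp$t_statistic)
  expect_equal(rev$p_value, cmp$p_value)

  # identical groups: t = 0, p = 1
  same <- compare_groups(1:3, 1:3)
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)

  expect_error(compare_groups(1, 1:3), "at least 2")
  expect_error(compare_groups(c(1, 1), c(1, 1)), "degenerate")
})

test_that("t-test direction of effect agrees with a permutation test", {
  set.seed(5)
  a <- rnorm(6, 1)
  b <- rnorm(6, 0)
  cmp <- compare_groups(a, b)
  pooled <- c(a, b)
  perm <- replicate(500, {
    idx <- sample(12, 6)
    mean(pooled[idx]) - mean(pooled[-idx])
  })
  # observed mean difference sits in the same tail as the t statistic
  obs <- mean(a) - mean(b)
  expect_equal(sign(obs), sign(cmp$t_statistic))
  p_perm <- mean(abs(perm) >= abs(obs))
  expect_equal(cmp$p_value < 0.5, p_perm < 0.5)
})

test_that("fraction_non_medial counts cells with no medial movement", {
  expect_equal(fraction_non_medial(c(0.1, 0.2)), 0)
  expect_equal(fraction_non_medial(c(-0.1, -0.2)), 1)
  expect_equal(fraction_non_medial(c(0.1, 0, -0.2)), 2 / 3)
})

test_that("preset cohorts reproduce the qualitative directionality claims", {
  kin_wt <- pipeline_kinematics(simulate_cohort(make_preset("wt")))
  kin_mut <- pipeline_kinematics(simulate_cohort(make_preset("ref_mutant")))
  expect_lt(fraction_non_medial(kin_wt), 0.1)
  expect_gt(fraction_non_medial(kin_mut), 0.5)

  s <- summarize_embryos(kin_mut)
  pre <- make_preset("ref_mutant")
  pheno <- pre$embryos$phenotype[match(s$embryo_id, pre$embryos$embryo_id)]
  # severe embryos: per-embryo mean ML velocity at or near zero or below
  expect_true(all(s$mean_velocity_ml[pheno == "severe"] < 0.02))
  # mild embryos fall within the wild-type per-embryo spread
  s_wt <- summarize_embryos(kin_wt)
  expect_true(all(s$mean_velocity_ml[pheno == "mild"] >
                    min(s_wt$mean_velocity_ml) - 0.02))
  expect_true(all(s$mean_velocity_ml[pheno == "mild"] <
                    max(s_wt$mean_velocity_ml) + 0.02))
})
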
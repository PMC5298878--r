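test_that("a stationary reference leaves cell positions unchanged", {
  tr <- toy_tracks(list(list(id = "a", x = c(0, 1, 3), y = c(0, 2, 4)),
                        stationary_ref(3)))
  out <- drift_correct(tr)
  expect_equal(out$x, c(0, 1, 3))
  expect_equal(out$y, c(0, 2, 4))
  expect_false(any(out$cell_class == "reference"))
  expect_true(attr(out, "drift_corrected"))
})

test_that("reference motion is subtracted with the right sign", {
  # cell stationary in raw coordinates, reference moves (0, -1) per step:
  # the corrected cell moves (0, +1) per step
  n <- 5L
  tr <- toy_tracks(list(
    list(id = "a", x = rep(2, n), y = rep(0, n)),
    list(id = "ref", class = "reference", side = "none",
         x = rep(0, n), y = -(0:(n - 1L)))))
  out <- drift_correct(tr)
  expect_equal(diff(out$y[order(out$t_index)]), rep(1, n - 1L))

  # reference at (k*delta, 0), cell at (k*delta + k, 0): corrected
  # displacement over K steps is K micrometres
  delta <- 2
  k <- 0:5
  tr2 <- toy_tracks(list(
    list(id = "a", x = k * delta + k, y = rep(0, 6L)),
    list(id = "ref", class = "reference", side = "none",
         x = k * delta, y = rep(0, 6L))))
  out2 <- drift_correct(tr2)
  xs <- out2$x[order(out2$t_index)]
  expect_equal(xs[length(xs)] - xs[1L], 5)
  expect_equal(diff(xs), rep(1, 5L))
})

test_that("drift correction demands one complete reference per embryo", {
  noref <- toy_tracks(list(list(id = "a", x = 0:2, y = 0:2)),
                      validate = FALSE)
  expect_error(drift_correct(noref), "no reference")

  partial <- toy_tracks(list(
    list(id = "a", x = 0:3, y = 0:3),
    list(id = "ref", class = "reference", side = "none",
         x = 0:2, y = 0:2)), validate = FALSE)
  expect_error(drift_correct(partial), "incomplete")
})

test_that("drift correction is idempotent with a stationary reference", {
  set.seed(42)
  tr <- random_embryo_tracks()
  once <- drift_correct(tr)
  with_ref <- rbind(as.data.frame(once),
                    as.data.frame(toy_tracks(
                      list(stationary_ref(11L, x = 50, y = 150)),
                      midline_x = 50)))
  with_ref <- track_table(with_ref, midline_x = 50, dt = 4)
  attr(with_ref, "drift_corrected") <- TRUE
  twice <- drift_correct(with_ref)
  expect_equal(twice$x, once$x)
  expect_equal(twice$y, once$y)
})

test_that("side alignment makes movement toward the midline positive", {
  midline <- 100
  tr <- toy_tracks(list(
    list(id = "L", side = "left", x = c(50, 52), y = c(0, 0)),
    list(id = "R", side = "right", x = c(150, 152), y = c(0, 0)),
    stationary_ref(2, x = midline)), midline_x = midline)
  out <- align_sides(drift_correct(tr))
  xmL <- out$xm[out$track_id == "L"]
  xmR <- out$xm[out$track_id == "R"]
  expect_equal(diff(xmL), 2)    # left cell moving +x: medial
  expect_equal(diff(xmR), -2)   # right cell moving +x: lateral
  expect_true(attr(out, "aligned"))

  unlabeled <- as.data.frame(tr)
  unlabeled$side[unlabeled$track_id == "L"] <- "none"
  unlabeled$cell_class[unlabeled$track_id == "L"] <- "cardiomyocyte"
  tt <- track_table(unlabeled, midline_x = midline, dt = 4,
                    validate = FALSE)
  attr(tt, "drift_corrected") <- TRUE
  expect_error(align_sides(tt), "L")
})

test_that("the pipeline is invariant under mirror reflection", {
  set.seed(7)
  tr <- random_embryo_tracks(n_cells = 8L)
  kin <- pipeline_kinematics(tr)
  kin_m <- pipeline_kinematics(mirror_tracks(tr))
  for (m in c("speed", "efficiency", "velocity_ml", "velocity_ap",
              "direction", "path_length", "displacement")) {
    expect_equal(kin_m[[m]], kin[[m]], tolerance = 1e-10, label = m)
  }
})

test_that("AP bands split cells into tertiles of initial y", {
  mk <- function(ids, y0) {
    toy_tracks(c(lapply(seq_along(ids), function(i) {
      list(id = ids[i], x = c(-60, -59), y = c(y0[i], y0[i]))
    }), list(stationary_ref(2))))
  }
  prep <- function(tr) {
    out <- split_ap_bands(align_sides(drift_correct(tr)))
    first <- out[out$t_index == 0 & out$cell_class == "cardiomyocyte", ]
    stats::setNames(first$ap_band, first$track_id)
  }
  # 9 distinct initial y values: 3/3/3, anterior (largest y) on top
  bands9 <- prep(mk(sprintf("c%d", 1:9), y0 = 9:1))
  expect_equal(unname(table(bands9)[c("top", "middle", "bottom")]),
               rep(3L, 3L), ignore_attr = TRUE)
  expect_equal(unname(bands9[c("c1", "c5", "c9")]),
               c("top", "middle", "bottom"))
  # 2 cells: top and bottom, middle empty
  bands2 <- prep(mk(c("a", "b"), y0 = c(10, 0)))
  expect_equal(unname(bands2[c("a", "b")]), c("top", "bottom"))
  # identical y: deterministic split by track_id order
  bands_tie <- prep(mk(sprintf("c%d", 1:6), y0 = rep(5, 6)))
  expect_equal(unname(bands_tie[sprintf("c%d", 1:6)]),
               c("top", "top", "middle", "middle", "bottom", "bottom"))
  expect_identical(bands_tie,
                   prep(mk(sprintf("c%d", 1:6), y0 = rep(5, 6))))
})
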
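#' Simulation configuration for bilateral trajectory cohorts
#'
#' Parameters of the biased-random-walk generator used to emulate
#' timelapse tracking data of bilateral cardiomyocyte populations
#' converging on the midline. Per-step cell displacement is the sum of a
#' deterministic drift, an embryo-level coherent random increment shared
#' by all cells (drawn once per embryo per timestep in the medial/AP
#' frame and applied mirrored to the two sides, modelling collective
#' movement with low neighbor exchange), and independent per-cell noise.
#' A single reference-landmark track per embryo retracts posteriorly and
#' shares the imaging drift applied to all objects; drift correction must
#' remove exactly that shared component.
#'
#' @param cells_per_side integer length-2: number of cells on the
#'   (left, right) side.
#' @param n_timepoints number of sampled timepoints (>= 2); the default 31
#'   gives 120 min at the default cadence.
#' @param dt sampling interval, minutes.
#' @param medial_drift expected per-cell medial velocity, um/min
#'   (+ = toward the midline).
#' @param ap_drift expected anterior-posterior velocity, um/min
#'   (+ = anterior).
#' @param coherent_fraction share of the stochastic step variance drawn
#'   once per embryo per timestep and shared by all its cells, in [0, 1].
#' @param noise_sigma total stochastic step standard deviation per XY
#'   component, um per step.
#' @param z_noise_sigma step standard deviation along z, um per step
#'   (small: these cells move negligibly in z).
#' @param initial_gap distance between the left and right population
#'   centroid columns at t = 0, um.
#' @param reference_retraction posterior drift speed of the reference
#'   landmark, um/min.
#' @param imaging_drift numeric length-2 (x, y) stage/imaging drift in
#'   um/min applied to every object including the reference.
#' @param midline_x midline x-coordinate, um.
#' @param seed integer seed; together with the embryo identifier it fully
#'   determines the simulated tracks.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(cells_per_side = c(11L, 10L),
                              n_timepoints = 31L,
                              dt = 4,
                              medial_drift = 0.19,
                              ap_drift = 0,
                              coherent_fraction = 0.5,
                              noise_sigma = 0.3,
                              z_noise_sigma = 0.05,
                              initial_gap = 150,
                              reference_retraction = 0.05,
                              imaging_drift = c(0.1, 0.1),
                              midline_x = 0,
                              seed = 1L) {
  cfg <- list(cells_per_side = as.integer(rep_len(cells_per_side, 2L)),
              n_timepoints = as.integer(n_timepoints), dt = dt,
              medial_drift = medial_drift, ap_drift = ap_drift,
              coherent_fraction = coherent_fraction,
              noise_sigma = noise_sigma, z_noise_sigma = z_noise_sigma,
              initial_gap = initial_gap,
              reference_retraction = reference_retraction,
              imaging_drift = as.numeric(rep_len(imaging_drift, 2L)),
              midline_x = midline_x, seed = as.integer(seed))
  validate_simulation_config(cfg)
  class(cfg) <- "simulation_config"
  cfg
}

validate_simulation_config <- function(cfg) {
  if (!is.finite(cfg$dt) || cfg$dt <= 0) {
    stop("dt must be positive", call. = FALSE)
  }
  if (cfg$n_timepoints < 2L) {
    stop("n_timepoints must be at least 2", call. = FALSE)
  }
  if (cfg$noise_sigma < 0 || cfg$z_noise_sigma < 0) {
    stop("noise sigmas must be non-negative", call. = FALSE)
  }
  if (cfg$coherent_fraction < 0 || cfg$coherent_fraction > 1) {
    stop("coherent_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (any(cfg$cells_per_side < 1L)) {
    stop("cells_per_side must be at least 1 per side", call. = FALSE)
  }
  invisible(cfg)
}

# run code with a private RNG stream, restoring the caller's state
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# deterministic 31-bit seed from (seed, embryo_id)
embryo_seed <- function(seed, embryo_id) {
  h <- 0
  for (k in utf8ToInt(as.character(embryo_id))) {
    h <- (h * 31 + k) %% 1000003
  }
  as.integer((abs(as.numeric(seed)) * 2017 + h) %% 2147483647)
}

#' Simulate one embryo's bilateral cell tracks
#'
#' Generates complete tracks (a position at every timepoint) for the left
#' and right populations, placed as two cell columns per side symmetric
#' about `midline_x`, plus one reference-landmark track (`cell_class =
#' "reference"`) that retracts posteriorly at `reference_retraction` and
#' shares the imaging drift. Deterministic given `(config$seed,
#' embryo_id)`.
#'
#' @param config a [simulation_config()].
#' @param embryo_id embryo identifier.
#' @param group cohort label stored in the `group` column.
#' @return A [track_table()].
#' @export
simulate_embryo <- function(config, embryo_id, group = "wt") {
  validate_simulation_config(config)
  with_local_seed(embryo_seed(config$seed, embryo_id), {
    n_l <- config$cells_per_side[1L]
    n_r <- config$cells_per_side[2L]
    n_tp <- config$n_timepoints
    n_steps <- n_tp - 1L
    dt <- config$dt

    place_side <- function(n, sign) {
      # two cell columns per side; the medial column sits initial_gap/2
      # from the midline, the second 8 um more lateral
      col <- rep_len(c(0L, 1L), n)
      idx <- stats::ave(seq_len(n), col, FUN = seq_along)
      n_in_col <- stats::ave(seq_len(n), col, FUN = length)
      y0 <- -40 + 80 * (idx - 1) / pmax(n_in_col - 1, 1) +
        stats::runif(n, -2, 2)
      x0 <- config$midline_x + sign * (config$initial_gap / 2 + col * 8) +
        stats::runif(n, -2, 2)
      list(x = x0, y = y0)
    }
    left0 <- place_side(n_l, sign = -1)
    right0 <- place_side(n_r, sign = +1)

    sigma <- config$noise_sigma
    coh_sd <- sqrt(config$coherent_fraction) * sigma
    ind_sd <- sqrt(1 - config$coherent_fraction) * sigma
    # embryo-coherent increments, one per timestep, in (medial, AP) frame
    coh_m <- stats::rnorm(n_steps, 0, coh_sd)
    coh_y <- stats::rnorm(n_steps, 0, coh_sd)

    n_cells <- n_l + n_r
    side <- c(rep("left", n_l), rep("right", n_r))
    medial_sign <- ifelse(side == "left", +1, -1)  # raw-x direction of medial
    x0 <- c(left0$x, right0$x)
    y0 <- c(left0$y, right0$y)

    # per-cell independent noise, per step
    e_m <- matrix(stats::rnorm(n_cells * n_steps, 0, ind_sd), n_cells)
    e_y <- matrix(stats::rnorm(n_cells * n_steps, 0, ind_sd), n_cells)
    e_z <- matrix(stats::rnorm(n_cells * n_steps, 0, config$z_noise_sigma),
                  n_cells)

    step_m <- sweep(e_m, 2L, coh_m + config$medial_drift * dt, `+`)
    step_y <- sweep(e_y, 2L, coh_y + config$ap_drift * dt, `+`)
    drift_x <- config$imaging_drift[1L] * dt
    drift_y <- config$imaging_drift[2L] * dt

    x <- cbind(x0, x0 + t(apply(step_m * medial_sign + drift_x, 1L, cumsum)))
    y <- cbind(y0, y0 + t(apply(step_y + drift_y, 1L, cumsum)))
    z <- cbind(0, t(apply(e_z, 1L, cumsum)))

    t_index <- 0:(n_tp - 1L)
    ref_x <- config$midline_x + drift_x * t_index
    ref_y <- 100 + (drift_y - config$reference_retraction * dt) * t_index
    cell_ids <- sprintf("c%02d", seq_len(n_cells))

    rows <- data.frame(
      embryo_id = embryo_id,
      group = group,
      track_id = c(rep(cell_ids, each = n_tp), rep("ref", n_tp)),
      cell_class = c(rep("cardiomyocyte", n_cells * n_tp),
                     rep("reference", n_tp)),
      side = c(rep(side, each = n_tp), rep("none", n_tp)),
      t_index = rep(t_index, n_cells + 1L),
      t = rep(t_index * dt, n_cells + 1L),
      x = c(as.vector(t(x)), ref_x),
      y = c(as.vector(t(y)), ref_y),
      z = c(as.vector(t(z)), rep(0, n_tp)),
      stringsAsFactors = FALSE
    )
    track_table(rows, midline_x = config$midline_x, dt = dt)
  })
}

# printed cohort mean medial-lateral velocities the presets are
# calibrated to (um/min)
WT_ML_VELOCITY <- 0.19
MUTANT_ML_VELOCITY <- 0.016

#' Calibrated cohort presets
#'
#' Builds the built-in study cohorts. The `wt` preset has 8 embryos and
#' 168 cells in total (21 per embryo, 11 left + 10 right), with
#' per-embryo medial drifts spread symmetrically over 0.15-0.23 um/min so
#' every embryo drifts medially and the cell-weighted cohort mean is
#' exactly 0.19 um/min. The `ref_mutant` preset has 6 embryos and 137
#' cells: 2 "mild" embryos at the wild-type cohort drift and 4 "severe"
#' embryos sharing a single drift value solved in closed form so the
#' cell-weighted cohort mean equals 0.016 um/min,
#' \deqn{d_{severe} = (N \bar v - n_{mild} v_{wt}) / n_{severe},}
#' which evaluates to about -0.072 um/min (movement away from the
#' midline).
#'
#' @param name `"wt"` or `"ref_mutant"`.
#' @param seed integer base seed for the cohort.
#' @return A `cohort_preset` list with elements `name`, `group`,
#'   `config` (the shared [simulation_config()]), `embryos` (data frame:
#'   `embryo_id`, `phenotype`, `medial_drift`, `n_left`, `n_right`),
#'   `total_cells` and `target_ml_velocity`.
#' @export
make_preset <- function(name = c("wt", "ref_mutant"), seed = 1L) {
  name <- match.arg(name)
  config <- simulation_config(seed = seed)
  if (name == "wt") {
    offsets <- c(0.04, 0.03, 0.02, 0.01, -0.01, -0.02, -0.03, -0.04)
    embryos <- data.frame(
      embryo_id = sprintf("wt%d", 1:8),
      phenotype = "wt",
      medial_drift = WT_ML_VELOCITY + offsets,
      n_left = 11L, n_right = 10L,
      stringsAsFactors = FALSE
    )
    group <- "wt"
    target <- WT_ML_VELOCITY
  } else {
    n_cells <- c(23L, 23L, 23L, 23L, 23L, 22L)
    n_left <- c(12L, 12L, 12L, 12L, 12L, 11L)
    phenotype <- c("mild", "mild", rep("severe", 4L))
    n_mild <- sum(n_cells[phenotype == "mild"])
    n_severe <- sum(n_cells[phenotype == "severe"])
    total <- n_mild + n_severe
    severe_drift <- (total * MUTANT_ML_VELOCITY - n_mild * WT_ML_VELOCITY) /
      n_severe
    embryos <- data.frame(
      embryo_id = c("mild1", "mild2", sprintf("severe%d", 1:4)),
      phenotype = phenotype,
      medial_drift = ifelse(phenotype == "mild", WT_ML_VELOCITY,
                            severe_drift),
      n_left = n_left, n_right = n_cells - n_left,
      stringsAsFactors = FALSE
    )
    group <- "mutant"
    target <- MUTANT_ML_VELOCITY
  }
  weights <- embryos$n_left + embryos$n_right
  stopifnot(abs(sum(weights * embryos$medial_drift) / sum(weights) -
                  target) < 1e-12)
  structure(list(name = name, group = group, config = config,
                 embryos = embryos, total_cells = sum(weights),
                 target_ml_velocity = target),
            class = "cohort_preset")
}

#' @export
print.cohort_preset <- function(x, ...) {
  cat(sprintf(
    "<cohort_preset '%s'> %d embryos, %d cells; target ML velocity %g um/min\n",
    x$name, nrow(x$embryos), x$total_cells, x$target_ml_velocity))
  print.data.frame(x$embryos)
  invisible(x)
}

#' Simulate a full cohort from a preset
#'
#' Runs [simulate_embryo()] for every embryo of the preset, applying its
#' per-embryo drift and cell-count overrides, and concatenates the
#' results. Reproducible from the preset's seed.
#'
#' @param preset a [make_preset()] result.
#' @return A multi-embryo [track_table()].
#' @export
simulate_cohort <- function(preset) {
  stopifnot(inherits(preset, "cohort_preset"))
  parts <- vector("list", nrow(preset$embryos))
  for (i in seq_len(nrow(preset$embryos))) {
    e <- preset$embryos[i, ]
    cfg <- preset$config
    cfg$medial_drift <- e$medial_drift
    cfg$cells_per_side <- c(e$n_left, e$n_right)
    parts[[i]] <- simulate_embryo(cfg, e$embryo_id, group = preset$group)
  }
  out <- do.call(rbind, lapply(parts, as.data.frame))
  track_table(out, midline_x = preset$config$midline_x,
              dt = preset$config$dt)
}
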
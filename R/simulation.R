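#' Scenario configuration
#'
#' Collects everything that determines a simulation run: grid geometry,
#' tip-zone threshold, mechanics and growth parameters, the scenario name,
#' total simulated time and the trace recording interval. The core model is
#' deterministic; `rng_seed` is reserved for stochastic extensions and
#' recorded with the run.
#'
#' @param scenario one of `"wildtype"`, `"reduced_upper_elongation"`,
#'   `"fewer_upper_cells"`, `"graded_cell_number"`, `"symmetric"`.
#' @param n_cols,n_rows,cell_width,cell_height grid geometry (defaults
#'   20 x 6 cells of 10 x 10 um: a ~200 um stage II organ).
#' @param tip_zone_length length of the non-growing tip zone in um
#'   (default 180: the two base-proximal cell columns elongate, matching
#'   the observation that only the first two cells of a stage II lateral
#'   root have entered elongation).
#' @param mechanics a [mechanics_params()].
#' @param growth a [growth_field()].
#' @param total_time simulated hours (default 9; runs terminate after 9 h
#'   of growth).
#' @param record_every growth steps between trace records (default 10).
#' @param k_cells `k` for the cell-number scenarios (default 1).
#' @param rng_seed optional integer, recorded only.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(scenario = "wildtype",
                            n_cols = 20L, n_rows = 6L,
                            cell_width = 10, cell_height = 10,
                            tip_zone_length = 180,
                            mechanics = mechanics_params(),
                            growth = growth_field(),
                            total_time = 9, record_every = 10L,
                            k_cells = 1L, rng_seed = NULL) {
  stopifnot(inherits(mechanics, "mechanics_params"),
            inherits(growth, "growth_field"))
  if (!is.numeric(total_time) || total_time <= 0)
    stop("total_time must be positive")
  if (record_every < 1) stop("record_every must be >= 1")
  structure(list(scenario = scenario, n_cols = as.integer(n_cols),
                 n_rows = as.integer(n_rows), cell_width = cell_width,
                 cell_height = cell_height,
                 tip_zone_length = tip_zone_length,
                 mechanics = mechanics, growth = growth,
                 total_time = total_time,
                 record_every = as.integer(record_every),
                 k_cells = as.integer(k_cells), rng_seed = rng_seed),
            class = "scenario_config")
}

#' Read a scenario configuration from YAML or JSON
#'
#' Any subset of the [scenario_config()] arguments may appear in the file
#' (nested `mechanics:` and `growth:` blocks take the corresponding
#' constructor arguments); missing entries keep their defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A `scenario_config`.
#' @export
read_scenario_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path)
  else yaml::read_yaml(path)
  mech <- do.call(mechanics_params, as.list(raw$mechanics))
  grow <- do.call(growth_field, as.list(raw$growth))
  raw$mechanics <- NULL; raw$growth <- NULL
  do.call(scenario_config,
          c(raw, list(mechanics = mech, growth = grow)))
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf(
    "Scenario '%s': %dx%d grid (%gx%g um), tip zone %g um, %g h (dt %g h)\n",
    x$scenario, x$n_cols, x$n_rows, x$cell_width, x$cell_height,
    x$tip_zone_length, x$total_time, x$growth$dt_growth))
  invisible(x)
}

#' Run a bending scenario
#'
#' Orchestrates a full simulation: builds the cell grid, assigns zones,
#' derives the scenario's growth field, pre-relaxes the turgor-inflated
#' mesh (the relaxed state is the reference configuration, so the initial
#' angle is measured at mechanical equilibrium), then alternates growth
#' steps with mechanical relaxation until `total_time`, recording the
#' bending angle, per-row mean axial cell lengths and relaxation iteration
#' counts every `record_every` growth steps. The run is fully
#' deterministic: identical configurations give bit-identical traces.
#'
#' @param config a [scenario_config()].
#' @param engine relaxation engine, `"cpp"` (default) or `"r"`.
#' @param snapshot_times optional vector of times (hours) at which to keep
#'   full tissue snapshots (the final tissue is always kept).
#' @return An object of class `lr_sim`: list with `config`, `trace` (a
#'   data frame with columns `time_h`, `angle_deg`, `relax_iters` and
#'   `row<i>_mean_len_um` for each cell row), the final `tissue`, any
#'   requested `snapshots`, and the effective per-cell elongating mask.
#' @examples
#' \donttest{
#' sim <- run_scenario(scenario_config("wildtype"))
#' summary(sim)
#' }
#' @export
run_scenario <- function(config, engine = c("cpp", "r"),
                         snapshot_times = NULL) {
  engine <- match.arg(engine)
  stopifnot(inherits(config, "scenario_config"))
  mech <- config$mechanics
  tissue <- build_lr_grid(config$n_cols, config$n_rows,
                          config$cell_width, config$cell_height,
                          stiffness = mech$k_x)
  tissue <- assign_zones(tissue, config$tip_zone_length)
  field <- scenario_field(config$scenario, config$growth, tissue,
                          k = config$k_cells)

  relax <- relax_to_equilibrium(tissue, mech, engine = engine)
  tissue <- relax$tissue

  n_steps <- as.integer(round(config$total_time / field$dt_growth))
  rec_steps <- unique(c(0L, seq.int(config$record_every, n_steps,
                                    by = config$record_every), n_steps))
  rec_steps <- sort(rec_steps)
  n_rec <- length(rec_steps)
  times <- numeric(n_rec)
  angles <- numeric(n_rec)
  iters <- integer(n_rec)
  row_len <- matrix(NA_real_, n_rec, config$n_rows)
  snaps <- list()
  snap_steps <- if (is.null(snapshot_times)) integer(0) else
    unique(pmin(pmax(as.integer(round(snapshot_times / field$dt_growth)),
                     0L), n_steps))

  record <- function(slot, step, it) {
    times[slot] <<- step * field$dt_growth
    angles[slot] <<- bending_angle(tissue)
    iters[slot] <<- it
    cl <- cell_axial_lengths(tissue)
    for (r in seq_len(config$n_rows))
      row_len[slot, r] <<- mean(cl[tissue$cell_row == r - 1L])
    if (any(cell_areas(tissue) <= 0))
      stop(sprintf("non-positive cell area at growth step %d", step))
  }

  slot <- 1L
  record(slot, 0L, relax$iterations)
  if (0L %in% snap_steps) snaps[["0"]] <- tissue
  for (step in seq_len(n_steps)) {
    tissue <- apply_growth_step(tissue, field, check_relaxed = FALSE)
    relax <- tryCatch(
      relax_to_equilibrium(tissue, mech, engine = engine),
      error = function(e)
        stop(sprintf("growth step %d: %s", step, conditionMessage(e)),
             call. = FALSE))
    tissue <- relax$tissue
    if (step %in% rec_steps) {
      slot <- slot + 1L
      record(slot, step, relax$iterations)
    }
    if (step %in% snap_steps)
      snaps[[as.character(step)]] <- tissue
  }

  trace <- data.frame(time_h = times, angle_deg = angles,
                      relax_iters = iters)
  colnames(row_len) <- sprintf("row%d_mean_len_um",
                               seq_len(config$n_rows) - 1L)
  trace <- cbind(trace, as.data.frame(row_len))
  structure(list(config = config, field = field, trace = trace,
                 tissue = tissue, snapshots = snaps,
                 elongating_mask = if (is.null(field$elongating_mask))
                   tissue$elongating else field$elongating_mask),
            class = "lr_sim")
}

#' Bending angle at a given time
#'
#' Reads the recorded set-point angle at the trace record closest to
#' `time`.
#'
#' @param sim an `lr_sim`.
#' @param time hours.
#' @return Angle in degrees.
#' @export
angle_at <- function(sim, time) {
  stopifnot(inherits(sim, "lr_sim"))
  i <- which.min(abs(sim$trace$time_h - time))
  sim$trace$angle_deg[i]
}

#' @export
print.lr_sim <- function(x, ...) {
  tr <- x$trace
  cat(sprintf("Lateral-root bending simulation ('%s', %g h)\n",
              x$config$scenario, x$config$total_time))
  cat(sprintf("  angle: %.1f deg -> %.1f deg (at ~8 h: %.1f deg)\n",
              tr$angle_deg[1], tr$angle_deg[nrow(tr)], angle_at(x, 8)))
  invisible(x)
}

#' @export
summary.lr_sim <- function(object, ...) {
  tr <- object$trace
  out <- list(
    scenario = object$config$scenario,
    total_time = object$config$total_time,
    initial_angle = tr$angle_deg[1],
    final_angle = tr$angle_deg[nrow(tr)],
    angle_8h = angle_at(object, 8),
    flank_fold_change = flank_fold_change(object$tissue),
    total_relax_iters = sum(tr$relax_iters),
    n_records = nrow(tr))
  class(out) <- "summary.lr_sim"
  out
}

#' @export
print.summary.lr_sim <- function(x, ...) {
  cat(sprintf("Scenario '%s' over %g h:\n", x$scenario, x$total_time))
  cat(sprintf("  set-point angle: %.2f deg (t=0) -> %.2f deg (end); %.2f deg at ~8 h\n",
              x$initial_angle, x$final_angle, x$angle_8h))
  cat(sprintf("  upper/lower flank cell-length fold change: %.2f\n",
              x$flank_fold_change))
  cat(sprintf("  %d trace records, %d relaxation iterations in total\n",
              x$n_records, x$total_relax_iters))
  invisible(x)
}

#' Plot the time evolution of the set-point angle
#'
#' @param x an `lr_sim`.
#' @param type `"angle"` for the angle-vs-time trace, `"tissue"` for the
#'   final mesh.
#' @param ... passed on to the underlying plot.
#' @export
plot.lr_sim <- function(x, type = c("angle", "tissue"), ...) {
  type <- match.arg(type)
  if (type == "tissue") return(plot(x$tissue, ...))
  graphics::plot(x$trace$time_h, x$trace$angle_deg, type = "l",
                 xlab = "time (h)", ylab = "set-point angle (deg)",
                 ylim = c(min(x$trace$angle_deg) - 5, 95), ...)
  graphics::abline(h = 90, lty = 3, col = "grey50")
  invisible(x)
}

#' Write a simulation trace to CSV
#'
#' @param sim an `lr_sim`.
#' @param path output file.
#' @export
write_trace <- function(sim, path) {
  stopifnot(inherits(sim, "lr_sim"))
  utils::write.csv(sim$trace, path, row.names = FALSE)
  invisible(path)
}
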
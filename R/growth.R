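#' Anisotropic growth field
#'
#' Parameters of the growth law `dL/dt = L * rho(d)` that extends the
#' resting lengths of axial wall springs. The measured flank elongation rates are
#' linearly interpolated across the flanks: `r(0) = r_min` at the lowermost
#' (gravity-side) flank to `r(1) = r_max` at the top flank, where `d` is the
#' material flank coordinate (wall row / n_rows, fixed at build time). In
#' the default relative mode the per-hour relative rate is
#' `rho(d) = r(d) / reference_length`, with `reference_length` the axial
#' length of the real epidermal cells whose elongation rates the model
#' encodes (the model draws cells at 10 um for numerical convenience; the
#' measured rates refer to cells an order of magnitude longer). An absolute
#' mode (`dL/dt = r(d)`, rates applied directly in um/h) is available for
#' sensitivity analysis.
#'
#' @param r_min,r_max elongation rates at the bottom and top flank in um/h
#'   (defaults 5 and 15).
#' @param dt_growth growth time step in hours (default 0.003).
#' @param reference_length reference cell length (um) converting absolute
#'   rates into relative ones (default 100; see the methods vignette for the
#'   calibration).
#' @param upper_flank_scale multiplier in (0, 1] applied to the rate on the
#'   upper flank rows; 0.9 reproduces the 10%-reduced upper-flank
#'   elongation scenario.
#' @param top_rows how many top cell rows count as the "upper flank" for
#'   `upper_flank_scale` (default 1).
#' @param mode `"relative"` (default) or `"absolute"`.
#' @param elongating_mask optional per-cell logical vector overriding the
#'   tissue's `elongating` flags (used by the cell-number scenarios).
#' @return An object of class `growth_field`.
#' @export
growth_field <- function(r_min = 5, r_max = 15, dt_growth = 0.003,
                         reference_length = 100, upper_flank_scale = 1,
                         top_rows = 1L, mode = c("relative", "absolute"),
                         elongating_mask = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(r_min) || !is.numeric(r_max) || r_min <= 0 ||
      r_max < r_min)
    stop("need r_max >= r_min > 0")
  if (!is.numeric(dt_growth) || dt_growth <= 0)
    stop("dt_growth must be positive")
  if (!is.numeric(reference_length) || reference_length <= 0)
    stop("reference_length must be positive")
  if (!is.numeric(upper_flank_scale) || upper_flank_scale <= 0 ||
      upper_flank_scale > 1)
    stop("upper_flank_scale must lie in (0, 1]")
  if (top_rows < 1) stop("top_rows must be >= 1")
  if (!is.null(elongating_mask) && !is.logical(elongating_mask))
    stop("elongating_mask must be logical")
  structure(list(r_min = r_min, r_max = r_max, dt_growth = dt_growth,
                 reference_length = reference_length,
                 upper_flank_scale = upper_flank_scale,
                 top_rows = as.integer(top_rows), mode = mode,
                 elongating_mask = elongating_mask),
            class = "growth_field")
}

#' @export
print.growth_field <- function(x, ...) {
  cat(sprintf(
    "Growth field: r %g -> %g um/h (%s, ref %g um), dt %g h, upper-flank scale %g (%d row%s)\n",
    x$r_min, x$r_max, x$mode, x$reference_length, x$dt_growth,
    x$upper_flank_scale, x$top_rows, if (x$top_rows > 1) "s" else ""))
  if (!is.null(x$elongating_mask))
    cat(sprintf("  per-cell mask: %d of %d cells elongating\n",
                sum(x$elongating_mask), length(x$elongating_mask)))
  invisible(x)
}

#' Interpolated elongation rate across the flanks
#'
#' `r(d) = r_min + d * (r_max - r_min)` in um/h, where `d` in \[0, 1\] is the
#' relative flank position (0 = bottom/gravity side, 1 = top). On upper
#' flank rows the rate is multiplied by `upper_flank_scale`.
#'
#' @param d relative flank position(s) in \[0, 1\].
#' @param field a [growth_field()].
#' @param row_is_top logical (recycled): does the position belong to the
#'   upper flank rows the scale applies to?
#' @return Elongation rate(s) in um/h.
#' @export
elongation_rate <- function(d, field, row_is_top = FALSE) {
  if (any(!is.finite(d)) || any(d < 0) || any(d > 1))
    stop("d must lie in [0, 1]")
  r <- field$r_min + d * (field$r_max - field$r_min)
  ifelse(rep_len(row_is_top, length(r)), r * field$upper_flank_scale, r)
}

# growing-wall mask and per-wall growth factors; static for a fixed tissue
# topology, so run_scenario() precomputes them once
wall_growth_factors <- function(tissue, field) {
  elong <- tissue$elongating
  if (!is.null(field$elongating_mask)) {
    if (length(field$elongating_mask) != length(elong))
      stop("elongating_mask length does not match the cell count")
    elong <- field$elongating_mask
  }
  nw <- length(tissue$wall_from)
  touched <- rep(FALSE, nw)
  if (any(elong))
    touched[unique(as.vector(tissue$cell_walls[elong, , drop = FALSE]))] <- TRUE
  grow <- touched & tissue$wall_orient == "axial"
  d <- tissue$wall_row / tissue$n_rows
  is_top <- tissue$wall_row >= tissue$n_rows - field$top_rows
  r <- elongation_rate(pmin(pmax(d, 0), 1), field, is_top)
  if (field$mode == "relative") {
    factor <- 1 + (r / field$reference_length) * field$dt_growth
    list(grow = grow, factor = ifelse(grow, factor, 1), add = NULL)
  } else {
    list(grow = grow, factor = NULL,
         add = ifelse(grow, r * field$dt_growth, 0))
  }
}

#' Apply one growth step to the resting lengths
#'
#' Extends the resting length of every axial wall that belongs to at least
#' one elongating cell by one growth increment of duration `dt_growth`:
#' multiplicatively by `1 + rho(d) * dt_growth` in relative mode
#' (`rho(d) = r(d)/reference_length`), or additively by `r(d) * dt_growth`
#' in absolute mode. `d` is the wall's material flank coordinate (row index
#' / n_rows). Transverse walls and walls touching only non-elongating cells
#' are unchanged (anisotropic growth). Advances `sim_time` by `dt_growth`.
#'
#' @param tissue an `lr_tissue`, mechanically relaxed.
#' @param field a [growth_field()].
#' @param check_relaxed verify the mechanics residual before growing
#'   (default `TRUE`; [run_scenario()] disables the recheck because growth
#'   there always follows a relaxation).
#' @param params [mechanics_params()] used for the relaxation check.
#' @return The grown tissue.
#' @export
apply_growth_step <- function(tissue, field, check_relaxed = TRUE,
                              params = mechanics_params()) {
  if (check_relaxed) {
    f <- total_forces(tissue, params)
    rf <- max(sqrt(rowSums(f * f))) / params$mass
    if (rf >= 10 * params$equilibrium_tol)
      stop(sprintf(
        "growth step requires a relaxed tissue (force residual %g)", rf))
  }
  w <- wall_growth_factors(tissue, field)
  if (identical(field$mode, "relative")) {
    tissue$wall_rest <- tissue$wall_rest * w$factor
  } else {
    tissue$wall_rest <- tissue$wall_rest + w$add
  }
  tissue$sim_time <- tissue$sim_time + field$dt_growth
  tissue
}

#' Growth fields for the shipped perturbation scenarios
#'
#' Derives the effective growth field for a named scenario from a base
#' field and the tissue it will act on:
#' \describe{
#'   \item{`wildtype`}{the base field, unchanged.}
#'   \item{`reduced_upper_elongation`}{elongation rate on the upper flank
#'     reduced by 10% (`upper_flank_scale = 0.9`).}
#'   \item{`fewer_upper_cells`}{the `k` tip-most elongation-zone cells of
#'     the top row stop elongating (asymmetric cell number).}
#'   \item{`graded_cell_number`}{the number of silenced tip-most
#'     elongation-zone cells decreases linearly from `k` in the top row to 0
#'     in the bottom row (graded asymmetric meristem input).}
#'   \item{`symmetric`}{`r_max` set equal to `r_min`: a no-asymmetry
#'     control that cannot bend.}
#' }
#'
#' @param scenario scenario name (see above).
#' @param base a [growth_field()] to modify.
#' @param tissue the `lr_tissue` the field will be applied to (needed for
#'   the cell-number masks).
#' @param k number of silenced top-row cells for the cell-number scenarios
#'   (default 1).
#' @return A [growth_field()].
#' @export
scenario_field <- function(scenario, base = growth_field(), tissue,
                           k = 1L) {
  scenarios <- c("wildtype", "reduced_upper_elongation",
                 "fewer_upper_cells", "graded_cell_number", "symmetric")
  if (!is.character(scenario) || length(scenario) != 1 ||
      !scenario %in% scenarios)
    stop("unknown scenario: ", paste(scenario, collapse = ", "))
  field <- base
  if (scenario == "reduced_upper_elongation") {
    field$upper_flank_scale <- 0.9
  } else if (scenario == "symmetric") {
    field$r_max <- field$r_min
  } else if (scenario %in% c("fewer_upper_cells", "graded_cell_number")) {
    stopifnot(inherits(tissue, "lr_tissue"))
    if (k < 0) stop("k must be non-negative")
    mask <- tissue$elongating
    n_rows <- tissue$n_rows
    for (row in 0:(n_rows - 1L)) {
      n_clear <- if (scenario == "fewer_upper_cells") {
        if (row == n_rows - 1L) k else 0L
      } else {
        as.integer(round(k * row / (n_rows - 1L)))
      }
      if (n_clear == 0L) next
      in_row <- which(tissue$cell_row == row & tissue$zone == "elongation")
      in_row <- in_row[order(tissue$cell_col[in_row])]  # tip-most first
      mask[utils::head(in_row, n_clear)] <- FALSE
    }
    field$elongating_mask <- mask
  }
  field
}
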
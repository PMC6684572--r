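#' Mechanics parameters for the mass-spring model
#'
#' Bundles the mechanical constants of the model: wall-spring stiffness
#' `k_x`, turgor pressure `p_const` (force per unit wall length), damping
#' constant `beta`, vertex point mass `mass`, the mechanics time step
#' `dt_mech` (model-hours) and the relaxation stopping rule. A conservative
#' stability bound `dt_mech < 2 * min(beta * mass / k_x, 1 / beta)` for the
#' damped oscillator update is enforced at construction.
#'
#' @param k_x spring stiffness (default 0.9, used in all simulations).
#' @param p_const turgor pressure (default 0.05).
#' @param beta damping constant (default 0.2).
#' @param mass vertex point mass (default 1).
#' @param dt_mech mechanics integration step in model-hours (default 0.2).
#'   The relaxation fixed point does not depend on the step, only the
#'   transient path does, so the default is chosen for speed well inside
#'   the stability bound; use a smaller step to resolve the transients.
#' @param equilibrium_tol residual tolerance on both max |force|/mass and
#'   max |velocity| at which the mesh counts as relaxed (default 1e-5).
#' @param max_relax_iters iteration cap for [relax_to_equilibrium()]
#'   (default 1e5).
#' @param euler `"semi"` (velocity update applied before the position
#'   update; default) or `"forward"` (positions advanced with the previous
#'   velocity).
#' @return An object of class `mechanics_params`.
#' @export
mechanics_params <- function(k_x = 0.9, p_const = 0.05, beta = 0.2,
                             mass = 1, dt_mech = 0.2,
                             equilibrium_tol = 1e-5,
                             max_relax_iters = 1e5,
                             euler = c("semi", "forward")) {
  euler <- match.arg(euler)
  for (nm in c("k_x", "p_const", "beta", "mass", "dt_mech")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      stop(nm, " must be a positive scalar")
  }
  if (!is.numeric(equilibrium_tol) || equilibrium_tol < 0)
    stop("equilibrium_tol must be non-negative")
  if (max_relax_iters < 1) stop("max_relax_iters must be >= 1")
  bound <- 2 * min(beta * mass / k_x, 1 / beta)
  if (dt_mech >= bound)
    stop(sprintf("dt_mech = %g violates the stability bound %g", dt_mech,
                 bound))
  structure(list(k_x = k_x, p_const = p_const, beta = beta, mass = mass,
                 dt_mech = dt_mech, equilibrium_tol = equilibrium_tol,
                 max_relax_iters = as.integer(max_relax_iters),
                 euler = euler),
            class = "mechanics_params")
}

#' @export
print.mechanics_params <- function(x, ...) {
  cat(sprintf(
    "Mechanics: k_x=%g p_const=%g beta=%g m=%g dt=%g tol=%g (%s Euler)\n",
    x$k_x, x$p_const, x$beta, x$mass, x$dt_mech, x$equilibrium_tol,
    x$euler))
  invisible(x)
}

#' Spring force on one endpoint
#'
#' Force exerted on vertex u by the linear spring (u, v):
#' `stiffness * (L - |p_u - p_v|) * (p_u - p_v) / |p_u - p_v|`, positive
#' magnitude under compression. The force on v is equal and opposite.
#'
#' @param p_u,p_v endpoint positions (2-vectors, micrometres).
#' @param resting_length rest length `L` of the spring.
#' @param stiffness spring constant.
#' @return 2-vector force on u.
#' @export
spring_force <- function(p_u, p_v, resting_length, stiffness) {
  d <- p_u - p_v
  len <- sqrt(sum(d * d))
  if (len < 1e-12)
    stop("degenerate geometry: coincident spring endpoints")
  stiffness * (resting_length - len) * d / len
}

#' Turgor-pressure forces exerted by one cell on its vertices
#'
#' For each wall of the cell a force of magnitude
#' `p_const * |p_u - p_v|` acts along the wall's outward normal (outward
#' with respect to this cell) and is split equally between the wall's two
#' endpoint vertices. Over a closed cell these contributions sum to zero.
#'
#' @param cell cell index.
#' @param tissue an `lr_tissue`.
#' @param p_const turgor pressure.
#' @return A 4 x 2 matrix of forces, with `rownames` the vertex indices of
#'   the cell in counter-clockwise order.
#' @export
cell_pressure_forces <- function(cell, tissue, p_const) {
  v <- tissue$cell_verts[cell, ]
  p <- tissue$pos[v, , drop = FALSE]
  nxt <- c(2, 3, 4, 1)
  e <- p[nxt, ] - p            # CCW edge vectors v_i -> v_{i+1}
  elen <- sqrt(rowSums(e * e))
  if (any(elen < 1e-12))
    stop("degenerate geometry: zero-length cell wall")
  area <- 0.5 * sum(p[, 1] * p[nxt, 2] - p[nxt, 1] * p[, 2])
  if (area <= 1e-12)
    stop("degenerate geometry: non-positive cell area")
  # outward normal of a CCW edge (ex, ey) is (ey, -ex)/|e|; the per-wall
  # force p_const * |e| * n-hat reduces to p_const * (ey, -ex)
  fwall <- p_const * cbind(e[, 2], -e[, 1])
  out <- 0.5 * fwall + 0.5 * fwall[c(4, 1, 2, 3), ]  # half to each endpoint
  rownames(out) <- v
  colnames(out) <- c("x", "y")
  out
}

#' Total force field on all vertices
#'
#' Sums, for every vertex, the spring forces of all incident walls and the
#' turgor-pressure contributions of every cell the vertex bounds. Interior
#' walls receive opposing pressure from their two flanking cells.
#'
#' @param tissue an `lr_tissue`.
#' @param params a [mechanics_params()] object.
#' @param zero_fixed zero the x-component of the force on `fixed_x`
#'   vertices (the boundary condition used by the integrator); default
#'   `TRUE`.
#' @return An n-vertex x 2 matrix of forces.
#' @export
total_forces <- function(tissue, params, zero_fixed = TRUE) {
  nv <- nrow(tissue$pos)
  d <- tissue$pos[tissue$wall_to, , drop = FALSE] -
    tissue$pos[tissue$wall_from, , drop = FALSE]
  len <- sqrt(rowSums(d * d))
  if (any(len < 1e-12))
    stop("degenerate geometry: coincident spring endpoints")
  mag <- tissue$wall_stiff * (tissue$wall_rest - len) / len
  f_from <- -mag * d           # on `from`: mag * (p_from - p_to)/len * len
  idx <- c(tissue$wall_from, tissue$wall_to)
  contrib <- rbind(f_from, -f_from)
  f <- rowsum(contrib, group = factor(idx, levels = seq_len(nv)))
  f <- unname(as.matrix(f))

  if (!is.null(tissue$cell_verts) && nrow(tissue$cell_verts) > 0) {
    v <- tissue$cell_verts
    nxt <- c(2L, 3L, 4L, 1L)
    px <- matrix(tissue$pos[v, 1], nrow(v), 4)
    py <- matrix(tissue$pos[v, 2], nrow(v), 4)
    ex <- px[, nxt, drop = FALSE] - px
    ey <- py[, nxt, drop = FALSE] - py
    area <- 0.5 * rowSums(px * py[, nxt] - px[, nxt] * py)
    if (any(area <= 1e-12))
      stop("degenerate geometry: non-positive cell area")
    fx <- params$p_const * ey
    fy <- -params$p_const * ex
    prv <- c(4L, 1L, 2L, 3L)
    gx <- 0.5 * (fx + fx[, prv, drop = FALSE])
    gy <- 0.5 * (fy + fy[, prv, drop = FALSE])
    pf <- rowsum(cbind(as.vector(gx), as.vector(gy)),
                 group = factor(as.vector(v), levels = seq_len(nv)))
    f <- f + unname(as.matrix(pf))
  }
  if (zero_fixed) f[tissue$fixed_x, 1] <- 0
  colnames(f) <- c("x", "y")
  f
}

#' One step of the damped Newtonian integrator
#'
#' Forward-Euler update of `dVel/dt = F/m - beta * Vel`, `dp/dt = Vel`. In
#' the default semi-implicit ordering the velocity is updated first and the
#' position advanced with the new velocity. Vertices with `fixed_x` keep
#' their x-coordinate: the x-components of their force and velocity are
#' zeroed.
#'
#' @param tissue an `lr_tissue`.
#' @param params a [mechanics_params()] object.
#' @param forces force matrix for the current state; computed via
#'   [total_forces()] when missing.
#' @return The advanced tissue.
#' @export
integrate_step <- function(tissue, params,
                           forces = total_forces(tissue, params)) {
  dt <- params$dt_mech
  forces[tissue$fixed_x, 1] <- 0
  vel_new <- tissue$vel + dt * (forces / params$mass -
                                  params$beta * tissue$vel)
  vel_new[tissue$fixed_x, 1] <- 0
  step_vel <- if (params$euler == "semi") vel_new else tissue$vel
  tissue$pos <- tissue$pos + dt * step_vel
  tissue$vel <- vel_new
  if (!all(is.finite(tissue$pos)))
    stop("numerical blow-up: non-finite vertex positions after step")
  tissue
}

#' Relax the mesh to transient equilibrium
#'
#' Repeats force evaluation and integration until both the maximum
#' |force|/mass and the maximum |velocity| over vertices fall below
#' `equilibrium_tol`. Growth steps are only applied to relaxed meshes, so
#' this is the workhorse between growth increments. The compiled engine
#' (`"cpp"`) runs the identical update loop in C++; the reference `"r"`
#' engine is retained for small meshes and cross-checks.
#'
#' @param tissue an `lr_tissue`.
#' @param params a [mechanics_params()] object.
#' @param engine `"cpp"` (default) or `"r"`.
#' @return A list with elements `tissue` (relaxed), `iterations`,
#'   `residual_force` and `residual_velocity`.
#' @export
relax_to_equilibrium <- function(tissue, params,
                                 engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (engine == "cpp") {
    cv <- tissue$cell_verts
    if (is.null(cv)) cv <- matrix(integer(0), 0, 4)
    res <- relax_cpp(tissue$pos, tissue$vel,
                     tissue$wall_from, tissue$wall_to,
                     tissue$wall_rest, tissue$wall_stiff,
                     cv, tissue$fixed_x,
                     params$p_const, params$beta, params$mass,
                     params$dt_mech, params$equilibrium_tol,
                     params$max_relax_iters,
                     params$euler == "semi")
    if (!res$converged)
      stop(sprintf(
        "relaxation did not converge in %d iterations (force residual %g, velocity residual %g)",
        params$max_relax_iters, res$residual_force, res$residual_velocity))
    dimnames(res$pos) <- dimnames(tissue$pos)
    dimnames(res$vel) <- dimnames(tissue$vel)
    tissue$pos <- res$pos
    tissue$vel <- res$vel
    return(list(tissue = tissue, iterations = res$iterations,
                residual_force = res$residual_force,
                residual_velocity = res$residual_velocity))
  }
  iters <- 0L
  repeat {
    f <- total_forces(tissue, params)
    rf <- max(sqrt(rowSums(f * f))) / params$mass
    rv <- max(sqrt(rowSums(tissue$vel * tissue$vel)))
    if (rf < params$equilibrium_tol && rv < params$equilibrium_tol)
      return(list(tissue = tissue, iterations = iters,
                  residual_force = rf, residual_velocity = rv))
    if (iters >= params$max_relax_iters)
      stop(sprintf(
        "relaxation did not converge in %d iterations (force residual %g, velocity residual %g)",
        iters, rf, rv))
    tissue <- integrate_step(tissue, params, forces = f)
    iters <- iters + 1L
  }
}

# total mechanical energy: spring elastic + kinetic - pressure work
# (pressure potential = -p_const * total cell area); used by the
# dissipation checks
mech_energy <- function(tissue, params) {
  len <- wall_lengths(tissue)
  elastic <- 0.5 * sum(tissue$wall_stiff * (tissue$wall_rest - len)^2)
  kinetic <- 0.5 * params$mass * sum(tissue$vel^2)
  pressure <- -params$p_const * sum(cell_areas(tissue))
  elastic + kinetic + pressure
}
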
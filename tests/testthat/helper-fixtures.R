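# shared fixtures and independent oracles for the test suite

# cache for full-length scenario runs so the acceptance blocks and the
# property blocks reuse one simulation per scenario
.run_cache <- new.env(parent = emptyenv())

cached_run <- function(scenario) {
  if (!exists(scenario, envir = .run_cache)) {
    sim <- run_scenario(scenario_config(scenario))
    assign(scenario, sim, envir = .run_cache)
  }
  get(scenario, envir = .run_cache)
}

# minimal hand-built tissue: arbitrary vertices/walls, optional cells;
# exercises the mechanics layer outside the rectangular-grid constructor
make_raw_tissue <- function(pos, from = integer(0), to = integer(0),
                            rest = numeric(0), stiff = 0.9,
                            fixed_x = rep(FALSE, nrow(pos)),
                            cell_verts = NULL) {
  nw <- length(from)
  structure(list(
    pos = pos, vel = matrix(0, nrow(pos), 2),
    fixed_x = fixed_x, v_row = rep(0L, nrow(pos)),
    v_col = seq_len(nrow(pos)) - 1L,
    wall_from = as.integer(from), wall_to = as.integer(to),
    wall_rest = rest, wall_orient = rep("axial", nw),
    wall_row = rep(0L, nw), wall_col = seq_len(nw) - 1L,
    wall_stiff = rep_len(stiff, nw),
    cell_row = integer(0), cell_col = integer(0),
    cell_walls = matrix(integer(0), 0, 4),
    cell_verts = if (is.null(cell_verts)) matrix(integer(0), 0, 4)
      else cell_verts,
    n_cols = max(2L, nrow(pos) - 1L), n_rows = 1L,
    cell_width = 1, cell_height = 1,
    gravity = c(0, -1), sim_time = 0
  ), class = "lr_tissue")
}

# independent brute-force force summation, written directly from the model
# formulas (per-wall spring term, per-cell per-edge pressure term); kept
# deliberately naive and separate from total_forces()
brute_force_forces <- function(tissue, p_const) {
  nv <- nrow(tissue$pos)
  f <- matrix(0, nv, 2)
  for (w in seq_along(tissue$wall_from)) {
    u <- tissue$wall_from[w]; v <- tissue$wall_to[w]
    d <- tissue$pos[u, ] - tissue$pos[v, ]
    len <- sqrt(sum(d^2))
    fu <- tissue$wall_stiff[w] * (tissue$wall_rest[w] - len) * d / len
    f[u, ] <- f[u, ] + fu
    f[v, ] <- f[v, ] - fu
  }
  if (nrow(tissue$cell_verts) > 0) {
    for (ci in seq_len(nrow(tissue$cell_verts))) {
      vids <- tissue$cell_verts[ci, ]
      for (e in 1:4) {
        a <- vids[e]; b <- vids[if (e == 4) 1 else e + 1]
        ev <- tissue$pos[b, ] - tissue$pos[a, ]
        len <- sqrt(sum(ev^2))
        nrm <- c(ev[2], -ev[1]) / len        # outward for CCW order
        fwall <- p_const * len * nrm
        f[a, ] <- f[a, ] + fwall / 2
        f[b, ] <- f[b, ] + fwall / 2
      }
    }
  }
  f
}

# O(n^2) brute-force two-sample KS statistic: sup of |ECDF difference|
# evaluated by explicit counting at every pooled observation
brute_force_ks_D <- function(a, b) {
  best <- 0
  for (x in c(a, b)) {
    fa <- sum(a <= x) / length(a)
    fb <- sum(b <= x) / length(b)
    best <- max(best, abs(fa - fb))
  }
  best
}

# closed-form moments of the normal truncated to [lo, hi]
trunc_normal_mean <- function(mu, sigma, lo = 0, hi = 180) {
  a <- (lo - mu) / sigma; b <- (hi - mu) / sigma
  Z <- pnorm(b) - pnorm(a)
  mu + sigma * (dnorm(a) - dnorm(b)) / Z
}

trunc_normal_interval_mass <- function(mu, sigma, from, to, lo = 0,
                                       hi = 180) {
  Z <- pnorm(hi, mu, sigma) - pnorm(lo, mu, sigma)
  (pnorm(to, mu, sigma) - pnorm(from, mu, sigma)) / Z
}
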
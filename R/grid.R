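#' Solver configuration
#'
#' Parameters of the finite-difference zero-salt Poisson solver. The
#' defaults are the standard production set for two-dielectric protein
#' electrostatics: 2 grid points per Angstrom, the solute filling 70%
#' of the box edge (perfil), dielectric 2 inside the solute and 80 in
#' water, zero salt, and the dipole boundary condition (boundary
#' potentials from the system's monopole + dipole moment screened by
#' the solvent dielectric).
#'
#' @param scale grid points per Angstrom.
#' @param perfil percentage of the box edge filled by the solute extent.
#' @param eps_in,eps_out relative dielectric inside / outside the solute.
#' @param boundary `"dipole"`, `"coulombic"` or `"zero"`.
#' @param tolerance convergence threshold: maximum potential change per
#'   sweep, kT/e.
#' @param max_iterations sweep limit.
#' @param omega successive over-relaxation factor.
#' @export
solver_config <- function(scale = 2, perfil = 70, eps_in = 2, eps_out = 80,
                          boundary = c("dipole", "coulombic", "zero"),
                          tolerance = 1e-4, max_iterations = 5000,
                          omega = 1.9) {
  boundary <- match.arg(boundary)
  if (perfil <= 0 || perfil >= 100) stop("perfil must be in (0, 100)")
  if (eps_in <= 0 || eps_out <= 0) stop("dielectrics must be positive")
  structure(list(scale = scale, perfil = perfil, eps_in = eps_in,
                 eps_out = eps_out, boundary = boundary,
                 tolerance = tolerance, max_iterations = max_iterations,
                 omega = omega),
            class = "solver_config")
}

#' Grid geometry
#'
#' @param origin coordinates of node (1,1,1), Angstrom.
#' @param spacing node spacing, Angstrom (= 1/scale).
#' @param dims three odd integers.
#' @export
grid_spec <- function(origin, spacing, dims) {
  dims <- as.integer(dims)
  if (length(dims) == 1) dims <- rep(dims, 3)
  if (any(dims %% 2 == 0)) stop("grid dims must be odd")
  if (spacing <= 0) stop("spacing must be positive")
  structure(list(origin = as.numeric(origin), spacing = spacing, dims = dims),
            class = "grid_spec")
}

grid_axis <- function(grid, d) grid$origin[d] + (seq_len(grid$dims[d]) - 1) *
  grid$spacing

grid_center <- function(grid) grid$origin + (grid$dims - 1) / 2 * grid$spacing

#' Plan a cubic grid around one or more models
#'
#' The box is centred on the joint bounding-box centre of all models;
#' the edge is the maximum coordinate extent divided by perfil/100, and
#' the node count per axis is the nearest odd integer to
#' edge x scale + 1.
#'
#' @param models a [mol_model()] or list of them.
#' @param config a [solver_config()].
#' @return a [grid_spec()].
#' @export
plan_grid <- function(models, config = solver_config()) {
  if (inherits(models, "mol_model")) models <- list(models)
  if (!length(models)) stop("no models supplied")
  xyz <- do.call(rbind, lapply(models, coords))
  lo <- apply(xyz, 2, min)
  hi <- apply(xyz, 2, max)
  extent <- max(hi - lo)
  edge <- extent / (config$perfil / 100)
  n <- round(edge * config$scale) + 1
  if (n %% 2 == 0) n <- n + 1
  n <- max(n, 9)
  spacing <- 1 / config$scale
  center <- (lo + hi) / 2
  grid_spec(center - (n - 1) / 2 * spacing, spacing, rep(n, 3))
}

#' Rasterize a system onto a grid
#'
#' Builds the per-node dielectric map (eps_in within any cavity atom's
#' radius, eps_out elsewhere; the solute surface is the union of atom
#' spheres) and spreads each atom's charge onto its 8 surrounding nodes
#' by trilinear weights, which conserves total charge exactly.
#'
#' @param model `mol_model` providing the charges.
#' @param grid a [grid_spec()].
#' @param config a [solver_config()].
#' @param cavity model(s) defining the dielectric cavity (defaults to
#'   `model`); pass a [combine_models()] result to carve several bodies.
#' @param clip drop atoms outside the grid instead of erroring (used by
#'   computational focusing, where out-of-box charges act through the
#'   boundary values).
#' @export
rasterize <- function(model, grid, config = solver_config(), cavity = model,
                      clip = FALSE) {
  dims <- grid$dims
  eps <- array(config$eps_out, dim = dims)
  # carve the union-of-spheres cavity
  for (k in seq_len(nrow(cavity$atoms))) {
    at <- cavity$atoms[k, ]
    if (at$radius <= 0) next
    u <- (c(at$x, at$y, at$z) - grid$origin) / grid$spacing
    r <- at$radius / grid$spacing
    lo <- pmax(ceiling(u - r), 0)
    hi <- pmin(floor(u + r), dims - 1)
    if (any(lo > hi)) next
    ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
    dx2 <- (ix - u[1])^2; dy2 <- (iy - u[2])^2; dz2 <- (iz - u[3])^2
    inside <- outer(outer(dx2, dy2, "+"), dz2, "+") <= r^2
    sub <- eps[ix + 1, iy + 1, iz + 1]
    sub[inside] <- config$eps_in
    eps[ix + 1, iy + 1, iz + 1] <- sub
  }
  # trilinear charge spreading
  charge <- array(0, dim = dims)
  a <- model$atoms
  qidx <- which(a$charge != 0)
  dropped <- 0L
  for (k in qidx) {
    u <- (c(a$x[k], a$y[k], a$z[k]) - grid$origin) / grid$spacing
    i0 <- floor(u)
    if (any(i0 < 0) || any(i0 > dims - 2)) {
      if (clip) { dropped <- dropped + 1L; next }
      stop("atom ", a$serial[k], " lies outside the grid interior")
    }
    f <- u - i0
    for (oz in 0:1) for (oy in 0:1) for (ox in 0:1) {
      w <- (if (ox) f[1] else 1 - f[1]) * (if (oy) f[2] else 1 - f[2]) *
        (if (oz) f[3] else 1 - f[3])
      charge[i0[1] + ox + 1, i0[2] + oy + 1, i0[3] + oz + 1] <-
        charge[i0[1] + ox + 1, i0[2] + oy + 1, i0[3] + oz + 1] + w * a$charge[k]
    }
  }
  structure(list(grid = grid, dielectric = eps, charge = charge,
                 total_charge = sum(charge), dropped_atoms = dropped,
                 config = config),
            class = "rasterized_system")
}

boundary_mask <- function(dims) {
  m <- array(FALSE, dim = dims)
  m[c(1, dims[1]), , ] <- TRUE
  m[, c(1, dims[2]), ] <- TRUE
  m[, , c(1, dims[3])] <- TRUE
  m
}

#' Boundary potentials for a rasterized system
#'
#' `"dipole"`: the analytic potential of the system's total charge and
#' dipole moment placed at the charge centroid, screened by eps_out
#' (zero salt, so plain 1/r and dipole terms). `"coulombic"`: the full
#' sum over charged nodes. `"zero"`: grounded box.
#'
#' @param system a [rasterize()] result.
#' @param config solver configuration (eps_out and boundary mode used).
#' @return array of the grid shape with boundary faces filled (interior
#'   zero), class `boundary_values`.
#' @export
boundary_potential <- function(system, config = system$config) {
  grid <- system$grid
  dims <- grid$dims
  mask <- boundary_mask(dims)
  idx <- which(mask, arr.ind = TRUE)
  pts <- cbind(grid_axis(grid, 1)[idx[, 1]], grid_axis(grid, 2)[idx[, 2]],
               grid_axis(grid, 3)[idx[, 3]])
  vals <- array(0, dim = dims)
  qi <- which(system$charge != 0, arr.ind = TRUE)
  if (nrow(qi) && config$boundary != "zero") {
    q <- system$charge[cbind(qi[, 1], qi[, 2], qi[, 3])]
    xq <- cbind(grid_axis(grid, 1)[qi[, 1]], grid_axis(grid, 2)[qi[, 2]],
                grid_axis(grid, 3)[qi[, 3]])
    if (config$boundary == "dipole") {
      w <- abs(q) / sum(abs(q))
      x0 <- colSums(xq * w)
      qtot <- sum(q)
      p <- colSums(q * sweep(xq, 2, x0))
      dr <- sweep(pts, 2, x0)
      r <- sqrt(rowSums(dr^2))
      phi <- .kCoulomb / config$eps_out *
        (qtot / r + (dr %*% p) / r^3)
      vals[mask] <- phi
    } else {
      phi <- numeric(nrow(pts))
      for (k in seq_along(q)) {
        r <- sqrt(rowSums(sweep(pts, 2, xq[k, ])^2))
        phi <- phi + q[k] / r
      }
      vals[mask] <- .kCoulomb / config$eps_out * phi
    }
  }
  structure(vals, class = "boundary_values")
}

#' Solve the zero-salt Poisson equation on a grid
#'
#' Gauss-Seidel relaxation with successive over-relaxation and
#' checkerboard ordering of the discrete equation
#' `div(eps grad phi) = -4 pi C rho`, with harmonic-mean link
#' dielectrics and Dirichlet boundaries. Potential is in kT/e.
#'
#' @param system a [rasterize()] result.
#' @param boundary a [boundary_potential()] array (defaults to the
#'   system's configured boundary mode).
#' @param config a [solver_config()].
#' @return a `potential_map`: grid + 3D value array + iteration count
#'   and final residual.
#' @export
solve_poisson <- function(system, boundary = NULL,
                          config = system$config) {
  grid <- system$grid
  if (is.null(boundary)) boundary <- boundary_potential(system, config)
  dims <- grid$dims
  phi0 <- array(0, dim = dims)
  mask <- boundary_mask(dims)
  phi0[mask] <- unclass(boundary)[mask]
  res <- .sor_poisson(as.numeric(system$dielectric),
                      as.numeric(system$charge),
                      as.numeric(phi0),
                      dims[1], dims[2], dims[3], grid$spacing,
                      4 * pi * .kCoulomb, config$omega, config$tolerance,
                      config$max_iterations)
  if (!res$converged)
    stop(sprintf(
      "Poisson solver did not converge in %d sweeps (residual %.3g kT/e)",
      res$iterations, res$max_change))
  structure(list(grid = grid, values = array(res$phi, dim = dims),
                 iterations = res$iterations, max_change = res$max_change),
            class = "potential_map")
}

#' @export
print.potential_map <- function(x, ...) {
  cat(sprintf(
    "<potential_map> %dx%dx%d nodes, spacing %.3g A, %s sweeps, residual %.2g kT/e\n",
    x$grid$dims[1], x$grid$dims[2], x$grid$dims[3], x$grid$spacing,
    format(x$iterations), x$max_change))
  invisible(x)
}

#' Interpolate a potential map at points
#'
#' @param pmap a `potential_map`.
#' @param points n x 3 matrix of coordinates, Angstrom.
#' @return potential values, kT/e.
#' @export
interpolate_potential <- function(pmap, points) {
  trilinear(pmap$values, pmap$grid$origin, pmap$grid$spacing, points)
}

grid_contains <- function(outer, inner, strict = TRUE) {
  lo_o <- outer$origin
  hi_o <- outer$origin + (outer$dims - 1) * outer$spacing
  lo_i <- inner$origin
  hi_i <- inner$origin + (inner$dims - 1) * inner$spacing
  pad <- if (strict) outer$spacing * 1e-9 else -1e-9
  all(lo_i >= lo_o + pad) && all(hi_i <= hi_o - pad)
}

#' Computational focusing: solve a fine grid inside a coarse solution
#'
#' Boundary values of the fine grid are trilinearly interpolated from
#' the coarse solution, so the fine solve feels the whole system while
#' only resolving the subregion.
#'
#' @param system_fine a [rasterize()] result on the fine grid.
#' @param coarse_solution `potential_map` whose grid contains the fine
#'   grid.
#' @param config a [solver_config()].
#' @export
focus_solve <- function(system_fine, coarse_solution,
                        config = system_fine$config) {
  gf <- system_fine$grid
  if (!grid_contains(coarse_solution$grid, gf, strict = FALSE))
    stop("fine grid is not contained in the coarse grid")
  dims <- gf$dims
  mask <- boundary_mask(dims)
  idx <- which(mask, arr.ind = TRUE)
  pts <- cbind(grid_axis(gf, 1)[idx[, 1]], grid_axis(gf, 2)[idx[, 2]],
               grid_axis(gf, 3)[idx[, 3]])
  bvals <- array(0, dim = dims)
  bvals[mask] <- interpolate_potential(coarse_solution, pts)
  solve_poisson(system_fine, structure(bvals, class = "boundary_values"),
                config)
}
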
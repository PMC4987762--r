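#' Rigid-body pose lattice
#'
#' Cylindrical (or planar) enumeration window for probe poses around a
#' filament: a longitudinal window, an angular (or lateral) window, a
#' normal approach range, and a small set of orientation rotamers.
#' Counting is half-open on every axis (the closing endpoint is
#' excluded), so a +/-20 A window at 0.5 A steps gives exactly 80
#' positions; the production default window
#' (+/-20 A, +/-12 deg, 20 A normal, 0.5 steps, 9 rotamers) enumerates
#' 80 x 48 x 40 x 9 = 1,382,400 poses.
#'
#' @param long_half_window,long_step longitudinal window half-width and
#'   step, Angstrom.
#' @param ang_half_window,ang_step angular window half-width and step,
#'   degrees (planar frames reinterpret these as lateral Angstrom).
#' @param normal_range,normal_step normal approach range and step,
#'   Angstrom (0 = contact reference).
#' @param n_rotamers 1 (identity) or 9 (identity + 8 tilts).
#' @param rotamer_tilt tilt magnitude of the non-identity rotamers,
#'   degrees.
#' @export
pose_grid <- function(long_half_window = 20, long_step = 0.5,
                      ang_half_window = 12, ang_step = 0.5,
                      normal_range = 20, normal_step = 0.5,
                      n_rotamers = 9, rotamer_tilt = 5) {
  if (long_step <= 0 || ang_step <= 0 || normal_step <= 0)
    stop("steps must be positive")
  n_long <- round(2 * long_half_window / long_step)
  n_ang <- round(2 * ang_half_window / ang_step)
  n_norm <- round(normal_range / normal_step)
  if (n_long < 1 || n_ang < 1 || n_norm < 1) stop("zero-size pose axis")
  structure(list(long_half_window = long_half_window, long_step = long_step,
                 ang_half_window = ang_half_window, ang_step = ang_step,
                 normal_range = normal_range, normal_step = normal_step,
                 n_rotamers = as.integer(n_rotamers),
                 rotamer_tilt = rotamer_tilt,
                 n_long = n_long, n_ang = n_ang, n_norm = n_norm),
            class = "pose_grid")
}

pose_axis_long <- function(g) -g$long_half_window + (seq_len(g$n_long) - 1) *
  g$long_step
pose_axis_ang <- function(g) -g$ang_half_window + (seq_len(g$n_ang) - 1) *
  g$ang_step
pose_axis_norm <- function(g) (seq_len(g$n_norm) - 1) * g$normal_step

#' Orientation rotamers
#'
#' The identity plus eight small tilts: all combinations of
#' +/-`tilt_magnitude` about the two probe axes orthogonal to the
#' binding-face normal (and their four diagonal combinations). The
#' binding face stays oriented toward the filament: the face normal
#' never deviates by more than twice the tilt magnitude.
#'
#' @param n 9 (default) or 1 (identity only).
#' @param tilt_magnitude degrees.
#' @return list of [rigid_transform()]s, identity first.
#' @export
rotamer_set <- function(n = 9, tilt_magnitude = 5) {
  if (n == 1) return(list(rigid_transform()))
  if (n != 9) stop("unsupported rotamer count: ", n, " (use 1 or 9)")
  out <- list(rigid_transform())
  for (a in c(-tilt_magnitude, 0, tilt_magnitude))
    for (b in c(-tilt_magnitude, 0, tilt_magnitude)) {
      if (a == 0 && b == 0) next
      out[[length(out) + 1L]] <- rigid_transform(rot_x(a) %*% rot_y(b))
    }
  out
}

#' Pose frames: how lattice indices become rigid transforms
#'
#' A planar frame samples a flat binding surface: longitudinal = x,
#' the "angular" axis reinterpreted as lateral y displacement in
#' Angstrom, normal = +z above the surface; `origin` is the probe
#' centre position at window centre and normal 0 (contact).
#' A cylindrical frame samples around a filament on the +z axis:
#' poses rotate about z by the angular offset, translate along z
#' longitudinally, and move radially outward with the normal; the probe
#' binding face (its -z face in the reference orientation) is rotated
#' to point radially inward.
#'
#' @param origin probe centre at the window centre / contact pose.
#' @export
planar_frame <- function(origin) {
  structure(list(type = "planar", origin = as.numeric(origin)),
            class = "pose_frame")
}

#' @rdname planar_frame
#' @param contact_radius axis-to-probe-centre distance at contact,
#'   Angstrom.
#' @param z_ref,theta_ref longitudinal and azimuthal window centre
#'   (Angstrom, degrees).
#' @export
cylindrical_frame <- function(contact_radius, z_ref = 0, theta_ref = 0) {
  structure(list(type = "cylindrical", contact_radius = contact_radius,
                 z_ref = z_ref, theta_ref = theta_ref),
            class = "pose_frame")
}

# Place the probe centre for cell (u = longitudinal, v = angular/lateral,
# w = normal); returns list(rotation, translation) *before* the rotamer.
frame_placement <- function(frame, u, v, w) {
  if (frame$type == "planar") {
    list(rotation = diag(3),
         translation = frame$origin + c(u, v, w))
  } else {
    theta <- frame$theta_ref + v
    R <- rot_z(theta) %*% rot_y(90)
    r <- frame$contact_radius + w
    list(rotation = R,
         translation = c(r * cos(theta * pi / 180),
                         r * sin(theta * pi / 180),
                         frame$z_ref + u))
  }
}

pose_transform <- function(grid, frame, i_long, i_ang, i_norm, i_rot,
                           rotamers = rotamer_set(grid$n_rotamers,
                                                  grid$rotamer_tilt)) {
  u <- pose_axis_long(grid)[i_long]
  v <- pose_axis_ang(grid)[i_ang]
  w <- pose_axis_norm(grid)[i_norm]
  pl <- frame_placement(frame, u, v, w)
  rigid_transform(pl$rotation %*% rotamers[[i_rot]]$rotation, pl$translation)
}

#' Enumerate the pose lattice
#'
#' @param grid a [pose_grid()].
#' @param frame a [planar_frame()] or [cylindrical_frame()] (optional;
#'   needed only to realize transforms).
#' @return list with `count`, the per-axis counts, and `pose(k)`, a
#'   deterministic long-major realizer mapping linear index `k`
#'   (1-based) to indices + transform (rotamer fastest, then normal,
#'   then angular, then longitudinal).
#' @export
enumerate_poses <- function(grid, frame = NULL) {
  rotamers <- rotamer_set(grid$n_rotamers, grid$rotamer_tilt)
  count <- grid$n_long * grid$n_ang * grid$n_norm * grid$n_rotamers
  realize <- function(k) {
    stopifnot(k >= 1, k <= count)
    k0 <- k - 1
    i_rot <- k0 %% grid$n_rotamers
    k0 <- k0 %/% grid$n_rotamers
    i_norm <- k0 %% grid$n_norm
    k0 <- k0 %/% grid$n_norm
    i_ang <- k0 %% grid$n_ang
    i_long <- k0 %/% grid$n_ang
    idx <- c(i_long = i_long + 1L, i_ang = i_ang + 1L, i_norm = i_norm + 1L,
             i_rot = i_rot + 1L)
    pose <- list(indices = idx)
    if (!is.null(frame))
      pose$transform <- pose_transform(grid, frame, idx[1], idx[2], idx[3],
                                       idx[4], rotamers)
    pose
  }
  list(count = count, n_long = grid$n_long, n_ang = grid$n_ang,
       n_norm = grid$n_norm, n_rotamers = grid$n_rotamers, pose = realize)
}

# Fine focusing box for one (longitudinal, angular) cell: a cube centred
# on the probe centre at mid normal range, wide enough for the probe at
# any normal offset and tilt. Deterministic in (grid, frame, probe
# extent), so re-scoring a reconstructed pose reuses the identical box.
fine_box_for_cell <- function(grid, frame, i_long, i_ang, probe_extent,
                              config, margin = 6) {
  u <- pose_axis_long(grid)[i_long]
  v <- pose_axis_ang(grid)[i_ang]
  mid <- grid$normal_range / 2
  pl <- frame_placement(frame, u, v, mid)
  edge <- 2 * probe_extent + grid$normal_range + 2 * margin
  n <- round(edge * config$scale) + 1
  if (n %% 2 == 0) n <- n + 1
  spacing <- 1 / config$scale
  grid_spec(pl$translation - (n - 1) / 2 * spacing, spacing, rep(n, 3))
}

probe_extent <- function(probe) {
  xyz <- coords(probe)
  ctr <- colMeans(xyz)
  max(sqrt(rowSums(sweep(xyz, 2, ctr)^2)) + probe$atoms$radius)
}

#' Default van der Waals scoring parameters
#'
#' A 6-12 Lennard-Jones with `r_min` the sum of the pair radii, one
#' uniform well depth, and a hard clash rejection when any pair
#' distance drops below `overlap_factor * r_min`. Rigid-body scoring
#' needs only short-range repulsion plus mild attraction, so the well
#' depth is a single number (0.1 kcal/mol).
#'
#' @param well_depth_kcal well depth, kcal/mol.
#' @param overlap_factor clash threshold as a fraction of `r_min`.
#' @param cutoff pair cutoff, Angstrom.
#' @export
vdw_params <- function(well_depth_kcal = 0.1, overlap_factor = 0.5,
                       cutoff = 12) {
  list(well_depth_kT = well_depth_kcal / .kT_kcal_mol,
       overlap_factor = overlap_factor, cutoff = cutoff)
}

# Shared scoring cache: the coarse filament solution plus memoized
# per-cell fine solutions and filament coordinate/parameter vectors.
make_score_cache <- function(probe, filament, grid, frame, config) {
  ext <- probe_extent(probe)
  corners <- do.call(rbind, lapply(list(
    c(1L, 1L), c(grid$n_long, 1L), c(1L, grid$n_ang),
    c(grid$n_long, grid$n_ang)), function(ij) {
      w <- c(0, grid$normal_range)
      t(vapply(w, function(wk)
        frame_placement(frame, pose_axis_long(grid)[ij[1]],
                        pose_axis_ang(grid)[ij[2]], wk)$translation,
        numeric(3)))
    }))
  pad <- ext + 3
  bounds <- mol_model(data.frame(
    serial = seq_len(2 * nrow(corners)), name = "X", resname = "BND",
    resid = 1, chain = "X",
    x = c(corners[, 1] - pad, corners[, 1] + pad),
    y = c(corners[, 2] - pad, corners[, 2] + pad),
    z = c(corners[, 3] - pad, corners[, 3] + pad)))
  coarse_cfg <- config
  coarse_cfg$scale <- min(config$scale, 0.5)  # coarse stage resolves shape only
  coarse_grid <- plan_grid(list(filament, bounds), coarse_cfg)
  coarse_sys <- rasterize(filament, coarse_grid, coarse_cfg)
  coarse <- solve_poisson(coarse_sys, config = coarse_cfg)
  list(probe_ext = ext, coarse = coarse, fine = new.env(parent = emptyenv()),
       fil_xyz = coords(filament), fil_q = filament$atoms$charge,
       fil_r = filament$atoms$radius)
}

cell_fine_solution <- function(cache, filament, grid, frame, i_long, i_ang,
                               config) {
  key <- paste(i_long, i_ang)
  if (!is.null(cache$fine[[key]])) return(cache$fine[[key]])
  fgrid <- fine_box_for_cell(grid, frame, i_long, i_ang, cache$probe_ext,
                             config)
  if (!grid_contains(cache$coarse$grid, fgrid, strict = FALSE))
    stop("pose fine box extends outside the coarse grid")
  fsys <- rasterize(filament, fgrid, config, clip = TRUE)
  sol <- focus_solve(fsys, cache$coarse, config)
  cache$fine[[key]] <- sol
  sol
}

#' Score one rigid-body pose
#'
#' Electrostatics (default `method = "interaction"`): the filament's
#' potential is solved once on a coarse grid and focused into a fine
#' box around the pose cell; the pose energy is
#' `sum_i q_i phi_filament(x_i)` over the probe atoms. This is the
#' interaction component that shapes the rigid-body funnel; the full
#' three-state decomposition (with per-pose desolvation) is available
#' as `method = "full"`, which calls [binding_energy()] for the pose.
#' Van der Waals: 6-12 Lennard-Jones, see [vdw_params()]. Any pair
#' closer than the overlap threshold flags a clash and the total is
#' +Inf.
#'
#' @param probe,filament `mol_model`s; the probe in its reference
#'   orientation (binding face toward -z, centred at the origin).
#' @param pose pose indices `c(i_long, i_ang, i_norm, i_rot)` (1-based).
#' @param grid a [pose_grid()].
#' @param frame a [planar_frame()] or [cylindrical_frame()].
#' @param config a [solver_config()].
#' @param vdw [vdw_params()].
#' @param cache optional shared cache from a [build_energy_map()] run.
#' @param method `"interaction"` or `"full"`.
#' @return list of class `pose_energy`: `electrostatic`, `vdw`, `total`
#'   (kT), `clash`.
#' @export
score_pose <- function(probe, filament, pose, grid, frame,
                       config = solver_config(), vdw = vdw_params(),
                       cache = NULL, method = c("interaction", "full")) {
  method <- match.arg(method)
  idx <- if (is.list(pose)) pose$indices else pose
  tf <- pose_transform(grid, frame, idx[1], idx[2], idx[3], idx[4])
  probe_t <- apply_transform(probe, tf)
  xyz <- coords(probe_t)
  lj <- .lj_score(xyz, probe_t$atoms$radius, coords(filament),
                  filament$atoms$radius, vdw$well_depth_kT,
                  vdw$overlap_factor, vdw$cutoff)
  if (lj$clash)
    return(structure(list(electrostatic = NA_real_, vdw = Inf, total = Inf,
                          clash = TRUE), class = "pose_energy"))
  elec <- if (method == "full") {
    binding_energy(probe_t, filament, config)$delta_G
  } else {
    if (is.null(cache))
      cache <- make_score_cache(probe, filament, grid, frame, config)
    sol <- cell_fine_solution(cache, filament, grid, frame, idx[1], idx[2],
                              config)
    sum(probe_t$atoms$charge * interpolate_potential(sol, xyz))
  }
  structure(list(electrostatic = elec, vdw = lj$energy,
                 total = elec + lj$energy, clash = FALSE),
            class = "pose_energy")
}

#' Build the 2D minimum-energy funnel map
#'
#' Scores every pose of the lattice and reduces the 4D energy array to
#' a (longitudinal x angular) map holding, per cell, the minimum total
#' energy over the normal x rotamer axes -- the most favourable
#' approach at that surface position. Ties break toward the smaller
#' normal distance, then the lower rotamer index.
#'
#' @inheritParams score_pose
#' @return `energy_map2d`: axes, value matrix, per-cell best
#'   normal/rotamer indices, and the argmin cell.
#' @export
build_energy_map <- function(probe, filament, grid, frame,
                             config = solver_config(), vdw = vdw_params()) {
  cache <- make_score_cache(probe, filament, grid, frame, config)
  rotamers <- rotamer_set(grid$n_rotamers, grid$rotamer_tilt)
  pxyz <- coords(probe)
  pq <- probe$atoms$charge
  pr <- probe$atoms$radius
  rot_xyz <- lapply(rotamers, function(r) pxyz %*% t(r$rotation))
  vals <- matrix(Inf, grid$n_long, grid$n_ang)
  best_norm <- matrix(NA_integer_, grid$n_long, grid$n_ang)
  best_rot <- matrix(NA_integer_, grid$n_long, grid$n_ang)
  norms <- pose_axis_norm(grid)
  for (il in seq_len(grid$n_long)) {
    for (ia in seq_len(grid$n_ang)) {
      sol <- cell_fine_solution(cache, filament, grid, frame, il, ia, config)
      for (iw in seq_len(grid$n_norm)) {
        pl <- frame_placement(frame, pose_axis_long(grid)[il],
                              pose_axis_ang(grid)[ia], norms[iw])
        for (ir in seq_len(grid$n_rotamers)) {
          xyz <- sweep(rot_xyz[[ir]] %*% t(pl$rotation), 2, pl$translation,
                       "+")
          lj <- .lj_score(xyz, pr, cache$fil_xyz, cache$fil_r,
                          vdw$well_depth_kT, vdw$overlap_factor, vdw$cutoff)
          if (lj$clash) next
          tot <- lj$energy +
            sum(pq * interpolate_potential(sol, xyz))
          if (tot < vals[il, ia]) {
            vals[il, ia] <- tot
            best_norm[il, ia] <- iw
            best_rot[il, ia] <- ir
          }
        }
      }
    }
  }
  am <- which(vals == min(vals), arr.ind = TRUE)[1, ]
  structure(list(long = pose_axis_long(grid), ang = pose_axis_ang(grid),
                 values = vals, best_norm = best_norm, best_rot = best_rot,
                 argmin = c(long = pose_axis_long(grid)[am[1]],
                            ang = pose_axis_ang(grid)[am[2]]),
                 argmin_index = am, grid = grid, frame = frame),
            class = "energy_map2d")
}

#' @export
print.energy_map2d <- function(x, ...) {
  cat(sprintf(
    "<energy_map2d> %d x %d cells; min %.3f kT at (long %.1f, ang %.1f)\n",
    nrow(x$values), ncol(x$values), min(x$values), x$argmin[1], x$argmin[2]))
  invisible(x)
}

#' @export
plot.energy_map2d <- function(x, ...) {
  graphics::image(x$long, x$ang, x$values, xlab = "longitudinal (A)",
                  ylab = "angular / lateral", main = "binding energy (kT)",
                  ...)
  graphics::points(x$argmin[1], x$argmin[2], pch = 4)
  invisible(x)
}

#' Write an energy map as TSV (longitudinal, angular, energy kT)
#' @param map an `energy_map2d`.
#' @param path output file.
#' @export
write_energy_map <- function(map, path) {
  df <- expand.grid(longitudinal = map$long, angular = map$ang)
  df$energy_kT <- as.numeric(map$values)
  write.table(format(df, digits = 10), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
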
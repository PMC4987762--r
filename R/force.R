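#' Electric field of a source at probe atom positions
#'
#' The probe is charge-silenced: the grid is solved with the source's
#' charges only, while (by default) the probe's atoms still carve their
#' dielectric cavity. The field E = -grad(phi) is taken by central
#' differences on the solved grid and trilinearly interpolated to the
#' probe atom positions.
#'
#' @param source charged `mol_model` generating the field.
#' @param probe `mol_model` whose atom positions sample the field (its
#'   charges are ignored here).
#' @param config a [solver_config()].
#' @param grid optional shared [grid_spec()]; defaults to a grid planned
#'   over source and probe together.
#' @param include_probe_cavity keep the probe's dielectric cavity in the
#'   map (TRUE, the charge-silencing reading of the protocol) or treat
#'   the probe region as solvent (FALSE).
#' @return n x 3 matrix of field vectors, kT/(e Angstrom).
#' @export
field_at_atoms <- function(source, probe, config = solver_config(),
                           grid = NULL, include_probe_cavity = TRUE) {
  if (is.null(grid)) grid <- plan_grid(list(source, probe), config)
  cavity <- if (include_probe_cavity) combine_models(source, probe)
  else source
  sys <- rasterize(source, grid, config, cavity = cavity)
  pmap <- solve_poisson(sys, config = config)
  h <- grid$spacing
  d <- grid$dims
  v <- pmap$values
  grad_axis <- function(axis) {
    g <- array(0, dim = d)
    if (axis == 1) g[2:(d[1] - 1), , ] <-
        (v[3:d[1], , ] - v[1:(d[1] - 2), , ]) / (2 * h)
    if (axis == 2) g[, 2:(d[2] - 1), ] <-
        (v[, 3:d[2], ] - v[, 1:(d[2] - 2), ]) / (2 * h)
    if (axis == 3) g[, , 2:(d[3] - 1)] <-
        (v[, , 3:d[3]] - v[, , 1:(d[3] - 2)]) / (2 * h)
    g
  }
  pts <- coords(probe)
  qsrc <- source$atoms[source$atoms$charge != 0, , drop = FALSE]
  if (nrow(qsrc)) {
    dmin <- apply(pts, 1, function(p)
      min(sqrt((qsrc$x - p[1])^2 + (qsrc$y - p[2])^2 + (qsrc$z - p[3])^2)))
    if (any(dmin < 2 * h))
      warning("probe atom within 2 grid spacings of a source charge; ",
              "gradient unreliable there")
  }
  E <- cbind(-trilinear(grad_axis(1), grid$origin, h, pts),
             -trilinear(grad_axis(2), grid$origin, h, pts),
             -trilinear(grad_axis(3), grid$origin, h, pts))
  colnames(E) <- c("Ex", "Ey", "Ez")
  E
}

#' Net electrostatic force on a probe from labelled sources
#'
#' F_i = q_i E(x_i) on each probe atom, summed; 1 kT/A = 41.14 pN at
#' 298 K. With a partition of the source atoms each subset is charged
#' alone (the equation is linear, so the per-source fields superpose)
#' and the total is the exact sum of the per-source forces.
#'
#' @param source charged `mol_model`.
#' @param probe charged `mol_model` (charges used as multipliers only).
#' @param config a [solver_config()].
#' @param partition named list of atom selections of `source` (logical
#'   or integer indices, or predicate functions); must jointly cover
#'   every charged source atom. Default: one source labelled `"all"`.
#' @param grid optional shared grid.
#' @param include_probe_cavity see [field_at_atoms()].
#' @return `force_decomposition`: `total` (pN 3-vector) and
#'   `per_source` (named list of pN 3-vectors).
#' @export
net_force <- function(source, probe, config = solver_config(),
                      partition = NULL, grid = NULL,
                      include_probe_cavity = TRUE) {
  if (is.null(grid)) grid <- plan_grid(list(source, probe), config)
  if (is.null(partition)) partition <- list(all = seq_len(n_atoms(source)))
  idx_of <- function(sel) {
    if (is.function(sel)) which(sel(source$atoms))
    else if (is.logical(sel)) which(sel)
    else as.integer(sel)
  }
  sets <- lapply(partition, idx_of)
  covered <- sort(unique(unlist(sets)))
  charged <- which(source$atoms$charge != 0)
  if (!all(charged %in% covered))
    stop("partition does not cover all charged source atoms")
  per <- lapply(sets, function(idx) {
    sub <- source
    sub$atoms$charge[-idx] <- 0
    E <- field_at_atoms(sub, probe, config, grid, include_probe_cavity)
    .pN_per_kT_A * colSums(probe$atoms$charge * E)
  })
  total <- Reduce(`+`, per)
  structure(list(total = total, per_source = per), class = "force_decomposition")
}

#' @export
print.force_decomposition <- function(x, ...) {
  cat(sprintf("total force: (%.3f, %.3f, %.3f) pN, |F| = %.3f pN\n",
              x$total[1], x$total[2], x$total[3], sqrt(sum(x$total^2))))
  for (nm in names(x$per_source)) {
    f <- x$per_source[[nm]]
    cat(sprintf("  %-10s (%.3f, %.3f, %.3f) pN\n", nm, f[1], f[2], f[3]))
  }
  invisible(x)
}

#' Force versus separation scan
#'
#' Translates the probe rigidly along `direction` by each distance
#' (0 = the bound reference pose) and evaluates [net_force()] at every
#' separation, on one grid planned to hold the whole scan.
#'
#' @inheritParams net_force
#' @param direction 3-vector along which the probe is displaced
#'   (normalised internally).
#' @param distances increasing separations in Angstrom.
#' @return `separation_scan`: distances, per-distance
#'   [net_force()] decompositions, the direction, and a tidy
#'   force-table data.frame.
#' @export
separation_scan <- function(source, probe, direction = c(0, 0, 1),
                            distances = seq(4, 20, by = 2),
                            config = solver_config(), partition = NULL,
                            include_probe_cavity = TRUE) {
  if (is.unsorted(distances, strictly = TRUE))
    stop("distances must be strictly increasing")
  direction <- direction / sqrt(sum(direction^2))
  far <- apply_transform(probe, rigid_transform(diag(3),
                                                max(distances) * direction))
  grid <- plan_grid(list(source, probe, far), config)
  forces <- lapply(distances, function(d) {
    probe_d <- apply_transform(probe, rigid_transform(diag(3), d * direction))
    net_force(source, probe_d, config, partition, grid, include_probe_cavity)
  })
  labels <- names(forces[[1]]$per_source)
  table <- do.call(rbind, lapply(seq_along(distances), function(i) {
    do.call(rbind, lapply(labels, function(nm) {
      f <- forces[[i]]$per_source[[nm]]
      data.frame(distance = distances[i], source = nm, Fx = f[1], Fy = f[2],
                 Fz = f[3], Fmag = sqrt(sum(f^2)))
    }))
  }))
  structure(list(distances = distances, forces = forces,
                 direction = direction, table = table),
            class = "separation_scan")
}

#' @export
print.separation_scan <- function(x, ...) {
  cat(sprintf("<separation_scan> %d distances (%g..%g A), sources: %s\n",
              length(x$distances), min(x$distances), max(x$distances),
              paste(unique(x$table$source), collapse = ", ")))
  print(x$table, row.names = FALSE)
  invisible(x)
}

trapezoid <- function(x, y) sum(diff(x) * (head(y, -1) + y[-1]) / 2)

#' Work of detachment from a force-distance scan
#'
#' Trapezoidal integration of the force over the separation distance,
#' per source and in total. `method = "magnitude"` integrates |F|
#' (the small-angle assumption between force and displacement, which
#' overestimates); `method = "projected"` integrates the force
#' component opposing the displacement, -F . direction. Magnitude work
#' is always >= projected work.
#'
#' @param scan a [separation_scan()].
#' @param method `"magnitude"` (default) or `"projected"`.
#' @return `work_estimate` with per-source and total work in pN nm and
#'   kT.
#' @export
integrate_work <- function(scan, method = c("magnitude", "projected")) {
  method <- match.arg(method)
  if (length(scan$distances) < 2)
    stop("need at least two scan points to integrate")
  labels <- unique(scan$table$source)
  per <- vapply(labels, function(nm) {
    f <- lapply(scan$forces, function(fd) fd$per_source[[nm]])
    y <- if (method == "magnitude") vapply(f, function(v) sqrt(sum(v^2)),
                                           numeric(1))
    else vapply(f, function(v) -sum(v * scan$direction), numeric(1))
    trapezoid(scan$distances / 10, y)  # Angstrom -> nm
  }, numeric(1))
  total <- sum(per)
  structure(list(per_source_pN_nm = per,
                 per_source_kT = per / .kT_pN_nm,
                 total_pN_nm = total, total_kT = total / .kT_pN_nm,
                 method = method),
            class = "work_estimate")
}

#' @export
print.work_estimate <- function(x, ...) {
  cat(sprintf("work of detachment (%s method):\n", x$method))
  for (nm in names(x$per_source_pN_nm))
    cat(sprintf("  %-10s %8.2f pN nm = %6.2f kT\n", nm,
                x$per_source_pN_nm[[nm]], x$per_source_kT[[nm]]))
  cat(sprintf("  %-10s %8.2f pN nm = %6.2f kT\n", "total",
              x$total_pN_nm, x$total_kT))
  invisible(x)
}
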
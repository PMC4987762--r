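#' Molecular models
#'
#' A `mol_model` is the structural currency of the package: an ordered
#' atom table with coordinates (Angstrom), partial charges (e) and radii
#' (Angstrom). It is deliberately minimal -- no connectivity, no
#' altloc/insertion bookkeeping -- because every stage of the pipeline
#' treats structures as rigid charged bodies.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `resname`, `resid`, `chain`, `x`, `y`, `z`, `charge`, `radius`.
#'   Missing `element`, `charge`, `radius` columns are filled with
#'   defaults ("", 0, 0).
#' @param label free-text label carried through the pipeline.
#' @return An object of class `mol_model`.
#' @export
mol_model <- function(atoms, label = "") {
  required <- c("name", "resname", "resid", "chain", "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (is.null(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))
  if (is.null(atoms$element)) atoms$element <- rep("", nrow(atoms))
  if (is.null(atoms$charge)) atoms$charge <- rep(0, nrow(atoms))
  if (is.null(atoms$radius)) atoms$radius <- rep(0, nrow(atoms))
  atoms <- atoms[c("serial", "name", "element", "resname", "resid", "chain",
                   "x", "y", "z", "charge", "radius")]
  if (anyDuplicated(atoms$serial))
    stop("atom serials must be unique within a model")
  pos <- as.matrix(atoms[c("x", "y", "z")])
  if (!all(is.finite(pos))) stop("non-finite atom coordinates")
  if (any(atoms$radius < 0)) stop("negative atom radius")
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, label = label), class = "mol_model")
}

#' @export
print.mol_model <- function(x, ...) {
  cat(sprintf("<mol_model> %s: %d atoms, %d residues, net charge %+.3f e\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              nrow(x$atoms), nrow(unique(x$atoms[c("chain", "resid")])),
              sum(x$atoms$charge)))
  invisible(x)
}

#' @rdname mol_model
#' @param model a `mol_model`.
#' @export
n_atoms <- function(model) nrow(model$atoms)

#' @rdname mol_model
#' @export
coords <- function(model) unname(as.matrix(model$atoms[c("x", "y", "z")]))

set_coords <- function(model, xyz) {
  model$atoms$x <- xyz[, 1]
  model$atoms$y <- xyz[, 2]
  model$atoms$z <- xyz[, 3]
  model
}

#' Combine models into one (atoms concatenated, serials renumbered)
#' @param ... `mol_model` objects.
#' @param label label for the combined model.
#' @export
combine_models <- function(..., label = "complex") {
  parts <- list(...)
  atoms <- do.call(rbind, lapply(parts, function(m) m$atoms))
  atoms$serial <- seq_len(nrow(atoms))
  mol_model(atoms, label = label)
}

#' Trajectories
#'
#' An ordered list of snapshots sharing one topology (identical atom
#' count, names and order).
#'
#' @param snapshots list of `mol_model` objects.
#' @param timestep_label free text describing the sampling interval.
#' @export
mol_trajectory <- function(snapshots, timestep_label = "") {
  if (length(snapshots) < 1) stop("trajectory needs at least one snapshot")
  ref <- snapshots[[1]]$atoms$name
  for (s in snapshots) {
    if (length(s$atoms$name) != length(ref) || any(s$atoms$name != ref))
      stop("snapshots do not share one topology")
  }
  structure(list(snapshots = snapshots, timestep_label = timestep_label),
            class = "mol_trajectory")
}

#' @export
print.mol_trajectory <- function(x, ...) {
  cat(sprintf("<mol_trajectory> %d snapshots of %d atoms%s\n",
              length(x$snapshots), nrow(x$snapshots[[1]]$atoms),
              if (nzchar(x$timestep_label))
                paste0(" (", x$timestep_label, ")") else ""))
  invisible(x)
}

#' @export
length.mol_trajectory <- function(x) length(x$snapshots)

#' Rigid-body transforms
#'
#' @param rotation 3x3 proper orthogonal matrix (det +1).
#' @param translation length-3 numeric, Angstrom.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- unname(as.matrix(rotation))
  if (!all(dim(rotation) == c(3, 3))) stop("rotation must be 3x3")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    stop("rotation is not orthogonal")
  if (abs(det(rotation) - 1) > 1e-8)
    stop("rotation must be proper (det +1, no reflection)")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' @rdname rigid_transform
#' @param t2,t1 transforms; the composition applies `t1` first.
#' @export
compose_transforms <- function(t2, t1) {
  rigid_transform(t2$rotation %*% t1$rotation,
                  as.numeric(t2$rotation %*% t1$translation) + t2$translation)
}

#' Apply a rigid transform to a model
#'
#' Positions map x -> R x + t; charges and radii are untouched.
#' @param model a `mol_model`.
#' @param transform a [rigid_transform()].
#' @export
apply_transform <- function(model, transform) {
  xyz <- coords(model) %*% t(transform$rotation)
  xyz <- sweep(xyz, 2, transform$translation, "+")
  set_coords(model, xyz)
}

#' Formal net charge at pH 7
#'
#' Residue-level proxy: +1 per Arg/Lys, -1 per Asp/Glu, His and all
#' other residues 0; termini ignored. This is the formal-charge
#' bookkeeping used for sanity checks, not a pKa calculation.
#' @param model a `mol_model`.
#' @return integer net charge in e.
#' @export
formal_net_charge <- function(model) {
  res <- unique(model$atoms[c("chain", "resid", "resname")])
  pos <- sum(res$resname %in% c("ARG", "LYS"))
  neg <- sum(res$resname %in% c("ASP", "GLU"))
  as.integer(pos - neg)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation + translation minimising the RMSD of the
#' selected atoms of `mobile` onto those of `target`.
#'
#' @param mobile,target `mol_model` objects.
#' @param selection `NULL` (all atoms), a logical/integer index into the
#'   atom table, or a predicate `function(atoms) -> logical`.
#' @return list with `transform` (a [rigid_transform()]) and `rmsd`
#'   (Angstrom, post-fit, over the selection).
#' @export
superpose <- function(mobile, target, selection = NULL) {
  pick <- function(model) {
    a <- model$atoms
    idx <- if (is.null(selection)) seq_len(nrow(a))
    else if (is.function(selection)) which(selection(a))
    else selection
    unname(as.matrix(a[idx, c("x", "y", "z")]))
  }
  xm <- pick(mobile)
  xt <- pick(target)
  if (nrow(xm) != nrow(xt))
    stop("selection yields different atom counts (", nrow(xm), " vs ",
         nrow(xt), ")")
  if (nrow(xm) < 3) stop("need at least 3 atoms to superpose")
  cm <- colMeans(xm)
  ct <- colMeans(xt)
  am <- sweep(xm, 2, cm)
  at <- sweep(xt, 2, ct)
  H <- crossprod(am, at)
  sv <- svd(H)
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1))
    stop("degenerate (collinear) selection; superposition undefined")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- as.numeric(ct - R %*% cm)
  fitted <- sweep(xm %*% t(R), 2, tr, "+")
  rmsd <- sqrt(mean(rowSums((fitted - xt)^2)))
  list(transform = rigid_transform(R, tr), rmsd = rmsd)
}

#' Helical filament lattice specification
#'
#' Geometry of an ideal filament built from one subunit: protofilaments
#' are azimuthal copies (360 / n_protofilaments degrees apart, plus an
#' optional extra twist), dimers are axial copies along +z.
#'
#' @param n_protofilaments number of protofilaments (>= 1).
#' @param n_dimers dimers per protofilament.
#' @param axial_repeat Angstrom per dimer along the axis.
#' @param radius Angstrom from the filament axis to the subunit centre
#'   (0 keeps the subunit on the axis).
#' @param twist_per_protofilament extra azimuthal twist in degrees added
#'   per protofilament beyond the even 360/n spacing.
#' @param stagger axial shift in Angstrom added per protofilament
#'   (0 = unseamed ideal lattice).
#' @export
filament_spec <- function(n_protofilaments = 13, n_dimers = 16,
                          axial_repeat = 80, radius = 0,
                          twist_per_protofilament = 0, stagger = 0) {
  if (n_protofilaments < 1) stop("n_protofilaments must be >= 1")
  if (axial_repeat <= 0) stop("axial_repeat must be positive")
  structure(list(n_protofilaments = as.integer(n_protofilaments),
                 n_dimers = as.integer(n_dimers),
                 axial_repeat = axial_repeat, radius = radius,
                 twist_per_protofilament = twist_per_protofilament,
                 stagger = stagger),
            class = "filament_spec")
}

#' Build an ideal helical filament from one subunit
#'
#' Places `n_protofilaments * n_dimers` rigid copies of `unit` (a
#' dimer-equivalent subunit centred at the origin): each copy is shifted
#' radially to `spec$radius`, rotated about +z to its protofilament
#' azimuth, and translated axially by its dimer index (plus any
#' per-protofilament stagger). The total axial length
#' `n_dimers * axial_repeat` is attached as attribute `"length"`.
#'
#' A list of explicit [rigid_transform()]s may be supplied instead of a
#' spec, for lattices taken from deposited transformation matrices.
#'
#' @param unit a `mol_model` centred at the origin.
#' @param spec a [filament_spec()] or a list of [rigid_transform()]s.
#' @export
build_filament <- function(unit, spec) {
  transforms <- if (inherits(spec, "filament_spec")) {
    out <- list()
    for (p in seq_len(spec$n_protofilaments) - 1L) {
      theta <- p * (360 / spec$n_protofilaments + spec$twist_per_protofilament)
      Rp <- rot_z(theta)
      for (d in seq_len(spec$n_dimers) - 1L) {
        tr <- as.numeric(Rp %*% c(spec$radius, 0, 0)) +
          c(0, 0, d * spec$axial_repeat + p * spec$stagger)
        out[[length(out) + 1L]] <- rigid_transform(Rp, tr)
      }
    }
    out
  } else if (is.list(spec) && all(vapply(spec, inherits, TRUE,
                                         "rigid_transform"))) {
    spec
  } else stop("spec must be a filament_spec or a list of rigid transforms")

  span <- diff(range(unit$atoms$resid)) + 1L
  copies <- lapply(seq_along(transforms), function(k) {
    a <- apply_transform(unit, transforms[[k]])$atoms
    a$resid <- a$resid + (k - 1L) * span  # keep residues distinct per copy
    a
  })
  atoms <- do.call(rbind, copies)
  atoms$serial <- seq_len(nrow(atoms))
  out <- mol_model(atoms, label = paste0("filament[", unit$label, "]"))
  if (inherits(spec, "filament_spec"))
    attr(out, "length") <- spec$n_dimers * spec$axial_repeat
  out
}
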
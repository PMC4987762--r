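# Seeded generators for toy systems with known ground truth. Each is a
# pure function of its spec (seed included): randomness goes through a
# private RNG stream and the caller's RNG state is untouched. Ground
# truth is attached to each output as the "truth" attribute and written
# to the sidecar metadata file by save_with_metadata().

#' Synthetic probe: a net-neutral rigid body with a charged binding face
#'
#' Emulates a small motor domain whose binding face carries a strong
#' positive potential while the domain as a whole is close to neutral:
#' atoms on a compact ball, `face_charge` spread over the lowest-z
#' quarter of atoms (the binding face, which points toward the filament)
#' and the compensating `net_charge - face_charge` over the highest-z
#' quarter.
#'
#' @param n_atoms number of atoms.
#' @param net_charge total charge, e.
#' @param face_charge charge on the binding (-z) face, e.
#' @param radius_atom uniform atom radius, Angstrom.
#' @param jitter Gaussian positional jitter applied to the lattice,
#'   Angstrom.
#' @param seed integer seed; same seed, same atoms.
#' @return a [mol_model()] with a `truth` attribute.
#' @export
make_probe <- function(n_atoms = 60, net_charge = 0, face_charge = 4,
                       radius_atom = 1.7, jitter = 0.15, seed = 1) {
  spacing <- 2 * radius_atom * 0.95
  half <- ceiling((n_atoms * 3 / (4 / 3 * pi))^(1 / 3))
  lat <- as.matrix(expand.grid(x = -half:half, y = -half:half,
                               z = -half:half)) * spacing
  ord <- order(rowSums(lat^2), lat[, 1], lat[, 2], lat[, 3])
  xyz <- lat[ord[seq_len(n_atoms)], , drop = FALSE]
  xyz <- sweep(xyz, 2, colMeans(xyz))
  xyz <- with_seed(seed, xyz + matrix(rnorm(length(xyz), sd = jitter),
                                      ncol = 3))
  nq <- max(1L, floor(n_atoms / 4))
  zord <- order(xyz[, 3])
  charge <- numeric(n_atoms)
  charge[zord[seq_len(nq)]] <- face_charge / nq
  charge[zord[seq(n_atoms - nq + 1, n_atoms)]] <- (net_charge - face_charge) / nq
  atoms <- data.frame(serial = seq_len(n_atoms), name = "Q",
                      element = "C", resname = "PRB",
                      resid = seq_len(n_atoms), chain = "P",
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      charge = charge, radius = radius_atom)
  out <- mol_model(atoms, label = "synthetic probe")
  attr(out, "truth") <- list(net_charge = net_charge,
                             face_charge = face_charge, seed = seed)
  out
}

#' Synthetic binding surface: a neutral slab with a charged pocket
#'
#' A rectangular slab of neutral atoms whose top face lies at z = 0,
#' plus `round(abs(pocket_charge))` single-atom acidic pseudo-residues
#' (residue name ASP so that formal-charge bookkeeping sees them)
#' arranged on a ring around `pocket_center`. `pocket_asymmetry` skews
#' the ring along the longitudinal (x) axis; at 0 the pocket is exactly
#' mirror-symmetric about its centre.
#'
#' @param slab_dim c(Lx, Ly) slab extent, Angstrom.
#' @param pocket_center c(x, y) pocket centre on the surface, Angstrom.
#' @param pocket_charge total pocket charge, e (negative).
#' @param pocket_asymmetry scalar skew (0 = symmetric).
#' @param pocket_radius ring radius, Angstrom.
#' @param spacing slab lattice spacing, Angstrom.
#' @param n_layers slab thickness in atom layers.
#' @param radius_atom uniform atom radius, Angstrom.
#' @param seed integer seed (the construction is deterministic; the seed
#'   is recorded with the truth metadata).
#' @export
make_binding_surface <- function(slab_dim = c(60, 60), pocket_center = c(0, 0),
                                 pocket_charge = -8, pocket_asymmetry = 0.5,
                                 pocket_radius = 4, spacing = 3,
                                 n_layers = 2, radius_atom = 1.7, seed = 1) {
  gx <- seq(-slab_dim[1] / 2, slab_dim[1] / 2, by = spacing)
  gy <- seq(-slab_dim[2] / 2, slab_dim[2] / 2, by = spacing)
  gz <- -(seq_len(n_layers) - 1) * spacing
  lat <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  slab <- data.frame(serial = NA, name = "Q", element = "C", resname = "SLB",
                     resid = seq_len(nrow(lat)), chain = "S",
                     x = lat[, 1], y = lat[, 2], z = lat[, 3],
                     charge = 0, radius = radius_atom)
  n_sites <- max(1L, round(abs(pocket_charge)))
  theta <- (seq_len(n_sites) - 0.5) * 2 * pi / n_sites  # reflection-closed set
  px <- pocket_radius * cos(theta)
  px <- px * (1 + pocket_asymmetry * (px > 0))  # skew the +x half outward
  py <- pocket_radius * sin(theta)
  pocket <- data.frame(serial = NA, name = "OD1", element = "O",
                       resname = "ASP",
                       resid = max(slab$resid) + seq_len(n_sites), chain = "S",
                       x = pocket_center[1] + px, y = pocket_center[2] + py,
                       z = 0, charge = pocket_charge / n_sites,
                       radius = radius_atom)
  atoms <- rbind(slab, pocket)
  atoms$serial <- seq_len(nrow(atoms))
  out <- mol_model(atoms, label = "synthetic binding surface")
  attr(out, "truth") <- list(pocket_center = pocket_center,
                             pocket_charge = pocket_charge,
                             pocket_asymmetry = pocket_asymmetry, seed = seed)
  out
}

#' Synthetic two-segment trajectory with planted hinges
#'
#' A Calpha-only chain on ideal alpha-helical geometry (rise 1.5 A,
#' 100 degrees per residue, radius 2.3 A). In every snapshot each
#' interior residue bends the downstream chain about a random axis
#' perpendicular to the local chain direction by an angle drawn from
#' N(0, baseline_sigma); residues listed in `hinge_residue` use
#' N(0, hinge_sigma) instead. The planted truth is recorded in the
#' `truth` attribute.
#'
#' @param n_residues chain length.
#' @param hinge_residue integer index (or vector of indices) of the
#'   planted hinge(s); must lie more than 10 residues from either end.
#' @param baseline_sigma background bend s.d., degrees.
#' @param hinge_sigma hinge bend s.d., degrees (> baseline_sigma unless
#'   both are 0).
#' @param n_snapshots number of snapshots.
#' @param seed integer seed.
#' @return a [mol_trajectory()] with a `truth` attribute.
#' @export
make_hinged_trajectory <- function(n_residues = 80, hinge_residue = 40,
                                   baseline_sigma = 2, hinge_sigma = 15,
                                   n_snapshots = 200, seed = 1) {
  if (any(hinge_residue <= 10 | hinge_residue >= n_residues - 10))
    stop("hinge_residue must be > 10 and < n_residues - 10")
  if (hinge_sigma < baseline_sigma)
    stop("hinge_sigma must be >= baseline_sigma")
  i <- seq_len(n_residues)
  ideal <- cbind(2.3 * cos(i * 100 * pi / 180),
                 2.3 * sin(i * 100 * pi / 180),
                 i * 1.5)
  base <- mol_model(data.frame(
    serial = i, name = "CA", element = "C", resname = "ALA", resid = i,
    chain = "A", x = ideal[, 1], y = ideal[, 2], z = ideal[, 3],
    charge = 0, radius = 1.7), label = "synthetic hinged chain")

  snaps <- with_seed(seed, {
    lapply(seq_len(n_snapshots), function(s) {
      xyz <- ideal
      for (j in 2:(n_residues - 1)) {
        sig <- if (j %in% hinge_residue) hinge_sigma else baseline_sigma
        if (sig <= 0) next
        ang <- rnorm(1, 0, sig)
        tangent <- xyz[j + 1, ] - xyz[j - 1, ]
        tangent <- tangent / sqrt(sum(tangent^2))
        ref <- rnorm(3)
        axis <- ref - sum(ref * tangent) * tangent
        axis <- axis / sqrt(sum(axis^2))
        down <- (j + 1):n_residues
        xyz[down, ] <- sweep(sweep(xyz[down, , drop = FALSE], 2, xyz[j, ]) %*%
                               t(rot_axis(axis, ang)), 2, xyz[j, ], "+")
      }
      set_coords(base, xyz)
    })
  })
  out <- mol_trajectory(snaps, timestep_label = "synthetic")
  attr(out, "truth") <- list(hinge_residue = hinge_residue,
                             baseline_sigma = baseline_sigma,
                             hinge_sigma = hinge_sigma, seed = seed)
  out
}

#' Synthetic energy-phenotype dataset with a planted linear relation
#'
#' energy_i = true_slope * predictor_i + true_intercept + N(0,
#' noise_sigma), with predictors evenly spaced over `predictor_range`.
#' Defaults mirror the low-affinity velocity calibration (5 constructs,
#' slope 0.35 kT s/nm, intercept -43 kT).
#'
#' @param n_constructs number of constructs (>= 3).
#' @param true_slope planted slope, kT per phenotype unit.
#' @param true_intercept planted intercept, kT.
#' @param noise_sigma Gaussian noise s.d., kT.
#' @param predictor_range c(min, max) of the phenotype predictor.
#' @param seed integer seed.
#' @return data.frame with columns `predictor` and `energy`, plus a
#'   `truth` attribute.
#' @export
make_phenotype_dataset <- function(n_constructs = 5, true_slope = 0.35,
                                   true_intercept = -43, noise_sigma = 1,
                                   predictor_range = c(60, 120), seed = 1) {
  if (n_constructs < 3) stop("need at least 3 constructs")
  predictor <- seq(predictor_range[1], predictor_range[2],
                   length.out = n_constructs)
  energy <- with_seed(seed, true_slope * predictor + true_intercept +
                        rnorm(n_constructs, 0, noise_sigma))
  out <- data.frame(predictor = predictor, energy = energy)
  attr(out, "truth") <- list(true_slope = true_slope,
                             true_intercept = true_intercept,
                             noise_sigma = noise_sigma, seed = seed)
  out
}

#' Write a synthetic model with its ground-truth sidecar
#'
#' Writes the structure as PQR and the `truth` attribute as a YAML
#' sidecar next to it (`<path>.truth.yaml`).
#' @param model a generated [mol_model()].
#' @param path output PQR path.
#' @export
save_with_metadata <- function(model, path) {
  save_structure(model, path, format = "pqr")
  truth <- attr(model, "truth")
  if (!is.null(truth))
    yaml::write_yaml(truth, paste0(path, ".truth.yaml"))
  invisible(path)
}
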
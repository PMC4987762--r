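test_that("PQR records map to atom fields, fixed-width and free-whitespace", {
  tmp <- withr::local_tempfile(fileext = ".pqr")
  writeLines("ATOM 1 N GLU A 1 0.0 0.0 0.0 -0.30 1.55", tmp)
  m <- load_structure(tmp, "pqr")
  expect_equal(n_atoms(m), 1)
  expect_equal(m$atoms$charge, -0.30)
  expect_equal(m$atoms$radius, 1.55)
  expect_equal(m$atoms$resname, "GLU")
  expect_equal(m$atoms$chain, "A")

  # chain-less variant
  writeLines("ATOM 1 N GLU 1 1.0 2.0 3.0 -0.30 1.55", tmp)
  m2 <- load_structure(tmp, "pqr")
  expect_equal(c(m2$atoms$x, m2$atoms$y, m2$atoms$z), c(1, 2, 3))
})

test_that("PDB and PQR round trips preserve coordinates and parameters", {
  probe <- make_probe(n_atoms = 20, seed = 3)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  save_structure(probe, pdb)
  back <- load_structure(pdb)
  expect_equal(coords(back), round(coords(probe), 3), tolerance = 1e-9)
  expect_equal(back$atoms$charge, rep(0, 20))  # PDB carries no charges

  pqr <- withr::local_tempfile(fileext = ".pqr")
  save_structure(probe, pqr)
  back2 <- load_structure(pqr)
  expect_equal(coords(back2), round(coords(probe), 3), tolerance = 1e-9)
  expect_equal(back2$atoms$charge, round(probe$atoms$charge, 4),
               tolerance = 1e-9)
  expect_equal(back2$atoms$radius, probe$atoms$radius, tolerance = 1e-3)
})

test_that("trajectories write as MODEL blocks and read back", {
  probe <- make_probe(n_atoms = 10, seed = 1)
  snaps <- lapply(0:2, function(k)
    apply_transform(probe, rigid_transform(diag(3), c(k, 0, 0))))
  traj <- mol_trajectory(snaps)
  tmp <- withr::local_tempfile(fileext = ".pdb")
  save_structure(traj, tmp)
  expect_equal(sum(grepl("^MODEL", readLines(tmp))), 3)
  back <- load_trajectory(tmp)
  expect_equal(length(back), 3)
  expect_equal(coords(back$snapshots[[3]]), round(coords(snaps[[3]]), 3),
               tolerance = 1e-9)
})

test_that("malformed and overflowing records are reported usefully", {
  tmp <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("ATOM      1  CA  ALA A   1       0.000   0.000   0.000",
               "ATOM      2  CA  ALA A   2       x.xxx   0.000   0.000"),
             tmp)
  expect_error(load_structure(tmp), "line 2")

  big <- make_ion(x = 12000)
  expect_error(save_structure(big, withr::local_tempfile(fileext = ".pdb")),
               "9999.999")
})

test_that("parameter assignment gives integer residue charges and is idempotent", {
  chain <- make_chain(c("GLY", "GLU", "LYS", "ARG", "ASP", "SER", "TRP"))
  m <- assign_parameters(chain)
  sums <- tapply(m$atoms$charge, m$atoms$resid, sum)
  expect_equal(as.vector(sums), c(0, -1, 1, 1, -1, 0, 0), tolerance = 1e-3)
  expect_true(all(m$atoms$radius > 0))
  m2 <- assign_parameters(m)
  expect_identical(m2$atoms, m$atoms)
})

test_that("unmatched atoms error in strict mode and default with warning otherwise", {
  odd <- mol_model(data.frame(serial = 1, name = "XX1", resname = "UNK",
                              resid = 1, chain = "A", x = 0, y = 0, z = 0))
  expect_error(assign_parameters(odd), "UNK XX1")
  expect_warning(lenient <- assign_parameters(odd, strict = FALSE),
                 "charge 0")
  expect_equal(lenient$atoms$charge, 0)
  expect_equal(lenient$atoms$radius, 1.5)
})

test_that("formal net charge counts basic minus acidic residues", {
  expect_equal(formal_net_charge(make_chain(c("GLU", "GLU", "LYS"))), -1)
  expect_equal(formal_net_charge(make_chain(rep("ALA", 6))), 0)
  surf <- make_binding_surface(pocket_charge = -8, seed = 1)
  expect_equal(formal_net_charge(surf), -8)
})

test_that("superposition recovers planted transforms", {
  probe <- make_probe(n_atoms = 40, seed = 5)
  self <- superpose(probe, probe)
  expect_equal(self$transform$rotation, diag(3), tolerance = 1e-9)
  expect_equal(self$rmsd, 0, tolerance = 1e-9)

  R <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)  # 90 deg about z
  moved <- apply_transform(probe, rigid_transform(R, c(3, -2, 7)))
  fit <- superpose(probe, moved)
  expect_equal(fit$transform$rotation, R, tolerance = 1e-6)
  expect_equal(fit$transform$translation, c(3, -2, 7), tolerance = 1e-6)
  expect_lt(fit$rmsd, 1e-9)
})

test_that("superposition rmsd scales with coordinate noise", {
  probe <- make_probe(n_atoms = 100, seed = 2)
  noisy <- probe
  set.seed(11)
  xyz <- coords(probe) + matrix(rnorm(300, sd = 0.1), ncol = 3)
  noisy$atoms$x <- xyz[, 1]; noisy$atoms$y <- xyz[, 2]
  noisy$atoms$z <- xyz[, 3]
  fit <- superpose(noisy, probe)
  expect_lt(fit$rmsd, 0.25)
  expect_gt(fit$rmsd, 0.05)
})

test_that("superposition rmsd is invariant under a common pre-rotation", {
  probe <- make_probe(n_atoms = 30, seed = 9)
  target <- apply_transform(probe, rigid_transform(rot_axis(c(1, 1, 0), 30),
                                                   c(1, 2, 3)))
  common <- rigid_transform(rot_axis(c(0, 1, 1), 77), c(-4, 5, 6))
  r1 <- superpose(probe, target)$rmsd
  r2 <- superpose(apply_transform(probe, common),
                  apply_transform(target, common))$rmsd
  expect_equal(r1, r2, tolerance = 1e-9)
})

test_that("degenerate superpositions are rejected", {
  line <- mol_model(data.frame(serial = 1:5, name = "CA", resname = "ALA",
                               resid = 1:5, chain = "A", x = 1:5, y = 0,
                               z = 0))
  expect_error(superpose(line, line), "collinear|degenerate")
  expect_error(superpose(make_probe(n_atoms = 10, seed = 1),
                         make_probe(n_atoms = 15, seed = 1)),
               "different atom counts")
})

test_that("rigid transforms compose and preserve internal geometry", {
  probe <- make_probe(n_atoms = 15, seed = 4)
  expect_equal(coords(apply_transform(probe, rigid_transform())),
               coords(probe))
  t1 <- rigid_transform(rot_axis(c(1, 0, 2), 40), c(1, -1, 2))
  t2 <- rigid_transform(rot_axis(c(0, 1, 1), -25), c(0, 3, -5))
  seq2 <- apply_transform(apply_transform(probe, t1), t2)
  once <- apply_transform(probe, compose_transforms(t2, t1))
  expect_equal(coords(seq2), coords(once), tolerance = 1e-9)
  d0 <- dist(coords(probe))
  d1 <- dist(coords(seq2))
  expect_equal(as.numeric(d1), as.numeric(d0), tolerance = 1e-9)
})

test_that("improper rotations are rejected", {
  expect_error(rigid_transform(diag(c(1, 1, -1))), "proper")
})

test_that("filament builder produces the lattice geometry", {
  unit <- make_probe(n_atoms = 7, seed = 1)
  spec <- filament_spec(n_protofilaments = 13, n_dimers = 16,
                        axial_repeat = 80, radius = 150)
  fil <- build_filament(unit, spec)
  expect_equal(n_atoms(fil), 13 * 16 * 7)
  expect_equal(attr(fil, "length"), 1280)

  single <- build_filament(unit, filament_spec(1, 1, 80, radius = 0))
  expect_equal(coords(single), coords(unit), tolerance = 1e-9)
  expect_equal(single$atoms$charge, unit$atoms$charge)

  # explicit transform list route
  tlist <- list(rigid_transform(), rigid_transform(diag(3), c(0, 0, 80)))
  fil2 <- build_filament(unit, tlist)
  expect_equal(n_atoms(fil2), 14)
  expect_equal(coords(fil2)[8:14, 3], coords(unit)[, 3] + 80)
})

test_that("transform tables read as rigid transforms", {
  tmp <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(paste(c(1, 0, 0, 0, 1, 0, 0, 0, 1, 5, 6, 7), collapse = " "),
               paste(c(0, -1, 0, 1, 0, 0, 0, 0, 1, 0, 0, 80),
                     collapse = " ")), tmp)
  tl <- read_transforms(tmp)
  expect_length(tl, 2)
  expect_equal(tl[[1]]$translation, c(5, 6, 7))
  expect_equal(tl[[2]]$rotation[1, 2], -1)
})
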
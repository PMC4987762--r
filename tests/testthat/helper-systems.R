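# Small fixture builders shared across test files. Everything is built
# in code; no data files.

# single ion at an off-node position (so charge spreading is exercised)
make_ion <- function(x = 0.13, y = 0.21, z = -0.1, charge = 1, radius = 1.5,
                     chain = "A") {
  mol_model(data.frame(serial = 1, name = "Q", resname = "ION", resid = 1,
                       chain = chain, x = x, y = y, z = z,
                       charge = charge, radius = radius))
}

# uniform-dielectric water configuration: the reaction field vanishes and
# Coulomb's law is the exact oracle
uniform_water <- function(scale = 2, ...) {
  solver_config(scale = scale, eps_in = 80, eps_out = 80,
                boundary = "coulombic", ...)
}

# a +1/-1 pair separated by `d` Angstrom along x, off-node
make_pair <- function(d = 5) {
  list(a = make_ion(x = -d / 2, y = 0.1, z = 0.1, charge = 1, chain = "A"),
       b = make_ion(x = d / 2, y = 0.1, z = 0.1, charge = -1, chain = "B"))
}

# probe centre height at contact above a surface slab (planar frame)
contact_z <- function(probe, surface, gap = 1) {
  ctr <- colMeans(coords(probe))
  max(surface$atoms$z + surface$atoms$radius) +
    (ctr[3] - min(probe$atoms$z - probe$atoms$radius)) + gap
}

# one amino-acid "residue" with named atoms at given offsets from a base
# position; used to build parameterisable mini-chains
make_residue <- function(resname, resid, base, chain = "A",
                         names = c("N", "CA", "C", "O"),
                         spread = 0.8) {
  n <- length(names)
  offs <- cbind(seq(0, by = spread, length.out = n), 0, 0)
  data.frame(serial = NA, name = names, element = substr(names, 1, 1),
             resname = resname, resid = resid, chain = chain,
             x = base[1] + offs[, 1], y = base[2] + offs[, 2],
             z = base[3] + offs[, 3], charge = 0, radius = 1.5)
}

full_residue_atoms <- function(resname) {
  tab <- default_parameter_table()
  tab$name[tab$resname == resname]
}

# mini peptide with complete heavy atoms for the given residue sequence
make_chain <- function(resnames, chain = "A", spacing = 4) {
  rows <- lapply(seq_along(resnames), function(i) {
    make_residue(resnames[i], i, c(i * spacing, 0, 0), chain = chain,
                 names = full_residue_atoms(resnames[i]))
  })
  atoms <- do.call(rbind, rows)
  atoms$serial <- seq_len(nrow(atoms))
  mol_model(atoms, label = paste(resnames, collapse = "-"))
}
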
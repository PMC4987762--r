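test_that("the interpolated field matches Coulomb's law away from the source", {
  cfg <- uniform_water(scale = 2)
  src <- make_ion(x = 0, y = 0, z = 0)
  shell <- rbind(c(8, 1, 0), c(-6, 6, 2), c(0, -9, 4))
  probe <- mol_model(data.frame(serial = 1:3, name = "Q", resname = "PRB",
                                resid = 1:3, chain = "P", x = shell[, 1],
                                y = shell[, 2], z = shell[, 3], charge = 1,
                                radius = 1.5))
  g <- grid_spec(rep(-15, 3) + 0.05, 0.5, 61)
  E <- field_at_atoms(src, probe, cfg, g)
  r <- sqrt(rowSums(shell^2))
  expect_lt(max(abs(sqrt(rowSums(E^2)) / (561.0 / (80 * r^2)) - 1)), 0.07)
  # field points radially outward from a positive source
  expect_true(all(rowSums(E * shell) > 0))
})

test_that("the field is zero for a silent source and odd under charge flip", {
  cfg <- uniform_water(scale = 1)
  g <- grid_spec(rep(-10, 3), 1, 21)
  probe <- make_probe(n_atoms = 5, seed = 1)
  silent <- make_ion(charge = 0)
  expect_equal(max(abs(field_at_atoms(silent, probe, cfg, g))), 0)
  pos <- make_ion(charge = 1)
  neg <- make_ion(charge = -1)
  # probe atoms sit close to the source here: the proximity diagnostic
  # is expected, the antisymmetry must hold regardless
  expect_warning(En <- field_at_atoms(neg, probe, cfg, g), "2 grid spacings")
  expect_warning(Ep <- field_at_atoms(pos, probe, cfg, g), "2 grid spacings")
  expect_equal(En, -Ep, tolerance = 1e-9)
})

test_that("point-charge forces match the closed form and Newton's third law", {
  cfg <- uniform_water(scale = 2)
  a <- make_ion(x = 0.1, y = 0.1, z = 0.1, charge = 1, chain = "A")
  b <- make_ion(x = 10.1, y = 0.1, z = 0.1, charge = -1, chain = "B")
  g <- grid_spec(rep(-12, 3) + 0.15, 0.5, 49 + 26)  # covers both, odd dims
  f_ab <- net_force(a, b, cfg, grid = g)   # force on b from a
  f_ba <- net_force(b, a, cfg, grid = g)
  expected <- 561.0 * 41.14 / (80 * 100)   # pN, attractive
  expect_equal(sqrt(sum(f_ab$total^2)), expected, tolerance = 0.10)
  expect_lt(f_ab$total[1], 0)  # b is pulled back toward a (-x)
  expect_equal(f_ab$total, -f_ba$total, tolerance = 0.05 * expected)
})

test_that("per-source forces partition the total exactly", {
  cfg <- uniform_water(scale = 1)
  src <- mol_model(data.frame(serial = 1:2, name = "Q", resname = "ION",
                              resid = 1:2, chain = "A", x = c(-4, 4),
                              y = 0.1, z = 0.1, charge = c(-1, -2),
                              radius = 1.5))
  probe <- make_ion(x = 0.1, y = 0.1, z = 8.1, charge = 1, chain = "P")
  g <- grid_spec(rep(-14, 3) + 0.1, 1, 29)
  fd <- net_force(src, probe, cfg, grid = g,
                  partition = list(alpha = 1, beta = 2))
  expect_equal(fd$total, fd$per_source$alpha + fd$per_source$beta,
               tolerance = 1e-12)
  expect_error(net_force(src, probe, cfg, grid = g,
                         partition = list(alpha = 1)),
               "does not cover")
})

test_that("a net-neutral probe feels almost no force in a far field", {
  cfg <- uniform_water(scale = 1)
  src <- make_ion(x = 0.1, y = 0.1, z = -20, charge = 4)
  dipole <- mol_model(data.frame(serial = 1:2, name = "Q", resname = "PRB",
                                 resid = 1:2, chain = "P", x = c(-1, 1),
                                 y = 0.1, z = 20.1, charge = c(1, -1),
                                 radius = 1.5))
  g <- grid_spec(c(-30, -30, -35) + 0.1, 1, 61)
  fd <- net_force(src, dipole, cfg, grid = g)
  single <- net_force(src, make_ion(x = 0.1, y = 0.1, z = 20.1, charge = 1,
                                    chain = "P"), cfg, grid = g)
  expect_lt(sqrt(sum(fd$total^2)), 0.2 * sqrt(sum(single$total^2)))
})

test_that("separation scans decay with distance and honour their contract", {
  probe <- make_probe(n_atoms = 16, seed = 4)
  surf <- make_binding_surface(slab_dim = c(24, 24), pocket_radius = 2,
                               seed = 4)
  cfg <- uniform_water(scale = 0.5)
  bound <- apply_transform(probe, rigid_transform(
    diag(3), c(0, 0, contact_z(probe, surf)) - colMeans(coords(probe))))
  scan <- separation_scan(surf, bound, c(0, 0, 1), seq(4, 16, 4), cfg)
  mags <- vapply(scan$forces, function(f) sqrt(sum(f$total^2)), numeric(1))
  expect_true(all(diff(mags) < 0))

  expect_error(separation_scan(surf, bound, c(0, 0, 1), c(8, 4), cfg),
               "increasing")

  mute <- bound
  mute$atoms$charge <- 0
  scan0 <- separation_scan(surf, mute, c(0, 0, 1), c(4, 8), cfg)
  expect_equal(max(abs(scan0$table[c("Fx", "Fy", "Fz")])), 0)
})

# hand-built scan with known forces, for the integration arithmetic
fake_scan <- function(distances, fz_by_source, direction = c(0, 0, 1)) {
  forces <- lapply(seq_along(distances), function(i) {
    per <- lapply(fz_by_source, function(fz) c(0, 0, fz[i]))
    list(total = Reduce(`+`, per), per_source = per)
  })
  table <- do.call(rbind, lapply(seq_along(distances), function(i) {
    do.call(rbind, lapply(names(fz_by_source), function(nm)
      data.frame(distance = distances[i], source = nm, Fx = 0, Fy = 0,
                 Fz = fz_by_source[[nm]][i],
                 Fmag = abs(fz_by_source[[nm]][i]))))
  }))
  structure(list(distances = distances, forces = forces,
                 direction = direction, table = table),
            class = "separation_scan")
}

test_that("work integration follows the trapezoidal rule", {
  const <- fake_scan(seq(0, 10, 2), list(all = rep(-5, 6)))  # 5 pN over 1 nm
  w <- integrate_work(const, "magnitude")
  expect_equal(w$total_pN_nm, 5)
  wp <- integrate_work(const, "projected")
  expect_equal(wp$total_pN_nm, 5)  # force opposes displacement exactly

  ramp <- fake_scan(seq(0, 20, 2), list(all = -seq(10, 0, by = -1)))
  expect_equal(integrate_work(ramp, "magnitude")$total_pN_nm, 10)

  expect_error(integrate_work(fake_scan(0, list(all = -5))), "at least two")
})

test_that("magnitude work bounds projected work and converts to kT", {
  skewed <- fake_scan(seq(0, 10, 5), list(a = c(-4, -2, -1)))
  skewed$forces <- lapply(skewed$forces, function(f) {
    f$per_source$a <- f$per_source$a + c(3, 0, 0)  # sideways component
    f$total <- f$per_source$a
    f
  })
  wm <- integrate_work(skewed, "magnitude")
  wp <- integrate_work(skewed, "projected")
  expect_gte(wm$total_pN_nm, wp$total_pN_nm)
  expect_equal(wm$total_kT, wm$total_pN_nm / 4.114, tolerance = 1e-12)

  # two tubulin-like sources worth 50 and 55 pN nm give 12 + 13 = 25 kT
  per <- c(alpha = 50, beta = 55)
  kt <- round(convert_energy_units(per, "pN_nm", "kT"))
  expect_equal(unname(kt), c(12, 13))
  expect_equal(sum(kt), 25)
})

test_that("projected detachment work agrees with the binding-energy drop", {
  probe <- make_probe(n_atoms = 16, seed = 4)
  surf <- make_binding_surface(slab_dim = c(24, 24), pocket_radius = 2,
                               seed = 4)
  cfg <- uniform_water(scale = 0.5)
  bound <- apply_transform(probe, rigid_transform(
    diag(3), c(0, 0, contact_z(probe, surf)) - colMeans(coords(probe))))
  scan <- separation_scan(surf, bound, c(0, 0, 1), seq(0, 16, 2), cfg)
  work <- integrate_work(scan, "projected")$total_kT
  far <- apply_transform(bound, rigid_transform(diag(3), c(0, 0, 16)))
  dG <- binding_energy(far, surf, cfg, reaction_field = FALSE)$delta_G -
    binding_energy(bound, surf, cfg, reaction_field = FALSE)$delta_G
  expect_equal(work, dG, tolerance = 0.15)
})
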
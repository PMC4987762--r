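test_that("grid planning follows the perfil/scale box rule", {
  two <- mol_model(data.frame(serial = 1:2, name = "Q", resname = "ION",
                              resid = 1:2, chain = "A", x = c(0, 35),
                              y = 0, z = 0))
  cfg <- solver_config(scale = 2, perfil = 70)
  g <- plan_grid(two, cfg)
  expect_equal(g$dims, rep(101L, 3))       # 35 / 0.70 = 50 A edge
  expect_equal(g$spacing, 0.5)
  expect_equal(grid_center(g), c(17.5, 0, 0))

  # model order cannot matter
  g2 <- plan_grid(list(make_ion(x = 35, y = 0, z = 0), make_ion()), cfg)
  g3 <- plan_grid(list(make_ion(), make_ion(x = 35, y = 0, z = 0)), cfg)
  expect_equal(g2, g3)

  # doubling the scale halves the spacing
  g4 <- plan_grid(two, solver_config(scale = 4, perfil = 70))
  expect_equal(g4$spacing, 0.25)
  expect_error(plan_grid(list()), "no models")
})

test_that("rasterization conserves charge and marks the cavity", {
  cfg <- solver_config()
  g <- grid_spec(rep(-5, 3), 0.5, 21)
  on_node <- make_ion(x = 0, y = 0, z = 0, radius = 1.5)
  sys <- rasterize(on_node, g, cfg)
  expect_equal(max(sys$charge), 1)          # all charge on one node
  expect_equal(sum(sys$charge != 0), 1)
  expect_equal(sys$total_charge, 1, tolerance = 1e-12)
  centre_idx <- (g$dims + 1) / 2
  expect_equal(sys$dielectric[centre_idx[1], centre_idx[2], centre_idx[3]],
               cfg$eps_in)
  expect_equal(sys$dielectric[1, 1, 1], cfg$eps_out)

  off_node <- make_ion(x = 0.27, y = -0.13, z = 0.08)
  sys2 <- rasterize(off_node, g, cfg)
  expect_equal(sum(sys2$charge), 1, tolerance = 1e-12)
  expect_equal(sum(sys2$charge != 0), 8)    # trilinear cloud

  empty <- mol_model(data.frame(serial = integer(), name = character(),
                                resname = character(), resid = integer(),
                                chain = character(), x = numeric(),
                                y = numeric(), z = numeric()))
  sys3 <- rasterize(empty, g, cfg)
  expect_true(all(sys3$dielectric == cfg$eps_out))
  expect_equal(sum(abs(sys3$charge)), 0)

  outside <- make_ion(x = 50)
  expect_error(rasterize(outside, g, cfg), "outside the grid")
  expect_equal(rasterize(outside, g, cfg, clip = TRUE)$dropped_atoms, 1L)
})

test_that("boundary conditions match their closed forms", {
  cfg <- solver_config(boundary = "dipole")
  g <- grid_spec(rep(-10, 3), 0.5, 41)
  # monopole: a single +1e at the centre; dipole term vanishes
  ion <- make_ion(x = 0, y = 0, z = 0)
  b <- boundary_potential(rasterize(ion, g, cfg), cfg)
  pts <- rbind(c(-10, 0, 0), c(10, 10, 10), c(0, -10, 10))
  idx <- rbind(c(1, 21, 21), c(41, 41, 41), c(21, 1, 41))
  for (k in 1:3) {
    r <- sqrt(sum(pts[k, ]^2))
    expect_equal(unclass(b)[idx[k, 1], idx[k, 2], idx[k, 3]],
                 561.0 / (80 * r), tolerance = 1e-6)
  }

  # quadrupole-ish cluster: zero monopole and zero dipole -> zero boundary
  quad <- mol_model(data.frame(serial = 1:4, name = "Q", resname = "ION",
                               resid = 1:4, chain = "A",
                               x = c(-1, 1, -1, 1), y = c(-1, -1, 1, 1),
                               z = 0, charge = c(1, -1, -1, 1),
                               radius = 1.5))
  bq <- boundary_potential(rasterize(quad, g, cfg), cfg)
  expect_equal(max(abs(unclass(bq))), 0, tolerance = 1e-12)

  # zero mode grounds the box
  cfg0 <- solver_config(boundary = "zero")
  b0 <- boundary_potential(rasterize(ion, g, cfg0), cfg0)
  expect_equal(max(abs(unclass(b0))), 0)

  # dipole vs full coulombic boundary differ < 2% when the charges sit
  # well inside the solute box (perfil 70)
  set.seed(1)
  qx <- matrix(rnorm(12, sd = 0.8), 4, 3)
  cluster <- mol_model(data.frame(
    serial = 1:6, name = "Q", resname = "ION", resid = 1:6, chain = "A",
    x = c(qx[, 1], -10.5, 10.5), y = c(qx[, 2], 0, 0),
    z = c(qx[, 3], 0, 0), charge = c(1.5, 1, -0.5, 1, 0, 0), radius = 1.5))
  gc_ <- plan_grid(cluster, cfg)
  sys <- rasterize(cluster, gc_, cfg)
  bd <- boundary_potential(sys, cfg)
  cfg_c <- solver_config(boundary = "coulombic")
  bc <- boundary_potential(sys, cfg_c)
  mask <- unclass(bc) != 0
  expect_lt(max(abs((unclass(bd)[mask] - unclass(bc)[mask]) /
                      unclass(bc)[mask])), 0.02)
})

test_that("solver reproduces Coulomb's law in a uniform dielectric", {
  cfg <- uniform_water(scale = 2)
  ion <- make_ion()
  g <- grid_spec(rep(-15, 3) + 0.05, 0.5, 61)
  pm <- solve_poisson(rasterize(ion, g, cfg), config = cfg)
  pts <- rbind(c(5, 1, 0.5), c(-6, 2, -1), c(0.5, -8, 3), c(4, 4, 4))
  r <- sqrt(rowSums(sweep(pts, 2, c(0.13, 0.21, -0.1))^2))
  phi <- interpolate_potential(pm, pts)
  expect_lt(max(abs(phi / (561.0 / (80 * r)) - 1)), 0.05)
})

test_that("solver is linear in the source charges", {
  cfg <- uniform_water(scale = 2)
  g <- grid_spec(rep(-10, 3), 0.5, 41)
  a <- make_ion(x = -2.3, y = 0.4, z = 0.2, charge = 1)
  b <- make_ion(x = 3.1, y = -0.7, z = 0.5, charge = -2)
  both <- combine_models(a, b)
  pa <- solve_poisson(rasterize(a, g, cfg, cavity = both), config = cfg)
  pb <- solve_poisson(rasterize(b, g, cfg, cavity = both), config = cfg)
  pab <- solve_poisson(rasterize(both, g, cfg, cavity = both), config = cfg)
  expect_equal(pab$values, pa$values + pb$values, tolerance = 5e-3)
})

test_that("zero charge with grounded boundary stays identically zero", {
  cfg <- solver_config(boundary = "zero")
  g <- grid_spec(rep(-5, 3), 0.5, 21)
  neutral <- make_ion(charge = 0)
  pm <- solve_poisson(rasterize(neutral, g, cfg), config = cfg)
  expect_equal(max(abs(pm$values)), 0)
})

test_that("mirror symmetry of the system reflects the potential exactly", {
  cfg <- solver_config(scale = 2)
  g <- grid_spec(rep(-8, 3), 0.5, 33)
  m <- mol_model(data.frame(serial = 1:2, name = "Q", resname = "ION",
                            resid = 1:2, chain = "A", x = c(-2, 3),
                            y = c(0.5, -0.5), z = 0, charge = c(1, -1),
                            radius = c(2, 1.5)))
  mirr <- m
  mirr$atoms$x <- -mirr$atoms$x
  p1 <- solve_poisson(rasterize(m, g, cfg), config = cfg)
  p2 <- solve_poisson(rasterize(mirr, g, cfg), config = cfg)
  expect_equal(p1$iterations, p2$iterations)
  expect_equal(p2$values, p1$values[g$dims[1]:1, , ], tolerance = 1e-9)
})

test_that("error against the Coulomb oracle shrinks with grid refinement", {
  ion <- make_ion()
  # near-field points, where charge spreading dominates the error
  pts <- rbind(c(2.5, 0.7, 0.3), c(-2, 1.5, 1), c(1, -2.5, 1.5),
               c(3.5, 1, -1))
  r <- sqrt(rowSums(sweep(pts, 2, c(0.13, 0.21, -0.1))^2))
  oracle <- 561.0 / (80 * r)
  errs <- vapply(c(1, 2, 4), function(sc) {
    cfg <- uniform_water(scale = sc)
    g <- grid_spec(rep(-12, 3), 1 / sc, 24 * sc + 1)
    pm <- solve_poisson(rasterize(ion, g, cfg), config = cfg)
    mean(abs(interpolate_potential(pm, pts) - oracle))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("non-convergence is reported with the residual", {
  cfg <- solver_config(max_iterations = 2)
  g <- grid_spec(rep(-10, 3), 0.5, 41)
  expect_error(solve_poisson(rasterize(make_ion(), g, cfg), config = cfg),
               "did not converge")
})

test_that("computational focusing reproduces the direct fine solve", {
  ion <- make_ion()
  cfg <- uniform_water(scale = 2)
  cfg_coarse <- uniform_water(scale = 1)
  gc_ <- grid_spec(rep(-25, 3), 1, 51)
  coarse <- solve_poisson(rasterize(ion, gc_, cfg_coarse), config = cfg_coarse)
  gf <- grid_spec(rep(-6, 3), 0.5, 25)
  fsys <- rasterize(ion, gf, cfg)
  focused <- focus_solve(fsys, coarse, cfg)
  direct <- solve_poisson(fsys, config = cfg)
  pts <- rbind(c(4, 1, 0), c(-3, -3, 2), c(0, 4, -3))
  expect_lt(max(abs(interpolate_potential(focused, pts) /
                      interpolate_potential(direct, pts) - 1)), 0.03)

  # fine grid equal to the coarse grid: boundary interpolation is the
  # identity, so the solution is the straight re-solve
  same <- focus_solve(rasterize(ion, gc_, cfg_coarse), coarse, cfg_coarse)
  expect_equal(same$values, coarse$values, tolerance = 1e-6)

  # containment is enforced
  gbig <- grid_spec(rep(-40, 3), 1, 101)
  expect_error(focus_solve(rasterize(ion, gbig, cfg, clip = TRUE), coarse),
               "not contained")
})

test_that("a focused far-field potential is insensitive to fine-box placement", {
  surf <- make_binding_surface(slab_dim = c(30, 30), seed = 1)
  cfg <- solver_config(scale = 1)
  coarse_grid <- plan_grid(surf, solver_config(scale = 0.5, perfil = 50))
  coarse_cfg <- solver_config(scale = 0.5, perfil = 50)
  coarse <- solve_poisson(rasterize(surf, coarse_grid, coarse_cfg),
                          config = coarse_cfg)
  site <- c(0, 0, 12)
  vals <- vapply(list(c(0, 0, 0), c(1.5, 0.5, -0.5), c(-1, 1, 1)),
                 function(off) {
    gf <- grid_spec(site - 6 + off, 1, 13)
    sol <- focus_solve(rasterize(surf, gf, cfg, clip = TRUE), coarse, cfg)
    interpolate_potential(sol, rbind(site))
  }, numeric(1))
  expect_lt(max(abs(vals / vals[1] - 1)), 0.05)
})

test_that("OpenDX export round-trips grid and values", {
  cfg <- uniform_water(scale = 1)
  g <- grid_spec(c(-4.5, -4, -3.5), 1, 9)
  pm <- solve_poisson(rasterize(make_ion(), g, cfg), config = cfg)
  tmp <- withr::local_tempfile(fileext = ".dx")
  write_dx(pm, tmp)
  back <- read_dx(tmp)
  expect_equal(back$grid$dims, g$dims)
  expect_equal(back$grid$origin, g$origin, tolerance = 1e-6)
  expect_equal(back$values, pm$values, tolerance = 1e-5)
})
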
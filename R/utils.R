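# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All stochastic generators route their
# randomness through this so that they are pure functions of their spec.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

# Trilinear interpolation of a 3D array `values` living on a regular grid
# (origin, spacing) at an n x 3 matrix of points. Points must lie inside
# the grid hull.
trilinear <- function(values, origin, spacing, points) {
  points <- rbind(points)
  dims <- dim(values)
  u <- sweep(points, 2, origin, "-") / spacing
  i0 <- floor(u)
  for (d in 1:3) {
    if (any(u[, d] < -1e-9 | u[, d] > dims[d] - 1 + 1e-9))
      stop("interpolation point outside grid")
    i0[, d] <- pmin(pmax(i0[, d], 0), dims[d] - 2)
  }
  f <- u - i0
  idx <- function(ox, oy, oz) {
    (i0[, 1] + ox) + dims[1] * ((i0[, 2] + oy) + dims[2] * (i0[, 3] + oz)) + 1
  }
  v <- values
  dim(v) <- NULL
  out <- v[idx(0, 0, 0)] * (1 - f[, 1]) * (1 - f[, 2]) * (1 - f[, 3]) +
    v[idx(1, 0, 0)] * f[, 1] * (1 - f[, 2]) * (1 - f[, 3]) +
    v[idx(0, 1, 0)] * (1 - f[, 1]) * f[, 2] * (1 - f[, 3]) +
    v[idx(1, 1, 0)] * f[, 1] * f[, 2] * (1 - f[, 3]) +
    v[idx(0, 0, 1)] * (1 - f[, 1]) * (1 - f[, 2]) * f[, 3] +
    v[idx(1, 0, 1)] * f[, 1] * (1 - f[, 2]) * f[, 3] +
    v[idx(0, 1, 1)] * (1 - f[, 1]) * f[, 2] * f[, 3] +
    v[idx(1, 1, 1)] * f[, 1] * f[, 2] * f[, 3]
  unname(out)
}

# Rotation matrices about the coordinate axes, angle in degrees.
rot_x <- function(deg) {
  a <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}
rot_y <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}
rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

# Rotation by `deg` degrees about an arbitrary unit axis (Rodrigues).
rot_axis <- function(axis, deg) {
  axis <- axis / sqrt(sum(axis^2))
  a <- deg * pi / 180
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}
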
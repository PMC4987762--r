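#' Segment angle at a residue
#'
#' The angle at the Calpha of residue `i` between the vector to the
#' Calpha of residue `i - window` and the vector to the Calpha of
#' residue `i + window`, in degrees in [0, 180]. Collinear segments
#' (an ideally straight chain) give 180 degrees.
#'
#' @param snapshot a `mol_model` with CA atoms.
#' @param i residue index (as in the source file).
#' @param window segment length in residues (default 10).
#' @param chain chain id (default: the first chain in the model).
#' @export
segment_angle <- function(snapshot, i, window = 10, chain = NULL) {
  if (window < 2) stop("window must be >= 2")
  ca <- snapshot$atoms[snapshot$atoms$name == "CA", , drop = FALSE]
  if (is.null(chain)) chain <- ca$chain[1]
  ca <- ca[ca$chain == chain, , drop = FALSE]
  pick <- function(res) {
    row <- ca[ca$resid == res, , drop = FALSE]
    if (nrow(row) != 1)
      stop("missing CA for residue ", res, " on chain ", chain)
    c(row$x, row$y, row$z)
  }
  v1 <- pick(i - window) - pick(i)
  v2 <- pick(i + window) - pick(i)
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

#' Hinge profile of a trajectory
#'
#' For each interior residue the population standard deviation of its
#' segment angle across snapshots. Flexible positions (hinges) show up
#' as peaks; the first and last `window` residues cannot be evaluated.
#' Hinge calls are the global argmax plus any local maxima above
#' `call_fraction` of the maximum deviation (so that two independent
#' hinges are both reported).
#'
#' @param traj a [mol_trajectory()] (>= 2 snapshots).
#' @param window segment length in residues.
#' @param call_fraction local maxima above this fraction of the peak
#'   deviation are called.
#' @param chain chain id (default first).
#' @return `hinge_profile`: data.frame of residue, mean and s.d. of the
#'   segment angle (degrees), plus `hinge_calls`.
#' @export
hinge_profile <- function(traj, window = 10, call_fraction = 0.8,
                          chain = NULL) {
  if (!inherits(traj, "mol_trajectory"))
    stop("traj must be a mol_trajectory")
  if (length(traj) < 2) stop("need at least two snapshots")
  ca0 <- traj$snapshots[[1]]$atoms
  ca0 <- ca0[ca0$name == "CA", , drop = FALSE]
  if (is.null(chain)) chain <- ca0$chain[1]
  resids <- sort(ca0$resid[ca0$chain == chain])
  residues <- resids[resids >= min(resids) + window &
                       resids <= max(resids) - window]
  angmat <- vapply(traj$snapshots, function(s) {
    ca <- s$atoms[s$atoms$name == "CA" & s$atoms$chain == chain, ,
                  drop = FALSE]
    ca <- ca[order(ca$resid), ]
    xyz <- unname(as.matrix(ca[c("x", "y", "z")]))
    pos <- match(residues, ca$resid)
    lo <- match(residues - window, ca$resid)
    hi <- match(residues + window, ca$resid)
    v1 <- xyz[lo, , drop = FALSE] - xyz[pos, , drop = FALSE]
    v2 <- xyz[hi, , drop = FALSE] - xyz[pos, , drop = FALSE]
    cosang <- rowSums(v1 * v2) /
      sqrt(rowSums(v1^2) * rowSums(v2^2))
    acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  }, numeric(length(residues)))
  m <- rowMeans(angmat)
  n <- ncol(angmat)
  s <- sqrt(rowMeans((angmat - m)^2))  # population s.d.
  peak <- max(s)
  is_local_max <- vapply(seq_along(s), function(k) {
    left <- if (k > 1) s[k - 1] else -Inf
    right <- if (k < length(s)) s[k + 1] else -Inf
    s[k] >= left && s[k] >= right
  }, logical(1))
  calls <- residues[is_local_max & s >= call_fraction * peak & s > 0]
  structure(list(profile = data.frame(residue = residues, mean_angle = m,
                                      angle_std = s),
                 hinge_calls = calls, window = window, n_snapshots = n),
            class = "hinge_profile")
}

#' @export
print.hinge_profile <- function(x, ...) {
  cat(sprintf(
    "<hinge_profile> %d residues over %d snapshots (window %d); hinges: %s\n",
    nrow(x$profile), x$n_snapshots, x$window,
    if (length(x$hinge_calls)) paste(x$hinge_calls, collapse = ", ")
    else "none"))
  invisible(x)
}

#' @export
plot.hinge_profile <- function(x, ...) {
  plot(x$profile$residue, x$profile$angle_std, type = "l",
       xlab = "residue", ylab = "segment-angle s.d. (deg)", ...)
  graphics::abline(v = x$hinge_calls, lty = 3)
  invisible(x)
}

#' Write a hinge profile as TSV (residue, mean deg, s.d. deg)
#' @param profile a [hinge_profile()].
#' @param path output file.
#' @export
write_hinge_profile <- function(profile, path) {
  write.table(format(profile$profile, digits = 8), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

acidic_oxygens <- function(atoms) {
  atoms[(atoms$resname == "ASP" & atoms$name %in% c("OD1", "OD2")) |
          (atoms$resname == "GLU" & atoms$name %in% c("OE1", "OE2")), ,
        drop = FALSE]
}

basic_nitrogens <- function(atoms, include_his = TRUE) {
  keep <- (atoms$resname == "LYS" & atoms$name == "NZ") |
    (atoms$resname == "ARG" & atoms$name %in% c("NE", "NH1", "NH2"))
  if (include_his)
    keep <- keep | (atoms$resname == "HIS" & atoms$name %in% c("ND1", "NE2"))
  atoms[keep, , drop = FALSE]
}

#' Find salt bridges between (or within) models
#'
#' A bridge is an acidic side-chain oxygen (Asp OD1/OD2, Glu OE1/OE2)
#' within `cutoff` Angstrom (inclusive) of a basic side-chain nitrogen
#' (Lys NZ, Arg NE/NH1/NH2, optionally His ND1/NE2). Reported per
#' residue pair with the minimum O-N distance.
#'
#' @param a,b `mol_model`s; with one model, bridges are searched within
#'   it, otherwise acidic atoms of each model are paired with basic
#'   atoms of the other.
#' @param cutoff Angstrom (default 4, the standard salt-bridge
#'   threshold).
#' @param include_his count histidine as basic.
#' @return data.frame: acidic chain/resid/resname, basic
#'   chain/resid/resname, distance.
#' @export
find_salt_bridges <- function(a, b = NULL, cutoff = 4, include_his = TRUE) {
  if (cutoff <= 0) stop("cutoff must be positive")
  pairs <- if (is.null(b)) list(list(acidic_oxygens(a$atoms),
                                     basic_nitrogens(a$atoms, include_his)))
  else list(list(acidic_oxygens(a$atoms), basic_nitrogens(b$atoms, include_his)),
            list(acidic_oxygens(b$atoms), basic_nitrogens(a$atoms, include_his)))
  rows <- list()
  for (p in pairs) {
    ox <- p[[1]]; ni <- p[[2]]
    if (!nrow(ox) || !nrow(ni)) next
    d <- sqrt(outer(ox$x, ni$x, "-")^2 + outer(ox$y, ni$y, "-")^2 +
                outer(ox$z, ni$z, "-")^2)
    okey <- paste(ox$chain, ox$resid)
    nkey <- paste(ni$chain, ni$resid)
    for (ok in unique(okey)) for (nk in unique(nkey)) {
      if (ok == nk) next
      dmin <- min(d[okey == ok, nkey == nk])
      if (dmin <= cutoff) {
        oi <- which(okey == ok)[1]
        nii <- which(nkey == nk)[1]
        rows[[length(rows) + 1L]] <- data.frame(
          acidic_chain = ox$chain[oi], acidic_resid = ox$resid[oi],
          acidic_resname = ox$resname[oi],
          basic_chain = ni$chain[nii], basic_resid = ni$resid[nii],
          basic_resname = ni$resname[nii], distance = dmin)
      }
    }
  }
  if (!length(rows))
    return(data.frame(acidic_chain = character(), acidic_resid = integer(),
                      acidic_resname = character(), basic_chain = character(),
                      basic_resid = integer(), basic_resname = character(),
                      distance = numeric()))
  out <- do.call(rbind, rows)
  out[!duplicated(out[c("acidic_chain", "acidic_resid", "basic_chain",
                        "basic_resid")]), ]
}

#' Salt-bridge occupancy over a trajectory
#'
#' Fraction of snapshots in which the given acidic/basic residue pair
#' satisfies the bridge criterion.
#'
#' @param traj a [mol_trajectory()].
#' @param acidic,basic `c(chain, resid)` identifying each residue.
#' @param cutoff Angstrom.
#' @param include_his count histidine as basic.
#' @return fraction in [0, 1].
#' @export
bridge_occupancy <- function(traj, acidic, basic, cutoff = 4,
                             include_his = TRUE) {
  a0 <- traj$snapshots[[1]]$atoms
  ok <- any(a0$chain == acidic[1] & a0$resid == as.integer(acidic[2])) &&
    any(a0$chain == basic[1] & a0$resid == as.integer(basic[2]))
  if (!ok) stop("pair not resolvable in the trajectory topology")
  hits <- vapply(traj$snapshots, function(s) {
    br <- find_salt_bridges(s, cutoff = cutoff, include_his = include_his)
    any(br$acidic_chain == acidic[1] & br$acidic_resid == as.integer(acidic[2]) &
          br$basic_chain == basic[1] & br$basic_resid == as.integer(basic[2]))
  }, logical(1))
  mean(hits)
}
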
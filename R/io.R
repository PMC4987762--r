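#' Read a structure file
#'
#' PDB fixed-width and PQR (charge/radius in the last two columns)
#' formats. Parsing is delegated to bio3d; free-whitespace PQR files
#' (which bio3d's fixed-width reader rejects) fall back to a tolerant
#' tokenizer. Only the first MODEL is returned; use [load_trajectory()]
#' for multi-model files.
#'
#' @param path file path.
#' @param format `"pdb"`, `"pqr"`, or `"auto"` (from the extension).
#' @return a [mol_model()]. PQR populates charge/radius; PDB leaves
#'   them 0.
#' @export
load_structure <- function(path, format = c("auto", "pdb", "pqr")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.pqr$", path, ignore.case = TRUE)) "pqr" else "pdb"
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "pqr") return(read_pqr_model(path))
  check_pdb_lines(path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  bio3d_to_model(pdb$atom, label = basename(path))
}

#' Read a multi-model PDB file as a trajectory
#'
#' @param path a PDB file with MODEL/ENDMDL blocks (one block is fine).
#' @export
load_trajectory <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  check_pdb_lines(path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  base <- bio3d_to_model(pdb$atom, label = basename(path))
  xyz <- pdb$xyz
  snaps <- lapply(seq_len(nrow(xyz)), function(i) {
    set_coords(base, matrix(xyz[i, ], ncol = 3, byrow = TRUE))
  })
  mol_trajectory(snaps)
}

# Light syntactic validation so that malformed coordinate records are
# reported with their line number instead of surfacing as a scan() error.
check_pdb_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grep("^(ATOM  |HETATM)", lines)
  for (ln in rec) {
    xyz <- suppressWarnings(as.numeric(c(substr(lines[ln], 31, 38),
                                         substr(lines[ln], 39, 46),
                                         substr(lines[ln], 47, 54))))
    if (anyNA(xyz))
      stop("malformed ATOM record at line ", ln, " of ", basename(path))
  }
  invisible(TRUE)
}

read_pqr_model <- function(path) {
  parsed <- tryCatch(suppressWarnings(bio3d::read.pqr(path, verbose = FALSE)),
                     error = function(e) NULL)
  if (!is.null(parsed)) {
    atom <- parsed$atom
    atom$charge <- atom$o
    atom$radius <- atom$b
    return(bio3d_to_model(atom, label = basename(path), keep_qr = TRUE))
  }
  # whitespace-delimited PQR
  lines <- readLines(path, warn = FALSE)
  rec <- grep("^(ATOM|HETATM)\\b", lines)
  if (!length(rec)) stop("no ATOM records in ", path)
  rows <- lapply(rec, function(ln) {
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    has_chain <- length(tok) >= 11
    if (length(tok) < 10)
      stop("malformed ATOM record at line ", ln, " of ", basename(path))
    num <- suppressWarnings(as.numeric(tok[(length(tok) - 4):length(tok)]))
    if (anyNA(num))
      stop("malformed ATOM record at line ", ln, " of ", basename(path))
    data.frame(serial = as.integer(tok[2]), name = tok[3], resname = tok[4],
               chain = if (has_chain) tok[5] else "A",
               resid = as.integer(tok[if (has_chain) 6 else 5]),
               x = num[1], y = num[2], z = num[3],
               charge = num[4], radius = num[5])
  })
  atoms <- do.call(rbind, rows)
  atoms$element <- substr(atoms$name, 1, 1)
  mol_model(atoms, label = basename(path))
}

bio3d_to_model <- function(atom, label = "", keep_qr = FALSE) {
  atoms <- data.frame(serial = atom$eleno, name = atom$elety,
                      element = atom$elesy %||% substr(atom$elety, 1, 1),
                      resname = atom$resid, resid = atom$resno,
                      chain = ifelse(is.na(atom$chain), "A", atom$chain),
                      x = atom$x, y = atom$y, z = atom$z,
                      charge = if (keep_qr) atom$charge else 0,
                      radius = if (keep_qr) atom$radius else 0)
  atoms$element[is.na(atoms$element)] <- ""
  mol_model(atoms, label = label)
}

#' Write a structure or trajectory
#'
#' PDB via bio3d (trajectories become MODEL/ENDMDL blocks); PQR carries
#' the charge and radius columns.
#'
#' @param x a [mol_model()] or [mol_trajectory()].
#' @param path output file.
#' @param format `"pdb"` or `"pqr"` (default from extension).
#' @export
save_structure <- function(x, path, format = c("auto", "pdb", "pqr")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.pqr$", path, ignore.case = TRUE)) "pqr" else "pdb"
  if (inherits(x, "mol_trajectory")) {
    if (format != "pdb") stop("trajectories are written as multi-model PDB")
    blocks <- vapply(seq_along(x$snapshots), function(i) {
      tmp <- tempfile(fileext = ".pdb")
      on.exit(unlink(tmp))
      write_one(x$snapshots[[i]], tmp, "pdb")
      body <- grep("^(ATOM|HETATM|TER)", readLines(tmp, warn = FALSE),
                   value = TRUE)
      paste(c(sprintf("MODEL     %4d", i), body, "ENDMDL"), collapse = "\n")
    }, character(1))
    writeLines(c(blocks, "END"), path)
    return(invisible(path))
  }
  write_one(x, path, format)
  invisible(path)
}

write_one <- function(model, path, format) {
  a <- model$atoms
  xyz <- as.numeric(t(as.matrix(a[c("x", "y", "z")])))
  if (max(abs(xyz)) > 9999.999)
    stop("coordinate exceeds the PDB fixed-width field (|x| > 9999.999)")
  if (format == "pdb") {
    bio3d::write.pdb(file = path, xyz = xyz, type = rep("ATOM", nrow(a)),
                     resno = a$resid, resid = a$resname, eleno = a$serial,
                     elety = a$name, chain = a$chain,
                     o = rep(1, nrow(a)), b = rep(0, nrow(a)))
  } else {
    bio3d::write.pqr(file = path, xyz = xyz,
                     resno = a$resid, resid = a$resname, eleno = a$serial,
                     elety = a$name, chain = a$chain,
                     o = a$charge, b = a$radius)
  }
}

#' Read rigid transforms from a whitespace-delimited table
#'
#' Each row holds 12 numbers: the rotation matrix in row-major order
#' followed by the translation vector, the layout used for deposited
#' filament-lattice matrices.
#' @param path file path.
#' @return list of [rigid_transform()].
#' @export
read_transforms <- function(path) {
  m <- as.matrix(read.table(path))
  if (ncol(m) != 12) stop("expected 12 numbers per row (9 rotation + 3 translation)")
  lapply(seq_len(nrow(m)), function(i) {
    rigid_transform(matrix(m[i, 1:9], 3, 3, byrow = TRUE), m[i, 10:12])
  })
}

#' OpenDX scalar-field export / import
#'
#' Writes a [potential map][solve_poisson()] as an OpenDX regular-grid
#' scalar field (the interchange format used by grid electrostatics
#' tools), and reads such files back.
#'
#' @param pmap a `potential_map`.
#' @param path output file.
#' @export
write_dx <- function(pmap, path) {
  g <- pmap$grid
  d <- g$dims
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# OpenDX scalar field (potential, kT/e)",
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.6f %.6f %.6f", g$origin[1], g$origin[2], g$origin[3]),
    sprintf("delta %.6f 0.000000 0.000000", g$spacing),
    sprintf("delta 0.000000 %.6f 0.000000", g$spacing),
    sprintf("delta 0.000000 0.000000 %.6f", g$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))), con)
  # DX stores with the last index varying fastest (z fastest)
  v <- aperm(pmap$values, c(3, 2, 1))
  vals <- sprintf("%.6e", as.numeric(v))
  pad <- (-length(vals)) %% 3
  if (pad) vals <- c(vals, rep("", pad))
  writeLines(apply(matrix(vals, ncol = 3, byrow = TRUE), 1, paste,
                   collapse = " "), con)
  writeLines(c('attribute "dep" string "positions"',
               'object "regular positions regular connections" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
  invisible(path)
}

#' @rdname write_dx
#' @export
read_dx <- function(path) {
  lines <- readLines(path, warn = FALSE)
  cline <- grep("class gridpositions counts", lines, value = TRUE)[1]
  dims <- as.integer(strsplit(sub(".*counts +", "", cline), "\\s+")[[1]])
  oline <- grep("^origin", lines, value = TRUE)[1]
  origin <- as.numeric(strsplit(trimws(sub("^origin", "", oline)), "\\s+")[[1]])
  dlines <- grep("^delta", lines, value = TRUE)
  deltas <- t(vapply(dlines, function(l)
    as.numeric(strsplit(trimws(sub("^delta", "", l)), "\\s+")[[1]]),
    numeric(3)))
  spacing <- max(deltas)
  start <- grep("data follows", lines)[1] + 1
  end <- grep("^attribute|^object \"", lines)
  end <- min(end[end > start]) - 1
  vals <- as.numeric(unlist(strsplit(trimws(lines[start:end]), "\\s+")))
  stopifnot(length(vals) == prod(dims))
  arr <- aperm(array(vals, dim = rev(dims)), c(3, 2, 1))
  structure(list(grid = grid_spec(origin, spacing, dims), values = arr,
                 iterations = NA_integer_, max_change = NA_real_),
            class = "potential_map")
}
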
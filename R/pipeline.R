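#' Run a declarative analysis pipeline
#'
#' Executes a staged configuration (a YAML file or an equivalent list):
#' each stage names one operation of the package and its parameters,
#' stages run in order, every referenced input must either exist on
#' disk or be produced by an earlier stage (checked before anything
#' runs), and a manifest of all outputs with checksums is written at
#' the end. The same config and seed reproduce identical outputs.
#'
#' Supported stages and their main parameters:
#' \describe{
#'   \item{simulate}{`kind` (probe / surface / hinged_trajectory /
#'     phenotype), `output`, plus the generator's arguments.}
#'   \item{map}{`probe`, `surface` (PQR paths), pose-window and solver
#'     parameters; writes the funnel map TSV and an argmin summary.}
#'   \item{force_scan}{`probe`, `surface`, `distances`; writes the
#'     force-distance TSV.}
#'   \item{work}{`scan` (a force_scan TSV); writes the work summary.}
#'   \item{hinge}{`trajectory` (multi-model PDB), `window`; writes the
#'     profile TSV and hinge calls.}
#'   \item{fit}{`data` (TSV with predictor/energy columns); writes the
#'     calibration coefficients.}
#'   \item{predict}{`fit` (a fit YAML), `energies`; writes predicted
#'     phenotypes.}
#' }
#'
#' @param config path to a YAML file or a list.
#' @param output_dir overrides `config$output_dir`.
#' @return (invisibly) the manifest: per-stage outputs with md5
#'   checksums.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  outdir <- output_dir %||% config$output_dir
  if (is.null(outdir)) stop("config must give an output_dir")
  seed <- config$seed %||% 1L
  stages <- config$stages
  if (!length(stages)) stop("config has no stages")

  # validate the dependency order before running anything
  input_keys <- c("probe", "surface", "trajectory", "scan", "data", "fit")
  planned <- character()
  for (s in stages) {
    nm <- s$stage %||% stop("every stage needs a 'stage' name")
    for (key in intersect(input_keys, names(s))) {
      p <- s[[key]]
      if (!file.exists(p) && !file.exists(file.path(outdir, p)) &&
          !(p %in% planned))
        stop("stage '", nm, "' references missing input: ", p)
    }
    if (!is.null(s$output)) planned <- c(planned, s$output)
    planned <- c(planned, paste0(s$name %||% nm, c(".tsv", ".yaml")))
  }

  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  resolve <- function(p) if (file.exists(p)) p else file.path(outdir, p)
  manifest <- list()
  for (k in seq_along(stages)) {
    s <- stages[[k]]
    nm <- s$stage
    label <- s$name %||% nm
    outputs <- tryCatch(
      run_stage(nm, s, outdir, resolve, seed + k),
      error = function(e) stop("stage '", label, "' failed: ",
                               conditionMessage(e), call. = FALSE))
    manifest[[label]] <- list(stage = nm,
                              parameters = s[setdiff(names(s),
                                                     c("stage", "name"))],
                              outputs = lapply(outputs, function(f)
                                list(file = basename(f),
                                     md5 = unname(tools::md5sum(f)))))
  }
  meta <- list(package = "efunnel",
               version = as.character(utils::packageVersion("efunnel")),
               seed = seed, stages = manifest)
  yaml::write_yaml(meta, file.path(outdir, "manifest.yaml"))
  invisible(meta)
}

take_args <- function(s, fn) {
  keep <- intersect(names(s), names(formals(fn)))
  s[keep]
}

write_tsv <- function(df, path) {
  write.table(format(df, digits = 10, trim = TRUE), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  path
}

run_stage <- function(nm, s, outdir, resolve, seed) {
  out <- function(f) file.path(outdir, f)
  switch(
    nm,
    simulate = {
      kind <- s$kind %||% stop("simulate needs a 'kind'")
      gen <- switch(kind,
                    probe = make_probe, surface = make_binding_surface,
                    hinged_trajectory = make_hinged_trajectory,
                    phenotype = make_phenotype_dataset,
                    stop("unknown simulate kind: ", kind))
      args <- take_args(s, gen)
      if (is.null(args$seed)) args$seed <- seed
      obj <- do.call(gen, args)
      dest <- out(s$output %||% paste0(kind, ".pqr"))
      if (inherits(obj, "mol_model")) {
        save_with_metadata(obj, dest)
        c(dest, paste0(dest, ".truth.yaml"))
      } else if (inherits(obj, "mol_trajectory")) {
        save_structure(obj, dest, format = "pdb")
        dest
      } else {
        write_tsv(obj, dest)
        dest
      }
    },
    map = {
      probe <- load_structure(resolve(s$probe), "pqr")
      surface <- load_structure(resolve(s$surface), "pqr")
      grid <- do.call(pose_grid, take_args(s, pose_grid))
      config <- do.call(solver_config, take_args(s, solver_config))
      frame <- planar_frame(contact_origin(probe, surface))
      map <- build_energy_map(probe, surface, grid, frame, config)
      f1 <- write_energy_map(map, out(paste0(s$name %||% "map", ".tsv")))
      f2 <- out(paste0(s$name %||% "map", ".yaml"))
      yaml::write_yaml(list(argmin = as.list(map$argmin),
                            min_energy_kT = min(map$values)), f2)
      c(f1, f2)
    },
    force_scan = {
      probe <- load_structure(resolve(s$probe), "pqr")
      surface <- load_structure(resolve(s$surface), "pqr")
      config <- do.call(solver_config, take_args(s, solver_config))
      scan <- separation_scan(surface, probe,
                              direction = unlist(s$direction %||% c(0, 0, 1)),
                              distances = unlist(s$distances %||%
                                                   seq(4, 20, 2)),
                              config = config)
      write_tsv(scan$table, out(paste0(s$name %||% "force_scan", ".tsv")))
    },
    work = {
      tab <- read.table(resolve(s$scan), header = TRUE, sep = "\t")
      scan <- scan_from_table(tab, unlist(s$direction %||% c(0, 0, 1)))
      w <- integrate_work(scan, method = s$method %||% "magnitude")
      f <- out(paste0(s$name %||% "work", ".yaml"))
      yaml::write_yaml(list(method = w$method,
                            per_source_pN_nm = as.list(w$per_source_pN_nm),
                            total_pN_nm = w$total_pN_nm,
                            total_kT = w$total_kT), f)
      f
    },
    hinge = {
      traj <- load_trajectory(resolve(s$trajectory))
      prof <- hinge_profile(traj, window = s$window %||% 10)
      f1 <- write_hinge_profile(prof, out(paste0(s$name %||% "hinge",
                                                 ".tsv")))
      f2 <- out(paste0(s$name %||% "hinge", ".yaml"))
      yaml::write_yaml(list(hinge_calls = as.integer(prof$hinge_calls)), f2)
      c(f1, f2)
    },
    fit = {
      tab <- read.table(resolve(s$data), header = TRUE, sep = "\t")
      fit <- fit_phenotype(tab$energy, tab$predictor,
                           phenotype_type = s$phenotype_type %||% "velocity",
                           conformation = s$conformation)
      f <- out(paste0(s$name %||% "fit", ".yaml"))
      yaml::write_yaml(list(slope = fit$slope, intercept = fit$intercept,
                            r = fit$r, phenotype = fit$phenotype,
                            conformation = fit$conformation), f)
      f
    },
    predict = {
      co <- yaml::read_yaml(resolve(s$fit))
      fit <- phenotype_fit_from_coefficients(co$slope, co$intercept, co$r,
                                             co$phenotype,
                                             co$conformation)
      energies <- unlist(s$energies)
      pred <- predict_phenotype(energies, fit)
      write_tsv(data.frame(energy_kT = energies, prediction = pred,
                           rounded = round_phenotype(pred, fit$phenotype)),
                out(paste0(s$name %||% "predict", ".tsv")))
    },
    stop("unknown stage: ", nm)
  )
}

# probe centre position at contact above the surface top (planar frames)
contact_origin <- function(probe, surface, gap = 1) {
  ctr <- colMeans(coords(probe))
  z_top <- max(surface$atoms$z + surface$atoms$radius)
  reach <- ctr[3] - min(probe$atoms$z - probe$atoms$radius)
  c(0, 0, z_top + reach + gap)
}

scan_from_table <- function(tab, direction) {
  direction <- direction / sqrt(sum(direction^2))
  distances <- sort(unique(tab$distance))
  forces <- lapply(distances, function(d) {
    sub <- tab[tab$distance == d, ]
    per <- lapply(seq_len(nrow(sub)), function(i)
      c(sub$Fx[i], sub$Fy[i], sub$Fz[i]))
    names(per) <- sub$source
    list(total = Reduce(`+`, per), per_source = per)
  })
  structure(list(distances = distances, forces = forces,
                 direction = direction, table = tab),
            class = "separation_scan")
}
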
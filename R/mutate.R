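#' Mutation specification
#'
#' Identifies one residue to neutralise by truncation to alanine.
#' @param residue_index residue number (as in the source file).
#' @param chain chain id.
#' @param from_residue expected current residue name (checked if given).
#' @export
mutation_spec <- function(residue_index, chain = "A", from_residue = NULL) {
  structure(list(residue_index = as.integer(residue_index), chain = chain,
                 from_residue = from_residue, to_residue = "ALA"),
            class = "mutation_spec")
}

#' @export
print.mutation_spec <- function(x, ...) {
  cat(sprintf("%s%d%s -> ALA\n", x$from_residue %||% "", x$residue_index,
              if (is.na(x$chain)) "" else paste0(" (chain ", x$chain, ")")))
  invisible(x)
}

#' Truncate a residue to alanine
#'
#' Side-chain atoms beyond Cbeta are removed and the remaining atoms
#' take standard alanine charges from the bundled parameter table; the
#' backbone geometry is untouched and no relaxation is attempted, so
#' the change is purely electrostatic. Glycine targets (no Cbeta) are
#' rejected. Applying the same mutation twice is idempotent.
#'
#' @param model a `mol_model`.
#' @param spec a [mutation_spec()] (or a residue index, with `chain`).
#' @param chain used when `spec` is a bare index.
#' @export
mutate_to_alanine <- function(model, spec, chain = "A") {
  if (!inherits(spec, "mutation_spec")) spec <- mutation_spec(spec, chain)
  a <- model$atoms
  sel <- a$chain == spec$chain & a$resid == spec$residue_index
  if (!any(sel)) stop("residue ", spec$residue_index, " (chain ", spec$chain,
                      ") not found")
  resname <- unique(a$resname[sel])
  if (!is.null(spec$from_residue) && !identical(resname, spec$from_residue))
    stop("residue ", spec$residue_index, " is ", resname, ", expected ",
         spec$from_residue)
  if (!any(a$name[sel] == "CB"))
    stop("residue ", spec$residue_index, " has no CB (glycine targets ",
         "cannot be truncated to alanine)")
  keep_names <- c("N", "CA", "C", "O", "CB", "OXT", "H", "HA")
  drop <- sel & !(a$name %in% keep_names)
  a <- a[!drop, , drop = FALSE]
  sel <- a$chain == spec$chain & a$resid == spec$residue_index
  a$resname[sel] <- "ALA"
  # only the side chain takes alanine parameters; the backbone keeps its
  # existing charges (the mutation is a pure side-chain neutralisation)
  tab <- default_parameter_table()
  cb <- sel & a$name == "CB"
  a$charge[cb] <- tab$charge[tab$resname == "ALA" & tab$name == "CB"]
  mol_model(a, label = paste0(model$label, " ", resname,
                              spec$residue_index, "A"))
}

#' Select acidic residues remote from a binding partner
#'
#' All Glu/Asp residues of `probe` whose every atom is farther than
#' `min_distance` from every atom of `partner` -- the residues whose
#' neutralisation probes long-range electrostatics without touching the
#' interface.
#'
#' @param probe,partner `mol_model`s in complex coordinates.
#' @param min_distance Angstrom (default 10).
#' @return list of [mutation_spec()]s.
#' @export
select_remote_acidics <- function(probe, partner, min_distance = 10) {
  a <- probe$atoms
  pxyz <- coords(partner)
  res <- unique(a[a$resname %in% c("GLU", "ASP"), c("chain", "resid",
                                                    "resname")])
  specs <- list()
  for (k in seq_len(nrow(res))) {
    sel <- a$chain == res$chain[k] & a$resid == res$resid[k]
    rxyz <- unname(as.matrix(a[sel, c("x", "y", "z")]))
    dmin <- min(vapply(seq_len(nrow(rxyz)), function(i)
      min(sqrt(colSums((t(pxyz) - rxyz[i, ])^2))), numeric(1)))
    if (dmin > min_distance)
      specs[[length(specs) + 1L]] <- mutation_spec(res$resid[k], res$chain[k],
                                                   res$resname[k])
  }
  specs
}

#' Ensemble-averaged electrostatic binding energy
#'
#' [binding_energy()] evaluated on each snapshot of a conformational
#' ensemble (a mutation, if given, is applied identically to the probe
#' part of every snapshot), summarised as mean +/- standard error of
#' the mean.
#'
#' @param snapshots list of `list(a = probe_model, b = partner_model)`
#'   complexes sharing one topology.
#' @param mutation optional [mutation_spec()] applied to the `a` part.
#' @param config a [solver_config()].
#' @param reaction_field passed to [binding_energy()]; FALSE restricts
#'   to the Coulombic component (exact in a uniform dielectric).
#' @return `ensemble_energy`: `mean`, `sem`, `n`, and the per-snapshot
#'   energies.
#' @export
ensemble_binding_energy <- function(snapshots, mutation = NULL,
                                    config = solver_config(),
                                    reaction_field = TRUE) {
  if (!length(snapshots)) stop("need at least one snapshot")
  ref <- snapshots[[1]]$a$atoms$name
  energies <- vapply(snapshots, function(s) {
    if (length(s$a$atoms$name) != length(ref))
      stop("snapshot topology mismatch")
    a <- if (is.null(mutation)) s$a else mutate_to_alanine(s$a, mutation)
    binding_energy(a, s$b, config, reaction_field = reaction_field)$delta_G
  }, numeric(1))
  n <- length(energies)
  structure(list(mean = mean(energies),
                 sem = if (n > 1) sd(energies) / sqrt(n) else 0,
                 n = n, energies = energies, mutation = mutation),
            class = "ensemble_energy")
}

#' @export
print.ensemble_energy <- function(x, ...) {
  cat(sprintf("ensemble binding energy: %.3f +/- %.3f kT (n = %d)\n",
              x$mean, x$sem, x$n))
  invisible(x)
}

#' Alanine scan over remote acidic residues
#'
#' Runs [ensemble_binding_energy()] for the wild type and for each
#' mutation, reporting mean binding energy, SEM and the change relative
#' to wild type.
#'
#' @inheritParams ensemble_binding_energy
#' @param mutations list of [mutation_spec()]s (e.g. from
#'   [select_remote_acidics()]).
#' @return data.frame: mutation label, mean delta_G (kT), sem, n,
#'   ddG_vs_wt.
#' @export
mutation_scan <- function(snapshots, mutations, config = solver_config(),
                          reaction_field = TRUE) {
  wt <- ensemble_binding_energy(snapshots, NULL, config, reaction_field)
  rows <- lapply(mutations, function(m) {
    e <- ensemble_binding_energy(snapshots, m, config, reaction_field)
    data.frame(mutation = paste0(m$from_residue %||% "X", m$residue_index,
                                 "A"),
               mean_dG = e$mean, sem = e$sem, n = e$n,
               ddG_vs_wt = e$mean - wt$mean)
  })
  out <- rbind(data.frame(mutation = "WT", mean_dG = wt$mean, sem = wt$sem,
                          n = wt$n, ddG_vs_wt = 0),
               do.call(rbind, rows))
  rownames(out) <- NULL
  out
}
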
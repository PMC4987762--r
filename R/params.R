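# Bundled per-atom charge/radius table for the 20 standard amino acids.
#
# This is a simplified heavy-atom set: hydrogen charges are absorbed into
# their bonded heavy atom so that structures without explicit hydrogens
# (Calpha traces, backbone-only or heavy-atom models) can be parameterised
# directly. The constraint the table honours -- and the one the energetics
# relies on -- is that every residue's charges sum to its formal charge
# at pH 7 (Arg/Lys +1, Asp/Glu -1, everything else 0). Radii are
# element-based van der Waals values.

.elem_radius <- c(C = 1.70, N = 1.55, O = 1.40, S = 1.85)

.backbone_charges <- c(N = -0.16, CA = 0.16, C = 0.51, O = -0.51)

.sidechain_charges <- list(
  ALA = c(CB = 0),
  ARG = c(CB = 0, CG = 0, CD = 0, NE = -0.24, CZ = 0.64,
          NH1 = 0.30, NH2 = 0.30),
  ASN = c(CB = 0.30, CG = 0.55, OD1 = -0.55, ND2 = -0.30),
  ASP = c(CB = 0, CG = 0.50, OD1 = -0.75, OD2 = -0.75),
  CYS = c(CB = 0.23, SG = -0.23),
  GLN = c(CB = 0, CG = 0.30, CD = 0.55, OE1 = -0.55, NE2 = -0.30),
  GLU = c(CB = 0, CG = 0, CD = 0.50, OE1 = -0.75, OE2 = -0.75),
  GLY = c(),
  HIS = c(CB = 0, CG = 0.25, ND1 = -0.40, CD2 = 0.10, CE1 = 0.25,
          NE2 = -0.20),
  ILE = c(CB = 0, CG1 = 0, CG2 = 0, CD1 = 0),
  LEU = c(CB = 0, CG = 0, CD1 = 0, CD2 = 0),
  LYS = c(CB = 0, CG = 0, CD = 0, CE = 0.21, NZ = 0.79),
  MET = c(CB = 0, CG = 0.12, SD = -0.24, CE = 0.12),
  PHE = c(CB = 0, CG = 0, CD1 = 0, CD2 = 0, CE1 = 0, CE2 = 0, CZ = 0),
  PRO = c(CB = 0, CG = 0, CD = 0),
  SER = c(CB = 0.35, OG = -0.35),
  THR = c(CB = 0.35, OG1 = -0.35, CG2 = 0),
  TRP = c(CB = 0, CG = 0, CD1 = 0.10, CD2 = 0, NE1 = -0.35,
          CE2 = 0.25, CE3 = 0, CZ2 = 0, CZ3 = 0, CH2 = 0),
  TYR = c(CB = 0, CG = 0, CD1 = 0, CD2 = 0, CE1 = 0, CE2 = 0,
          CZ = 0.35, OH = -0.35),
  VAL = c(CB = 0, CG1 = 0, CG2 = 0)
)

#' Bundled amino-acid charge/radius lookup
#'
#' Returns the package's parameter table: one row per (residue, atom)
#' pair for the 20 standard amino acids, heavy atoms only, with hydrogen
#' charges absorbed into their bonded heavy atom. Per-residue charges
#' sum to the residue's formal charge at pH 7.
#'
#' @return data.frame with columns `resname`, `name`, `charge`, `radius`.
#' @export
default_parameter_table <- function() {
  rows <- lapply(names(.sidechain_charges), function(res) {
    q <- c(.backbone_charges, .sidechain_charges[[res]])
    el <- substr(names(q), 1, 1)
    el[!el %in% names(.elem_radius)] <- "C"
    data.frame(resname = res, name = names(q), charge = unname(q),
               radius = unname(.elem_radius[el]))
  })
  do.call(rbind, rows)
}

#' Assign partial charges and radii from a parameter table
#'
#' Looks every atom up by (residue name, atom name). In strict mode
#' (default) any unmatched atom is an error, because silently zeroed
#' charges corrupt every downstream energy; in lenient mode unmatched
#' atoms get charge 0 / radius 1.5 with a warning. Reassignment is
#' idempotent. Synthetic models built by the package carry explicit
#' charges and radii and do not need this step.
#'
#' @param model a [mol_model()].
#' @param table lookup with columns `resname`, `name`, `charge`,
#'   `radius`; defaults to [default_parameter_table()].
#' @param strict error (TRUE) or default-and-warn (FALSE) on unmatched
#'   atoms.
#' @export
assign_parameters <- function(model, table = default_parameter_table(),
                              strict = TRUE) {
  key <- paste(model$atoms$resname, model$atoms$name)
  hit <- match(key, paste(table$resname, table$name))
  if (anyNA(hit)) {
    offenders <- unique(key[is.na(hit)])
    if (strict)
      stop("no parameters for atom(s): ", paste(offenders, collapse = ", "),
           " (use strict = FALSE to default them)")
    warning("defaulting unmatched atom(s) to charge 0, radius 1.5: ",
            paste(offenders, collapse = ", "))
  }
  model$atoms$charge <- ifelse(is.na(hit), 0, table$charge[hit])
  model$atoms$radius <- ifelse(is.na(hit), 1.5, table$radius[hit])
  model
}
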
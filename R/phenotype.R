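#' Linear energy-phenotype calibration
#'
#' Ordinary least squares with the electrostatic binding energy as the
#' response: `energy = slope * phenotype + intercept` (the orientation
#' in which motility calibrations are tabulated). Phenotypes are
#' single-molecule velocity (nm/s) or run length (um). The fit is done
#' with `lm()`; the Pearson correlation is reported alongside.
#'
#' @param energy binding energies, kT.
#' @param phenotype phenotype values (velocity nm/s or run length um).
#' @param phenotype_type `"velocity"` or `"run_length"`.
#' @param conformation optional `"high"` or `"low"` affinity label;
#'   enables the calibrated-range warning in [predict_phenotype()].
#' @return S3 object `phenotype_fit` with `slope`, `intercept`, `r`.
#' @export
fit_phenotype <- function(energy, phenotype,
                          phenotype_type = c("velocity", "run_length"),
                          conformation = NULL) {
  phenotype_type <- match.arg(phenotype_type)
  if (length(energy) != length(phenotype))
    stop("energy and phenotype lengths differ")
  if (length(energy) < 3) stop("need at least 3 observations")
  if (sd(phenotype) == 0) stop("degenerate (constant) predictor")
  fit <- lm(energy ~ phenotype)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r = cor(phenotype, energy),
                 phenotype = phenotype_type,
                 conformation = conformation,
                 lm = fit, n = length(energy)),
            class = "phenotype_fit")
}

#' @export
print.phenotype_fit <- function(x, ...) {
  unit <- if (x$phenotype == "velocity") "kT s/nm" else "kT/um"
  cat(sprintf("energy = %.4g %s * %s %+.4g kT   (R = %.3f, n = %d%s)\n",
              x$slope, unit, x$phenotype, x$intercept, x$r, x$n,
              if (!is.null(x$conformation))
                paste0(", ", x$conformation, "-affinity") else ""))
  invisible(x)
}

#' @export
coef.phenotype_fit <- function(object, ...) {
  c(slope = object$slope, intercept = object$intercept)
}

#' Construct a fit from tabulated coefficients
#'
#' For reusing published calibration coefficients without the raw data.
#' @param slope,intercept coefficients of `energy = slope * phenotype +
#'   intercept`.
#' @param r correlation coefficient (optional, for the record).
#' @inheritParams fit_phenotype
#' @export
phenotype_fit_from_coefficients <- function(slope, intercept, r = NA,
                                            phenotype_type = c("velocity",
                                                               "run_length"),
                                            conformation = NULL) {
  phenotype_type <- match.arg(phenotype_type)
  structure(list(slope = slope, intercept = intercept, r = r,
                 phenotype = phenotype_type, conformation = conformation,
                 lm = NULL, n = NA_integer_),
            class = "phenotype_fit")
}

# calibrated energy ranges (kT) within which the linear relation holds
.linear_range <- list(high = c(-35, -15), low = c(-25, -5))

#' Predict a phenotype from a binding energy
#'
#' Inverts the calibration algebraically:
#' `phenotype = (energy - intercept) / slope`. Energies outside the
#' calibrated linear range for the fit's conformation (high-affinity
#' -35..-15 kT, low-affinity -25..-5 kT) are predicted anyway but
#' flagged with a warning. With `round = TRUE` the reporting convention
#' is applied: velocity to the nearest integer nm/s, run length to one
#' decimal um (two significant figures below 1 um).
#'
#' @param energy binding energy (kT), vectorised.
#' @param fit a [fit_phenotype()] or
#'   [phenotype_fit_from_coefficients()] object.
#' @param round apply the reporting rounding convention.
#' @export
predict_phenotype <- function(energy, fit, round = FALSE) {
  if (!inherits(fit, "phenotype_fit")) stop("fit must be a phenotype_fit")
  if (fit$slope == 0) stop("zero slope: calibration cannot be inverted")
  if (!is.null(fit$conformation)) {
    rng <- .linear_range[[fit$conformation]]
    if (!is.null(rng) && any(energy < rng[1] | energy > rng[2]))
      warning(sprintf(
        "energy outside the calibrated %s-affinity linear range (%g..%g kT)",
        fit$conformation, rng[1], rng[2]))
  }
  value <- (energy - fit$intercept) / fit$slope
  if (round) round_phenotype(value, fit$phenotype) else value
}

#' @export
#' @param object a `phenotype_fit`.
#' @param energy energies (kT) at which to predict.
#' @param ... unused.
#' @rdname predict_phenotype
predict.phenotype_fit <- function(object, energy, ...) {
  predict_phenotype(energy, object)
}

#' @rdname predict_phenotype
#' @param value phenotype value(s).
#' @param type `"velocity"` or `"run_length"`.
#' @export
round_phenotype <- function(value, type = c("velocity", "run_length")) {
  type <- match.arg(type)
  if (type == "velocity") round(value)
  else ifelse(abs(value) < 1, signif(value, 2), round(value, 1))
}

#' Average high- and low-affinity predictions
#'
#' The arithmetic mean of the per-conformation predicted phenotypes,
#' the convention used when one number per mutant is reported.
#'
#' @param high,low numeric vectors (or lists with `velocity` /
#'   `run_length` elements) of per-conformation predictions.
#' @export
average_predictions <- function(high, low) {
  if (is.numeric(high) && is.numeric(low)) return((high + low) / 2)
  if (is.list(high) && is.list(low)) {
    keys <- union(names(high), names(low))
    if (!all(keys %in% names(high)) || !all(keys %in% names(low)))
      stop("both conformations must supply the same phenotypes")
    return(setNames(lapply(keys, function(k) (high[[k]] + low[[k]]) / 2),
                    keys))
  }
  stop("both conformations must be present (numeric or named lists)")
}
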
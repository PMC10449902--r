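#' Fit the SEC molecular-weight calibration curve
#'
#' Least-squares regression of log10(molecular weight) on apex fraction for
#' a set of calibration standards (a commercial protein mixture can be
#' supplemented with a purified large species such as a 70S ribosome to
#' extend the curve towards the void volume). Log-linear mapping is the SEC
#' convention: elution volume is linear in the log of the hydrodynamic
#' size over the column's resolving range.
#'
#' @param standards Tibble with columns `name`, `mw_da`, `apex_fraction`
#'   (see [read_calibration_standards()]).
#' @return An object of class `cf_calibration`: `slope` (log10 Da per
#'   fraction, negative — earlier fractions hold larger species),
#'   `intercept` (log10 Da), `valid_fraction_range`, `fit_r2`, and the
#'   standards with fitted residuals.
#' @export
fit_calibration <- function(standards) {
  if (nrow(standards) < 2) {
    stop("fit error: need at least 2 calibration standards", call. = FALSE)
  }
  if (length(unique(standards$apex_fraction)) < 2) {
    stop("fit error: standards have coincident apex fractions", call. = FALSE)
  }
  fit <- stats::lm(log10(mw_da) ~ apex_fraction, data = standards)
  slope <- unname(stats::coef(fit)[2])
  r2 <- if (nrow(standards) == 2) 1 else summary(fit)$r.squared
  out <- list(
    slope = slope,
    intercept = unname(stats::coef(fit)[1]),
    valid_fraction_range = range(standards$apex_fraction),
    fit_r2 = r2,
    standards = dplyr::mutate(
      standards,
      fitted_log10_mw = unname(stats::fitted(fit)),
      residual = log10(.data$mw_da) - unname(stats::fitted(fit))
    )
  )
  if (slope >= 0) {
    warning("calibration slope is non-negative; earlier fractions should ",
            "hold larger species", call. = FALSE)
  }
  class(out) <- "cf_calibration"
  out
}

#' @export
print.cf_calibration <- function(x, ...) {
  cat("SEC calibration: log10(MW Da) =", format(x$intercept, digits = 4),
      if (x$slope < 0) "-" else "+", format(abs(x$slope), digits = 4),
      "* fraction\n")
  cat("  standards:", nrow(x$standards),
      " valid fractions:", format(x$valid_fraction_range, digits = 4),
      " fit r2:", format(x$fit_r2, digits = 4), "\n")
  invisible(x)
}

#' Apparent molecular weight of an elution position
#'
#' Evaluates the calibration curve at one or more apex fractions. Queries
#' outside the fraction range spanned by the standards are extrapolated
#' (SEC estimates beyond the external calibration curve carry extra error)
#' and flagged.
#'
#' @param apex_fraction Numeric vector of apex fractions, or a peak tibble
#'   from [detect_peaks()].
#' @param curve A `cf_calibration` fit.
#' @return For a numeric input, a tibble `apex_fraction`, `apparent_mw_da`,
#'   `extrapolated`; for a peak tibble, the same columns appended.
#' @export
apparent_mw <- function(apex_fraction, curve) {
  stopifnot(inherits(curve, "cf_calibration"))
  peaks <- NULL
  if (is.data.frame(apex_fraction)) {
    peaks <- apex_fraction
    apex_fraction <- peaks$apex_fraction
  }
  mw <- 10^(curve$slope * apex_fraction + curve$intercept)
  extra <- apex_fraction < curve$valid_fraction_range[1] |
    apex_fraction > curve$valid_fraction_range[2]
  if (is.null(peaks)) {
    tibble::tibble(apex_fraction = apex_fraction, apparent_mw_da = mw,
                   extrapolated = extra)
  } else {
    peaks$apparent_mw_da <- mw
    peaks$extrapolated <- extra
    peaks
  }
}

# Average residue masses from elemental composition (C 12.0107, H 1.00794,
# N 14.0067, O 15.9994, S 32.065); a peptide bond releases one water, so a
# chain is the residue-mass sum plus one water (18.01528 Da).
residue_mass_table <- function() {
  el <- c(C = 12.0107, H = 1.00794, N = 14.0067, O = 15.9994, S = 32.065)
  comp <- list(
    G = c(C = 2, H = 3, N = 1, O = 1), A = c(C = 3, H = 5, N = 1, O = 1),
    S = c(C = 3, H = 5, N = 1, O = 2), P = c(C = 5, H = 7, N = 1, O = 1),
    V = c(C = 5, H = 9, N = 1, O = 1), T = c(C = 4, H = 7, N = 1, O = 2),
    C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
    L = c(C = 6, H = 11, N = 1, O = 1), I = c(C = 6, H = 11, N = 1, O = 1),
    N = c(C = 4, H = 6, N = 2, O = 2), D = c(C = 4, H = 5, N = 1, O = 3),
    Q = c(C = 5, H = 8, N = 2, O = 2), K = c(C = 6, H = 12, N = 2, O = 1),
    E = c(C = 5, H = 7, N = 1, O = 3),
    M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
    H = c(C = 6, H = 7, N = 3, O = 1), F = c(C = 9, H = 9, N = 1, O = 1),
    R = c(C = 6, H = 12, N = 4, O = 1), Y = c(C = 9, H = 9, N = 1, O = 2),
    W = c(C = 11, H = 10, N = 2, O = 1)
  )
  vapply(comp, function(cc) sum(el[names(cc)] * cc), 0)
}

WATER_MASS_DA <- 18.01528

#' Monomeric mass of a protein sequence
#'
#' Average (not monoisotopic) molecular mass: the sum of average residue
#' masses plus one water.
#'
#' @param sequence Character vector of one-letter amino-acid sequences.
#' @return Numeric vector of masses in Da.
#' @examples
#' monomeric_mass("GG")  # 132.118 Da
#' @export
monomeric_mass <- function(sequence) {
  tab <- residue_mass_table()
  vapply(sequence, function(s) {
    aa <- strsplit(toupper(s), "")[[1]]
    bad <- which(!aa %in% names(tab))
    if (length(bad) > 0) {
      stop("unknown residue '", aa[bad[1]], "' at position ", bad[1],
           call. = FALSE)
    }
    sum(tab[aa]) + WATER_MASS_DA
  }, 0, USE.NAMES = FALSE)
}

#' Classify peaks as monomeric or assembled
#'
#' A peak is called `assembled` when its apparent molecular weight is at
#' least twice the protein's monomeric mass (boundary inclusive); the
#' protein-level summary is `assembled` if any of its peaks is.
#'
#' @param peaks Peak tibble with `apparent_mw_da` (see [apparent_mw()]) and
#'   a `protein_id` column, or a numeric vector of apparent MWs.
#' @param monomer_mw Monomeric mass in Da: a single value, or a named
#'   vector indexed by `protein_id`.
#' @param ratio Assembled threshold as a multiple of the monomer mass
#'   (default 2).
#' @return For a peak tibble: the tibble with a `state` column plus a
#'   `protein_summary` attribute (tibble `protein_id`, `state`); for a
#'   numeric vector, a character vector of states.
#' @export
assembly_state <- function(peaks, monomer_mw, ratio = 2) {
  if (is.numeric(peaks)) {
    return(ifelse(peaks >= ratio * monomer_mw, "assembled", "monomeric"))
  }
  mm <- if (length(monomer_mw) == 1 && is.null(names(monomer_mw))) {
    rep(monomer_mw, nrow(peaks))
  } else {
    unname(monomer_mw[peaks$protein_id])
  }
  peaks$state <- ifelse(peaks$apparent_mw_da >= ratio * mm,
                        "assembled", "monomeric")
  summ <- dplyr::summarise(
    dplyr::group_by(peaks, .data$protein_id),
    state = if (any(.data$state == "assembled")) "assembled" else "monomeric",
    .groups = "drop"
  )
  attr(peaks, "protein_summary") <- summ
  peaks
}
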
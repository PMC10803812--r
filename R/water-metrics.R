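#' Fraction of cells that are intact (ICC/TCC)
#'
#' Flow cytometry distinguishes intact cell counts (ICC, membrane-intact
#' cells) from total cell counts (TCC). Their ratio is a standard viability
#' indicator in drinking water; in chloraminated systems it rises as
#' disinfectant residual decays.
#'
#' @param icc intact cell count (cells/mL bulk or cells/cm2 biofilm)
#' @param tcc total cell count, same units as \code{icc}
#' @return fraction in [0, 1]; vectorized
#' @examples
#' intactFraction(2.2e4, 3.9e4)  # ~0.56
#' @export
intactFraction <- function(icc, tcc) {
  if (any(!is.finite(icc)) || any(!is.finite(tcc))) {
    stop("icc and tcc must be finite")
  }
  if (any(tcc <= 0)) stop("intact fraction undefined: tcc must be > 0")
  if (any(icc < 0)) stop("icc out of range: must be >= 0")
  if (any(icc > tcc)) stop("icc out of range: exceeds tcc")
  icc / tcc
}

#' Fraction of ATP that is intracellular (ATPi/ATPt)
#'
#' Total ATP splits into an intracellular (cell-bound) and an extracellular
#' pool; the intracellular fraction tracks the share of biomass-associated
#' activity.
#'
#' @param atpi intracellular ATP (nM)
#' @param atpt total ATP (nM)
#' @return fraction in [0, 1]; vectorized
#' @examples
#' intracellularAtpFraction(3.8e-2, 4.4e-2)  # ~0.86
#' @export
intracellularAtpFraction <- function(atpi, atpt) {
  if (any(!is.finite(atpi)) || any(!is.finite(atpt))) {
    stop("atpi and atpt must be finite")
  }
  if (any(atpt <= 0)) stop("ATP fraction undefined: atpt must be > 0")
  if (any(atpi < 0)) stop("atpi out of range: must be >= 0")
  if (any(atpi > atpt)) {
    stop("atpi out of range: exceeds atpt (clamp via extracellularAtp first)")
  }
  atpi / atpt
}

#' Extracellular ATP (ATPe = ATPt - ATPi), clamped at zero
#'
#' Because ATPi and ATPt are measured on separate triplicates, noise can
#' drive the difference slightly negative; such values are clamped to zero
#' and flagged via the \code{"clamped"} attribute rather than treated as an
#' error.
#'
#' @param atpt total ATP (nM)
#' @param atpi intracellular ATP (nM)
#' @return non-negative nM values with logical attribute \code{clamped}
#' @examples
#' extracellularAtp(4.4e-2, 3.8e-2)  # 6e-3
#' @export
extracellularAtp <- function(atpt, atpi) {
  if (any(atpt < 0) || any(atpi < 0)) {
    stop("ATP concentrations out of range: must be >= 0")
  }
  d <- atpt - atpi
  clamped <- d < 0
  d[clamped] <- 0
  attr(d, "clamped") <- clamped
  d
}

#' ATP per intact cell
#'
#' Converts a bulk intracellular ATP concentration (nM = nmol/L) and an
#' intact cell concentration (cells/mL) into nmol of ATP per intact cell, a
#' per-cell activity proxy.
#'
#' @param atpi intracellular ATP (nM)
#' @param icc intact cell count (cells/mL)
#' @return nmol ATP per intact cell
#' @examples
#' atpPerIntactCell(7.5e-3, 2.2e4)  # ~3.4e-10 nmol/cell
#' @export
atpPerIntactCell <- function(atpi, icc) {
  if (any(icc <= 0)) stop("ATP per cell undefined: icc must be > 0")
  if (any(atpi < 0)) stop("atpi out of range: must be >= 0")
  # nM is nmol/L; icc cells/mL -> icc * 1000 cells/L
  atpi / (icc * 1000)
}

#' Biofilm share of the whole-reactor cell pool
#'
#' Fraction of cells residing in the wall biofilm relative to the whole
#' reactor (bulk + biofilm): \eqn{C_{BF} A / (C_{BF} A + C_{AR} V)}.
#'
#' @param c_bf areal biofilm concentration (cells/cm2)
#' @param area_cm2 colonizable biofilm area A (cm2)
#' @param c_ar bulk concentration (cells/mL)
#' @param volume_ml bulk volume V (mL)
#' @return fraction in [0, 1]
#' @export
biofilmFractionOfWhole <- function(c_bf, area_cm2, c_ar, volume_ml) {
  if (any(c(c_bf, area_cm2, c_ar, volume_ml) < 0)) {
    stop("inputs out of range: must be >= 0")
  }
  bf <- c_bf * area_cm2
  bulk <- c_ar * volume_ml
  if (any(bf + bulk <= 0)) {
    stop("biofilm fraction undefined: both pools are zero")
  }
  bf / (bf + bulk)
}

#' Hydraulic residence time
#'
#' Mean time water spends in a vessel, V/Q, reported in hours.
#'
#' @param volume_ml vessel volume (mL)
#' @param flow_ml_min flow (mL/min)
#' @return residence time in hours
#' @examples
#' hydraulicResidenceTime(10000, 150)  # 10 L reservoir at 150 mL/min, ~1 h
#' hydraulicResidenceTime(1008, 2.1)   # reactor, 8 h
#' @export
hydraulicResidenceTime <- function(volume_ml, flow_ml_min) {
  if (any(flow_ml_min <= 0)) stop("flow must be > 0")
  if (any(volume_ml < 0)) stop("volume out of range: must be >= 0")
  volume_ml / flow_ml_min / 60
}

#' Geometric mean and geometric coefficient of variation
#'
#' Cell counts and ATP span orders of magnitude and are summarized
#' geometrically: geomean = exp(mean(ln x)); the geometric coefficient of
#' variation (gCV) is the geometric standard deviation minus one, with the
#' sample (n-1) convention for the SD of the ln-values. Zeros and negatives
#' are rejected rather than substituted; callers wanting an LoQ/2
#' substitution must apply it explicitly.
#'
#' @param values strictly positive numeric vector
#' @return list with elements \code{geomean} and \code{gcv} (gCV is NA for
#'   a single value)
#' @examples
#' geometricSummary(c(10, 1000))$geomean  # 100
#' @export
geometricSummary <- function(values) {
  if (length(values) < 1L) stop("need at least one value")
  if (anyNA(values) || any(!is.finite(values))) {
    stop("values must be finite and non-missing")
  }
  if (any(values <= 0)) {
    stop("geometric summary undefined for values <= 0; pre-filter or substitute explicitly")
  }
  lx <- log(values)
  gcv <- if (length(lx) > 1L) exp(stats::sd(lx)) - 1 else NA_real_
  list(geomean = exp(mean(lx)), gcv = gcv)
}

#' Kendall's tau-b rank correlation
#'
#' Rank correlation with tie correction (tau-b), appropriate for
#' water-quality series with many tied values. Thin wrapper over
#' \code{stats::cor(method = "kendall")}, which applies the tie-corrected
#' denominator.
#'
#' @param x,y numeric vectors of equal length >= 2
#' @return tau-b in [-1, 1]
#' @export
kendallTauB <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("need at least two observations")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    stop("tau-b undefined: all values tied in one argument")
  }
  suppressWarnings(stats::cor(x, y, method = "kendall"))
}

#' Phase-level ratio of two measured series
#'
#' Two defensible conventions exist for a phase-average ratio such as
#' ICC/TCC: the ratio of geometric means (equal to the geometric mean of
#' per-sample ratios) and the arithmetic mean of per-sample ratios. The two
#' can differ by a few percent on skewed data, so both are exposed and the
#' choice is explicit.
#'
#' @param num,den positive numeric vectors of equal length (e.g. ICC and TCC)
#' @param method \code{"geometric"} (ratio of geometric means) or
#'   \code{"arithmetic"} (mean of per-sample ratios)
#' @return a single fraction
#' @export
phaseRatio <- function(num, den, method = c("geometric", "arithmetic")) {
  method <- match.arg(method)
  if (length(num) != length(den)) stop("num and den must have equal length")
  if (method == "geometric") {
    geometricSummary(num)$geomean / geometricSummary(den)$geomean
  } else {
    mean(num / den)
  }
}
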
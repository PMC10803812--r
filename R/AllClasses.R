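#' @import methods
NULL

#' Physical configuration of a bench-scale reactor and its imaging geometry
#'
#' Holds the constants entering the cell number balances (bulk volume
#' \eqn{V}, influent flow \eqn{Q}, colonizable biofilm area \eqn{A}) and the
#' voxel geometry of the confocal imaging (in-plane pixel size, z-slice
#' interval, frame side). Defaults describe the study system: a 1008 mL
#' annular reactor fed at 2.1 mL/min (8 h hydraulic residence time), with
#' 1024 x 1024 px frames spanning 212.5 x 212.5 um and 1 um z steps. The
#' bulk volume default is derived as Q x HRT = 2.1 mL/min x 480 min; the
#' colonizable area default (190 cm2) is a synthetic stand-in that must be
#' supplied explicitly for real coupon geometries.
#'
#' @slot volume_ml bulk water volume V (mL)
#' @slot flow_ml_min influent flow Q (mL/min)
#' @slot biofilm_area_cm2 colonizable biofilm area A (cm2)
#' @slot pixel_um in-plane pixel size (um)
#' @slot slice_um z-slice interval (um)
#' @slot frame_um imaging frame side (um)
#' @slot frame_px pixels per frame side
#' @name ReactorConfig-class
#' @aliases ReactorConfig-class
#' @exportClass ReactorConfig
setClass("ReactorConfig",
  representation(
    volume_ml = "numeric",
    flow_ml_min = "numeric",
    biofilm_area_cm2 = "numeric",
    pixel_um = "numeric",
    slice_um = "numeric",
    frame_um = "numeric",
    frame_px = "numeric"
  )
)

setValidity("ReactorConfig", function(object) {
  vals <- c(
    volume_ml = object@volume_ml, flow_ml_min = object@flow_ml_min,
    biofilm_area_cm2 = object@biofilm_area_cm2, pixel_um = object@pixel_um,
    slice_um = object@slice_um, frame_um = object@frame_um,
    frame_px = object@frame_px
  )
  if (length(vals) != 7L || anyNA(vals) || any(!is.finite(vals))) {
    return("all configuration fields must be single finite numbers")
  }
  if (any(vals <= 0)) {
    return("all configuration fields must be strictly positive")
  }
  # pixel grid must tile the stated frame side
  rel <- abs(object@frame_px * object@pixel_um - object@frame_um) / object@frame_um
  if (rel > 0.001) {
    return("frame_px * pixel_um must equal frame_um within 0.1%")
  }
  TRUE
})

#' Construct a ReactorConfig
#'
#' @param volume_ml bulk volume V (mL); default 1008 (Q x 8 h HRT)
#' @param flow_ml_min influent flow Q (mL/min); default 2.1
#' @param biofilm_area_cm2 colonizable biofilm area A (cm2); default 190
#'   (synthetic stand-in, supply the real coupon area for real data)
#' @param pixel_um in-plane pixel size (um); default 212.5/1024
#' @param slice_um z interval (um); default 1
#' @param frame_um frame side (um); default 212.5
#' @param frame_px pixels per side; default 1024
#' @return a validated \code{ReactorConfig}
#' @examples
#' cfg <- ReactorConfig()
#' hydraulicResidenceTime(volumeMl(cfg), flowMlMin(cfg))  # ~8 h
#' @export
ReactorConfig <- function(volume_ml = 1008, flow_ml_min = 2.1,
                          biofilm_area_cm2 = 190,
                          pixel_um = 212.5 / 1024, slice_um = 1,
                          frame_um = 212.5, frame_px = 1024) {
  new("ReactorConfig",
    volume_ml = as.numeric(volume_ml),
    flow_ml_min = as.numeric(flow_ml_min),
    biofilm_area_cm2 = as.numeric(biofilm_area_cm2),
    pixel_um = as.numeric(pixel_um), slice_um = as.numeric(slice_um),
    frame_um = as.numeric(frame_um), frame_px = as.numeric(frame_px)
  )
}

#' Three-channel confocal z-stack
#'
#' Voxel intensities on an 8-bit scale, indexed (channel, z, y, x) with z = 1
#' at the substrate. Channel order is fixed: nucleic-acid stain (syto9),
#' protein stain (sypro_orange), polysaccharide stain (cona).
#'
#' @slot intensities 4-D numeric array (channel, z, y, x), values in 0..255
#' @slot channels character vector of the three channel names
#' @slot pixel_um in-plane pixel size (um)
#' @slot slice_um z interval (um)
#' @name ZStack-class
#' @aliases ZStack-class
#' @exportClass ZStack
setClass("ZStack",
  representation(
    intensities = "array",
    channels = "character",
    pixel_um = "numeric",
    slice_um = "numeric"
  )
)

.ZSTACK_CHANNELS <- c("syto9", "sypro_orange", "cona")

setValidity("ZStack", function(object) {
  d <- dim(object@intensities)
  if (length(d) != 4L) {
    return("intensities must be a 4-D array (channel, z, y, x)")
  }
  if (d[1] != 3L || length(object@channels) != 3L) {
    return("exactly 3 channels are required (syto9, sypro_orange, cona)")
  }
  if (anyNA(object@intensities)) return("intensities must not contain NA")
  rng <- range(object@intensities)
  if (rng[1] < 0 || rng[2] > 255) {
    return("intensities must lie on the 8-bit scale [0, 255]")
  }
  if (object@pixel_um <= 0 || object@slice_um <= 0) {
    return("pixel_um and slice_um must be strictly positive")
  }
  TRUE
})

#' Construct a ZStack
#'
#' @param intensities 4-D array (channel, z, y, x), 8-bit scale
#' @param pixel_um in-plane pixel size (um)
#' @param slice_um z interval (um)
#' @param channels channel names; default \code{c("syto9", "sypro_orange", "cona")}
#' @return a validated \code{ZStack}
#' @export
ZStack <- function(intensities, pixel_um = 212.5 / 1024, slice_um = 1,
                   channels = .ZSTACK_CHANNELS) {
  new("ZStack",
    intensities = intensities, channels = channels,
    pixel_um = as.numeric(pixel_um), slice_um = as.numeric(slice_um)
  )
}

#' Binary segmentation mask of a z-stack
#'
#' A voxelwise detection mask (z, y, x) carrying the source geometry and a
#' processing log. \code{degenerate} is TRUE when the mask came from a
#' constant (untresholdable) channel and is therefore empty by construction.
#'
#' @slot mask 3-D logical array (z, y, x)
#' @slot pixel_um in-plane pixel size (um)
#' @slot slice_um z interval (um)
#' @slot provenance character log of the processing steps applied
#' @slot degenerate logical flag for constant-channel input
#' @name BinaryStack-class
#' @aliases BinaryStack-class
#' @exportClass BinaryStack
setClass("BinaryStack",
  representation(
    mask = "array",
    pixel_um = "numeric",
    slice_um = "numeric",
    provenance = "character",
    degenerate = "logical"
  )
)

setValidity("BinaryStack", function(object) {
  if (length(dim(object@mask)) != 3L) {
    return("mask must be a 3-D array (z, y, x)")
  }
  if (!is.logical(object@mask)) return("mask must be logical")
  if (object@pixel_um <= 0 || object@slice_um <= 0) {
    return("pixel_um and slice_um must be strictly positive")
  }
  if (length(object@degenerate) != 1L) return("degenerate must be length 1")
  TRUE
})

#' Construct a BinaryStack
#'
#' @param mask 3-D logical array (z, y, x)
#' @param pixel_um in-plane pixel size (um)
#' @param slice_um z interval (um)
#' @param provenance processing log entries
#' @param degenerate constant-channel flag
#' @return a validated \code{BinaryStack}
#' @export
BinaryStack <- function(mask, pixel_um, slice_um,
                        provenance = character(), degenerate = FALSE) {
  storage.mode(mask) <- "logical"
  new("BinaryStack",
    mask = mask, pixel_um = as.numeric(pixel_um),
    slice_um = as.numeric(slice_um), provenance = provenance,
    degenerate = degenerate
  )
}

#' Quantitative metrics of one biofilm z-stack
#'
#' Output of \code{\link{quantifyStack}}: area coverage (fraction of the
#' frame covered in the maximal slice), maximum area (um2), maximum biofilm
#' height (MBH, um), biovolume (um3), EPS biovolume from the protein +
#' polysaccharide channels (um3), and the EPS fraction (EPS biovolume /
#' total biovolume, NA when the total is zero). The EPS mask uses a
#' different channel subset, so the EPS biovolume is not constrained to be
#' a subset of the total.
#'
#' @slot area_coverage fraction in [0, 1]
#' @slot max_area_um2 um2
#' @slot mbh_um maximum biofilm height (um)
#' @slot biovolume_um3 um3
#' @slot eps_biovolume_um3 um3
#' @slot eps_fraction fraction, NA when total biovolume is 0
#' @slot n_slices_analyzed slices remaining after base-slice removal
#' @name BiofilmImageMetrics-class
#' @aliases BiofilmImageMetrics-class
#' @exportClass BiofilmImageMetrics
setClass("BiofilmImageMetrics",
  representation(
    area_coverage = "numeric",
    max_area_um2 = "numeric",
    mbh_um = "numeric",
    biovolume_um3 = "numeric",
    eps_biovolume_um3 = "numeric",
    eps_fraction = "numeric",
    n_slices_analyzed = "numeric"
  )
)

setValidity("BiofilmImageMetrics", function(object) {
  nonneg <- c(
    object@area_coverage, object@max_area_um2, object@mbh_um,
    object@biovolume_um3, object@eps_biovolume_um3, object@n_slices_analyzed
  )
  if (any(nonneg < 0, na.rm = TRUE)) return("metrics must be non-negative")
  if (object@area_coverage > 1 + 1e-12) {
    return("area_coverage must not exceed 1")
  }
  TRUE
})
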
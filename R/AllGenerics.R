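#' Accessors for aquage classes
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param x an aquage object
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("volumeMl", function(x) standardGeneric("volumeMl"))
#' @rdname accessors
#' @export
setGeneric("flowMlMin", function(x) standardGeneric("flowMlMin"))
#' @rdname accessors
#' @export
setGeneric("biofilmAreaCm2", function(x) standardGeneric("biofilmAreaCm2"))
#' @rdname accessors
#' @export
setGeneric("pixelUm", function(x) standardGeneric("pixelUm"))
#' @rdname accessors
#' @export
setGeneric("sliceUm", function(x) standardGeneric("sliceUm"))
#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setGeneric("intensityArray", function(x) standardGeneric("intensityArray"))
#' @rdname accessors
#' @export
setGeneric("maskArray", function(x) standardGeneric("maskArray"))
#' @rdname accessors
#' @export
setGeneric("nSlices", function(x) standardGeneric("nSlices"))
#' @rdname accessors
#' @export
setGeneric("frameAreaUm2", function(x) standardGeneric("frameAreaUm2"))
#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setGeneric("isDegenerate", function(x) standardGeneric("isDegenerate"))

#' @rdname accessors
setMethod("volumeMl", "ReactorConfig", function(x) x@volume_ml)
#' @rdname accessors
setMethod("flowMlMin", "ReactorConfig", function(x) x@flow_ml_min)
#' @rdname accessors
setMethod("biofilmAreaCm2", "ReactorConfig", function(x) x@biofilm_area_cm2)
#' @rdname accessors
setMethod("pixelUm", "ReactorConfig", function(x) x@pixel_um)
#' @rdname accessors
setMethod("sliceUm", "ReactorConfig", function(x) x@slice_um)

#' @rdname accessors
setMethod("pixelUm", "ZStack", function(x) x@pixel_um)
#' @rdname accessors
setMethod("sliceUm", "ZStack", function(x) x@slice_um)
#' @rdname accessors
setMethod("channelNames", "ZStack", function(x) x@channels)
#' @rdname accessors
setMethod("intensityArray", "ZStack", function(x) x@intensities)
#' @rdname accessors
setMethod("nSlices", "ZStack", function(x) dim(x@intensities)[2])
#' @rdname accessors
setMethod("frameAreaUm2", "ZStack", function(x) {
  d <- dim(x@intensities)
  d[3] * d[4] * x@pixel_um^2
})

#' @rdname accessors
setMethod("pixelUm", "BinaryStack", function(x) x@pixel_um)
#' @rdname accessors
setMethod("sliceUm", "BinaryStack", function(x) x@slice_um)
#' @rdname accessors
setMethod("maskArray", "BinaryStack", function(x) x@mask)
#' @rdname accessors
setMethod("nSlices", "BinaryStack", function(x) dim(x@mask)[1])
#' @rdname accessors
setMethod("frameAreaUm2", "BinaryStack", function(x) {
  d <- dim(x@mask)
  d[2] * d[3] * x@pixel_um^2
})
#' @rdname accessors
setMethod("provenance", "BinaryStack", function(x) x@provenance)
#' @rdname accessors
setMethod("isDegenerate", "BinaryStack", function(x) x@degenerate)

setMethod("show", "ReactorConfig", function(object) {
  cat("ReactorConfig\n")
  cat(sprintf("  bulk volume V     : %g mL\n", object@volume_ml))
  cat(sprintf("  influent flow Q   : %g mL/min (HRT %.2f h)\n",
    object@flow_ml_min, object@volume_ml / object@flow_ml_min / 60))
  cat(sprintf("  biofilm area A    : %g cm2\n", object@biofilm_area_cm2))
  cat(sprintf("  voxel geometry    : %.4f um/px, %g um z-step, %g um frame (%d px)\n",
    object@pixel_um, object@slice_um, object@frame_um, as.integer(object@frame_px)))
})

setMethod("show", "ZStack", function(object) {
  d <- dim(object@intensities)
  cat(sprintf("ZStack: %d channels (%s), %d slices, %d x %d px\n",
    d[1], paste(object@channels, collapse = ", "), d[2], d[3], d[4]))
  cat(sprintf("  geometry: %.4f um/px, %g um z-step\n",
    object@pixel_um, object@slice_um))
})

setMethod("show", "BinaryStack", function(object) {
  d <- dim(object@mask)
  cat(sprintf("BinaryStack: %d slices, %d x %d px, %d detected voxels%s\n",
    d[1], d[2], d[3], sum(object@mask),
    if (object@degenerate) " [degenerate input]" else ""))
  if (length(object@provenance)) {
    cat("  provenance:", paste(object@provenance, collapse = " | "), "\n")
  }
})

setMethod("show", "BiofilmImageMetrics", function(object) {
  cat("BiofilmImageMetrics\n")
  cat(sprintf("  area coverage   : %.1f %%\n", 100 * object@area_coverage))
  cat(sprintf("  max area        : %.1f um2\n", object@max_area_um2))
  cat(sprintf("  max height (MBH): %.1f um\n", object@mbh_um))
  cat(sprintf("  biovolume       : %.1f um3\n", object@biovolume_um3))
  cat(sprintf("  EPS biovolume   : %.1f um3\n", object@eps_biovolume_um3))
  cat(sprintf("  EPS fraction    : %s\n",
    if (is.na(object@eps_fraction)) "undefined (zero biovolume)"
    else sprintf("%.1f %%", 100 * object@eps_fraction)))
  cat(sprintf("  slices analyzed : %d\n", as.integer(object@n_slices_analyzed)))
})

#' Convert stack metrics to a one-row data.frame
#'
#' @param x a \code{BiofilmImageMetrics}
#' @param row.names,optional,... passed through for generic consistency
#' @return one-row \code{data.frame}
#' @export
as.data.frame.BiofilmImageMetrics <- function(x, row.names = NULL,
                                              optional = FALSE, ...) {
  data.frame(
    area_coverage = x@area_coverage,
    max_area_um2 = x@max_area_um2,
    mbh_um = x@mbh_um,
    biovolume_um3 = x@biovolume_um3,
    eps_biovolume_um3 = x@eps_biovolume_um3,
    eps_fraction = x@eps_fraction,
    n_slices_analyzed = x@n_slices_analyzed,
    row.names = row.names, stringsAsFactors = FALSE
  )
}
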
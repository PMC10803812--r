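#' In-plane median denoising of a z-stack
#'
#' Applies a square median filter to every (channel, slice) plane; z
#' neighbours are never mixed. Delegates to \code{EBImage::medianFilter}
#' (constant-time median), which is exact on the 8-bit integer scale;
#' \code{kernel = 1} is the identity.
#'
#' @param stack a \code{\link{ZStack}}
#' @param kernel odd side length of the square footprint (default 3)
#' @return a denoised \code{ZStack} of identical shape
#' @export
medianDenoise <- function(stack, kernel = 3L) {
  stopifnot(is(stack, "ZStack"))
  kernel <- as.integer(kernel)
  if (length(kernel) != 1L || is.na(kernel) || kernel < 1L || kernel %% 2L == 0L) {
    stop("kernel must be a single odd integer >= 1")
  }
  if (kernel == 1L) return(stack)
  r <- (kernel - 1L) %/% 2L
  arr <- intensityArray(stack)
  d <- dim(arr)
  for (ch in seq_len(d[1])) {
    for (z in seq_len(d[2])) {
      plane <- arr[ch, z, , ] / 255
      arr[ch, z, , ] <- round(EBImage::medianFilter(plane, r) * 255)
    }
  }
  ZStack(arr, pixel_um = pixelUm(stack), slice_um = sliceUm(stack),
         channels = channelNames(stack))
}

#' Otsu threshold of an 8-bit intensity sample
#'
#' Exhaustively maximizes the between-class variance
#' \eqn{w_0 w_1 (\mu_0 - \mu_1)^2} over all 8-bit thresholds, with class 0
#' defined as intensities \code{<= t}. Ties are broken toward the smallest
#' threshold. Returns NA for a constant sample.
#'
#' @param values numeric vector of intensities on the 0..255 scale
#' @return the threshold (background is \code{<= t}), or NA if constant
#' @export
otsuThreshold <- function(values) {
  v <- as.integer(round(values))
  if (any(v < 0L | v > 255L)) stop("intensities must lie in [0, 255]")
  counts <- tabulate(v + 1L, nbins = 256L)
  n <- sum(counts)
  if (sum(counts > 0L) < 2L) return(NA_real_)
  lev <- 0:255
  w0 <- cumsum(counts)                  # class 0: <= t, t = 0..255
  m0 <- cumsum(counts * lev)
  tot <- m0[256]
  w1 <- n - w0
  # between-class variance, defined where both classes are non-empty
  ok <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, 256)
  bcv[ok] <- (m0[ok] / w0[ok] - (tot - m0[ok]) / w1[ok])^2 *
    (w0[ok] / n) * (w1[ok] / n)
  lev[which.max(bcv)]
}

#' Binarize one channel of a z-stack by global Otsu thresholding
#'
#' The threshold is computed from the channel's full 3-D intensity
#' histogram (all slices pooled), not per slice, so that empty slices do
#' not get thresholds fitted to pure noise. Voxels strictly above the
#' threshold are detected. Two degenerate cases yield an empty mask
#' flagged \code{degenerate}: a constant channel (nothing to threshold),
#' and a channel whose two Otsu classes are separated by less than
#' \code{min_contrast} intensity levels — Otsu always splits a histogram,
#' so without this noise-floor guard a stain-free frame of pure detector
#' noise would be segmented as biomass.
#'
#' @param stack a \code{\link{ZStack}}
#' @param channel channel name or index
#' @param min_contrast minimum separation of the two class means (8-bit
#'   levels) for the channel to count as containing signal; default 16
#' @return a \code{\link{BinaryStack}}
#' @export
otsuBinarize <- function(stack, channel, min_contrast = 16) {
  stopifnot(is(stack, "ZStack"))
  if (is.character(channel)) {
    ch <- match(channel, channelNames(stack))
    if (is.na(ch)) stop(sprintf("unknown channel '%s'", channel))
  } else {
    ch <- as.integer(channel)
    if (ch < 1L || ch > length(channelNames(stack))) stop("channel index out of range")
  }
  name <- channelNames(stack)[ch]
  v <- intensityArray(stack)[ch, , , , drop = TRUE]
  dim(v) <- dim(intensityArray(stack))[2:4]
  thr <- otsuThreshold(v)
  if (!is.na(thr)) {
    contrast <- mean(v[v > thr]) - mean(v[v <= thr])
  }
  if (is.na(thr) || contrast < min_contrast) {
    why <- if (is.na(thr)) "constant channel" else {
      sprintf("class contrast %.1f below noise floor %g", contrast, min_contrast)
    }
    return(BinaryStack(array(FALSE, dim(v)),
      pixel_um = pixelUm(stack), slice_um = sliceUm(stack),
      provenance = sprintf("otsu[%s]: %s, empty mask", name, why),
      degenerate = TRUE
    ))
  }
  BinaryStack(v > thr,
    pixel_um = pixelUm(stack), slice_um = sliceUm(stack),
    provenance = sprintf("otsu[%s] threshold=%g (global 3-D histogram)", name, thr),
    degenerate = FALSE
  )
}

#' Remove substrate-adjacent base slices from a mask
#'
#' Stained sterile controls show an artifactual >1% area coverage in the
#' first z slices where dyes bind the substrate; the standard correction is
#' to drop the first \code{n} slices (default 4) and reindex z from the new
#' bottom.
#'
#' @param mask a \code{\link{BinaryStack}}
#' @param n number of base slices to drop (default 4); 0 is the identity
#' @return a \code{\link{BinaryStack}} with \code{n} fewer slices
#' @export
removeBaseSlices <- function(mask, n = 4L) {
  stopifnot(is(mask, "BinaryStack"))
  n <- as.integer(n)
  if (n < 0L) stop("n must be >= 0")
  if (n == 0L) return(mask)
  nz <- nSlices(mask)
  if (nz <= n) {
    stop(sprintf("insufficient depth: stack has %d slices, need more than %d", nz, n))
  }
  BinaryStack(maskArray(mask)[(n + 1L):nz, , , drop = FALSE],
    pixel_um = pixelUm(mask), slice_um = sliceUm(mask),
    provenance = c(provenance(mask), sprintf("removed %d base slices", n)),
    degenerate = isDegenerate(mask)
  )
}

#' Merge binary masks by voxelwise OR
#'
#' @param masks list of \code{\link{BinaryStack}} objects of identical shape
#' @return the merged \code{\link{BinaryStack}}; degenerate only if all
#'   inputs were degenerate
#' @export
mergeBinary <- function(masks) {
  stopifnot(is.list(masks), length(masks) >= 1L,
            all(vapply(masks, is, logical(1), "BinaryStack")))
  dims <- lapply(masks, function(m) dim(maskArray(m)))
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L) {
    stop("shape mismatch: all masks must have identical dimensions")
  }
  merged <- Reduce(`|`, lapply(masks, maskArray))
  BinaryStack(merged,
    pixel_um = pixelUm(masks[[1L]]), slice_um = sliceUm(masks[[1L]]),
    provenance = c(unlist(lapply(masks, provenance)),
                   sprintf("merged %d masks (voxelwise OR)", length(masks))),
    degenerate = all(vapply(masks, isDegenerate, logical(1)))
  )
}

#' Detected area per z-slice
#'
#' @param mask a \code{\link{BinaryStack}}
#' @return numeric vector, detected-pixel count x pixel area (um2) per slice
#' @export
sliceAreas <- function(mask) {
  stopifnot(is(mask, "BinaryStack"))
  apply(maskArray(mask), 1L, sum) * pixelUm(mask)^2
}

#' Maximum detected area across slices, with frame coverage
#'
#' The slice with the most detected pixels defines the maximum area; the
#' coverage fraction is that area over the frame area.
#'
#' @param mask a \code{\link{BinaryStack}}
#' @return list with \code{max_area_um2} and \code{coverage}
#' @export
maxArea <- function(mask) {
  a <- sliceAreas(mask)
  m <- if (length(a)) max(a) else 0
  list(max_area_um2 = m, coverage = m / frameAreaUm2(mask))
}

#' Maximum biofilm height (MBH)
#'
#' The number of z slices containing at least one detected voxel, times the
#' slice thickness. Occupied slices need not be contiguous: a detached
#' voxel high above the substrate extends the count, matching a literal
#' occupied-slice-count definition.
#'
#' @param mask a \code{\link{BinaryStack}}
#' @return height in um
#' @export
maxBiofilmHeight <- function(mask) {
  stopifnot(is(mask, "BinaryStack"))
  sum(apply(maskArray(mask), 1L, any)) * sliceUm(mask)
}

#' Biovolume of a binary stack
#'
#' Sum of the detected area of each slice multiplied by the slice
#' thickness.
#'
#' @param mask a \code{\link{BinaryStack}}
#' @return volume in um3
#' @export
biovolume <- function(mask) {
  sum(sliceAreas(mask)) * sliceUm(mask)
}

#' Quantify a three-channel biofilm z-stack
#'
#' Runs the full pipeline: per-channel median denoising, per-channel global
#' Otsu binarization, base-slice removal, then channel merging — all three
#' channels for the total-biomass metrics, and the protein + polysaccharide
#' channels only for the EPS metrics. The EPS fraction is the EPS biovolume
#' over the total biovolume (NA when the total is zero). Otsu statistics
#' include the base slices (they are removed after thresholding); see the
#' package vignette for the rationale.
#'
#' @param stack a \code{\link{ZStack}} with at least 5 slices
#' @param kernel median filter side length (odd; default 3; 1 disables
#'   denoising)
#' @param base_slices number of substrate slices to remove (default 4)
#' @param eps_channels channel names entering the EPS merge
#' @return a \code{\link{BiofilmImageMetrics}}
#' @examples
#' sim <- simulateZStack(stackScenario(seed = 1))
#' quantifyStack(sim$stack)
#' @export
quantifyStack <- function(stack, kernel = 3L, base_slices = 4L,
                          eps_channels = c("sypro_orange", "cona")) {
  stopifnot(is(stack, "ZStack"))
  if (nSlices(stack) < 5L) stop("insufficient depth: need at least 5 z slices")
  den <- medianDenoise(stack, kernel)
  masks <- lapply(channelNames(den), function(ch) otsuBinarize(den, ch))
  names(masks) <- channelNames(den)
  masks <- lapply(masks, removeBaseSlices, n = base_slices)

  total <- mergeBinary(masks)
  eps_idx <- match(eps_channels, names(masks))
  if (anyNA(eps_idx)) stop("eps_channels must name channels of the stack")
  eps <- mergeBinary(masks[eps_idx])

  ma <- maxArea(total)
  bv <- biovolume(total)
  ebv <- biovolume(eps)
  new("BiofilmImageMetrics",
    area_coverage = ma$coverage,
    max_area_um2 = ma$max_area_um2,
    mbh_um = maxBiofilmHeight(total),
    biovolume_um3 = bv,
    eps_biovolume_um3 = ebv,
    eps_fraction = if (bv > 0) ebv / bv else NA_real_,
    n_slices_analyzed = nSlices(total)
  )
}
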
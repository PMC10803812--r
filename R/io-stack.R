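#' Write a z-stack to a multi-page TIFF
#'
#' Pages are ordered z-major within channel: all slices of the
#' nucleic-acid channel first, then the protein channel, then the
#' polysaccharide channel. 8-bit, uncompressed.
#'
#' @param stack a \code{\link{ZStack}}
#' @param path output TIFF path
#' @return invisibly, \code{path}
#' @export
writeZStack <- function(stack, path) {
  stopifnot(is(stack, "ZStack"))
  arr <- intensityArray(stack)
  d <- dim(arr)
  pages <- vector("list", d[1] * d[2])
  i <- 0L
  for (ch in seq_len(d[1])) {
    for (z in seq_len(d[2])) {
      i <- i + 1L
      pages[[i]] <- arr[ch, z, , ] / 255
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "none")
  invisible(path)
}

#' Read a z-stack from TIFF
#'
#' Accepts either one multi-page TIFF (pages z-major within channel, in
#' the fixed channel order) or three single-channel files given in channel
#' order. Page count and shape consistency are validated.
#'
#' @param path one multi-channel TIFF path, or a character vector of three
#'   single-channel TIFF paths
#' @param pixel_um in-plane pixel size (um)
#' @param slice_um z interval (um)
#' @param channels channel names (fixed order)
#' @return a \code{\link{ZStack}}
#' @export
readZStack <- function(path, pixel_um = 212.5 / 1024, slice_um = 1,
                       channels = c("syto9", "sypro_orange", "cona")) {
  if (length(channels) != 3L) stop("channel-count error: exactly 3 channels required")
  readPages <- function(p) {
    pages <- tiff::readTIFF(p, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    lapply(pages, function(m) {
      if (length(dim(m)) == 3L) {
        if (dim(m)[3] != 1L) {
          stop("channel-count error: pages must be single-channel grayscale")
        }
        m <- m[, , 1L]
      }
      m
    })
  }
  if (length(path) == 1L) {
    pages <- readPages(path)
    if (length(pages) %% 3L != 0L) {
      stop(sprintf(
        "format error: page count %d is not divisible by 3 channels", length(pages)
      ))
    }
    nz <- length(pages) %/% 3L
    byChannel <- split(pages, rep(seq_len(3L), each = nz))
  } else if (length(path) == 3L) {
    byChannel <- lapply(path, readPages)
    if (length(unique(vapply(byChannel, length, integer(1)))) != 1L) {
      stop("format error: single-channel files differ in page count")
    }
    nz <- length(byChannel[[1L]])
  } else {
    stop("path must be one multi-channel TIFF or three single-channel TIFFs")
  }
  shapes <- unique(unlist(lapply(byChannel, function(ps) {
    vapply(ps, function(m) paste(dim(m), collapse = "x"), character(1))
  })))
  if (length(shapes) != 1L) stop("format error: inconsistent page shapes")
  dims <- dim(byChannel[[1L]][[1L]])
  arr <- array(0, c(3L, nz, dims[1L], dims[2L]))
  for (ch in seq_len(3L)) {
    for (z in seq_len(nz)) {
      arr[ch, z, , ] <- round(byChannel[[ch]][[z]] * 255)
    }
  }
  ZStack(arr, pixel_um = pixel_um, slice_um = slice_um, channels = channels)
}
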
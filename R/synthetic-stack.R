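#' Scenario for a synthetic confocal z-stack
#'
#' Describes a stack of sparse heterogeneous biofilm clusters on a
#' substrate, the regime seen in drinking-water biofilms: low area
#' coverage (order 10%), cluster heights from a few to tens of um, and a
#' dominant EPS share (>90% of cluster voxels carrying only the protein /
#' polysaccharide stains). Clusters are hemispheres resting on the
#' substrate or hollow shells (emulating limited dye penetration into
#' large clusters). Optional Gaussian background noise and an optional
#' base-slice staining artifact (high-intensity speckle confined to the
#' first four slices, as dyes binding the bare substrate produce) can be
#' added.
#'
#' @param frame_px frame side in pixels
#' @param n_slices number of z slices
#' @param pixel_um in-plane pixel size (um)
#' @param slice_um z interval (um)
#' @param clusters list of cluster descriptions; each a list with
#'   \code{center_um} (x, y), \code{radius_um}, \code{shape}
#'   (\code{"hemisphere"} or \code{"hollow-shell"}), optional
#'   \code{shell_um} (shell thickness, default 3) and optional
#'   \code{intensity} (8-bit triple for syto9, sypro_orange, cona)
#' @param eps_voxel_fraction fraction of cluster voxels assigned only to
#'   the EPS channels (sypro_orange + cona); the remaining voxels are
#'   cells (syto9), placed as compact in-plane cores nearest the cluster
#'   axis in each slice
#' @param background_mean,background_sd Gaussian background intensity
#'   (8-bit scale; 0/0 = clean background)
#' @param base_artifact plant the base staining artifact in slices 1-4?
#' @param base_artifact_coverage fraction of pixels speckled per base
#'   slice (default 0.03, i.e. above the 1% level seen in controls)
#' @param base_artifact_intensity 8-bit intensity of the artifact speckle
#' @param seed RNG seed; fully determines the output
#' @return a \code{StackScenario} list
#' @export
stackScenario <- function(frame_px = 96, n_slices = 30,
                          pixel_um = 0.5, slice_um = 1,
                          clusters = list(list(
                            center_um = c(24, 24), radius_um = 10,
                            shape = "hemisphere"
                          )),
                          eps_voxel_fraction = 0.92,
                          background_mean = 0, background_sd = 0,
                          base_artifact = FALSE,
                          base_artifact_coverage = 0.03,
                          base_artifact_intensity = 200,
                          seed = 1L) {
  frame_um <- frame_px * pixel_um
  for (cl in clusters) {
    stopifnot(length(cl$center_um) == 2L, cl$radius_um > 0)
    if (any(cl$center_um - cl$radius_um < 0) ||
        any(cl$center_um + cl$radius_um > frame_um)) {
      stop("cluster does not fit within the frame")
    }
  }
  stopifnot(eps_voxel_fraction >= 0, eps_voxel_fraction <= 1)
  structure(list(
    frame_px = as.integer(frame_px), n_slices = as.integer(n_slices),
    pixel_um = pixel_um, slice_um = slice_um, clusters = clusters,
    eps_voxel_fraction = eps_voxel_fraction,
    background_mean = background_mean, background_sd = background_sd,
    base_artifact = isTRUE(base_artifact),
    base_artifact_coverage = base_artifact_coverage,
    base_artifact_intensity = base_artifact_intensity,
    seed = as.integer(seed)
  ), class = "StackScenario")
}

# rasterize one cluster into a (z, y, x) logical array using voxel centers
.rasterizeCluster <- function(cl, nz, ny, nx, pixel_um, slice_um) {
  xs <- (seq_len(nx) - 0.5) * pixel_um
  ys <- (seq_len(ny) - 0.5) * pixel_um
  zs <- (seq_len(nz) - 0.5) * slice_um # height above substrate
  dx2 <- (xs - cl$center_um[1])^2
  dy2 <- (ys - cl$center_um[2])^2
  r2 <- cl$radius_um^2
  shape <- if (is.null(cl$shape)) "hemisphere" else cl$shape
  inner2 <- if (shape == "hollow-shell") {
    shell <- if (is.null(cl$shell_um)) 3 else cl$shell_um
    max(cl$radius_um - shell, 0)^2
  } else {
    -1
  }
  out <- array(FALSE, c(nz, ny, nx))
  plane <- outer(dy2, dx2, `+`)
  for (k in seq_len(nz)) {
    d2 <- plane + zs[k]^2
    out[k, , ] <- d2 <= r2 & d2 > inner2
  }
  out
}

#' Simulate a three-channel biofilm z-stack with exact ground truth
#'
#' Rasterizes the scenario's clusters onto the voxel grid (voxel-center
#' inclusion test), splits cluster voxels into cells (nucleic-acid channel)
#' and EPS-only voxels (protein + polysaccharide channels) — in every
#' slice, cells form a compact in-plane core nearest the cluster axis,
#' embedded in the EPS matrix, so cell regions survive median denoising
#' the way real microcolonies do and the cell share is uniform along z —
#' then adds Gaussian background and, optionally, the
#' base staining artifact. The truth record stores exact voxel counts so
#' every downstream metric can be checked without re-deriving geometry.
#'
#' @param scn a \code{\link{stackScenario}}
#' @return list with \code{stack} (a \code{\link{ZStack}}) and
#'   \code{truth}: \code{mask} and \code{eps_mask} (z, y, x logical
#'   arrays), \code{voxel_count}, \code{eps_voxel_count},
#'   \code{per_slice_counts}, \code{per_slice_eps_counts},
#'   \code{occupied_slices}, \code{mbh_um}, \code{biovolume_um3},
#'   \code{eps_biovolume_um3}, \code{max_area_um2}, \code{area_coverage}
#' @examples
#' sim <- simulateZStack(stackScenario(seed = 7))
#' sim$truth$biovolume_um3
#' @export
simulateZStack <- function(scn) {
  stopifnot(inherits(scn, "StackScenario"))
  nx <- scn$frame_px
  ny <- scn$frame_px
  nz <- scn$n_slices
  set.seed(scn$seed)

  mask <- array(FALSE, c(nz, ny, nx))
  d2min <- array(Inf, c(nz, ny, nx)) # distance^2 to the nearest cluster center
  sig <- vector("list", length(scn$clusters))
  default_int <- c(180, 170, 190)
  xs <- (seq_len(nx) - 0.5) * scn$pixel_um
  ys <- (seq_len(ny) - 0.5) * scn$pixel_um
  zs <- (seq_len(nz) - 0.5) * scn$slice_um
  for (i in seq_along(scn$clusters)) {
    cl <- scn$clusters[[i]]
    cmask <- .rasterizeCluster(cl, nz, ny, nx, scn$pixel_um, scn$slice_um)
    mask <- mask | cmask
    plane <- outer((ys - cl$center_um[2])^2, (xs - cl$center_um[1])^2, `+`)
    for (k in seq_len(nz)) {
      d2min[k, , ] <- pmin(d2min[k, , ], plane + zs[k]^2)
    }
    sig[[i]] <- list(
      mask = cmask,
      intensity = if (is.null(cl$intensity)) default_int else cl$intensity
    )
  }

  # cells form a compact in-plane core (microcolony cross-section) nearest
  # the cluster axis in every slice, embedded in an EPS matrix; per-slice
  # assignment keeps the cell share uniform in z, so the EPS fraction is
  # insensitive to how many base slices are later removed
  eps_mask <- array(FALSE, dim(mask))
  for (k in seq_len(nz)) {
    sl <- mask[k, , ]
    idx <- which(sl)
    if (length(idx) == 0L) next
    n_cell <- length(idx) - round(scn$eps_voxel_fraction * length(idx))
    d2 <- d2min[k, , ][idx]
    ord <- idx[order(d2, idx)]
    esl <- array(FALSE, dim(sl))
    if (n_cell < length(ord)) esl[ord[(n_cell + 1L):length(ord)]] <- TRUE
    eps_mask[k, , ] <- esl
  }

  # background first, signal overwrites
  arr <- array(0, c(3, nz, ny, nx))
  if (scn$background_sd > 0 || scn$background_mean > 0) {
    for (ch in 1:3) {
      bg <- stats::rnorm(nz * ny * nx, scn$background_mean, scn$background_sd)
      arr[ch, , , ] <- pmin(pmax(round(bg), 0), 255)
    }
  }
  cellm <- mask & !eps_mask
  for (s in sig) {
    cm <- s$mask & cellm
    em <- s$mask & eps_mask
    a1 <- arr[1, , , ]; a2 <- arr[2, , , ]; a3 <- arr[3, , , ]
    a1[cm] <- pmax(a1[cm], s$intensity[1])           # cells: nucleic-acid stain
    a2[em] <- pmax(a2[em], s$intensity[2])           # EPS: protein stain
    a3[em] <- pmax(a3[em], s$intensity[3])           # EPS: polysaccharide stain
    arr[1, , , ] <- a1; arr[2, , , ] <- a2; arr[3, , , ] <- a3
  }

  if (scn$base_artifact) {
    nbase <- min(4L, nz)
    npix <- max(1L, round(scn$base_artifact_coverage * ny * nx))
    for (k in seq_len(nbase)) {
      pick <- sample(ny * nx, npix)
      for (ch in 1:3) {
        plane <- arr[ch, k, , ]
        plane[pick] <- scn$base_artifact_intensity
        arr[ch, k, , ] <- plane
      }
    }
  }

  per_slice <- apply(mask, 1L, sum)
  per_slice_eps <- apply(eps_mask, 1L, sum)
  pa <- scn$pixel_um^2
  truth <- list(
    mask = mask, eps_mask = eps_mask,
    voxel_count = sum(per_slice), eps_voxel_count = sum(per_slice_eps),
    per_slice_counts = per_slice, per_slice_eps_counts = per_slice_eps,
    occupied_slices = sum(per_slice > 0),
    mbh_um = sum(per_slice > 0) * scn$slice_um,
    biovolume_um3 = sum(per_slice) * pa * scn$slice_um,
    eps_biovolume_um3 = sum(per_slice_eps) * pa * scn$slice_um,
    max_area_um2 = if (nz) max(per_slice) * pa else 0,
    area_coverage = if (nz) max(per_slice) / (ny * nx) else 0
  )
  list(
    stack = ZStack(arr, pixel_um = scn$pixel_um, slice_um = scn$slice_um),
    truth = truth
  )
}

#' Write a canonical suite of synthetic fixtures
#'
#' Generates three reactor series scenarios (steady NGTR, a tenfold NGTR
#' step mimicking a phase shift, and a decay period with negative NGTR)
#' and four stack scenarios (blank noise-only control, single hemisphere,
#' hollow shell, high coverage), writing for each the CSV/TIFF inputs and
#' a JSON truth record. The same seed reproduces the directory exactly.
#'
#' @param dir output directory (created if needed)
#' @param seed integer seed controlling every scenario
#' @return invisibly, the paths written
#' @export
makeFixtureSuite <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)
  paths <- character(0)

  step_ngtr <- function(day) ifelse(day < 20, 5e7, 5e8)
  series <- list(
    steady = seriesScenario(noise_gcv = 0.3, seed = seed),
    step = seriesScenario(ngtr_profile = step_ngtr, noise_gcv = 0.3,
                          seed = seed + 1L),
    decay = seriesScenario(ngtr_profile = -2e6, biofilm_accum_profile = 0,
                           noise_gcv = 0.3, seed = seed + 2L)
  )
  for (nm in names(series)) {
    sim <- simulateReactorSeries(series[[nm]])
    bp <- file.path(dir, paste0("series_", nm, "_bulk.csv"))
    fp <- file.path(dir, paste0("series_", nm, "_biofilm.csv"))
    tp <- file.path(dir, paste0("series_", nm, "_truth.json"))
    writeBulkSeries(sim$bulk, bp)
    writeBiofilmSeries(sim$biofilm, fp)
    jsonlite::write_json(list(
      sample_days = sim$truth$sample_days,
      biofilm_sample_days = sim$truth$biofilm_sample_days,
      c_ar_sampled = sim$truth$c_ar_sampled,
      n_bf_sampled = sim$truth$n_bf_sampled,
      ngtr_at_samples = sim$truth$ngtr[match(sim$truth$sample_days, sim$truth$time)]
    ), tp, digits = NA)
    paths <- c(paths, bp, fp, tp)
  }

  stacks <- list(
    blank = stackScenario(clusters = list(), background_mean = 12,
                          background_sd = 4, seed = seed + 10L),
    single = stackScenario(seed = seed + 11L),
    hollow = stackScenario(clusters = list(list(
      center_um = c(24, 24), radius_um = 14, shape = "hollow-shell",
      shell_um = 3
    )), seed = seed + 12L),
    high_coverage = stackScenario(clusters = list(
      list(center_um = c(14, 14), radius_um = 12),
      list(center_um = c(34, 32), radius_um = 13),
      list(center_um = c(14, 36), radius_um = 10)
    ), seed = seed + 13L)
  )
  for (nm in names(stacks)) {
    sim <- simulateZStack(stacks[[nm]])
    sp <- file.path(dir, paste0("stack_", nm, ".tif"))
    tp <- file.path(dir, paste0("stack_", nm, "_truth.json"))
    writeZStack(sim$stack, sp)
    tr <- sim$truth
    tr$mask <- NULL
    tr$eps_mask <- NULL
    jsonlite::write_json(tr, tp, digits = NA)
    paths <- c(paths, sp, tp)
  }
  invisible(paths)
}
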
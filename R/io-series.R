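.BULK_COLS <- c(
  "day", "source", "phase", "tcc_cells_ml", "icc_cells_ml",
  "atpt_nM", "atpi_nM", "cl2_total_mg_l", "temp_c", "ph"
)
.BULK_NUMERIC <- setdiff(.BULK_COLS, c("source", "phase"))
.BIOFILM_COLS <- c(
  "day", "reactor", "tcc_cells_cm2", "icc_cells_cm2",
  "atpt_nmol_cm2", "atpi_nmol_cm2"
)

#' Chlorine limit of detection (mg/L as Cl2) for the DPD total-chlorine assay
#' @export
CL2_LOD_MG_L <- 0.02

# coerce a raw character column to numeric, reporting the first bad row
.parseNumeric <- function(raw, col) {
  raw <- trimws(raw)
  empty <- is.na(raw) | raw == ""
  out <- suppressWarnings(as.numeric(raw))
  bad <- which(!empty & is.na(out))
  if (length(bad)) {
    stop(sprintf("parse error: non-numeric value '%s' in column '%s', row %d",
                 raw[bad[1]], col, bad[1]))
  }
  out
}

#' Read a bulk-water time series CSV
#'
#' Expects the exact columns \code{day, source, phase, tcc_cells_ml,
#' icc_cells_ml, atpt_nM, atpi_nM, cl2_total_mg_l, temp_c, ph}
#' (comma-separated, header row, '.' decimal, missing values as empty
#' fields). Empty chlorine fields are below-LoD observations: they are
#' stored as 0 with \code{cl2_below_lod = TRUE} rather than as measured
#' zeros. Rows come back sorted by (source, day); ICC > TCC is rejected.
#'
#' @param path CSV file path
#' @return typed \code{data.frame} with an extra logical
#'   \code{cl2_below_lod} column
#' @export
readBulkSeries <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE)
  missing <- setdiff(.BULK_COLS, names(raw))
  if (length(missing)) {
    stop(sprintf("schema error: missing required column(s): %s",
                 paste(missing, collapse = ", ")))
  }
  out <- raw[.BULK_COLS]
  for (col in .BULK_NUMERIC) out[[col]] <- .parseNumeric(raw[[col]], col)
  below <- is.na(out$cl2_total_mg_l)
  out$cl2_total_mg_l[below] <- 0
  out$cl2_below_lod <- below
  if (anyNA(out$day)) stop("parse error: missing day value")
  both <- !is.na(out$icc_cells_ml) & !is.na(out$tcc_cells_ml)
  if (any(out$icc_cells_ml[both] > out$tcc_cells_ml[both])) {
    stop("invalid series: icc_cells_ml exceeds tcc_cells_ml")
  }
  out <- out[order(out$source, out$day), , drop = FALSE]
  if (anyDuplicated(out[c("source", "day")])) {
    stop("invalid series: duplicate (source, day) sampling events")
  }
  rownames(out) <- NULL
  out
}

#' Write a bulk-water time series CSV
#'
#' Inverse of \code{\link{readBulkSeries}}: rows flagged
#' \code{cl2_below_lod} are written with an empty chlorine field, so a
#' write/read round trip is the identity.
#'
#' @param df bulk series \code{data.frame}
#' @param path output CSV path
#' @return invisibly, \code{path}
#' @export
writeBulkSeries <- function(df, path) {
  missing <- setdiff(.BULK_COLS, names(df))
  if (length(missing)) {
    stop(sprintf("schema error: missing required column(s): %s",
                 paste(missing, collapse = ", ")))
  }
  out <- df[.BULK_COLS]
  if (!is.null(df$cl2_below_lod)) {
    out$cl2_total_mg_l[df$cl2_below_lod] <- NA
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a biofilm time series CSV
#'
#' Expects the exact columns \code{day, reactor, tcc_cells_cm2,
#' icc_cells_cm2, atpt_nmol_cm2, atpi_nmol_cm2}. Rows come back sorted by
#' (reactor, day); negative values and ICC > TCC are rejected.
#'
#' @param path CSV file path
#' @return typed \code{data.frame}
#' @export
readBiofilmSeries <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE)
  missing <- setdiff(.BIOFILM_COLS, names(raw))
  if (length(missing)) {
    stop(sprintf("schema error: missing required column(s): %s",
                 paste(missing, collapse = ", ")))
  }
  out <- raw[.BIOFILM_COLS]
  for (col in setdiff(.BIOFILM_COLS, "reactor")) {
    out[[col]] <- .parseNumeric(raw[[col]], col)
  }
  num <- out[setdiff(.BIOFILM_COLS, "reactor")]
  if (any(unlist(num) < 0, na.rm = TRUE)) {
    stop("invalid series: negative biofilm measurements")
  }
  both <- !is.na(out$icc_cells_cm2) & !is.na(out$tcc_cells_cm2)
  if (any(out$icc_cells_cm2[both] > out$tcc_cells_cm2[both])) {
    stop("invalid series: icc_cells_cm2 exceeds tcc_cells_cm2")
  }
  out <- out[order(out$reactor, out$day), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a biofilm time series CSV
#'
#' @param df biofilm series \code{data.frame}
#' @param path output CSV path
#' @return invisibly, \code{path}
#' @export
writeBiofilmSeries <- function(df, path) {
  missing <- setdiff(.BIOFILM_COLS, names(df))
  if (length(missing)) {
    stop(sprintf("schema error: missing required column(s): %s",
                 paste(missing, collapse = ", ")))
  }
  utils::write.csv(df[.BIOFILM_COLS], path, row.names = FALSE, na = "")
  invisible(path)
}
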
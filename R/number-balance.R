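#' @keywords internal
.flowMlDay <- function(config) flowMlMin(config) * 1440

# Assemble one estimate row; the conservation identity
# accumulation = tap_input - effluent + ngtr holds by construction.
.ngtrEstimate <- function(method, t1, t2, ngtr, tap_input, effluent,
                          accumulation, reactor = NA_character_) {
  data.frame(
    method = method,
    reactor = reactor,
    t1 = t1,
    t2 = t2,
    ngtr_cells_day = ngtr,
    tap_input_cells_day = tap_input,
    effluent_cells_day = effluent,
    accumulation_cells_day = accumulation,
    ratio_tap_ngtr = if (is.finite(ngtr) && ngtr > 0) tap_input / ngtr else NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Instantaneous steady-state (ISS) NGTR estimate
#'
#' Models the reactor as a continuously stirred tank at an instantaneous
#' steady state during one sampling event: \eqn{0 = C_{tap} Q - C_{AR} Q +
#' NGTR}, so \eqn{NGTR = (C_{AR} - C_{tap}) Q}. Requires no biofilm
#' measurement. Negative values (net decay, e.g. under high chlorine) are
#' reported as-is; the tap/NGTR ratio is flagged NA for NGTR <= 0.
#'
#' @param c_tap influent (tap reservoir) intact cell count (cells/mL)
#' @param c_ar reactor bulk intact cell count (cells/mL)
#' @param config a \code{\link{ReactorConfig}} supplying Q
#' @param day sampling day recorded as \code{t2} (optional)
#' @param reactor reactor identifier carried into the output (optional)
#' @return one-row \code{data.frame} (an NGTR estimate record) with columns
#'   method, reactor, t1, t2, ngtr_cells_day, tap_input_cells_day,
#'   effluent_cells_day, accumulation_cells_day, ratio_tap_ngtr
#' @examples
#' ngtrInstantaneous(990, 2.2e4, ReactorConfig())  # ~6.4e7 cells/day
#' @export
ngtrInstantaneous <- function(c_tap, c_ar, config, day = NA_real_,
                              reactor = NA_character_) {
  stopifnot(is(config, "ReactorConfig"))
  if (c_tap < 0 || c_ar < 0) {
    stop("concentrations out of range: must be >= 0")
  }
  q <- .flowMlDay(config)
  .ngtrEstimate(
    method = "ISS", t1 = NA_real_, t2 = day,
    ngtr = (c_ar - c_tap) * q,
    tap_input = c_tap * q, effluent = c_ar * q,
    accumulation = 0, reactor = reactor
  )
}

#' Arithmetic mean of a field over a half-open time window
#'
#' Averages all sampling events with \code{t1 < day <= t2}, the windowing
#' used for the influent/effluent terms of the non-steady-state balance.
#'
#' @param series \code{data.frame} with a \code{day} column
#' @param t1,t2 window bounds (days), \code{t1 < t2}
#' @param field column to average
#' @return arithmetic mean of \code{field} over the window
#' @export
intervalAverage <- function(series, t1, t2, field = "icc_cells_ml") {
  stopifnot(is.data.frame(series), "day" %in% names(series),
            field %in% names(series))
  if (!(t1 < t2)) stop("t1 must be < t2")
  sel <- series$day > t1 & series$day <= t2
  vals <- series[[field]][sel]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) {
    stop(sprintf("insufficient data: no sampling events in (%g, %g]", t1, t2))
  }
  mean(vals)
}

# Nearest event to `day` within `tol_days`, else error.
.nearestEvent <- function(series, day, tol_days, field) {
  d <- abs(series$day - day)
  i <- which.min(d)
  if (length(i) == 0L || d[i] > tol_days) {
    stop(sprintf(
      "insufficient data: no bulk event within %g days of day %g", tol_days, day
    ))
  }
  series[[field]][i]
}

#' Non-steady-state (NSS) NGTR estimate between two biofilm samplings
#'
#' Models the reactor as a continuously stirred tank with accumulation in
#' both the bulk water and the biofilm between two consecutive biofilm
#' sampling days \eqn{t_1 < t_2}:
#' \deqn{\Delta N / \Delta t = C_{tap,avg} Q - C_{AR,avg} Q + NGTR}
#' where \eqn{N = C_{AR} V + C_{BF} A} and the influent/effluent terms use
#' arithmetic means of all events in the half-open window \eqn{(t_1, t_2]}.
#' The storage-term bulk concentrations at the endpoints come from the bulk
#' events nearest each biofilm day (default), or from trailing-window means
#' (\code{endpoint = "window-mean"}), since which the original workflow used
#' is not documented.
#'
#' @param bulk bulk-water series \code{data.frame} (schema of
#'   \code{\link{readBulkSeries}}) containing both the tap-reservoir source
#'   and the reactor's source
#' @param bf1,bf2 one-row biofilm records (columns \code{day},
#'   \code{reactor} and \code{bf_field}) with \code{bf1$day < bf2$day},
#'   same reactor
#' @param config a \code{\link{ReactorConfig}} supplying V, Q and A
#' @param tap_source value of \code{bulk$source} holding influent samples
#' @param reactor_source value of \code{bulk$source} holding this reactor's
#'   bulk samples; defaults to \code{bf1$reactor}
#' @param tol_days matching tolerance between a biofilm day and the nearest
#'   bulk event (default 3 days)
#' @param field bulk concentration column (default intact cell counts)
#' @param bf_field biofilm areal concentration column
#' @param endpoint how to take C_AR at t1/t2 for the storage term:
#'   \code{"nearest"} event or trailing \code{"window-mean"} over
#'   \code{(t - tol_days, t]}
#' @return one-row estimate \code{data.frame}, as
#'   \code{\link{ngtrInstantaneous}} but with \code{method = "NSS"} and a
#'   nonzero accumulation term
#' @export
ngtrNonsteady <- function(bulk, bf1, bf2, config,
                          tap_source = "tapres", reactor_source = NULL,
                          tol_days = 3, field = "icc_cells_ml",
                          bf_field = "icc_cells_cm2",
                          endpoint = c("nearest", "window-mean")) {
  stopifnot(is(config, "ReactorConfig"))
  endpoint <- match.arg(endpoint)
  bf1 <- as.data.frame(bf1)[1, ]
  bf2 <- as.data.frame(bf2)[1, ]
  if (!identical(as.character(bf1$reactor), as.character(bf2$reactor))) {
    stop("biofilm samples must come from the same reactor")
  }
  t1 <- bf1$day
  t2 <- bf2$day
  if (!(t1 < t2)) stop("t1 must be < t2")
  if (is.null(reactor_source)) reactor_source <- as.character(bf1$reactor)

  tap <- bulk[bulk$source == tap_source, , drop = FALSE]
  ar <- bulk[bulk$source == reactor_source, , drop = FALSE]
  if (nrow(tap) == 0L) stop("insufficient data: no tap-reservoir events in bulk series")
  if (nrow(ar) == 0L) {
    stop(sprintf("insufficient data: no bulk events for source '%s'", reactor_source))
  }

  car1 <- switch(endpoint,
    "nearest" = .nearestEvent(ar, t1, tol_days, field),
    "window-mean" = intervalAverage(ar, t1 - tol_days, t1, field)
  )
  car2 <- switch(endpoint,
    "nearest" = .nearestEvent(ar, t2, tol_days, field),
    "window-mean" = intervalAverage(ar, t2 - tol_days, t2, field)
  )

  v <- volumeMl(config)
  a <- biofilmAreaCm2(config)
  q <- .flowMlDay(config)

  dN <- (car2 * v + bf2[[bf_field]] * a) - (car1 * v + bf1[[bf_field]] * a)
  acc <- dN / (t2 - t1)

  tap_mean <- intervalAverage(tap, t1, t2, field)
  ar_mean <- intervalAverage(ar, t1, t2, field)

  .ngtrEstimate(
    method = "NSS", t1 = t1, t2 = t2,
    ngtr = acc - q * (tap_mean - ar_mean),
    tap_input = q * tap_mean, effluent = q * ar_mean,
    accumulation = acc, reactor = as.character(bf1$reactor)
  )
}

#' Ratio of tap cell input to the NGTR
#'
#' The share of reactor cell input attributable to the influent relative to
#' net growth/transfer. Undefined (NA) when NGTR <= 0, i.e. during net
#' decay.
#'
#' @param est estimate \code{data.frame} from \code{\link{ngtrInstantaneous}},
#'   \code{\link{ngtrNonsteady}} or \code{\link{balanceSeries}}
#' @return numeric vector of ratios, NA where NGTR <= 0
#' @export
tapToNgtrRatio <- function(est) {
  stopifnot(is.data.frame(est),
            all(c("ngtr_cells_day", "tap_input_cells_day") %in% names(est)))
  ifelse(est$ngtr_cells_day > 0,
         est$tap_input_cells_day / est$ngtr_cells_day, NA_real_)
}

#' Apply both number balances across full series
#'
#' Produces one ISS estimate per reactor bulk event (paired with the
#' tap-reservoir event nearest in time, within \code{tol_days}) and one NSS
#' estimate per consecutive pair of biofilm sampling events of each
#' reactor. Unpairable events are skipped with a warning.
#'
#' @inheritParams ngtrNonsteady
#' @param biofilm biofilm series \code{data.frame} (schema of
#'   \code{\link{readBiofilmSeries}}); may be empty or NULL for ISS-only
#' @return \code{data.frame} of estimates, ISS rows first, ordered by
#'   (reactor, day)
#' @export
balanceSeries <- function(bulk, biofilm = NULL, config,
                          tap_source = "tapres", tol_days = 3,
                          field = "icc_cells_ml", bf_field = "icc_cells_cm2",
                          endpoint = c("nearest", "window-mean")) {
  stopifnot(is.data.frame(bulk), is(config, "ReactorConfig"))
  endpoint <- match.arg(endpoint)
  tap <- bulk[bulk$source == tap_source, , drop = FALSE]
  tap <- tap[order(tap$day), , drop = FALSE]
  if (nrow(tap) == 0L) stop("insufficient data: no tap-reservoir events in bulk series")

  out <- list()
  reactors <- sort(setdiff(unique(bulk$source), tap_source))
  for (r in reactors) {
    ar <- bulk[bulk$source == r, , drop = FALSE]
    ar <- ar[order(ar$day), , drop = FALSE]
    for (i in seq_len(nrow(ar))) {
      d <- abs(tap$day - ar$day[i])
      j <- which.min(d)
      if (d[j] > tol_days) {
        warning(sprintf(
          "skipping %s day %g: no tap event within %g days", r, ar$day[i], tol_days
        ))
        next
      }
      out[[length(out) + 1L]] <- ngtrInstantaneous(
        tap[[field]][j], ar[[field]][i], config,
        day = ar$day[i], reactor = r
      )
    }
  }

  if (!is.null(biofilm) && nrow(biofilm) > 0L) {
    for (r in sort(unique(as.character(biofilm$reactor)))) {
      bf <- biofilm[biofilm$reactor == r, , drop = FALSE]
      bf <- bf[order(bf$day), , drop = FALSE]
      if (nrow(bf) < 2L) next
      for (i in seq_len(nrow(bf) - 1L)) {
        est <- tryCatch(
          ngtrNonsteady(bulk, bf[i, ], bf[i + 1L, ], config,
            tap_source = tap_source, tol_days = tol_days,
            field = field, bf_field = bf_field, endpoint = endpoint
          ),
          error = function(e) {
            warning(sprintf(
              "skipping NSS %s (%g, %g]: %s", r, bf$day[i], bf$day[i + 1L],
              conditionMessage(e)
            ))
            NULL
          }
        )
        if (!is.null(est)) out[[length(out) + 1L]] <- est
      }
    }
  }

  if (length(out) == 0L) stop("no estimable intervals in the input series")
  res <- do.call(rbind, out)
  res[order(res$method == "NSS", res$reactor, res$t2), , drop = FALSE]
}
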
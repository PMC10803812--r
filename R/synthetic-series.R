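#' Scenario for a synthetic reactor time series
#'
#' Describes a forward simulation of the reactor cell balance
#' \deqn{V \, dC_{AR}/dt = Q (C_{tap} - C_{AR}) + NGTR(t) - r_{bf}(t)}
#' with a biofilm pool \eqn{N_{bf}(t) = \int r_{bf}\,dt}, where
#' \eqn{r_{bf}} is the rate at which cells accumulate on the wall.
#' Profiles may be given as constants or as functions of the day
#' (piecewise-constant steps via \code{stats::stepfun} work); NGTR may be
#' negative (net decay). Measurement noise is multiplicative lognormal
#' with a stated geometric CV, matching the geometric-mean reporting used
#' for cell counts. Default constants echo the study scale: Q = 2.1
#' mL/min, V = 1008 mL, tap ICC ~1e3 cells/mL, reactor ICC in the
#' 1e4-1e5 cells/mL range — realistic magnitudes, not fitted values.
#'
#' @param config a \code{\link{ReactorConfig}}
#' @param duration_days simulated duration (days)
#' @param sample_interval_days spacing of bulk sampling events (days)
#' @param tap_profile influent ICC (cells/mL); constant or function(day)
#' @param ngtr_profile NGTR (cells/day); constant or function(day)
#' @param biofilm_accum_profile wall accumulation rate (cells/day);
#'   constant or function(day)
#' @param noise_gcv geometric CV of the multiplicative lognormal
#'   measurement noise (0 = noise-free)
#' @param c0 initial bulk ICC (cells/mL); default the analytic steady
#'   state of the day-0 rates
#' @param biofilm_sample_days days on which the biofilm pool is sampled;
#'   default 5 evenly spaced bulk sampling days
#' @param seed RNG seed; fully determines the output
#' @return a \code{SeriesScenario} list
#' @export
seriesScenario <- function(config = ReactorConfig(),
                           duration_days = 40,
                           sample_interval_days = 1,
                           tap_profile = 1e3,
                           ngtr_profile = 5e7,
                           biofilm_accum_profile = 1e6,
                           noise_gcv = 0.3,
                           c0 = NULL,
                           biofilm_sample_days = NULL,
                           seed = 1L) {
  asFun <- function(p) if (is.function(p)) p else {
    force(p); function(day) rep_len(p, length(day))
  }
  tap <- asFun(tap_profile)
  ngtr <- asFun(ngtr_profile)
  bfa <- asFun(biofilm_accum_profile)
  q_day <- flowMlMin(config) * 1440
  if (is.null(c0)) {
    # steady state of the day-0 rates: Q(Ctap - C) + NGTR - r_bf = 0
    c0 <- tap(0) + (ngtr(0) - bfa(0)) / q_day
  }
  if (is.null(biofilm_sample_days)) {
    days <- seq(0, duration_days, by = sample_interval_days)
    biofilm_sample_days <- days[unique(round(seq(1, length(days), length.out = 5)))]
  }
  structure(list(
    config = config, duration_days = duration_days,
    sample_interval_days = sample_interval_days,
    tap_profile = tap, ngtr_profile = ngtr,
    biofilm_accum_profile = bfa, noise_gcv = noise_gcv,
    c0 = c0, biofilm_sample_days = biofilm_sample_days,
    seed = as.integer(seed)
  ), class = "SeriesScenario")
}

# one multiplicative lognormal noise factor per value; sdlog chosen so
# that the geometric SD is 1 + gcv
.lognoise <- function(n, gcv) {
  if (gcv <= 0) return(rep(1, n))
  exp(stats::rnorm(n, mean = 0, sd = log(1 + gcv)))
}

#' Simulate a reactor bulk/biofilm time series with known truth
#'
#' Integrates the scenario's cell balance with fixed-step fourth-order
#' Runge-Kutta at 1/100 of the sampling interval, samples bulk water
#' (influent and reactor) at every interval and the biofilm pool at the
#' scenario's biofilm days, and applies multiplicative lognormal
#' measurement noise. Besides intact cell counts, plausible companion
#' columns (TCC, ATP, chlorine, temperature, pH) are filled in so the
#' output matches the bulk/biofilm CSV schemas. The returned truth record
#' holds the exact state trajectory on the fine integration grid.
#'
#' @param scn a \code{\link{seriesScenario}}
#' @return list with \code{bulk} (data.frame, tap-reservoir source
#'   \code{"tapres"} and reactor source \code{"AR1"}), \code{biofilm}
#'   (data.frame, reactor \code{"AR1"}) and \code{truth} (list: fine-grid
#'   \code{time}, \code{c_ar}, \code{n_bf}, \code{ngtr}, \code{tap},
#'   \code{bf_accum}, plus the sampled days)
#' @examples
#' sim <- simulateReactorSeries(seriesScenario(noise_gcv = 0, seed = 1))
#' head(sim$bulk)
#' @export
simulateReactorSeries <- function(scn) {
  stopifnot(inherits(scn, "SeriesScenario"))
  cfg <- scn$config
  v <- volumeMl(cfg)
  q <- flowMlMin(cfg) * 1440
  dt <- scn$sample_interval_days / 100
  times <- seq(0, scn$duration_days, by = dt)

  deriv <- function(t, y, parms) {
    list(c(
      C = (q * (scn$tap_profile(t) - y[1]) + scn$ngtr_profile(t) -
             scn$biofilm_accum_profile(t)) / v,
      N = scn$biofilm_accum_profile(t)
    ))
  }
  sol <- deSolve::rk4(y = c(C = scn$c0, N = 0), times = times, func = deriv,
                      parms = NULL)
  c_ar <- sol[, "C"]
  n_bf <- sol[, "N"]
  if (any(c_ar < 0)) {
    stop("simulation infeasible: bulk concentration driven negative")
  }

  sample_days <- seq(0, scn$duration_days, by = scn$sample_interval_days)
  si <- vapply(sample_days, function(d) which.min(abs(times - d)), integer(1))
  bf_days <- scn$biofilm_sample_days
  bi <- vapply(bf_days, function(d) which.min(abs(times - d)), integer(1))

  set.seed(scn$seed)
  ns <- length(sample_days)
  tap_true <- scn$tap_profile(sample_days)
  ar_true <- c_ar[si]

  mkBulk <- function(source, icc_true) {
    icc <- icc_true * .lognoise(ns, scn$noise_gcv)
    tcc <- icc / 0.6 * .lognoise(ns, scn$noise_gcv / 2)
    atpi <- icc * 1000 * 3.4e-10 * .lognoise(ns, scn$noise_gcv) # ~nmol/cell scale
    atpt <- atpi / 0.8 * .lognoise(ns, scn$noise_gcv / 2)
    data.frame(
      day = sample_days, source = source, phase = "I",
      tcc_cells_ml = tcc, icc_cells_ml = icc,
      atpt_nM = atpt, atpi_nM = atpi,
      cl2_total_mg_l = 0.1, temp_c = 23, ph = 8.8,
      stringsAsFactors = FALSE
    )
  }
  bulk <- rbind(mkBulk("tapres", tap_true), mkBulk("AR1", ar_true))

  a <- biofilmAreaCm2(cfg)
  nb <- length(bf_days)
  icc_area <- pmax(n_bf[bi], 0) / a * .lognoise(nb, scn$noise_gcv)
  biofilm <- data.frame(
    day = bf_days, reactor = "AR1",
    tcc_cells_cm2 = icc_area / 0.6,
    icc_cells_cm2 = icc_area,
    atpt_nmol_cm2 = icc_area * 4e-10,
    atpi_nmol_cm2 = icc_area * 3.4e-10,
    stringsAsFactors = FALSE
  )

  list(
    bulk = bulk, biofilm = biofilm,
    truth = list(
      time = times, c_ar = c_ar, n_bf = n_bf,
      ngtr = scn$ngtr_profile(times), tap = scn$tap_profile(times),
      bf_accum = scn$biofilm_accum_profile(times),
      sample_days = sample_days, biofilm_sample_days = bf_days,
      c_ar_sampled = ar_true, n_bf_sampled = n_bf[bi]
    )
  )
}

#' Time-averaged truth over a window
#'
#' Mean of a truth-record trajectory over the half-open window
#' \code{(t1, t2]} on the fine integration grid — the quantity a
#' non-steady-state estimate over that window targets.
#'
#' @param truth the \code{truth} element of
#'   \code{\link{simulateReactorSeries}} output
#' @param t1,t2 window bounds (days)
#' @param what trajectory name, e.g. \code{"ngtr"}
#' @return the window mean
#' @export
truthWindowMean <- function(truth, t1, t2, what = "ngtr") {
  sel <- truth$time > t1 & truth$time <= t2
  if (!any(sel)) stop("empty truth window")
  mean(truth[[what]][sel])
}
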
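#' Culture measurements for burden calibration
#'
#' The experimental scalars from an induction run that fix the
#' production flux and growth-rate constraints of the recombinant model.
#'
#' @param titer final product titer, mg/L.
#' @param duration induction duration, h.
#' @param od_initial,od_final OD600 at induction and harvest.
#' @param od_to_cdw conversion factor, g/L cell dry weight per OD600
#'   (0.74 for *P. haloplanktis* TAC125).
#' @param protein_mw product molecular weight, mg/mmol.
#' @return object of class `burden_measurements`.
#' @export
burden_measurements <- function(titer, duration, od_initial, od_final,
                                od_to_cdw = 0.74, protein_mw) {
  vals <- c(titer = titer, duration = duration, od_initial = od_initial,
            od_final = od_final, od_to_cdw = od_to_cdw, protein_mw = protein_mw)
  if (any(vals[-1] <= 0)) stop("all measurements except titer must be positive")
  if (titer < 0) stop("titer must be non-negative")
  if (od_final < od_initial) stop("od_final below od_initial: culture did not grow")
  structure(as.list(vals), class = "burden_measurements")
}

#' Cell dry weight from optical density
#'
#' @param od OD600.
#' @param od_to_cdw g/L CDW per OD600 unit (default 0.74).
#' @return g/L cell dry weight.
#' @export
cdw_from_od <- function(od, od_to_cdw = 0.74) od * od_to_cdw

#' Average specific production flux from a culture run
#'
#' `(titer / duration) / protein_mw / (od_final * od_to_cdw)`:
#' volumetric production rate, converted to moles, per final biomass.
#' Units: mmol/gCDW/h. For the hCDKL5 run (5.2 mg/L over 8 h,
#' MW 128,082.77, 1.887 gCDW/L) this is 2.7e-6.
#'
#' @param m a `burden_measurements` object.
#' @return specific production flux, mmol/gCDW/h.
#' @export
average_production_flux <- function(m) {
  stopifnot(inherits(m, "burden_measurements"))
  (m$titer / m$duration) / m$protein_mw / cdw_from_od(m$od_final, m$od_to_cdw)
}

#' Average exponential growth rate between two OD readings
#'
#' `(ln od_final - ln od_initial) / duration`.
#'
#' @param od_initial,od_final OD600 readings (positive).
#' @param duration elapsed time, h.
#' @return growth rate, 1/h.
#' @export
average_growth_rate <- function(od_initial, od_final, duration) {
  if (od_initial <= 0 || od_final <= 0) stop("OD readings must be positive")
  if (duration <= 0) stop("duration must be positive")
  (log(od_final) - log(od_initial)) / duration
}

#' Growth-rate burden of production, in percent
#'
#' `100 * (1 - mu_recomb / mu_wt)`: the relative reduction in growth
#' rate of the producing strain against the wild type.
#'
#' @param mu_recomb,mu_wt growth rates, 1/h.
#' @return percent reduction (not rounded; round for reporting).
#' @export
burden_percent <- function(mu_recomb, mu_wt) {
  if (mu_wt <= 0) stop("mu_wt must be positive")
  100 * (1 - mu_recomb / mu_wt)
}

#' Substrate consumption time series
#'
#' @param times sampling times, h (strictly increasing, length >= 3).
#' @param concentrations data.frame or matrix of substrate
#'   concentrations, mM, one column per substrate.
#' @param biomass culture biomass, gCDW/L, same length as `times`; or
#'   supply `od` plus `od_to_cdw` instead.
#' @param od optional OD600 readings used when `biomass` is missing.
#' @param od_to_cdw conversion factor when `od` is given.
#' @return object of class `consumption_series`.
#' @export
consumption_series <- function(times, concentrations, biomass = NULL,
                               od = NULL, od_to_cdw = 0.74) {
  if (is.null(biomass)) {
    if (is.null(od)) stop("supply biomass or od")
    biomass <- cdw_from_od(od, od_to_cdw)
  }
  concentrations <- as.data.frame(concentrations)
  if (length(times) < 3) stop("need at least 3 time points")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (nrow(concentrations) != length(times) || length(biomass) != length(times)) {
    stop("times, concentrations and biomass lengths disagree")
  }
  if (any(as.matrix(concentrations) < 0)) stop("concentrations must be non-negative")
  if (any(biomass <= 0)) stop("biomass must be positive")
  structure(list(times = as.numeric(times), concentrations = concentrations,
                 biomass = as.numeric(biomass)),
            class = "consumption_series")
}

#' Read a consumption series from CSV
#'
#' Expects a `time` column, one column per substrate, and either a `cdw`
#' column (gCDW/L) or an `od` column (converted with `od_to_cdw`).
#'
#' @param path CSV file.
#' @param od_to_cdw OD conversion factor if only `od` is present.
#' @return a `consumption_series`.
#' @export
read_consumption_csv <- function(path, od_to_cdw = 0.74) {
  df <- utils::read.csv(path)
  if (!"time" %in% names(df)) stop("CSV needs a 'time' column")
  bio_col <- intersect(c("cdw", "od"), names(df))[1]
  if (is.na(bio_col)) stop("CSV needs a 'cdw' or 'od' column")
  subs <- setdiff(names(df), c("time", "cdw", "od"))
  consumption_series(df$time, df[, subs, drop = FALSE],
                     biomass = if (bio_col == "cdw") df$cdw else NULL,
                     od = if (bio_col == "od") df$od else NULL,
                     od_to_cdw = od_to_cdw)
}

## trapezoidal cumulative integral of y over x
cum_trapz <- function(x, y) {
  c(0, cumsum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2))
}

#' Estimate specific substrate uptake rates
#'
#' Under balanced growth with a constant specific uptake rate q, the
#' consumed substrate obeys `C0 - C(t) = q * integral(X dt)`, so q is
#' the slope of consumption regressed on the time-integral of biomass.
#' The regression is restricted per substrate to the active-consumption
#' window: from the first sample to the last one before the
#' concentration falls below `depletion_frac` of its initial value
#' (after depletion the residual concentration is flat and carries no
#' rate information).
#'
#' @param series a `consumption_series`.
#' @param depletion_frac fraction of the initial concentration below
#'   which a substrate is considered depleted (default 0.05).
#' @param min_points minimum samples required in the window.
#' @return named numeric vector of positive uptake rates, mmol/gCDW/h.
#' @export
estimate_uptake_rates <- function(series, depletion_frac = 0.05,
                                  min_points = 3L) {
  stopifnot(inherits(series, "consumption_series"))
  integral <- cum_trapz(series$times, series$biomass)
  rates <- vapply(names(series$concentrations), function(s) {
    conc <- series$concentrations[[s]]
    c0 <- conc[1]
    if (c0 <= 0) return(0)
    active <- which(conc >= depletion_frac * c0)
    k <- if (length(active)) max(active) else 1L
    idx <- seq_len(k)
    if (length(idx) < min_points) {
      stop("substrate '", s, "': fewer than ", min_points,
           " samples before depletion; cannot estimate a rate")
    }
    consumed <- c0 - conc[idx]
    total <- consumed[length(consumed)]
    spread <- stats::sd(conc[idx])
    if (total <= 0 && spread < .Machine$double.eps^0.5 * max(c0, 1)) {
      return(0)                                  # flat concentration: no uptake
    }
    if (total < -0.05 * c0) {
      stop("substrate '", s, "': concentration rises over the series; ",
           "no consumption window detectable")
    }
    fit <- stats::lm(consumed ~ integral[idx])
    abs(unname(stats::coef(fit)[2]))
  }, numeric(1))
  rates
}
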
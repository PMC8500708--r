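#' Specific growth rate under exponential growth
#'
#' @param N0,NT cell counts at the start and end of the interval.
#' @param T_h interval duration in hours.
#' @return growth rate `mu = ln(NT / N0) / T` in 1/h.
#' @export
growth_rate <- function(N0, NT, T_h) {
  if (N0 <= 0 || NT <= 0) stop("cell counts must be positive")
  if (T_h <= 0) stop("duration must be positive")
  log(NT / N0) / T_h
}

#' Per-cell uptake flux from media depletion
#'
#' Converts start/end media concentrations and cell counts into a per-cell
#' exchange flux assuming exponential growth: the cell-time integral is
#' `(NT - N0) / mu` (or `N0 * T` in the zero-growth limit). Uptake is
#' positive, secretion negative.
#'
#' @param C0,CT media concentrations at time 0 and T (uM).
#' @param V_mL media volume (mL).
#' @param N0,NT cell counts (cells).
#' @param T_h duration (h).
#' @return flux in nmol per 10^6 cells per hour.
#' @export
uptake_flux <- function(C0, CT, V_mL, N0, NT, T_h) {
  if (C0 < 0 || CT < 0) stop("concentrations must be non-negative")
  mu <- growth_rate(N0, NT, T_h)
  cell_hours <- if (abs(mu) < 1e-12) N0 * T_h else (NT - N0) / mu
  (C0 - CT) * V_mL * 1e6 / cell_hours
}

#' Per-cell uptake fluxes from a media measurement table
#'
#' @param tab data.frame with columns `metabolite`, `C0_uM`, `CT_uM`,
#'   `V_mL`, `N0`, `NT`, `T_h`.
#' @return the table with added columns `mu` (1/h) and `flux`
#'   (nmol per 10^6 cells per h; uptake positive).
#' @export
uptake_flux_table <- function(tab) {
  need <- c("metabolite", "C0_uM", "CT_uM", "V_mL", "N0", "NT", "T_h")
  missing <- setdiff(need, names(tab))
  if (length(missing)) stop("missing columns: ", paste(missing, collapse = ", "))
  tab$mu <- mapply(growth_rate, tab$N0, tab$NT, tab$T_h)
  tab$flux <- mapply(uptake_flux, tab$C0_uM, tab$CT_uM, tab$V_mL,
                     tab$N0, tab$NT, tab$T_h)
  tab
}

#' Concentrations from a calibration standard curve
#'
#' Ordinary linear regression of signal on concentration across the
#' calibration standards, inverted to map sample signals to
#' concentrations. Samples outside the standards' signal range are
#' flagged as extrapolated.
#'
#' @param signals sample signals (numeric).
#' @param standards data.frame with columns `concentration` and `signal`
#'   (>= 2 distinct concentrations).
#' @return list with `concentration`, `extrapolated` (logical),
#'   `r_squared`, `slope`, `intercept`.
#' @export
standard_curve_concentration <- function(signals, standards) {
  stopifnot(all(c("concentration", "signal") %in% names(standards)))
  if (nrow(standards) < 2 || length(unique(standards$concentration)) < 2)
    stop("need at least two standards with distinct concentrations")
  fitlm <- lm(signal ~ concentration, data = standards)
  slope <- coef(fitlm)[["concentration"]]
  if (abs(slope) < .Machine$double.eps)
    stop("degenerate standard curve: zero slope")
  conc <- (signals - coef(fitlm)[["(Intercept)"]]) / slope
  rng <- range(standards$signal)
  # suppress the "essentially perfect fit" note on exact calibration lines
  r2 <- suppressWarnings(summary(fitlm)$r.squared)
  list(concentration = conc,
       extrapolated = signals < rng[1] | signals > rng[2],
       r_squared = r2,
       slope = slope, intercept = coef(fitlm)[["(Intercept)"]])
}
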
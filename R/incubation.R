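#' Net release rate from a start/end concentration pair
#'
#' A closed chamber turns a concentration change into a flux:
#' rate = (c_end - c_start) * volume / duration. Positive values are net
#' release into the water, negative values net uptake by the animal; the
#' sign is never clipped.
#'
#' @param c_start,c_end Concentrations at the start and end of the
#'   incubation, umol L^-1 (uM).
#' @param volume Chamber volume in L, > 0.
#' @param duration Incubation duration in h, > 0.
#' @return Net rate in umol h^-1.
#' @examples
#' net_release_rate(73.5, 75.5, volume = 4.8, duration = 10)  # 0.96
#' @export
net_release_rate <- function(c_start, c_end, volume, duration) {
  if (any(!is.finite(volume) | volume <= 0) ||
      any(!is.finite(duration) | duration <= 0)) {
    stop("invalid geometry: `volume` and `duration` must be > 0",
         call. = FALSE)
  }
  (c_end - c_start) * volume / duration
}

#' Refill-corrected effective start concentration
#'
#' When the start sample is drawn from the incubation chamber itself and the
#' removed water is replaced with refill water of known composition, the
#' concentration actually present at the start of the incubation is the
#' volume-weighted mixture
#' \deqn{c_{eff} = c_{meas}(1 - v_r/V) + c_{refill}\, v_r/V.}
#' The result is a convex combination and always lies between the two inputs.
#'
#' @param c_measured Concentration of the pre-refill start sample, uM.
#' @param c_refill Concentration of the refill water, uM.
#' @param refill_volume Volume replaced, L; 0 <= refill_volume < chamber.
#' @param chamber_volume Chamber volume, L.
#' @return Effective start concentration, uM.
#' @examples
#' refill_corrected_start(100, 50, refill_volume = 1, chamber_volume = 4.8)
#' @export
refill_corrected_start <- function(c_measured, c_refill, refill_volume,
                                   chamber_volume) {
  if (any(refill_volume < 0 | refill_volume >= chamber_volume)) {
    stop("invalid refill: need 0 <= refill_volume < chamber_volume",
         call. = FALSE)
  }
  w <- refill_volume / chamber_volume
  c_measured * (1 - w) + c_refill * w
}

#' Oxygen consumption rate from a logged O2 series
#'
#' Fits an ordinary-least-squares line to the O2 concentration time series
#' and converts the (negative) slope into a whole-chamber consumption rate:
#' rate = -slope * volume. Positive values mean consumption.
#'
#' @param time_h Sampling times in h; at least 3 points spanning > 0 h.
#' @param o2_um O2 concentrations in uM, same length as `time_h`.
#' @param volume Chamber volume in L.
#' @return List with `rate` (umol O2 h^-1), `slope` (uM h^-1) and
#'   `r_squared` of the linear fit.
#' @examples
#' t <- 0:10
#' oxygen_consumption_rate(t, 300 - 10 * t, volume = 1.3)  # 13 umol O2/h
#' @export
oxygen_consumption_rate <- function(time_h, o2_um, volume) {
  if (length(time_h) < 3L || length(o2_um) != length(time_h)) {
    stop("insufficient series: need >= 3 (time, O2) points", call. = FALSE)
  }
  if (diff(range(time_h)) <= 0) {
    stop("insufficient series: time points must span > 0 h", call. = FALSE)
  }
  fit <- stats::lm(o2_um ~ time_h)
  slope <- unname(stats::coef(fit)[2L])
  ss_tot <- sum((o2_um - mean(o2_um))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  list(rate = -slope * volume, slope = slope, r_squared = r2)
}

#' Carbon respiration from oxygen consumption
#'
#' Applies the respiratory quotient: C rate = O2 rate * RQ. With the default
#' RQ of 1 (O2:C = 1) this is the identity.
#'
#' @param o2_rate Oxygen consumption in umol O2 h^-1.
#' @param constants An [iso_constants()] object carrying the respiratory
#'   quotient.
#' @return Carbon respiration in umol C h^-1.
#' @export
respiration_from_oxygen <- function(o2_rate, constants = iso_constants()) {
  o2_rate * constants$respiratory_quotient
}

#' Tracer-carbon release rate for a DIC or POC pool
#'
#' The excess-13C inventory of the pool is computed at the start and at the
#' end of the incubation as \eqn{E = (F(\delta) - F_{bg})\, C\, V} (umol 13C),
#' and the substrate-derived carbon flux follows as
#' \deqn{(E_{end} - E_{start}) / duration / F_{substrate}.}
#' By default the background atom fraction is the start sample's own atom
#' fraction, which makes `E_start` zero and controls for enrichment carried
#' over from the feeding phase; a fixed background (e.g. unfed-animal water)
#' can be supplied instead.
#'
#' @param c_start,c_end Pool concentrations, uM.
#' @param d13c_start,d13c_end Pool delta-13C, per-mil.
#' @param volume Chamber volume, L.
#' @param duration Incubation duration, h.
#' @param f_substrate Substrate atom fraction, (0, 1].
#' @param f_background Background atom fraction; `NULL` (default) uses the
#'   start sample's atom fraction.
#' @param constants An [iso_constants()] object.
#' @return Tracer-carbon release in umol substrate-C h^-1.
#' @export
tracer_release_rate <- function(c_start, c_end, d13c_start, d13c_end,
                                volume, duration, f_substrate,
                                f_background = NULL,
                                constants = iso_constants()) {
  if (any(is.na(c(d13c_start, d13c_end)))) {
    stop("missing isotope: start and end delta-13C are required for a ",
         "tracer flux", call. = FALSE)
  }
  if (any(!is.finite(volume) | volume <= 0) ||
      any(!is.finite(duration) | duration <= 0)) {
    stop("invalid geometry: `volume` and `duration` must be > 0",
         call. = FALSE)
  }
  f_start <- delta_to_atom_fraction(d13c_start, constants)
  f_end <- delta_to_atom_fraction(d13c_end, constants)
  if (is.null(f_background)) f_background <- f_start
  e_start <- (f_start - f_background) * c_start * volume
  e_end <- (f_end - f_background) * c_end * volume
  tracer_carbon(e_end - e_start, f_substrate) / duration
}

#' Control-corrected flux
#'
#' Subtracts the mean rate of the parallel no-organism control chambers from
#' an animal's rate, removing background drift of the water itself
#' (microbial activity, wall effects, analytical offsets). With no controls
#' available, the rate is returned unchanged with a warning.
#'
#' @param rate Animal rate, umol h^-1.
#' @param control_rates Numeric vector of control rates computed with the
#'   same formula on the same pool; may be empty.
#' @return Corrected rate, umol h^-1.
#' @examples
#' control_corrected(5, c(1, 3))  # 3
#' @export
control_corrected <- function(rate, control_rates) {
  if (length(control_rates) == 0L) {
    warning("no control chambers supplied; rate returned uncorrected",
            call. = FALSE)
    return(rate)
  }
  rate - mean(control_rates)
}

#' Standardize a whole-chamber rate to tissue biomass
#'
#' Divides a raw chamber rate (umol h^-1) by the animal's tissue organic
#' carbon (mol OC), giving the budget unit umol C (mol OC)^-1 h^-1.
#'
#' @param raw_rate Whole-chamber rate, umol h^-1.
#' @param tissue_oc Tissue organic carbon, mol, > 0.
#' @return Standardized rate, umol C (mol OC)^-1 h^-1.
#' @examples
#' standardize_to_biomass(2, 0.02)  # 100
#' @export
standardize_to_biomass <- function(raw_rate, tissue_oc) {
  if (any(!is.finite(tissue_oc) | tissue_oc <= 0)) {
    stop("invalid biomass: `tissue_oc` must be > 0", call. = FALSE)
  }
  raw_rate / tissue_oc
}

#' Pool POC filter subsamples into one concentration and delta value
#'
#' POC is collected on one to three filters per chamber, each filtering a
#' known water volume. The subsample carbon amounts are summed over the total
#' filtered volume, and the delta-13C is combined as a carbon-weighted mean
#' of the subsample values (filters partition one water volume, so carbon
#' amounts -- not volumes -- weight the isotope signal).
#'
#' @param c_umol Carbon amount on each filter, umol.
#' @param volume_l Water volume filtered through each filter, L.
#' @param d13c delta-13C of each filter's carbon, per-mil.
#' @return List with `concentration_um` and `d13c`.
#' @export
pool_poc_filters <- function(c_umol, volume_l, d13c) {
  stopifnot(length(c_umol) == length(volume_l),
            length(c_umol) == length(d13c), length(c_umol) >= 1L)
  if (any(volume_l <= 0)) stop("filtered volumes must be > 0", call. = FALSE)
  conc <- sum(c_umol) / sum(volume_l)
  dw <- if (sum(c_umol) > 0) sum(d13c * c_umol) / sum(c_umol) else mean(d13c)
  list(concentration_um = conc, d13c = dw)
}
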
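#' Assemble a per-animal carbon budget row
#'
#' Combines the standardized flux components of one animal into the machine
#' form of a total-C / tracer-C budget. Total-C turnover is the sum of
#' respiration, POC release and DOC release. Tracer fractions partition the
#' utilized substrate carbon over tissue incorporation, respiration and POC
#' release only -- no tracer DOC is measured -- and are reported only when
#' all three tracer terms are non-negative and their sum is positive.
#'
#' All rates must share the unit umol C (mol OC)^-1 h^-1.
#'
#' @param specimen_id Specimen label.
#' @param respiration_total,poc_total,doc_total Standardized total-C fluxes.
#' @param incorporation_tracer,respiration_tracer,poc_tracer Standardized
#'   tracer-C fluxes.
#' @return A one-row data.frame with the components, `total_turnover`, the
#'   tracer fractions (`frac_incorporation`, `frac_respiration`, `frac_poc`,
#'   `NA` when undefined) and `tracer_fractions_defined`.
#' @examples
#' assemble_budget("ac1", 10, 5, 5, 88, 9, 3)
#' @export
assemble_budget <- function(specimen_id, respiration_total, poc_total,
                            doc_total, incorporation_tracer,
                            respiration_tracer, poc_tracer) {
  tot <- respiration_total + poc_total + doc_total
  tr <- c(incorporation_tracer, respiration_tracer, poc_tracer)
  ok <- all(is.finite(tr)) && all(tr >= 0) && sum(tr) > 0
  fr <- if (ok) tr / sum(tr) else rep(NA_real_, 3L)
  data.frame(
    specimen_id = specimen_id,
    respiration_total = respiration_total,
    poc_total = poc_total,
    doc_total = doc_total,
    total_turnover = tot,
    incorporation_tracer = incorporation_tracer,
    respiration_tracer = respiration_tracer,
    poc_tracer = poc_tracer,
    frac_incorporation = fr[1L],
    frac_respiration = fr[2L],
    frac_poc = fr[3L],
    tracer_fractions_defined = ok,
    stringsAsFactors = FALSE
  )
}

#' Tissue carbon turned over as POC per day
#'
#' Converts a standardized POC release rate (umol C per mol tissue OC per
#' hour) into the percentage of the tissue carbon pool released per day:
#' percent d^-1 = rate * 24 * 1e-6 * 100.
#'
#' @param poc_rate Standardized POC release, umol C (mol OC)^-1 h^-1.
#' @return Percent of tissue carbon per day.
#' @examples
#' tissue_poc_turnover(100)  # 0.24 % per day
#' @export
tissue_poc_turnover <- function(poc_rate) {
  poc_rate * 24 * 1e-6 * 100
}

#' Scale a per-individual flux to an areal flux
#'
#' Multiplies a per-individual rate by a population density, e.g. to scale
#' (pseudo-)fecal POC release of single bivalves to a reef-patch flux.
#'
#' @param per_individual_rate Rate per individual, umol C ind^-1 h^-1.
#' @param density Individuals per m^2, >= 0.
#' @param signif_digits If not `NULL`, round the result to this many
#'   significant figures for reporting (raw product also returned).
#' @return List with `raw` and `rounded` (equal to `raw` when
#'   `signif_digits` is `NULL`), umol C m^-2 h^-1.
#' @examples
#' areal_flux(2.6, 23, signif_digits = 2)  # 59.8 -> 60
#' @export
areal_flux <- function(per_individual_rate, density, signif_digits = NULL) {
  if (any(density < 0)) {
    stop("invalid density: `density` must be >= 0", call. = FALSE)
  }
  raw <- per_individual_rate * density
  rounded <- if (is.null(signif_digits)) raw else signif(raw, signif_digits)
  list(raw = raw, rounded = rounded)
}

#' Food-chain transfer efficiency
#'
#' Percentage of the labelled (pseudo-)fecal carbon produced by the
#' producers that ended up incorporated in the consumers' tissue over the
#' same period: 100 * consumer 13C / fecal 13C. Values above 100 indicate a
#' mass-balance violation and trigger a warning (measurement noise or
#' unaccounted pools), but are returned unclipped.
#'
#' @param fecal_13c_produced Excess 13C in the (pseudo-)feces, umol, > 0.
#' @param consumer_13c_incorporated Excess 13C in consumer tissue, umol.
#' @return Transfer efficiency in percent.
#' @examples
#' transfer_efficiency(10, 3.7)  # 37
#' @export
transfer_efficiency <- function(fecal_13c_produced,
                                consumer_13c_incorporated) {
  if (any(!is.finite(fecal_13c_produced) | fecal_13c_produced <= 0)) {
    stop("invalid denominator: fecal 13C production must be > 0",
         call. = FALSE)
  }
  eff <- 100 * consumer_13c_incorporated / fecal_13c_produced
  if (any(eff > 100, na.rm = TRUE)) {
    warning("transfer efficiency above 100%: consumers appear to have ",
            "incorporated more 13C than was produced (mass-balance warning)",
            call. = FALSE)
  }
  eff
}

#' Total substrate supply over repeated feeding cycles
#'
#' per_day * n_cycles; e.g. a daily ration repeated over four
#' feeding/collection cycles gives the whole-experiment carbon supply.
#'
#' @param per_day Supply per cycle, umol C d^-1.
#' @param n_cycles Number of cycles, integer >= 1.
#' @return Total supply, umol C.
#' @examples
#' daily_supply_total(7.2, 4)  # 28.8
#' @export
daily_supply_total <- function(per_day, n_cycles) {
  if (any(n_cycles < 1)) stop("`n_cycles` must be >= 1", call. = FALSE)
  per_day * n_cycles
}
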
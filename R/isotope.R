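#' Physical constants for carbon-isotope mass balance
#'
#' Bundles the two constants every conversion in the package depends on: the
#' \eqn{^{13}C/^{12}C} isotope ratio of the Vienna Pee Dee Belemnite (VPDB)
#' standard, and the respiratory quotient used to convert oxygen consumption
#' into carbon respiration.
#'
#' @param r_vpdb Isotope ratio \eqn{^{13}C/^{12}C} of the VPDB standard
#'   (dimensionless). Default 0.0111802.
#' @param respiratory_quotient Mol C respired per mol O2 consumed. Default 1,
#'   i.e. O2 consumption maps one-to-one onto CO2 production.
#' @return An object of class `iso_constants`, a named list with elements
#'   `r_vpdb` and `respiratory_quotient`.
#' @examples
#' iso_constants()
#' iso_constants(respiratory_quotient = 0.8)
#' @export
iso_constants <- function(r_vpdb = 0.0111802, respiratory_quotient = 1.0) {
  if (!is.numeric(r_vpdb) || length(r_vpdb) != 1L || !is.finite(r_vpdb) ||
      r_vpdb <= 0) {
    stop("`r_vpdb` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(respiratory_quotient) || length(respiratory_quotient) != 1L ||
      !is.finite(respiratory_quotient) || respiratory_quotient <= 0) {
    stop("`respiratory_quotient` must be a single positive number",
         call. = FALSE)
  }
  structure(list(r_vpdb = r_vpdb,
                 respiratory_quotient = respiratory_quotient),
            class = "iso_constants")
}

#' @export
print.iso_constants <- function(x, ...) {
  cat("Isotope constants\n")
  cat(sprintf("  R (VPDB 13C/12C)     : %.7f\n", x$r_vpdb))
  cat(sprintf("  respiratory quotient : %g mol C (mol O2)^-1\n",
              x$respiratory_quotient))
  invisible(x)
}

#' Convert delta-13C to 13C atom fraction
#'
#' The delta notation expresses a sample ratio relative to the VPDB standard:
#' \deqn{R_{sample} = (\delta/1000 + 1)\, R_{VPDB}}
#' and the atom fraction (fractional abundance of \eqn{^{13}C} among all
#' carbon atoms) follows as \eqn{F = R_{sample} / (1 + R_{sample})}. Atom
#' fraction is the linear currency for isotope mass balance; delta values are
#' not additive at strong enrichment.
#'
#' @param delta delta-13C in per-mil vs VPDB. Vectorised. Must be > -1000
#'   (at -1000 the sample would contain no 13C at all).
#' @param constants An [iso_constants()] object.
#' @return Atom fraction(s) in (0, 1).
#' @examples
#' delta_to_atom_fraction(0)      # F of the standard itself, ~0.011057
#' delta_to_atom_fraction(1000)   # doubled isotope ratio
#' @seealso [atom_fraction_to_delta()] for the inverse.
#' @export
delta_to_atom_fraction <- function(delta, constants = iso_constants()) {
  stopifnot(inherits(constants, "iso_constants"))
  if (!is.numeric(delta)) stop("`delta` must be numeric", call. = FALSE)
  if (any(delta <= -1000, na.rm = TRUE)) {
    stop("invalid delta: values <= -1000 per-mil imply a non-positive ",
         "isotope ratio", call. = FALSE)
  }
  r <- (delta / 1000 + 1) * constants$r_vpdb
  r / (1 + r)
}

#' Convert 13C atom fraction to delta-13C
#'
#' Closed-form inverse of [delta_to_atom_fraction()]:
#' \eqn{\delta = 1000\,(F / ((1 - F)\,R_{VPDB}) - 1)}.
#'
#' @param f Atom fraction(s), strictly inside (0, 1). Vectorised.
#' @param constants An [iso_constants()] object.
#' @return delta-13C in per-mil vs VPDB.
#' @examples
#' atom_fraction_to_delta(delta_to_atom_fraction(42.5))  # 42.5
#' @export
atom_fraction_to_delta <- function(f, constants = iso_constants()) {
  stopifnot(inherits(constants, "iso_constants"))
  if (!is.numeric(f)) stop("`f` must be numeric", call. = FALSE)
  if (any(f <= 0 | f >= 1, na.rm = TRUE)) {
    stop("invalid fraction: atom fractions must lie strictly in (0, 1)",
         call. = FALSE)
  }
  1000 * (f / ((1 - f) * constants$r_vpdb) - 1)
}

#' Excess 13C in a carbon pool
#'
#' The amount of 13C above natural background in a pool of known size:
#' \deqn{E = (F_{sample} - F_{background})\; C}
#' with both atom fractions dimensionless and the pool size in umol C, so the
#' result is in umol 13C. Negative values (sample below background) are
#' legitimate measurement noise and are returned unclipped, with a warning,
#' so that downstream budgets stay mass-balanced.
#'
#' @param f_sample Atom fraction of the sample, in \[0, 1).
#' @param f_background Atom fraction of the unenriched background, in \[0, 1).
#' @param carbon_amount Pool size in umol C, >= 0.
#' @return Excess 13C in umol.
#' @examples
#' excess_carbon13(0.030, 0.011, 100)  # 1.9 umol 13C
#' @export
excess_carbon13 <- function(f_sample, f_background, carbon_amount) {
  if (any(f_sample < 0 | f_sample >= 1, na.rm = TRUE) ||
      any(f_background < 0 | f_background >= 1, na.rm = TRUE)) {
    stop("atom fractions must lie in [0, 1)", call. = FALSE)
  }
  if (any(carbon_amount < 0, na.rm = TRUE)) {
    stop("invalid amount: `carbon_amount` must be >= 0", call. = FALSE)
  }
  e <- (f_sample - f_background) * carbon_amount
  if (any(e < 0, na.rm = TRUE)) {
    warning("negative excess 13C (sample below background); ",
            "value propagated unclipped", call. = FALSE)
  }
  e
}

#' Substrate-derived tracer carbon from excess 13C
#'
#' Divides excess 13C by the substrate's atom fraction to recover the amount
#' of substrate-derived carbon (both its 13C and its 12C) in the pool:
#' tracer C = E / F_substrate. With a fully labelled substrate
#' (F_substrate = 1) tracer C equals the excess 13C itself.
#'
#' @param excess_13c Excess 13C in umol (may be negative; passed through).
#' @param f_substrate Atom fraction of the labelled substrate, in (0, 1\].
#' @return Substrate-derived carbon in umol C.
#' @examples
#' tracer_carbon(1.9, 0.95)  # 2 umol substrate C
#' @export
tracer_carbon <- function(excess_13c, f_substrate) {
  if (any(f_substrate <= 0 | f_substrate > 1, na.rm = TRUE)) {
    stop("invalid substrate fraction: `f_substrate` must lie in (0, 1]",
         call. = FALSE)
  }
  excess_13c / f_substrate
}
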
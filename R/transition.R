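#' Two-state unfolding transition
#'
#' A single two-state unfolding event characterised by its van't Hoff
#' enthalpy and melting temperature. The calorimetric amplitude `dH_cal`
#' (the area the transition contributes to the excess heat capacity curve)
#' defaults to `dH_vH`; letting the two differ is what makes a multi-peak
#' deconvolution "non-2-state".
#'
#' @param dH_vH van't Hoff enthalpy, kJ/mol; must be positive.
#' @param Tm melting temperature, kelvin; must be positive.
#' @param dH_cal calorimetric amplitude, kJ/mol; non-negative
#'   (zero gives a transition with no heat signature). Defaults to `dH_vH`.
#' @param celsius_Tm alternative to `Tm`: melting temperature in degrees
#'   Celsius, converted on construction.
#' @return An object of class `"transition"`.
#' @examples
#' transition(98.9, celsius_Tm = 67.2)
#' @export
transition <- function(dH_vH, Tm = NULL, dH_cal = dH_vH, celsius_Tm = NULL) {
  if (is.null(Tm)) {
    if (is.null(celsius_Tm)) stop("supply Tm (K) or celsius_Tm (degrees C)")
    Tm <- celsius_to_kelvin(celsius_Tm)
  }
  stopifnot(is.numeric(dH_vH), length(dH_vH) == 1L,
            is.numeric(Tm), length(Tm) == 1L,
            is.numeric(dH_cal), length(dH_cal) == 1L)
  if (!is.finite(dH_vH) || dH_vH <= 0) stop("dH_vH must be positive (kJ/mol)")
  if (!is.finite(Tm) || Tm <= 0) stop("Tm must be positive (K)")
  if (!is.finite(dH_cal) || dH_cal < 0) stop("dH_cal must be non-negative (kJ/mol)")
  structure(list(dH_vH = dH_vH, Tm = Tm, dH_cal = dH_cal),
            class = "transition")
}

#' @param x,... print method arguments.
#' @rdname transition
#' @export
print.transition <- function(x, ...) {
  cat(sprintf(
    "two-state transition: dH_vH = %.1f kJ/mol, Tm = %.2f K (%.2f degC)",
    x$dH_vH, x$Tm, kelvin_to_celsius(x$Tm)))
  if (!isTRUE(all.equal(x$dH_cal, x$dH_vH)))
    cat(sprintf(", dH_cal = %.1f kJ/mol", x$dH_cal))
  cat("\n")
  invisible(x)
}

# Normalise a transition / list of transitions / matrix-like input into a
# plain list of "transition" objects.
as_transitions <- function(trs) {
  if (inherits(trs, "transition")) return(list(trs))
  if (is.list(trs) && all(vapply(trs, inherits, logical(1), "transition")))
    return(trs)
  stop("expected a transition or a list of transition objects")
}

transitions_df <- function(trs) {
  trs <- as_transitions(trs)
  data.frame(
    dH_vH  = vapply(trs, `[[`, numeric(1), "dH_vH"),
    Tm     = vapply(trs, `[[`, numeric(1), "Tm"),
    dH_cal = vapply(trs, `[[`, numeric(1), "dH_cal"))
}

#' Sampled DSC thermogram
#'
#' A temperature / molar excess heat capacity trace on a strictly increasing
#' temperature grid, with optional sample metadata.
#'
#' @param T temperature grid, kelvin, strictly increasing, length >= 2.
#' @param Cp excess heat capacity at each grid point, kJ/(mol K).
#' @param strand_conc strand concentration, mol/L (metadata).
#' @param scan_rate scan rate, K/h (metadata).
#' @return An object of class `"thermogram"`.
#' @export
thermogram <- function(T, Cp, strand_conc = NA_real_, scan_rate = NA_real_) {
  stopifnot(is.numeric(T), is.numeric(Cp))
  if (length(T) != length(Cp)) stop("T and Cp must have equal length")
  if (length(T) < 2L) stop("a thermogram needs at least 2 grid points")
  if (anyNA(T) || anyNA(Cp)) stop("T and Cp must be finite")
  if (any(diff(T) <= 0)) stop("temperature grid must be strictly increasing")
  if (any(T <= 0)) stop("temperatures must be positive kelvin")
  structure(list(T = as.numeric(T), Cp = as.numeric(Cp),
                 strand_conc = strand_conc, scan_rate = scan_rate),
            class = "thermogram")
}

#' @export
print.thermogram <- function(x, ...) {
  cat(sprintf(
    "DSC thermogram: %d points, %.2f-%.2f degC, Cp range [%.3g, %.3g] kJ/(mol K)\n",
    length(x$T), kelvin_to_celsius(min(x$T)), kelvin_to_celsius(max(x$T)),
    min(x$Cp), max(x$Cp)))
  invisible(x)
}

#' @export
plot.thermogram <- function(x, ...,
                            xlab = "Temperature (°C)",
                            ylab = expression(C[p] ~ "(kJ " * mol^-1 * K^-1 * ")"),
                            type = "l") {
  plot(kelvin_to_celsius(x$T), x$Cp, type = type, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}
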
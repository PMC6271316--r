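#' Van't Hoff equilibrium constant of a two-state transition
#'
#' For a unimolecular two-state unfolding equilibrium with a
#' temperature-independent van't Hoff enthalpy (no heat-capacity increment),
#' \deqn{K(T) = \exp[-(\Delta H_{vH}/R)\,(1/T - 1/T_m)].}
#' `K(Tm) = 1` by construction, and K increases with temperature for
#' positive enthalpy.
#'
#' @param T temperature(s), kelvin; must be positive.
#' @param tr a [transition()].
#' @return Dimensionless equilibrium constant(s), same length as `T`.
#' @examples
#' tr <- transition(98.9, celsius_Tm = 67.2)
#' vant_hoff_K(tr$Tm, tr)   # exactly 1
#' @export
vant_hoff_K <- function(T, tr) {
  stopifnot(inherits(tr, "transition"), is.numeric(T))
  if (any(!is.finite(T)) || any(T <= 0))
    stop("temperatures must be positive kelvin")
  exp(-(tr$dH_vH / R_GAS) * (1 / T - 1 / tr$Tm))
}

#' Excess heat capacity of a sum of independent two-state transitions
#'
#' The "non-2-state" DSC model: each transition i contributes
#' \deqn{C_p^{(i)}(T) = \Delta H_{cal,i}\,
#'   \frac{\Delta H_{vH,i}}{R T^2}\, \frac{K_i}{(1+K_i)^2},}
#' and the curve is the sum over transitions. For a single transition with
#' `dH_cal = dH_vH` the maximum sits at `Tm` with height
#' `dH^2 / (4 R Tm^2)`, and the area under the curve equals `dH_cal`.
#'
#' @param T temperature(s), kelvin.
#' @param trs a [transition()] or non-empty list of them.
#' @return Excess heat capacity, kJ/(mol K), same length as `T`.
#' @export
excess_heat_capacity <- function(T, trs) {
  trs <- as_transitions(trs)
  if (length(trs) == 0L) stop("at least one transition is required")
  cp <- numeric(length(T))
  for (tr in trs) {
    K <- vant_hoff_K(T, tr)
    cp <- cp + tr$dH_cal * (tr$dH_vH / (R_GAS * T^2)) * K / (1 + K)^2
  }
  cp
}

#' Total unfolding enthalpy by curve integration
#'
#' Trapezoidal integral of a baseline-corrected excess heat capacity trace
#' over its temperature grid: the model-free calorimetric estimate of the
#' total unfolding enthalpy. The trace is assumed baseline-corrected
#' (Cp near zero at both ends); enthalpy carried by transition tails outside
#' the scanned window is necessarily missed.
#'
#' @param curve a [thermogram()] (baseline-corrected).
#' @return Total enthalpy, kJ/mol.
#' @seealso [tm_total()], [fit_baseline()]
#' @export
total_enthalpy <- function(curve) {
  stopifnot(inherits(curve, "thermogram"))
  pracma::trapz(curve$T, curve$Cp)
}

#' Aggregate melting temperature by curve integration
#'
#' The area-median temperature of a baseline-corrected thermogram: the
#' temperature at which the cumulative trapezoidal integral of Cp reaches
#' half the total area, located by linear interpolation between grid points.
#' For a single symmetric peak this is the peak Tm; for a multi-peak curve
#' it is an area-weighted aggregate melting temperature.
#'
#' @inheritParams total_enthalpy
#' @return Aggregate melting temperature, kelvin.
#' @export
tm_total <- function(curve) {
  stopifnot(inherits(curve, "thermogram"))
  cum <- pracma::cumtrapz(curve$T, curve$Cp)[, 1]
  total <- cum[length(cum)]
  if (!is.finite(total) || total <= 0)
    stop("total area under the curve must be positive")
  half <- total / 2
  i <- which(cum >= half)[1]
  if (i == 1L) return(curve$T[1])
  # linear interpolation of the cumulative area between grid points
  frac <- (half - cum[i - 1]) / (cum[i] - cum[i - 1])
  curve$T[i - 1] + frac * (curve$T[i] - curve$T[i - 1])
}

#' Melt summary of a thermogram
#'
#' Convenience wrapper bundling the integral quantities ([total_enthalpy()],
#' [tm_total()]) with an optional per-transition decomposition.
#'
#' @inheritParams total_enthalpy
#' @param transitions optional list of fitted [transition()]s.
#' @return A list of class `"melt_summary"` with `dH_tot` (kJ/mol),
#'   `Tm_tot` (K) and `per_transition`.
#' @export
melt_summary <- function(curve, transitions = NULL) {
  out <- list(dH_tot = total_enthalpy(curve),
              Tm_tot = tm_total(curve),
              per_transition = if (is.null(transitions)) list()
                               else as_transitions(transitions))
  if (out$dH_tot <= 0) stop("dH_tot must be positive for an unfolding curve")
  class(out) <- "melt_summary"
  out
}

#' @export
print.melt_summary <- function(x, ...) {
  cat(sprintf("melt summary: dH_tot = %.1f kJ/mol, Tm_tot = %.2f degC\n",
              x$dH_tot, kelvin_to_celsius(x$Tm_tot)))
  for (tr in x$per_transition) print(tr)
  invisible(x)
}
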
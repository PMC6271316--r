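#' Molar water concentration of a glycerol solution
#'
#' Water concentration of a glycerol solution at `pct` % w/v, assuming
#' additive volumes: one litre contains `1000 - 10 * pct` grams of water,
#' so `[H2O] = (1000 - 10 * pct) / 18.015` mol/L. Density corrections are
#' deliberately omitted (documented model simplification).
#'
#' @param glycerol_pct_wv glycerol concentration, percent weight/volume,
#'   in `[0, 50]`.
#' @return Water concentration, mol/L.
#' @examples
#' water_concentration(0)   # 55.51 mol/L
#' water_concentration(5)   # 52.73 mol/L
#' @export
water_concentration <- function(glycerol_pct_wv) {
  stopifnot(is.numeric(glycerol_pct_wv))
  if (any(glycerol_pct_wv < 0)) stop("glycerol percentage cannot be negative")
  if (any(glycerol_pct_wv > 50)) stop("glycerol percentage above 50% w/v is unsupported")
  (1000 - 10 * glycerol_pct_wv) / 18.015
}

#' Apparent ln K at a reference temperature by van't Hoff extrapolation
#'
#' Extrapolates the unfolding equilibrium constant measured at the melting
#' temperature (`K(Tm) = 1`) to a common reference temperature:
#' \deqn{\ln K(T_{ref}) = -(\Delta H / R)\,(1/T_{ref} - 1/T_m).}
#' Zero when `Tm == T_ref`; negative (folded favoured) when the sample
#' melts above the reference.
#'
#' @param Tm observed melting temperature, K.
#' @param dH unfolding enthalpy used for the extrapolation, kJ/mol.
#' @param T_ref reference temperature, K.
#' @return Dimensionless ln K at `T_ref`.
#' @export
apparent_lnK <- function(Tm, dH, T_ref) {
  stopifnot(is.numeric(Tm), is.numeric(dH), is.numeric(T_ref))
  if (any(Tm <= 0) || any(T_ref <= 0)) stop("temperatures must be positive kelvin")
  if (any(dH <= 0)) stop("dH must be positive (kJ/mol)")
  -(dH / R_GAS) * (1 / T_ref - 1 / Tm)
}

#' Osmotic-stress melting series
#'
#' Per-glycerol-level melting results used by the water-counting regression
#' [delta_nw()]. By default the reference temperature is the 0 %-glycerol
#' melting temperature (so ln K at 0 % is exactly zero) and the reference
#' enthalpy is the 0 %-glycerol unfolding enthalpy, anchoring the
#' extrapolation in measured quantities.
#'
#' @param glycerol_pct_wv vector of glycerol levels, % w/v (>= 3 distinct
#'   levels).
#' @param Tm melting temperature at each level, K.
#' @param dH optional per-level unfolding enthalpy, kJ/mol.
#' @param dH_ref enthalpy used for the van't Hoff extrapolation at every
#'   level, kJ/mol; defaults to the 0 % level's `dH`.
#' @param T_ref reference temperature, K; defaults to the 0 % level's Tm.
#' @return An object of class `"osmolyte_series"`.
#' @export
osmolyte_series <- function(glycerol_pct_wv, Tm, dH = NULL,
                            dH_ref = NULL, T_ref = NULL) {
  stopifnot(is.numeric(glycerol_pct_wv), is.numeric(Tm))
  if (length(glycerol_pct_wv) != length(Tm))
    stop("glycerol_pct_wv and Tm must have equal length")
  if (any(glycerol_pct_wv < 0) || any(glycerol_pct_wv > 50))
    stop("glycerol percentages must lie in [0, 50] % w/v")
  if (any(!is.finite(Tm)) || any(Tm <= 0)) stop("Tm values must be positive kelvin")
  if (length(unique(glycerol_pct_wv)) < 3L)
    stop("an osmolyte series needs at least 3 distinct glycerol levels")
  if (!is.null(dH) && length(dH) != length(Tm))
    stop("dH must match the number of points")
  i0 <- which(glycerol_pct_wv == 0)[1]
  if (is.null(T_ref)) {
    if (is.na(i0)) stop("T_ref must be given when the series has no 0% level")
    T_ref <- Tm[i0]
  }
  if (is.null(dH_ref)) {
    if (is.null(dH) || is.na(i0))
      stop("dH_ref must be given when per-level dH (with a 0% level) is absent")
    dH_ref <- dH[i0]
  }
  structure(list(points = data.frame(glycerol_pct_wv = glycerol_pct_wv,
                                     Tm = Tm,
                                     dH = if (is.null(dH)) rep(dH_ref, length(Tm)) else dH),
                 dH_ref = dH_ref, T_ref = T_ref),
            class = "osmolyte_series")
}

#' @export
print.osmolyte_series <- function(x, ...) {
  cat(sprintf("osmolyte series: %d glycerol levels (%g-%g%% w/v), T_ref = %.2f degC, dH_ref = %.1f kJ/mol\n",
              nrow(x$points), min(x$points$glycerol_pct_wv),
              max(x$points$glycerol_pct_wv),
              kelvin_to_celsius(x$T_ref), x$dH_ref))
  invisible(x)
}

#' Count the waters taken up on unfolding (osmotic-stress regression)
#'
#' The osmotic-stress water count: each glycerol level's melting result is
#' converted to an apparent ln K at the series reference temperature by
#' van't Hoff extrapolation, and ln K is regressed by ordinary least squares
#' on the log water concentration. The slope
#' \deqn{\Delta n_w = d\,\ln K / d\,\ln[H_2O]}
#' is the change in the number of bound waters per strand on unfolding; a
#' positive slope means water uptake. The reference enthalpy `dH_ref`
#' (by default the 0 %-glycerol value) is used at every level.
#'
#' @param series an [osmolyte_series()].
#' @return An object of class `"water_count"`: `delta_nw` (waters/strand),
#'   `stderr` (standard error of the slope), `r_squared`, `n_points`, and
#'   the underlying `lm` fit.
#' @examples
#' s <- gen_osmolyte_series(61.1, dH = 154.5, Tm0 = 340.35, pcts = 0:5)
#' delta_nw(s)
#' @export
delta_nw <- function(series) {
  stopifnot(inherits(series, "osmolyte_series"))
  pts <- series$points
  if (nrow(pts) < 3L) stop("at least 3 points are required")
  lnW <- log(water_concentration(pts$glycerol_pct_wv))
  if (diff(range(lnW)) < .Machine$double.eps * 100)
    stop("zero variance in ln[H2O]: all glycerol levels are identical")
  lnK <- apparent_lnK(pts$Tm, series$dH_ref, series$T_ref)
  fit <- lm(lnK ~ lnW)
  sm <- summary(fit)
  ssr <- sum(residuals(fit)^2)
  sst <- sum((lnK - mean(lnK))^2)
  r2 <- if (sst < 1e-300) 1 else 1 - ssr / sst
  se <- sm$coefficients["lnW", "Std. Error"]
  if (!is.finite(se)) se <- 0
  structure(list(delta_nw = unname(coef(fit)["lnW"]),
                 stderr = se,
                 r_squared = max(0, min(1, r2)),
                 n_points = nrow(pts),
                 fit = fit,
                 T_ref = series$T_ref, dH_ref = series$dH_ref),
            class = "water_count")
}

#' @export
print.water_count <- function(x, ...) {
  cat(sprintf("osmotic-stress water count: delta_nw = %.1f +/- %.1f waters/strand (R^2 = %.4f, n = %d)\n",
              x$delta_nw, x$stderr, x$r_squared, x$n_points))
  invisible(x)
}

#' @export
coef.water_count <- function(object, ...) {
  c(delta_nw = object$delta_nw)
}

#' @export
summary.water_count <- function(object, ...) summary(object$fit, ...)
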
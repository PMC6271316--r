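# Synthetic instrument traces with known ground truth.
#
# Raw scans for this kind of experiment are rarely deposited, so every
# analysis stage has a matching generator that produces an
# instrument-realistic trace from stated thermodynamic truth. Composing a
# noiseless generator with its analysis recovers the injected value; that
# identity is the package's central validation surface. All generators are
# bit-reproducible under a fixed seed and never touch global RNG state.

#' Generate a synthetic DSC thermogram
#'
#' Builds an excess heat capacity trace as the van't Hoff model curve of
#' the supplied transitions plus a cubic instrument baseline and optional
#' Gaussian noise. The default grid mirrors the instrument protocol
#' (5-110 degC, 0.1 K pitch). Baseline coefficients follow the
#' [fit_baseline()] convention (powers of temperature in degrees Celsius).
#'
#' @param trs a [transition()] or non-empty list of them (the ground
#'   truth).
#' @param baseline_coeffs cubic baseline coefficients `c(c0, c1, c2, c3)`,
#'   kJ/(mol K) per (degC)^k; defaults to no baseline.
#' @param grid temperature grid, kelvin (default `seq(278.15, 383.15,
#'   0.1)`).
#' @param noise_sd Gaussian noise standard deviation, kJ/(mol K).
#' @param seed RNG seed fixing the noise; `NULL` uses (and advances) the
#'   caller's RNG only if noise is requested.
#' @return A [thermogram()].
#' @examples
#' trs <- list(transition(57.4, celsius_Tm = 53.5),
#'             transition(98.9, celsius_Tm = 67.2))
#' cur <- gen_dsc_thermogram(trs)
#' total_enthalpy(cur)
#' @export
gen_dsc_thermogram <- function(trs, baseline_coeffs = c(0, 0, 0, 0),
                               grid = seq(278.15, 383.15, by = 0.1),
                               noise_sd = 0, seed = NULL) {
  trs <- as_transitions(trs)
  if (length(trs) == 0L) stop("at least one transition is required")
  stopifnot(is.numeric(baseline_coeffs), length(baseline_coeffs) == 4L,
            noise_sd >= 0)
  tc <- kelvin_to_celsius(grid)
  cp <- excess_heat_capacity(grid, trs) +
    baseline_coeffs[1] + baseline_coeffs[2] * tc +
    baseline_coeffs[3] * tc^2 + baseline_coeffs[4] * tc^3
  if (noise_sd > 0)
    cp <- cp + with_local_seed(seed, rnorm(length(grid), 0, noise_sd))
  thermogram(grid, cp)
}

#' Generate a synthetic osmotic-stress melting series
#'
#' Produces per-glycerol melting temperatures consistent with an injected
#' water-uptake number. For each level the target
#' `ln K = delta_nw_true * (ln[H2O](pct) - ln[H2O](0))` is inverted through
#' the van't Hoff extrapolation in closed form,
#' `1/Tm = 1/Tm0 + R ln K / dH`, so the noiseless series regresses back to
#' `delta_nw_true` exactly. A positive water uptake makes Tm rise with
#' glycerol (osmolyte withdraws water and stabilises the folded state).
#'
#' @param delta_nw_true injected water-uptake number, waters per strand.
#' @param dH unfolding enthalpy used for the inversion and stored as the
#'   series reference enthalpy, kJ/mol.
#' @param Tm0 melting temperature at 0 % glycerol, kelvin.
#' @param pcts glycerol levels, % w/v; must include 0.
#' @param tm_noise_sd Gaussian noise on each Tm, kelvin.
#' @param seed RNG seed for the noise.
#' @return An [osmolyte_series()].
#' @export
gen_osmolyte_series <- function(delta_nw_true, dH, Tm0, pcts = 0:5,
                                tm_noise_sd = 0, seed = NULL) {
  stopifnot(is.numeric(delta_nw_true), length(delta_nw_true) == 1L,
            dH > 0, Tm0 > 0, tm_noise_sd >= 0)
  if (!0 %in% pcts) stop("the glycerol levels must include 0%")
  lnK <- delta_nw_true *
    (log(water_concentration(pcts)) - log(water_concentration(0)))
  invTm <- 1 / Tm0 + R_GAS * lnK / dH
  if (any(invTm <= 0))
    stop("unphysical parameter combination: inverted Tm is not positive")
  Tm <- 1 / invTm
  if (tm_noise_sd > 0)
    Tm <- Tm + with_local_seed(seed, rnorm(length(Tm), 0, tm_noise_sd))
  osmolyte_series(pcts, Tm, dH = rep(dH, length(pcts)),
                  dH_ref = dH, T_ref = Tm[which(pcts == 0)[1]])
}

#' Generate a synthetic four-scan PPC quartet
#'
#' Builds the water/water, buffer/water, buffer/buffer and sample/buffer
#' pulse-heat traces of a pressure-perturbation experiment around an
#' injected unfolding volume change. The solute expansion-coefficient truth
#' is a two-level progress baseline plus a logistic-derivative transition
#' peak scaled so that the baseline-subtracted integral times the molar
#' volume equals `delta_V_true`; pulse heats are obtained by inverting the
#' expansion-coefficient relation, and the reference scans carry the
#' solvent trace and a shared smooth instrument offset. Defaults follow the
#' instrument protocol: 1 K pulse spacing over 5-120 degC and a 70 psi
#' pressure step.
#'
#' @param delta_V_true injected unfolding volume change, mL/mol (negative
#'   for a volume decrease).
#' @param Tm transition midpoint, kelvin.
#' @param width logistic transition width parameter, kelvin.
#' @param alpha_pre,alpha_post pre-/post-transition solute expansion
#'   levels, 1/K.
#' @param dP pressure step, pascal (default 70 psi).
#' @param m_s solute mass in the cell, g.
#' @param V_s solute partial specific volume, mL/g.
#' @param molar_mass strand molar mass, g/mol; the molar volume
#'   `molar_mass * V_s` scales the injected peak.
#' @param V_cell calorimeter cell volume, cubic metres (shared with
#'   [ppc_baseline_chain()]).
#' @param grid pulse temperature grid, kelvin.
#' @param noise_sd Gaussian noise on each pulse heat, joule.
#' @param seed RNG seed for the noise.
#' @return A list of four [ppc_scan()]s (roles `water_water`,
#'   `buffer_water`, `buffer_buffer`, `sample_buffer`), with the injected
#'   truth attached as attribute `"truth"`.
#' @examples
#' q <- gen_ppc_trace(-0.106, Tm = 340.35)
#' ac <- alpha_solute(ppc_baseline_chain(q))
#' delta_volume(ac, c(320.35, 360.35), molar_volume = 6966 * 0.55)
#' @export
gen_ppc_trace <- function(delta_V_true, Tm, width = 3,
                          alpha_pre = 3.0e-4, alpha_post = 3.2e-4,
                          dP = psi_to_pa(70), m_s = 3.5e-3, V_s = 0.55,
                          molar_mass = 6966, V_cell = 5e-7,
                          grid = seq(278.15, 393.15, by = 1),
                          noise_sd = 0, seed = NULL) {
  stopifnot(is.numeric(delta_V_true), length(delta_V_true) == 1L,
            width > 0, Tm > 0, noise_sd >= 0)
  molar_volume <- molar_mass * V_s
  if (!is.finite(molar_volume) || molar_volume <= 0)
    stop("molar volume must be positive")

  theta <- stats::plogis((grid - Tm) / width)
  peak <- theta * (1 - theta) / width          # unit-area logistic derivative
  a_s <- alpha_pre + (alpha_post - alpha_pre) * theta +
    (delta_V_true / molar_volume) * peak

  # solvent trace: water-like expansivity rising roughly linearly with T
  a_o <- 2.6e-4 + 6.5e-6 * (grid - 298.15)

  msVs_m3 <- m_s * V_s * 1e-6
  dQ_solute <- (a_o - a_s) * grid * dP * msVs_m3
  # smooth shared instrument offset common to all four scans
  q0 <- 1e-6 * (1 + 5e-4 * (grid - 300) + 2e-6 * (grid - 300)^2)

  noise <- function(k) {
    if (noise_sd == 0) return(numeric(length(grid)))
    with_local_seed(if (is.null(seed)) NULL else seed + k,
                    rnorm(length(grid), 0, noise_sd))
  }
  scans <- list(
    ppc_scan(grid, q0 + noise(1), dP, "water_water"),
    ppc_scan(grid, q0 + a_o * grid * dP * V_cell + noise(2), dP, "buffer_water"),
    ppc_scan(grid, q0 + noise(3), dP, "buffer_buffer"),
    ppc_scan(grid, q0 + dQ_solute + noise(4), dP, "sample_buffer",
             m_s = m_s, V_s = V_s))
  attr(scans, "truth") <- list(delta_V = delta_V_true, Tm = Tm,
                               width = width, alpha_s = a_s,
                               molar_volume = molar_volume)
  scans
}

#' Generate a synthetic CD spectrum
#'
#' Sum of Gaussian bands on the instrument wavelength grid (225-325 nm,
#' 0.5 nm pitch by default) plus optional Gaussian noise. An empty band
#' table yields a flat spectrum.
#'
#' @param bands data frame (or list coercible to one) with columns
#'   `center` (nm), `amplitude` (signed, mdeg) and `width` (Gaussian sigma,
#'   nm); zero rows allowed.
#' @param noise_sd Gaussian noise standard deviation, mdeg.
#' @param seed RNG seed for the noise.
#' @param grid wavelength grid, nm.
#' @return A [cd_spectrum()].
#' @export
gen_cd_spectrum <- function(bands, noise_sd = 0, seed = NULL,
                            grid = seq(225, 325, by = 0.5)) {
  bands <- as.data.frame(bands)
  if (nrow(bands) > 0) {
    stopifnot(all(c("center", "amplitude", "width") %in% names(bands)))
    if (any(bands$center < min(grid)) || any(bands$center > max(grid)))
      stop("band centers must lie within the wavelength grid")
    if (any(bands$width <= 0)) stop("band widths must be positive")
  }
  y <- numeric(length(grid))
  for (i in seq_len(nrow(bands)))
    y <- y + bands$amplitude[i] *
      exp(-(grid - bands$center[i])^2 / (2 * bands$width[i]^2))
  if (noise_sd > 0)
    y <- y + with_local_seed(seed, rnorm(length(grid), 0, noise_sd))
  cd_spectrum(grid, y)
}
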
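#' Cubic instrument-baseline correction of a DSC trace
#'
#' Fits a cubic polynomial by ordinary least squares to the points lying in
#' two user-chosen temperature windows flanking the transition region
#' (where no excess heat is expected), and subtracts it from the whole
#' trace. Polynomial coefficients are expressed in degrees Celsius
#' (`Cp = c0 + c1 t + c2 t^2 + c3 t^3`, `t = T - 273.15`) for numerical
#' conditioning and instrument convention.
#'
#' @param curve a [thermogram()] (raw, baseline not yet removed).
#' @param windows list of two half-open temperature intervals `c(lo, hi)` in
#'   kelvin, `[lo, hi)`, flanking the transition region and lying inside the
#'   curve's range.
#' @return A list with components `baseline` (class `"baseline_model"`:
#'   `coeffs`, `fit_windows`) and `corrected` (the baseline-subtracted
#'   [thermogram()]).
#' @examples
#' trs <- list(transition(57.4, celsius_Tm = 53.5),
#'             transition(98.9, celsius_Tm = 67.2))
#' raw <- gen_dsc_thermogram(trs, baseline_coeffs = c(0.5, -2e-3, 0, 0))
#' bc <- fit_baseline(raw, list(c(278.15, 303.15), c(368.15, 383.25)))
#' total_enthalpy(bc$corrected)
#' @export
fit_baseline <- function(curve, windows) {
  stopifnot(inherits(curve, "thermogram"))
  windows <- validate_windows(windows, curve)
  in_win <- in_windows(curve$T, windows)
  if (sum(in_win) < 4L)
    stop("baseline windows must contain at least 4 points in total")
  for (w in windows)
    if (sum(curve$T >= w[1] & curve$T < w[2]) < 4L)
      warning("a baseline window contains fewer than 4 points")
  tc <- kelvin_to_celsius(curve$T)
  fit <- lm(curve$Cp[in_win] ~ tc[in_win] + I(tc[in_win]^2) + I(tc[in_win]^3))
  co <- unname(coef(fit))
  co[is.na(co)] <- 0
  base <- co[1] + co[2] * tc + co[3] * tc^2 + co[4] * tc^3
  corrected <- thermogram(curve$T, curve$Cp - base,
                          strand_conc = curve$strand_conc,
                          scan_rate = curve$scan_rate)
  model <- structure(list(coeffs = co, fit_windows = windows),
                     class = "baseline_model")
  list(baseline = model, corrected = corrected)
}

validate_windows <- function(windows, curve) {
  if (!is.list(windows) || length(windows) != 2L ||
      !all(vapply(windows, function(w) is.numeric(w) && length(w) == 2L,
                  logical(1))))
    stop("windows must be a list of two c(lo, hi) intervals in kelvin")
  windows <- lapply(windows, as.numeric)
  windows <- windows[order(vapply(windows, `[`, numeric(1), 1))]
  if (windows[[1]][2] > windows[[2]][1])
    stop("baseline windows must not overlap")
  rng <- range(curve$T)
  for (w in windows) {
    if (w[1] >= w[2]) stop("each window needs lo < hi")
    if (w[1] < rng[1] - 1e-9 || w[2] > rng[2] + max(diff(curve$T)) + 1e-9)
      stop("baseline windows must lie inside the curve's temperature range")
  }
  windows
}

in_windows <- function(T, windows) {
  hit <- rep(FALSE, length(T))
  for (w in windows) hit <- hit | (T >= w[1] & T < w[2])
  hit
}

#' Deconvolve a DSC thermogram into independent two-state transitions
#'
#' Nonlinear least-squares fit of a baseline-corrected excess heat capacity
#' trace to a sum of `n_transitions` independent van't Hoff transitions
#' (the "non-2-state" model), via bounded Levenberg-Marquardt
#' ([minpack.lm::nls.lm()]). Enthalpies are constrained to (0, 1000] kJ/mol
#' and melting temperatures to the data range; unconstrained fits drift on
#' noisy shoulders.
#'
#' Initial values, when not supplied, come from peak-picking a 5-point
#' moving-average smooth of the trace: the `n_transitions` tallest local
#' maxima separated by at least 3 K (ties broken toward lower temperature)
#' seed the Tm guesses, and peak heights seed the enthalpies through
#' `dH = sqrt(4 R Tm^2 Cp_peak)`. A trace with no interior maximum falls
#' back to midpoint initialisation and flags the result. If the first fit
#' fails to converge, up to three seeded jittered restarts are attempted.
#'
#' @param curve a baseline-corrected [thermogram()].
#' @param n_transitions number of transitions to fit (>= 1).
#' @param init optional list of [transition()]s used as starting values
#'   (overrides peak-picking).
#' @param free_amplitude if `TRUE`, each transition's calorimetric amplitude
#'   `dH_cal` is fitted independently of its van't Hoff enthalpy; by default
#'   the two are tied (`dH_cal = dH_vH`).
#' @param restart_seed seed for the jittered restarts taken on
#'   non-convergence.
#' @return An object of class `"non2state"`: a list with `transitions`
#'   (sorted by ascending Tm), `residual_rms` (kJ/(mol K)), `converged`,
#'   `covariance`, `n_iter`, `degenerate`, plus the data and fitted values.
#'   Supports `print`, `summary`, `coef`, `fitted`, `residuals`, `predict`,
#'   `plot` and `simulate`.
#' @examples
#' trs <- list(transition(57.4, celsius_Tm = 53.5),
#'             transition(98.9, celsius_Tm = 67.2))
#' cur <- gen_dsc_thermogram(trs)
#' fit <- fit_non2state(cur, 2)
#' coef(fit)
#' @export
fit_non2state <- function(curve, n_transitions, init = NULL,
                          free_amplitude = FALSE, restart_seed = 1L) {
  stopifnot(inherits(curve, "thermogram"))
  n <- as.integer(n_transitions)
  if (is.na(n) || n < 1L) stop("n_transitions must be a positive integer")
  if (length(curve$T) < 2L * n + 2L)
    stop("too few grid points for the requested number of transitions")

  degenerate <- FALSE
  if (is.null(init)) {
    picked <- pick_peaks(curve, n)
    init_df <- picked$init
    degenerate <- picked$degenerate
  } else {
    init_df <- transitions_df(init)
    if (nrow(init_df) != n)
      stop("init must supply exactly n_transitions starting transitions")
  }

  lowerT <- min(curve$T); upperT <- max(curve$T)
  init_df$Tm <- pmin(pmax(init_df$Tm, lowerT), upperT)
  init_df$dH_vH <- pmin(pmax(init_df$dH_vH, 1), 1000)

  pack <- function(df) {
    p <- c(df$dH_vH, df$Tm)
    if (free_amplitude) p <- c(p, df$dH_cal)
    p
  }
  unpack <- function(p) {
    dH <- p[seq_len(n)]
    Tm <- p[n + seq_len(n)]
    dHc <- if (free_amplitude) p[2L * n + seq_len(n)] else dH
    mapply(function(h, t, hc) transition(h, t, dH_cal = hc),
           dH, Tm, dHc, SIMPLIFY = FALSE)
  }
  resid_fn <- function(p) excess_heat_capacity(curve$T, unpack(p)) - curve$Cp

  lower <- c(rep(1e-6, n), rep(lowerT, n))
  upper <- c(rep(1000, n), rep(upperT, n))
  if (free_amplitude) {
    lower <- c(lower, rep(0, n))
    upper <- c(upper, rep(2000, n))
  }

  run_fit <- function(p0) {
    minpack.lm::nls.lm(
      par = pmin(pmax(p0, lower), upper), lower = lower, upper = upper,
      fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 500))
  }

  best <- run_fit(pack(init_df))
  tries <- 0L
  while (!(best$info %in% 1:3) && tries < 3L) {
    tries <- tries + 1L
    jit <- with_local_seed(restart_seed + tries, {
      p0 <- pack(init_df)
      p0 * (1 + 0.1 * rnorm(length(p0)))
    })
    cand <- run_fit(jit)
    if ((cand$info %in% 1:3) || cand$deviance < best$deviance) best <- cand
  }

  trs <- unpack(best$par)
  ord <- order(vapply(trs, `[[`, numeric(1), "Tm"))
  trs <- trs[ord]

  res <- resid_fn(best$par)
  covm <- fit_covariance(best, res)

  structure(list(
    transitions = trs,
    residual_rms = sqrt(mean(res^2)),
    converged = best$info %in% 1:3,
    covariance = covm,
    n_iter = best$niter,
    degenerate = degenerate,
    free_amplitude = free_amplitude,
    data = curve,
    fitted = curve$Cp + res,
    init = init_df), class = "non2state")
}

# Parameter covariance from the LM normal-equations hessian (~ 2 J'J);
# returns a matrix of NAs when the hessian is singular.
fit_covariance <- function(fit, res) {
  p <- length(fit$par)
  dof <- max(length(res) - p, 1L)
  sigma2 <- sum(res^2) / dof
  out <- tryCatch(2 * sigma2 * solve(fit$hessian),
                  error = function(e) matrix(NA_real_, p, p))
  out
}

# Moving-average smoothing + local-maximum picking used to seed the fit.
pick_peaks <- function(curve, n) {
  Cp <- curve$Cp
  sm <- stats::filter(Cp, rep(1 / 5, 5), sides = 2)
  sm <- as.numeric(sm)
  sm[is.na(sm)] <- Cp[is.na(sm)]
  m <- length(sm)
  is_max <- c(FALSE, sm[2:(m - 1)] > sm[1:(m - 2)] &
                     sm[2:(m - 1)] >= sm[3:m], FALSE)
  idx <- which(is_max)
  degenerate <- FALSE
  kept <- integer(0)
  if (length(idx)) {
    # tallest first; ties toward lower temperature; >= 3 K apart
    idx <- idx[order(-sm[idx], curve$T[idx])]
    for (i in idx) {
      if (all(abs(curve$T[i] - curve$T[kept]) >= 3)) kept <- c(kept, i)
      if (length(kept) == n) break
    }
  }
  if (length(kept) < n) {
    degenerate <- TRUE
    need <- n - length(kept)
    mid <- (min(curve$T) + max(curve$T)) / 2
    fillT <- mid + seq_len(need) * 4 - 2 * need  # spread around midpoint
    fill <- vapply(fillT, function(t) which.min(abs(curve$T - t)), integer(1))
    kept <- c(kept, fill)
  }
  Tm0 <- curve$T[kept]
  h0 <- pmax(Cp[kept], 1e-3)
  dH0 <- sqrt(4 * R_GAS * Tm0^2 * h0)
  list(init = data.frame(dH_vH = dH0, Tm = Tm0, dH_cal = dH0),
       degenerate = degenerate)
}

#' @export
print.non2state <- function(x, ...) {
  cat(sprintf("non-2-state DSC fit: %d transition(s), residual rms %.3g kJ/(mol K)%s\n",
              length(x$transitions), x$residual_rms,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  for (tr in x$transitions) print(tr)
  invisible(x)
}

#' @export
coef.non2state <- function(object, ...) {
  df <- transitions_df(object$transitions)
  m <- as.matrix(df)
  rownames(m) <- paste0("transition", seq_len(nrow(m)))
  m
}

#' @export
fitted.non2state <- function(object, ...) object$fitted

#' @export
residuals.non2state <- function(object, ...) object$data$Cp - object$fitted

#' @export
predict.non2state <- function(object, newdata = NULL, ...) {
  T <- if (is.null(newdata)) object$data$T
       else if (is.list(newdata)) newdata$T else newdata
  excess_heat_capacity(T, object$transitions)
}

#' @export
summary.non2state <- function(object, ...) {
  df <- transitions_df(object$transitions)
  ms <- melt_summary(object$data, object$transitions)
  structure(list(fit = object, table = df,
                 dH_tot = ms$dH_tot, Tm_tot = ms$Tm_tot,
                 dH_cal_sum = sum(df$dH_cal)), class = "summary.non2state")
}

#' @export
print.summary.non2state <- function(x, ...) {
  print(x$fit)
  cat(sprintf("curve integral dH_tot = %.1f kJ/mol, area-median Tm_tot = %.2f degC\n",
              x$dH_tot, kelvin_to_celsius(x$Tm_tot)))
  cat(sprintf("sum of fitted amplitudes = %.1f kJ/mol\n", x$dH_cal_sum))
  invisible(x)
}

#' @export
plot.non2state <- function(x, ...) {
  plot(x$data, ...)
  lines(kelvin_to_celsius(x$data$T), x$fitted, col = 2, lwd = 2)
  for (tr in x$transitions)
    lines(kelvin_to_celsius(x$data$T),
          excess_heat_capacity(x$data$T, tr), col = 4, lty = 2)
  legend("topleft", bty = "n", col = c(1, 2, 4), lty = c(1, 1, 2),
         legend = c("data", "fit", "components"))
  invisible(x)
}

#' @export
simulate.non2state <- function(object, nsim = 1, seed = NULL,
                               noise_sd = object$residual_rms, ...) {
  with_local_seed(seed, {
    replicate(nsim, simplify = FALSE,
      thermogram(object$data$T,
                 excess_heat_capacity(object$data$T, object$transitions) +
                   rnorm(length(object$data$T), 0, noise_sd)))
  })
}
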
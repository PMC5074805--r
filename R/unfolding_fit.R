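# Two-state analysis of equilibrium unfolding curves followed by circular
# dichroism at 222 nm.
#
# Chemical (urea) denaturation follows the linear extrapolation model
# (LEM): dG(D) = dG_H2O - m * [D], with the observed signal a
# population-weighted average of folded and unfolded baselines. Thermal
# melts are summarised by the inflection temperature Tm of a Boltzmann
# sigmoid with linear baselines.

#' Gas constant in kcal/(mol K)
#' @export
R_KCAL <- 1.987e-3

#' Construct an unfolding curve
#'
#' @param x Denaturant concentration (M urea) or temperature (degrees C);
#'   must be strictly increasing.
#' @param y CD signal at 222 nm (arbitrary units, e.g. mdeg).
#' @param mode `"chemical"` or `"thermal"`.
#' @return An object of class `tpr_unfolding_curve` (data.frame `x`, `y`
#'   with attribute `mode`).
#' @export
unfolding_curve <- function(x, y, mode = c("chemical", "thermal")) {
  mode <- match.arg(mode)
  if (length(x) != length(y)) {
    tpr_abort("x and y must have equal length", "tpr_shape_error")
  }
  if (length(x) < 8L) {
    tpr_abort("at least 8 points are required for fitting",
              "tpr_value_error")
  }
  if (any(diff(x) <= 0)) {
    tpr_abort("x must be strictly increasing", "tpr_value_error")
  }
  structure(data.frame(x = x, y = y),
            class = c("tpr_unfolding_curve", "data.frame"), mode = mode)
}

curve_mode <- function(curve) attr(curve, "mode")

#' Read an unfolding curve from CSV
#'
#' Expects a header and two columns (x, y).
#'
#' @param path CSV file.
#' @param mode Curve mode.
#' @return A `tpr_unfolding_curve`.
#' @export
read_unfolding_curve <- function(path, mode = c("chemical", "thermal")) {
  df <- utils::read.csv(path)
  unfolding_curve(df[[1L]], df[[2L]], mode = match.arg(mode))
}

#' Fraction of unfolded protein from baseline signals
#'
#' f_U = (y_F - y) / (y_F - y_U). Values are deliberately not clipped to
#' `[0, 1]`: noise legitimately pushes points slightly outside, and clipping
#' would bias subsequent fits.
#'
#' @param y Observed signal(s).
#' @param y_F,y_U Folded and unfolded baseline signals (must differ).
#' @return Numeric fraction(s) unfolded.
#' @export
fraction_unfolded <- function(y, y_F, y_U) {
  if (y_F == y_U) {
    tpr_abort("degenerate baselines: y_F equals y_U", "tpr_baseline_error")
  }
  (y_F - y) / (y_F - y_U)
}

# Forward two-state LEM signal model.
two_state_signal <- function(x, y_F, m_F, y_U, m_U, dG, m,
                             temperature_K = 296.15) {
  K <- exp(-(dG - m * x) / (R_KCAL * temperature_K))
  (y_F + m_F * x + (y_U + m_U * x) * K) / (1 + K)
}

# Shared no-transition detection: is the curve adequately explained by a
# straight line?
.is_featureless <- function(x, y) {
  fit <- lm(y ~ x)
  ss_res <- sum(resid(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  ss_tot < 1e-12 || (1 - ss_res / max(ss_tot, 1e-12)) > 0.98
}

#' Fit a two-state linear-extrapolation model to a chemical denaturation curve
#'
#' Nonlinear least squares of
#' \deqn{y([D]) = \frac{(y_F + m_F[D]) + (y_U + m_U[D])\,K}{1 + K},\quad
#'       K = e^{-(\Delta G_{H_2O} - m[D])/RT}}
#' Starting values come from linear fits to the first and last three points
#' (baselines) and the steepest-slope midpoint. A cooperative fit requires
#' `m > 0` and a midpoint `Cm = dG/m` inside the data range; flat or purely
#' linear curves raise a `tpr_no_transition_error`.
#'
#' @param curve A `tpr_unfolding_curve` with mode `"chemical"`.
#' @param temperature_K Temperature in Kelvin (default 296.15, i.e. 23 C).
#' @param baseline_slopes Fit sloped baselines (default `TRUE`); set `FALSE`
#'   for flat baselines.
#' @return An object of class `tpr_two_state_fit`: `dG_H2O` (kcal/mol),
#'   `m_value` (kcal/mol/M), `Cm` (M), baselines `y_F`, `m_F`, `y_U`, `m_U`,
#'   `temperature_K`, `se` (parameter standard errors), `covariance`,
#'   `fitted`, plus the input curve.
#' @export
fit_two_state <- function(curve, temperature_K = 296.15,
                          baseline_slopes = TRUE) {
  stopifnot(inherits(curve, "tpr_unfolding_curve"))
  if (curve_mode(curve) != "chemical") {
    tpr_abort("fit_two_state expects a chemical denaturation curve",
              "tpr_value_error")
  }
  x <- curve$x; y <- curve$y
  if (.is_featureless(x, y)) {
    tpr_abort("no unfolding transition detected (curve is linear/flat)",
              "tpr_no_transition_error")
  }
  n <- length(x)
  head_fit <- lm(y[1:3] ~ x[1:3])
  tail_fit <- lm(y[(n - 2):n] ~ x[(n - 2):n])
  yF0 <- coef(head_fit)[[1L]]; mF0 <- coef(head_fit)[[2L]]
  yU0 <- coef(tail_fit)[[1L]]; mU0 <- coef(tail_fit)[[2L]]
  slope <- diff(y) / diff(x)
  cm0 <- x[which.max(abs(slope))] + 0.5 * diff(x)[which.max(abs(slope))]
  m0 <- 1.5
  start <- if (baseline_slopes) {
    list(y_F = yF0, m_F = mF0, y_U = yU0, m_U = mU0,
         dG = m0 * cm0, m = m0)
  } else list(y_F = yF0, y_U = yU0, dG = m0 * cm0, m = m0)
  formula <- if (baseline_slopes) {
    y ~ two_state_signal(x, y_F, m_F, y_U, m_U, dG, m, temperature_K)
  } else {
    y ~ two_state_signal(x, y_F, 0, y_U, 0, dG, m, temperature_K)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      formula, data = data.frame(x = x, y = y), start = start,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15)),
    error = function(e) NULL)
  if (is.null(fit)) {
    tpr_abort("two-state fit failed to converge", "tpr_fit_error")
  }
  p <- as.list(coef(fit))
  if (!baseline_slopes) { p$m_F <- 0; p$m_U <- 0 }
  cm <- p$dG / p$m
  if (p$m <= 0 || cm < min(x) || cm > max(x)) {
    tpr_abort(sprintf(
      "no cooperative transition inside the data range (m = %.3g, Cm = %.3g)",
      p$m, cm), "tpr_no_transition_error")
  }
  vc <- tryCatch(vcov(fit), error = function(e) NULL)
  structure(
    list(dG_H2O = p$dG, m_value = p$m, Cm = cm,
         y_F = p$y_F, m_F = p$m_F, y_U = p$y_U, m_U = p$m_U,
         temperature_K = temperature_K,
         se = tryCatch(summary(fit)$coefficients[, "Std. Error"],
                       error = function(e) NULL),
         covariance = vc,
         fitted = two_state_signal(x, p$y_F, p$m_F, p$y_U, p$m_U, p$dG, p$m,
                                   temperature_K),
         curve = curve, baseline_slopes = baseline_slopes),
    class = "tpr_two_state_fit"
  )
}

#' @export
print.tpr_two_state_fit <- function(x, ...) {
  cat(sprintf(
    "<tpr_two_state_fit> dG_H2O = %.2f kcal/mol, m = %.2f kcal/mol/M, Cm = %.2f M\n",
    x$dG_H2O, x$m_value, x$Cm))
  invisible(x)
}

# Forward Boltzmann melt model; Tm is the inflection of the sigmoid.
melt_signal <- function(x, y_F, m_F, y_U, m_U, Tm, k) {
  f <- 1 / (1 + exp((Tm - x) / k))
  (y_F + m_F * x) * (1 - f) + (y_U + m_U * x) * f
}

#' Fit a thermal melt and extract Tm
#'
#' Boltzmann sigmoid with linear baselines; `Tm` is the inflection
#' temperature, `k` the transition width (degrees C). Linear/flat input
#' raises a `tpr_no_transition_error`.
#'
#' @param curve A `tpr_unfolding_curve` with mode `"thermal"` (x in degrees
#'   C).
#' @param baseline_slopes Fit sloped baselines (default `TRUE`).
#' @return An object of class `tpr_melt_fit` with `Tm`, `k`, baselines, `se`
#'   and `fitted`.
#' @export
fit_melt_tm <- function(curve, baseline_slopes = TRUE) {
  stopifnot(inherits(curve, "tpr_unfolding_curve"))
  if (curve_mode(curve) != "thermal") {
    tpr_abort("fit_melt_tm expects a thermal melt curve", "tpr_value_error")
  }
  x <- curve$x; y <- curve$y
  if (.is_featureless(x, y)) {
    tpr_abort("no melting transition detected (curve is linear/flat)",
              "tpr_no_transition_error")
  }
  n <- length(x)
  yF0 <- mean(y[1:3]); yU0 <- mean(y[(n - 2):n])
  slope <- diff(y) / diff(x)
  tm0 <- x[which.max(abs(slope))]
  start <- if (baseline_slopes) {
    list(y_F = yF0, m_F = 0, y_U = yU0, m_U = 0, Tm = tm0, k = 2)
  } else list(y_F = yF0, y_U = yU0, Tm = tm0, k = 2)
  formula <- if (baseline_slopes) {
    y ~ melt_signal(x, y_F, m_F, y_U, m_U, Tm, k)
  } else y ~ melt_signal(x, y_F, 0, y_U, 0, Tm, k)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      formula, data = data.frame(x = x, y = y), start = start,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15)),
    error = function(e) NULL)
  if (is.null(fit)) {
    tpr_abort("melt fit failed to converge", "tpr_fit_error")
  }
  p <- as.list(coef(fit))
  if (!baseline_slopes) { p$m_F <- 0; p$m_U <- 0 }
  if (p$k <= 0 || p$Tm < min(x) || p$Tm > max(x)) {
    tpr_abort("no melting transition inside the data range",
              "tpr_no_transition_error")
  }
  structure(
    list(Tm = p$Tm, k = p$k, y_F = p$y_F, m_F = p$m_F, y_U = p$y_U,
         m_U = p$m_U,
         se = tryCatch(summary(fit)$coefficients[, "Std. Error"],
                       error = function(e) NULL),
         fitted = melt_signal(x, p$y_F, p$m_F, p$y_U, p$m_U, p$Tm, p$k),
         curve = curve, baseline_slopes = baseline_slopes),
    class = "tpr_melt_fit"
  )
}

#' @export
print.tpr_melt_fit <- function(x, ...) {
  cat(sprintf("<tpr_melt_fit> Tm = %.1f C (width k = %.2f C)\n", x$Tm, x$k))
  invisible(x)
}
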
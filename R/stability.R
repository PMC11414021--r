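#' Formic-acid dissolution series
#'
#' SDS-PAGE band intensities of fibril material released at increasing
#' formic-acid concentrations, together with the concentration of the
#' normalization lane (by default the 98% FA lane, at which fibrils are
#' fully dissolved).
#'
#' @param fa_percent Formic acid concentrations, % v/v, in `[0, 100]`.
#' @param intensity Band intensities, arbitrary units (>= 0).
#' @param reference_fa Concentration of the reference lane (must be
#'   present in `fa_percent`).
#' @return A data frame of class `dissolution_series` with an attribute
#'   `reference_fa`.
#' @export
dissolution_series <- function(fa_percent, intensity, reference_fa = 98) {
  if (!is.numeric(fa_percent) || !is.numeric(intensity) ||
      length(fa_percent) != length(intensity))
    .stopf("fa_percent and intensity must be numeric vectors of equal length")
  if (any(!is.finite(fa_percent)) || any(fa_percent < 0 | fa_percent > 100))
    .stopf("fa_percent must lie in [0, 100]")
  if (any(!is.finite(intensity)) || any(intensity < 0))
    .stopf("intensities must be finite and >= 0")
  if (!any(fa_percent == reference_fa))
    .stopf("reference lane (%g%% FA) not present in the series",
           reference_fa)
  structure(data.frame(fa_percent = fa_percent, intensity = intensity),
            reference_fa = reference_fa,
            class = c("dissolution_series", "data.frame"))
}

#' Normalize band intensities to the reference lane
#'
#' Converts raw band intensities into percent dissolved,
#' \eqn{y_{diss} = 100\, I / I_{ref}}, with the reference lane mapping to
#' exactly 100. Any common multiplicative rescaling of the intensities
#' (exposure, loading) cancels.
#'
#' @param series A [dissolution_series()].
#' @return The series with an added `y_diss` column (% dissolved).
#' @export
normalize_to_reference <- function(series) {
  stopifnot(inherits(series, "dissolution_series"))
  ref_fa <- attr(series, "reference_fa")
  iref <- series$intensity[series$fa_percent == ref_fa][1]
  if (!is.finite(iref) || iref <= 0)
    .stopf("reference lane intensity must be > 0")
  series$y_diss <- 100 * series$intensity / iref
  series
}

# two-state dissolution model; m_fa < 0 gives a curve increasing in FA
.dissolution_model <- function(fa, fa50, m_fa) {
  100 / (1 + 10^(-m_fa * (fa50 - fa) / 1.36))
}

#' Fit the two-state formic-acid dissolution model
#'
#' Least-squares fit of
#' \deqn{y_{diss} = \frac{100}{1 + 10^{-m_{FA}([FA]_{50} - [FA])/1.36}}}
#' to percent-dissolved data, yielding the denaturation midpoint
#' \eqn{[FA]_{50}} and the steepness \eqn{m_{FA}}
#' (kcal mol\eqn{^{-1}} (%FA)\eqn{^{-1}}; the constant 1.36 = 2.303 RT at
#' 25 C puts it on the free-energy scale). As printed, the model is an
#' increasing sigmoid only for negative \eqn{m_{FA}}; the fit is
#' unconstrained but must yield an increasing curve, and `m_fa_abs`
#' reports the magnitude. The dissolution free energy is reported via the
#' linear-extrapolation identity \eqn{\Delta G = |m_{FA}|\,[FA]_{50}}.
#'
#' @param fa Formic-acid concentrations, % v/v.
#' @param y Percent dissolved (0-100 scale).
#' @return An object of class `dissolution_fit` with `fa50`, `fa50_se`,
#'   `m_fa` (signed), `m_fa_abs`, `m_fa_se`, `dg`, `dg_se` (delta-method),
#'   `residual_rms`, `converged`.
#' @export
fit_dissolution <- function(fa, y) {
  if (!is.numeric(fa) || !is.numeric(y) || length(fa) != length(y))
    .stopf("fa and y must be numeric vectors of equal length")
  if (length(fa) < 4L)
    .stopf("need >= 4 points spanning the transition")
  if (all(y < 10) || all(y > 90))
    .stopf("no transition in data (all ~0 or all ~100); fit not identifiable")
  df <- data.frame(fa = fa, y = y)
  # midpoint start: FA where y crosses 50, by interpolation on sorted data
  o <- order(fa)
  fa50_0 <- tryCatch(stats::approx(y[o], fa[o], xout = 50, ties = mean)$y,
                     error = function(e) NA_real_)
  if (!is.finite(fa50_0)) fa50_0 <- mean(range(fa))
  # unconstrained Gauss-Newton first; steep noisy transitions can make its
  # gradient singular, in which case a bounded port fit (m_fa < 0, the
  # increasing branch) takes over
  fit <- tryCatch(
    suppressWarnings(
      nls(y ~ 100 / (1 + 10^(-m_fa * (fa50 - fa) / 1.36)), data = df,
          start = list(fa50 = fa50_0, m_fa = -1),
          control = nls.control(scaleOffset = 1, maxiter = 500,
                                warnOnly = TRUE))),
    error = function(e) NULL)
  if (is.null(fit) || !all(is.finite(tryCatch(diag(vcov(fit)),
                                              error = function(e) NA)))) {
    # convergence trouble here is reported through the `converged` flag
    fit <- suppressWarnings(
      nls(y ~ 100 / (1 + 10^(-m_fa * (fa50 - fa) / 1.36)), data = df,
          start = list(fa50 = fa50_0, m_fa = -1),
          algorithm = "port",
          lower = c(fa50 = 0.1, m_fa = -50),
          upper = c(fa50 = 99.9, m_fa = -1e-4),
          control = nls.control(scaleOffset = 1, maxiter = 500,
                                warnOnly = TRUE)))
  }
  cf <- coef(fit)
  if (cf[["m_fa"]] > 0)
    .stopf("fitted curve decreases with formic acid; data do not describe dissolution")
  sm <- summary(fit)$coefficients
  fa50 <- cf[["fa50"]]; m <- cf[["m_fa"]]
  se_fa50 <- sm["fa50", "Std. Error"]; se_m <- sm["m_fa", "Std. Error"]
  V <- tryCatch(vcov(fit), error = function(e) NULL)
  cov_fm <- if (!is.null(V)) V["fa50", "m_fa"] else 0
  dg <- abs(m) * fa50
  # delta method for dG = |m| * fa50 (sign of m fixed at the optimum)
  dg_se <- sqrt((abs(m) * se_fa50)^2 + (fa50 * se_m)^2 +
                  2 * abs(m) * fa50 * abs(cov_fm))
  res <- stats::residuals(fit)
  structure(list(fa50 = fa50, fa50_se = se_fa50,
                 m_fa = m, m_fa_abs = abs(m), m_fa_se = se_m,
                 dg = dg, dg_se = dg_se,
                 residual_rms = sqrt(mean(res^2)),
                 converged = fit$convInfo$isConv),
            class = "dissolution_fit")
}

#' Predict percent dissolved from a dissolution fit
#'
#' Evaluates the fitted two-state model; at `fa = fa50` the value is
#' exactly 50.
#'
#' @param fit A `dissolution_fit`.
#' @param fa Formic acid concentrations, % v/v.
#' @return Percent dissolved, same length as `fa`.
#' @export
predict_dissolution <- function(fit, fa) {
  stopifnot(inherits(fit, "dissolution_fit"))
  .dissolution_model(fa, fit$fa50, fit$m_fa)
}

#' @export
print.dissolution_fit <- function(x, ...) {
  cat("Two-state formic-acid dissolution fit\n")
  cat(sprintf("  FA50 = %.3f +/- %.3f %%  |m_FA| = %.4g +/- %.2g kcal/mol/%%FA\n",
              x$fa50, x$fa50_se, x$m_fa_abs, x$m_fa_se))
  cat(sprintf("  dG = %.3g +/- %.2g kcal/mol  residual RMS = %.3g\n",
              x$dg, x$dg_se, x$residual_rms))
  invisible(x)
}
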
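#' Thioflavin T fluorescence trace
#'
#' A plate-reader time course of ThT fluorescence during amyloid
#' fibrillation. Time must be strictly increasing with at least 10 points
#' (traces are typically sampled every 10 min).
#'
#' @param time_h Time, hours, strictly increasing.
#' @param fluorescence Fluorescence, arbitrary units.
#' @param variant,concentration_uM,condition Optional metadata.
#' @return A data frame of class `tht_trace` with metadata attributes.
#' @export
tht_trace <- function(time_h, fluorescence, variant = NA_character_,
                      concentration_uM = NA_real_,
                      condition = NA_character_) {
  if (!is.numeric(time_h) || !is.numeric(fluorescence) ||
      length(time_h) != length(fluorescence))
    .stopf("time and fluorescence must be numeric vectors of equal length")
  if (length(time_h) < 10L)
    .stopf("need >= 10 points in a ThT trace")
  if (any(diff(time_h) <= 0))
    .stopf("time must be strictly increasing")
  if (any(!is.finite(fluorescence)))
    .stopf("fluorescence must be finite")
  structure(data.frame(time_h = time_h, fluorescence = fluorescence),
            variant = variant, concentration_uM = concentration_uM,
            condition = condition,
            class = c("tht_trace", "data.frame"))
}

#' Single-fibril length time series
#'
#' TIRF-microscopy measurements of one fibril's length over time.
#'
#' @param time_s Time, seconds, strictly increasing (>= 2 points).
#' @param length_um Fibril length, micrometres (>= 0).
#' @return A data frame of class `fibril_length_series`.
#' @export
fibril_length_series <- function(time_s, length_um) {
  if (!is.numeric(time_s) || !is.numeric(length_um) ||
      length(time_s) != length(length_um))
    .stopf("time and length must be numeric vectors of equal length")
  if (length(time_s) < 2L) .stopf("need >= 2 points")
  if (any(diff(time_s) <= 0)) .stopf("time must be strictly increasing")
  if (any(!is.finite(length_um)) || any(length_um < 0))
    .stopf("lengths must be finite and >= 0")
  structure(data.frame(time_s = time_s, length_um = length_um),
            class = c("fibril_length_series", "data.frame"))
}

#' Extract kinetic features from a ThT trace
#'
#' Fits the Boltzmann sigmoid
#' \deqn{F(t) = F_0 + \frac{F_{max} - F_0}{1 + e^{-(t - t_{1/2})/\tau_g}}}
#' and reports the standard kinetic features: `lag_time` by the
#' tangent-intercept convention \eqn{t_{1/2} - 2\tau_g}, maximal
#' `growth_rate` \eqn{(F_{max} - F_0)/(4\tau_g)}, `plateau`, `baseline`
#' and `t_half`.
#'
#' Traces whose amplitude is indistinguishable from noise (less than 3x a
#' robust noise estimate from the first 10% of the trace), or that
#' decrease overall, are flagged non-aggregating and returned with `NA`
#' features rather than force-fitted.
#'
#' @param trace A [tht_trace()].
#' @return An object of class `kinetic_features` with fields `lag_time`
#'   (h), `growth_rate` (fluorescence/h), `plateau`, `baseline`, `t_half`
#'   (h), `tau_g` (h), `converged`, `aggregating`.
#' @export
fit_sigmoid <- function(trace) {
  stopifnot(inherits(trace, "tht_trace"))
  t <- trace$time_h
  F <- trace$fluorescence
  n <- length(t)
  nb <- max(3L, ceiling(0.1 * n))
  base0 <- median(F[seq_len(nb)])
  noise <- mad(F[seq_len(nb)])
  # noise floor: robust scale can be 0 on noiseless data
  floor_ <- max(noise, 1e-8 * max(abs(F), 1), 1e-12)
  amp0 <- quantile(F, 0.98, names = FALSE) - base0
  if (amp0 < 3 * floor_ || F[n] < F[1]) {
    return(structure(list(lag_time = NA_real_, growth_rate = NA_real_,
                          plateau = NA_real_, baseline = base0,
                          t_half = NA_real_, tau_g = NA_real_,
                          converged = FALSE, aggregating = FALSE),
                     class = "kinetic_features"))
  }
  plateau0 <- quantile(F, 0.98, names = FALSE)
  thalf0 <- t[which.min(abs(F - (base0 + amp0 / 2)))]
  # rise span from 25% to 75% amplitude ~ 2.2 tau
  t25 <- t[which(F >= base0 + 0.25 * amp0)[1]]
  t75 <- t[which(F >= base0 + 0.75 * amp0)[1]]
  tau0 <- max((t75 - t25) / 2.2, diff(range(t)) / (10 * n), 1e-3)
  fit <- tryCatch(
    nls(fluorescence ~ F0 + (Fmax - F0) / (1 + exp(-(time_h - thalf) / tau)),
        data = trace,
        start = list(F0 = base0, Fmax = plateau0, thalf = thalf0,
                     tau = tau0),
        algorithm = "port",
        lower = c(F0 = -Inf, Fmax = -Inf, thalf = min(t), tau = 1e-6),
        control = nls.control(scaleOffset = 1, maxiter = 500,
                              warnOnly = TRUE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(lag_time = NA_real_, growth_rate = NA_real_,
                          plateau = NA_real_, baseline = base0,
                          t_half = NA_real_, tau_g = NA_real_,
                          converged = FALSE, aggregating = TRUE),
                     class = "kinetic_features"))
  }
  cf <- coef(fit)
  structure(list(lag_time = max(cf[["thalf"]] - 2 * cf[["tau"]], 0),
                 growth_rate = (cf[["Fmax"]] - cf[["F0"]]) /
                   (4 * cf[["tau"]]),
                 plateau = cf[["Fmax"]], baseline = cf[["F0"]],
                 t_half = cf[["thalf"]], tau_g = cf[["tau"]],
                 converged = isTRUE(fit$convInfo$isConv),
                 aggregating = TRUE),
            class = "kinetic_features")
}

#' @export
print.kinetic_features <- function(x, ...) {
  if (!x$aggregating) {
    cat("ThT trace: non-aggregating (amplitude within noise)\n")
  } else {
    cat(sprintf("ThT features: lag = %.3g h, growth = %.3g a.u./h, plateau = %.4g, t1/2 = %.3g h\n",
                x$lag_time, x$growth_rate, x$plateau, x$t_half))
  }
  invisible(x)
}

#' Single-fibril elongation rate from a TIRF length series
#'
#' The elongation rate is the net length change divided by the elapsed
#' time, with the end of growth taken as the last point of the series:
#' \eqn{(L_{end} - L_{start}) / (t_{end} - t_{start})}, returned in nm/s.
#'
#' @param series A [fibril_length_series()] (time s, length um).
#' @return A list with `rate_nm_s` and `shrinkage` (`TRUE` when the net
#'   growth is negative).
#' @examples
#' s <- fibril_length_series(c(0, 10800), c(0, 20.088))
#' growth_rate_tirf(s)$rate_nm_s  # 1.86 nm/s
#' @export
growth_rate_tirf <- function(series) {
  stopifnot(inherits(series, "fibril_length_series"))
  dt <- series$time_s[nrow(series)] - series$time_s[1]
  if (dt <= 0) .stopf("zero elapsed time")
  dl_um <- series$length_um[nrow(series)] - series$length_um[1]
  rate <- 1000 * dl_um / dt  # um/s -> nm/s
  list(rate_nm_s = rate, shrinkage = rate < 0)
}
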
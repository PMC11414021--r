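#' Noise specification for synthetic datasets
#'
#' @param kind `"additive"` (Gaussian noise added to the signal) or
#'   `"multiplicative"` (signal scaled by `1 + N(0, sigma)`).
#' @param sigma Noise scale, in signal units (additive) or as a relative
#'   fraction (multiplicative); >= 0. `sigma = 0` gives the exact
#'   deterministic model.
#' @param seed Integer seed; identical specs produce identical datasets.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(kind = c("additive", "multiplicative"), sigma = 0,
                       seed = 1L) {
  kind <- match.arg(kind)
  .check_scalar(sigma, "sigma", nonneg = TRUE)
  .check_scalar(seed, "seed")
  structure(list(kind = kind, sigma = sigma, seed = as.integer(seed)),
            class = "noise_spec")
}

# Deterministic seed fan-out: one top-level seed plus a dataset label give
# a reproducible per-dataset stream (31-adic hash mod the Mersenne prime
# 2^31 - 1, exact in double precision).
#' Derive a per-dataset seed from a top-level seed and a label
#' @param seed Top-level integer seed.
#' @param label Character label identifying the dataset/stream.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  h <- as.double(seed) %% 2147483647
  for (b in utf8ToInt(as.character(label)))
    h <- (h * 31 + b) %% 2147483647
  as.integer(h + 1)
}

.apply_noise <- function(x, noise) {
  stopifnot(inherits(noise, "noise_spec"))
  if (noise$sigma == 0) return(x)
  set.seed(noise$seed)
  eps <- rnorm(length(x), 0, noise$sigma)
  if (noise$kind == "additive") x + eps else x * (1 + eps)
}

#' Generate a synthetic DEST dataset
#'
#' Forward-simulates attenuation profiles with [simulate_profile()] and
#' applies the requested noise (the field default, additive Gaussian with
#' sigma = 0.01 on the attenuation ratio, mimics the smooth two-field
#' profiles seen experimentally). The noise sigma is recorded in the
#' `sigma` column.
#'
#' @param params An [exchange_parameters()] object.
#' @param scheme A [saturation_scheme()] object.
#' @param noise A [noise_spec()].
#' @return A `dest_dataset`.
#' @export
gen_dest_dataset <- function(params, scheme,
                             noise = noise_spec("additive", 0.01)) {
  d <- simulate_profile(params, scheme)
  d$attenuation <- .apply_noise(d$attenuation, noise)
  # keep within the container's tolerance band for extreme noise draws
  d$attenuation <- pmin(pmax(d$attenuation, -0.05), 1.05)
  d$sigma <- if (noise$sigma > 0) noise$sigma else NA_real_
  d
}

#' Generate a synthetic relaxation decay series
#'
#' \eqn{I(\tau) = I_0 e^{-R_2 \tau}} on the standard 8-point CPMG delay
#' schedule spanning 0-250 ms, plus noise.
#'
#' @param r2 Transverse relaxation rate, 1/s.
#' @param i0 Initial intensity.
#' @param delays Delay schedule, s.
#' @param noise A [noise_spec()] (`"multiplicative"` emulates constant
#'   relative intensity error).
#' @return A [decay_series()].
#' @export
gen_decay <- function(r2, i0 = 1,
                      delays = seq(0, 0.25, length.out = 8),
                      noise = noise_spec("multiplicative", 0)) {
  .check_scalar(r2, "r2", positive = TRUE)
  .check_scalar(i0, "i0", positive = TRUE)
  I <- .apply_noise(i0 * exp(-r2 * delays), noise)
  decay_series(delays, I)
}

#' Generate a synthetic inversion-recovery series
#'
#' \eqn{I(t) = I_\infty (1 - 2 a e^{-R_1 t})} plus noise.
#'
#' @param r1 Longitudinal relaxation rate, 1/s.
#' @param iinf Equilibrium intensity.
#' @param a Inversion efficiency (1 = perfect inversion).
#' @param delays Recovery delays, s.
#' @param noise A [noise_spec()].
#' @return A [recovery_series()].
#' @export
gen_recovery <- function(r1, iinf = 1, a = 1,
                         delays = seq(0, 2, length.out = 10),
                         noise = noise_spec("additive", 0)) {
  .check_scalar(r1, "r1", positive = TRUE)
  I <- .apply_noise(iinf * (1 - 2 * a * exp(-r1 * delays)), noise)
  recovery_series(delays, I)
}

#' Generate a synthetic formic-acid dissolution series
#'
#' Band intensities proportional to the two-state dissolution model, with
#' the reference lane appended if missing so normalization is always
#' possible.
#'
#' @param fa50 Midpoint, % FA.
#' @param m_fa Steepness (negative for an increasing curve; a positive
#'   value is negated with a message).
#' @param lanes FA concentrations of the gel lanes, % v/v.
#' @param reference_fa Normalization lane, % v/v.
#' @param i0 Intensity scale of the reference lane's noiseless model
#'   value.
#' @param noise A [noise_spec()] applied to the intensities.
#' @return A [dissolution_series()].
#' @export
gen_dissolution <- function(fa50, m_fa,
                            lanes = c(0, 30, 45, 50, 55, 57.5, 60, 62.5,
                                      65, 70, 80, 98),
                            reference_fa = 98, i0 = 1,
                            noise = noise_spec("multiplicative", 0)) {
  .check_scalar(fa50, "fa50", positive = TRUE)
  .check_scalar(m_fa, "m_fa")
  if (m_fa > 0) m_fa <- -m_fa
  if (!any(lanes == reference_fa)) lanes <- c(lanes, reference_fa)
  y <- .dissolution_model(lanes, fa50, m_fa)
  I <- .apply_noise(i0 * y / 100, noise)
  I <- pmax(I, 0)
  dissolution_series(lanes, I, reference_fa = reference_fa)
}

#' Generate a synthetic ThT trace
#'
#' A Boltzmann sigmoid parameterized by the observable kinetic features:
#' lag time (tangent-intercept convention), maximal growth rate and
#' plateau. Sampling every 10 min (`step = 1/6` h) follows standard
#' plate-reader practice.
#'
#' @param lag Lag time, h.
#' @param rate Maximal growth rate, fluorescence/h (> 0 for an
#'   aggregating trace; with `plateau == baseline` the trace is flat).
#' @param plateau Final fluorescence.
#' @param baseline Initial fluorescence.
#' @param duration Trace length, h.
#' @param step Sampling interval, h.
#' @param noise A [noise_spec()].
#' @return A [tht_trace()].
#' @export
gen_tht <- function(lag, rate, plateau, baseline = 0, duration = 80,
                    step = 1 / 6, noise = noise_spec("additive", 0)) {
  .check_scalar(lag, "lag", nonneg = TRUE)
  .check_scalar(rate, "rate", nonneg = TRUE)
  t <- seq(0, duration, by = step)
  amp <- plateau - baseline
  F <- if (amp == 0 || rate == 0) {
    rep(baseline, length(t))
  } else {
    tau <- amp / (4 * rate)
    thalf <- lag + 2 * tau
    baseline + amp / (1 + exp(-(t - thalf) / tau))
  }
  tht_trace(t, .apply_noise(F, noise))
}

#' Generate a synthetic single-fibril growth series
#'
#' Linear elongation at a constant rate, imaged at a fixed frame interval
#' (default one frame every 30 s for 3 h).
#'
#' @param rate Elongation rate, nm/s.
#' @param duration Observation time, s.
#' @param frame_interval Time between frames, s.
#' @param noise A [noise_spec()] on the lengths (um).
#' @return A [fibril_length_series()].
#' @export
gen_fibril_growth <- function(rate, duration = 10800, frame_interval = 30,
                              noise = noise_spec("additive", 0)) {
  .check_scalar(rate, "rate", nonneg = TRUE)
  .check_scalar(duration, "duration", positive = TRUE)
  t <- seq(0, duration, by = frame_interval)
  L <- .apply_noise(rate * t / 1000, noise)  # nm/s * s -> um
  fibril_length_series(t, pmax(L, 0))
}
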
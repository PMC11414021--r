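#' Read and write the CSV dialects used by the fitters
#'
#' All pipeline stages exchange small headed CSV files:
#' \describe{
#'   \item{DEST}{`rf_field_hz, offset_hz, attenuation, sigma` (sigma
#'     optional/blank; one file may hold several RF fields)}
#'   \item{relaxation}{`delay_s, intensity`}
#'   \item{dissolution}{`fa_percent, intensity`}
#'   \item{ThT}{`time_h, fluorescence` (+ optional metadata columns
#'     `variant`, `concentration_uM`, `condition`)}
#'   \item{TIRF}{`time_s, length_um`}
#' }
#'
#' A small synthetic example dataset ships with the package:
#' `system.file("extdata", "dest_wt_synthetic.csv", package = "fibrildyn")`,
#' a seeded two-field DEST profile simulated at koff = 900 1/s with
#' additive sigma = 0.01 noise.
#'
#' @param path File path.
#' @name fibrildyn-io
NULL

#' @rdname fibrildyn-io
#' @export
read_dest_csv <- function(path) {
  df <- read.csv(path)
  if (is.null(df$sigma)) df$sigma <- NA_real_
  dest_dataset(df[, c("rf_field_hz", "offset_hz", "attenuation", "sigma")])
}

#' @rdname fibrildyn-io
#' @param data Object to serialize.
#' @export
write_dest_csv <- function(data, path) {
  stopifnot(inherits(data, "dest_dataset"))
  write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

#' @rdname fibrildyn-io
#' @param type `"decay"` or `"recovery"`.
#' @export
read_relaxation_csv <- function(path, type = c("decay", "recovery")) {
  type <- match.arg(type)
  df <- read.csv(path)
  if (type == "decay") decay_series(df$delay_s, df$intensity)
  else recovery_series(df$delay_s, df$intensity)
}

#' @rdname fibrildyn-io
#' @export
write_relaxation_csv <- function(data, path) {
  write.csv(data.frame(delay_s = data$delay_s, intensity = data$intensity),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname fibrildyn-io
#' @param reference_fa Reference lane, % FA.
#' @export
read_dissolution_csv <- function(path, reference_fa = 98) {
  df <- read.csv(path)
  dissolution_series(df$fa_percent, df$intensity,
                     reference_fa = reference_fa)
}

#' @rdname fibrildyn-io
#' @export
write_dissolution_csv <- function(data, path) {
  write.csv(data.frame(fa_percent = data$fa_percent,
                       intensity = data$intensity),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname fibrildyn-io
#' @export
read_tht_csv <- function(path) {
  df <- read.csv(path)
  tht_trace(df$time_h, df$fluorescence,
            variant = if (!is.null(df$variant)) df$variant[1]
                      else NA_character_,
            concentration_uM = if (!is.null(df$concentration_uM))
                                 df$concentration_uM[1] else NA_real_,
            condition = if (!is.null(df$condition)) df$condition[1]
                        else NA_character_)
}

#' @rdname fibrildyn-io
#' @export
write_tht_csv <- function(data, path) {
  write.csv(data.frame(time_h = data$time_h,
                       fluorescence = data$fluorescence),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname fibrildyn-io
#' @export
read_tirf_csv <- function(path) {
  df <- read.csv(path)
  fibril_length_series(df$time_s, df$length_um)
}

#' @rdname fibrildyn-io
#' @export
write_tirf_csv <- function(data, path) {
  write.csv(data.frame(time_s = data$time_s, length_um = data$length_um),
            path, row.names = FALSE)
  invisible(path)
}

#' Serialize a DEST fit (with its fixed parameters) to JSON
#'
#' All fixed parameters are echoed for provenance.
#'
#' @param fit A `dest_fit`.
#' @param path Output path; `NULL` returns the JSON string.
#' @return The path (invisibly) or the JSON string.
#' @export
write_dest_fit_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "dest_fit"))
  x <- list(koff_hat = fit$koff_hat, koff_se = fit$koff_se,
            pB_hat = fit$pB_hat, bound_percent = 100 * fit$pB_hat,
            residual_rms = fit$residual_rms, converged = fit$converged,
            identifiable = fit$identifiable, n_points = fit$n_points,
            fixed_params = unclass(fit$fixed_params))
  if (is.null(path))
    return(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
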
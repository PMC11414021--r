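# Shared fixtures: the standard exchange regime and small schemes.

wt_params <- function(koff = 900, ...) {
  args <- utils::modifyList(
    list(kon_app = 4.3, koff = koff, r1_free = 3, r2_free = 9.1,
         r2_dark = 31000),
    list(...))
  do.call(exchange_parameters, args)
}

two_field_scheme <- function(...) saturation_scheme(...)

small_scheme <- function() {
  saturation_scheme(sat_time = 0.7, rf_fields = c(180, 350),
                    offsets = c(-20000, -5000, -1000, 1000, 5000, 20000))
}

# Random physical parameter set, for property-style sweeps.
random_params <- function() {
  exchange_parameters(
    kon_app = stats::runif(1, 0.5, 20),
    koff = stats::runif(1, 100, 20000),
    r1_free = stats::runif(1, 0.5, 5),
    r2_free = stats::runif(1, 1, 30),
    r2_dark = stats::runif(1, 1000, 50000),
    delta_free = stats::runif(1, -3000, 3000),
    delta_dark = stats::runif(1, -3000, 3000))
}
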
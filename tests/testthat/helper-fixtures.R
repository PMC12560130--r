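# Shared fixtures: everything is generated in code at test time.

# Coarse spectrograph (0.5 nm rows over 600-800 nm) keeps optical-path
# tests fast; readout must still deliver the uniform 0.1 nm output grid.
coarse_cal <- function() default_calibration(600, 800, 0.5)

noiseless_model <- function(...) response_model(intensity_noise_sd = 0,
                                                lambda_noise_sd = 0, ...)

# Two-sample, one-class-each catalogue for fast session tests
tiny_catalog <- function() {
  list(
    liquid_sample("vodka_t", "vodka", analyte_composition(abv = 40)),
    liquid_sample("beer_t", "beer",
                  analyte_composition(abv = 5, sugars = 25,
                                      macromolecules = 3,
                                      organic_acids = 1.5)),
    liquid_sample("DI", "di_water", analyte_composition())
  )
}

# Brute-force dense-grid argmin of the analytic Lorentzian dip:
# the independent oracle for every minimum-extraction check.
oracle_argmin <- function(lambda0, depth = 0.5, fwhm = 80,
                          from = 555, to = 895, step = 1e-3) {
  grid <- seq(from, to, by = step)
  grid[which.min(lorentzian_dip(grid, lambda0, depth, fwhm))]
}
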
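# shared fixtures, all built in code

planted_lignin_centers <- c(1417, 1423, 1464, 1472, 1515, 1521, 1617, 1623)
planted_cellulose_centers <- c(898, 1030, 1060, 1110, 1160, 1315, 1370)

planted_peaks <- function(halfwidth = 4) {
  data.frame(center = planted_lignin_centers, window_halfwidth = halfwidth)
}

# a distortion-free instrument on the default grid
noiseless_instrument <- function() {
  instrument_model(scatter_multiplier_sd = 0,
                   baseline_poly_coeffs_sd = c(0, 0, 0), noise_sd = 0)
}

# cache expensive shared fixtures across test files
.fixture_cache <- new.env()
fixture <- function(name, expr) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- force(expr)
  .fixture_cache[[name]]
}

noiseless_standards <- function() {
  fixture("std0", generate_mixture_series(n_mixtures = 13,
                                          instrument = noiseless_instrument(),
                                          seed = 1))
}

noiseless_cohort <- function() {
  fixture("coh0", generate_cohort(
    cohort_spec(fraction_sd = 0, seed = 1),
    instrument = noiseless_instrument()))
}

# small hand-built spectrum set for unit tests of single stages
toy_set <- function(values, grid = seq_len(ncol(values)), stage = "raw",
                    group = "control") {
  n <- nrow(values)
  spectrum_set(grid, values,
               data.frame(sample_id = sprintf("t%02d", seq_len(n)),
                          group = group, scan = 1,
                          true_fraction = NA_real_),
               stage = stage)
}

# analyse one synthetic cohort with a fixed peak list; returns per_peak table
quantify_cohort <- function(seed, change, noise_sd = 0.01, fraction_sd = 0.015) {
  inst <- instrument_model(noise_sd = noise_sd)
  coh <- generate_cohort(cohort_spec(lignin_change_percent = change,
                                     fraction_sd = fraction_sd, seed = seed),
                         instrument = inst)
  proc <- run_pretreatment(coh)
  hts <- compute_peak_heights(proc, planted_peaks())
  compare_groups(hts)$per_peak
}
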
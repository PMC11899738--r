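# peak discovery, standard curves, correlation gate

test_that("detect_peaks finds planted bands and respects the floor", {
  g <- seq(1380, 1460, by = 0.5)
  gauss <- function(c0, s, a) a * exp(-(g - c0)^2 / (2 * s^2))

  # single band -> exactly one peak at the center (+/- 1 grid point)
  one <- toy_set(matrix(gauss(1420, 3, 1), 1), grid = g)
  d1 <- savgol_second_derivative(one)
  pk1 <- detect_peaks(d1, prominence_floor = 0.5)
  expect_equal(nrow(pk1), 1)
  expect_lt(abs(pk1$center - 1420), 0.5 + 1e-9)

  # the doublet regime: two bands 6 cm^-1 apart, sigma 3, both resolved
  two <- toy_set(matrix(gauss(1417, 3, 0.55) + gauss(1423, 3, 0.50), 1), grid = g)
  d2 <- savgol_second_derivative(two)
  pk2 <- detect_peaks(d2, prominence_floor = 0.2)
  expect_equal(nrow(pk2), 2)
  expect_lt(abs(pk2$center[1] - 1417), 1)
  expect_lt(abs(pk2$center[2] - 1423), 1)

  # prominence_floor = 1 keeps at most the global extremum
  pk3 <- detect_peaks(d2, prominence_floor = 1)
  expect_lte(nrow(pk3), 1)

  # flat spectrum -> empty list, not an error
  flat <- toy_set(matrix(0, 1, length(g)), grid = g)
  df <- savgol_second_derivative(flat)
  expect_equal(nrow(detect_peaks(df)), 0)
})

test_that("lignin-specific peak identification on the noiseless series", {
  std <- fixture("std0_proc", run_pretreatment(noiseless_standards()))
  sam <- fixture("coh0_proc", run_pretreatment(noiseless_cohort()))
  pk <- find_lignin_specific_peaks(std, sam)
  expect_equal(nrow(pk), 8)
  expect_lt(max(abs(pk$center - planted_lignin_centers)), 1)

  # a shared band center must be excluded by the specificity rule
  inst <- noiseless_instrument()
  shared <- component_profile("lignin", mapply(
    band, c(planted_lignin_centers, 1030), 3, c(.55, .5, .45, .4, 1, .6, .7, .55, .9),
    SIMPLIFY = FALSE))
  cel <- default_profiles()$cellulose
  expect_error(check_profiles(shared, cel), class = "invalid_design_error")

  # missing endpoint standards
  std_mid <- subset_spectra(std, std$meta$true_fraction > 0)
  expect_error(find_lignin_specific_peaks(std_mid, sam),
               class = "invalid_design_error")

  # match_tolerance = 0: only exact coincidences survive (sub-grid refined
  # centers essentially never coincide exactly)
  pk0 <- find_lignin_specific_peaks(std, sam, match_tolerance = 0)
  expect_lte(nrow(pk0), nrow(pk))
})

test_that("standard curves: perfect line, oracle r, degenerate designs", {
  std <- fixture("std0_proc", run_pretreatment(noiseless_standards()))
  curves <- build_standard_curves(planted_peaks(), std)
  expect_equal(nrow(curves), 8)
  # noiseless mixtures: exactly linear heights, r = 1 within 1e-9
  expect_true(all(curves$pearson_r > 1 - 1e-9))
  expect_true(all(curves$p_value < 0.05))
  expect_true(all(curves$slope > 0))

  # hand-rolled Pearson oracle on a fixed quintet
  x <- c(0, 0.25, 0.5, 0.75, 1); y <- c(1, 2, 3, 5, 4)
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r_oracle, 0.9, tolerance = 0.01)
  t_or <- r_oracle * sqrt(3) / sqrt(1 - r_oracle^2)
  p_oracle <- 2 * stats::pt(t_or, 3, lower.tail = FALSE)
  expect_equal(ftirlignin:::pearson_p_value(r_oracle, 5), p_oracle)
  expect_equal(unname(stats::cor.test(x, y)$p.value), p_oracle)

  # constant heights across fractions -> non-informative, never selected
  g <- seq(1400, 1440, by = 0.5)
  v <- -exp(-(g - 1417)^2 / 18) # one fixed derivative dip, identical rows
  const <- spectrum_set(g, rbind(v, v, v, v, v),
                        data.frame(sample_id = sprintf("s%d", 1:5),
                                   group = "standard", scan = 1,
                                   true_fraction = seq(0, 1, 0.25)),
                        stage = "raw")
  const$stage <- "second_derivative" # container built directly at this stage
  ccurves <- build_standard_curves(
    data.frame(center = 1417, window_halfwidth = 4), const)
  expect_false(ccurves$informative)
  expect_true(is.na(ccurves$pearson_r))
  expect_warning(sel0 <- select_peaks(ccurves), "no peaks")
  expect_equal(nrow(sel0$peaks), 0)

  # zero variance in fractions is a degenerate design
  same <- std; same$meta$true_fraction <- 0.5
  expect_error(build_standard_curves(planted_peaks(), same),
               class = "degenerate_design_error")
})

test_that("select_peaks applies the conjunction gate with >= semantics", {
  curves <- data.frame(
    peak_center = c(1417, 1464, 1515, 1521, 1617),
    window_halfwidth = 4,
    slope = 1, intercept = 0,
    pearson_r = c(0.9, 0.74, 0.8, 0.75, 0.9),
    p_value = c(0.01, 0.01, 0.01, 0.01, 0.2),
    n = c(13, 13, 13, 13, 4),
    informative = TRUE)
  class(curves) <- c("standard_curves", "data.frame")
  sel <- select_peaks(curves)
  # r gate is >=: 0.75 kept, 0.74 dropped; p gate drops the n = 4 curve
  expect_equal(sel$peaks$center, c(1417, 1515, 1521))

  # high r with too few points really does fail the p gate (n = 4, r = 0.9)
  expect_gt(ftirlignin:::pearson_p_value(0.9, 4), 0.05)

  # selection is monotone in the gate
  sel9 <- select_peaks(curves, r_min = 0.9)
  expect_true(all(sel9$peaks$center %in% sel$peaks$center))

  # empty selection warns but is allowed
  expect_warning(select_peaks(curves, r_min = 0.99), "no peaks")
  expect_error(select_peaks(curves[0, ]), class = "empty_input_error")
})

test_that("compute_peak_heights: magnitudes, clipping, table shape", {
  sam <- fixture("coh0_proc", run_pretreatment(noiseless_cohort()))
  hts <- compute_peak_heights(sam, planted_peaks()[1:4, ])
  expect_equal(nrow(hts), 49 * 4) # 49 samples x 4 peaks
  expect_true(all(hts$height >= 0))
  expect_false(any(hts$clipped))

  # doubled band amplitude approximately doubles the height (linearity of the
  # derivative; the projective normalization is common to both runs)
  g <- seq(800, 1800, by = 0.5)
  gauss <- function(c0, s, a) a * exp(-(g - c0)^2 / (2 * s^2))
  base <- gauss(1515, 3, 1) + gauss(1030, 4, 1)
  twice <- gauss(1515, 3, 2) + gauss(1030, 4, 1)
  d <- savgol_second_derivative(toy_set(rbind(base, twice), grid = g))
  h <- compute_peak_heights(d, data.frame(center = 1515, window_halfwidth = 4))
  expect_equal(h$height[2] / h$height[1], 2, tolerance = 1e-6)

  # flat spectrum: height 0, flagged
  flat <- savgol_second_derivative(toy_set(matrix(0, 1, length(g)), grid = g))
  hf <- compute_peak_heights(flat, data.frame(center = 1515, window_halfwidth = 4))
  expect_equal(hf$height, 0)
  expect_true(hf$clipped)

  # window outside the grid
  expect_error(compute_peak_heights(d, data.frame(center = 4000,
                                                  window_halfwidth = 4)),
               class = "window_error")
})
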
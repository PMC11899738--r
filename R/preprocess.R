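# spectral pretreatment: replicate averaging, ATR correction, unit vector
# normalization, Savitzky-Golay second derivative, EMSC

#' Average replicate scans per sample
#'
#' Pointwise arithmetic mean of all scans sharing a `sample_id`; group and
#' composition metadata are preserved.
#'
#' @param set a raw [spectrum_set()].
#' @return a `spectrum_set` with one spectrum per sample, stage `"averaged"`.
#' @export
average_replicates <- function(set) {
  ids <- unique(set$meta$sample_id)
  vals <- matrix(NA_real_, length(ids), length(set$grid))
  meta <- set$meta[match(ids, set$meta$sample_id), , drop = FALSE]
  meta$scan <- NA_integer_
  for (i in seq_along(ids)) {
    rows <- set$meta$sample_id == ids[i]
    vals[i, ] <- colMeans(set$values[rows, , drop = FALSE])
  }
  out <- set
  out$values <- vals
  out$meta <- meta
  rownames(out$meta) <- NULL
  advance_stage(out, "averaged", allowed = "raw")
}

#' Basic ATR penetration-depth correction
#'
#' In attenuated total reflectance the effective path length scales as
#' 1/wavenumber; the correction multiplies every point by
#' `wavenumber / reference_wavenumber`, leaving the value at the reference
#' unchanged.
#'
#' @param set a `spectrum_set` at stage raw or averaged.
#' @param reference_wavenumber anchor wavenumber (cm^-1).
#' @return the corrected `spectrum_set`, stage `"atr_corrected"`.
#' @export
atr_correct <- function(set, reference_wavenumber = 2000) {
  if (any(set$grid <= 0)) abort("wavenumbers must be positive", "domain_error")
  stopifnot_scalar_number(reference_wavenumber, "reference_wavenumber",
                          positive = TRUE)
  out <- set
  out$values <- sweep(set$values, 2, set$grid / reference_wavenumber, `*`)
  advance_stage(out, "atr_corrected", allowed = c("raw", "averaged"))
}

#' Unit vector normalization (UVN)
#'
#' Scales each spectrum to unit Euclidean norm, removing multiplicative
#' intensity differences. The norm is computed over the working window only
#' so that normalization never depends on discarded spectral regions.
#'
#' @param set a `spectrum_set`.
#' @param window wavenumber window the norm is computed over (default the
#'   fingerprint region).
#' @return the normalized `spectrum_set`, stage `"normalized"`.
#' @export
unit_vector_normalize <- function(set, window = c(800, 1800)) {
  keep <- set$grid >= window[1] & set$grid <= window[2]
  norms <- sqrt(rowSums(set$values[, keep, drop = FALSE]^2))
  if (any(norms == 0)) {
    abort("all-zero spectrum cannot be unit-vector normalized",
          "degenerate_input_error")
  }
  out <- set
  out$values <- set$values / norms
  advance_stage(out, "normalized",
                allowed = c("raw", "averaged", "atr_corrected"))
}

# Savitzky-Golay second-derivative convolution weights for a window of
# `w` points and polynomial order `p`: rows of the least-squares projector
sg_second_derivative_weights <- function(w, p) {
  if (w %% 2 == 0) abort("Savitzky-Golay window must be odd", "parameter_error")
  if (p >= w) abort("window must exceed polynomial order", "parameter_error")
  if (p < 2) abort("polynomial order must be >= 2 for a second derivative",
                   "parameter_error")
  half <- (w - 1) / 2
  X <- outer(seq(-half, half), 0:p, `^`)
  A <- solve(crossprod(X), t(X))
  2 * A[3, ] # second derivative of the fitted polynomial at the window center
}

# filter one spectrum; NA at the (w-1)/2 edge points
sg_filter_vector <- function(v, w, p, spacing) {
  wt <- sg_second_derivative_weights(w, p)
  out <- stats::filter(v, rev(wt), sides = 2)
  as.numeric(out) / spacing^2
}

#' Savitzky-Golay second derivative
#'
#' Local least-squares polynomial fit in a sliding window; the second
#' derivative of the fitted polynomial, scaled by 1/spacing^2 so units are
#' absorbance * cm^2 per cm^2 of wavenumber. The first and last
#' `(window - 1) / 2` points are marked `NA` (invalid) and excluded from all
#' downstream peak work. Requires a uniform grid.
#'
#' @param set a pre-derivative `spectrum_set`.
#' @param window_points odd window length (default 15).
#' @param poly_order polynomial order (default 2).
#' @return the derivative `spectrum_set`, stage `"second_derivative"`.
#' @export
savgol_second_derivative <- function(set, window_points = 15, poly_order = 2) {
  h <- grid_spacing(set) # errors on non-uniform grids
  if (length(set$grid) < window_points) {
    abort("series shorter than the filter window", "parameter_error")
  }
  wt <- sg_second_derivative_weights(window_points, poly_order)
  out <- set
  # stats::filter handles multivariate series: one C call for all spectra
  filtered <- unclass(stats::filter(t(set$values), rev(wt), sides = 2))
  attr(filtered, "tsp") <- NULL
  out$values <- t(filtered) / h^2
  advance_stage(out, "second_derivative",
                allowed = c("raw", "averaged", "atr_corrected", "normalized",
                            "emsc_corrected"))
}

#' Extended multiplicative scatter correction (EMSC)
#'
#' Least-squares decomposition of each spectrum `x` against the set's
#' pointwise mean `ref`:
#' `x = a + b * ref + sum_k d_k p_k(nu) + e` with orthogonal polynomials
#' `p_k` of the wavenumber, replacing `x` by `ref + e / b`. Removes additive
#' polynomial baselines and multiplicative scatter relative to the common
#' reference.
#'
#' @param set a `spectrum_set` with >= 2 spectra (any stage before EMSC;
#'   the chain applies it after the second derivative by default).
#' @param poly_order order of the polynomial baseline model.
#' @param b_floor spectra whose multiplicative coefficient `|b|` falls below
#'   this floor are unrelated to the reference; degenerate-fit error.
#' @param reference optional fixed reference spectrum (full grid length,
#'   `NA` at invalid points). The default uses the set's pointwise mean;
#'   note that the set-mean reference itself shifts under per-spectrum
#'   distortions, so exact distortion invariance requires fixing the
#'   reference of a prior run (the usual calibrate-then-predict workflow).
#' @return the corrected `spectrum_set`, stage `"emsc_corrected"`.
#' @export
emsc_correct <- function(set, poly_order = 2, b_floor = 1e-6,
                         reference = NULL) {
  if (n_spectra(set) < 2) abort("EMSC needs at least 2 spectra", "empty_input_error")
  ok <- apply(set$values, 2, function(col) all(is.finite(col)))
  if (sum(ok) < poly_order + 3) abort("too few valid grid points", "window_error")
  V <- set$values[, ok, drop = FALSE]
  if (is.null(reference)) {
    ref <- colMeans(V)
  } else {
    if (length(reference) != length(set$grid)) {
      abort("reference must have one value per grid point", "grid_mismatch_error")
    }
    ref <- reference[ok]
    if (anyNA(ref)) abort("reference is NA on valid grid points", "grid_mismatch_error")
  }
  X <- cbind(intercept = 1, ref = ref, stats::poly(set$grid[ok], poly_order))
  qrX <- qr(X)
  B <- qr.coef(qrX, t(V))          # (2 + poly_order + ...) x n coefficients
  E <- t(V) - X %*% B              # residuals, one column per spectrum
  b <- B["ref", ]
  if (any(abs(b) < b_floor)) {
    abort(sprintf("EMSC multiplicative coefficient below %g for spectra: %s",
                  b_floor,
                  paste(set$meta$sample_id[abs(b) < b_floor], collapse = ", ")),
          "degenerate_fit_error")
  }
  out <- set
  out$values[, ok] <- t(ref + sweep(E, 2, b, `/`))
  out$values[, !ok] <- NA_real_
  ref_full <- rep(NA_real_, length(set$grid))
  ref_full[ok] <- ref
  attr(out, "emsc_reference") <- ref_full
  advance_stage(out, "emsc_corrected",
                allowed = c("raw", "averaged", "atr_corrected", "normalized",
                            "second_derivative"))
}

#' Run the full pretreatment chain
#'
#' Executes, in order: replicate averaging, basic ATR correction, unit
#' vector normalization, Savitzky-Golay second-derivative filtering
#' (15-point window, 2nd order), and EMSC, then windows the result to the
#' fingerprint region. The EMSC step operates on derivative spectra by
#' default (the literal listed order); set `emsc_on = "absorbance"` for the
#' conventional pre-derivative placement.
#'
#' @param set a raw [spectrum_set()] (replicate scans allowed).
#' @param sg_window,sg_poly_order Savitzky-Golay parameters.
#' @param emsc_poly_order EMSC baseline polynomial order.
#' @param emsc_on `"derivative"` (default) or `"absorbance"`.
#' @param atr_reference ATR correction anchor (cm^-1); `NA` disables the
#'   correction.
#' @param emsc_reference optional fixed EMSC reference from a previous run
#'   (the `emsc_reference` attribute of its result); defaults to the set
#'   mean.
#' @param window fingerprint window bounds (cm^-1).
#' @return the processed `spectrum_set` (stage `"emsc_corrected"` or
#'   `"second_derivative"` depending on `emsc_on`), windowed, with a
#'   `processing_log` attribute recording each stage.
#' @export
run_pretreatment <- function(set, sg_window = 15, sg_poly_order = 2,
                             emsc_poly_order = 2,
                             emsc_on = c("derivative", "absorbance"),
                             atr_reference = 2000, emsc_reference = NULL,
                             window = c(800, 1800)) {
  emsc_on <- match.arg(emsc_on)
  if (!inherits(set, "spectrum_set")) abort("not a spectrum_set", "empty_input_error")
  log <- character()
  note <- function(fmt, ...) log <<- c(log, sprintf(fmt, ...))

  note("input: %d spectra, stage %s", n_spectra(set), set$stage)
  set <- average_replicates(set)
  note("average_replicates: %d samples", n_spectra(set))
  if (!is.na(atr_reference)) {
    set <- atr_correct(set, atr_reference)
    note("atr_correct: reference %g cm-1", atr_reference)
  }
  set <- unit_vector_normalize(set, window = window)
  note("unit_vector_normalize: window %g-%g cm-1", window[1], window[2])
  if (emsc_on == "absorbance") {
    set <- emsc_correct(set, emsc_poly_order, reference = emsc_reference)
    note("emsc_correct (absorbance): poly order %d", emsc_poly_order)
  }
  set <- savgol_second_derivative(set, sg_window, sg_poly_order)
  note("savgol_second_derivative: window %d, order %d", sg_window, sg_poly_order)
  if (emsc_on == "derivative") {
    set <- emsc_correct(set, emsc_poly_order, reference = emsc_reference)
    note("emsc_correct (derivative): poly order %d", emsc_poly_order)
  }
  emsc_ref <- attr(set, "emsc_reference")
  set <- window_spectra(set, window[1], window[2], drop_invalid = TRUE)
  note("window: %g-%g cm-1, %d valid points", window[1], window[2],
       length(set$grid))
  attr(set, "emsc_reference") <- emsc_ref # on the pre-window grid
  attr(set, "processing_log") <- log
  set
}
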
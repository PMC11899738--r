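# calibration: peak discovery on second-derivative spectra, standard curves
# against known lignin fractions, correlation-gated peak selection

# local minima of a derivative vector above a prominence floor; sub-grid
# center by 3-point parabola
detect_minima <- function(v, grid, prominence_floor) {
  mag <- pmax(-v, 0)
  mag[is.na(mag)] <- 0
  top <- max(mag)
  if (top == 0) {
    return(data.frame(center = numeric(0), magnitude = numeric(0)))
  }
  n <- length(v)
  idx <- which(mag >= prominence_floor * top)
  idx <- idx[idx > 1 & idx < n]
  left <- v[idx - 1]; mid <- v[idx]; right <- v[idx + 1]
  is_min <- !is.na(left) & !is.na(right) & mid < left & mid <= right & mid < 0
  idx <- idx[is_min]
  h <- grid[2] - grid[1]
  center <- vapply(idx, function(i) {
    a <- v[i - 1]; b <- v[i]; d <- v[i + 1]
    den <- a - 2 * b + d
    if (den <= 0) return(grid[i])
    grid[i] + 0.5 * (a - d) / den * h
  }, numeric(1))
  ord <- order(center)
  data.frame(center = center[ord], magnitude = mag[idx][ord])
}

#' Detect peaks in a second-derivative spectrum
#'
#' Absorbance maxima appear as derivative minima; a peak is a local minimum
#' whose magnitude reaches `prominence_floor` times the global maximum
#' magnitude. Centers are refined to sub-grid precision by a three-point
#' parabola. A flat spectrum yields an empty list (not an error).
#'
#' @param set a processed `spectrum_set` (second derivative).
#' @param which spectrum row to analyse, or `"mean"` for the pointwise mean
#'   spectrum.
#' @param prominence_floor fraction of the global maximum magnitude.
#' @return data.frame of peak definitions: `center`, `magnitude`,
#'   ordered by wavenumber.
#' @export
detect_peaks <- function(set, which = 1, prominence_floor = 0.05) {
  if (!set$stage %in% c("second_derivative", "emsc_corrected")) {
    abort("detect_peaks expects second-derivative spectra", "stage_error")
  }
  v <- if (identical(which, "mean")) colMeans(set$values) else set$values[which, ]
  detect_minima(v, set$grid, prominence_floor)
}

#' Identify lignin-specific peaks from standards and samples
#'
#' A candidate peak must (i) appear in the pure-lignin standard, (ii) have
#' no pure-cellulose peak within `match_tolerance`, and (iii) have a
#' matching peak in the mean sample spectrum within `match_tolerance`. The
#' reported center is the sample-side center. The cellulose veto uses a
#' higher prominence floor than the lignin side: genuine cellulose bands sit
#' far above the noise floor, and a low veto threshold would let noise
#' minima disqualify true lignin bands.
#'
#' @param standards processed standards `spectrum_set` with
#'   `meta$true_fraction` including both endpoints 0 and 1.
#' @param samples processed plant-sample `spectrum_set`.
#' @param match_tolerance peak matching tolerance (cm^-1); defaults to the
#'   4 cm^-1 instrument resolution.
#' @param window_halfwidth half-width of the peak-height window attached to
#'   each returned peak (cm^-1).
#' @param floor_lignin,floor_exclude,floor_samples prominence floors for the
#'   pure-lignin, pure-cellulose (veto) and sample-side detections.
#' @return data.frame of peak definitions (`center`, `window_halfwidth`,
#'   `source`), ordered by wavenumber.
#' @export
find_lignin_specific_peaks <- function(standards, samples,
                                       match_tolerance = 4,
                                       window_halfwidth = match_tolerance,
                                       floor_lignin = 0.05,
                                       floor_exclude = 0.10,
                                       floor_samples = 0.01) {
  fr <- standards$meta$true_fraction
  if (is.null(fr) || !any(fr == 1) || !any(fr == 0)) {
    abort("standards must include pure lignin (fraction 1) and pure cellulose (fraction 0)",
          "invalid_design_error")
  }
  pk_lig <- detect_peaks(standards, which = which(fr == 1)[1], floor_lignin)
  pk_cel <- detect_peaks(standards, which = which(fr == 0)[1], floor_exclude)
  pk_sam <- detect_peaks(samples, which = "mean", floor_samples)
  keep <- vapply(pk_lig$center, function(cc) {
    specific <- nrow(pk_cel) == 0 || all(abs(pk_cel$center - cc) > match_tolerance)
    matched <- nrow(pk_sam) > 0 && any(abs(pk_sam$center - cc) <= match_tolerance)
    specific && matched
  }, logical(1))
  centers <- vapply(pk_lig$center[keep], function(cc) {
    pk_sam$center[which.min(abs(pk_sam$center - cc))] # sample-side center
  }, numeric(1))
  centers <- sort(unique(centers))
  data.frame(center = centers,
             window_halfwidth = rep(window_halfwidth, length(centers)),
             source = rep("matched", length(centers)))
}

#' Second-derivative peak heights
#'
#' Height is the negated minimum of the second derivative within the peak
#' window, clipped at zero (derivative minima correspond to absorbance
#' maxima, so informative heights are positive magnitudes). Windows without
#' a negative minimum yield height 0 and are flagged.
#'
#' @param set a processed `spectrum_set`.
#' @param peaks data.frame with `center` and `window_halfwidth`.
#' @return data.frame with one row per (sample, peak): `sample_id`, `group`,
#'   `true_fraction` (if known), `peak_center`, `height`, `clipped`.
#' @export
compute_peak_heights <- function(set, peaks) {
  peaks <- as.data.frame(peaks)
  if (nrow(peaks) == 0) abort("no peaks supplied", "empty_input_error")
  out <- list()
  for (j in seq_len(nrow(peaks))) {
    cc <- peaks$center[j]
    hw <- peaks$window_halfwidth[j]
    idx <- which(set$grid >= cc - hw & set$grid <= cc + hw)
    if (length(idx) == 0) {
      abort(sprintf("peak window at %g cm^-1 lies outside the grid", cc),
            "window_error")
    }
    mins <- apply(set$values[, idx, drop = FALSE], 1, function(v) {
      v <- v[!is.na(v)]
      if (length(v) == 0) NA_real_ else min(v)
    })
    height <- pmax(0, -mins)
    out[[j]] <- data.frame(
      sample_id = set$meta$sample_id,
      group = set$meta$group,
      true_fraction = if (!is.null(set$meta$true_fraction)) set$meta$true_fraction else NA_real_,
      peak_center = cc,
      height = height,
      clipped = !is.na(mins) & mins >= 0
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Build per-peak standard curves
#'
#' Ordinary least-squares line of second-derivative peak height versus known
#' lignin weight fraction, with Pearson's r and its two-sided p-value from
#' the exact t transform on n - 2 degrees of freedom (appropriate for the
#' small calibration designs used here). Peaks whose heights do not vary are
#' flagged non-informative and can never be selected.
#'
#' @param peaks data.frame of peak definitions (`center`,
#'   `window_halfwidth`).
#' @param standards processed standards `spectrum_set` with
#'   `meta$true_fraction`.
#' @return data.frame of class `standard_curves`: `peak_center`,
#'   `window_halfwidth`, `slope`, `intercept`, `pearson_r`, `p_value`, `n`,
#'   `informative`.
#' @export
build_standard_curves <- function(peaks, standards) {
  fr <- standards$meta$true_fraction
  if (is.null(fr) || length(unique(fr)) < 2) {
    abort("standards need at least two distinct lignin fractions",
          "degenerate_design_error")
  }
  if (length(fr) < 3) abort("need >= 3 standards", "degenerate_design_error")
  hts <- compute_peak_heights(standards, peaks)
  out <- lapply(split(hts, hts$peak_center), function(d) {
    x <- d$true_fraction; y <- d$height
    n <- length(x)
    sxx <- sum((x - mean(x))^2)
    sxy <- sum((x - mean(x)) * (y - mean(y)))
    syy <- sum((y - mean(y))^2)
    slope <- sxy / sxx
    intercept <- mean(y) - slope * mean(x)
    if (syy == 0) {
      r <- NA_real_; p <- NA_real_; informative <- FALSE
    } else {
      r <- sxy / sqrt(sxx * syy)
      r <- max(-1, min(1, r))
      p <- pearson_p_value(r, n)
      informative <- TRUE
    }
    data.frame(peak_center = d$peak_center[1],
               window_halfwidth = peaks$window_halfwidth[
                 match(d$peak_center[1], peaks$center)],
               slope = slope, intercept = intercept, pearson_r = r,
               p_value = p, n = n, informative = informative)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$peak_center), ]
  rownames(res) <- NULL
  class(res) <- c("standard_curves", "data.frame")
  res
}

# exact two-sided p for Pearson's r via the t transform, n - 2 df
pearson_p_value <- function(r, n) {
  if (abs(r) >= 1) return(0)
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * stats::pt(abs(t), df = n - 2, lower.tail = FALSE)
}

#' Select calibration peaks by the correlation gate
#'
#' Keeps peaks whose standard curve satisfies `pearson_r >= r_min` and
#' `p_value < alpha` (defaults r >= 0.75, p < 0.05). An empty selection is
#' allowed, with a warning.
#'
#' @param curves a `standard_curves` data.frame.
#' @param r_min minimum Pearson correlation (gate is `>=`).
#' @param alpha significance level (gate is `<`).
#' @return a `selected_peak_set`: list with `peaks` (data.frame `center`,
#'   `window_halfwidth`, `source`), `curves` (the selected rows) and the
#'   gate used.
#' @export
select_peaks <- function(curves, r_min = 0.75, alpha = 0.05) {
  if (nrow(curves) == 0) abort("no curves supplied", "empty_input_error")
  keep <- !is.na(curves$pearson_r) & curves$informative &
    curves$pearson_r >= r_min & curves$p_value < alpha
  sel <- curves[keep, , drop = FALSE]
  sel <- sel[order(sel$peak_center), , drop = FALSE]
  if (nrow(sel) == 0) warning("no peaks pass the correlation gate")
  structure(list(
    peaks = data.frame(center = sel$peak_center,
                       window_halfwidth = sel$window_halfwidth,
                       source = rep("matched", nrow(sel))),
    curves = sel,
    r_min = r_min, alpha = alpha
  ), class = "selected_peak_set")
}

#' @export
print.selected_peak_set <- function(x, ...) {
  cat(sprintf("<selected_peak_set> %d peaks (gate: r >= %g, p < %g)\n",
              nrow(x$peaks), x$r_min, x$alpha))
  if (nrow(x$curves)) {
    print(x$curves[, c("peak_center", "slope", "pearson_r", "p_value")],
          row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Write a calibration report CSV
#'
#' @param curves all candidate `standard_curves`.
#' @param selection a `selected_peak_set`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_calibration_report <- function(curves, selection, path) {
  curves$selected <- curves$peak_center %in% selection$peaks$center
  utils::write.csv(curves, path, row.names = FALSE)
  invisible(path)
}
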
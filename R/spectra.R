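# spectrum containers: a set of spectra sharing one wavenumber grid

# declared order of pretreatment stages; transitions may skip forward but
# never move backward or repeat
.stages <- c("raw", "averaged", "atr_corrected", "normalized",
             "second_derivative", "emsc_corrected")

#' Construct a spectrum set
#'
#' The central container of the pipeline: `n` spectra sharing one strictly
#' monotone wavenumber grid, stored as an `n x p` absorbance (or derivative)
#' matrix plus per-spectrum metadata.
#'
#' @param grid numeric vector of wavenumbers (cm^-1), strictly monotone
#'   increasing.
#' @param values numeric matrix, one row per spectrum, `length(grid)` columns.
#' @param meta data.frame with one row per spectrum. Columns `sample_id` and
#'   `group` are required; `scan` and `true_fraction` are used when present.
#' @param stage processing stage label, one of
#'   `r paste0('"', paste(c("raw","averaged","atr_corrected","normalized","second_derivative","emsc_corrected"), collapse = '", "'), '"')`.
#' @return an object of class `spectrum_set`.
#' @export
spectrum_set <- function(grid, values, meta, stage = "raw") {
  grid <- as.numeric(grid)
  if (length(grid) < 2 || any(diff(grid) <= 0)) {
    abort("grid must be strictly monotone increasing", "grid_error")
  }
  values <- as.matrix(values)
  if (ncol(values) != length(grid)) {
    abort("values must have one column per grid point", "grid_error")
  }
  if (nrow(values) == 0L) abort("a spectrum set must be non-empty", "empty_input_error")
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (nrow(meta) != nrow(values)) {
    abort("meta must have one row per spectrum", "domain_error")
  }
  for (col in c("sample_id", "group")) {
    if (is.null(meta[[col]])) abort(sprintf("meta must contain `%s`", col), "domain_error")
  }
  stage <- match.arg(stage, .stages)
  structure(
    list(grid = grid, values = values, meta = meta, stage = stage,
         history = stage),
    class = "spectrum_set"
  )
}

#' Number of spectra in a set
#' @param set a `spectrum_set`.
#' @return integer count.
#' @export
n_spectra <- function(set) nrow(set$values)

grid_spacing <- function(set) {
  d <- diff(set$grid)
  if (diff(range(d)) > 1e-8 * mean(d)) {
    abort("grid spacing is non-uniform; resample_spectra() first", "resample_required_error")
  }
  mean(d)
}

advance_stage <- function(set, new_stage, allowed) {
  if (new_stage %in% set$history) {
    abort(sprintf("stage `%s` already applied (stages may not repeat)", new_stage),
          "stage_error")
  }
  if (!set$stage %in% allowed) {
    abort(sprintf("operation requires stage in {%s}, got `%s`",
                  paste(allowed, collapse = ", "), set$stage), "stage_error")
  }
  set$stage <- new_stage
  set$history <- c(set$history, new_stage)
  set
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set> %d spectra x %d points | %.1f-%.1f cm-1 | stage: %s\n",
              n_spectra(x), length(x$grid), min(x$grid), max(x$grid), x$stage))
  cat("groups:", paste(sprintf("%s=%d", names(table(x$meta$group)),
                               table(x$meta$group)), collapse = " "), "\n")
  invisible(x)
}

#' Subset a spectrum set by spectrum index
#'
#' @param set a `spectrum_set`.
#' @param i integer or logical row index.
#' @return a `spectrum_set` with the selected spectra.
#' @export
subset_spectra <- function(set, i) {
  out <- set
  out$values <- set$values[i, , drop = FALSE]
  out$meta <- set$meta[i, , drop = FALSE]
  if (nrow(out$values) == 0L) abort("subset selects no spectra", "empty_input_error")
  out
}

#' Combine spectrum sets sharing one grid
#'
#' @param ... `spectrum_set` objects at the same stage and on identical grids.
#' @return the row-bound `spectrum_set`.
#' @export
combine_spectra <- function(...) {
  sets <- list(...)
  stopifnot(length(sets) >= 1)
  g <- sets[[1]]$grid
  for (s in sets[-1]) {
    if (length(s$grid) != length(g) || any(abs(s$grid - g) > 1e-9)) {
      abort("spectrum sets are on different grids", "grid_mismatch_error")
    }
    if (s$stage != sets[[1]]$stage) abort("stages differ", "stage_error")
  }
  out <- sets[[1]]
  out$values <- do.call(rbind, lapply(sets, `[[`, "values"))
  cols <- Reduce(intersect, lapply(sets, function(s) names(s$meta)))
  out$meta <- do.call(rbind, lapply(sets, function(s) s$meta[, cols, drop = FALSE]))
  out
}

#' Restrict a spectrum set to a wavenumber window
#'
#' @param set a `spectrum_set`.
#' @param wmin,wmax window bounds in cm^-1.
#' @param drop_invalid drop grid points whose values are `NA` in every
#'   spectrum (e.g. Savitzky-Golay edge points).
#' @return a windowed `spectrum_set`.
#' @export
window_spectra <- function(set, wmin = 800, wmax = 1800, drop_invalid = TRUE) {
  keep <- set$grid >= wmin & set$grid <= wmax
  if (drop_invalid) keep <- keep & apply(set$values, 2, function(v) any(!is.na(v)))
  if (!any(keep)) abort("window retains no grid points", "window_error")
  out <- set
  out$grid <- set$grid[keep]
  out$values <- set$values[, keep, drop = FALSE]
  out
}

#' Resample spectra onto a uniform grid by linear interpolation
#'
#' Non-uniform grids are rejected by the derivative stage rather than
#' silently interpolated; this is the explicit resampling step.
#'
#' @param set a `spectrum_set`.
#' @param grid target wavenumber grid (strictly monotone increasing).
#' @return a `spectrum_set` on `grid`.
#' @export
resample_spectra <- function(set, grid) {
  grid <- as.numeric(grid)
  if (any(diff(grid) <= 0)) abort("target grid must be strictly increasing", "grid_error")
  vals <- t(apply(set$values, 1, function(v) {
    stats::approx(set$grid, v, xout = grid, rule = 1)$y
  }))
  out <- set
  out$grid <- grid
  out$values <- vals
  out
}
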
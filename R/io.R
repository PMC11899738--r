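# CSV interchange: one two-column file per scan plus a samples manifest

#' Write a spectrum set as per-scan CSV files
#'
#' Writes one `wavenumber_cm-1,absorbance` CSV per scan, a samples manifest
#' (`sample_id, group, scan, scan_file, true_fraction`), and a flat
#' key/value ground-truth sidecar.
#'
#' @param set a `spectrum_set`.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix for the scan files.
#' @return the manifest path, invisibly.
#' @export
write_spectrum_set <- function(set, dir, prefix = "scan") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- n_spectra(set)
  files <- character(n)
  for (i in seq_len(n)) {
    files[i] <- sprintf("%s_%04d.csv", prefix, i)
    utils::write.csv(
      data.frame(`wavenumber_cm-1` = set$grid, absorbance = set$values[i, ],
                 check.names = FALSE),
      file.path(dir, files[i]), row.names = FALSE)
  }
  manifest <- cbind(set$meta, scan_file = files)
  manifest_path <- file.path(dir, "samples_manifest.csv")
  utils::write.csv(manifest, manifest_path, row.names = FALSE)
  write_kv(list(stage = set$stage, n_spectra = n,
                grid_min = min(set$grid), grid_max = max(set$grid),
                grid_points = length(set$grid)),
           file.path(dir, "ground_truth.txt"))
  invisible(manifest_path)
}

#' Read a spectrum set from a samples manifest
#'
#' @param manifest_path path to a `samples_manifest.csv` written by
#'   [write_spectrum_set()].
#' @param stage stage label to assign.
#' @return a `spectrum_set`.
#' @export
read_spectrum_set <- function(manifest_path, stage = "raw") {
  if (!file.exists(manifest_path)) {
    abort(sprintf("manifest not found: %s", manifest_path), "usage_error")
  }
  manifest <- utils::read.csv(manifest_path, check.names = FALSE)
  dir <- dirname(manifest_path)
  grid <- NULL
  vals <- NULL
  for (i in seq_len(nrow(manifest))) {
    f <- file.path(dir, manifest$scan_file[i])
    if (!file.exists(f)) abort(sprintf("scan file not found: %s", f), "usage_error")
    d <- utils::read.csv(f, check.names = FALSE)
    if (is.null(grid)) {
      grid <- d[[1]]
      vals <- matrix(NA_real_, nrow(manifest), length(grid))
    } else if (length(d[[1]]) != length(grid) ||
               any(abs(d[[1]] - grid) > 1e-9)) {
      abort(sprintf("scan %s is on a different grid", f), "grid_mismatch_error")
    }
    vals[i, ] <- d[[2]]
  }
  meta <- manifest[, setdiff(names(manifest), "scan_file"), drop = FALSE]
  spectrum_set(grid, vals, meta, stage)
}
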
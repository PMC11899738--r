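# synthetic-data module: binary mixture standards, plant cohorts,
# dose-response tables and gene-universe draws with known ground truth

#' Define a vibrational band
#'
#' @param center band center (cm^-1).
#' @param width Gaussian sigma, or Lorentzian half-width at half-maximum
#'   (cm^-1); must be > 0.
#' @param amplitude peak absorbance; must be >= 0.
#' @param shape `"gaussian"` or `"lorentzian"`.
#' @return a `band` object.
#' @export
band <- function(center, width, amplitude, shape = c("gaussian", "lorentzian")) {
  shape <- match.arg(shape)
  stopifnot_scalar_number(center, "center")
  stopifnot_scalar_number(width, "width", positive = TRUE)
  stopifnot_scalar_number(amplitude, "amplitude")
  if (amplitude < 0) abort("amplitude must be >= 0", "domain_error")
  structure(list(center = center, width = width, amplitude = amplitude,
                 shape = shape), class = "band")
}

#' Define a pure-component band profile
#'
#' @param name component label, e.g. `"lignin"`.
#' @param bands list of [band()] objects (at least one).
#' @return a `component_profile` object.
#' @export
component_profile <- function(name, bands) {
  if (length(bands) < 1) abort("a profile needs at least one band", "invalid_design_error")
  stopifnot(all(vapply(bands, inherits, logical(1), "band")))
  structure(list(name = name, bands = bands), class = "component_profile")
}

band_centers <- function(profile) vapply(profile$bands, `[[`, numeric(1), "center")

#' Evaluate a component profile on a wavenumber grid
#'
#' @param profile a [component_profile()].
#' @param grid wavenumber grid (cm^-1).
#' @return numeric absorbance vector.
#' @export
profile_spectrum <- function(profile, grid) {
  v <- numeric(length(grid))
  for (b in profile$bands) {
    v <- v + switch(b$shape,
      gaussian = b$amplitude * exp(-(grid - b$center)^2 / (2 * b$width^2)),
      lorentzian = b$amplitude / (1 + ((grid - b$center) / b$width)^2)
    )
  }
  v
}

#' Describe the emulated ATR-FTIR instrument
#'
#' The distortion model is exactly what the pretreatment chain is designed to
#' remove: a lognormal multiplicative scatter factor, an additive quadratic
#' baseline, iid Gaussian detector noise, and (optionally) the 1/wavenumber
#' intensity weighting of ATR sampling.
#'
#' @param wmin,wmax,spacing wavenumber grid (cm^-1). The grid must cover at
#'   least 800-1800 cm^-1. The default 0.5 cm^-1 spacing corresponds to the
#'   data-point density a 4 cm^-1-resolution instrument produces with
#'   standard zero-filling, and makes the 15-point derivative window span
#'   about 7 cm^-1 so that 6 cm^-1 doublets remain resolvable.
#' @param scatter_multiplier_sd sd of log multiplicative scatter factor.
#' @param baseline_poly_coeffs_sd per-order sds of the additive polynomial
#'   baseline (constant, linear, quadratic on the scaled grid).
#' @param noise_sd sd of additive white noise (absorbance units).
#' @param atr_distortion apply the 1/wavenumber ATR intensity weighting
#'   (anchored at `atr_reference`).
#' @param atr_reference anchor wavenumber of the ATR weighting (cm^-1).
#' @return an `instrument_model` object.
#' @export
instrument_model <- function(wmin = 800, wmax = 1800, spacing = 0.5,
                             scatter_multiplier_sd = 0.1,
                             baseline_poly_coeffs_sd = c(0.05, 0.05, 0.05),
                             noise_sd = 0.01,
                             atr_distortion = TRUE,
                             atr_reference = 2000) {
  stopifnot_scalar_number(spacing, "spacing", positive = TRUE)
  if (wmin > 800 || wmax < 1800) {
    abort("instrument grid must cover the 800-1800 cm^-1 fingerprint window",
          "invalid_design_error")
  }
  if (any(c(scatter_multiplier_sd, baseline_poly_coeffs_sd, noise_sd) < 0)) {
    abort("distortion sds must be >= 0", "domain_error")
  }
  structure(list(grid = seq(wmin, wmax, by = spacing),
                 scatter_multiplier_sd = scatter_multiplier_sd,
                 baseline_poly_coeffs_sd = baseline_poly_coeffs_sd,
                 noise_sd = noise_sd,
                 atr_distortion = atr_distortion,
                 atr_reference = atr_reference),
            class = "instrument_model")
}

# canonical lignin band set: aromatic skeletal/CH-deformation doublets
.lignin_centers <- c(1417, 1423, 1464, 1472, 1515, 1521, 1617, 1623)
.lignin_amps    <- c(0.55, 0.50, 0.45, 0.40, 1.00, 0.60, 0.70, 0.55)
# standard cellulose assignments (C-O/C-C stretching, ring modes)
.cellulose_centers <- c(898, 1030, 1060, 1110, 1160, 1315, 1370)
.cellulose_amps    <- c(0.45, 1.00, 0.80, 0.55, 0.60, 0.40, 0.45)

.profile_cache <- new.env(parent = emptyenv())

#' Default norm-balanced lignin and cellulose profiles
#'
#' Returns the package's default pure-component profiles. The lignin profile
#' places the eight canonical aromatic bands (doublets at
#' 1417/1423, 1464/1472, 1515/1521 and 1617/1623 cm^-1) with width sigma = 3
#' cm^-1. The cellulose profile uses seven standard polysaccharide band
#' positions; its common width and overall amplitude are calibrated
#' numerically so that both profiles carry the same Euclidean norm in
#' absorbance space *and* in Savitzky-Golay second-derivative space on the
#' working grid. This equal-weight idealization makes the projective
#' UVN+EMSC normalization composition-neutral: standard curves are exactly
#' linear in the lignin fraction and the cohort relative-change estimator is
#' nearly unbiased (see the methods vignette for the derivation).
#'
#' @param grid wavenumber grid the balance is computed on.
#' @param sg_window,sg_order Savitzky-Golay parameters used downstream.
#' @return list with elements `lignin` and `cellulose`
#'   ([component_profile()] objects).
#' @export
default_profiles <- function(grid = instrument_model()$grid,
                             sg_window = 15, sg_order = 2) {
  key <- paste(range(grid), length(grid), sg_window, sg_order, collapse = "_")
  if (!is.null(.profile_cache[[key]])) return(.profile_cache[[key]])
  h <- mean(diff(grid))
  d2 <- function(v) {
    d <- sg_filter_vector(v, sg_window, sg_order, h)
    d[!is.na(d)]
  }
  lig <- component_profile("lignin", mapply(band, .lignin_centers, 3,
                                            .lignin_amps, SIMPLIFY = FALSE))
  L <- profile_spectrum(lig, grid)
  target <- sqrt(sum(d2(L)^2)) / sqrt(sum(L^2))
  cel_at <- function(width, amps = .cellulose_amps) {
    component_profile("cellulose", mapply(band, .cellulose_centers, width,
                                          amps, SIMPLIFY = FALSE))
  }
  ratio <- function(width) {
    Cv <- profile_spectrum(cel_at(width), grid)
    sqrt(sum(d2(Cv)^2)) / sqrt(sum(Cv^2)) - target
  }
  # the deriv/abs norm ratio is non-monotone in width (narrow bands are
  # attenuated by the SG window); take the broad, physically plausible root
  width <- stats::uniroot(ratio, c(3.05, 12), tol = 1e-12)$root
  Cv <- profile_spectrum(cel_at(width), grid)
  scale <- sqrt(sum(L^2)) / sqrt(sum(Cv^2))
  cel <- cel_at(width, .cellulose_amps * scale)
  out <- list(lignin = lig, cellulose = cel)
  .profile_cache[[key]] <- out
  out
}

check_profiles <- function(lignin, cellulose, tolerance = 4) {
  cl <- band_centers(lignin)
  cc <- band_centers(cellulose)
  if (min(abs(outer(cl, cc, `-`))) < tolerance) {
    abort(sprintf("lignin and cellulose band centers closer than %g cm^-1: 'lignin-specific' would be ill-defined",
                  tolerance), "invalid_design_error")
  }
  invisible(TRUE)
}

# one raw scan: composition signal + instrument distortions (consumes RNG)
simulate_scan <- function(signal, instrument) {
  g <- instrument$grid
  v <- signal
  if (instrument$atr_distortion) v <- v * instrument$atr_reference / g
  u <- 2 * (g - mean(range(g))) / diff(range(g)) # scaled to [-1, 1]
  bsd <- instrument$baseline_poly_coeffs_sd
  coef <- stats::rnorm(length(bsd), 0, bsd)
  baseline <- drop(outer(u, seq_along(bsd) - 1, `^`) %*% coef)
  mult <- stats::rlnorm(1, 0, instrument$scatter_multiplier_sd)
  v * mult + baseline + stats::rnorm(length(g), 0, instrument$noise_sd)
}

#' Generate a binary lignin/cellulose mixture standard series
#'
#' Emulates gravimetric binary mixtures spanning pure cellulose to pure
#' lignin: mixture i has absorbance
#' `fraction_i * lignin + (1 - fraction_i) * cellulose` plus instrument
#' distortions, with fractions evenly spaced on \[0, 1\] including both
#' endpoints.
#'
#' @param lignin_profile,cellulose_profile [component_profile()] objects;
#'   default to the norm-balanced pair from [default_profiles()].
#' @param n_mixtures number of standards (>= 3; 13 matches the classic
#'   bench design).
#' @param instrument an [instrument_model()].
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @param n_scans replicate scans per standard.
#' @return a raw-stage [spectrum_set()] whose `meta$true_fraction` records
#'   the known lignin weight fraction of every scan.
#' @export
generate_mixture_series <- function(lignin_profile = NULL,
                                    cellulose_profile = NULL,
                                    n_mixtures = 13,
                                    instrument = instrument_model(),
                                    seed = 1, n_scans = 1) {
  if (n_mixtures < 3) {
    abort("n_mixtures must be >= 3 (a correlation cannot be fit otherwise)",
          "invalid_design_error")
  }
  if (is.null(lignin_profile) || is.null(cellulose_profile)) {
    prof <- default_profiles(instrument$grid)
    if (is.null(lignin_profile)) lignin_profile <- prof$lignin
    if (is.null(cellulose_profile)) cellulose_profile <- prof$cellulose
  }
  check_profiles(lignin_profile, cellulose_profile)
  g <- instrument$grid
  L <- profile_spectrum(lignin_profile, g)
  C <- profile_spectrum(cellulose_profile, g)
  fractions <- seq(0, 1, length.out = n_mixtures)
  with_seed(seed, {
    rows <- list()
    meta <- list()
    k <- 0L
    for (i in seq_len(n_mixtures)) {
      signal <- fractions[i] * L + (1 - fractions[i]) * C
      for (s in seq_len(n_scans)) {
        k <- k + 1L
        rows[[k]] <- simulate_scan(signal, instrument)
        meta[[k]] <- data.frame(sample_id = sprintf("std_%02d", i),
                                group = "standard", scan = s,
                                true_fraction = fractions[i])
      }
    }
    spectrum_set(g, do.call(rbind, rows), do.call(rbind, meta), "raw")
  })
}

#' Describe a simulated exposure cohort
#'
#' @param n_exposed,n_control sample counts (>= 1).
#' @param n_scans_per_sample replicate scans per plant sample.
#' @param lignin_fraction_control mean lignin weight fraction of control
#'   plants, in \[0, 1\]. Default 0.12, a typical Klason-lignin share of
#'   young whole-plant tissue.
#' @param lignin_change_percent signed percent change of the exposed group's
#'   mean fraction relative to control.
#' @param fraction_sd between-plant biological sd of the lignin fraction
#'   (absolute units).
#' @param seed integer seed.
#' @return a `cohort_spec` object.
#' @export
cohort_spec <- function(n_exposed = 16, n_control = 33, n_scans_per_sample = 3,
                        lignin_fraction_control = 0.12,
                        lignin_change_percent = 25,
                        fraction_sd = 0.015, seed = 1) {
  if (n_exposed < 1 || n_control < 1 || n_scans_per_sample < 1) {
    abort("counts must be >= 1", "invalid_design_error")
  }
  if (lignin_fraction_control < 0 || lignin_fraction_control > 1) {
    abort("lignin_fraction_control must be in [0, 1]", "invalid_design_error")
  }
  exposed <- lignin_fraction_control * (1 + lignin_change_percent / 100)
  if (exposed < 0 || exposed > 1) {
    abort("implied exposed lignin fraction falls outside [0, 1]",
          "invalid_design_error")
  }
  structure(list(n_exposed = n_exposed, n_control = n_control,
                 n_scans_per_sample = n_scans_per_sample,
                 lignin_fraction_control = lignin_fraction_control,
                 lignin_change_percent = lignin_change_percent,
                 lignin_fraction_exposed = exposed,
                 fraction_sd = fraction_sd, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate an exposed-versus-control plant cohort
#'
#' Each plant sample draws a lignin weight fraction from a truncated normal
#' around its group mean and yields `n_scans_per_sample` replicate scans
#' sharing that composition but with independent instrument distortions.
#'
#' @param spec a [cohort_spec()].
#' @param profiles list with `lignin` and `cellulose`
#'   [component_profile()] objects (defaults to [default_profiles()]).
#' @param instrument an [instrument_model()].
#' @return a raw-stage [spectrum_set()]; `meta` carries `sample_id`, `group`
#'   (`"exposed"`/`"control"`), `scan` and the true per-sample fraction.
#' @export
generate_cohort <- function(spec = cohort_spec(), profiles = NULL,
                            instrument = instrument_model()) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(profiles)) profiles <- default_profiles(instrument$grid)
  check_profiles(profiles$lignin, profiles$cellulose)
  g <- instrument$grid
  L <- profile_spectrum(profiles$lignin, g)
  C <- profile_spectrum(profiles$cellulose, g)
  with_seed(spec$seed, {
    n <- spec$n_exposed + spec$n_control
    group <- rep(c("exposed", "control"), c(spec$n_exposed, spec$n_control))
    mu <- ifelse(group == "exposed", spec$lignin_fraction_exposed,
                 spec$lignin_fraction_control)
    fr <- pmin(pmax(stats::rnorm(n, mu, spec$fraction_sd), 0), 1)
    rows <- list(); meta <- list(); k <- 0L
    for (i in seq_len(n)) {
      signal <- fr[i] * L + (1 - fr[i]) * C
      for (s in seq_len(spec$n_scans_per_sample)) {
        k <- k + 1L
        rows[[k]] <- simulate_scan(signal, instrument)
        meta[[k]] <- data.frame(sample_id = sprintf("s%03d", i),
                                group = group[i], scan = s,
                                true_fraction = fr[i])
      }
    }
    spectrum_set(g, do.call(rbind, rows), do.call(rbind, meta), "raw")
  })
}

#' Define ground truth for a four-parameter logistic dose-response
#'
#' @param bottom,top asymptotic responses (`top != bottom`).
#' @param ec50 dose of half-maximal effect (mg/L, > 0).
#' @param hill Hill slope (nonzero).
#' @param noise_sd response-scale Gaussian noise sd.
#' @param doses dose levels (mg/L); at least 4 distinct values.
#' @return a `dose_response_truth` object.
#' @export
dose_response_truth <- function(bottom = 0, top = 100, ec50 = 8.1, hill = 1.5,
                                noise_sd = 10,
                                doses = c(0, 1, 2.5, 5, 10, 25)) {
  if (top == bottom) abort("top must differ from bottom", "invalid_design_error")
  stopifnot_scalar_number(ec50, "ec50", positive = TRUE)
  if (hill == 0) abort("hill slope must be nonzero", "invalid_design_error")
  if (length(unique(doses)) < 4) {
    abort("need >= 4 distinct doses (the model has 4 parameters)",
          "invalid_design_error")
  }
  if (any(doses < 0)) abort("doses must be >= 0", "domain_error")
  structure(list(bottom = bottom, top = top, ec50 = ec50, hill = hill,
                 noise_sd = noise_sd, doses = sort(doses)),
            class = "dose_response_truth")
}

#' Four-parameter logistic response function
#'
#' `bottom + (top - bottom) / (1 + (x / ec50)^hill)`; at dose 0 the response
#' equals the `top` asymptote for positive Hill slopes (`bottom` for
#' negative ones).
#'
#' @param x dose vector (>= 0).
#' @param bottom,top,ec50,hill model parameters.
#' @return response vector.
#' @export
logistic4 <- function(x, bottom, top, ec50, hill) {
  r <- (x / ec50)^hill # 0^positive = 0 -> top; 0^negative = Inf -> bottom
  bottom + (top - bottom) / (1 + r)
}

#' Generate a dose-response table
#'
#' @param truth a [dose_response_truth()].
#' @param seed integer seed.
#' @param n_replicates biological replicates per dose.
#' @return data.frame with columns `dose` and `response`.
#' @export
generate_dose_response <- function(truth = dose_response_truth(), seed = 1,
                                   n_replicates = 3) {
  stopifnot(inherits(truth, "dose_response_truth"))
  d <- rep(truth$doses, each = n_replicates)
  mu <- logistic4(d, truth$bottom, truth$top, truth$ec50, truth$hill)
  with_seed(seed, {
    data.frame(dose = d,
               response = mu + stats::rnorm(length(d), 0, truth$noise_sd))
  })
}

# deterministic gene labels, memoized (repeated simulation draws reuse them)
.gene_label_cache <- new.env(parent = emptyenv())
gene_labels <- function(n) {
  key <- as.character(n)
  if (is.null(.gene_label_cache[[key]])) {
    .gene_label_cache[[key]] <- sprintf("g%05d", seq_len(n))
  }
  .gene_label_cache[[key]]
}

#' Generate a gene universe with planted category enrichment
#'
#' Draws a set of differentially expressed genes (DEGs) such that category
#' j's expected DEG count is
#' `size_j * (n_deg / universe_size) * planted_enrichment_j`: each DEG
#' independently lands in category j with probability
#' `size_j * enrichment_j / universe_size`. Categories are disjoint gene
#' subsets.
#'
#' @param universe_size total genes.
#' @param n_deg number of DEGs (`<= universe_size`).
#' @param categories data.frame with columns `label`, `size`,
#'   `planted_enrichment`.
#' @param seed integer seed.
#' @return list with `membership` (data.frame `gene_id`, `category`,
#'   `is_deg`) and `truth` (per-category expected and observed counts).
#' @export
generate_enrichment_universe <- function(universe_size, n_deg, categories,
                                         seed = 1) {
  categories <- as.data.frame(categories)
  stopifnot(all(c("label", "size", "planted_enrichment") %in% names(categories)))
  if (n_deg > universe_size) abort("n_deg exceeds universe_size", "invalid_design_error")
  if (sum(categories$size) > universe_size) {
    abort("category sizes exceed universe (categories are disjoint here)",
          "invalid_design_error")
  }
  expected <- categories$size * (n_deg / universe_size) * categories$planted_enrichment
  p_cat <- categories$size * categories$planted_enrichment / universe_size
  if (any(expected > categories$size) || any(p_cat > 1)) {
    abort("infeasible planted enrichment (expected count exceeds category size)",
          "invalid_design_error")
  }
  with_seed(seed, {
    n_cat <- nrow(categories)
    gene_id <- gene_labels(universe_size)
    category <- rep(NA_character_, universe_size)
    pos <- sample.int(universe_size, sum(categories$size))
    idx <- split(pos, rep(seq_len(n_cat), categories$size))
    for (j in seq_len(n_cat)) category[idx[[j]]] <- categories$label[j]
    observed <- stats::rbinom(n_cat, n_deg, p_cat)
    observed <- pmin(observed, categories$size)
    if (sum(observed) > n_deg) {
      abort("infeasible planted enrichment (category DEGs exceed n_deg)",
            "invalid_design_error")
    }
    is_deg <- rep(FALSE, universe_size)
    for (j in seq_len(n_cat)) {
      if (observed[j] > 0) {
        is_deg[sample(idx[[j]], observed[j])] <- TRUE
      }
    }
    bg <- which(is.na(category))
    is_deg[sample(bg, n_deg - sum(observed))] <- TRUE
    truth <- cbind(categories, expected_null = categories$size * n_deg / universe_size,
                   expected_planted = expected, observed = observed)
    list(membership = data.frame(gene_id = gene_id, category = category,
                                 is_deg = is_deg),
         truth = truth)
  })
}
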
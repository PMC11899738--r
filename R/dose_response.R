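# dose-response: four-parameter logistic (variable slope) fit with
# bootstrap EC50 uncertainty, and germination-rate summaries

fourpl_ss <- function(theta, x, y) {
  mu <- logistic4(x, theta[1], theta[2], exp(theta[3]), theta[4])
  sum((y - mu)^2)
}

# one optimisation pass from a given start; returns list(theta, ss, conv)
fourpl_optim <- function(start, x, y) {
  fit <- try(stats::optim(start, fourpl_ss, x = x, y = y, method = "BFGS",
                          control = list(maxit = 2000, reltol = 1e-15)),
             silent = TRUE)
  if (inherits(fit, "try-error")) return(NULL)
  list(theta = fit$par, ss = fit$value, conv = fit$convergence == 0)
}

# Gauss-Newton polish of the BFGS winner; scaleOffset handles the
# zero-residual (noiseless round-trip) case that defeats plain nls
fourpl_polish <- function(best, x, y) {
  th <- best$theta
  fit <- try(suppressWarnings(stats::nls(
    y ~ logistic4(x, b, t, exp(le), h),
    start = list(b = th[1], t = th[2], le = th[3], h = th[4]),
    algorithm = "port",
    control = stats::nls.control(maxiter = 500, scaleOffset = 1,
                                 warnOnly = TRUE))), silent = TRUE)
  if (!inherits(fit, "try-error")) {
    cf <- stats::coef(fit)
    cand <- list(theta = unname(cf), ss = sum(stats::resid(fit)^2),
                 conv = best$conv)
    if (cand$ss <= best$ss + 1e-30) best <- cand
  }
  refined <- fourpl_optim(best$theta, x, y)
  if (!is.null(refined) && refined$ss <= best$ss) refined else best
}

#' Fit the four-parameter logistic dose-response model
#'
#' Nonlinear least squares on
#' `y = bottom + (top - bottom) / (1 + (x / ec50)^hill)` (the
#' "inhibitor-versus-response, variable slope" family; EC50 and IC50 are
#' synonyms for the half-maximal dose here). Initialization is multi-start:
#' EC50 starts at three log-dose quantiles and the Hill slope tries both
#' orientations, so increasing and decreasing curves are both reachable.
#' EC50 uncertainty comes from a case-resampling bootstrap rather than the
#' asymptotic covariance, which is unreliable at the small dose designs
#' typical of growth assays.
#'
#' @param doses dose vector (>= 0; dose 0 anchors the `top` asymptote).
#' @param responses response vector.
#' @param n_bootstrap bootstrap replicates for the EC50 sd (0 disables).
#' @param seed integer seed for the bootstrap.
#' @return a `dose_response_fit`: list with `bottom`, `top`, `ec50`, `hill`,
#'   `ec50_sd`, `residual_sd`, `converged`, `n_points`.
#' @export
fit_4pl <- function(doses, responses, n_bootstrap = 1000, seed = 1) {
  if (any(doses < 0)) abort("doses must be >= 0", "domain_error")
  if (length(doses) != length(responses) || any(!is.finite(responses))) {
    abort("doses and responses must be finite and of equal length", "domain_error")
  }
  pos <- unique(doses[doses > 0])
  if (length(pos) < 4) abort("need >= 4 distinct positive doses", "invalid_design_error")
  if (stats::sd(responses) == 0) {
    abort("flat response: the model is not identifiable", "non_identifiable_error")
  }
  x <- doses; y <- responses
  b0 <- min(y); t0 <- max(y)
  lq <- stats::quantile(log(pos), c(0.25, 0.5, 0.75), names = FALSE)
  starts <- list()
  for (le in lq) for (hl in c(1, 2, 0.5, -1, -2, -0.5)) {
    starts[[length(starts) + 1]] <- c(b0, t0, le, hl)
  }
  best <- NULL
  for (s in starts) {
    fit <- fourpl_optim(s, x, y)
    if (!is.null(fit) && (is.null(best) || fit$ss < best$ss)) best <- fit
  }
  if (is.null(best)) abort("4PL fit failed from every start", "non_identifiable_error")
  best <- fourpl_polish(best, x, y)
  th <- best$theta
  ec50_sd <- NA_real_
  if (n_bootstrap > 0) {
    ec <- with_seed(seed, {
      vapply(seq_len(n_bootstrap), function(i) {
        idx <- sample.int(length(x), replace = TRUE)
        f <- fourpl_optim(th, x[idx], y[idx])
        if (is.null(f)) NA_real_ else exp(f$theta[3])
      }, numeric(1))
    })
    # half-width of the central 68% percentile interval: matches the +/- 1 sd
    # convention while staying robust to the occasional divergent refit
    qs <- stats::quantile(ec, c(0.16, 0.84), na.rm = TRUE, names = FALSE)
    ec50_sd <- (qs[2] - qs[1]) / 2
  }
  structure(list(
    bottom = th[1], top = th[2], ec50 = exp(th[3]), hill = th[4],
    ec50_sd = ec50_sd,
    residual_sd = sqrt(best$ss / max(1, length(x) - 4)),
    converged = isTRUE(best$conv), n_points = length(x)
  ), class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("<dose_response_fit> EC50 = %.3g +/- %.2g | hill = %.3g | bottom = %.3g, top = %.3g | %s\n",
              x$ec50, x$ec50_sd, x$hill, x$bottom, x$top,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Summarize germination counts per dose
#'
#' Germination fraction per dose (reported to 3 decimals) and a two-sided
#' Fisher exact test of each dose against the dose-0 control on the
#' (germinated, not germinated) counts.
#'
#' @param counts data.frame with columns `dose`, `germinated`, `planted`;
#'   must include dose 0.
#' @return data.frame with `dose`, `germinated`, `planted`, `fraction`
#'   (3 decimals), `p_value` (vs control; `NA` for the control row itself).
#' @export
summarize_germination <- function(counts) {
  counts <- as.data.frame(counts)
  stopifnot(all(c("dose", "germinated", "planted") %in% names(counts)))
  if (any(counts$planted <= 0)) abort("zero planted seeds", "domain_error")
  if (any(counts$germinated < 0 | counts$germinated > counts$planted)) {
    abort("germinated counts must lie in [0, planted]", "domain_error")
  }
  if (!any(counts$dose == 0)) abort("control (dose 0) row required", "domain_error")
  ctrl <- counts[counts$dose == 0, ][1, ]
  p <- vapply(seq_len(nrow(counts)), function(i) {
    if (counts$dose[i] == 0) return(NA_real_)
    m <- matrix(c(counts$germinated[i], counts$planted[i] - counts$germinated[i],
                  ctrl$germinated, ctrl$planted - ctrl$germinated), nrow = 2)
    stats::fisher.test(m)$p.value
  }, numeric(1))
  data.frame(dose = counts$dose, germinated = counts$germinated,
             planted = counts$planted,
             fraction = round(counts$germinated / counts$planted, 3),
             p_value = p)
}

#' Write a dose-response fit report
#'
#' @param fit a `dose_response_fit`.
#' @param path flat key/value report path.
#' @param curve_path optional CSV of the fitted curve for plotting.
#' @param n_curve number of curve points.
#' @return `path`, invisibly.
#' @export
write_dose_response_report <- function(fit, path, curve_path = NULL,
                                       n_curve = 100) {
  write_kv(list(bottom = fit$bottom, top = fit$top, ec50 = fit$ec50,
                hill = fit$hill, ec50_sd = fit$ec50_sd,
                residual_sd = fit$residual_sd,
                converged = fit$converged, n_points = fit$n_points), path)
  if (!is.null(curve_path)) {
    xs <- exp(seq(log(fit$ec50 / 100), log(fit$ec50 * 100),
                  length.out = n_curve))
    utils::write.csv(data.frame(
      dose = xs,
      response = logistic4(xs, fit$bottom, fit$top, fit$ec50, fit$hill)
    ), curve_path, row.names = FALSE)
  }
  invisible(path)
}
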
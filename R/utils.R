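# internal helpers shared across modules

#' Evaluate code with a temporary RNG state
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's random number
#' stream afterwards, so seeded generators never perturb user-level
#' reproducibility.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1) # initialise the RNG so there is a state to restore
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "ftirlignin_error")))
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name), "domain_error")
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be > 0", name), "domain_error")
  }
  invisible(x)
}

# flat "key: value" sidecar files (no YAML dependency in the environment)
write_kv <- function(x, path) {
  stopifnot(is.list(x))
  lines <- vapply(names(x), function(k) {
    v <- x[[k]]
    paste0(k, ": ", paste(format(v, digits = 15, trim = TRUE), collapse = " "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

read_kv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) != 3) abort(sprintf("malformed line in %s: %s", path, ln), "io_error")
    key <- trimws(m[2])
    vals <- strsplit(trimws(m[3]), "\\s+")[[1]]
    num <- suppressWarnings(as.numeric(vals))
    out[[key]] <- if (!anyNA(num)) num else paste(vals, collapse = " ")
  }
  out
}
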
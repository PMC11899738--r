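# transcriptome summary: differential-expression thresholds and
# hypergeometric Gene Ontology fold-enrichment arithmetic

#' Apply differential-expression thresholds
#'
#' Classifies genes as upregulated (fold change > 2), downregulated
#' (fold change < 0.5) or unchanged, requiring an adjusted p-value below
#' `alpha` for either call. The fold-change gates are strict inequalities by
#' default; set `strict = FALSE` for `>= 2` / `<= 0.5`.
#'
#' @param table data.frame with columns `gene_id`, `fold_change`
#'   (expression ratio exposed/control, > 0) and `adjusted_p`.
#' @param fc_up,fc_down fold-change gates.
#' @param alpha adjusted-p gate.
#' @param strict use strict fold-change inequalities.
#' @return list with `records` (the table plus a `direction` column),
#'   `n_up`, `n_down`, `pct_up`, `pct_down` (percent of DEGs, 1 decimal).
#' @export
filter_degs <- function(table, fc_up = 2, fc_down = 0.5, alpha = 0.05,
                        strict = TRUE) {
  table <- as.data.frame(table)
  stopifnot(all(c("gene_id", "fold_change", "adjusted_p") %in% names(table)))
  if (any(table$fold_change <= 0)) {
    abort("fold changes must be positive ratios", "domain_error")
  }
  if (any(table$adjusted_p < 0 | table$adjusted_p > 1)) {
    abort("adjusted p-values must lie in [0, 1]", "domain_error")
  }
  up <- if (strict) table$fold_change > fc_up else table$fold_change >= fc_up
  down <- if (strict) table$fold_change < fc_down else table$fold_change <= fc_down
  sig <- table$adjusted_p < alpha
  direction <- ifelse(up & sig, "up", ifelse(down & sig, "down", "none"))
  n_up <- sum(direction == "up"); n_down <- sum(direction == "down")
  n_deg <- n_up + n_down
  table$direction <- direction
  list(records = table, n_up = n_up, n_down = n_down,
       pct_up = if (n_deg) round(100 * n_up / n_deg, 1) else NA_real_,
       pct_down = if (n_deg) round(100 * n_down / n_deg, 1) else NA_real_)
}

#' Fold enrichment of an observed count over an expected count
#'
#' @param observed observed DEG count in a category.
#' @param expected expected count under proportional sampling.
#' @return `observed / expected` (`NA` if expected is 0).
#' @export
fold_enrichment <- function(observed, expected) {
  ifelse(expected > 0, observed / expected, NA_real_)
}

#' Build a fold-enrichment table with hypergeometric p-values
#'
#' For each category: `expected = size * deg_count / universe_size`,
#' `fold_enrichment = observed / expected`, upper-tail hypergeometric
#' `raw_p = P[X >= observed]` for `X ~ Hypergeometric(universe_size, size,
#' deg_count)`, Bonferroni adjustment across the listed terms, and the
#' reporting gate `fold_enrichment >= fe_min & adjusted_p < alpha`.
#'
#' @param categories data.frame with columns `term`, `size`, `observed`.
#' @param deg_count total DEGs.
#' @param universe_size total genes in the universe.
#' @param fe_min,alpha reporting gate (defaults: enrichment >= 1.5,
#'   Bonferroni p < 0.05).
#' @return data.frame with `term`, `size`, `observed`, `expected`,
#'   `fold_enrichment` (both reported to 2 decimals in the `*_2dp` columns),
#'   `raw_p`, `adjusted_p`, `passes_gate`.
#' @export
fold_enrichment_table <- function(categories, deg_count, universe_size,
                                  fe_min = 1.5, alpha = 0.05) {
  categories <- as.data.frame(categories)
  stopifnot(all(c("term", "size", "observed") %in% names(categories)))
  if (any(categories$size > universe_size)) {
    abort("category size exceeds universe", "consistency_error")
  }
  if (any(categories$observed > pmin(categories$size, deg_count))) {
    abort("observed count exceeds category size or DEG count",
          "consistency_error")
  }
  expected <- categories$size * deg_count / universe_size
  fe <- fold_enrichment(categories$observed, expected)
  raw_p <- stats::phyper(categories$observed - 1, categories$size,
                         universe_size - categories$size, deg_count,
                         lower.tail = FALSE)
  adj <- pmin(1, raw_p * nrow(categories))
  data.frame(term = categories$term, size = categories$size,
             observed = categories$observed,
             expected = expected, expected_2dp = round(expected, 2),
             fold_enrichment = fe, fold_enrichment_2dp = round(fe, 2),
             raw_p = raw_p, adjusted_p = adj,
             passes_gate = !is.na(fe) & fe >= fe_min & adj < alpha)
}

#' Lower-tail (depletion) p-value for an enrichment row
#'
#' Under-represented categories are supported by
#' `P[X <= observed]` under the same hypergeometric model.
#'
#' @param observed,size observed DEG count and category size.
#' @param deg_count,universe_size totals.
#' @return lower-tail p-value.
#' @export
depletion_support <- function(observed, size, deg_count, universe_size) {
  stats::phyper(observed, size, universe_size - size, deg_count,
                lower.tail = TRUE)
}

#' Estimate the gene-universe size from one enrichment row
#'
#' Reported enrichment tables rarely state the universe; it can be
#' recovered from any row as `size * deg_count / expected`.
#'
#' @param size,deg_count,expected the row's category size, total DEGs, and
#'   expected count.
#' @return estimated universe size.
#' @export
estimate_universe_size <- function(size, deg_count, expected) {
  if (any(expected <= 0)) abort("expected must be > 0", "domain_error")
  size * deg_count / expected
}
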
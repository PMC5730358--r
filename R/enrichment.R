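#' Build the 2x2 contingency table for one term
#'
#' Cross-tabulates DEG membership against term membership over the
#' enrichment universe: `a` DEGs in the term, `b` DEGs outside it, `c`
#' non-DEG universe genes in the term, `d` the remainder.
#'
#' @param deg_genes Character vector of DEG ids (must lie in `universe`).
#' @param term_genes Character vector of the term's gene ids (must lie in
#'   `universe`).
#' @param universe Character vector of all measured, annotated gene ids.
#' @return Object of class `contingency_table`: list with integer cells
#'   `a`, `b`, `c`, `d`.
#' @export
build_table <- function(deg_genes, term_genes, universe) {
  deg_genes <- unique(deg_genes)
  term_genes <- unique(term_genes)
  universe <- unique(universe)
  if (!all(deg_genes %in% universe))
    stop("DEG gene(s) outside the universe; universe mismatch upstream")
  if (!all(term_genes %in% universe))
    stop("term gene(s) outside the universe; universe mismatch upstream")
  a <- length(intersect(deg_genes, term_genes))
  b <- length(deg_genes) - a
  c_ <- length(term_genes) - a
  d <- length(universe) - a - b - c_
  structure(list(a = a, b = b, c = c_, d = d), class = "contingency_table")
}

#' One-sided Fisher's exact test on a 2x2 table
#'
#' Tests overrepresentation (alternative "greater"): the p-value is the
#' upper hypergeometric tail `P(K >= a)` given the table margins. The odds
#' ratio is the sample estimate `ad / bc`, reported as `Inf` when
#' `b * c = 0` with `a * d > 0` and as 0 when `a * d = 0`. A
#' Haldane-Anscombe estimate (0.5 added to every cell) is also returned for
#' rank-based downstream comparisons where finite values are needed.
#'
#' @param table A `contingency_table`.
#' @return List with `p_value`, `odds_ratio`, `odds_ratio_haldane`.
#' @export
fisher_exact <- function(table) {
  a <- table$a; b <- table$b; c_ <- table$c; d <- table$d
  if (min(a, b, c_, d) < 0) stop("negative cell count")
  # margins: term size m = a + c, non-term n = b + d, DEGs drawn k = a + b
  p <- stats::phyper(a - 1L, a + c_, b + d, a + b, lower.tail = FALSE)
  or <- if (a * d == 0) {
    0
  } else if (b * c_ == 0) {
    Inf
  } else {
    (a / b) * (d / c_)
  }
  or_h <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
  list(p_value = min(p, 1), odds_ratio = or, odds_ratio_haldane = or_h)
}

#' Adjust p-values for multiple testing (B-H or B-Y)
#'
#' Step-up adjusted values via [stats::p.adjust()]. Benjamini-Yekutieli
#' multiplies by the harmonic-sum factor and is valid under arbitrary
#' dependence; Benjamini-Hochberg is the classical FDR step-up.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @param method `"BY"` (default) or `"BH"`.
#' @return Numeric vector of adjusted values, capped at 1.
#' @export
adjust_pvalues <- function(p, method = c("BY", "BH")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0, 1]")
  stats::p.adjust(p, method = method)
}

#' Term overrepresentation among DEGs across a catalog
#'
#' Runs the one-sided Fisher's exact test for every catalog term against
#' the called DEG set, adjusts p-values across terms, and flags
#' significance at `fdr <= alpha` (inclusive). With zero DEGs every term
#' gets `a = 0`, p = 1, and nothing is significant.
#'
#' @param deg_calls data.frame from [call_degs()].
#' @param catalog A `gene_set_catalog` whose universe covers the profiled
#'   genes.
#' @param alpha FDR threshold (default 0.05).
#' @param method Multiple-testing correction, `"BY"` (default) or `"BH"`.
#' @return data.frame sorted by `p_value` with columns `term_id`,
#'   `term_name`, `a`, `b`, `c`, `d`, `odds_ratio`, `odds_ratio_haldane`,
#'   `p_value`, `fdr`, `significant`.
#' @export
run_enrichment <- function(deg_calls, catalog, alpha = 0.05,
                           method = c("BY", "BH")) {
  method <- match.arg(method)
  deg <- deg_calls$gene_id[deg_calls$is_deg]
  deg <- intersect(deg, catalog$universe)
  terms <- names(catalog$term_sets)
  rows <- lapply(terms, function(t) {
    tab <- build_table(deg, catalog$term_sets[[t]], catalog$universe)
    ft <- fisher_exact(tab)
    data.frame(term_id = t,
               a = tab$a, b = tab$b, c = tab$c, d = tab$d,
               odds_ratio = ft$odds_ratio,
               odds_ratio_haldane = ft$odds_ratio_haldane,
               p_value = ft$p_value,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$term_name <- unname(catalog$term_names[res$term_id])
  res$term_name[is.na(res$term_name)] <- res$term_id[is.na(res$term_name)]
  res$fdr <- adjust_pvalues(res$p_value, method)
  res$significant <- res$fdr <= alpha
  res <- res[order(res$p_value, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  res[c("term_id", "term_name", "a", "b", "c", "d", "odds_ratio",
        "odds_ratio_haldane", "p_value", "fdr", "significant")]
}
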
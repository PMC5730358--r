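#' Pair a candidate ranking with a reference truth set
#'
#' Restricts both analyses to their common terms (exact term-id matching).
#' The reference may be a full table of tested terms with a `significant`
#' flag, or just a character vector of significant term ids (in which case
#' the candidate's tested terms define the domain).
#'
#' @param candidate data.frame with columns `term_id`, `p_value` and
#'   optionally `odds_ratio` / `odds_ratio_haldane`.
#' @param reference data.frame with columns `term_id`, `significant`, or a
#'   character vector of significant term ids.
#' @return Object of class `reference_comparison`: list with
#'   `common_terms`, `p_value` (named), `odds_ratio` (named, may be NULL),
#'   `label` (named logical truth flags).
#' @export
make_reference_comparison <- function(candidate, reference) {
  if (!all(c("term_id", "p_value") %in% names(candidate)))
    stop("candidate needs columns term_id and p_value")
  if (is.character(reference)) {
    ref_domain <- candidate$term_id
    ref_sig <- reference
  } else {
    if (!all(c("term_id", "significant") %in% names(reference)))
      stop("reference needs columns term_id and significant")
    ref_domain <- reference$term_id
    ref_sig <- reference$term_id[as.logical(reference$significant)]
  }
  common <- intersect(candidate$term_id, ref_domain)
  if (length(common) == 0L) stop("no terms shared by candidate and reference")
  idx <- match(common, candidate$term_id)
  p <- candidate$p_value[idx]
  names(p) <- common
  or_col <- intersect(c("odds_ratio_haldane", "odds_ratio"), names(candidate))
  or <- if (length(or_col)) {
    v <- candidate[[or_col[1]]][idx]
    names(v) <- common
    v
  } else NULL
  label <- common %in% ref_sig
  names(label) <- common
  structure(list(common_terms = common, p_value = p, odds_ratio = or,
                 label = label),
            class = "reference_comparison")
}

#' ROC curve and AUC of a candidate ranking against reference labels
#'
#' Terms are ranked by candidate p-value ascending (smaller p = stronger
#' call). Tied p-values are grouped, giving one ROC vertex per distinct
#' score, and the AUC is the trapezoidal area — equal to the tie-corrected
#' Mann-Whitney probability that a random reference-positive term
#' outranks a random negative.
#'
#' @param cmp A `reference_comparison`.
#' @return List with `fpr`, `tpr` (vectors starting at 0 and ending at 1)
#'   and `auc`.
#' @export
roc_curve <- function(cmp) {
  lab <- cmp$label
  npos <- sum(lab)
  nneg <- sum(!lab)
  if (npos == 0L || nneg == 0L)
    stop("reference must contain at least one positive and one negative")
  p <- cmp$p_value
  # Mann-Whitney with average ranks on confidence = -p
  r <- rank(-p, ties.method = "average")
  auc <- (sum(r[lab]) - npos * (npos + 1) / 2) / (npos * nneg)

  ord <- order(p)
  ps <- p[ord]; ls <- lab[ord]
  grp <- cumsum(!duplicated(ps))
  tp <- cumsum(ls); fp <- cumsum(!ls)
  last <- !duplicated(grp, fromLast = TRUE)   # last index of each tie group
  list(fpr = c(0, fp[last] / nneg),
       tpr = c(0, tp[last] / npos),
       auc = auc)
}

#' Precision-recall curve against reference labels
#'
#' At each threshold `t` the candidate calls every term with `p <= t`;
#' precision is TP/(TP+FP) (defined as 1 when nothing is called) and
#' recall is TP/(TP+FN).
#'
#' @param cmp A `reference_comparison`.
#' @param threshold_grid Thresholds on the candidate p-value; defaults to
#'   the sorted distinct p-values.
#' @return List with `threshold`, `precision`, `recall`.
#' @export
precision_recall <- function(cmp, threshold_grid = NULL) {
  lab <- cmp$label
  if (sum(lab) == 0L || sum(!lab) == 0L)
    stop("reference must contain at least one positive and one negative")
  p <- cmp$p_value
  if (is.null(threshold_grid)) threshold_grid <- sort(unique(p))
  npos <- sum(lab)
  prec <- rec <- numeric(length(threshold_grid))
  for (i in seq_along(threshold_grid)) {
    called <- p <= threshold_grid[i]
    tp <- sum(called & lab)
    prec[i] <- if (sum(called) == 0L) 1 else tp / sum(called)
    rec[i] <- tp / npos
  }
  list(threshold = threshold_grid, precision = prec, recall = rec)
}

#' Spearman rank correlation of two odds-ratio orderings
#'
#' Computed over the common terms with average-rank ties; the p-value uses
#' the t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2`
#' degrees of freedom (0 at |rho| = 1). Use Haldane-corrected odds ratios
#' so every rank is finite.
#'
#' @param candidate_or,reference_or Named numeric vectors of odds ratios.
#' @return List with `rho`, `p_value`, `n`.
#' @export
rank_correlation <- function(candidate_or, reference_or) {
  common <- intersect(names(candidate_or), names(reference_or))
  if (length(common) < 3L) stop("need at least 3 common terms")
  x <- rank(candidate_or[common], ties.method = "average")
  y <- rank(reference_or[common], ties.method = "average")
  rho <- stats::cor(x, y)
  n <- length(common)
  p <- if (abs(rho) >= 1) {
    0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n)
}

#' Cross-replicate overlap of significant term sets
#'
#' Counts the terms significant in every replicate, optionally intersected
#' with a reference set, and reports overlap fractions under both
#' conventions: per-replicate (intersection size over each replicate's own
#' count) and smallest-input (intersection over the smallest set involved).
#'
#' @param replicate_sets List of >= 2 character vectors of significant
#'   term ids.
#' @param reference Optional character vector of reference-significant
#'   term ids.
#' @return Object of class `overlap_summary`: list with `n_per_replicate`,
#'   `n_all_replicates`, `frac_per_replicate`, `frac_smallest`, and — when
#'   a reference is given — `n_all_with_reference`,
#'   `frac_smallest_with_reference`.
#' @export
overlap_summary <- function(replicate_sets, reference = NULL) {
  if (length(replicate_sets) < 2L) stop("need at least 2 replicate sets")
  replicate_sets <- lapply(replicate_sets, unique)
  inter <- Reduce(intersect, replicate_sets)
  sizes <- vapply(replicate_sets, length, 1L)
  frac_per <- ifelse(sizes > 0L, length(inter) / sizes, NA_real_)
  out <- list(n_per_replicate = sizes,
              n_all_replicates = length(inter),
              frac_per_replicate = frac_per,
              frac_smallest = if (min(sizes) > 0L)
                length(inter) / min(sizes) else NA_real_)
  if (!is.null(reference)) {
    reference <- unique(reference)
    inter_ref <- intersect(inter, reference)
    all_sizes <- c(sizes, length(reference))
    out$n_reference <- length(reference)
    out$n_all_with_reference <- length(inter_ref)
    out$frac_smallest_with_reference <- if (min(all_sizes) > 0L)
      length(inter_ref) / min(all_sizes) else NA_real_
  }
  structure(out, class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat("overlap_summary:", length(x$n_per_replicate), "replicates,",
      x$n_all_replicates, "terms common to all\n")
  cat("  per-replicate fractions:",
      paste(sprintf("%.2f", x$frac_per_replicate), collapse = " "), "\n")
  if (!is.null(x$n_all_with_reference))
    cat("  with reference:", x$n_all_with_reference,
        sprintf("(%.2f of smallest input)\n",
                x$frac_smallest_with_reference))
  invisible(x)
}
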
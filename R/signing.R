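#' Functional sign of a gene's change with respect to a term
#'
#' Genes annotated (through propagation) to a direct `negatively_regulates`
#' child of the term are functional repressors of that term: their
#' expression change has the opposite functional effect on the term, so
#' their sign is flipped. All other genes keep their expression direction.
#' A gene in both the term's own set and its repressor set is treated as a
#' repressor — the curated repressor role is the more specific claim.
#'
#' @param gene Gene id.
#' @param term Term id.
#' @param expression_direction `"up"` or `"down"`.
#' @param catalog A `gene_set_catalog`.
#' @return `"up_functional"` or `"down_functional"`.
#' @export
effective_sign <- function(gene, term, expression_direction, catalog) {
  expression_direction <- match.arg(expression_direction, c("up", "down"))
  reps <- catalog$repressor_sets[[term]]
  in_term <- gene %in% catalog$term_sets[[term]]
  in_rep <- !is.null(reps) && gene %in% reps
  if (!in_term && !in_rep)
    stop("gene ", gene, " is unrelated to term ", term)
  flipped <- if (in_rep) {
    if (expression_direction == "up") "down" else "up"
  } else {
    expression_direction
  }
  paste0(flipped, "_functional")
}

# genome-wide functionally-up / functionally-down DEG pools for one term:
# repressor genes of the term have their expression direction flipped
functional_pools <- function(term, up_degs, down_degs, catalog) {
  reps <- catalog$repressor_sets[[term]]
  if (is.null(reps)) reps <- character(0)
  list(up = c(setdiff(up_degs, reps), intersect(down_degs, reps)),
       down = c(setdiff(down_degs, reps), intersect(up_degs, reps)))
}

# a term's gene column for the directional tests: its own set plus its
# repressor genes
term_column <- function(term, catalog) {
  unique(c(catalog$term_sets[[term]], catalog$repressor_sets[[term]]))
}

#' Partition a term's DEGs by functional sign
#'
#' Splits the DEGs relevant to one term (members of its gene set or of its
#' repressor set, excluding genes with log2FC exactly 0) into the
#' "up-regulated and up-regulatory" side and the "down-regulated and
#' down-regulatory" side according to [effective_sign()].
#'
#' @param term Term id present in the catalog.
#' @param deg_calls data.frame from [call_degs()].
#' @param catalog A `gene_set_catalog`.
#' @return Object of class `signed_partition`: list with `term_id`,
#'   `up_upregulatory`, `down_downregulatory`.
#' @export
build_signed_partition <- function(term, deg_calls, catalog) {
  if (!term %in% names(catalog$term_sets) &&
      !term %in% names(catalog$repressor_sets))
    stop("term ", term, " not in catalog")
  up_degs <- deg_calls$gene_id[deg_calls$is_deg & deg_calls$direction == "up"]
  down_degs <- deg_calls$gene_id[deg_calls$is_deg &
                                 deg_calls$direction == "down"]
  pools <- functional_pools(term, up_degs, down_degs, catalog)
  col <- term_column(term, catalog)
  structure(list(term_id = term,
                 up_upregulatory = intersect(pools$up, col),
                 down_downregulatory = intersect(pools$down, col)),
            class = "signed_partition")
}

#' Assign the categorical functional direction of a term
#'
#' Four mutually exclusive cases from the two directional FET FDRs:
#' activated (up significant only), reduced activity (down significant
#' only), bidirectional (both), ambiguous (neither). Significance is
#' `fdr <= alpha`; "non-significant" is its strict complement.
#'
#' @param fdr_up,fdr_down FDRs of the up- and down-directional tests
#'   (vectorised).
#' @param alpha Significance threshold (default 0.05).
#' @return Character vector in `{"activated", "reduced_activity",
#'   "bidirectional", "ambiguous"}`.
#' @export
assign_direction <- function(fdr_up, fdr_down, alpha = 0.05) {
  up <- fdr_up <= alpha
  down <- fdr_down <= alpha
  ifelse(up & !down, "activated",
         ifelse(!up & down, "reduced_activity",
                ifelse(up & down, "bidirectional", "ambiguous")))
}

#' Directional enrichment tests and functional signing of all terms
#'
#' For every term in the base enrichment result, two auxiliary one-sided
#' FETs are run: one testing overrepresentation of the term's
#' "up-regulated and up-regulatory" genes among the genome-wide
#' functionally-up DEG pool (expression-up non-repressors plus
#' expression-down repressors of that term), and the mirror-image test on
#' the functionally-down side. Each uses the term's gene set extended by
#' its repressor genes as the term column and the same universe as the
#' base test. FDR is computed per direction across all candidate terms
#' with Benjamini-Hochberg and the four-case rule of [assign_direction()]
#' yields the categorical direction. Base enrichment statistics (p, OR,
#' FDR from the full DEG set) are carried through unchanged.
#'
#' @param enrichment data.frame from [run_enrichment()].
#' @param deg_calls data.frame from [call_degs()].
#' @param catalog A `gene_set_catalog`.
#' @param alpha FDR threshold for the directional tests and the default
#'   reporting filter (default 0.05).
#' @param all_terms If `FALSE` (default) only terms significant in the
#'   base analysis are returned; if `TRUE`, every tested term.
#' @return data.frame with columns `term_id`, `term_name`, `odds_ratio`,
#'   `p_value`, `fdr`, `significant`, `n_up_upregulatory`,
#'   `n_down_downregulatory`, `p_up`, `p_down`, `fdr_up`, `fdr_down`,
#'   `direction`.
#' @export
sign_all <- function(enrichment, deg_calls, catalog, alpha = 0.05,
                     all_terms = FALSE) {
  up_degs <- deg_calls$gene_id[deg_calls$is_deg & deg_calls$direction == "up"]
  down_degs <- deg_calls$gene_id[deg_calls$is_deg &
                                 deg_calls$direction == "down"]
  up_degs <- intersect(up_degs, catalog$universe)
  down_degs <- intersect(down_degs, catalog$universe)

  terms <- enrichment$term_id
  p_up <- numeric(length(terms))
  p_down <- numeric(length(terms))
  n_up <- integer(length(terms))
  n_down <- integer(length(terms))
  for (i in seq_along(terms)) {
    t <- terms[i]
    pools <- functional_pools(t, up_degs, down_degs, catalog)
    col <- term_column(t, catalog)
    tab_up <- build_table(pools$up, col, catalog$universe)
    tab_down <- build_table(pools$down, col, catalog$universe)
    p_up[i] <- fisher_exact(tab_up)$p_value
    p_down[i] <- fisher_exact(tab_down)$p_value
    n_up[i] <- tab_up$a
    n_down[i] <- tab_down$a
  }
  fdr_up <- adjust_pvalues(p_up, "BH")
  fdr_down <- adjust_pvalues(p_down, "BH")

  out <- data.frame(term_id = terms,
                    term_name = enrichment$term_name,
                    odds_ratio = enrichment$odds_ratio,
                    p_value = enrichment$p_value,
                    fdr = enrichment$fdr,
                    significant = enrichment$significant,
                    n_up_upregulatory = n_up,
                    n_down_downregulatory = n_down,
                    p_up = p_up, p_down = p_down,
                    fdr_up = fdr_up, fdr_down = fdr_down,
                    direction = assign_direction(fdr_up, fdr_down, alpha),
                    stringsAsFactors = FALSE)
  if (!all_terms) out <- out[out$significant, , drop = FALSE]
  rownames(out) <- NULL
  out
}
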
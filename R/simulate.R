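#' Configuration for a synthetic single-subject experiment
#'
#' Bundles and validates all generator parameters. Defaults describe a
#' bulk transcriptome of 15,000 genes annotated to a 300-term ontology in
#' which 20 terms carry an implanted, direction-known perturbation with a
#' mean effect of 2 log2FC units against 0.3 log2FC units of biological
#' and technical noise, plus 2% background inter-individual alteration.
#'
#' @param n_genes Number of genes (default 15000).
#' @param n_terms Total ontology terms including the root and
#'   `negatively_regulates` children (default 300).
#' @param term_size_range Inclusive bounds for catalog term sizes
#'   (default `c(15, 500)`); direct annotation sizes are drawn between the
#'   lower bound and `min(100, upper)`.
#' @param frac_negreg_children Fraction of core terms given a
#'   `negatively_regulates` child (default 0.2).
#' @param n_implanted Number of perturbed terms (default 20).
#' @param implant_directions Directions recycled over the implanted terms
#'   (default activated / reduced / bidirectional).
#' @param effect_size_mean,effect_size_sd Mean and SD of the absolute
#'   log2FC effect of altered genes (defaults 2 and 0.4).
#' @param noise_sd SD of the log2FC noise on every gene (default 0.3).
#' @param background_altered_frac Fraction of genes altered outside the
#'   implanted terms (default 0.02).
#' @param n_replicates Paired replicates sharing the same altered-gene
#'   assignment (default 3).
#' @param seed Integer seed; all generator randomness derives from it.
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 15000L, n_terms = 300L,
                       term_size_range = c(15L, 500L),
                       frac_negreg_children = 0.2,
                       n_implanted = 20L,
                       implant_directions = c("activated", "reduced",
                                              "bidirectional"),
                       effect_size_mean = 2, effect_size_sd = 0.4,
                       noise_sd = 0.3, background_altered_frac = 0.02,
                       n_replicates = 3L, seed = 1L) {
  stopifnot(n_terms >= 2L, n_genes >= term_size_range[2],
            term_size_range[1] <= term_size_range[2],
            term_size_range[1] >= 1L,
            frac_negreg_children >= 0, frac_negreg_children <= 1,
            background_altered_frac >= 0, background_altered_frac <= 1,
            effect_size_sd > 0, noise_sd > 0,
            n_implanted >= 0L, n_replicates >= 1L)
  if (n_implanted > 0L)
    implant_directions <- rep_len(implant_directions, n_implanted)
  ok <- implant_directions %in% c("activated", "reduced", "bidirectional")
  if (!all(ok)) stop("unknown implant direction(s): ",
                     paste(unique(implant_directions[!ok]), collapse = ", "))
  structure(list(n_genes = as.integer(n_genes),
                 n_terms = as.integer(n_terms),
                 term_size_range = as.integer(term_size_range),
                 frac_negreg_children = frac_negreg_children,
                 n_implanted = as.integer(n_implanted),
                 implant_directions = implant_directions,
                 effect_size_mean = effect_size_mean,
                 effect_size_sd = effect_size_sd,
                 noise_sd = noise_sd,
                 background_altered_frac = background_altered_frac,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "sim_config")
}

sim_gene_ids <- function(n) sprintf("G%05d", seq_len(n))
sim_term_ids <- function(n) sprintf("GO:%07d", seq_len(n))

#' Generate a toy ontology with annotations and implant assignments
#'
#' Builds a random DAG: a root term, "core" process terms attached to the
#' root by `is_a` (a quarter of them also nested under an earlier core
#' term), and `negatively_regulates` child terms for the configured
#' fraction of core terms. Direct gene annotations are drawn so that leaf
#' terms land inside the catalog size range after propagation. Implanted
#' terms are chosen among core leaves and each receives a
#' `negatively_regulates` child, so every implant exercises the repressor
#' flip logic. The root accumulates all annotations by propagation and is
#' removed by the catalog's upper size bound.
#'
#' @param config A [sim_config()].
#' @return Object of class `sim_ontology`: list with `graph`
#'   (`ontology_graph`), `annotations` (GAF-shaped data.frame), `implants`
#'   (data.frame `term_id`, `direction`, `negreg_child`), `direct_sets`
#'   (named list of direct gene annotations), `config`.
#' @export
simulate_ontology <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  genes <- sim_gene_ids(config$n_genes)

  frac <- config$frac_negreg_children
  n_core <- max(1L, as.integer(round((config$n_terms - 1L) / (1 + frac))))
  n_neg <- config$n_terms - 1L - n_core
  if (config$n_implanted > 0L && n_neg < config$n_implanted)
    stop("not enough negatively_regulates children for the implants; ",
         "raise frac_negreg_children or n_terms")
  ids <- sim_term_ids(config$n_terms)
  root <- ids[1]
  core <- ids[1L + seq_len(n_core)]
  negs <- if (n_neg > 0L) ids[1L + n_core + seq_len(n_neg)] else character(0)

  child <- core
  parent <- rep(root, n_core)
  relation <- rep("is_a", n_core)
  # nest a quarter of later core terms under an earlier core term
  nested_parents <- character(0)
  if (n_core > 4L) {
    candidates <- core[-seq_len(4L)]
    nested <- candidates[stats::runif(length(candidates)) < 0.25]
    for (c_ in nested) {
      p <- sample(core[seq_len(match(c_, core) - 1L)], 1L)
      child <- c(child, c_); parent <- c(parent, p)
      relation <- c(relation, "is_a")
      nested_parents <- c(nested_parents, p)
    }
    nested_children <- nested
  } else {
    nested_children <- character(0)
  }
  # implant candidates: terms subsumed only by the root, so an implant's
  # signal reaches no other catalog term through propagation
  leaves <- setdiff(core, c(nested_parents, nested_children))

  # implanted terms: core leaves, each guaranteed a negreg child below
  implants <- NULL
  if (config$n_implanted > 0L) {
    if (length(leaves) < config$n_implanted)
      stop("not enough leaf terms to implant; raise n_terms")
    implant_terms <- sort(sample(leaves, config$n_implanted))
    implants <- data.frame(term_id = implant_terms,
                           direction = config$implant_directions,
                           stringsAsFactors = FALSE)
  }

  neg_parents <- character(0)
  if (n_neg > 0L) {
    neg_parents <- if (is.null(implants)) character(0) else implants$term_id
    extra <- setdiff(core, neg_parents)
    n_extra <- n_neg - length(neg_parents)
    if (n_extra > 0L)
      neg_parents <- c(neg_parents, sample(extra, n_extra))
    neg_parents <- neg_parents[seq_len(n_neg)]
    child <- c(child, negs, negs)
    parent <- c(parent, rep(root, n_neg), neg_parents)
    relation <- c(relation, rep("is_a", n_neg),
                  rep("negatively_regulates", n_neg))
  }
  if (!is.null(implants)) {
    implants$negreg_child <- negs[match(implants$term_id, neg_parents)]
  }

  term_names <- c("biological_process",
                  sprintf("synthetic process %d", seq_len(n_core)),
                  if (n_neg > 0L)
                    sprintf("negative regulation of synthetic process %d",
                            match(neg_parents, core)))
  names(term_names) <- c(root, core, negs)

  graph <- structure(list(terms = ids, term_names = term_names,
                          edges = data.frame(child = child, parent = parent,
                                             relation = relation,
                                             stringsAsFactors = FALSE)),
                     class = "ontology_graph")

  # direct gene annotations
  lo <- config$term_size_range[1]
  hi <- min(100L, config$term_size_range[2])
  direct_sets <- vector("list", length(ids))
  names(direct_sets) <- ids
  direct_sets[[root]] <- character(0)
  for (t in core) {
    sz <- sample(lo:hi, 1L)
    direct_sets[[t]] <- sample(genes, sz)
  }
  for (i in seq_along(negs)) {
    # repressor children are small, specialised subterms: they stay below
    # the catalog size floor and clear of their parent's own members
    pool <- setdiff(genes, direct_sets[[neg_parents[i]]])
    sz <- sample(seq(max(2L, lo %/% 2L), max(2L, lo - 1L)), 1L)
    direct_sets[[negs[i]]] <- sample(pool, sz)
  }

  ann_terms <- rep(ids, vapply(direct_sets, length, 1L))
  annotations <- data.frame(
    gene_id = unlist(direct_sets, use.names = FALSE),
    term_id = ann_terms,
    qualifier = "",
    stringsAsFactors = FALSE)

  structure(list(graph = graph, annotations = annotations,
                 implants = implants, direct_sets = direct_sets,
                 config = config),
            class = "sim_ontology")
}

#' Generate paired expression replicates with implanted perturbations
#'
#' Assigns every gene a true effect: members of an implanted "activated"
#' term get expression up, members of a "reduced" term expression down,
#' "bidirectional" members split 50/50 — and genes annotated to the
#' implant's `negatively_regulates` child get the opposite expression
#' direction, mirroring repressor biology. A configured background
#' fraction of the remaining genes is altered with random sign. Absolute
#' effect sizes are `|N(effect_size_mean, effect_size_sd^2)|`, shared by
#' all replicates; each replicate adds independent
#' `N(0, noise_sd^2)` log2FC noise on every gene. Control expression is
#' `N(8, 2^2)` per gene (log2 scale) and case = control + log2FC.
#'
#' @param sim A `sim_ontology`.
#' @return Object of class `sim_experiment`: list with `profiles` (list of
#'   `paired_profile`), `gene_truth` (data.frame `gene_id`, `altered`,
#'   `expression_sign`, `implant_term`), `term_truth` (data.frame
#'   `term_id`, `direction`), `config`.
#' @export
simulate_expression <- function(sim) {
  stopifnot(inherits(sim, "sim_ontology"))
  config <- sim$config
  set.seed(config$seed + 1000L)
  genes <- sim_gene_ids(config$n_genes)
  n <- config$n_genes

  sign_vec <- rep(0, n)
  names(sign_vec) <- genes
  implant_term <- rep(NA_character_, n)
  names(implant_term) <- genes

  assign_sign <- function(gs, s, term) {
    gs <- gs[sign_vec[gs] == 0]
    sign_vec[gs] <<- s
    implant_term[gs] <<- term
  }
  if (!is.null(sim$implants)) {
    for (i in seq_len(nrow(sim$implants))) {
      t <- sim$implants$term_id[i]
      dir <- sim$implants$direction[i]
      members <- sim$direct_sets[[t]]
      reps <- sim$direct_sets[[sim$implants$negreg_child[i]]]
      if (dir == "bidirectional") {
        ms <- sample(c(-1, 1), length(members), replace = TRUE)
        rs <- sample(c(-1, 1), length(reps), replace = TRUE)
        for (j in seq_along(members)) assign_sign(members[j], ms[j], t)
        for (j in seq_along(reps)) assign_sign(reps[j], rs[j], t)
      } else {
        s <- if (dir == "activated") 1 else -1
        assign_sign(members, s, t)
        assign_sign(reps, -s, t)   # repressor: expression opposes function
      }
    }
  }
  n_bg <- round(config$background_altered_frac * n)
  if (n_bg > 0L) {
    free <- genes[sign_vec == 0]
    bg <- sample(free, min(n_bg, length(free)))
    sign_vec[bg] <- sample(c(-1, 1), length(bg), replace = TRUE)
  }

  altered <- sign_vec != 0
  effect <- rep(0, n)
  effect[altered] <- sign_vec[altered] *
    abs(stats::rnorm(sum(altered), config$effect_size_mean,
                     config$effect_size_sd))

  profiles <- vector("list", config$n_replicates)
  for (r in seq_len(config$n_replicates)) {
    control <- stats::rnorm(n, 8, 2)
    lfc <- effect + stats::rnorm(n, 0, config$noise_sd)
    case <- control + lfc
    names(case) <- names(control) <- genes
    profiles[[r]] <- make_paired_profile(case, control,
                                         input_scale = "log2")
  }

  structure(list(
    profiles = profiles,
    gene_truth = data.frame(gene_id = genes, altered = altered,
                            expression_sign = unname(sign_vec),
                            implant_term = unname(implant_term),
                            stringsAsFactors = FALSE),
    term_truth = if (is.null(sim$implants))
      data.frame(term_id = character(0), direction = character(0))
    else sim$implants[c("term_id", "direction")],
    config = config), class = "sim_experiment")
}

#' Generate a complete synthetic experiment
#'
#' Convenience wrapper: [simulate_ontology()] followed by
#' [simulate_expression()].
#'
#' @param config A [sim_config()].
#' @return List with `ontology` (`sim_ontology`) and `experiment`
#'   (`sim_experiment`).
#' @export
simulate_experiment <- function(config) {
  ont <- simulate_ontology(config)
  list(ontology = ont, experiment = simulate_expression(ont))
}

#' Write an ontology graph as an OBO file
#'
#' Deterministic output: terms in id order, one stanza each, with `is_a:`
#' and `relationship:` lines sorted. Round-trips losslessly through
#' [load_obo()].
#'
#' @param graph An `ontology_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(graph, path) {
  e <- graph$edges
  lines <- c("format-version: 1.2", "ontology: synthetic-go-bp")
  for (t in graph$terms) {
    nm <- graph$term_names[t]
    if (is.na(nm)) nm <- t
    lines <- c(lines, "", "[Term]", paste0("id: ", t),
               paste0("name: ", nm), "namespace: biological_process")
    isa <- sort(e$parent[e$child == t & e$relation == "is_a"])
    for (p in isa) lines <- c(lines, paste0("is_a: ", p))
    rel <- e[e$child == t & e$relation != "is_a", , drop = FALSE]
    if (nrow(rel) > 0L) {
      rel <- rel[order(rel$relation, rel$parent), , drop = FALSE]
      lines <- c(lines,
                 paste0("relationship: ", rel$relation, " ", rel$parent))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write annotations as a GAF 2.2 file
#'
#' Deterministic output, one row per annotation, aspect `P`. Round-trips
#' through [load_gaf()].
#'
#' @param annotations data.frame with columns `gene_id`, `term_id` and
#'   optionally `qualifier`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gaf <- function(annotations, path) {
  qual <- if ("qualifier" %in% names(annotations))
    annotations$qualifier else ""
  rows <- paste("SIM", annotations$gene_id, annotations$gene_id, qual,
                annotations$term_id, "SIM_REF:0000001", "IEA", "", "P",
                annotations$gene_id, "", "protein", "taxon:10090",
                "20180101", "SIM", "", "",
                sep = "\t")
  writeLines(c("!gaf-version: 2.2", rows), path)
  invisible(path)
}

#' Write a paired profile as a three-column TSV
#'
#' Columns `gene_id`, `case`, `control` (log2 scale).
#'
#' @param profile A `paired_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(profile, path) {
  df <- data.frame(gene_id = profile$gene_ids,
                   case = profile$expr_case,
                   control = profile$expr_control)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a paired profile from a three-column TSV
#'
#' Expects columns `gene_id`, `case`, `control`.
#'
#' @param path Input path.
#' @param input_scale Passed to [make_paired_profile()].
#' @param pseudocount Passed to [make_paired_profile()].
#' @return A `paired_profile`.
#' @export
read_expression_tsv <- function(path, input_scale = "log2",
                                pseudocount = 1) {
  if (!file.exists(path)) stop("cannot read expression TSV: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "case", "control")
  if (!all(need %in% names(df)))
    stop("expression TSV needs columns: ", paste(need, collapse = ", "))
  case <- stats::setNames(df$case, df$gene_id)
  control <- stats::setNames(df$control, df$gene_id)
  make_paired_profile(case, control, input_scale = input_scale,
                      pseudocount = pseudocount)
}
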
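#' @keywords internal
GO_RELATIONS <- c("is_a", "part_of", "regulates",
                  "positively_regulates", "negatively_regulates")

#' Parse an OBO ontology file
#'
#' Reads an OBO 1.2/1.4 file and returns the term graph. Only `[Term]`
#' stanzas are considered; terms flagged `is_obsolete: true` are skipped
#' (and counted in a message). `is_a:` and `relationship:` lines are mapped
#' to the five Gene Ontology relation kinds (`is_a`, `part_of`, `regulates`,
#' `positively_regulates`, `negatively_regulates`); lines with any other
#' relation are dropped with a warning.
#'
#' @param path Path to an OBO file.
#' @return An object of class `ontology_graph`: a list with `terms`
#'   (character vector of term ids), `term_names` (named character vector),
#'   and `edges` (data.frame with columns `child`, `parent`, `relation`).
#' @export
load_obo <- function(path) {
  if (!file.exists(path)) stop("cannot read OBO file: ", path)
  lines <- readLines(path, warn = FALSE)

  # split into stanzas at headers like [Term], [Typedef]
  hdr <- grep("^\\[", lines)
  if (length(hdr) == 0L) stop("no stanzas found in OBO file: ", path)

  terms <- character(0)
  term_names <- character(0)
  child <- character(0); parent <- character(0); relation <- character(0)
  n_obsolete <- 0L
  n_unknown_rel <- 0L

  starts <- hdr
  ends <- c(hdr[-1L] - 1L, length(lines))
  for (i in seq_along(starts)) {
    if (lines[starts[i]] != "[Term]") next
    block <- lines[seq(starts[i], ends[i])]
    id <- sub("^id: *", "", grep("^id: ", block, value = TRUE)[1])
    if (is.na(id)) next
    if (any(grepl("^is_obsolete: *true", block))) {
      n_obsolete <- n_obsolete + 1L
      next
    }
    nm <- sub("^name: *", "", grep("^name: ", block, value = TRUE)[1])
    terms <- c(terms, id)
    term_names[id] <- if (is.na(nm)) id else nm

    for (ln in grep("^is_a: ", block, value = TRUE)) {
      tgt <- sub("^is_a: *([^ !]+).*$", "\\1", ln)
      child <- c(child, id); parent <- c(parent, tgt)
      relation <- c(relation, "is_a")
    }
    for (ln in grep("^relationship: ", block, value = TRUE)) {
      body <- sub("^relationship: *", "", ln)
      parts <- strsplit(sub(" *!.*$", "", body), "[ \t]+")[[1]]
      if (length(parts) < 2L) next
      rel <- parts[1]; tgt <- parts[2]
      if (!rel %in% GO_RELATIONS) {
        n_unknown_rel <- n_unknown_rel + 1L
        next
      }
      child <- c(child, id); parent <- c(parent, tgt)
      relation <- c(relation, rel)
    }
  }

  if (n_obsolete > 0L)
    message("load_obo: skipped ", n_obsolete, " obsolete term(s)")
  if (n_unknown_rel > 0L)
    warning("load_obo: dropped ", n_unknown_rel,
            " edge(s) with unrecognised relation")

  edges <- data.frame(child = child, parent = parent, relation = relation,
                      stringsAsFactors = FALSE)
  # drop edges pointing outside the parsed term set (e.g. cross-ontology)
  keep <- edges$child %in% terms & edges$parent %in% terms
  edges <- edges[keep, , drop = FALSE]

  g <- structure(list(terms = terms, term_names = term_names, edges = edges),
                 class = "ontology_graph")
  check_acyclic(g)
  g
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat("ontology_graph:", length(x$terms), "terms,", nrow(x$edges), "edges\n")
  tab <- table(x$edges$relation)
  for (r in names(tab)) cat(" ", r, ":", tab[[r]], "\n")
  invisible(x)
}

# parent adjacency restricted to subsumption (is_a/part_of) edges
subsumption_parents <- function(graph) {
  e <- graph$edges[graph$edges$relation %in% c("is_a", "part_of"), ,
                   drop = FALSE]
  split(e$parent, factor(e$child, levels = graph$terms))
}

# error if the is_a/part_of restriction of the graph has a cycle
check_acyclic <- function(graph) {
  parents <- subsumption_parents(graph)
  state <- new.env(parent = emptyenv())  # 1 = in stack, 2 = done
  visit <- function(t) {
    s <- state[[t]]
    if (!is.null(s)) {
      if (s == 1L) stop("cycle detected in is_a/part_of graph at ", t)
      return(invisible())
    }
    state[[t]] <- 1L
    for (p in parents[[t]]) visit(p)
    state[[t]] <- 2L
  }
  for (t in graph$terms) visit(t)
  invisible(TRUE)
}

# memoised ancestor closure over is_a/part_of edges (true-path rule)
ancestor_closure <- function(graph) {
  parents <- subsumption_parents(graph)
  memo <- new.env(parent = emptyenv())
  anc <- function(t) {
    got <- memo[[t]]
    if (!is.null(got)) return(got)
    ps <- parents[[t]]
    res <- if (length(ps) == 0L) character(0) else
      unique(c(ps, unlist(lapply(ps, anc), use.names = FALSE)))
    memo[[t]] <- res
    res
  }
  out <- lapply(graph$terms, anc)
  names(out) <- graph$terms
  out
}

#' Parse a GAF gene-annotation file
#'
#' Reads a GAF 2.x tab-separated annotation file. Comment lines starting
#' with `!` are ignored; rows with fewer than 15 columns are skipped and
#' counted in a warning. Only Biological Process annotations (aspect `P`)
#' are kept, rows whose qualifier contains `NOT` are dropped, and
#' (gene, term) pairs are deduplicated across evidence codes.
#'
#' @param path Path to a GAF file.
#' @return data.frame with columns `gene_id`, `term_id`, `qualifier`.
#' @export
load_gaf <- function(path) {
  if (!file.exists(path)) stop("cannot read GAF file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- vapply(fields, length, 1L) >= 15L
  if (any(!ok))
    warning("load_gaf: skipped ", sum(!ok), " malformed row(s)")
  fields <- fields[ok]
  if (length(fields) == 0L)
    return(data.frame(gene_id = character(0), term_id = character(0),
                      qualifier = character(0), stringsAsFactors = FALSE))
  gene <- vapply(fields, `[[`, "", 2L)
  qualifier <- vapply(fields, `[[`, "", 4L)
  term <- vapply(fields, `[[`, "", 5L)
  aspect <- vapply(fields, `[[`, "", 9L)

  keep <- aspect == "P" & !grepl("NOT", qualifier, fixed = TRUE)
  ann <- data.frame(gene_id = gene[keep], term_id = term[keep],
                    qualifier = qualifier[keep], stringsAsFactors = FALSE)
  ann[!duplicated(ann[c("gene_id", "term_id")]), , drop = FALSE]
}

#' Propagate annotations up the ontology (true-path rule)
#'
#' Each gene annotated to a term is made a member of every ancestor
#' reachable through `is_a` and `part_of` edges. Regulates-family edges do
#' not propagate membership. Annotations to terms absent from the graph are
#' skipped with a warning.
#'
#' @param graph An `ontology_graph`.
#' @param annotations data.frame as returned by [load_gaf()].
#' @return Named list mapping term id to a character vector of gene ids.
#' @export
propagate_annotations <- function(graph, annotations) {
  unknown <- !(annotations$term_id %in% graph$terms)
  if (any(unknown)) {
    warning("propagate_annotations: skipped ", sum(unknown),
            " annotation(s) to unknown terms")
    annotations <- annotations[!unknown, , drop = FALSE]
  }
  anc <- ancestor_closure(graph)
  direct <- split(annotations$gene_id,
                  factor(annotations$term_id, levels = graph$terms))
  acc <- new.env(parent = emptyenv())
  for (t in graph$terms) {
    g <- direct[[t]]
    if (length(g) == 0L) next
    for (tt in c(t, anc[[t]])) acc[[tt]] <- c(acc[[tt]], g)
  }
  out <- lapply(graph$terms, function(t) {
    g <- acc[[t]]
    if (is.null(g)) character(0) else unique(g)
  })
  names(out) <- graph$terms
  out[vapply(out, length, 1L) > 0L]
}

#' Build a size-filtered gene-set catalog with repressor partitions
#'
#' Propagates annotations, restricts every term's gene set to the measured
#' universe, and keeps terms whose universe-restricted size lies within
#' `[min_size, max_size]`. For every term (filtered or not) the repressor
#' set is the union of the propagated gene sets of its direct children
#' connected by a `negatively_regulates` edge, restricted to the universe.
#' Sizes are computed after the universe restriction so that downstream
#' contingency-table margins are consistent with the enrichment universe.
#'
#' @param graph An `ontology_graph`.
#' @param annotations data.frame as returned by [load_gaf()].
#' @param universe Character vector of measured gene ids.
#' @param min_size,max_size Inclusive bounds on universe-restricted term
#'   size (defaults 15 and 500).
#' @return Object of class `gene_set_catalog`: list with `term_sets`,
#'   `repressor_sets`, `universe`, `size_bounds`, `term_names`.
#' @export
build_catalog <- function(graph, annotations, universe,
                          min_size = 15L, max_size = 500L) {
  if (length(universe) == 0L) stop("universe must be nonempty")
  if (min_size > max_size) stop("min_size must be <= max_size")
  universe <- unique(universe)
  prop <- propagate_annotations(graph, annotations)
  # the enrichment universe is measured AND annotated genes, so every
  # contingency-table margin is consistent
  annotated <- unique(unlist(prop, use.names = FALSE))
  universe <- intersect(universe, annotated)
  if (length(universe) == 0L)
    stop("no measured gene is annotated; universe empty")
  prop <- lapply(prop, intersect, universe)

  sizes <- vapply(prop, length, 1L)
  term_sets <- prop[sizes >= min_size & sizes <= max_size]
  if (length(term_sets) == 0L)
    stop("no terms remain after size filtering to [",
         min_size, ", ", max_size, "]")

  neg <- graph$edges[graph$edges$relation == "negatively_regulates", ,
                     drop = FALSE]
  repressor_sets <- lapply(graph$terms, function(t) {
    kids <- neg$child[neg$parent == t]
    if (length(kids) == 0L) return(character(0))
    unique(unlist(prop[intersect(kids, names(prop))], use.names = FALSE))
  })
  names(repressor_sets) <- graph$terms

  structure(list(term_sets = term_sets,
                 repressor_sets = repressor_sets,
                 universe = universe,
                 size_bounds = c(min_size, max_size),
                 term_names = graph$term_names),
            class = "gene_set_catalog")
}

#' @export
print.gene_set_catalog <- function(x, ...) {
  cat("gene_set_catalog:", length(x$term_sets), "terms (size",
      x$size_bounds[1], "-", x$size_bounds[2], "),",
      length(x$universe), "universe genes\n")
  nrep <- sum(vapply(x$repressor_sets[names(x$term_sets)],
                     length, 1L) > 0L)
  cat("  terms with repressor genes:", nrep, "\n")
  invisible(x)
}

#' Export a catalog as a GMT gene-set file
#'
#' One tab-separated line per term: term id, term name, then the gene ids.
#'
#' @param catalog A `gene_set_catalog`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(catalog, path) {
  lines <- vapply(names(catalog$term_sets), function(t) {
    nm <- catalog$term_names[t]
    if (is.na(nm)) nm <- t
    paste(c(t, nm, sort(catalog$term_sets[[t]])), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Export repressor gene assignments as a two-column TSV
#'
#' Writes one row per (term, repressor gene) pair, covering every term that
#' has a nonempty repressor set.
#'
#' @param catalog A `gene_set_catalog`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_repressors_tsv <- function(catalog, path) {
  reps <- catalog$repressor_sets
  reps <- reps[vapply(reps, length, 1L) > 0L]
  df <- data.frame(
    term_id = rep(names(reps), vapply(reps, length, 1L)),
    repressor_gene = unlist(lapply(reps, sort), use.names = FALSE),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
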
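# Shared fixture builders. Everything is generated in code; no files are
# shipped with the tests.

write_tmp_lines <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# a 5-term ontology: root, two processes (P1 with repressor child N1),
# one obsolete term
toy_obo_lines <- function() {
  c("format-version: 1.2",
    "",
    "[Term]",
    "id: GO:0000001",
    "name: biological_process",
    "",
    "[Term]",
    "id: GO:0000002",
    "name: process one",
    "is_a: GO:0000001 ! biological_process",
    "",
    "[Term]",
    "id: GO:0000003",
    "name: process two",
    "is_a: GO:0000001",
    "relationship: part_of GO:0000002 ! process one",
    "",
    "[Term]",
    "id: GO:0000004",
    "name: negative regulation of process one",
    "is_a: GO:0000001",
    "relationship: negatively_regulates GO:0000002",
    "",
    "[Term]",
    "id: GO:0000005",
    "name: gone process",
    "is_obsolete: true")
}

gaf_row <- function(gene, term, qualifier = "", aspect = "P") {
  paste("SIM", gene, gene, qualifier, term, "SIM_REF:1", "IEA", "",
        aspect, gene, "", "protein", "taxon:10090", "20180101", "SIM",
        sep = "\t")
}

# random ontology_graph over is_a/part_of edges (each term points to
# earlier terms, hence acyclic), built directly without parsing
random_dag_graph <- function(n_terms, seed, extra_edge_prob = 0.3) {
  set.seed(seed)
  ids <- sprintf("GO:%07d", seq_len(n_terms))
  child <- character(0); parent <- character(0); relation <- character(0)
  for (i in 2:n_terms) {
    p <- sample(seq_len(i - 1L), 1L)
    child <- c(child, ids[i]); parent <- c(parent, ids[p])
    relation <- c(relation, sample(c("is_a", "part_of"), 1L))
    if (i > 2L && stats::runif(1) < extra_edge_prob) {
      p2 <- sample(seq_len(i - 1L), 1L)
      child <- c(child, ids[i]); parent <- c(parent, ids[p2])
      relation <- c(relation, "is_a")
    }
  }
  structure(list(terms = ids,
                 term_names = stats::setNames(ids, ids),
                 edges = data.frame(child = child, parent = parent,
                                    relation = relation,
                                    stringsAsFactors = FALSE)),
            class = "ontology_graph")
}

# independent reachability oracle: iterative transitive closure over
# is_a/part_of edges using plain matrix logic
brute_force_propagate <- function(graph, annotations) {
  ids <- graph$terms
  n <- length(ids)
  e <- graph$edges[graph$edges$relation %in% c("is_a", "part_of"), ]
  reach <- diag(n) > 0   # reach[i, j]: term j reachable (ancestor) from i
  adj <- matrix(FALSE, n, n)
  adj[cbind(match(e$child, ids), match(e$parent, ids))] <- TRUE
  repeat {
    nxt <- reach | (reach %*% adj > 0)
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  out <- lapply(seq_len(n), function(j) {
    below <- ids[reach[, j]]   # terms whose genes flow up into j
    sort(unique(annotations$gene_id[annotations$term_id %in% below]))
  })
  names(out) <- ids
  out[vapply(out, length, 1L) > 0L]
}

# hand-built catalog for signing tests: n_main terms of size `size` over a
# disjoint gene universe, each with a disjoint repressor set of size
# `rep_size`, plus `n_extra` unperturbed terms
constructed_catalog <- function(n_main = 9, size = 20, rep_size = 8,
                                n_extra = 6, n_filler = 300) {
  terms <- sprintf("T%02d", seq_len(n_main + n_extra))
  genes <- sprintf("g%04d", seq_len(n_main * (size + rep_size) +
                                    n_extra * size + n_filler))
  term_sets <- list(); repressor_sets <- list()
  k <- 0L
  for (i in seq_len(n_main)) {
    term_sets[[terms[i]]] <- genes[k + seq_len(size)]
    k <- k + size
    repressor_sets[[terms[i]]] <- genes[k + seq_len(rep_size)]
    k <- k + rep_size
  }
  for (i in n_main + seq_len(n_extra)) {
    term_sets[[terms[i]]] <- genes[k + seq_len(size)]
    k <- k + size
    repressor_sets[[terms[i]]] <- character(0)
  }
  structure(list(term_sets = term_sets, repressor_sets = repressor_sets,
                 universe = genes, size_bounds = c(15L, 500L),
                 term_names = stats::setNames(terms, terms)),
            class = "gene_set_catalog")
}

# deg_calls data.frame from explicit gene -> direction assignments
constructed_deg_calls <- function(universe, up = character(0),
                                  down = character(0)) {
  direction <- rep("zero", length(universe))
  lfc <- rep(0, length(universe))
  direction[universe %in% up] <- "up"
  lfc[universe %in% up] <- 1.5
  direction[universe %in% down] <- "down"
  lfc[universe %in% down] <- -1.5
  data.frame(gene_id = universe, log2fc = lfc,
             posterior_altered = as.numeric(direction != "zero"),
             is_deg = direction != "zero",
             direction = direction, stringsAsFactors = FALSE)
}

# noise-free signing scenario: 3 activated, 3 reduced, 2 bidirectional
# implants (members and repressor genes called as DEGs with the
# construction's expression directions), remaining terms untouched
constructed_signing_scenario <- function() {
  catalog <- constructed_catalog()
  ts <- catalog$term_sets; rs <- catalog$repressor_sets
  truth <- c(T01 = "activated", T02 = "activated", T03 = "activated",
             T04 = "reduced_activity", T05 = "reduced_activity",
             T06 = "reduced_activity",
             T07 = "bidirectional", T08 = "bidirectional")
  up <- character(0); down <- character(0)
  for (t in names(truth)) {
    m <- ts[[t]]; r <- rs[[t]]
    if (truth[[t]] == "activated") {
      up <- c(up, m); down <- c(down, r)       # repressors move opposite
    } else if (truth[[t]] == "reduced_activity") {
      down <- c(down, m); up <- c(up, r)
    } else {
      half <- length(m) %/% 2
      up <- c(up, m[seq_len(half)], r[seq_len(length(r) %/% 2)])
      down <- c(down, m[-seq_len(half)], r[-seq_len(length(r) %/% 2)])
    }
  }
  list(catalog = catalog, truth = truth,
       deg_calls = constructed_deg_calls(catalog$universe, up, down))
}

# small synthetic experiment reused by several test files
small_sim <- function(seed = 42, n_implanted = 6, ...) {
  cfg <- sim_config(n_genes = 3000, n_terms = 80,
                    n_implanted = n_implanted, seed = seed, ...)
  simulate_experiment(cfg)
}

catalog_of <- function(sim, profile = sim$experiment$profiles[[1]]) {
  build_catalog(sim$ontology$graph, sim$ontology$annotations,
                profile$gene_ids)
}
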
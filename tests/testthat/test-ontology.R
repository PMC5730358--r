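test_that("load_obo parses terms, relations, and skips obsolete stanzas", {
  f <- write_tmp_lines(toy_obo_lines(), ".obo")
  g <- suppressMessages(load_obo(f))

  expect_setequal(g$terms, sprintf("GO:%07d", 1:4))  # GO:0000005 obsolete
  expect_equal(unname(g$term_names["GO:0000002"]), "process one")

  neg <- g$edges[g$edges$relation == "negatively_regulates", ]
  expect_equal(nrow(neg), 1L)
  expect_equal(neg$child, "GO:0000004")
  expect_equal(neg$parent, "GO:0000002")
  expect_equal(sum(g$edges$relation == "part_of"), 1L)
})

test_that("load_obo drops unknown relations with a warning", {
  lines <- c(toy_obo_lines(),
             "", "[Term]", "id: GO:0000006", "name: odd",
             "relationship: occurs_in GO:0000001")
  f <- write_tmp_lines(lines, ".obo")
  expect_warning(g <- suppressMessages(load_obo(f)), "unrecognised relation")
  expect_false(any(g$edges$relation == "occurs_in"))
})

test_that("a cycle in the is_a graph is rejected", {
  lines <- c("format-version: 1.2", "",
             "[Term]", "id: GO:0000001", "name: a", "is_a: GO:0000002", "",
             "[Term]", "id: GO:0000002", "name: b", "is_a: GO:0000001")
  f <- write_tmp_lines(lines, ".obo")
  expect_error(load_obo(f), "cycle")
})

test_that("load_gaf keeps P-aspect rows, drops NOT and duplicates", {
  # 185 unique pairs + 5 duplicates of the first pairs + 10 NOT rows
  genes <- sprintf("g%03d", 1:185)
  rows <- vapply(seq_along(genes),
                 function(i) gaf_row(genes[i], sprintf("GO:%07d", i %% 9 + 1)),
                 "")
  dups <- vapply(1:5,
                 function(i) gaf_row(genes[i], sprintf("GO:%07d", i %% 9 + 1)),
                 "")
  nots <- vapply(1:10,
                 function(i) gaf_row(sprintf("x%03d", i), "GO:0000001",
                                     qualifier = "NOT|involved_in"),
                 "")
  f <- write_tmp_lines(c("!gaf-version: 2.2", rows, dups, nots), ".gaf")
  ann <- load_gaf(f)
  expect_equal(nrow(ann), 185L)
  expect_false(any(grepl("NOT", ann$qualifier)))
})

test_that("load_gaf drops non-P aspects and warns on malformed rows", {
  rows <- c(gaf_row("g1", "GO:0000001"),
            gaf_row("g2", "GO:0000001", aspect = "F"),
            "SIM\tg3\tbroken")
  f <- write_tmp_lines(c("!gaf-version: 2.2", rows), ".gaf")
  expect_warning(ann <- load_gaf(f), "malformed")
  expect_equal(ann$gene_id, "g1")
})

test_that("annotations propagate along is_a/part_of but not regulates", {
  f <- write_tmp_lines(toy_obo_lines(), ".obo")
  g <- suppressMessages(load_obo(f))
  ann <- data.frame(gene_id = c("gA", "gB"),
                    term_id = c("GO:0000003", "GO:0000004"),
                    qualifier = "", stringsAsFactors = FALSE)
  prop <- propagate_annotations(g, ann)

  # gA: GO:3 part_of GO:2 is_a GO:1 -> member of all three
  expect_true("gA" %in% prop[["GO:0000002"]])
  expect_true("gA" %in% prop[["GO:0000001"]])
  # gB: annotated to the repressor child; negatively_regulates must NOT
  # put it into GO:2
  expect_false("gB" %in% prop[["GO:0000002"]])
  expect_true("gB" %in% prop[["GO:0000001"]])  # via the child's own is_a
})

test_that("propagation equals brute-force transitive closure on random DAGs", {
  for (seed in c(1, 2, 3)) {
    g <- random_dag_graph(30, seed)
    set.seed(seed + 100)
    ann <- data.frame(gene_id = sprintf("g%03d", sample(100, 120, TRUE)),
                      term_id = sample(g$terms, 120, TRUE),
                      qualifier = "", stringsAsFactors = FALSE)
    ann <- ann[!duplicated(ann[1:2]), ]
    got <- propagate_annotations(g, ann)
    want <- brute_force_propagate(g, ann)
    expect_setequal(names(got), names(want))
    for (t in names(want)) expect_setequal(got[[t]], want[[t]])
  }
})

test_that("propagated membership is monotone along subsumption edges", {
  g <- random_dag_graph(100, 9)
  set.seed(909)
  ann <- data.frame(gene_id = sprintf("g%03d", sample(200, 400, TRUE)),
                    term_id = sample(g$terms, 400, TRUE),
                    qualifier = "", stringsAsFactors = FALSE)
  prop <- propagate_annotations(g, ann[!duplicated(ann[1:2]), ])
  e <- g$edges[g$edges$relation %in% c("is_a", "part_of"), ]
  for (i in seq_len(nrow(e))) {
    kid <- prop[[e$child[i]]]
    if (is.null(kid)) next
    expect_true(all(kid %in% prop[[e$parent[i]]]))
  }
})

test_that("catalog size filter is inclusive at both bounds", {
  # one flat graph, three terms with 14, 15 and 16 universe genes
  ids <- c("GO:0000001", "GO:0000002", "GO:0000003", "GO:0000004")
  g <- structure(list(terms = ids, term_names = stats::setNames(ids, ids),
                      edges = data.frame(child = character(0),
                                         parent = character(0),
                                         relation = character(0))),
                 class = "ontology_graph")
  mk <- function(term, n, off)
    data.frame(gene_id = sprintf("g%03d", off + seq_len(n)), term_id = term,
               qualifier = "", stringsAsFactors = FALSE)
  ann <- rbind(mk("GO:0000001", 14, 0), mk("GO:0000002", 15, 100),
               mk("GO:0000003", 16, 200), mk("GO:0000004", 30, 300))
  universe <- ann$gene_id
  cat15 <- build_catalog(g, ann, universe, min_size = 15, max_size = 16)
  expect_setequal(names(cat15$term_sets), c("GO:0000002", "GO:0000003"))
  sizes <- vapply(cat15$term_sets, length, 1L)
  expect_true(all(sizes >= 15 & sizes <= 16))
})

test_that("repressor sets are unions over direct children only", {
  # N1, N2 negatively_regulate P with overlapping gene sets (8 + 9,
  # overlap 2 -> union 15); a negreg grandchild must not contribute
  ids <- c("P", "N1", "N2", "C", "NG")
  edges <- data.frame(
    child = c("N1", "N2", "C", "NG"),
    parent = c("P", "P", "P", "C"),
    relation = c("negatively_regulates", "negatively_regulates",
                 "is_a", "negatively_regulates"),
    stringsAsFactors = FALSE)
  g <- structure(list(terms = ids, term_names = stats::setNames(ids, ids),
                      edges = edges), class = "ontology_graph")
  ann <- data.frame(
    gene_id = c(sprintf("a%02d", 1:8),            # N1
                sprintf("a%02d", 7:8), sprintf("b%02d", 1:7),  # N2 (8 overlap)
                sprintf("c%02d", 1:20),           # C
                sprintf("d%02d", 1:5),            # NG grandchild
                sprintf("p%02d", 1:20)),          # P direct
    term_id = c(rep("N1", 8), rep("N2", 9), rep("C", 20), rep("NG", 5),
                rep("P", 20)),
    qualifier = "", stringsAsFactors = FALSE)
  cat <- build_catalog(g, ann, unique(ann$gene_id), min_size = 5,
                       max_size = 500)
  expect_length(cat$repressor_sets[["P"]], 15L)
  expect_false(any(sprintf("d%02d", 1:5) %in% cat$repressor_sets[["P"]]))
  # direct-child-only: C's repressor set is NG's genes
  expect_setequal(cat$repressor_sets[["C"]], sprintf("d%02d", 1:5))
})

test_that("an empty catalog after filtering is a hard error", {
  ids <- c("GO:0000001")
  g <- structure(list(terms = ids, term_names = stats::setNames(ids, ids),
                      edges = data.frame(child = character(0),
                                         parent = character(0),
                                         relation = character(0))),
                 class = "ontology_graph")
  ann <- data.frame(gene_id = c("g1", "g2"), term_id = "GO:0000001",
                    qualifier = "", stringsAsFactors = FALSE)
  expect_error(build_catalog(g, ann, c("g1", "g2")), "no terms remain")
})

test_that("GMT and repressor TSV exports round-trip the catalog content", {
  sim <- small_sim()
  cat <- catalog_of(sim)
  gmt <- tempfile(fileext = ".gmt")
  write_gmt(cat, gmt)
  lines <- strsplit(readLines(gmt), "\t", fixed = TRUE)
  expect_length(lines, length(cat$term_sets))
  one <- lines[[1]]
  expect_setequal(one[-(1:2)], cat$term_sets[[one[1]]])

  tsv <- tempfile(fileext = ".tsv")
  write_repressors_tsv(cat, tsv)
  df <- read.delim(tsv, stringsAsFactors = FALSE)
  reps <- cat$repressor_sets[vapply(cat$repressor_sets, length, 1L) > 0]
  expect_equal(nrow(df), sum(vapply(reps, length, 1L)))
  t1 <- names(reps)[1]
  expect_setequal(df$repressor_gene[df$term_id == t1], reps[[t1]])
})
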
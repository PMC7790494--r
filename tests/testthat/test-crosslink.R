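test_that("alias references parse; plain aliases return NULL", {
  r <- parse_alias_reference("RNA-seq 040 in CCN201912131")
  expect_identical(r$target_taxonomy, "CCN201912131")
  expect_identical(r$labels, "RNA-seq 040")

  r2 <- parse_alias_reference(
    "RNA-seq 040, 046-047, 050-052, 068 in CCN201912131")
  expect_length(r2$labels, 7)
  # the typographic-dash dialect parses identically
  r3 <- parse_alias_reference(
    "RNA-seq 040, 046–047, 050–052, 068 in CCN201912131")
  expect_identical(r3, r2)

  expect_null(parse_alias_reference("Long-range projecting Sst"))
  expect_null(parse_alias_reference("Rosehip"))
  expect_error(parse_alias_reference("RNA-seq 040 in CCN2019"),
               "date digits")
})

test_that("the registry enforces unique taxonomy ids and accessions", {
  tax1 <- build_taxonomy(ccn_defaults("CCN202001010", prefix = "A"),
                         types = c("x", "y"))
  tax2 <- build_taxonomy(ccn_defaults("CCN202001011", prefix = "B"),
                         types = c("p", "q"))
  reg <- ccn_registry(list(tax1, tax2))
  expect_identical(length(reg$taxonomies), 2L)
  expect_error(registry_add(reg, tax1), "already registered")
  clone <- tax2
  clone$taxonomy_id <- "CCN202001012"
  expect_error(registry_add(reg, clone), "accession id")
})

test_that("the published registry manifest ingests with 18 distinct ids", {
  reg <- read_registry(system.file("extdata", "taxonomy_registry.csv",
                                   package = "ccntax"))
  ids <- names(reg$taxonomies)
  expect_identical(length(unique(ids)), 18L)
  expect_true("CCN201810310" %in% ids)
  expect_true(all(is_taxonomy_id(ids)))
})

test_that("manifest rows with files load their nomenclature tables", {
  dir <- withr::local_tempdir()
  tax <- build_taxonomy(ccn_defaults("CCN202001010", prefix = "A"),
                        types = c("x", "y"))
  write_nomenclature_table(tax, file.path(dir, "a.csv"))
  writeLines(c("taxonomy_id,description,citation,file",
               "CCN202001010,test taxonomy,,a.csv",
               "CCN209901010,stub only,,"),
             file.path(dir, "manifest.csv"))
  reg <- read_registry(file.path(dir, "manifest.csv"))
  expect_identical(n_cell_sets(reg$taxonomies$CCN202001010), 2L)
  expect_identical(n_cell_sets(reg$taxonomies$CCN209901010), 0L)
  expect_identical(reg$taxonomies$CCN209901010$description, "stub only")
})

test_that("shared aliases and parsed references link the interneuron records", {
  reg <- sst_chodl_registry()
  g <- build_link_graph(reg)
  expect_equal(igraph::vcount(g), 8)
  comp <- igraph::components(g)
  expect_equal(comp$no, 1)
  expect_equal(
    comp$csize[comp$membership[["CS201912131_40"]]], 8)
  # the record without an aligned alias is tied in only by its reference
  types <- igraph::E(g)$type
  ends_ref <- igraph::ends(g, igraph::E(g))[types == "reference", ,
                                            drop = FALSE]
  expect_true(any(apply(ends_ref, 1, function(e)
    setequal(e, c("CS202002272_12", "CS201912131_40")))))
})

test_that("taxonomies with no shared aliases give an edgeless graph", {
  tax1 <- build_taxonomy(ccn_defaults("CCN202001010", prefix = "A"),
                         types = c("x", "y"))
  tax2 <- build_taxonomy(ccn_defaults("CCN202001011", prefix = "B"),
                         types = c("p", "q"))
  g <- build_link_graph(ccn_registry(list(tax1, tax2)))
  expect_equal(igraph::ecount(g), 0)
  expect_equal(igraph::components(g)$no, 4)
})

test_that("identical aligned aliases within one taxonomy are not linked", {
  tax <- build_taxonomy(ccn_defaults("CCN202001010", prefix = "A"),
                        types = c("x", "y"))
  tax$cell_sets$cell_set_aligned_alias <- c("Pvalb 1", "Pvalb 1")
  g <- build_link_graph(ccn_registry(list(tax)))
  expect_equal(igraph::ecount(g), 0)
})

test_that("components match a brute-force transitive closure on random registries", {
  set.seed(21)
  alias_pool <- c("Pvalb 1", "Sst 2", "Vip 1", "Lamp5 3", "Microglia 1",
                  "L5 IT 1", "")
  for (rep in 1:10) {
    taxa <- lapply(1:4, function(i) {
      tax <- build_taxonomy(
        ccn_defaults(sprintf("CCN20200101%d", i - 1), prefix = "T"),
        types = paste("type", 1:sample(2:5, 1)))
      tax$cell_sets$cell_set_aligned_alias <-
        sample(alias_pool, n_cell_sets(tax), replace = TRUE)
      tax
    })
    reg <- ccn_registry(taxa)
    g <- build_link_graph(reg)

    all_sets <- do.call(rbind, lapply(unname(taxa), `[[`, "cell_sets"))
    nodes <- all_sets$cell_set_accession_id
    pairs <- which(
      outer(all_sets$cell_set_aligned_alias,
            all_sets$cell_set_aligned_alias, "==") &
      outer(all_sets$taxonomy_id, all_sets$taxonomy_id, "!=") &
      nzchar(all_sets$cell_set_aligned_alias),
      arr.ind = TRUE)
    edges <- cbind(nodes[pairs[, 1]], nodes[pairs[, 2]])
    oracle <- oracle_components(nodes, edges)
    got <- igraph::components(g)$membership[nodes]
    # same partition: equal components under relabelling
    expect_identical(
      unname(split(nodes, oracle)[order(vapply(split(nodes, oracle), `[`,
                                               "", 1))]),
      unname(split(nodes, got)[order(vapply(split(nodes, got), `[`,
                                            "", 1))]))
  }
})

test_that("restricted to alias edges, components equal alias equivalence classes", {
  reg <- sst_chodl_registry()
  g <- build_link_graph(reg)
  g_alias <- igraph::subgraph_from_edges(
    g, igraph::E(g)[igraph::E(g)$type == "alias"],
    delete.vertices = FALSE)
  comp <- igraph::components(g_alias)
  al <- igraph::V(g_alias)$aligned_alias
  shared <- nzchar(al) & al %in% al[duplicated(al)]
  expect_equal(comp$csize[comp$membership[shared]],
               rep(7, sum(shared)))
  expect_true(all(comp$csize[comp$membership[!shared]] == 1L))
})

test_that("references to a subset of a composite span resolve to leaves", {
  target <- build_taxonomy(ccn_defaults("CCN202001010", prefix = "RNA-seq"),
                           mtg_toy_tree())
  src <- build_taxonomy(ccn_defaults("CCN202001011", prefix = "DNAm"),
                        types = "methyl type")
  src$cell_sets$cell_set_additional_aliases <-
    "RNA-seq 001-002 in CCN202001010"
  g <- build_link_graph(ccn_registry(list(target, src)))
  nbrs <- igraph::neighbors(g, "CS202001011_1")$name
  # leaves 1 and 2, not the internal node spanning 1-2
  expect_setequal(nbrs, c("CS202001010_1", "CS202001010_2"))
})

test_that("co-cell edges link sets with identical member cells", {
  tax1 <- build_taxonomy(ccn_defaults("CCN202001010", prefix = "A"),
                         types = c("x", "y"))
  tax2 <- build_taxonomy(ccn_defaults("CCN202001011", prefix = "B"),
                         types = c("p", "q"))
  memberships <- list(
    CS202001010_1 = c("c1", "c2"), CS202001010_2 = c("c3"),
    CS202001011_1 = c("c2", "c1"), CS202001011_2 = c("c4"))
  g <- build_link_graph(ccn_registry(list(tax1, tax2)),
                        memberships = memberships)
  expect_equal(igraph::ecount(g), 1)
  expect_identical(igraph::E(g)$type, "co_cell")
  expect_setequal(igraph::ends(g, 1)[1, ],
                  c("CS202001010_1", "CS202001011_1"))
})

test_that("unresolvable references are skipped, not fatal", {
  tax <- build_taxonomy(ccn_defaults("CCN202001010", prefix = "A"),
                        types = "x")
  tax$cell_sets$cell_set_additional_aliases <-
    "RNA-seq 099 in CCN209912310"
  expect_no_error(g <- build_link_graph(ccn_registry(list(tax))))
  expect_equal(igraph::ecount(g), 0)
})

test_that("aligned alias transfer follows the correspondence and is idempotent", {
  src <- build_taxonomy(ccn_defaults("CCN202001010", prefix = "M1"),
                        types = c("ref a", "ref b"))
  src$cell_sets$cell_set_aligned_alias <- c("L2/3 IT 1", "Pvalb 1")
  tgt <- build_taxonomy(ccn_defaults("CCN202001011", prefix = "MTG"),
                        types = c("t a", "t b", "t c"))
  map <- c(CS202001011_1 = "CS202001010_1",
           CS202001011_3 = "CS202001010_2")
  out <- transfer_aligned_aliases(src, tgt, map)
  expect_identical(out$cell_sets$cell_set_aligned_alias,
                   c("L2/3 IT 1", "", "Pvalb 1"))
  expect_identical(out$transfer_log$source_taxonomy,
                   rep("CCN202001010", 2))
  again <- transfer_aligned_aliases(src, out, map)
  expect_identical(again, out)
  expect_identical(transfer_aligned_aliases(src, tgt, c()), tgt)
  expect_error(transfer_aligned_aliases(
    src, tgt, c(CS202001011_9 = "CS202001010_1")), "target accession")
})

test_that("component reports are ordered and complete", {
  reg <- sst_chodl_registry()
  rep <- link_components(build_link_graph(reg))
  expect_identical(names(rep),
                   c("component_id", "taxonomy_id",
                     "cell_set_accession_id", "preferred_alias",
                     "aligned_alias"))
  expect_identical(nrow(rep), 8L)
  expect_identical(unique(rep$component_id), 1L)
})
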
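test_that("build numbers leaves in tree order then nodes, with defaults", {
  tax <- mtg_toy_taxonomy()
  df <- tax$cell_sets

  leaf <- df[df$cell_set_kind == "leaf", ]
  expect_identical(leaf$cell_set_accession_id[1], "CS201908210_1")
  expect_identical(leaf$cell_set_preferred_alias[1], "Inh L1-2 PAX6 CDH12")
  expect_identical(leaf$cell_set_label, sprintf("MTG %03d", 1:8))

  node <- df[df$cell_set_kind == "node", ]
  expect_true("MTG 001-006" %in% node$cell_set_label)
  expect_true(all(node$cell_set_preferred_alias == ""))
  expect_identical(accession_number(node$cell_set_accession_id),
                   9:(8 + nrow(node)))

  expect_true(all(df$cell_set_structure == "middle temporal gyrus"))
  expect_true(all(df$cell_set_ontology_tag == "UBERON:0002771"))
  expect_true(all(df$cell_set_alias_assignee == "Trygve Bakken"))
})

test_that("a single-leaf taxonomy is one cell set labelled <prefix> 001", {
  d <- ccn_defaults("CCN202001010", prefix = "X")
  tax <- build_taxonomy(d, dend_node("only", original_label = "sole type"))
  expect_identical(nrow(tax$cell_sets), 1L)
  expect_identical(tax$cell_sets$cell_set_accession_id, "CS202001010_1")
  expect_identical(tax$cell_sets$cell_set_label, "X 001")
})

test_that("duplicate provisional type names abort the build", {
  tree <- dend_node("r", list(dend_node("a", original_label = "same"),
                              dend_node("b", original_label = "same")))
  expect_error(build_taxonomy(ccn_defaults("CCN202001010"), tree),
               "duplicate provisional cell type")
})

test_that("leaf spans of the built sets reconstruct the source topology", {
  sim <- simulate_taxonomy(20, branching = 3, seed = 5)
  tax <- build_taxonomy(ccn_defaults("CCN202001010", prefix = "SIM"),
                        sim$root)
  spans <- node_leaf_spans(sim$root)
  internal <- Filter(function(s) length(s) > 1, spans)
  node_labels <- tax$cell_sets$cell_set_label[
    tax$cell_sets$cell_set_kind == "node"]
  expect_setequal(node_labels,
                  vapply(internal, function(s) compact_labels("SIM", s),
                         character(1)))
  expect_identical(nrow(tax$cell_sets), 20L + length(internal))
})

test_that("flat provisional-type lists build leaf-only taxonomies", {
  tax <- build_taxonomy(ccn_defaults("CCN202001010", prefix = "ME"),
                        types = c("me-type 1", "me-type 2", "me-type 3"))
  expect_identical(tax$cell_sets$cell_set_kind, rep("leaf", 3))
  expect_identical(nrow(validate_taxonomy(tax)), 0L)
})

test_that("added cell sets extend accessions by max + 1 and never collide", {
  tax <- mtg_toy_taxonomy()
  n0 <- n_cell_sets(tax)
  top <- max(accession_number(tax$cell_sets$cell_set_accession_id))

  tax <- add_cell_set(tax, members = 1:6, preferred_alias = "LAMP5/PAX6 group",
                      label = "Group 001-006")
  tax <- add_cell_set(tax, members = "MTG 007-008",
                      preferred_alias = "rest", label = "Group 007-008")
  tax <- add_cell_set(tax, kind = "metadata",
                      preferred_alias = "Neurosurgical",
                      predicate = list(column = "tissue",
                                       value = "neurosurgical"))
  expect_identical(n_cell_sets(tax), n0 + 3L)
  added <- utils::tail(tax$cell_sets, 3)
  expect_identical(accession_number(added$cell_set_accession_id),
                   top + 1:3)
  # duplicate membership is allowed under a distinct label and accession
  expect_identical(label_numerals(added$cell_set_label[1]),
                   label_numerals("MTG 001-006"))
  expect_error(add_cell_set(tax, members = 1:6),  # default label collides
               "already in use")
  expect_error(add_cell_set(tax, members = c(1, 99)), "no leaf cell set")
  expect_error(add_cell_set(tax, members = 1:3, label = "Group 001-004"),
               "does not encode")
})

test_that("metadata cell sets take running Metadata numerals", {
  tax <- mtg_toy_taxonomy()
  tax <- add_cell_set(tax, kind = "metadata", preferred_alias = "Neurosurgical")
  tax <- add_cell_set(tax, kind = "metadata", preferred_alias = "Donor X")
  meta <- tax$cell_sets[tax$cell_sets$cell_set_kind == "metadata", ]
  expect_identical(meta$cell_set_label, c("Metadata 1", "Metadata 2"))
  expect_identical(meta$cell_set_preferred_alias[1], "Neurosurgical")
})

test_that("the nomenclature table round-trips losslessly", {
  tax <- mtg_toy_taxonomy()
  tax <- add_cell_set(tax, members = 1:6, preferred_alias = "grp",
                      label = "Group 001-006",
                      additional_aliases = c("alias one", "alias two"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_nomenclature_table(tax, path)
  header <- readLines(path, n = 1)
  expect_identical(header, paste0(
    "\"", paste(nomenclature_columns(), collapse = "\",\""), "\""))
  back <- read_nomenclature_table(path)
  expect_identical(back$cell_sets, tax$cell_sets)
  expect_identical(back$taxonomy_id, tax$taxonomy_id)
})

test_that("en-dash label files parse identically to hyphen files", {
  tax <- mtg_toy_taxonomy()
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_nomenclature_table(tax, p1)
  txt <- readLines(p1, encoding = "UTF-8")
  writeLines(gsub("001-006", "001–006", txt), p2, useBytes = FALSE)
  expect_identical(read_nomenclature_table(p2)$cell_sets, tax$cell_sets)
})

test_that("record files re-encode published cell set rows faithfully", {
  reg <- sst_chodl_registry()
  expect_identical(length(reg$taxonomies), 8L)
  all_sets <- do.call(rbind, lapply(reg$taxonomies, `[[`, "cell_sets"))
  expect_identical(nrow(all_sets), 8L)
  row8 <- all_sets[all_sets$cell_set_accession_id == "CS202002270_14", ]
  expect_identical(row8$cell_set_aligned_alias, "Sst Chodl")
  expect_identical(row8$cell_set_additional_aliases,
                   "Long-range projecting Sst")
  expect_identical(unique(all_sets$cell_set_structure),
                   "primary motor cortex")
  expect_identical(unique(all_sets$cell_set_ontology_tag), "UBERON:0001384")
})

test_that("missing required columns error; unknown columns warn", {
  tax <- mtg_toy_taxonomy()
  path <- withr::local_tempfile(fileext = ".csv")
  write_nomenclature_table(tax, path)
  df <- utils::read.csv(path, colClasses = "character")
  utils::write.csv(df[, -3], path, row.names = FALSE)
  expect_error(read_nomenclature_table(path), "cell_set_label")
  df$extra_notes <- "x"
  utils::write.csv(df, path, row.names = FALSE)
  expect_warning(read_nomenclature_table(path), "extra_notes")
})
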
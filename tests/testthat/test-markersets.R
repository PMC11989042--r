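test_that("TSV and GMT marker lists load with normalized symbols", {
  tsv <- file.path(tempdir(), "lists.tsv")
  write.table(data.frame(gene = c("KRT15", "krt15", "ITGB1", "Xpc", "Lgr6"),
                         dataset = c("hu1", "hu1", "hu1", "mo1", "mo1"),
                         species = c("human", "human", "human",
                                     "mouse", "mouse")),
              tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  gmt <- file.path(tempdir(), "lists.gmt")
  writeLines(c("setA\tna\tTP63\tKRT14\tKRT15",
               "setB\tna\tKRT5\tKRT14",
               "setC\tna\tCOL17A1"), gmt)
  on.exit(unlink(c(tsv, gmt)))
  col <- load_marker_lists(c(tsv, gmt), species = c("human", "human"))
  expect_identical(length(col$sets), 5L)              # 2 TSV + 3 GMT sets
  expect_identical(col$sets$hu1, c("KRT15", "ITGB1")) # duplicates collapse
  expect_identical(col$sets$mo1, c("XPC", "LGR6"))    # case mapping
  expect_identical(unname(col$species[["mo1"]]), "mouse")
  expect_error(marker_list_collection(list(a = "XPC"), "axolotl"),
               "species")
})

test_that("the packaged toy lists load and support the full set logic", {
  paths <- system.file("extdata",
                       c("basal_markers_toy.tsv", "basal_markers_toy.gmt"),
                       package = "stratiquant")
  col <- load_marker_lists(paths, species = c("human", "human"))
  expect_identical(length(col$sets), 6L)
  ss <- species_specific(col)
  # CAV1 and KRT15 are consensus in both species; LGR6 never in human
  expect_true("LGR6" %in% ss$mouse_specific)
  expect_true(all(c("CAV1", "KRT15") %in% ss$shared))
  vc <- venn_counts(col, species = "human")
  expect_identical(sum(vc),
                   length(unique(unlist(col$sets[col$species == "human"]))))
})

test_that("consensus follows the at-least-k-datasets rule", {
  col <- marker_list_collection(
    list(l1 = c("A", "B", "C"), l2 = c("B", "C"), l3 = "C"),
    species = "human")
  expect_identical(consensus(col, "human", 2), c("B", "C"))  # enumeration
  expect_identical(consensus(col, "human", 1), c("A", "B", "C"))  # union
  expect_identical(consensus(col, "human", 3), "C")
  expect_error(consensus(col, "human", 4), "exceeds")
  dup <- marker_list_collection(list(a = c("X", "Y"), b = c("X", "Y")),
                                species = "human")
  expect_identical(consensus(dup, "human", 2), c("X", "Y"))
})

test_that("species-specific sets follow consensus-minus-union", {
  col <- toy_collection()
  ss <- species_specific(col)
  # brute-force set arithmetic oracle
  hu_cons <- c("ITGB1", "KRT15")            # in both human lists
  mo_cons <- c("KRT15", "LGR6")             # in both mouse lists
  mo_union <- c("KRT15", "ITGB1", "LGR6", "COL17A1", "SOX2")
  hu_union <- c("KRT15", "ITGB1", "XPC", "COL17A1", "TP63")
  expect_identical(ss$human_specific, sort(setdiff(hu_cons, mo_union)))
  expect_identical(ss$mouse_specific, sort(setdiff(mo_cons, hu_union)))
  expect_identical(ss$shared, sort(intersect(hu_cons, mo_cons)))
  # identical lists for both species: nothing specific
  same <- marker_list_collection(list(h1 = c("A", "B"), h2 = c("A", "B"),
                                      m1 = c("A", "B"), m2 = c("A", "B")),
                                 species = c("human", "human",
                                             "mouse", "mouse"))
  ss2 <- species_specific(same)
  expect_length(ss2$human_specific, 0)
  expect_length(ss2$mouse_specific, 0)
  expect_identical(ss2$shared, c("A", "B"))
  # disjoint species lists: specifics equal the consensuses
  disj <- marker_list_collection(list(h1 = c("A", "B"), h2 = c("A", "B"),
                                      m1 = c("C", "D"), m2 = c("C", "D")),
                                 species = c("human", "human",
                                             "mouse", "mouse"))
  ss3 <- species_specific(disj)
  expect_identical(ss3$human_specific, c("A", "B"))
  expect_identical(ss3$mouse_specific, c("C", "D"))
  expect_length(ss3$shared, 0)
  solo <- marker_list_collection(list(h = "A"), "human")
  expect_error(species_specific(solo), "mouse")
})

test_that("Venn region counts always sum to the union size", {
  # trivial cases
  disj <- marker_list_collection(list(a = c("A", "B", "C"),
                                      b = c("D", "E", "F", "G")), "human")
  vc <- venn_counts(disj)
  expect_identical(sum(vc), 7L)
  expect_identical(unname(vc[c("a", "b")]), c(3L, 4L))
  expect_false("a&b" %in% names(vc))
  ident <- marker_list_collection(list(a = c("A", "B"), b = c("A", "B")),
                                  "human")
  vi <- venn_counts(ident)
  expect_identical(names(vi), "a&b")
  expect_identical(sum(vi), 2L)
  # random sets vs brute-force region assignment
  set.seed(4)
  pool <- LETTERS
  sets <- lapply(1:4, function(i) sample(pool, sample(5:15, 1)))
  names(sets) <- paste0("s", 1:4)
  col <- marker_list_collection(sets, "human")
  vc4 <- venn_counts(col)
  expect_identical(sum(vc4), length(unique(unlist(sets))))
  for (gene in unique(unlist(sets))) {  # each gene in exactly one region
    region <- paste(names(sets)[sapply(sets, function(s) gene %in% s)],
                    collapse = "&")
    expect_true(region %in% names(vc4))
  }
  too_many <- marker_list_collection(
    setNames(replicate(6, LETTERS[1:3], simplify = FALSE), letters[1:6]),
    "human")
  expect_error(venn_counts(too_many), "5")
  expect_error(venn_counts(marker_list_collection(list(a = "A"), "human")),
               "2")
})
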
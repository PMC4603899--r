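test_that("synonym standardisation renames, merges duplicates, is idempotent", {
  ds <- supertree_dataset(list(
    source_record(read_newick("((Panulirus_ornatus,X),Z);"), "s1", 2001,
                  "16S")),
    synonyms = c(Panulirus_ornatus = "Panulirus ornatus"))
  r <- standardize_names(ds)
  expect_true("Panulirus ornatus" %in% r$dataset$records[[1]]$tree$tip.label)
  expect_true(any(r$log$action == "renamed"))

  ## two leaves mapping to one accepted name merge into a single leaf
  ds2 <- supertree_dataset(list(
    source_record(read_newick("((X,Y),Z);"), "s1", 2001, "16S")),
    synonyms = c(X = "W", Y = "W"))
  r2 <- standardize_names(ds2)
  expect_identical(write_newick(r2$dataset$records[[1]]$tree), "(W,Z);")
  expect_true(any(r2$log$action == "merged"))

  ## identity on an empty map; applying twice equals applying once
  ds3 <- toy_dataset()
  r3 <- standardize_names(ds3)
  expect_identical(lapply(r3$dataset$records, function(x) write_newick(x$tree)),
                   lapply(ds3$records, function(x) write_newick(x$tree)))
  twice <- standardize_names(r$dataset)
  expect_identical(write_newick(twice$dataset$records[[1]]$tree),
                   write_newick(r$dataset$records[[1]]$tree))
})

test_that("non-idempotent synonym maps are rejected", {
  expect_error(
    supertree_dataset(list(
      source_record(read_newick("((A,B),C);"), "s", 2000, "16S")),
      synonyms = c(A = "B", B = "C")),
    "idempotent")
})

test_that("higher taxa become polytomies of constituents found elsewhere", {
  ds <- supertree_dataset(list(
    source_record(read_newick("(Scyllaridae,(A,B));"), "s1", 2001, "16S"),
    source_record(read_newick("((S1,S2),(A,B));"), "s2", 2005, "COI")),
    taxonomy = list(Scyllaridae = c("S1", "S2", "S3")))
  r <- substitute_higher_taxa(ds)
  expect_identical(write_newick(r$dataset$records[[1]]$tree),
                   "((A,B),(S1,S2));")
  ## the substituted pair is a genuine polytomy-born clade
  expect_true(any(vapply(clades(r$dataset$records[[1]]$tree),
                         function(cl) identical(cl, c("S1", "S2")),
                         logical(1))))

  ## singleton intersection renames; empty intersection deletes
  ds2 <- supertree_dataset(list(
    source_record(read_newick("(HT,(A,B));"), "s1", 2001, "16S"),
    source_record(read_newick("((S1,A),B);"), "s2", 2005, "COI")),
    taxonomy = list(HT = c("S1", "S9")))
  r2 <- substitute_higher_taxa(ds2)
  expect_identical(write_newick(r2$dataset$records[[1]]$tree),
                   "((A,B),S1);")

  ds3 <- supertree_dataset(list(
    source_record(read_newick("(HT,(A,B));"), "s1", 2001, "16S"),
    source_record(read_newick("((C,A),B);"), "s2", 2005, "COI")),
    taxonomy = list(HT = c("S8", "S9")))
  r3 <- substitute_higher_taxa(ds3)
  expect_identical(write_newick(r3$dataset$records[[1]]$tree), "(A,B);")
  expect_true(any(r3$log$action == "ht_removed"))
})

test_that("substitution never invents names absent from taxonomy and data", {
  for (seed in 1:5) {
    truth <- synthetic_truth(n_taxa = 12, k_trees = 5, subsample_min = 5,
                             subsample_max = 8, higher_taxon_rate = 0.3,
                             seed = seed)
    ds <- inject_noise(sample_source_trees(truth), truth)$dataset
    r <- substitute_higher_taxa(ds)
    allowed <- union(unlist(ds$taxonomy), dataset_taxa(ds))
    expect_true(all(dataset_taxa(r$dataset) %in% allowed))
  }
})

test_that("identical-signature groups share unit weight; subsets are removed within studies", {
  ds <- supertree_dataset(list(
    source_record(read_newick("((A,B),C);"), "s1", 2001, "16S", id = "a"),
    source_record(read_newick("((A,C),B);"), "s1", 2001, "16S", id = "b")))
  r <- apply_independence(ds)
  expect_identical(vapply(r$dataset$records, `[[`, integer(1), "weight_den"),
                   c(2L, 2L))
  ## weights within the group sum to 1
  expect_equal(sum(vapply(r$dataset$records, mrptree:::record_weight,
                          numeric(1))), 1)

  ds2 <- supertree_dataset(list(
    source_record(read_newick("((A,B),C);"), "s1", 2001, "16S", id = "small"),
    source_record(read_newick("(((A,B),C),D);"), "s1", 2001, "16S",
                  id = "big"),
    source_record(read_newick("((A,B),D);"), "s9", 2007, "COI",
                  id = "other")))
  r2 <- apply_independence(ds2)
  expect_setequal(vapply(r2$dataset$records, `[[`, character(1), "id"),
                  c("big", "other"))
  expect_true(any(r2$report$action == "removed_subset"))

  ## cross-study subset: flagged, not removed
  ds3 <- supertree_dataset(list(
    source_record(read_newick("((A,B),C);"), "s1", 2001, "16S", id = "x"),
    source_record(read_newick("(((A,B),C),D);"), "s2", 2004, "16S",
                  id = "y")))
  r3 <- apply_independence(ds3)
  expect_length(r3$dataset$records, 2L)
  expect_true(any(r3$report$action == "flagged_cross_study_subset"))

  ## all distinct: untouched
  r4 <- apply_independence(toy_dataset())
  expect_true(all(vapply(r4$dataset$records, `[[`, integer(1),
                         "weight_den") == 1L))
})

test_that("overlap check reports connectivity and is order-independent", {
  ds <- supertree_dataset(list(
    source_record(read_newick("((A,B),C);"), "s1", 2001, "16S", id = "r1"),
    source_record(read_newick("((B,C),D);"), "s2", 2002, "16S", id = "r2")))
  expect_true(check_overlap(ds)$pass)

  ds2 <- supertree_dataset(list(
    source_record(read_newick("((A,B),C);"), "s1", 2001, "16S", id = "r1"),
    source_record(read_newick("((C,D),E);"), "s2", 2002, "16S", id = "r2")))
  ov2 <- check_overlap(ds2)
  expect_false(ov2$pass)
  expect_identical(ov2$n_components, 2L)

  ## transitivity: t1-t2 and t2-t3 overlap, t1-t3 do not
  ds3 <- supertree_dataset(list(
    source_record(read_newick("((A,B),C);"), "s1", 2001, "16S", id = "r1"),
    source_record(read_newick("((B,C),(D,E));"), "s2", 2002, "16S",
                  id = "r2"),
    source_record(read_newick("((D,E),F);"), "s3", 2003, "16S", id = "r3")))
  expect_true(check_overlap(ds3)$pass)

  perm <- ds3
  perm$records <- perm$records[c(3, 1, 2)]
  m1 <- check_overlap(ds3)$membership
  m2 <- check_overlap(perm)$membership
  expect_identical(sort(names(m1[m1 == m1[["r1"]]])),
                   sort(names(m2[m2 == m2[["r1"]]])))
})

test_that("dataset summaries tabulate years, characters and sizes", {
  ds <- supertree_dataset(list(
    source_record(read_newick("((A,B),C);"), "s1", 2001, "16S"),
    source_record(read_newick("((A,C),B);"), "s2", 2001, "COI"),
    source_record(read_newick("(((A,B),C),(D,E));"), "s3", 2005,
                  c("16S", "COI"))))
  s <- dataset_summary(ds)
  expect_identical(s$trees_per_year,
                   data.frame(year = c(2001L, 2005L), n = c(2L, 1L)))
  expect_identical(s$tree_sizes$size, c(3L, 3L, 5L))
  expect_identical(sum(s$character_types_per_year$n), 4L)
  empty <- dataset_summary(supertree_dataset(list()))
  expect_identical(nrow(empty$trees_per_year), 0L)
})

test_that("bundle and XML round-trips preserve the dataset", {
  truth <- synthetic_truth(n_taxa = 10, k_trees = 4, subsample_min = 5,
                           subsample_max = 7, seed = 3)
  ds <- sample_source_trees(truth)
  ds$synonyms <- c(oldname = "t01")
  ds$taxonomy <- list(HT = c("t02", "t03"))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_identical(lapply(back$records, function(r) write_newick(r$tree)),
                   lapply(ds$records, function(r) write_newick(r$tree)))
  expect_identical(back$synonyms, ds$synonyms)
  expect_identical(back$taxonomy, ds$taxonomy)

  xf <- withr::local_tempfile(fileext = ".xml")
  write_dataset_xml(ds, xf)
  back2 <- read_dataset_xml(xf)
  expect_identical(lapply(back2$records, function(r) write_newick(r$tree)),
                   lapply(ds$records, function(r) write_newick(r$tree)))
  expect_identical(vapply(back2$records, `[[`, integer(1), "year"),
                   vapply(ds$records, `[[`, integer(1), "year"))
  expect_identical(back2$taxonomy, ds$taxonomy)
})
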
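test_that("source trees classify as support / conflict / permit / irrelevant", {
  expect_identical(classify_source_tree(c("A", "B"),
                                        read_newick("((A,B),C);")), "support")
  expect_identical(classify_source_tree(c("A", "B"),
                                        read_newick("((A,C),B);")), "conflict")
  expect_identical(classify_source_tree(c("A", "B"),
                                        read_newick("(A,B,C);")), "permit")
  ## fewer than two members present, or no outside taxon -> irrelevant
  expect_identical(classify_source_tree(c("A", "Z"),
                                        read_newick("((A,B),C);")),
                   "irrelevant")
  expect_identical(classify_source_tree(c("A", "B", "C"),
                                        read_newick("((A,B),C);")),
                   "irrelevant")
})

test_that("support classification cross-validates against a restriction-based path", {
  ## independent route: A is supported iff it appears as a clade of the
  ## source tree restricted to (A union one outside taxon at a time ... )
  ## simpler equivalent: a clade of restrict(tree, leaves) where relevant
  for (seed in 1:20) {
    tree <- yule_tree(10, seed = 6000 + seed)
    super <- yule_tree(10, seed = 6100 + seed)
    super$tip.label <- tree$tip.label[match(super$tip.label,
                                            sort(super$tip.label))]
    for (cl in clades(super)) {
      got <- classify_source_tree(cl, tree)
      A <- intersect(cl, tree$tip.label)
      if (length(A) < 2 || length(setdiff(tree$tip.label, cl)) < 1) {
        expect_identical(got, "irrelevant")
      } else if (got == "support") {
        keys <- vapply(clades(tree), paste, "", collapse = "|")
        expect_true(paste(sort(A), collapse = "|") %in% keys)
      }
    }
  }
})

test_that("V and V+ follow the count formulas and stated bounds", {
  mk <- function(trees) supertree_dataset(lapply(seq_along(trees),
    function(i) source_record(read_newick(trees[[i]]),
                              paste0("s", i), 2000 + i, "16S")))
  st <- read_newick("((A,B),C);")

  ## unanimous support: V = V+ = 1
  ds <- mk(list("((A,B),C);", "(((A,B),C),D);"))
  ns <- v_indices(st, ds)
  ab <- ns[ns$clade == "A;B", ]
  expect_identical(ab$s, 2L)
  expect_identical(ab$V, 1)
  expect_identical(ab$V_plus, 1)
  expect_identical(ab$category, "V=1")

  ## s=1, q=1, p=0 -> V = 0, V+ = 0
  ds2 <- mk(list("((A,B),C);", "((A,C),B);"))
  ns2 <- v_indices(st, ds2)
  ab2 <- ns2[ns2$clade == "A;B", ]
  expect_identical(ab2$V, 0)
  expect_identical(ab2$V_plus, 0)

  ## s=1, q=1, p=2 -> V = 0, V+ = 0.5
  ds3 <- mk(list("((A,B),C);", "((A,C),B);", "(A,B,C);", "(A,B,C,D);"))
  ns3 <- v_indices(st, ds3)
  ab3 <- ns3[ns3$clade == "A;B", ]
  expect_identical(c(ab3$s, ab3$q, ab3$p), c(1L, 1L, 2L))
  expect_identical(ab3$V, 0)
  expect_identical(ab3$V_plus, 0.5)

  ## counts always partition the source trees; nodes nobody can evaluate
  ## are NA, not zero
  ds4 <- mk(list("((X,Y),Z);", "((X,Z),Y);"))
  st4 <- read_newick("(((X,Y),Z),(P,Q));")
  ns4 <- v_indices(st4, ds4)
  expect_true(all(ns4$s + ns4$q + ns4$p + ns4$r == 2L))
  pq <- ns4[ns4$clade == "P;Q", ]
  expect_true(is.na(pq$V))
  expect_true(is.na(pq$V_plus))
  expect_identical(pq$category, "undefined")
})

test_that("V bounds, V+ >= V and count partition hold on synthetic runs", {
  for (seed in 1:5) {
    truth <- synthetic_truth(n_taxa = 15, k_trees = 8, subsample_min = 6,
                             subsample_max = 10, nni_moves = 2,
                             contract_probability = 0.2, seed = seed)
    ds <- sample_source_trees(truth)
    super <- yule_tree(15, seed = 660 + seed)
    super$tip.label <- truth$model_tree$tip.label[
      match(super$tip.label, sort(super$tip.label))]
    ns <- v_indices(super, ds)
    def <- !is.na(ns$V)
    expect_true(all(ns$V[def] >= -1 & ns$V[def] <= 1))
    defp <- !is.na(ns$V_plus)
    expect_true(all(ns$V_plus[defp] >= -1 & ns$V_plus[defp] <= 1))
    both <- def & defp
    expect_true(all(ns$V_plus[both] >= ns$V[both]))
    expect_true(all(ns$s + ns$q + ns$p + ns$r == length(ds$records)))
    expect_true(all((ns$V[both] == 1 & ns$p[both] == 0) ==
                      (ns$q[both] == 0 & ns$s[both] > 0 & ns$p[both] == 0)))
  }
})

test_that("novel clades are unsupported but evaluable; irrelevant ones are separate", {
  ds <- supertree_dataset(list(
    source_record(read_newick("((A,B),(C,D));"), "s1", 2001, "16S"),
    source_record(read_newick("((A,C),(B,D));"), "s2", 2002, "COI")))
  st <- read_newick("(((A,D),B),C);")
  nc <- novel_clades(st, ds)
  expect_true("A;D" %in% nc$novel$clade)      # relevant, supported by none
  st2 <- read_newick("((A,B),(C,D));")
  nc2 <- novel_clades(st2, ds)
  expect_false("A;B" %in% nc2$novel$clade)    # verbatim in a source tree

  ## clade irrelevant to every source tree: unevaluable, not novel
  ds3 <- supertree_dataset(list(
    source_record(read_newick("((A,B),C);"), "s1", 2001, "16S")))
  st3 <- read_newick("(((A,B),C),(P,Q));")
  nc3 <- novel_clades(st3, ds3)
  expect_false("P;Q" %in% nc3$novel$clade)
  expect_true("P;Q" %in% nc3$unevaluable$clade)
})

test_that("support outputs are written as CSV and annotated Newick", {
  ds <- supertree_dataset(list(
    source_record(read_newick("((A,B),C);"), "s1", 2001, "16S")))
  ns <- v_indices(read_newick("((A,B),C);"), ds)
  csv <- withr::local_tempfile(fileext = ".csv")
  nwk <- withr::local_tempfile(fileext = ".nwk")
  write_support_csv(ns, csv)
  expect_identical(utils::read.csv(csv)$clade, "A;B")
  write_support_tree(ns, nwk)
  expect_identical(readLines(nwk), "((A,B)1,C);")
})
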
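test_that("Yule trees are binary, deterministic per seed, with n-1 internal nodes", {
  for (n in c(3L, 5L, 11L)) {
    t <- yule_tree(n, seed = 1)
    expect_length(t$tip.label, n)
    expect_identical(t$Nnode, n - 1L)
  }
  expect_identical(write_newick(yule_tree(9, seed = 4)),
                   write_newick(yule_tree(9, seed = 4)))
  expect_false(write_newick(yule_tree(9, seed = 4)) ==
                 write_newick(yule_tree(9, seed = 5)))
  expect_error(yule_tree(2), ">= 3")
})

test_that("four-taxon topology frequencies match the exact Yule distribution", {
  ## Under equal-rates growth the balanced shape has probability 1/3 (1/9
  ## per labelled tree) and the caterpillar 2/3 (1/18 per labelled tree);
  ## uniform sampling over the 15 labelled topologies would give 1/5 vs 4/5
  ## instead, so this check pins the generator to the Yule null model.
  draws <- 3000
  keys <- vapply(seq_len(draws), function(i)
    write_newick(yule_tree(4, seed = 10000 + i)), "")
  shape_balanced <- grepl("^\\(\\(t0[0-9],t0[0-9]\\),\\(t0[0-9],t0[0-9]\\)\\);$",
                          keys)
  p_bal <- mean(shape_balanced)
  expect_true(abs(p_bal - 1 / 3) < 0.03)
  ## each labelled topology near its exact probability
  tab <- table(keys) / draws
  expect_identical(length(tab), 15L)
  bal_names <- grepl("^\\(\\(t0[0-9],t0[0-9]\\),\\(t0[0-9],t0[0-9]\\)\\);$",
                     names(tab))
  expect_true(all(abs(tab[bal_names] - 1 / 9) < 0.025))
  expect_true(all(abs(tab[!bal_names] - 1 / 18) < 0.025))
})

test_that("unperturbed source trees are exact restrictions of the model tree", {
  truth <- synthetic_truth(n_taxa = 20, k_trees = 10, subsample_min = 8,
                           subsample_max = 12, seed = 11)
  ds <- sample_source_trees(truth)
  expect_length(ds$records, 10L)
  for (r in ds$records) {
    n <- length(r$tree$tip.label)
    expect_true(n >= 8 && n <= 12)
    expect_identical(rf_distance(
      r$tree, restrict_tree(truth$model_tree, r$tree$tip.label)), 0L)
  }
  expect_true(check_overlap(ds)$pass)
  ## byte-identical regeneration from the same truth
  ds2 <- sample_source_trees(truth)
  expect_identical(lapply(ds$records, function(r) write_newick(r$tree)),
                   lapply(ds2$records, function(r) write_newick(r$tree)))
})

test_that("full contraction yields stars and an empty-matrix error downstream", {
  truth <- synthetic_truth(n_taxa = 12, k_trees = 4, subsample_min = 5,
                           subsample_max = 8, contract_probability = 1,
                           seed = 2)
  ds <- sample_source_trees(truth)
  expect_true(all(vapply(ds$records, function(r) r$tree$Nnode == 1L,
                         logical(1))))
  expect_error(encode_brs(ds), "empty matrix")
})

test_that("NNI perturbation changes topology but not the leaf set", {
  truth0 <- synthetic_truth(n_taxa = 15, k_trees = 5, subsample_min = 10,
                            subsample_max = 12, nni_moves = 0, seed = 6)
  truth5 <- synthetic_truth(n_taxa = 15, k_trees = 5, subsample_min = 10,
                            subsample_max = 12, nni_moves = 5, seed = 6)
  ds5 <- sample_source_trees(truth5)
  rf <- vapply(ds5$records, function(r)
    rf_distance(r$tree, restrict_tree(truth5$model_tree,
                                      r$tree$tip.label)), integer(1))
  expect_true(any(rf > 0))
  expect_true(all(vapply(ds5$records, function(r)
    all(r$tree$tip.label %in% truth5$model_tree$tip.label), logical(1))))
})

test_that("noise injection is invertible through curation", {
  ## synonyms only: exact restoration
  truth <- synthetic_truth(n_taxa = 14, k_trees = 6, subsample_min = 6,
                           subsample_max = 9, synonym_rate = 1, seed = 8)
  clean <- sample_source_trees(truth)
  noisy <- inject_noise(clean, truth)
  expect_true(all(grepl("_syn$", dataset_taxa(noisy$dataset))))
  restored <- standardize_names(noisy$dataset)$dataset
  for (i in seq_along(clean$records))
    expect_identical(rf_distance(restored$records[[i]]$tree,
                                 clean$records[[i]]$tree), 0L)

  ## zero rates: unchanged
  truth0 <- synthetic_truth(n_taxa = 10, k_trees = 4, subsample_min = 5,
                            subsample_max = 7, seed = 9)
  ds0 <- sample_source_trees(truth0)
  n0 <- inject_noise(ds0, truth0)
  expect_identical(lapply(n0$dataset$records, function(r) write_newick(r$tree)),
                   lapply(ds0$records, function(r) write_newick(r$tree)))

  ## higher-taxon labels disappear after curation; only model names remain
  truthH <- synthetic_truth(n_taxa = 14, k_trees = 6, subsample_min = 6,
                            subsample_max = 9, synonym_rate = 0.2,
                            higher_taxon_rate = 0.3, seed = 10)
  cleanH <- sample_source_trees(truthH)
  noisyH <- inject_noise(cleanH, truthH)
  cur <- standardize_names(noisyH$dataset)
  cur <- substitute_higher_taxa(cur$dataset)
  expect_true(all(dataset_taxa(cur$dataset) %in%
                    truthH$model_tree$tip.label))
})

test_that("supertree recovery degrades monotonically-ish with NNI noise", {
  ## mean RF to truth under heavier perturbation is at least that under
  ## no perturbation (averaged over seeds)
  mean_rf <- function(moves) {
    rfs <- vapply(1:3, function(seed) {
      truth <- synthetic_truth(n_taxa = 12, k_trees = 8, subsample_min = 6,
                               subsample_max = 9, nni_moves = moves,
                               seed = 20 + seed)
      ds <- sample_source_trees(truth)
      m <- encode_brs(ds)
      sr <- heuristic_search(m, replicates = 3, seed = seed, maxtrees = 60)
      ing <- lapply(sr$mpts, function(t)
        restrict_tree(t, setdiff(t$tip.label, "MRP_Outgroup")))
      cons <- strict_consensus(ing)
      rf_distance(cons, restrict_tree(truth$model_tree, cons$tip.label))
    }, integer(1))
    mean(rfs)
  }
  expect_true(mean_rf(6) >= mean_rf(0))
})
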
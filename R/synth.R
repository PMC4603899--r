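## Synthetic source-tree generator with known truth.  A model tree grown
## under a Yule (equal-rates) process is subsampled into partially
## overlapping source trees, optionally perturbed by random NNI moves and
## random polytomy formation, and optionally obscured by nomenclature noise
## (pseudo-synonyms and invented higher-taxon labels) whose key the
## curation module can use to restore the clean dataset.  Everything is
## deterministic for a given seed.

#' Simulate a Yule (pure-birth) tree
#'
#' Grows a binary rooted tree by repeatedly splitting a uniformly chosen
#' extant leaf, then assigns taxon labels (`t01`, `t02`, ...) by a random
#' permutation.
#'
#' @param n_taxa number of leaves (>= 3).
#' @param seed optional integer seed (the global RNG state is restored
#'   afterwards).
#' @return a binary rooted `"phylo"` with `n_taxa - 1` internal nodes.
#' @export
yule_tree <- function(n_taxa, seed = NULL) {
  if (n_taxa < 3L) stop("n_taxa must be >= 3")
  gen <- function() {
    n <- n_taxa
    ct <- ct_init_cherry(ct_new(n), 1L, 2L)
    for (i in 3L:n) {
      tips <- which(ct$act)
      ct <- ct_insert_leaf(ct, i, tips[sample.int(length(tips), 1L)])
    }
    labels <- sprintf("t%0*d", max(2L, nchar(n)), seq_len(n))
    ct_to_phylo(ct, labels[sample.int(n)])
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Define a synthetic truth (model tree plus generation parameters)
#'
#' @param n_taxa leaves of the model tree.
#' @param k_trees number of source trees to draw.
#' @param subsample_min,subsample_max inclusive range of source-tree sizes.
#' @param nni_moves random NNI perturbations applied to each source tree.
#' @param contract_probability probability that each internal (non-root)
#'   node of a source tree is collapsed into a polytomy.
#' @param synonym_rate fraction of taxa given a pseudo-synonym by
#'   [inject_noise()].
#' @param higher_taxon_rate fraction of taxa replaced by invented
#'   higher-taxon labels by [inject_noise()].
#' @param seed master seed; all generation draws derive from it.
#' @return an object of class `"synthetic_truth"` with fields `model_tree`
#'   and `params`.
#' @export
synthetic_truth <- function(n_taxa = 20L, k_trees = 10L,
                            subsample_min = 8L, subsample_max = 12L,
                            nni_moves = 0L, contract_probability = 0,
                            synonym_rate = 0, higher_taxon_rate = 0,
                            seed = 1L) {
  stopifnot(n_taxa >= 3L, k_trees >= 2L,
            subsample_min >= 3L, subsample_max >= subsample_min,
            subsample_max <= n_taxa,
            contract_probability >= 0, contract_probability <= 1,
            synonym_rate >= 0, synonym_rate <= 1,
            higher_taxon_rate >= 0, higher_taxon_rate <= 1)
  params <- list(n_taxa = as.integer(n_taxa), k_trees = as.integer(k_trees),
                 subsample_min = as.integer(subsample_min),
                 subsample_max = as.integer(subsample_max),
                 nni_moves = as.integer(nni_moves),
                 contract_probability = contract_probability,
                 synonym_rate = synonym_rate,
                 higher_taxon_rate = higher_taxon_rate,
                 seed = as.integer(seed))
  structure(list(model_tree = yule_tree(n_taxa, seed = seed),
                 params = params),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  p <- x$params
  cat("Synthetic truth: model tree on", p$n_taxa, "taxa;", p$k_trees,
      "source trees of", p$subsample_min, "-", p$subsample_max, "taxa\n")
  cat("  perturbation: nni_moves =", p$nni_moves, ", contract_probability =",
      p$contract_probability, "; seed =", p$seed, "\n")
  invisible(x)
}

#' Draw a synthetic source-tree dataset from a truth
#'
#' Each source tree is the model tree restricted to a uniform leaf
#' subsample, perturbed by `nni_moves` random rooted NNI moves and by
#' collapsing each internal (non-root) node with probability
#' `contract_probability`.  Meta-data (year, character types, method) are
#' drawn from fixed pools.  Taxonomic overlap (two shared taxa, connected
#' graph) is enforced by resampling violating trees up to `retry_cap`
#' times.
#'
#' @param truth a `"synthetic_truth"`.
#' @param retry_cap maximum connectivity-restoring resampling rounds.
#' @return a `"supertree_dataset"` (with empty synonym and taxonomy maps).
#' @export
sample_source_trees <- function(truth, retry_cap = 100L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  p <- truth$params
  with_seed(p$seed + 1L, {
    draw <- function(i) {
      size <- sample(seq(p$subsample_min, p$subsample_max), 1L)
      taxa <- sample(truth$model_tree$tip.label, size)
      tr <- restrict_tree(truth$model_tree, taxa)
      tr <- perturb_nni(tr, p$nni_moves)
      tr <- contract_edges(tr, p$contract_probability)
      source_record(tr,
                    study_key = sprintf("synth%02d", i),
                    year = sample(1992:2013, 1L),
                    character_types = sample(
                      c("morphology", "16S", "18S", "28S", "COI", "H3"),
                      sample(1:2, 1L)),
                    method = sample(c("parsimony", "likelihood",
                                      "bayesian", "distance"), 1L),
                    id = sprintf("synth%02d_t01", i))
    }
    records <- lapply(seq_len(p$k_trees), draw)
    ds <- supertree_dataset(records)
    tries <- 0L
    repeat {
      ov <- check_overlap(ds, min_shared = 2L)
      if (ov$pass) break
      tries <- tries + 1L
      if (tries > retry_cap)
        stop("could not connect the overlap graph after ", retry_cap,
             " resampling rounds; increase the subsample sizes")
      bad <- match(ov$removal_candidates, record_ids(ds))
      for (i in bad) ds$records[[i]] <- draw(i)
    }
    ds
  })
}

## random rooted NNI: pick an internal non-root node v, swap one of its
## children with its sibling.  Requires a binary tree; polytomies are
## introduced only afterwards by contract_edges().
perturb_nni <- function(tree, moves) {
  if (moves <= 0L) return(tree)
  labels <- tree$tip.label
  ct <- ct_from_phylo(tree, labels)
  n <- length(labels)
  for (i in seq_len(moves)) {
    internals <- setdiff(ct_nodes(ct), c(seq_len(n), ct$root))
    internals <- internals[internals > n]
    if (length(internals) == 0L) break
    v <- internals[sample.int(length(internals), 1L)]
    p <- ct$par[v]
    sib <- if (ct$kid1[p] == v) ct$kid2[p] else ct$kid1[p]
    child <- if (sample.int(2L, 1L) == 1L) ct$kid1[v] else ct$kid2[v]
    ## swap child <-> sib
    if (ct$kid1[v] == child) ct$kid1[v] <- sib else ct$kid2[v] <- sib
    if (ct$kid1[p] == sib) ct$kid1[p] <- child else ct$kid2[p] <- child
    ct$par[sib] <- v
    ct$par[child] <- p
  }
  ct_to_phylo(ct, labels)
}

## collapse each internal non-root node with probability p
contract_edges <- function(tree, prob) {
  if (prob <= 0) return(tree)
  ntip <- length(tree$tip.label)
  internal <- ntip + seq_len(tree$Nnode)
  candidates <- setdiff(internal, ntip + 1L)
  drop <- candidates[stats::runif(length(candidates)) < prob]
  if (length(drop) == 0L) return(tree)
  collapse_nodes(tree, drop)
}

## remove the given internal nodes, attaching their children to their
## parents (polytomy formation)
collapse_nodes <- function(tree, nodes) {
  e <- tree$edge
  for (v in nodes) {
    p <- e[e[, 2L] == v, 1L]
    e[e[, 1L] == v, 1L] <- p
    e <- e[e[, 2L] != v, , drop = FALSE]
  }
  ## renumber internal nodes consecutively
  ntip <- length(tree$tip.label)
  keep <- sort(unique(e[, 1L]))
  map <- integer(max(e))
  map[seq_len(ntip)] <- seq_len(ntip)
  map[keep] <- ntip + seq_along(keep)
  e2 <- cbind(map[e[, 1L]], map[e[, 2L]])
  storage.mode(e2) <- "integer"
  phy <- structure(list(edge = e2, tip.label = tree$tip.label,
                        Nnode = length(keep)), class = "phylo")
  ape::reorder.phylo(phy, "cladewise")
}

#' Inject nomenclature noise into a synthetic dataset
#'
#' Renames a fraction of taxa to pseudo-synonyms (`<name>_syn`) and
#' replaces a disjoint fraction with invented higher-taxon labels
#' (`Clade_<name>`) defined, in the emitted taxonomy, as the leaf set of
#' the smallest model-tree clade containing the replaced taxon.  The
#' emitted maps are stored in the returned dataset so that
#' [standardize_names()] and [substitute_higher_taxa()] can restore the
#' clean data (exactly for synonyms; up to local polytomies for
#' higher-taxon replacements).
#'
#' @param dataset a `"supertree_dataset"` from [sample_source_trees()].
#' @param truth the `"synthetic_truth"` that produced it.
#' @return `list(dataset = <noisy dataset carrying the key maps>,
#'   key = list(synonyms, taxonomy))`.
#' @export
inject_noise <- function(dataset, truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  p <- truth$params
  if (p$synonym_rate == 0 && p$higher_taxon_rate == 0)
    return(list(dataset = dataset,
                key = list(synonyms = character(0), taxonomy = list())))
  with_seed(p$seed + 2L, {
    taxa <- dataset_taxa(dataset)
    n <- length(taxa)
    n_syn <- round(p$synonym_rate * n)
    n_ht <- min(round(p$higher_taxon_rate * n), n - n_syn)
    picks <- sample(taxa, n_syn + n_ht)
    syn_taxa <- picks[seq_len(n_syn)]
    ht_taxa <- picks[n_syn + seq_len(n_ht)]
    synonyms <- if (length(syn_taxa))
      stats::setNames(syn_taxa, paste0(syn_taxa, "_syn")) else character(0)
    model_cl <- clades(truth$model_tree)
    taxonomy <- list()
    ht_label <- if (length(ht_taxa))
      stats::setNames(paste0("Clade_", ht_taxa), ht_taxa) else character(0)
    for (x in ht_taxa) {
      containing <- model_cl[vapply(model_cl, function(cl) x %in% cl,
                                    logical(1L))]
      def <- if (length(containing))
        containing[[which.min(lengths(containing))]] else x
      taxonomy[[ht_label[x]]] <- def
    }
    for (i in seq_along(dataset$records)) {
      labs <- dataset$records[[i]]$tree$tip.label
      hit <- labs %in% syn_taxa
      labs[hit] <- paste0(labs[hit], "_syn")
      hhit <- labs %in% ht_taxa
      labs[hhit] <- unname(ht_label[labs[hhit]])
      dataset$records[[i]]$tree$tip.label <- labs
      ## two leaves of one tree may now carry the same higher-taxon label;
      ## curation's merge rule handles that, but avoid creating parse-level
      ## duplicates here by merging immediately
      dataset$records[[i]]$tree <-
        merge_duplicate_leaves(dataset$records[[i]]$tree)
    }
    dataset$synonyms <- synonyms
    dataset$taxonomy <- taxonomy
    list(dataset = dataset,
         key = list(synonyms = synonyms, taxonomy = taxonomy))
  })
}
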
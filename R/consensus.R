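## Summaries of most-parsimonious tree sets: strict consensus and the
## maximum agreement subtree (MAST).  The pairwise MAST is the classical
## exact dynamic programme over node pairs of two rooted binary trees; the
## k-tree MAST is exact below a configurable size limit and otherwise a
## verified fold of the pairwise routine.

#' Strict consensus of rooted trees
#'
#' Returns the tree whose clades are exactly those present in every input
#' tree.
#'
#' @param trees a list (or `multiPhylo`) of `"phylo"` objects on identical
#'   leaf sets.
#' @return a `"phylo"` object (usually with polytomies).
#' @export
strict_consensus <- function(trees) {
  trees <- as_tree_list(trees)
  check_same_leaves(trees)
  if (length(trees) == 1L) return(trees[[1L]])
  cons <- ape::consensus(trees, p = 1, rooted = TRUE)
  sanitize_tree(cons)
}

as_tree_list <- function(trees) {
  if (inherits(trees, "phylo")) return(list(trees))
  stopifnot(length(trees) >= 1L)
  lapply(trees, function(t) { stopifnot(inherits(t, "phylo")); t })
}

check_same_leaves <- function(trees) {
  l1 <- sort(trees[[1L]]$tip.label)
  for (t in trees[-1L]) {
    if (!identical(sort(t$tip.label), l1))
      stop("trees do not share an identical leaf set")
  }
  invisible(TRUE)
}

#' Maximum agreement subtree of two rooted binary trees
#'
#' Exact dynamic programme over pairs of nodes: for internal/internal pairs
#' the recurrence takes the best of descending into either tree or matching
#' the two pairs of child subtrees.  Among equally large agreement sets the
#' lexicographically smallest taxon-name set is returned, making the result
#' deterministic and symmetric in its arguments.
#'
#' @param t1,t2 binary rooted `"phylo"` objects on identical leaf sets.
#' @return an object of class `"agreement_result"`: `leafset` (sorted
#'   character vector), `tree` (`t1` restricted to the leafset) and
#'   `is_exact = TRUE`.
#' @export
mast_pair <- function(t1, t2) {
  check_same_leaves(list(t1, t2))
  stopifnot(t1$Nnode == length(t1$tip.label) - 1L,
            t2$Nnode == length(t2$tip.label) - 1L)
  n1 <- length(t1$tip.label) + t1$Nnode
  n2 <- length(t2$tip.label) + t2$Nnode
  k1 <- children_list(t1)
  k2 <- children_list(t2)
  tips1 <- tipsets(t1)
  tips2 <- tipsets(t2)
  M <- vector("list", n1 * n2)
  idx <- function(u, v) (u - 1L) * n2 + v
  po1 <- node_postorder(t1)
  po2 <- node_postorder(t2)
  for (u in po1) {
    for (v in po2) {
      if (is_tip(t1, u) && is_tip(t2, v)) {
        lab <- t1$tip.label[u]
        M[[idx(u, v)]] <- if (lab == t2$tip.label[v]) lab else character(0)
      } else if (is_tip(t1, u)) {
        lab <- t1$tip.label[u]
        M[[idx(u, v)]] <- if (lab %in% tips2[[v]]) lab else character(0)
      } else if (is_tip(t2, v)) {
        lab <- t2$tip.label[v]
        M[[idx(u, v)]] <- if (lab %in% tips1[[u]]) lab else character(0)
      } else {
        u1 <- k1[[u]][1L]; u2 <- k1[[u]][2L]
        v1 <- k2[[v]][1L]; v2 <- k2[[v]][2L]
        cands <- list(
          M[[idx(u1, v)]], M[[idx(u2, v)]],
          M[[idx(u, v1)]], M[[idx(u, v2)]],
          sort(c(M[[idx(u1, v1)]], M[[idx(u2, v2)]]), method = "radix"),
          sort(c(M[[idx(u1, v2)]], M[[idx(u2, v1)]]), method = "radix"))
        M[[idx(u, v)]] <- best_set(cands)
      }
    }
  }
  leafset <- M[[idx(length(t1$tip.label) + 1L, length(t2$tip.label) + 1L)]]
  agreement_result(sort(leafset, method = "radix"),
                   restrict_tree(t1, leafset), TRUE)
}

is_tip <- function(tree, v) v <= length(tree$tip.label)

## every node in bottom-up order (children before parents), root last
node_postorder <- function(tree) {
  e <- ape::reorder.phylo(tree, "postorder")$edge
  c(e[, 2L], length(tree$tip.label) + 1L)
}

tipsets <- function(tree) {
  ntip <- length(tree$tip.label)
  n <- ntip + tree$Nnode
  out <- vector("list", n)
  for (i in seq_len(ntip)) out[[i]] <- tree$tip.label[i]
  e <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(e)))
    out[[e[i, 1L]]] <- c(out[[e[i, 1L]]], out[[e[i, 2L]]])
  out
}

## largest candidate set; ties broken by lexicographically smallest sorted
## name vector
best_set <- function(cands) {
  sizes <- lengths(cands)
  top <- which(sizes == max(sizes))
  best <- cands[[top[1L]]]
  for (i in top[-1L]) {
    if (set_less(cands[[i]], best)) best <- cands[[i]]
  }
  best
}

set_less <- function(a, b) {
  la <- length(a)
  for (i in seq_len(min(la, length(b)))) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

agreement_result <- function(leafset, tree, is_exact) {
  structure(list(leafset = leafset, tree = tree, is_exact = is_exact),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat("Agreement subtree on", length(x$leafset), "leaves (",
      if (x$is_exact) "exact" else "heuristic", ")\n")
  invisible(x)
}

#' Maximum agreement subtree of several trees
#'
#' For leaf sets of size at most `exact_limit` the exact MAST is found by
#' testing leaf subsets in decreasing size (lexicographic order within a
#' size, so ties resolve to the smallest name set).  Larger instances use a
#' heuristic: trees are folded through [mast_pair()] in input order and the
#' final leaf set is verified to be an agreement set for every input tree.
#' Tree sets larger than `cap` are first subsampled uniformly with the
#' given seed (logged via a message).
#'
#' @param trees list of binary rooted `"phylo"` objects, identical leaf
#'   sets.
#' @param exact_limit maximum leaf count for the exact subset search.
#' @param cap maximum number of trees folded; larger sets are subsampled.
#' @param seed seed for the subsampling draw.
#' @return an `"agreement_result"`; `is_exact` records which path ran.
#' @export
mast_k <- function(trees, exact_limit = 8L, cap = 100L, seed = 1L) {
  trees <- as_tree_list(trees)
  if (length(trees) < 2L) {
    t1 <- trees[[1L]]
    return(agreement_result(sort(t1$tip.label, method = "radix"), t1, TRUE))
  }
  check_same_leaves(trees)
  if (length(trees) > cap) {
    message("mast_k: subsampling ", cap, " of ", length(trees),
            " trees (seed ", seed, ")")
    keep <- with_seed(seed, sample.int(length(trees), cap))
    trees <- trees[sort(keep)]
  }
  labels <- sort(trees[[1L]]$tip.label, method = "radix")
  n <- length(labels)
  if (n <= exact_limit) {
    for (s in seq(n, 2L)) {
      combos <- utils::combn(labels, s, simplify = FALSE)
      for (L in combos) {
        if (is_agreement_set(trees, L))
          return(agreement_result(L, restrict_tree(trees[[1L]], L), TRUE))
      }
    }
    stop("internal error: no agreement set of size >= 2 found")
  }
  cur <- trees[[1L]]
  for (i in 2L:length(trees)) {
    other <- restrict_tree(trees[[i]], cur$tip.label)
    cur <- mast_pair(cur, other)$tree
  }
  L <- sort(cur$tip.label, method = "radix")
  if (!is_agreement_set(trees, L))
    stop("internal error: heuristic MAST produced a non-agreement set")
  agreement_result(L, restrict_tree(trees[[1L]], L), FALSE)
}

## does every tree induce the same topology on L?
is_agreement_set <- function(trees, L) {
  if (length(L) < 2L) return(FALSE)
  ref <- topology_key(restrict_tree(trees[[1L]], L))
  for (t in trees[-1L]) {
    if (topology_key(restrict_tree(t, L)) != ref) return(FALSE)
  }
  TRUE
}

## run code with a local RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
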
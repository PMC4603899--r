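## Weighted Fitch parsimony scoring and tree search over an MRP matrix.
## The search works in integer arithmetic: rational character weights are
## scaled by their least common denominator once, so length comparisons are
## exact.  Missing entries ("?") carry the full state set {0,1} and are
## never penalised.

## tip-state code matrix (nchar x ntaxa): 1 = {0}, 2 = {1}, 3 = {0,1}
tip_state_codes <- function(m) {
  S <- t(m$mat) + 1L
  S[is.na(S)] <- 3L
  storage.mode(S) <- "integer"
  S
}

#' Weighted Fitch parsimony length of a tree
#'
#' Computes the minimum number of character-state changes for every column
#' of an MRP matrix on the given binary rooted tree (Fitch set-intersection
#' pass) and returns the weight-summed total.  Missing entries behave as
#' the full state set and the result is invariant under rerooting.
#'
#' @param tree a binary rooted `"phylo"` whose leaf set equals the matrix
#'   taxa (including the outgroup).
#' @param matrix an `"mrp_matrix"`.
#' @return the weighted parsimony length (numeric; exact for the default
#'   integer-reciprocal weights).
#' @examples
#' ds <- supertree_dataset(list(source_record(read_newick("((A,B),C);"),
#'   "s1", 2001, "16S")))
#' m <- encode_brs(ds)
#' fitch_length(read_newick("(((A,B),C),MRP_Outgroup);"), m)
#' @export
fitch_length <- function(tree, matrix) {
  check_matrix_tree(tree, matrix)
  ct <- ct_from_phylo(tree, matrix$taxa)
  S <- tip_state_codes(matrix)
  L <- weight_scale(matrix)
  ct_fitch(ct, S, integer_weights(matrix)) / L
}

check_matrix_tree <- function(tree, matrix) {
  stopifnot(inherits(tree, "phylo"), inherits(matrix, "mrp_matrix"))
  lt <- sort(tree$tip.label)
  lm <- sort(matrix$taxa)
  if (!identical(lt, lm))
    stop("tree/matrix taxon mismatch: ",
         paste(c(setdiff(lt, lm), setdiff(lm, lt)), collapse = ", "))
  if (tree$Nnode != length(tree$tip.label) - 1L)
    stop("fitch_length requires a binary (fully resolved) tree")
  invisible(TRUE)
}

## ---- heuristic search ----------------------------------------------------

#' Heuristic parsimony search (random addition + SPR/TBR)
#'
#' Each replicate builds a starting tree by stepwise addition of the taxa
#' in random order (greedy best insertion), then applies rounds of SPR and
#' TBR branch swapping with first-improvement acceptance until no move
#' shortens the tree.  Optimal trees are pooled across replicates; when
#' `collect_ties` is set, the pool is expanded with equally parsimonious
#' SPR neighbours of stored trees (plateau exploration) up to `maxtrees`.
#' The outgroup is an ordinary taxon during the search and result trees are
#' rooted on it.  Identical `(matrix, seed, config)` give identical
#' results.
#'
#' @param matrix an `"mrp_matrix"`.
#' @param replicates number of random-addition replicates (>= 1).
#' @param seed integer seed; replicate i uses `seed + i`.
#' @param maxtrees cap on the number of stored most-parsimonious trees.
#' @param collect_ties expand the MPT pool with equal-length neighbours.
#' @return an object of class `"parsimony_search"`: `best_length`, `mpts`
#'   (list of binary `"phylo"` rooted on the outgroup), `replicates_run`,
#'   `seed`.
#' @export
heuristic_search <- function(matrix, replicates = 20L, seed = 1L,
                             maxtrees = 1000L, collect_ties = TRUE) {
  stopifnot(replicates >= 1L)
  if (maxtrees < 1L) stop("maxtrees must be >= 1")
  S <- tip_state_codes(matrix)
  wint <- integer_weights(matrix)
  L <- weight_scale(matrix)
  n <- length(matrix$taxa)
  if (n < 3L) stop("need at least 3 taxa")
  best <- Inf
  pool <- list()
  keys <- character(0)
  for (rep_i in seq_len(replicates)) {
    set.seed(seed + rep_i)
    ct <- ras_tree(matrix, S, wint)
    res <- swap_to_optimum(ct, S, wint)
    if (res$len < best) {
      best <- res$len
      pool <- list()
      keys <- character(0)
    }
    if (res$len == best) {
      phy <- root_on_outgroup(ct_to_phylo(res$ct, matrix$taxa),
                              matrix$outgroup)
      k <- topology_key(phy)
      if (!(k %in% keys) && length(pool) < maxtrees) {
        pool[[length(pool) + 1L]] <- phy
        keys <- c(keys, k)
      }
    }
  }
  if (collect_ties)
    pool <- expand_plateau(pool, keys, best, matrix, S, wint, maxtrees)
  structure(list(best_length = best / L, best_length_scaled = best,
                 weight_scale = L, mpts = pool,
                 replicates_run = replicates, seed = seed),
            class = "parsimony_search")
}

#' @export
print.parsimony_search <- function(x, ...) {
  cat("Parsimony search: best length", x$best_length, "with",
      length(x$mpts), "stored MPT(s) (", x$replicates_run,
      "replicate(s), seed", x$seed, ")\n")
  invisible(x)
}

## greedy random-addition-sequence starting tree
ras_tree <- function(m, S, wint) {
  n <- length(m$taxa)
  ord <- sample.int(n)
  ct <- ct_init_cherry(ct_new(n), ord[1L], ord[2L])
  for (i in 3L:n) {
    tip <- ord[i]
    sites <- ct_nodes(ct)
    bestlen <- Inf
    bestsite <- sites[1L]
    for (u in sites) {
      cand <- ct_insert_leaf(ct, tip, u)
      len <- ct_fitch(cand, S, wint)
      if (len < bestlen) {
        bestlen <- len
        bestsite <- u
      }
    }
    ct <- ct_insert_leaf(ct, tip, bestsite)
  }
  ct
}

## all (prune, regraft[, subtree-reroot]) neighbours; visitor returns TRUE
## to stop early (first-improvement)
visit_spr_neighbours <- function(ct, tbr = FALSE, visit) {
  n <- length(ct$act)
  nodes <- ct_nodes(ct)
  for (v in nodes) {
    if (v == ct$root) next
    if (ct$nact < 4L) next
    p <- ct$par[v]
    sib <- if (ct$kid1[p] == v) ct$kid2[p] else ct$kid1[p]
    pr <- ct_prune(ct, v)
    rest <- pr$ct
    w <- pr$freed
    ## regrafting above the old sibling recreates the original tree
    targets <- setdiff(ct_nodes(rest), c(ct_subtree_nodes(rest, v), sib))
    subroots <- v
    if (tbr && v > n) {
      inner <- setdiff(ct_subtree_nodes(rest, v),
                       c(v, ct$kid1[v], ct$kid2[v]))
      subroots <- c(subroots, inner)
    }
    for (sr in subroots) {
      base <- rest
      svr <- v
      if (sr != v) {
        base <- ct_reroot_subtree(rest, v, sr)
        svr <- v                           # reroot reuses v's id as root
      }
      for (u in targets) {
        cand <- ct_regraft(base, svr, w, u)
        if (isTRUE(visit(cand))) return(invisible(TRUE))
      }
    }
  }
  invisible(FALSE)
}

## first-improvement SPR then TBR until local optimum
swap_to_optimum <- function(ct, S, wint) {
  len <- ct_fitch(ct, S, wint)
  repeat {
    improved <- FALSE
    for (tbr in c(FALSE, TRUE)) {
      repeat {
        found <- FALSE
        visit_spr_neighbours(ct, tbr = tbr, visit = function(cand) {
          l <- ct_fitch(cand, S, wint)
          if (l < len) {
            ct <<- cand
            len <<- l
            found <<- TRUE
            improved <<- TRUE
            return(TRUE)
          }
          FALSE
        })
        if (!found) break
      }
    }
    if (!improved) break
  }
  list(ct = ct, len = len)
}

## expand the MPT pool with equal-length SPR neighbours (breadth-first over
## stored trees) up to maxtrees
expand_plateau <- function(pool, keys, best, m, S, wint, maxtrees) {
  i <- 1L
  while (i <= length(pool) && length(pool) < maxtrees) {
    ct <- ct_from_phylo(pool[[i]], m$taxa)
    visit_spr_neighbours(ct, tbr = FALSE, visit = function(cand) {
      if (length(pool) >= maxtrees) return(TRUE)
      if (ct_fitch(cand, S, wint) == best) {
        phy <- root_on_outgroup(ct_to_phylo(cand, m$taxa), m$outgroup)
        k <- topology_key(phy)
        if (!(k %in% keys)) {
          pool[[length(pool) + 1L]] <<- phy
          keys <<- c(keys, k)
        }
      }
      FALSE
    })
    i <- i + 1L
  }
  pool
}

## root a binary tree on a tip (outgroup becomes child of the root)
root_on_outgroup <- function(phy, outgroup) {
  if (!(outgroup %in% phy$tip.label)) return(phy)
  r <- ape::root.phylo(phy, outgroup = outgroup, resolve.root = TRUE)
  sanitize_tree(r)
}

## ---- exact search --------------------------------------------------------

#' Exact minimum-length search by branch and bound
#'
#' Enumerates unrooted binary topologies by stepwise taxon insertion,
#' pruning any partial tree whose length already exceeds the best complete
#' tree found (partial Fitch length never decreases as taxa are added).
#' Returns the exact minimum and the complete set of most parsimonious
#' trees, rooted on the outgroup.
#'
#' @param matrix an `"mrp_matrix"` with at most `max_taxa` taxa.
#' @param max_taxa safety limit (default 12); beyond it use
#'   [heuristic_search()].
#' @param maxtrees cap on stored MPTs.
#' @return a `"parsimony_search"` object with the exact `best_length`.
#' @export
branch_and_bound <- function(matrix, max_taxa = 12L, maxtrees = 10000L) {
  n <- length(matrix$taxa)
  if (n > max_taxa)
    stop("matrix has ", n, " taxa (> ", max_taxa,
         "); use heuristic_search()")
  if (n < 3L) stop("need at least 3 taxa")
  S <- tip_state_codes(matrix)
  wint <- integer_weights(matrix)
  L <- weight_scale(matrix)
  env <- new.env(parent = emptyenv())
  env$best <- Inf
  env$pool <- list()
  env$keys <- character(0)
  ## fix taxon 1 at the top: full tree = (taxon1, R); insert taxa 3..n into
  ## nodes of R only, enumerating each unrooted topology exactly once
  ct0 <- ct_init_cherry(ct_new(n), 1L, 2L)
  recurse_bnb(ct0, 3L, n, S, wint, matrix, env, maxtrees, prune = TRUE)
  structure(list(best_length = env$best / L, best_length_scaled = env$best,
                 weight_scale = L, mpts = env$pool,
                 replicates_run = NA_integer_, seed = NA_integer_),
            class = "parsimony_search")
}

recurse_bnb <- function(ct, nexttip, n, S, wint, m, env, maxtrees, prune) {
  len <- ct_fitch(ct, S, wint)
  if (prune && len > env$best) return(invisible(NULL))
  if (nexttip > n) {
    if (len < env$best) {
      env$best <- len
      env$pool <- list()
      env$keys <- character(0)
    }
    if (len == env$best && length(env$pool) < maxtrees) {
      phy <- root_on_outgroup(ct_to_phylo(ct, m$taxa), m$outgroup)
      k <- topology_key(phy)
      if (!(k %in% env$keys)) {
        env$pool[[length(env$pool) + 1L]] <- phy
        env$keys <- c(env$keys, k)
      }
    }
    return(invisible(NULL))
  }
  ## insertion above any node except the root and except tip 1 would
  ## duplicate unrooted placements; tip 1 is never an insertion point and
  ## the root edge is represented by inserting above the root's non-tip-1
  ## child
  sites <- setdiff(ct_nodes(ct), c(ct$root, 1L))
  for (u in sites)
    recurse_bnb(ct_insert_leaf(ct, nexttip, u), nexttip + 1L, n, S, wint,
                m, env, maxtrees, prune)
  invisible(NULL)
}

## exhaustive enumeration (no pruning); exported for small-scale validation
#' Exhaustive parsimony search
#'
#' Scores every unrooted binary topology (feasible only for very small
#' taxon sets); mainly useful to validate [branch_and_bound()] and
#' [heuristic_search()] on toy matrices.
#'
#' @inheritParams branch_and_bound
#' @export
exhaustive_search <- function(matrix, max_taxa = 9L, maxtrees = 100000L) {
  n <- length(matrix$taxa)
  if (n > max_taxa) stop("too many taxa for exhaustive enumeration")
  if (n < 3L) stop("need at least 3 taxa")
  S <- tip_state_codes(matrix)
  wint <- integer_weights(matrix)
  L <- weight_scale(matrix)
  env <- new.env(parent = emptyenv())
  env$best <- Inf
  env$pool <- list()
  env$keys <- character(0)
  ct0 <- ct_init_cherry(ct_new(n), 1L, 2L)
  recurse_bnb(ct0, 3L, n, S, wint, matrix, env, maxtrees, prune = FALSE)
  structure(list(best_length = env$best / L, best_length_scaled = env$best,
                 weight_scale = L, mpts = env$pool,
                 replicates_run = NA_integer_, seed = NA_integer_),
            class = "parsimony_search")
}
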
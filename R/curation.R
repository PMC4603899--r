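## Data-processing protocol applied to a raw dataset before MRP encoding:
## nomenclature standardisation, higher-taxon substitution, independence
## weighting/removal, taxonomic-overlap checking, and summary tables.
## Every operation returns the modified dataset together with a change log
## so a run can be audited decision by decision.

empty_log <- function() {
  data.frame(record = character(0), action = character(0),
             from = character(0), to = character(0),
             stringsAsFactors = FALSE)
}

log_row <- function(record, action, from = "", to = "") {
  data.frame(record = record, action = action, from = from, to = to,
             stringsAsFactors = FALSE)
}

#' Standardise leaf nomenclature with a synonym map
#'
#' Replaces every leaf label by its accepted name according to the
#' dataset's synonym map.  When standardisation makes two leaves of one
#' tree identical they are merged into a single leaf: the occurrence first
#' in a pre-order traversal (i.e. nearest the root among the pair) is kept
#' and the others are pruned, with a log entry.  Names absent from the map
#' pass through unchanged and are logged once per record.
#'
#' @param dataset a `"supertree_dataset"` whose `synonyms` map is loaded.
#' @return `list(dataset = <standardised dataset>, log = <data.frame>)`.
#' @export
standardize_names <- function(dataset) {
  syn <- dataset$synonyms
  logs <- list(empty_log())
  for (i in seq_along(dataset$records)) {
    rec <- dataset$records[[i]]
    labs <- rec$tree$tip.label
    hit <- labs %in% names(syn)
    newlabs <- labs
    newlabs[hit] <- unname(syn[labs[hit]])
    changed <- which(newlabs != labs)
    for (j in changed)
      logs[[length(logs) + 1L]] <-
        log_row(rec$id, "renamed", labs[j], newlabs[j])
    unmatched <- setdiff(unique(labs[!hit]), unname(syn))
    if (length(syn) && length(unmatched))
      logs[[length(logs) + 1L]] <-
        log_row(rec$id, "unmatched", paste(unmatched, collapse = ";"))
    rec$tree$tip.label <- newlabs
    ## merge duplicates created by the renaming: keep the pre-order-first
    ## occurrence, drop the rest
    rec$tree <- merge_duplicate_leaves(rec$tree, function(kept, dropped) {
      logs[[length(logs) + 1L]] <<- log_row(rec$id, "merged", dropped, kept)
    })
    dataset$records[[i]] <- rec
  }
  list(dataset = dataset, log = do.call(rbind, logs))
}

## preorder sequence of tip indices (cladewise edge order)
preorder_tips <- function(tree) {
  e <- ape::reorder.phylo(tree, "cladewise")$edge
  kids <- e[, 2L]
  kids[kids <= length(tree$tip.label)]
}

merge_duplicate_leaves <- function(tree, note = function(kept, dropped) {}) {
  repeat {
    labs <- tree$tip.label
    if (!anyDuplicated(labs)) return(tree)
    ord <- preorder_tips(tree)
    lab <- labs[ord[duplicated(labs[ord])]][1L]
    occ <- ord[labs[ord] == lab]
    note(lab, lab)
    if (length(labs) - (length(occ) - 1L) < 2L) {
      ## merging would leave fewer than two leaves: collapse to one leaf
      return(single_tip_tree(lab))
    }
    tree <- ape::drop.tip(tree, occ[-1L])
  }
}

#' Substitute higher-taxon leaves by polytomies of their constituents
#'
#' Each leaf whose label is a key of the dataset's taxonomy map is replaced
#' by a polytomy of those constituent species that occur in the *other*
#' source trees.  If that intersection is a single species the leaf is
#' simply renamed; if it is empty the leaf is deleted (and the tree
#' re-suppressed).  Constituents already present in the focal tree are
#' never duplicated.  Records reduced below two leaves are removed.
#'
#' @param dataset a `"supertree_dataset"` with standardised names and a
#'   loaded taxonomy map.
#' @return `list(dataset, log)` as for [standardize_names()].
#' @export
substitute_higher_taxa <- function(dataset) {
  tax <- dataset$taxonomy
  logs <- list(empty_log())
  if (length(tax) == 0L) return(list(dataset = dataset, log = logs[[1L]]))
  keys <- names(tax)
  leafsets <- lapply(dataset$records, function(r) r$tree$tip.label)
  drop_records <- integer(0)
  for (i in seq_along(dataset$records)) {
    rec <- dataset$records[[i]]
    other <- setdiff(unique(unlist(leafsets[-i])), keys)
    guard <- 0L
    repeat {
      guard <- guard + 1L
      if (guard > 1000L) {
        warning("higher-taxon substitution did not converge for record ",
                rec$id, " (cyclic taxonomy definitions?)")
        break
      }
      labs <- rec$tree$tip.label
      hit <- which(labs %in% keys)
      if (length(hit) == 0L) break
      tip <- hit[1L]
      label <- labs[tip]
      members <- sort(setdiff(intersect(tax[[label]], other), labs),
                      method = "radix")
      if (length(members) == 0L) {
        logs[[length(logs) + 1L]] <- log_row(rec$id, "ht_removed", label)
        if (length(labs) <= 2L) {
          rec$tree <- single_tip_tree(setdiff(labs, label))
        } else {
          rec$tree <- ape::drop.tip(rec$tree, tip)
        }
      } else if (length(members) == 1L) {
        rec$tree$tip.label[tip] <- members
        logs[[length(logs) + 1L]] <-
          log_row(rec$id, "ht_renamed", label, members)
      } else {
        star <- star_tree(members)
        rec$tree <- sanitize_tree(ape::bind.tree(rec$tree, star, where = tip))
        logs[[length(logs) + 1L]] <-
          log_row(rec$id, "ht_expanded", label,
                  paste(members, collapse = ";"))
      }
    }
    if (length(rec$tree$tip.label) < 2L) {
      drop_records <- c(drop_records, i)
      logs[[length(logs) + 1L]] <-
        log_row(rec$id, "record_removed", "fewer than 2 leaves left")
    }
    dataset$records[[i]] <- rec
  }
  if (length(drop_records))
    dataset$records <- dataset$records[-drop_records]
  list(dataset = dataset, log = do.call(rbind, logs))
}

star_tree <- function(labels) {
  n <- length(labels)
  stopifnot(n >= 2L)
  structure(list(edge = cbind(rep(n + 1L, n), seq_len(n)),
                 tip.label = labels, Nnode = 1L),
            class = "phylo", order = "cladewise")
}

#' Down-weight or remove non-independent source trees
#'
#' Two rules, following the definition of non-independence as identical or
#' nested data matrices:
#' \itemize{
#'   \item records with identical signatures (same character-type set and
#'     same taxon set) form a group of size k and each receives weight 1/k;
#'   \item when two records from the same study share their character types
#'     and one taxon set is a strict subset of the other, the less
#'     inclusive record is removed.  Cross-study subsets are only flagged
#'     in the report, never removed automatically.
#' }
#'
#' @param dataset a curated `"supertree_dataset"`.
#' @return `list(dataset, report)`; the report lists every adjustment.
#' @export
apply_independence <- function(dataset) {
  recs <- dataset$records
  logs <- list(empty_log())
  taxsets <- lapply(recs, function(r) sort(r$tree$tip.label, method = "radix"))
  chars <- lapply(recs, `[[`, "character_types")
  keys <- vapply(recs, `[[`, character(1L), "study_key")
  ids <- vapply(recs, `[[`, character(1L), "id")
  n <- length(recs)
  ## subset removal first: removed records take no part in the weighting
  remove <- rep(FALSE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || remove[i] || remove[j]) next
      if (!identical(chars[[i]], chars[[j]])) next
      if (length(taxsets[[i]]) >= length(taxsets[[j]])) next
      if (!all(taxsets[[i]] %in% taxsets[[j]])) next
      if (keys[i] == keys[j]) {
        remove[i] <- TRUE
        logs[[length(logs) + 1L]] <-
          log_row(ids[i], "removed_subset", to = ids[j])
      } else {
        logs[[length(logs) + 1L]] <-
          log_row(ids[i], "flagged_cross_study_subset", to = ids[j])
      }
    }
  }
  keep <- which(!remove)
  sig <- vapply(keep, function(i)
    paste(paste(chars[[i]], collapse = ";"),
          paste(taxsets[[i]], collapse = ";"), sep = "|"), character(1L))
  groups <- split(keep, sig)
  for (g in groups) {
    k <- length(g)
    if (k > 1L) {
      for (i in g) {
        recs[[i]]$weight_num <- 1L
        recs[[i]]$weight_den <- k
        logs[[length(logs) + 1L]] <-
          log_row(ids[i], "reweighted", to = sprintf("1/%d", k))
      }
    }
  }
  dataset$records <- recs[keep]
  list(dataset = dataset, report = do.call(rbind, logs))
}

#' Check taxonomic overlap among source trees
#'
#' Builds a graph with one vertex per record and an edge wherever two
#' records share at least `min_shared` taxa, then reports its connected
#' components.  The dataset passes when the graph is a single component;
#' on failure the records outside the largest component are listed as
#' candidates for removal.
#'
#' @param dataset a `"supertree_dataset"` with at least two records.
#' @param min_shared minimum number of shared taxa per edge (default 2).
#' @return a list with elements `pass` (logical), `membership` (integer
#'   component id per record, named by record id), `n_components`, and
#'   `removal_candidates` (record ids outside the largest component).
#' @export
check_overlap <- function(dataset, min_shared = 2L) {
  n <- length(dataset$records)
  if (n < 2L) stop("overlap check needs at least two records")
  taxsets <- lapply(dataset$records, function(r) r$tree$tip.label)
  ids <- record_ids(dataset)
  adj <- matrix(0L, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (length(intersect(taxsets[[i]], taxsets[[j]])) >= min_shared)
        adj[i, j] <- adj[j, i] <- 1L
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  membership <- stats::setNames(as.integer(comp$membership), ids)
  biggest <- which.max(comp$csize)
  list(pass = comp$no == 1L,
       membership = membership,
       n_components = as.integer(comp$no),
       removal_candidates = ids[membership != biggest])
}

#' Summary tables for a dataset
#'
#' Reproduces the standard descriptive summaries of a source-tree
#' collection: trees per publication year, character types per year, taxon
#' presence counts (optionally partitioned by a user-supplied grouping such
#' as family membership), and the source-tree size distribution.
#'
#' @param dataset a `"supertree_dataset"`.
#' @param grouping optional named character vector mapping taxon name to a
#'   group label for the presence table.
#' @return a list of data.frames: `trees_per_year`,
#'   `character_types_per_year`, `taxon_presence`, `tree_sizes`.
#' @export
dataset_summary <- function(dataset, grouping = NULL) {
  recs <- dataset$records
  if (length(recs) == 0L) {
    e <- data.frame()
    return(list(trees_per_year = data.frame(year = integer(0), n = integer(0)),
                character_types_per_year =
                  data.frame(year = integer(0), character_type = character(0),
                             n = integer(0)),
                taxon_presence = data.frame(taxon = character(0),
                                            group = character(0),
                                            n_trees = integer(0)),
                tree_sizes = data.frame(id = character(0), size = integer(0))))
  }
  years <- vapply(recs, `[[`, integer(1L), "year")
  yt <- as.data.frame(table(year = years), stringsAsFactors = FALSE)
  trees_per_year <- data.frame(year = as.integer(yt$year), n = yt$Freq)
  ct <- do.call(rbind, lapply(recs, function(r)
    data.frame(year = r$year, character_type = r$character_types,
               stringsAsFactors = FALSE)))
  cpt <- stats::aggregate(list(n = rep(1L, nrow(ct))),
                          by = ct[c("year", "character_type")], FUN = sum)
  cpt <- cpt[order(cpt$year, cpt$character_type), , drop = FALSE]
  rownames(cpt) <- NULL
  taxa <- unlist(lapply(recs, function(r) unique(r$tree$tip.label)))
  pres <- as.data.frame(table(taxon = taxa), stringsAsFactors = FALSE)
  taxon_presence <- data.frame(taxon = pres$taxon,
                               group = if (is.null(grouping)) NA_character_
                               else unname(grouping[pres$taxon]),
                               n_trees = pres$Freq,
                               stringsAsFactors = FALSE)
  tree_sizes <- data.frame(id = record_ids(dataset),
                           size = vapply(recs, function(r)
                             length(r$tree$tip.label), integer(1L)),
                           stringsAsFactors = FALSE)
  list(trees_per_year = trees_per_year,
       character_types_per_year = cpt,
       taxon_presence = taxon_presence,
       tree_sizes = tree_sizes)
}
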
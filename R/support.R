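## Per-node supertree support against the source trees.  Every supertree
## clade is scored against every source tree as supporting (the clade's
## restriction to the source taxa is a clade of the source tree),
## conflicting (some source clade overlaps it without nesting), permitting
## (neither, e.g. compatible polytomies), or irrelevant (fewer than two
## clade members, or no outside taxon, in the source tree).  Counts give
##   V  = (s - q) / (s + q)
##   V+ = (s + p - q) / (s + p + q)
## Both lie in [-1, 1]; V+ >= V whenever both are defined.  Nodes that no
## source tree can evaluate get NA, never 0: a balance of support and
## conflict is a different statement from irrelevance.

#' Classify one source tree against one supertree clade
#'
#' @param node character vector: the leaf set of a supertree clade.
#' @param record a `"source_record"` (or a bare `"phylo"`).
#' @return one of `"support"`, `"conflict"`, `"permit"`, `"irrelevant"`.
#' @examples
#' classify_source_tree(c("A", "B"), read_newick("((A,B),C);"))   # support
#' classify_source_tree(c("A", "B"), read_newick("((A,C),B);"))   # conflict
#' classify_source_tree(c("A", "B"), read_newick("(A,B,C);"))     # permit
#' @export
classify_source_tree <- function(node, record) {
  tree <- if (inherits(record, "source_record")) record$tree else record
  classify_clade(node, tree$tip.label, clades(tree))
}

classify_clade <- function(node, leaves, tree_clades) {
  A <- intersect(node, leaves)
  B <- setdiff(leaves, node)
  if (length(A) < 2L || length(B) < 1L) return("irrelevant")
  A <- sort(A, method = "radix")
  akey <- paste(A, collapse = "\r")
  for (X in tree_clades) {
    if (identical(paste(X, collapse = "\r"), akey)) return("support")
  }
  for (X in tree_clades) {
    ix <- length(intersect(A, X))
    if (ix > 0L && ix < length(A) && ix < length(X)) return("conflict")
  }
  "permit"
}

#' V and V+ support indices for every supertree node
#'
#' Counts, for each nontrivial supertree clade, the source trees that
#' support (s), conflict with (q), permit (p) or are irrelevant to (r) the
#' clade, and derives the V and V+ indices.  Counts are per source tree and
#' unweighted (independence weights do not enter support scoring).
#'
#' @param supertree a `"phylo"`; the outgroup, if present, is dropped
#'   before scoring.
#' @param dataset the curated `"supertree_dataset"` the supertree was
#'   built from.
#' @param outgroup outgroup name to drop (default `"MRP_Outgroup"`).
#' @return a data.frame of class `"node_support"` with one row per
#'   nontrivial clade: `node` (ape node number), `clade`
#'   (semicolon-joined members), `size`, `s`, `q`, `p`, `r`, `V`, `V_plus`
#'   (`NA` where undefined) and `category` (`"V=1"`, `"0<V<1"`, `"V=0"`,
#'   `"V<0"`, `"undefined"`).  The supertree actually scored is attached as
#'   attribute `"supertree"`.
#' @export
v_indices <- function(supertree, dataset, outgroup = "MRP_Outgroup") {
  if (outgroup %in% supertree$tip.label)
    supertree <- restrict_tree(supertree,
                               setdiff(supertree$tip.label, outgroup))
  cl <- clades(supertree)
  recs <- dataset$records
  leaves_list <- lapply(recs, function(r) r$tree$tip.label)
  clades_list <- lapply(recs, function(r) clades(r$tree))
  rows <- lapply(seq_along(cl), function(i) {
    node <- cl[[i]]
    cls <- vapply(seq_along(recs), function(j)
      classify_clade(node, leaves_list[[j]], clades_list[[j]]),
      character(1L))
    s <- sum(cls == "support")
    q <- sum(cls == "conflict")
    p <- sum(cls == "permit")
    r <- sum(cls == "irrelevant")
    V <- if (s + q > 0L) (s - q) / (s + q) else NA_real_
    Vp <- if (s + p + q > 0L) (s + p - q) / (s + p + q) else NA_real_
    data.frame(node = as.integer(names(cl)[i]),
               clade = paste(node, collapse = ";"),
               size = length(node), s = s, q = q, p = p, r = r,
               V = V, V_plus = Vp,
               category = v_category(V), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(node = integer(0), clade = character(0),
                      size = integer(0), s = integer(0), q = integer(0),
                      p = integer(0), r = integer(0), V = numeric(0),
                      V_plus = numeric(0), category = character(0))
  attr(out, "supertree") <- supertree
  class(out) <- c("node_support", class(out))
  out
}

## colour classes used when plotting supertrees with support superimposed
v_category <- function(V) {
  if (is.na(V)) return("undefined")
  if (V == 1) return("V=1")
  if (V > 0) return("0<V<1")
  if (V == 0) return("V=0")
  "V<0"
}

#' Novel (unsupported but evaluable) supertree clades
#'
#' A known artefact of MRP is the creation of clades present in no source
#' tree.  A clade is *novel* when no source tree supports it (s = 0) while
#' at least one is relevant to it (q + p >= 1).  Clades irrelevant to every
#' source tree are reported separately: they are vacuously absent rather
#' than contradicted.
#'
#' @inheritParams v_indices
#' @return a list with `novel` and `unevaluable`, each a `"node_support"`
#'   subset of the full table.
#' @export
novel_clades <- function(supertree, dataset, outgroup = "MRP_Outgroup") {
  ns <- v_indices(supertree, dataset, outgroup)
  list(novel = ns[ns$s == 0L & (ns$q + ns$p) >= 1L, , drop = FALSE],
       unevaluable = ns[ns$s + ns$q + ns$p == 0L, , drop = FALSE])
}

#' Write node-support results
#'
#' `write_support_csv()` writes the per-node table; `write_support_tree()`
#' writes the scored supertree in Newick with V values as internal node
#' labels.
#'
#' @param ns a `"node_support"` table from [v_indices()].
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_support_csv <- function(ns, file) {
  utils::write.csv(as.data.frame(ns), file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_support_csv
#' @export
write_support_tree <- function(ns, file) {
  tree <- attr(ns, "supertree")
  if (is.null(tree)) stop("no supertree attached to this support table")
  nmax <- length(tree$tip.label) + tree$Nnode
  labels <- rep(NA_character_, nmax)
  labels[ns$node] <- ifelse(is.na(ns$V), "NA", formatC(ns$V, format = "g"))
  write_newick(tree, file = file, node_labels = labels)
}
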
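## Rooted-tree input/output and the clade primitives used throughout the
## package.  Trees are ape "phylo" objects; polytomies are allowed, branch
## lengths and internal node labels are read but discarded (the pipeline
## never uses them), and unifurcations are suppressed on input.

#' Parse a rooted tree from a Newick string
#'
#' Reads one rooted tree in Newick format.  Underscores in unquoted labels
#' are kept as literal underscores (not translated to spaces); quoted labels
#' may contain any character.  Branch lengths and internal node labels are
#' accepted and silently dropped.  Unifurcations (internal nodes with a
#' single child) are suppressed so that every internal node of the returned
#' tree has at least two children.
#'
#' @param text a character string containing one Newick tree terminated by
#'   `";"`.
#' @param file alternatively, path to a file whose first tree is read.
#' @return an object of class `"phylo"`.
#' @examples
#' tr <- read_newick("((A,B),C);")
#' clades(tr)
#' @export
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text)) {
    if (is.null(file)) stop("supply 'text' or 'file'")
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  text <- trimws(text)
  validate_newick_syntax(text)
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) stop("Newick parse error: ",
                                           conditionMessage(e), call. = FALSE))
  if (is.null(phy)) stop("Newick parse error: unreadable tree string")
  if (inherits(phy, "multiPhylo")) phy <- phy[[1L]]
  sanitize_tree(phy)
}

## Cheap syntactic scan so that malformed input is reported with a character
## position instead of an opaque downstream failure.  Not a parser: only
## bracket balance, quoting and the terminating semicolon are checked.
validate_newick_syntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  depth <- 0L
  quoted <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (quoted) {
      if (ch == "'") quoted <- FALSE
      next
    }
    if (ch == "'") quoted <- TRUE
    else if (ch == "(") depth <- depth + 1L
    else if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("Newick parse error: unmatched ')' at character ", i,
             call. = FALSE)
    }
  }
  if (quoted) stop("Newick parse error: unterminated quoted label",
                   call. = FALSE)
  if (depth > 0L)
    stop("Newick parse error: ", depth, " unclosed '(' at end of string",
         call. = FALSE)
  if (!grepl(";\\s*$", text))
    stop("Newick parse error: missing terminating ';' at character ",
         nchar(text), call. = FALSE)
  invisible(TRUE)
}

## Normalise a freshly parsed (or manipulated) tree: strip quotes ape leaves
## on labels, drop lengths/internal labels, suppress unifurcations, and
## enforce unique leaf labels.
sanitize_tree <- function(phy) {
  phy$tip.label <- unquote_label(phy$tip.label)
  if (!is.null(phy$edge.length)) phy$edge.length <- NULL
  if (!is.null(phy$node.label)) phy$node.label <- NULL
  if (!is.null(phy$root.edge)) phy$root.edge <- NULL
  phy <- ape::collapse.singles(phy)
  dup <- unique(phy$tip.label[duplicated(phy$tip.label)])
  if (length(dup))
    stop("duplicate leaf label(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  phy
}

unquote_label <- function(x) {
  q <- grepl("^'.*'$", x)
  x[q] <- gsub("''", "'", sub("^'(.*)'$", "\\1", x[q]))
  x
}

needs_quoting <- function(x) grepl("[][ (){}:;,'\"]", x)

format_label <- function(x) {
  q <- needs_quoting(x)
  x[q] <- paste0("'", gsub("'", "''", x[q]), "'")
  x
}

#' Write a rooted tree as a canonical Newick string
#'
#' Output is deterministic: at every internal node the children are ordered
#' by the lexicographically smallest leaf label they subtend, so that two
#' topologically identical trees always serialise to the same bytes.  Labels
#' containing spaces, brackets or other Newick metacharacters are
#' single-quoted; underscores are written literally.
#'
#' @param tree a `"phylo"` object.
#' @param file optional path; when given the string is also written there.
#' @param node_labels optional character vector of labels for internal
#'   nodes, indexed by ape node number (used e.g. to annotate support
#'   values); `NA` entries are omitted.
#' @return the Newick string, invisibly when `file` is given.
#' @export
write_newick <- function(tree, file = NULL, node_labels = NULL) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  kids <- children_list(tree)
  rec <- function(v) {
    if (v <= ntip)
      return(list(str = format_label(tree$tip.label[v]),
                  min = tree$tip.label[v]))
    parts <- lapply(kids[[v]], rec)
    keys <- vapply(parts, `[[`, character(1L), "min")
    ord <- order(keys, method = "radix")
    lab <- ""
    if (!is.null(node_labels) && length(node_labels) >= v &&
        !is.na(node_labels[v]))
      lab <- node_labels[v]
    list(str = paste0("(", paste(vapply(parts[ord], `[[`, character(1L),
                                        "str"), collapse = ","), ")", lab),
         min = min(keys))
  }
  out <- if (ntip == 1L) paste0(format_label(tree$tip.label), ";") else
    paste0(rec(ntip + 1L)$str, ";")
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

## children of every node as a list indexed by ape node number
children_list <- function(tree) {
  n <- length(tree$tip.label) + tree$Nnode
  kids <- vector("list", n)
  e <- tree$edge
  for (i in seq_len(nrow(e))) kids[[e[i, 1L]]] <- c(kids[[e[i, 1L]]], e[i, 2L])
  kids
}

#' Nontrivial clades of a rooted tree
#'
#' Returns the set of leaf-label sets subtended by each internal node other
#' than the root.  Singleton "clades" cannot occur (every internal node has
#' at least two children) and the root clade (all leaves) is excluded.
#'
#' @param tree a `"phylo"` object.
#' @return a named list of sorted character vectors; names are ape node
#'   numbers.
#' @examples
#' clades(read_newick("((A,B),(C,D));"))
#' @export
clades <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  if (ntip < 3L || tree$Nnode < 2L) return(structure(list(), names = character(0)))
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  out <- lapply(pp, function(idx) sort(labs[idx], method = "radix"))
  names(out) <- as.character(ntip + seq_along(out))
  keep <- vapply(out, length, integer(1L)) < ntip
  keep[1L] <- FALSE                      # root
  out[keep]
}

#' Restrict a tree to a subset of its leaves
#'
#' Computes the subtree induced by `keep`, suppressing any unifurcations the
#' pruning creates.  The clades of the result are exactly the nontrivial
#' intersections of the original clades with `keep`.
#'
#' @param tree a `"phylo"` object.
#' @param keep character vector of leaf labels to retain; labels absent from
#'   the tree are ignored, but the intersection must be nonempty.
#' @return a `"phylo"` object on `intersect(keep, tree$tip.label)`.
#' @export
restrict_tree <- function(tree, keep) {
  stopifnot(inherits(tree, "phylo"))
  keep <- intersect(tree$tip.label, keep)
  if (length(keep) == 0L)
    stop("restriction is empty: no requested leaf occurs in the tree")
  if (length(keep) == length(tree$tip.label)) return(tree)
  if (length(keep) == 1L) return(single_tip_tree(keep))
  ape::keep.tip(tree, keep)
}

single_tip_tree <- function(label) {
  structure(list(edge = matrix(c(2L, 1L), 1L, 2L), tip.label = label,
                 Nnode = 1L), class = "phylo", order = "cladewise")
}

#' Robinson-Foulds distance between two rooted trees
#'
#' The symmetric-difference count between the two trees' nontrivial clade
#' sets (rooted convention: clades are leaf sets subtended by internal
#' nodes, so the distance between `((A,B),C)` and `((A,C),B)` is 2).
#'
#' @param t1,t2 `"phylo"` objects on identical leaf sets.
#' @return a non-negative integer; 0 iff the trees are topologically
#'   identical as rooted trees.
#' @export
rf_distance <- function(t1, t2) {
  l1 <- sort(t1$tip.label)
  l2 <- sort(t2$tip.label)
  if (!identical(l1, l2))
    stop("leaf sets differ: ",
         paste(c(setdiff(l1, l2), setdiff(l2, l1)), collapse = ", "))
  k1 <- clade_keys(t1)
  k2 <- clade_keys(t2)
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

clade_keys <- function(tree) {
  unique(vapply(clades(tree), paste, character(1L), collapse = "\r"))
}

#' Read trees from a NEXUS TREES block
#'
#' Reads all trees from a NEXUS file, honouring any TRANSLATE table.  All
#' non-TREES blocks are ignored with a warning.  Each tree is normalised as
#' by [read_newick()].
#'
#' @param file path to a NEXUS file.
#' @return a list of `"phylo"` objects.
#' @export
read_nexus_trees <- function(file) {
  txt <- toupper(paste(readLines(file, warn = FALSE), collapse = "\n"))
  blocks <- unique(unlist(regmatches(txt, gregexpr("BEGIN +([A-Z]+)", txt))))
  other <- setdiff(sub("BEGIN +", "", blocks), "TREES")
  if (length(other))
    warning("ignoring non-TREES NEXUS block(s): ",
            paste(other, collapse = ", "), call. = FALSE)
  trs <- ape::read.nexus(file)
  if (inherits(trs, "phylo")) trs <- list(trs)
  lapply(trs, sanitize_tree)
}

## canonical topology fingerprint used for deduplication throughout
topology_key <- function(tree) write_newick(tree)
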
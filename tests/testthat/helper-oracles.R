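# Independent oracles used across the suite.  These deliberately take the
# slow, direct route (state-assignment enumeration, subset search, full
# topology enumeration) so they share no code path with the implementations
# they check.

# Minimum state changes for one binary character by brute force: enumerate
# 0/1 assignments to all internal nodes and all "?" tips, count edges whose
# endpoints differ, and minimise.  states: named vector over taxa with
# values 0, 1 or NA (missing).
bf_fitch_char <- function(tree, states) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  tipstate <- unname(states[tree$tip.label])
  free_tips <- which(is.na(tipstate))
  nfree <- nnode + length(free_tips)
  best <- Inf
  for (mask in 0:(2^nfree - 1)) {
    bits <- as.integer(intToBits(mask))[seq_len(nfree)]
    full <- c(tipstate, bits[seq_len(nnode)])
    if (length(free_tips))
      full[free_tips] <- bits[nnode + seq_along(free_tips)]
    changes <- sum(full[tree$edge[, 1]] != full[tree$edge[, 2]])
    if (changes < best) best <- changes
  }
  best
}

# Weighted brute-force parsimony length of a tree against an mrp_matrix.
bf_length <- function(tree, m) {
  w <- m$w_num / m$w_den
  total <- 0
  for (j in seq_len(ncol(m$mat))) {
    states <- m$mat[, j]
    names(states) <- m$taxa
    total <- total + w[j] * bf_fitch_char(tree, states)
  }
  total
}

# All rooted binary topologies on the given labels, built by stepwise
# insertion over nested lists (independent of the package's enumeration).
enumerate_topologies <- function(labels) {
  grow <- function(shape, lab) {
    if (is.character(shape))
      return(list(list(shape, lab)))
    out <- list(list(shape, lab))
    for (k in 1:2) {
      for (sub in grow(shape[[k]], lab)) {
        s2 <- shape
        s2[[k]] <- sub
        out <- c(out, list(s2))
      }
    }
    out
  }
  acc <- list(list(labels[1], labels[2]))
  for (lab in labels[-(1:2)]) {
    acc <- unlist(lapply(acc, grow, lab = lab), recursive = FALSE)
  }
  acc
}

shape_to_newick <- function(shape) {
  rec <- function(s) {
    if (is.character(s)) return(s)
    paste0("(", rec(s[[1]]), ",", rec(s[[2]]), ")")
  }
  paste0(rec(shape), ";")
}

# Exhaustive-maximisation MAST size for two trees on identical leaf sets.
bf_mast_size <- function(t1, t2) {
  labs <- sort(t1$tip.label)
  for (s in seq(length(labs), 2)) {
    for (L in utils::combn(labs, s, simplify = FALSE)) {
      if (write_newick(restrict_tree(t1, L)) ==
          write_newick(restrict_tree(t2, L)))
        return(s)
    }
  }
  0L
}

# Small curated dataset used by several files: three overlapping source
# trees on six taxa.
toy_dataset <- function() {
  supertree_dataset(list(
    source_record(read_newick("(((A,B),C),D);"), "studyA", 2001, "16S"),
    source_record(read_newick("((C,D),E);"), "studyB", 2005, "COI"),
    source_record(read_newick("(((D,E),F),A);"), "studyC", 2010,
                  "morphology")))
}

random_mrp_matrix <- function(n_taxa, n_chars, seed) {
  set.seed(seed)
  taxa <- c("OG", paste0("x", seq_len(n_taxa - 1L)))
  repeat {
    mat <- matrix(NA_integer_, n_taxa, n_chars,
                  dimnames = list(taxa, sprintf("c%04d", seq_len(n_chars))))
    for (j in seq_len(n_chars)) {
      repeat {
        present <- c(TRUE, runif(n_taxa - 1L) > 0.2)
        if (sum(present) >= 4L) break
      }
      np <- sum(present)
      k <- sample(2:(np - 2L), 1L)
      ones <- sample(which(present)[-1L], k)
      col <- rep(NA_integer_, n_taxa)
      col[present] <- 0L
      col[ones] <- 1L
      mat[, j] <- col
    }
    ok <- apply(mat, 2, function(cc)
      sum(cc == 1L, na.rm = TRUE) >= 2 && sum(cc == 0L, na.rm = TRUE) >= 1)
    if (all(ok)) break
  }
  mrptree:::new_mrp_matrix(mat, rep(1L, n_chars), rep(1L, n_chars), "OG")
}
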
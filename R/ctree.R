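## Internal lightweight representation of rooted binary trees used by the
## parsimony searches.  Nodes are integers: tips 1..n (aligned with a fixed
## label vector), internal nodes n+1..2n-1.  A ctree is a list with
##   par  : integer parent vector (0 for the root)
##   kid1 : integer first-child vector (0 for tips / unused slots)
##   kid2 : integer second-child vector
##   root : integer root id
##   nact : number of tips currently in the tree (for incremental builds)
##   act  : logical, which tip ids are present
## Unused internal slots have par = -1.  All move functions are pure: they
## return a modified copy.

ct_new <- function(ntips_total) {
  n <- ntips_total
  list(par = c(rep(0L, n), rep(-1L, n - 1L)),
       kid1 = integer(2L * n - 1L),
       kid2 = integer(2L * n - 1L),
       root = 0L, nact = 0L,
       act = rep(FALSE, n))
}

## start a tree from a cherry of two tip ids
ct_init_cherry <- function(ct, a, b) {
  n <- length(ct$act)
  r <- n + 1L
  ct$kid1[r] <- a; ct$kid2[r] <- b
  ct$par[a] <- r; ct$par[b] <- r; ct$par[r] <- 0L
  ct$root <- r
  ct$act[c(a, b)] <- TRUE
  ct$nact <- 2L
  ct
}

## free internal slot (first unused internal id)
ct_free_slot <- function(ct) {
  n <- length(ct$act)
  which(ct$par[(n + 1L):(2L * n - 1L)] == -1L)[1L] + n
}

## insert tip 'tip' above node 'u' (u may be the root: a new root is made)
ct_insert_leaf <- function(ct, tip, u) {
  w <- ct_free_slot(ct)
  p <- ct$par[u]
  ct$kid1[w] <- u; ct$kid2[w] <- tip
  ct$par[u] <- w; ct$par[tip] <- w
  if (p == 0L) {
    ct$par[w] <- 0L
    ct$root <- w
  } else {
    if (ct$kid1[p] == u) ct$kid1[p] <- w else ct$kid2[p] <- w
    ct$par[w] <- p
  }
  ct$act[tip] <- TRUE
  ct$nact <- ct$nact + 1L
  ct
}

## active node ids (tips and internals) in a valid ctree
ct_nodes <- function(ct) {
  n <- length(ct$act)
  c(which(ct$act), which(ct$par[(n + 1L):(2L * n - 1L)] != -1L) + n)
}

## postorder sequence of internal nodes (children before parents)
ct_postorder <- function(ct) {
  n <- length(ct$act)
  out <- integer(0L)
  stack <- ct$root
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (v > n) {
      out <- c(out, v)
      stack <- c(stack, ct$kid1[v], ct$kid2[v])
    }
  }
  rev(out)
}

## tip ids in the subtree rooted at v
ct_subtree_tips <- function(ct, v) {
  n <- length(ct$act)
  tips <- integer(0L)
  stack <- v
  while (length(stack)) {
    x <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (x <= n) tips <- c(tips, x)
    else stack <- c(stack, ct$kid1[x], ct$kid2[x])
  }
  tips
}

## all node ids in the subtree rooted at v (including v)
ct_subtree_nodes <- function(ct, v) {
  n <- length(ct$act)
  nodes <- integer(0L)
  stack <- v
  while (length(stack)) {
    x <- stack[length(stack)]
    stack <- stack[-length(stack)]
    nodes <- c(nodes, x)
    if (x > n) stack <- c(stack, ct$kid1[x], ct$kid2[x])
  }
  nodes
}

## Weighted Fitch length.  S is an integer matrix (nchar x ntips_total) of
## state codes: 1 = {0}, 2 = {1}, 3 = {0,1} ("?").  wint: integer character
## weights.  Returns total weighted changes (integer arithmetic).
ct_fitch <- function(ct, S, wint) {
  n <- length(ct$act)
  nc <- nrow(S)
  states <- matrix(0L, nc, 2L * n - 1L)
  states[, seq_len(n)] <- S
  changes <- integer(nc)
  for (v in ct_postorder(ct)) {
    a <- states[, ct$kid1[v]]
    b <- states[, ct$kid2[v]]
    i <- bitwAnd(a, b)
    z <- i == 0L
    if (any(z)) {
      changes[z] <- changes[z] + 1L
      i[z] <- bitwOr(a, b)[z]
    }
    states[, v] <- i
  }
  sum(as.numeric(wint) * changes)
}

## Prune the subtree rooted at v.  Returns list(ct = remaining tree with the
## parent of v suppressed, sub_root = v, freed = suppressed node id).
## v must not be the root nor a child of a two-child root whose other child
## would vanish -- callers guarantee v != root and nact >= 3.
ct_prune <- function(ct, v) {
  p <- ct$par[v]
  sib <- if (ct$kid1[p] == v) ct$kid2[p] else ct$kid1[p]
  g <- ct$par[p]
  if (g == 0L) {
    ct$root <- sib
    ct$par[sib] <- 0L
  } else {
    if (ct$kid1[g] == p) ct$kid1[g] <- sib else ct$kid2[g] <- sib
    ct$par[sib] <- g
  }
  ct$par[p] <- -1L
  ct$kid1[p] <- 0L; ct$kid2[p] <- 0L
  list(ct = ct, freed = p)
}

## Regraft a previously pruned subtree (root sv) above node u of ct, reusing
## freed internal id w.  u may be ct$root (new root is created).
ct_regraft <- function(ct, sv, w, u) {
  p <- ct$par[u]
  ct$kid1[w] <- u; ct$kid2[w] <- sv
  ct$par[u] <- w; ct$par[sv] <- w
  if (p == 0L) {
    ct$par[w] <- 0L
    ct$root <- w
  } else {
    if (ct$kid1[p] == u) ct$kid1[p] <- w else ct$kid2[p] <- w
    ct$par[w] <- p
  }
  ct
}

## Reroot the detached subtree rooted at v at the edge above node x (x a
## node inside the subtree, x != v and x not a child of v with the other
## child a leaf... any x in subtree, x != v).  The old root v is suppressed
## and its id reused for the new root, so the node-id set is unchanged.
## Returns the new subtree root id (== v).
ct_reroot_subtree <- function(ct, v, x) {
  n <- length(ct$act)
  ## collect directed edges of the subtree, then treat as undirected
  nodes <- ct_subtree_nodes(ct, v)
  adj <- new.env(hash = TRUE)
  addedge <- function(a, b) {
    ka <- as.character(a); kb <- as.character(b)
    adj[[ka]] <- c(if (!is.null(adj[[ka]])) adj[[ka]], b)
    adj[[kb]] <- c(if (!is.null(adj[[kb]])) adj[[kb]], a)
  }
  for (z in nodes) {
    if (z > n) {
      addedge(z, ct$kid1[z])
      addedge(z, ct$kid2[z])
    }
  }
  ## suppress old root v: join its two neighbours
  vk <- ct$kid1[v]; vk2 <- ct$kid2[v]
  adj[[as.character(vk)]] <- c(setdiff(adj[[as.character(vk)]], v), vk2)
  adj[[as.character(vk2)]] <- c(setdiff(adj[[as.character(vk2)]], v), vk)
  ## new root v sits on the edge (x, old-parent-of-x); orient away from v
  px <- ct$par[x]
  if (px == v) px <- if (vk == x) vk2 else vk
  ## detach edge x -- px, root between them
  adj[[as.character(x)]] <- setdiff(adj[[as.character(x)]], px)
  adj[[as.character(px)]] <- setdiff(adj[[as.character(px)]], x)
  ct$kid1[v] <- x; ct$kid2[v] <- px
  ct$par[x] <- v; ct$par[px] <- v; ct$par[v] <- 0L
  ## BFS orientation for the rest
  queue <- c(x, px)
  seen <- c(v, x, px)
  while (length(queue)) {
    a <- queue[1L]; queue <- queue[-1L]
    if (a <= n) next
    nb <- setdiff(adj[[as.character(a)]], seen)
    stopifnot(length(nb) == 2L)
    ct$kid1[a] <- nb[1L]; ct$kid2[a] <- nb[2L]
    ct$par[nb[1L]] <- a; ct$par[nb[2L]] <- a
    seen <- c(seen, nb)
    queue <- c(queue, nb)
  }
  ct
}

## convert an active ctree to phylo (labels: full tip label vector)
ct_to_phylo <- function(ct, labels) {
  n <- length(ct$act)
  tips <- which(ct$act)
  internals <- setdiff(ct_nodes(ct), tips)
  ntip <- length(tips)
  tipmap <- integer(2L * n - 1L)
  tipmap[tips] <- seq_len(ntip)
  ## internal numbering: root first (ape convention), then others
  internals <- c(ct$root, setdiff(internals, ct$root))
  tipmap[internals] <- ntip + seq_along(internals)
  edges <- matrix(0L, ntip + length(internals) - 1L, 2L)
  r <- 0L
  for (v in internals) {
    for (k in c(ct$kid1[v], ct$kid2[v])) {
      r <- r + 1L
      edges[r, ] <- c(tipmap[v], tipmap[k])
    }
  }
  phy <- structure(list(edge = edges, tip.label = labels[tips],
                        Nnode = length(internals)), class = "phylo")
  ape::reorder.phylo(phy, "cladewise")
}

## build a ctree from a rooted *binary* phylo whose tip labels are a subset
## of 'labels' (tip ids follow positions in 'labels')
ct_from_phylo <- function(phy, labels) {
  n <- length(labels)
  ntip <- length(phy$tip.label)
  stopifnot(phy$Nnode == ntip - 1L)
  ct <- ct_new(n)
  idx <- match(phy$tip.label, labels)
  stopifnot(!anyNA(idx))
  ## internal ids: assign fresh slots in order of ape numbering
  imap <- integer(ntip + phy$Nnode)
  imap[seq_len(ntip)] <- idx
  free <- n + seq_len(n - 1L)
  used <- 0L
  for (v in (ntip + 1L):(ntip + phy$Nnode)) {
    used <- used + 1L
    imap[v] <- free[used]
  }
  for (i in seq_len(nrow(phy$edge))) {
    p <- imap[phy$edge[i, 1L]]
    k <- imap[phy$edge[i, 2L]]
    if (ct$kid1[p] == 0L) ct$kid1[p] <- k else ct$kid2[p] <- k
    ct$par[k] <- p
  }
  ## unused internal slots keep par = -1 from ct_new(); the root (ape node
  ## ntip+1) gets par = 0
  ct$root <- imap[ntip + 1L]
  ct$par[ct$root] <- 0L
  ct$act[idx] <- TRUE
  ct$nact <- ntip
  ct
}
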
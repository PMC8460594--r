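#' @useDynLib treeurn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Internal representation ------------------------------------------------
#
# A tree is a list of parallel vectors indexed by vertex id (root is always
# vertex 1): parent, lchild, rchild (0 = none), labels (NA for interior
# vertices), plus `rooted` and `nleaf`.  Rooted trees keep the degree-one
# root rho as a real vertex so that the edge (rho, child) is selectable:
# with n leaves there are 2n vertices and 2n - 1 edges.  Unrooted trees are
# stored handle-rooted at a leaf (the root vertex is itself a labelled
# leaf), giving 2n - 2 vertices and 2n - 3 edges.  Every non-root vertex v
# identifies the edge (parent[v], v); that id is what `enumerate_edges()`
# reports and `attach_leaf()` consumes.

new_urn_tree <- function(parent, lchild, rchild, labels, rooted) {
  tree <- structure(
    list(parent = as.integer(parent), lchild = as.integer(lchild),
         rchild = as.integer(rchild), labels = as.character(labels),
         rooted = isTRUE(rooted), nleaf = sum(!is.na(labels))),
    class = "urn_tree")
  validate_urn_tree(tree)
}

#' Validate an urn_tree object
#'
#' Checks the structural invariants: a rooted tree with n leaves has 2n
#' vertices, the degree-one root, and every other interior vertex with two
#' children; an unrooted tree has 2n - 2 vertices and every interior vertex
#' of degree three.  Leaf labels must be unique.
#'
#' @param tree an `urn_tree`.
#' @return the tree, invisibly usable, after validation.
#' @export
validate_urn_tree <- function(tree) {
  stopifnot(inherits(tree, "urn_tree"))
  nv <- length(tree$parent)
  n <- tree$nleaf
  if (tree$rooted) {
    if (nv != 2L * n) stop("rooted tree with ", n, " leaves must have ", 2L * n,
                           " vertices (including the root), found ", nv)
    if (tree$lchild[1L] == 0L || tree$rchild[1L] != 0L)
      stop("root must have exactly one child")
    if (!is.na(tree$labels[1L])) stop("the root is not a leaf and cannot be labelled")
  } else {
    if (nv != 2L * n - 2L) stop("unrooted tree with ", n, " leaves must have ",
                                2L * n - 2L, " vertices, found ", nv)
    if (is.na(tree$labels[1L])) stop("unrooted trees must be handle-rooted at a leaf")
    if (n >= 2L && (tree$lchild[1L] == 0L || tree$rchild[1L] != 0L))
      stop("handle leaf must have exactly one child")
  }
  if (tree$parent[1L] != 0L) stop("vertex 1 must be the root")
  for (v in seq_len(nv)[-1L]) {
    p <- tree$parent[v]
    if (p < 1L || p > nv) stop("vertex ", v, " has invalid parent")
    if (tree$lchild[p] != v && tree$rchild[p] != v)
      stop("vertex ", v, " is not registered as a child of its parent")
    leaf <- !is.na(tree$labels[v])
    nkids <- (tree$lchild[v] != 0L) + (tree$rchild[v] != 0L)
    if (leaf && nkids != 0L) stop("leaf vertex ", v, " has children")
    if (!leaf && nkids != 2L)
      stop("interior vertex ", v, " is not binary (", nkids, " children)")
  }
  labs <- tree$labels[!is.na(tree$labels)]
  if (anyDuplicated(labs)) stop("leaf labels are not unique")
  tree
}

#' Number of leaves of a tree
#' @param tree an `urn_tree`.
#' @return integer leaf count.
#' @export
n_leaves <- function(tree) tree$nleaf

is_leaf_vertex <- function(tree, v) {
  if (tree$rooted) v != 1L & tree$lchild[v] == 0L
  else v == 1L | tree$lchild[v] == 0L
}

# natural order for taxon labels ("2" before "10" when all labels numeric)
label_order <- function(labels) {
  num <- suppressWarnings(as.numeric(labels))
  if (!anyNA(num)) order(num) else order(labels, method = "radix")
}

#' The unique two-leaf tree
#'
#' The starting point of both growth processes: two leaves joined below the
#' degree-one root (rooted), or a single edge between two leaves (unrooted).
#'
#' @param rooted logical.
#' @param labels two taxon labels.
#' @return an `urn_tree`.
#' @export
two_leaf_tree <- function(rooted = TRUE, labels = c("1", "2")) {
  stopifnot(length(labels) == 2L)
  if (rooted) {
    # 1 = rho, 2 = interior, 3, 4 = leaves
    new_urn_tree(parent = c(0L, 1L, 2L, 2L), lchild = c(2L, 3L, 0L, 0L),
                 rchild = c(0L, 4L, 0L, 0L),
                 labels = c(NA, NA, labels), rooted = TRUE)
  } else {
    new_urn_tree(parent = c(0L, 1L), lchild = c(2L, 0L), rchild = c(0L, 0L),
                 labels = labels, rooted = FALSE)
  }
}

# Conversion from / to ape ----------------------------------------------

# orient an adjacency list (list of integer vectors) from `handle`,
# returning an urn_tree with the given vertex labels (NA for interior)
adjacency_to_tree <- function(adj, labels, handle, rooted) {
  nv <- length(adj)
  newid <- integer(nv)
  parent <- integer(nv); lchild <- integer(nv); rchild <- integer(nv)
  newlab <- rep(NA_character_, nv)
  # iterative preorder from handle
  newid[handle] <- 1L
  newlab[1L] <- labels[handle]
  nxt <- 2L
  stack <- handle
  par_of <- integer(nv) # old-id parent
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    vid <- newid[v]
    kids <- setdiff(adj[[v]], par_of[v])
    if (length(kids) > 2L)
      stop("interior vertex with degree > 3 cannot be represented (vertex ", v, ")")
    for (k in kids) {
      kid <- nxt; nxt <- nxt + 1L
      newid[k] <- kid
      newlab[kid] <- labels[k]
      par_of[k] <- v
      parent[kid] <- vid
      if (lchild[vid] == 0L) lchild[vid] <- kid else rchild[vid] <- kid
      stack <- c(stack, k)
    }
  }
  new_urn_tree(parent, lchild, rchild, newlab, rooted)
}

from_phylo <- function(phy, rooted = TRUE) {
  ntip <- length(phy$tip.label)
  if (ntip < 2L) stop("a tree needs at least two leaves")
  nnode <- phy$Nnode
  nv_ape <- ntip + nnode
  edges <- phy$edge
  if (rooted) {
    kids <- vector("list", nv_ape)
    parent_ape <- integer(nv_ape)
    for (i in seq_len(nrow(edges))) {
      p <- edges[i, 1L]; c0 <- edges[i, 2L]
      kids[[p]] <- c(kids[[p]], c0)
      parent_ape[c0] <- p
    }
    aperoot <- ntip + 1L
    for (v in seq_len(nv_ape)) {
      nk <- length(kids[[v]])
      ok <- if (v <= ntip) nk == 0L else if (v == aperoot) nk %in% c(1L, 2L) else nk == 2L
      if (!ok) stop("non-binary interior vertex in Newick input (vertex ", v, ")")
    }
    add_rho <- length(kids[[aperoot]]) == 2L
    nv <- nv_ape + if (add_rho) 1L else 0L
    # map: rho = 1, ape vertex k -> k + 1 (or k shifted when rho comes from ape)
    off <- if (add_rho) 1L else 0L
    map <- seq_len(nv_ape) + off
    if (!add_rho) { # ape root is already the degree-one rho: place it at 1
      map <- ifelse(seq_len(nv_ape) == aperoot, 1L,
                    seq_len(nv_ape) + (seq_len(nv_ape) < aperoot))
    }
    parent <- integer(nv); lchild <- integer(nv); rchild <- integer(nv)
    labels <- rep(NA_character_, nv)
    labels[map[seq_len(ntip)]] <- phy$tip.label
    for (i in seq_len(nrow(edges))) {
      p <- map[edges[i, 1L]]; c0 <- map[edges[i, 2L]]
      parent[c0] <- p
      if (lchild[p] == 0L) lchild[p] <- c0 else rchild[p] <- c0
    }
    if (add_rho) {
      parent[map[aperoot]] <- 1L
      lchild[1L] <- map[aperoot]
    }
    new_urn_tree(parent, lchild, rchild, labels, rooted = TRUE)
  } else {
    # build adjacency, suppress degree-2 vertices (e.g. a rooted Newick's
    # basal node), then handle-root at the lowest-labelled leaf
    adj <- vector("list", nv_ape)
    for (i in seq_len(nrow(edges))) {
      p <- edges[i, 1L]; c0 <- edges[i, 2L]
      adj[[p]] <- c(adj[[p]], c0)
      adj[[c0]] <- c(adj[[c0]], p)
    }
    labels <- c(phy$tip.label, rep(NA_character_, nnode))
    keep <- rep(TRUE, nv_ape)
    repeat {
      deg <- vapply(adj, length, 1L)
      sup <- which(keep & deg == 2L & is.na(labels))
      if (!length(sup)) break
      v <- sup[1L]
      nb <- adj[[v]]
      adj[[nb[1L]]] <- c(setdiff(adj[[nb[1L]]], v), nb[2L])
      adj[[nb[2L]]] <- c(setdiff(adj[[nb[2L]]], v), nb[1L])
      adj[[v]] <- integer(0)
      keep[v] <- FALSE
    }
    deg <- vapply(adj, length, 1L)
    bad <- which(keep & is.na(labels) & deg != 3L)
    if (length(bad))
      stop("non-binary interior vertex in Newick input (vertex ", bad[1L], ")")
    # compact ids
    old <- which(keep)
    idx <- match(seq_len(nv_ape), old)
    adj2 <- lapply(old, function(v) idx[adj[[v]]])
    labels2 <- labels[old]
    tips <- which(!is.na(labels2))
    handle <- tips[label_order(labels2[tips])[1L]]
    adjacency_to_tree(adj2, labels2, handle, rooted = FALSE)
  }
}

to_phylo <- function(tree) {
  nv <- length(tree$parent)
  n <- tree$nleaf
  leaf <- !is.na(tree$labels)
  if (tree$rooted) {
    # drop the synthetic rho; ape root is rho's child
    r <- tree$lchild[1L]
    keep <- setdiff(seq_len(nv), 1L)
    tipold <- which(leaf)
    intold <- c(r, setdiff(keep[!leaf[keep]], r))
    map <- integer(nv)
    map[tipold] <- seq_len(n)
    map[intold] <- n + seq_along(intold)
    edges <- cbind(map[tree$parent[setdiff(keep, r)]], map[setdiff(keep, r)])
  } else {
    if (n == 2L) {
      edges <- cbind(c(3L, 3L), c(1L, 2L))
      phy <- structure(list(edge = edges, tip.label = tree$labels[1:2], Nnode = 1L),
                       class = "phylo", order = "cladewise")
      return(phy)
    }
    # ape root = the handle's neighbour, with the handle as an extra child
    h <- 1L
    r <- tree$lchild[h]
    tipold <- which(leaf)
    intold <- c(r, setdiff(which(!leaf), r))
    map <- integer(nv)
    map[tipold] <- seq_len(n)
    map[intold] <- n + seq_along(intold)
    rest <- setdiff(seq_len(nv), c(h, r))
    edges <- rbind(cbind(map[tree$parent[rest]], map[rest]),
                   c(map[r], map[h]))
  }
  nnode <- sum(!leaf) - if (tree$rooted) 1L else 0L
  structure(list(edge = edges, tip.label = tree$labels[!is.na(tree$labels)],
                 Nnode = nnode),
            class = "phylo", order = "cladewise")
}

# Newick I/O --------------------------------------------------------------

#' Parse a Newick string
#'
#' Branch lengths, if present, are accepted and dropped: all statistics in
#' this package are purely topological.  For rooted input whose Newick root
#' has two children, the degree-one root rho is synthesized above it; a
#' Newick string that already encodes a degree-one basal vertex is used
#' as-is.  Unrooted input may have a basal bi- or trifurcation; degree-two
#' vertices are suppressed.
#'
#' @param text a Newick string (semicolon-terminated).
#' @param rooted interpret the tree as rooted (default) or unrooted.
#' @return an `urn_tree`.
#' @examples
#' parse_newick("((1,2),3);")
#' parse_newick("((1,2),(3,4),5);", rooted = FALSE)
#' @export
parse_newick <- function(text, rooted = TRUE) {
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy)) stop("malformed Newick string")
  from_phylo(phy, rooted = rooted)
}

#' Read a Newick file
#' @param file path to a Newick file containing one tree.
#' @param rooted interpret as rooted (default) or unrooted.
#' @return an `urn_tree`.
#' @export
read_newick <- function(file, rooted = TRUE) {
  phy <- ape::read.tree(file)
  if (inherits(phy, "multiPhylo")) phy <- phy[[1L]]
  if (is.null(phy)) stop("malformed Newick file")
  from_phylo(phy, rooted = rooted)
}

#' Write a tree as a Newick string
#'
#' Rooted trees are written without the synthetic degree-one root (it is
#' re-synthesized on parsing); unrooted trees are written with a basal
#' trifurcation.  The round trip `parse_newick(write_newick(t))` yields a
#' tree isomorphic to `t` with the same labels.
#'
#' @param tree an `urn_tree`.
#' @param file optional path; when given the string is also written there.
#' @return the Newick string, invisibly when `file` is given.
#' @export
write_newick <- function(tree, file = NULL) {
  validate_urn_tree(tree)
  txt <- ape::write.tree(to_phylo(tree))
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' @export
print.urn_tree <- function(x, ...) {
  cat(sprintf("%s phylogenetic tree: %d leaves, %d edges\n",
              if (x$rooted) "rooted" else "unrooted",
              x$nleaf, length(x$parent) - 1L))
  cat(" ", write_newick(x), "\n")
  invisible(x)
}

# Edge enumeration and attachment ----------------------------------------

# smallest leaf label (by natural order rank) in each subtree
subtree_min_rank <- function(tree) {
  nv <- length(tree$parent)
  rank <- rep(NA_integer_, nv)
  labs <- which(!is.na(tree$labels))
  rank[labs] <- order(label_order(tree$labels[labs]))
  ord <- rev(preorder_vertices(tree))
  for (v in ord) {
    kids <- c(tree$lchild[v], tree$rchild[v])
    kids <- kids[kids != 0L]
    if (length(kids))
      rank[v] <- min(c(rank[v], rank[kids]), na.rm = TRUE)
  }
  rank
}

preorder_vertices <- function(tree) {
  nv <- length(tree$parent)
  out <- integer(nv)
  stack <- 1L
  k <- 0L
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    k <- k + 1L
    out[k] <- v
    kids <- c(tree$lchild[v], tree$rchild[v])
    kids <- kids[kids != 0L]
    if (length(kids)) stack <- c(stack, rev(kids))
  }
  out[seq_len(k)]
}

#' Enumerate the edges of a tree in canonical order
#'
#' Edges are identified by their child vertex and listed depth-first from
#' the root (the handle leaf, for unrooted trees), visiting children in
#' ascending order of the smallest leaf label in their subtree.  The order
#' is deterministic, so uniform sampling by index is reproducible.
#'
#' @param tree an `urn_tree`.
#' @return a data frame with columns `edge` (the child-vertex id used by
#'   [attach_leaf()]), `parent`, `child`, `pendant` (logical), and `label`
#'   (the leaf label for pendant edges of labelled leaves).
#' @export
enumerate_edges <- function(tree) {
  validate_urn_tree(tree)
  rank <- subtree_min_rank(tree)
  out <- integer(length(tree$parent) - 1L)
  k <- 0L
  stack <- 1L
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (v != 1L) { k <- k + 1L; out[k] <- v }
    kids <- c(tree$lchild[v], tree$rchild[v])
    kids <- kids[kids != 0L]
    if (length(kids) > 1L) kids <- kids[order(rank[kids])]
    if (length(kids)) stack <- c(stack, rev(kids))
  }
  ch <- out[seq_len(k)]
  pend <- if (tree$rooted) is_leaf_vertex(tree, ch) else
    is_leaf_vertex(tree, ch) | tree$parent[ch] == 1L
  data.frame(edge = ch, parent = tree$parent[ch], child = ch,
             pendant = pend, label = tree$labels[ch],
             stringsAsFactors = FALSE)
}

#' Attach a new leaf to an edge
#'
#' Implements the elementary growth move of both tree processes: the edge
#' (u, v) is subdivided by a new vertex w and the new leaf is hung from w,
#' adding one leaf and two edges.
#'
#' @param tree an `urn_tree`.
#' @param edge the edge id (child-vertex id, see [enumerate_edges()]).
#' @param label taxon label for the new leaf; defaults to `"t<k>"` with `k`
#'   the new leaf count.
#' @return the enlarged `urn_tree`.
#' @export
attach_leaf <- function(tree, edge, label = NULL) {
  nv <- length(tree$parent)
  edge <- as.integer(edge)
  if (length(edge) != 1L || is.na(edge) || edge < 2L || edge > nv)
    stop("unknown edge id: ", edge)
  if (is.null(label)) label <- default_new_labels(tree, 1L)
  if (label %in% tree$labels) stop("duplicate leaf label: ", label)
  w <- nv + 1L; x <- nv + 2L
  parent <- c(tree$parent, 0L, 0L)
  lchild <- c(tree$lchild, 0L, 0L)
  rchild <- c(tree$rchild, 0L, 0L)
  labels <- c(tree$labels, NA_character_, label)
  p <- parent[edge]
  if (lchild[p] == edge) lchild[p] <- w else rchild[p] <- w
  parent[w] <- p
  lchild[w] <- edge
  rchild[w] <- x
  parent[edge] <- w
  parent[x] <- w
  new_urn_tree(parent, lchild, rchild, labels, tree$rooted)
}

default_new_labels <- function(tree, k) {
  lab <- character(0)
  i <- tree$nleaf + 1L
  while (length(lab) < k) {
    cand <- paste0("t", i)
    if (!(cand %in% tree$labels)) lab <- c(lab, cand)
    i <- i + 1L
  }
  lab
}

#' Remove the root of a rooted tree
#'
#' Deletes the degree-one root rho and suppresses its (then degree-two)
#' child, producing the unrooted tree with 2n - 3 edges.
#'
#' @param tree a rooted `urn_tree` with at least 3 leaves.
#' @return an unrooted `urn_tree`.
#' @export
unroot <- function(tree) {
  validate_urn_tree(tree)
  if (!tree$rooted) return(tree)
  if (tree$nleaf < 3L)
    stop("unrooting needs at least 3 leaves (a 2-leaf tree degenerates to a single edge)")
  nv <- length(tree$parent)
  r <- tree$lchild[1L]
  adj <- vector("list", nv)
  for (v in seq_len(nv)[-1L]) {
    p <- tree$parent[v]
    if (p == 1L || v == r) next # skip the rho edge; r is suppressed below
    adj[[v]] <- c(adj[[v]], p)
    adj[[p]] <- c(adj[[p]], v)
  }
  # suppress r: connect its two children
  k1 <- tree$lchild[r]; k2 <- tree$rchild[r]
  adj[[k1]] <- c(setdiff(adj[[k1]], r), k2)
  adj[[k2]] <- c(setdiff(adj[[k2]], r), k1)
  adj[[r]] <- integer(0)
  keep <- setdiff(seq_len(nv), c(1L, r))
  idx <- match(seq_len(nv), keep)
  adj2 <- lapply(keep, function(v) idx[adj[[v]]])
  labels2 <- tree$labels[keep]
  tips <- which(!is.na(labels2))
  handle <- tips[label_order(labels2[tips])[1L]]
  adjacency_to_tree(adj2, labels2, handle, rooted = FALSE)
}
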
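#' Index a species tree for ancestral queries
#'
#' Precomputes parent pointers, depths, children lists and traversal orders
#' for a rooted `phylo` tree. All ancestral inference in the package runs
#' against this index; node ids are ape's integer ids (tips `1..n`, internal
#' nodes `n+1..n+Nnode`, root `n+1`).
#'
#' @param tree a rooted `ape::phylo` object with unique tip labels.
#' @return a list with elements `n_tip`, `root`, `parent` (NA at the root),
#'   `depth`, `children`, `tip_id` (named integer vector label -> id),
#'   `preorder`, `postorder` and `edge_length` (per child node; 1 when the
#'   tree carries no branch lengths).
#' @keywords internal
tree_index <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label) > 0L) {
    abort("tree tip labels must be unique")
  }
  n <- length(tree$tip.label)
  m <- tree$Nnode
  nn <- n + m
  parent <- rep(NA_integer_, nn)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  root <- tree$edge[1L, 1L]
  while (!is.na(parent[root])) root <- parent[root]
  children <- vector("list", nn)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1L]
    children[[p]] <- c(children[[p]], tree$edge[i, 2L])
  }
  # iterative preorder from the root
  pre <- integer(nn)
  stack <- root
  k <- 0L
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    k <- k + 1L
    pre[k] <- v
    kids <- children[[v]]
    if (length(kids)) stack <- c(stack, rev(kids))
  }
  pre <- pre[seq_len(k)]
  depth <- integer(nn)
  for (v in pre) if (!is.na(parent[v])) depth[v] <- depth[parent[v]] + 1L
  el <- rep(1, nn)
  if (!is.null(tree$edge.length)) el[tree$edge[, 2L]] <- tree$edge.length
  list(
    n_tip = n, root = root, parent = parent, depth = depth,
    children = children,
    tip_id = setNames(seq_len(n), tree$tip.label),
    preorder = pre, postorder = rev(pre), edge_length = el
  )
}

#' Most recent common ancestor of a node set
#'
#' @param idx a [tree_index()].
#' @param nodes integer node ids (length >= 1).
#' @return the MRCA node id.
#' @keywords internal
mrca_nodes <- function(idx, nodes) {
  nodes <- unique(as.integer(nodes))
  if (!length(nodes)) abort("empty node set has no MRCA")
  a <- nodes[1L]
  for (b in nodes[-1L]) {
    while (idx$depth[a] > idx$depth[b]) a <- idx$parent[a]
    while (idx$depth[b] > idx$depth[a]) b <- idx$parent[b]
    while (a != b) {
      a <- idx$parent[a]
      b <- idx$parent[b]
    }
  }
  a
}

#' Is `anc` an ancestor of (or equal to) `node`?
#' @keywords internal
is_ancestor <- function(idx, anc, node) {
  v <- node
  while (!is.na(v)) {
    if (v == anc) return(TRUE)
    v <- idx$parent[v]
  }
  FALSE
}

#' All nodes in the subtree rooted at `node` (preorder)
#' @keywords internal
subtree_nodes <- function(idx, node) {
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    out <- c(out, v)
    stack <- c(stack, idx$children[[v]])
  }
  out
}

#' Tip ids below a node
#' @keywords internal
subtree_tips <- function(idx, node) {
  nodes <- subtree_nodes(idx, node)
  nodes[nodes <= idx$n_tip]
}

#' Stable postorder node numbering for a species tree
#'
#' Assigns every node (tips included) a stable integer in postorder so that
#' ancestral nodes can be referred to by number across exports of the same
#' tree, in the style of node-numbered phylogeny figures.
#'
#' @param tree a rooted `ape::phylo`.
#' @return a tibble with columns `node` (ape id), `number` (postorder rank),
#'   `label` (tip label or empty), `is_tip`.
#' @export
#' @examples
#' tr <- simulate_species_tree(5, seed = 1)
#' node_numbers(tr)
node_numbers <- function(tree) {
  idx <- tree_index(tree)
  po <- idx$postorder
  tibble(
    node = po,
    number = seq_along(po),
    label = ifelse(po <= idx$n_tip, tree$tip.label[pmin(po, idx$n_tip)], ""),
    is_tip = po <= idx$n_tip
  )
}
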
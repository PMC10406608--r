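#' Edge supports keyed by bipartition
#'
#' Supports belong to splits, not to node indices, so they survive
#' rerooting only if tracked by the bipartition they annotate. Returns a
#' named numeric vector keyed by canonical split key.
#' @keywords internal
support_by_split <- function(tree) {
  if (is.null(tree$node.label)) return(setNames(numeric(0), character(0)))
  idx <- tree_index(tree)
  labs <- tree$tip.label
  out <- numeric(0)
  for (v in setdiff(seq_len(idx$n_tip + tree$Nnode), seq_len(idx$n_tip))) {
    if (is.na(idx$parent[v])) next  # root has no incoming edge
    below <- labs[subtree_tips(idx, v)]
    if (length(below) <= 1L || length(below) >= length(labs) - 1L) next
    s <- suppressWarnings(as.numeric(tree$node.label[v - idx$n_tip]))
    if (!is.na(s)) out[split_key(below, labs)] <- s
  }
  out
}

# canonical key for an unrooted bipartition: the side holding the globally
# smallest label, sorted and joined
split_key <- function(side, all_tips) {
  anchor <- min(all_tips)
  if (!(anchor %in% side)) side <- setdiff(all_tips, side)
  paste(sort(side), collapse = ",")
}

apply_split_supports <- function(tree, supports) {
  idx <- tree_index(tree)
  labs <- tree$tip.label
  nl <- character(tree$Nnode)
  for (v in setdiff(seq_len(idx$n_tip + tree$Nnode), seq_len(idx$n_tip))) {
    below <- labs[subtree_tips(idx, v)]
    if (length(below) <= 1L || length(below) >= length(labs) - 1L) next
    key <- split_key(below, labs)
    if (key %in% names(supports)) nl[v - idx$n_tip] <- as.character(supports[key])
  }
  tree$node.label <- nl
  tree
}

#' Contract weakly supported gene-tree edges into polytomies
#'
#' Every internal edge whose support is below `support_threshold` is
#' contracted (its child's children are reattached to its parent), giving a
#' multifurcating tree in which only well-supported splits remain. Branch
#' lengths along contracted paths are summed onto the surviving edges.
#' Edges without a numeric support are kept.
#'
#' @param tree rooted `ape::phylo` with supports in `node.label`.
#' @param support_threshold minimum support kept (default 80).
#' @return the contracted `phylo` (leaf set unchanged).
#' @export
collapse_weak_edges <- function(tree, support_threshold = 80) {
  idx <- tree_index(tree)
  n <- idx$n_tip
  nn <- n + tree$Nnode
  supp <- rep(NA_real_, nn)
  if (!is.null(tree$node.label)) {
    supp[(n + 1L):nn] <- suppressWarnings(as.numeric(tree$node.label))
  }
  keep <- rep(TRUE, nn)
  for (v in (n + 1L):nn) {
    if (!is.na(idx$parent[v]) && !is.na(supp[v]) &&
        supp[v] < support_threshold) {
      keep[v] <- FALSE
    }
  }
  if (all(keep)) return(tree)
  # climb to nearest kept ancestor, accumulating edge length
  new_parent <- rep(NA_integer_, nn)
  new_len <- rep(0, nn)
  for (v in seq_len(nn)) {
    if (!keep[v] || is.na(idx$parent[v])) next
    p <- idx$parent[v]
    len <- idx$edge_length[v]
    while (!keep[p]) {
      len <- len + idx$edge_length[p]
      p <- idx$parent[p]
    }
    new_parent[v] <- p
    new_len[v] <- len
  }
  kept_int <- which(keep & seq_len(nn) > n)
  renum <- integer(nn)
  renum[seq_len(n)] <- seq_len(n)
  renum[kept_int] <- n + seq_along(kept_int)
  child <- which(!is.na(new_parent))
  out <- list(
    edge = cbind(renum[new_parent[child]], renum[child]),
    tip.label = tree$tip.label,
    Nnode = length(kept_int),
    edge.length = if (is.null(tree$edge.length)) NULL else new_len[child],
    node.label = as.character(ifelse(is.na(supp[kept_int]), "",
                                     supp[kept_int]))
  )
  out <- out[!vapply(out, is.null, logical(1))]
  class(out) <- "phylo"
  ape::reorder.phylo(out, "cladewise")
}

#' LCA reconciliation of a gene tree against the species tree
#'
#' Maps every gene-tree node to the most recent common ancestor (in the
#' species tree) of its descendant species. An internal node is labelled a
#' duplication if any child maps to the node's own mapping, or if two of
#' its children map to the same species-tree node (polytomies are otherwise
#' treated conservatively, as speciations). Losses are counted per gene
#' edge as the number of species-tree edges skipped between the two
#' mappings, with the usual adjustment at duplication nodes.
#'
#' @param tree rooted (possibly multifurcating) `ape::phylo` gene tree.
#' @param stree rooted `ape::phylo` species tree.
#' @param species named character vector leaf label -> species name;
#'   default parses labels with [leaf_species()].
#' @return an object of class `reconciliation`: list with `tree`, `stree`,
#'   `nodes` (tibble `node`, `species_node`, `event`, `losses` where
#'   `losses` counts losses on the node's incoming edge), `n_duplications`,
#'   `n_losses`.
#' @export
lca_reconcile <- function(tree, stree, species = NULL) {
  gi <- tree_index(tree)
  si <- tree_index(stree)
  labs <- tree$tip.label
  if (is.null(species)) species <- setNames(leaf_species(labs), labs)
  sp <- unname(species[labs])
  if (anyNA(sp) || !all(sp %in% names(si$tip_id))) {
    bad <- unique(c(labs[is.na(sp)], sp[!sp %in% names(si$tip_id)]))
    abort(paste0("unknown species for leaves: ",
                 paste(stats::na.omit(bad), collapse = ", ")))
  }
  nn <- gi$n_tip + tree$Nnode
  map <- integer(nn)
  event <- character(nn)
  map[seq_len(gi$n_tip)] <- si$tip_id[sp]
  event[seq_len(gi$n_tip)] <- "leaf"
  for (v in gi$postorder) {
    if (v <= gi$n_tip) next
    kids <- gi$children[[v]]
    map[v] <- mrca_nodes(si, map[kids])
    dup <- any(map[kids] == map[v]) || anyDuplicated(map[kids]) > 0L
    event[v] <- if (dup) "duplication" else "speciation"
  }
  losses <- integer(nn)
  for (v in seq_len(nn)) {
    u <- gi$parent[v]
    if (is.na(u)) next
    k <- si$depth[map[v]] - si$depth[map[u]]
    losses[v] <- if (event[u] == "duplication") k else max(0L, k - 1L)
  }
  structure(
    list(
      tree = tree, stree = stree,
      species = setNames(sp, labs),
      nodes = tibble(node = seq_len(nn), species_node = map,
                     event = event, losses = losses),
      n_duplications = sum(event == "duplication"),
      n_losses = sum(losses)
    ),
    class = "reconciliation"
  )
}

#' @export
print.reconciliation <- function(x, ...) {
  cat("<reconciliation>\n")
  cat("  gene-tree leaves:", length(x$tree$tip.label), "\n")
  cat("  duplications:    ", x$n_duplications, "\n")
  cat("  losses:          ", x$n_losses, "\n")
  invisible(x)
}

#' Root a gene tree by minimizing reconciliation cost
#'
#' Tries every branch of the unrooted gene tree as a root position,
#' reconciles each candidate rooting against the species tree, and keeps
#' the rooting with the fewest duplications + losses. Ties are broken by
#' fewer duplications, then by the lexicographically smallest root
#' bipartition. Branch supports are re-attached by bipartition so
#' rerooting cannot misplace them.
#'
#' @inheritParams lca_reconcile
#' @param tree unrooted or arbitrarily rooted `ape::phylo` gene tree.
#' @return the rooted `phylo` (attribute `reconciliation` holds the
#'   winning [lca_reconcile()] result).
#' @export
root_gene_tree <- function(tree, stree, species = NULL) {
  labs <- tree$tip.label
  if (is.null(species)) species <- setNames(leaf_species(labs), labs)
  if (length(labs) == 2L) {
    rt <- if (ape::is.rooted(tree)) tree else
      ape::root(tree, outgroup = sort(labs)[1L], resolve.root = TRUE)
    attr(rt, "reconciliation") <- lca_reconcile(rt, stree, species)
    return(rt)
  }
  supports <- support_by_split(tree)
  ut <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  ui <- tree_index(ut)
  best <- NULL
  for (e in seq_len(nrow(ut$edge))) {
    below <- ut$tip.label[subtree_tips(ui, ut$edge[e, 2L])]
    if (length(below) == length(labs)) next
    rt <- tryCatch(
      ape::root(ut, outgroup = below, resolve.root = TRUE),
      error = function(err) NULL
    )
    if (is.null(rt) || !ape::is.rooted(rt)) next
    rt <- apply_split_supports(rt, supports)
    rec <- lca_reconcile(rt, stree, species)
    key <- split_key(below, labs)
    cand <- list(tree = rt, rec = rec, key = key,
                 cost = rec$n_duplications + rec$n_losses,
                 dups = rec$n_duplications)
    if (is.null(best) ||
        cand$cost < best$cost ||
        (cand$cost == best$cost && cand$dups < best$dups) ||
        (cand$cost == best$cost && cand$dups == best$dups &&
         cand$key < best$key)) {
      best <- cand
    }
  }
  if (is.null(best)) abort("no valid rooting found")
  out <- best$tree
  attr(out, "reconciliation") <- best$rec
  out
}

#' Delimit orthogroups from a reconciled gene tree
#'
#' Cuts the gene tree at every duplication node's child edges; each maximal
#' speciation-only subtree is one orthogroup, so every leaf belongs to
#' exactly one.
#'
#' @param rec a [lca_reconcile()] result.
#' @return tibble with columns `orthogroup`, `protein` (leaf label),
#'   `species`, `origin_node` (the orthogroup's MRCA in the species tree).
#' @export
delimit_orthogroups <- function(rec) {
  gi <- tree_index(rec$tree)
  si <- tree_index(rec$stree)
  nn <- gi$n_tip + rec$tree$Nnode
  grp <- integer(nn)
  nxt <- 1L
  grp[gi$root] <- nxt
  ev <- rec$nodes$event
  for (v in gi$preorder) {
    for (c in gi$children[[v]]) {
      if (ev[v] == "duplication") {
        nxt <- nxt + 1L
        grp[c] <- nxt
      } else {
        grp[c] <- grp[v]
      }
    }
  }
  leaves <- tibble(
    protein = rec$tree$tip.label,
    species = unname(rec$species[rec$tree$tip.label]),
    grp = grp[seq_len(gi$n_tip)]
  )
  og_ids <- leaves |>
    group_by(.data$grp) |>
    summarise(rep = min(.data$protein), .groups = "drop") |>
    arrange(.data$rep) |>
    mutate(orthogroup = sprintf("OG%04d", row_number()))
  leaves |>
    left_join(og_ids[, c("grp", "orthogroup")], by = "grp") |>
    group_by(.data$orthogroup) |>
    mutate(origin_node = mrca_nodes(si, si$tip_id[unique(.data$species)])) |>
    ungroup() |>
    select("orthogroup", "protein", "species", "origin_node") |>
    arrange(.data$orthogroup, .data$protein)
}
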
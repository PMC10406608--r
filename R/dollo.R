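#' Dollo parsimony mapping of a presence pattern
#'
#' Under Dollo parsimony a family is gained exactly once — at the MRCA of
#' the species that carry it — and explained absences are losses: one loss
#' on the root edge of every maximal subtree below the gain node that
#' contains no member species.
#'
#' @param species character vector of species carrying the family
#'   (non-empty, all tips of `stree`).
#' @param stree rooted `ape::phylo` species tree.
#' @return list with `gain_node` (species-tree node id) and `loss_nodes`
#'   (ids of subtree roots whose incoming branch carries a loss).
#' @export
#' @examples
#' st <- ape::read.tree(text = "((A,B),(C,D));")
#' dollo_map(c("A", "C"), st)
dollo_map <- function(species, stree) {
  si <- tree_index(stree)
  species <- unique(species)
  if (!length(species)) abort("empty species set cannot be Dollo-mapped")
  if (!all(species %in% names(si$tip_id))) {
    abort(paste0("species not in tree: ",
                 paste(setdiff(species, names(si$tip_id)), collapse = ", ")))
  }
  tips <- unname(si$tip_id[species])
  gain <- mrca_nodes(si, tips)
  sub <- subtree_nodes(si, gain)
  live <- presence_below(si, sub, tips)
  loss_nodes <- sub[!live[sub] &
                      si$parent[sub] %in% sub[live[sub]] &
                      !is.na(si$parent[sub])]
  # only maximal dead subtrees: parent must be live and inside the subtree
  list(gain_node = gain, loss_nodes = sort(loss_nodes))
}

# logical vector over all nodes: does the node (within `sub`) have a
# present tip at or below it?
presence_below <- function(si, sub, present_tips) {
  live <- rep(FALSE, length(si$parent))
  live[present_tips] <- TRUE
  for (v in si$postorder) {
    if (v %in% sub && length(si$children[[v]])) {
      live[v] <- any(live[si$children[[v]]])
    }
  }
  live
}

#' Reconstruct one family's copy-number history by Dollo + L1 parsimony
#'
#' Dollo-maps the family's presence pattern (gain at the MRCA, one loss per
#' maximal absent subtree), then reconstructs ancestral copy numbers within
#' the surviving part of the clade. In `"counts"` mode, ancestral counts
#' are the integer assignment minimizing the total absolute copy-number
#' change along branches (dynamic programming over integer states), with
#' ties resolved toward the parent's value — and toward 1 at the gain node —
#' to avoid spurious duplication-loss pairs. In `"presence"` mode every
#' surviving node simply carries one copy.
#'
#' Branch events follow from the reconstruction: a copy-number increase on
#' a branch is that many duplications, a decrease that many losses; the
#' branch into a fully absent subtree loses all of its parent's copies
#' (one loss in presence mode); the gain node receives one gain plus
#' `copies - 1` duplications.
#'
#' @param counts named non-negative integer vector of per-species copy
#'   numbers (names = tips of `stree`); at least one positive entry.
#' @param stree rooted `ape::phylo` species tree.
#' @param mode `"counts"` (default) or `"presence"`.
#' @return tibble with one row per species-tree node carrying the family:
#'   `node`, `copies`, `gain` (logical), `duplications`, `losses`, plus
#'   rows for loss-branch heads (`copies = 0`, positive `losses`).
#' @export
reconstruct_family_history <- function(counts, stree,
                                       mode = c("counts", "presence")) {
  mode <- match.arg(mode)
  si <- tree_index(stree)
  if (is.null(names(counts)) || !all(names(counts) %in% names(si$tip_id))) {
    abort("`counts` must be named by species-tree tips")
  }
  present <- names(counts)[counts >= 1]
  if (!length(present)) abort("family is absent from every species")
  dm <- dollo_map(present, stree)
  gain <- dm$gain_node
  sub <- subtree_nodes(si, gain)
  live <- presence_below(si, sub, unname(si$tip_id[present]))
  live_nodes <- sub[live[sub]]

  tipc <- integer(si$n_tip)
  tipc[si$tip_id[names(counts)]] <- as.integer(counts)

  copies <- integer(length(si$parent))
  if (mode == "presence") {
    copies[live_nodes] <- 1L
  } else {
    S <- max(tipc)
    states <- seq_len(S)  # live nodes carry >= 1 copy (Dollo: no regain)
    cost <- matrix(Inf, nrow = length(si$parent), ncol = S)
    for (v in intersect(si$postorder, live_nodes)) {
      if (v <= si$n_tip) {
        cost[v, ] <- ifelse(states == tipc[v], 0, Inf)  # leaves are observed
      } else {
        kids <- intersect(si$children[[v]], live_nodes)
        for (s in states) {
          tot <- 0
          for (k in kids) tot <- tot + min(cost[k, ] + abs(states - s))
          cost[v, s] <- tot
        }
      }
    }
    pick <- function(v, target) {
      cs <- cost[v, ] + abs(states - target)
      cand <- states[cs == min(cs)]
      cand[order(abs(cand - target), cand)][1L]
    }
    copies[gain] <- {
      cand <- states[cost[gain, ] == min(cost[gain, ])]
      cand[order(abs(cand - 1L), cand)][1L]
    }
    for (v in intersect(si$preorder, live_nodes)) {
      if (v == gain) next
      copies[v] <- pick(v, copies[si$parent[v]])
    }
  }

  rows_nodes <- sort(unique(c(live_nodes, dm$loss_nodes)))
  dup <- loss <- integer(length(si$parent))
  gainv <- logical(length(si$parent))
  gainv[gain] <- TRUE
  dup[gain] <- copies[gain] - 1L
  for (v in setdiff(live_nodes, gain)) {
    d <- copies[v] - copies[si$parent[v]]
    if (d > 0L) dup[v] <- d else loss[v] <- -d
  }
  for (v in dm$loss_nodes) {
    loss[v] <- if (mode == "presence") 1L else copies[si$parent[v]]
  }
  tibble(
    node = rows_nodes,
    copies = copies[rows_nodes],
    gain = gainv[rows_nodes],
    duplications = dup[rows_nodes],
    losses = loss[rows_nodes]
  )
}

#' Aggregate per-family Dollo histories into a per-node event map
#'
#' Reconstructs every family's gain/duplication/loss history from a
#' families-by-species copy-number matrix (see
#' [reconstruct_family_history()]) and sums them per species-tree node,
#' yielding ancestral proteome sizes and per-branch event totals. The
#' bookkeeping identity `copies(node) = copies(parent) + gains +
#' duplications - losses` holds exactly at every non-root node.
#'
#' @param counts families x species non-negative integer matrix; families
#'   absent everywhere are not allowed.
#' @param stree rooted `ape::phylo` species tree.
#' @param mode `"counts"` (default) or `"presence"`; see
#'   [reconstruct_family_history()].
#' @return object of class `event_map`: list with `by_node` (tibble `node`,
#'   `gains`, `duplications`, `losses`, `copies` over all species-tree
#'   nodes), `by_family` (per-family node rows), `gain_node` (named integer
#'   vector family -> gain node), `tree`, `mode`.
#' @export
aggregate_events <- function(counts, stree, mode = c("counts", "presence")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(counts))
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("fam%05d", seq_len(nrow(counts)))
  }
  si <- tree_index(stree)
  nn <- si$n_tip + stree$Nnode
  fams <- rownames(counts)
  per_fam <- vector("list", length(fams))
  for (f in seq_along(fams)) {
    h <- reconstruct_family_history(counts[f, ], stree, mode = mode)
    h$family <- fams[f]
    per_fam[[f]] <- h
  }
  by_family <- list_rbind(per_fam)
  by_node <- by_family |>
    group_by(.data$node) |>
    summarise(
      gains = sum(.data$gain),
      duplications = sum(.data$duplications),
      losses = sum(.data$losses),
      copies = sum(.data$copies),
      .groups = "drop"
    ) |>
    tidyr::complete(node = seq_len(nn),
                    fill = list(gains = 0L, duplications = 0L,
                                losses = 0L, copies = 0L)) |>
    arrange(.data$node)
  gain_node <- by_family |>
    filter(.data$gain) |>
    (\(d) setNames(d$node, d$family))()
  structure(
    list(by_node = by_node, by_family = by_family,
         gain_node = gain_node, tree = stree, mode = mode),
    class = "event_map"
  )
}

#' @export
print.event_map <- function(x, ...) {
  cat("<event_map> (", x$mode, " mode)\n", sep = "")
  cat("  families:", length(x$gain_node), "\n")
  cat("  total gains/duplications/losses: ",
      sum(x$by_node$gains), "/", sum(x$by_node$duplications), "/",
      sum(x$by_node$losses), "\n", sep = "")
  invisible(x)
}

#' Verify the event-map bookkeeping identity
#'
#' Checks `copies(node) = copies(parent) + gains + duplications - losses`
#' at every non-root node (exact integer identity).
#'
#' @param em an [aggregate_events()] result.
#' @return invisibly `TRUE`; aborts listing offending nodes otherwise.
#' @export
check_event_bookkeeping <- function(em) {
  si <- tree_index(em$tree)
  b <- em$by_node
  cp <- setNames(b$copies, b$node)
  bad <- integer(0)
  for (v in b$node) {
    p <- si$parent[v]
    if (is.na(p)) next
    lhs <- cp[as.character(v)]
    rhs <- cp[as.character(p)] + b$gains[b$node == v] +
      b$duplications[b$node == v] - b$losses[b$node == v]
    if (lhs != rhs) bad <- c(bad, v)
  }
  if (length(bad)) {
    abort(paste0("bookkeeping identity violated at nodes: ",
                 paste(bad, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Net change in gene numbers at a node
#'
#' The net expansion (positive) or contraction (negative) of a genome at a
#' node: gains minus losses.
#'
#' @param gains,losses non-negative integer vectors.
#' @return `gains - losses`, elementwise.
#' @export
#' @examples
#' net_change(1114, 323)
net_change <- function(gains, losses) {
  if (any(gains < 0) || any(losses < 0)) {
    abort("`gains` and `losses` must be non-negative")
  }
  gains - losses
}
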
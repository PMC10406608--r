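#' Build the inter-cluster connection network
#'
#' Summarises a protein similarity graph at the cluster level: for every
#' pair of clusters joined by at least one inter-cluster protein edge, the
#' raw connection count and a size-normalized weight are recorded. The
#' normalization divides by the smaller cluster size (default), so a small
#' cluster strongly attached to a large one ranks as a strong link; `"mean"`
#' divides by the mean size.
#'
#' @param partition tibble `protein`, `hg` assigning every edge endpoint.
#' @param graph similarity edge tibble (`protein1`, `protein2`, ...).
#' @param normalize `"min"` (default) or `"mean"`.
#' @return tibble of class `cluster_graph` with columns `hg1`, `hg2`
#'   (`hg1 < hg2`), `n_edges`, `weight`; attribute `sizes` holds the cluster
#'   size table. Clusters without inter-edges are isolated (present in
#'   `sizes`, absent from edges).
#' @export
build_cluster_network <- function(partition, graph,
                                  normalize = c("min", "mean")) {
  normalize <- match.arg(normalize)
  memb <- setNames(partition$hg, partition$protein)
  if (nrow(graph) &&
      !all(c(graph$protein1, graph$protein2) %in% names(memb))) {
    abort("every edge endpoint must be assigned in `partition`")
  }
  sizes <- partition |> count(.data$hg, name = "size")
  if (!nrow(graph)) {
    return(new_cluster_graph(
      tibble(hg1 = character(), hg2 = character(),
             n_edges = integer(), weight = double()),
      sizes
    ))
  }
  e <- tibble(a = unname(memb[graph$protein1]),
              b = unname(memb[graph$protein2])) |>
    filter(.data$a != .data$b) |>
    mutate(hg1 = pmin(.data$a, .data$b), hg2 = pmax(.data$a, .data$b)) |>
    count(.data$hg1, .data$hg2, name = "n_edges")
  size_of <- setNames(sizes$size, sizes$hg)
  s1 <- size_of[e$hg1]
  s2 <- size_of[e$hg2]
  denom <- if (normalize == "min") pmin(s1, s2) else (s1 + s2) / 2
  e$weight <- e$n_edges / unname(denom)
  new_cluster_graph(e, sizes)
}

new_cluster_graph <- function(edges, sizes) {
  out <- as_tibble(edges)
  attr(out, "sizes") <- sizes
  class(out) <- c("cluster_graph", class(out))
  out
}

#' Prune a cluster network to a maximum component diameter
#'
#' Iteratively removes the weakest link of every connected component whose
#' unweighted diameter exceeds `max_diameter`, until all components comply.
#' Ties on weight are broken by the lexicographically smallest `(hg1, hg2)`
#' pair, making the pruning deterministic.
#'
#' @param cg a `cluster_graph` from [build_cluster_network()].
#' @param max_diameter maximum allowed unweighted diameter (default 3).
#' @return the pruned `cluster_graph`.
#' @export
prune_to_diameter <- function(cg, max_diameter = 3) {
  if (max_diameter < 1) abort("`max_diameter` must be >= 1")
  edges <- as_tibble(cg)[c("hg1", "hg2", "n_edges", "weight")]
  repeat {
    if (!nrow(edges)) break
    g <- igraph::graph_from_data_frame(edges[c("hg1", "hg2")],
                                       directed = FALSE)
    comp <- igraph::components(g)$membership
    offenders <- character(0)
    for (cid in unique(comp)) {
      sub <- igraph::induced_subgraph(g, names(comp)[comp == cid])
      if (igraph::diameter(sub, weights = NA) > max_diameter) {
        offenders <- c(offenders, igraph::V(sub)$name)
      }
    }
    if (!length(offenders)) break
    # one weakest edge per offending component, then drop them all
    in_off <- edges$hg1 %in% offenders  # components are vertex-disjoint
    cand <- edges[in_off, ]
    cand$comp <- comp[cand$hg1]
    drop <- cand |>
      group_by(.data$comp) |>
      arrange(.data$weight, .data$hg1, .data$hg2, .by_group = TRUE) |>
      slice(1L) |>
      ungroup()
    edges <- anti_join(edges, drop[c("hg1", "hg2")], by = c("hg1", "hg2"))
  }
  new_cluster_graph(edges, attr(cg, "sizes"))
}
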
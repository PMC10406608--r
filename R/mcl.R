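#' Markov clustering of a protein similarity graph
#'
#' Clusters proteins by Markov clustering (MCL) of the weighted similarity
#' graph: the column-stochastic transition matrix (with self-loops) is
#' alternately expanded (matrix squaring) and inflated (entrywise power
#' followed by column renormalization) until convergence; clusters are read
#' off as the connected components of the limit matrix's support. Proteins
#' absent from any edge become singleton clusters.
#'
#' Self-loops are set to each node's maximum incident weight and entries
#' below `prune_tol` are zeroed after each inflation, the usual measures for
#' fast, stable convergence.
#'
#' @param graph similarity edge tibble (`protein1`, `protein2`, `score`);
#'   edge weight is `score`.
#' @param inflation inflation exponent (> 1; default 2).
#' @param nodes optional character vector of all proteins (so isolated
#'   proteins appear as singletons); defaults to the proteins on edges.
#' @param convergence_tol maximum absolute matrix change defining
#'   convergence (default 1e-6).
#' @param max_iter iteration cap; on hitting it a warning is issued and the
#'   current matrix is interpreted as is (default 100).
#' @param prune_tol entries below this are zeroed after inflation
#'   (default 1e-8).
#' @return tibble with columns `protein`, `hg` (cluster id `HG00001`, ...).
#'   Cluster ids are assigned in order of each cluster's lexicographically
#'   smallest member, so the labelling is stable under node permutation.
#' @export
#' @examples
#' g <- simulate_similarity_graph(planted_partition(2, 5),
#'                                inter_edge_prob = 0, seed = 1)
#' mcl_cluster(g)
mcl_cluster <- function(graph, inflation = 2, nodes = NULL,
                        convergence_tol = 1e-6, max_iter = 100L,
                        prune_tol = 1e-8) {
  if (inflation <= 1) abort("`inflation` must be > 1")
  prot <- sort(unique(c(nodes, graph$protein1, graph$protein2)))
  if (!length(prot)) abort("graph has no nodes")
  n <- length(prot)
  M <- matrix(0, n, n, dimnames = list(prot, prot))
  if (nrow(graph)) {
    i <- match(graph$protein1, prot)
    j <- match(graph$protein2, prot)
    w <- graph$score
    M[cbind(i, j)] <- pmax(M[cbind(i, j)], w)
    M[cbind(j, i)] <- pmax(M[cbind(j, i)], w)
  }
  loop <- apply(M, 2L, max)
  loop[loop == 0] <- 1
  diag(M) <- loop
  M <- sweep(M, 2L, colSums(M), "/")
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M            # expansion
    M2 <- M2^inflation       # inflation
    M2[M2 < prune_tol] <- 0
    M2 <- sweep(M2, 2L, colSums(M2), "/")
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < convergence_tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn("MCL did not converge within `max_iter`; interpreting current matrix")
  }
  supp <- (M > 0) | (t(M) > 0)
  g <- igraph::graph_from_adjacency_matrix(supp, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  canonical_partition(tibble(protein = prot, cluster = comp))
}

#' Relabel a clustering so ids are stable under permutation
#'
#' Orders clusters by their lexicographically smallest member and renames
#' them `HG00001`, `HG00002`, ...
#' @keywords internal
canonical_partition <- function(df) {
  rep_by_cluster <- df |>
    group_by(.data$cluster) |>
    summarise(rep = min(.data$protein), .groups = "drop") |>
    arrange(.data$rep) |>
    mutate(hg = sprintf("HG%05d", row_number()))
  df |>
    left_join(rep_by_cluster[, c("cluster", "hg")], by = "cluster") |>
    select("protein", "hg") |>
    arrange(.data$protein)
}
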
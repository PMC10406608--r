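#' Simulate a planted-partition protein similarity graph
#'
#' Builds an all-vs-all similarity edge list over proteins whose true family
#' memberships are known, emulating the tabular output of an all-vs-all
#' search: within-family edges are dense with high scores and tiny e-values,
#' between-family edges sparse and weak. A configurable fraction of edges is
#' given coverages below the asymmetric coverage thresholds so that the
#' coverage filter has work to do.
#'
#' @param partition tibble with columns `protein`, `family` giving the true
#'   (planted) family of every protein.
#' @param intra_edge_prob probability of an edge within a family (default 0.9).
#' @param inter_edge_prob probability of an edge between families (default 0.02).
#' @param intra_score,inter_score mean bit score of intra/inter edges
#'   (defaults 200 and 40; s.d. one tenth of the mean).
#' @param intra_logev,inter_logev length-2 ranges of -log10(e-value) for
#'   intra (default 20..60) and inter (default 1..6) edges; inter edges
#'   therefore straddle the usual 1e-4 acceptance threshold.
#' @param frac_fail_coverage fraction of edges whose short-side coverage is
#'   drawn below the 0.8 filter threshold (default 0.1).
#' @param seed integer random seed; `NULL` uses the current RNG state.
#' @return a tibble of class `similarity_graph` with columns `protein1`,
#'   `protein2`, `score`, `evalue`, `cov_long`, `cov_short` and an attribute
#'   `self_scores` (tibble `protein`, `self_score`). No self edges are stored.
#' @export
#' @examples
#' part <- planted_partition(3, 4)
#' g <- simulate_similarity_graph(part, inter_edge_prob = 0, seed = 1)
simulate_similarity_graph <- function(partition,
                                      intra_edge_prob = 0.9,
                                      inter_edge_prob = 0.02,
                                      intra_score = 200,
                                      inter_score = 40,
                                      intra_logev = c(20, 60),
                                      inter_logev = c(1, 6),
                                      frac_fail_coverage = 0.1,
                                      seed = NULL) {
  stopifnot(all(c("protein", "family") %in% names(partition)))
  if (nrow(partition) < 1L) abort("`partition` must be non-empty")
  if (inter_edge_prob < 0 || inter_edge_prob > 1) {
    abort("`inter_edge_prob` must be in [0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  prot <- partition$protein
  fam <- partition$family
  n <- length(prot)
  if (n < 2L) {
    g <- tibble(protein1 = character(), protein2 = character(),
                score = double(), evalue = double(),
                cov_long = double(), cov_short = double())
    return(new_similarity_graph(g, tibble(protein = prot,
                                          self_score = 2 * intra_score)))
  }
  pairs <- combn(n, 2L)
  i <- pairs[1L, ]
  j <- pairs[2L, ]
  intra <- fam[i] == fam[j]
  keep <- runif(length(i)) < ifelse(intra, intra_edge_prob, inter_edge_prob)
  i <- i[keep]; j <- j[keep]; intra <- intra[keep]
  m <- length(i)
  score <- ifelse(intra,
                  rnorm(m, intra_score, intra_score / 10),
                  rnorm(m, inter_score, inter_score / 10))
  score <- pmax(score, 1)
  logev <- ifelse(intra,
                  runif(m, intra_logev[1], intra_logev[2]),
                  runif(m, inter_logev[1], inter_logev[2]))
  fail_cov <- runif(m) < frac_fail_coverage
  cov_short <- ifelse(fail_cov, runif(m, 0.2, 0.75), runif(m, 0.85, 1))
  cov_long <- runif(m, 0.25, 1)
  g <- tibble(
    protein1 = prot[i], protein2 = prot[j],
    score = score, evalue = 10^(-logev),
    cov_long = cov_long, cov_short = cov_short
  )
  self <- tibble(protein = prot,
                 self_score = rnorm(n, 2 * intra_score, intra_score / 20))
  new_similarity_graph(g, self)
}

#' Construct a planted partition membership table
#'
#' @param n_families number of families.
#' @param n_per proteins per family.
#' @return tibble with columns `protein`, `family`.
#' @export
planted_partition <- function(n_families, n_per) {
  fam <- sprintf("fam%03d", seq_len(n_families))
  tibble(
    family = rep(fam, each = n_per),
    protein = sprintf("%s_p%02d", rep(fam, each = n_per),
                      rep(seq_len(n_per), times = n_families))
  ) |> select("protein", "family")
}

new_similarity_graph <- function(edges, self_scores = NULL) {
  out <- as_tibble(edges)
  attr(out, "self_scores") <- self_scores
  class(out) <- c("similarity_graph", class(out))
  out
}

#' Self-score table of a similarity graph
#' @param graph a `similarity_graph`.
#' @return tibble `protein`, `self_score`, or `NULL` if not recorded.
#' @export
self_scores <- function(graph) attr(graph, "self_scores")
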
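#' Simulate a rooted species tree under a pure-birth process
#'
#' Generates a rooted, binary, ultrametric-in-expectation species tree by a
#' Yule (pure-birth) process, the usual null model for clade shapes. Tips are
#' labelled `sp001, sp002, ...`. The result is deterministic for a fixed
#' seed.
#'
#' @param n_tips number of extant species (>= 2).
#' @param seed integer random seed; `NULL` uses the current RNG state.
#' @param birth per-lineage speciation rate (default 1; only rescales branch
#'   lengths).
#' @return an `ape::phylo` rooted binary tree with positive branch lengths.
#' @export
#' @examples
#' tr <- simulate_species_tree(8, seed = 1)
#' ape::Ntip(tr)
simulate_species_tree <- function(n_tips, seed = NULL, birth = 1) {
  if (!is.numeric(n_tips) || length(n_tips) != 1L || n_tips < 2) {
    abort("`n_tips` must be a single integer >= 2")
  }
  n_tips <- as.integer(n_tips)
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = birth, death = 0)
  tree$tip.label <- sprintf("sp%03d", seq_len(n_tips))
  tree
}
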
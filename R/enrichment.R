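#' GO term enrichment by Fisher's exact test
#'
#' One-sided hypergeometric over-representation test of every term among a
#' study set against a population. Annotations are propagated up the term
#' DAG (a gene annotated to a term is annotated to all its ancestors)
#' before testing. Two modes are available: `"classic"` tests each term
#' independently; `"elim"` processes terms bottom-up and removes the genes
#' of significantly enriched terms from their ancestors before the
#' ancestors are tested, decorrelating nested terms.
#'
#' @param study character vector of study genes (subset of `population`,
#'   non-empty).
#' @param population character vector of population genes.
#' @param term_map tibble with columns `gene`, `term` (direct annotations).
#' @param dag optional tibble with columns `child`, `parent` describing the
#'   term DAG; `NULL` means a flat vocabulary (no propagation, elim acts on
#'   direct ancestors only, i.e. equals classic).
#' @param alpha significance level for flagging and for the elim cut
#'   (default 0.05).
#' @param method `"classic"` (default) or `"elim"`.
#' @param adjust add a Benjamini-Hochberg adjusted column (default `FALSE`;
#'   the raw p-value remains the decision column either way).
#' @return tibble `term`, `study_count`, `study_size`, `population_count`,
#'   `population_size`, `p_value`, `significant` (+ `p_adjusted` when
#'   `adjust`), sorted by p-value.
#' @export
#' @examples
#' tm <- tibble::tibble(gene = paste0("g", 1:5), term = "GO:1")
#' fisher_enrichment(paste0("g", 1:5), paste0("g", 1:20), tm)
fisher_enrichment <- function(study, population, term_map, dag = NULL,
                              alpha = 0.05, method = c("classic", "elim"),
                              adjust = FALSE) {
  method <- match.arg(method)
  study <- unique(study)
  population <- unique(population)
  if (!length(study)) abort("`study` must be non-empty")
  if (!all(study %in% population)) {
    abort("`study` must be a subset of `population`")
  }
  anc <- term_ancestors(dag, unique(term_map$term))
  genes_of <- propagate_annotations(term_map, anc)
  genes_of <- lapply(genes_of, intersect, population)
  genes_of <- genes_of[lengths(genes_of) > 0]
  if (!length(genes_of)) {
    return(tibble(term = character(), study_count = integer(),
                  study_size = integer(), population_count = integer(),
                  population_size = integer(), p_value = double(),
                  significant = logical()))
  }
  N <- length(population)
  n <- length(study)
  depth <- term_depths(dag, names(genes_of))
  order_terms <- names(genes_of)[order(-depth[names(genes_of)],
                                       names(genes_of))]
  removed <- lapply(genes_of, function(x) character(0))
  rows <- vector("list", length(order_terms))
  for (i in seq_along(order_terms)) {
    tm <- order_terms[i]
    gset <- setdiff(genes_of[[tm]], removed[[tm]])
    K <- length(gset)
    k <- length(intersect(gset, study))
    p <- hypergeom_test_p(k, K, N, n)
    rows[[i]] <- tibble(term = tm, study_count = k, study_size = n,
                        population_count = K, population_size = N,
                        p_value = p)
    if (method == "elim" && p < alpha && !is.null(dag)) {
      for (a in anc[[tm]]) {
        if (a %in% names(removed)) {
          removed[[a]] <- union(removed[[a]], genes_of[[tm]])
        }
      }
    }
  }
  out <- list_rbind(rows) |>
    mutate(significant = .data$p_value < alpha) |>
    arrange(.data$p_value, .data$term)
  if (adjust) out$p_adjusted <- stats::p.adjust(out$p_value, "BH")
  out
}

#' One-sided hypergeometric over-representation p-value
#'
#' The upper tail `P(X >= k)` for drawing `k` annotated genes in a study of
#' size `n` from a population of `N` genes of which `K` are annotated —
#' the p-value of the one-sided Fisher's exact test. Vectorized over its
#' arguments.
#'
#' @param k study genes carrying the annotation.
#' @param K population genes carrying the annotation.
#' @param N population size.
#' @param n study size.
#' @return p-values in `(0, 1]`.
#' @export
hypergeom_test_p <- function(k, K, N, n) {
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

# all strict ancestors per term (empty dag -> empty sets)
term_ancestors <- function(dag, terms) {
  anc <- setNames(vector("list", length(terms)), terms)
  if (is.null(dag) || !nrow(dag)) {
    return(lapply(anc, function(x) character(0)))
  }
  parents <- split(dag$parent, dag$child)
  get_anc <- function(t, seen = character(0)) {
    ps <- setdiff(parents[[t]] %||% character(0), seen)
    out <- ps
    for (p in ps) out <- union(out, get_anc(p, c(seen, ps)))
    out
  }
  for (t in union(terms, unique(c(dag$child, dag$parent)))) {
    anc[[t]] <- get_anc(t)
  }
  anc
}

# genes annotated to each term, including via descendants
propagate_annotations <- function(term_map, anc) {
  direct <- split(unique(term_map[c("gene", "term")])$gene,
                  unique(term_map[c("gene", "term")])$term)
  all_terms <- union(names(direct), names(anc))
  out <- setNames(lapply(all_terms, function(t) direct[[t]] %||%
                           character(0)), all_terms)
  for (t in names(direct)) {
    for (a in anc[[t]] %||% character(0)) {
      out[[a]] <- union(out[[a]] %||% character(0), direct[[t]])
    }
  }
  out
}

# longest path to a root, for bottom-up processing
term_depths <- function(dag, terms) {
  d <- setNames(rep(0L, length(terms)), terms)
  if (is.null(dag) || !nrow(dag)) return(d)
  parents <- split(dag$parent, dag$child)
  memo <- new.env(parent = emptyenv())
  depth_of <- function(t) {
    if (!is.null(memo[[t]])) return(memo[[t]])
    ps <- parents[[t]] %||% character(0)
    val <- if (!length(ps)) 0L else 1L + max(vapply(ps, depth_of, integer(1)))
    memo[[t]] <- val
    val
  }
  for (t in terms) d[t] <- depth_of(t)
  d
}

#' Minimal OBO reader for term parent extraction
#'
#' Parses just enough of an OBO file to recover `is_a` parent edges for use
#' as the DAG input of [fisher_enrichment()].
#'
#' @param path path to an OBO-format file.
#' @return tibble `child`, `parent`.
#' @export
read_obo_edges <- function(path) {
  lines <- readLines(path, warn = FALSE)
  cur <- NA_character_
  ch <- pa <- character(0)
  for (ln in lines) {
    if (ln == "[Term]") cur <- NA_character_
    if (startsWith(ln, "id: ")) cur <- sub("^id: ", "", ln)
    if (startsWith(ln, "is_a: ") && !is.na(cur)) {
      ch <- c(ch, cur)
      pa <- c(pa, sub(" !.*$", "", sub("^is_a: ", "", ln)))
    }
  }
  tibble(child = ch, parent = pa)
}
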
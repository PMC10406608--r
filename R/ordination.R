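#' Select homologous groups for gene-content ordination
#'
#' Keeps HGs with at least `min_proteins` member proteins and at least
#' `min_conservation` conservation in at least one clade — the filter used
#' before presence/absence ordination so that tiny or scattered groups do
#' not dominate the distances.
#'
#' @param presence HGs x species presence (logical or counts) matrix.
#' @param sizes named integer vector HG -> number of member proteins.
#' @param clades named list of character vectors (species clades).
#' @param min_proteins minimum member count (default 4).
#' @param min_conservation inclusive conservation threshold (default 0.5).
#' @return character vector of retained HG ids.
#' @export
select_pcoa_hgs <- function(presence, sizes, clades, min_proteins = 4,
                            min_conservation = 0.5) {
  hgs <- rownames(presence)
  keep <- map_lgl(hgs, function(hg) {
    if ((sizes[[hg]] %||% 0) < min_proteins) return(FALSE)
    sp <- colnames(presence)[presence[hg, ] >= 1]
    any(map_dbl(clades, ~ conservation(sp, .x)) >= min_conservation)
  })
  hgs[keep]
}

#' Binary gene-content distance between species
#'
#' The asymmetric-mismatch coefficient `d(i,j) = (b + c) / (a + b + c)`
#' where `a` counts HGs present in both species and `b`, `c` those present
#' in only one (the Jaccard complement, the standard "binary" distance).
#' Species with no presences at all are at distance 0 from identically
#' empty species and 1 from everything else.
#'
#' @param presence HGs x species presence matrix (nonzero = present).
#' @return a symmetric `dist`-compatible matrix over species.
#' @export
binary_distance <- function(presence) {
  x <- t(presence >= 1)  # species x HGs
  d <- as.matrix(dist(x, method = "binary"))
  empty <- rowSums(x) == 0
  if (any(empty)) {
    d[empty, ] <- 1
    d[, empty] <- 1
    d[empty, empty] <- 0
  }
  diag(d) <- 0
  d
}

#' Principal coordinate analysis of a species distance matrix
#'
#' Classical metric scaling: the doubly centred `-d^2/2` matrix is
#' eigendecomposed and coordinates are eigenvectors scaled by the square
#' roots of their eigenvalues. Axes with non-positive eigenvalues are
#' reported but never used for coordinates. A minimum spanning tree over
#' the input distances is attached for overlay plotting.
#'
#' @param d symmetric distance matrix with zero diagonal (e.g. from
#'   [binary_distance()]).
#' @param k number of coordinate axes to return (default 2; capped at the
#'   number of positive eigenvalues).
#' @param mst attach a minimum spanning tree (default `TRUE`).
#' @return object of class `gc_pcoa`: list with `points` (tibble `label`,
#'   `axis1`, ... `axisk`), `eigenvalues` (all, descending),
#'   `prop_variance` (shares of the positive eigenvalue total), `mst`
#'   (tibble `from`, `to`, `weight` or `NULL`).
#' @export
gc_pcoa <- function(d, k = 2, mst = TRUE) {
  d <- as.matrix(d)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8))) {
    abort("`d` must be symmetric")
  }
  n <- nrow(d)
  labs <- rownames(d) %||% as.character(seq_len(n))
  sc <- suppressWarnings(cmdscale(as.dist(d), k = n - 1L, eig = TRUE))
  eig <- sc$eig  # already descending
  pos <- min(sum(eig > n * sqrt(.Machine$double.eps) * max(abs(eig), 1)),
             ncol(sc$points))
  k_use <- min(k, pos)
  pts <- sc$points[, seq_len(k_use), drop = FALSE]
  if (k_use) colnames(pts) <- paste0("axis", seq_len(k_use))
  points <- bind_cols(tibble(label = labs), as_tibble(pts))
  structure(
    list(
      points = points,
      coordinates_full = sc$points[, seq_len(pos), drop = FALSE],
      eigenvalues = eig,
      prop_variance = pmax(eig, 0) / sum(pmax(eig, 0)),
      mst = if (mst && n >= 2L) mst_edges(d) else NULL
    ),
    class = "gc_pcoa"
  )
}

#' @export
print.gc_pcoa <- function(x, ...) {
  cat("<gc_pcoa> ", nrow(x$points), " points, ",
      ncol(x$coordinates_full), " positive axes\n", sep = "")
  cat("  variance on first axes:",
      paste0(round(100 * head(x$prop_variance, 3), 1), "%", collapse = ", "),
      "\n")
  invisible(x)
}

#' Minimum spanning tree of a distance matrix
#'
#' Kruskal's algorithm with deterministic tie-breaking (equal-weight edges
#' are taken in lexicographic label order), returning the `n - 1` tree
#' edges.
#'
#' @param d symmetric distance matrix with labelled rows.
#' @return tibble `from`, `to`, `weight`.
#' @export
mst_edges <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  labs <- rownames(d) %||% as.character(seq_len(n))
  if (n < 2L) abort("need >= 2 points for a spanning tree")
  pairs <- combn(n, 2L)
  e <- tibble(i = pairs[1L, ], j = pairs[2L, ],
              from = labs[pairs[1L, ]], to = labs[pairs[2L, ]],
              weight = d[cbind(pairs[1L, ], pairs[2L, ])]) |>
    arrange(.data$weight, .data$from, .data$to)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  keep <- logical(nrow(e))
  taken <- 0L
  for (r in seq_len(nrow(e))) {
    ri <- find(e$i[r]); rj <- find(e$j[r])
    if (ri != rj) {
      parent[rj] <- ri
      keep[r] <- TRUE
      taken <- taken + 1L
      if (taken == n - 1L) break
    }
  }
  e[keep, c("from", "to", "weight")]
}
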
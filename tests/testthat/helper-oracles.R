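# Independent oracles used by unit and acceptance tests. Each is written
# as a separate, straight-line implementation so it shares no code with the
# package's own algorithms.

# --- exhaustive Dollo minimization -------------------------------------

# Minimum-loss (gain node, loss count) by trying every gain node and every
# subset of branches below it, smallest subsets first.
brute_dollo <- function(tree, present_species) {
  idx <- dollodyn:::tree_index(tree)
  present <- unname(idx$tip_id[present_species])
  nn <- idx$n_tip + tree$Nnode
  best_gain <- NA_integer_
  best_losses <- Inf
  for (g in seq_len(nn)) {
    sub <- dollodyn:::subtree_nodes(idx, g)
    tips_below <- sub[sub <= idx$n_tip]
    if (!all(present %in% tips_below)) next
    branches <- setdiff(sub, g)
    path_of <- lapply(tips_below, function(t) {
      v <- t
      p <- integer(0)
      while (v != g) {
        p <- c(p, v)
        v <- idx$parent[v]
      }
      p
    })
    want_hit <- !(tips_below %in% present)
    found <- NA_integer_
    for (k in 0:length(branches)) {
      if (k >= best_losses) break
      combos <- utils::combn(seq_along(branches), k, simplify = FALSE)
      for (S in combos) {
        loss <- branches[S]
        hit <- vapply(path_of, function(p) any(p %in% loss), logical(1))
        if (all(hit == want_hit)) {
          found <- k
          break
        }
      }
      if (!is.na(found)) break
    }
    if (!is.na(found) && found < best_losses) {
      best_losses <- found
      best_gain <- g
    }
  }
  list(gain_node = best_gain, n_losses = best_losses)
}

# all rooted binary tree shapes with n tips, as newick with tips t1..tn
tree_shapes <- function(n) {
  shapes <- function(m) {
    if (m == 1L) return("x")
    out <- character(0)
    for (i in seq_len(m %/% 2L)) {
      for (a in shapes(i)) {
        for (b in shapes(m - i)) {
          out <- c(out, paste0("(", a, ",", b, ")"))
        }
      }
    }
    unique(out)
  }
  vapply(shapes(n), function(s) {
    for (i in seq_len(n)) s <- sub("x", paste0("t", i), s, fixed = TRUE)
    paste0(s, ";")
  }, character(1), USE.NAMES = FALSE)
}

# --- reference MCL ------------------------------------------------------

# A second, independently written Markov clustering pass (plain loops, its
# own convergence test and component extraction).
ref_mcl <- function(edges, nodes, inflation = 2) {
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(edges))) {
    i <- edges$protein1[r]
    j <- edges$protein2[r]
    A[i, j] <- max(A[i, j], edges$score[r])
    A[j, i] <- A[i, j]
  }
  for (v in seq_len(n)) {
    mx <- max(A[, v])
    A[v, v] <- if (mx > 0) mx else 1
  }
  M <- A %*% diag(1 / colSums(A))
  for (it in 1:200) {
    Mn <- (M %*% M)^inflation
    Mn[Mn < 1e-8] <- 0
    Mn <- Mn %*% diag(1 / colSums(Mn))
    done <- max(abs(Mn - M)) < 1e-7
    M <- Mn
    if (done) break
  }
  adj <- (M + t(M)) > 0
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1L]
      queue <- queue[-1L]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  unname(split(nodes, comp))
}

# compare two partitions as sets of sets
same_partition <- function(a, b) {
  norm <- function(p) unname(sort(vapply(p, function(s)
    paste(sort(s), collapse = "|"), character(1), USE.NAMES = FALSE)))
  identical(norm(a), norm(b))
}

partition_from_tibble <- function(df) unname(split(df$protein, df$hg))

# --- Monte-Carlo oracle for the gene-content simulator ------------------

# Vectorized re-implementation of the generative model; returns the
# per-replicate mean tip copy number for non-extinct replicates.
mc_tip_copy_means <- function(tree, duplication_rate, loss_rate, reps,
                              seed) {
  set.seed(seed)
  idx <- dollodyn:::tree_index(tree)
  nn <- idx$n_tip + tree$Nnode
  origins <- sample.int(nn, reps, replace = TRUE)
  copies <- matrix(0L, reps, nn)
  has_parent <- !is.na(idx$parent[origins])
  odup <- integer(reps)
  odup[has_parent] <- stats::rpois(sum(has_parent),
                                   duplication_rate *
                                     idx$edge_length[origins[has_parent]])
  copies[cbind(seq_len(reps), origins)] <- 1L + odup
  for (v in idx$preorder) {
    p <- idx$parent[v]
    if (is.na(p)) next
    cp <- copies[, p]
    act <- cp > 0L & origins != v
    if (!any(act)) next
    lam <- cp[act] * idx$edge_length[v]
    d <- stats::rpois(sum(act), duplication_rate * lam)
    l <- pmin(stats::rpois(sum(act), loss_rate * lam), cp[act] + d)
    copies[act, v] <- cp[act] + d - l
  }
  tips <- copies[, seq_len(idx$n_tip), drop = FALSE]
  keep <- rowSums(tips) > 0L
  rowMeans(tips[keep, , drop = FALSE])
}

# --- exact hypergeometric tail -----------------------------------------

hyper_tail <- function(k, K, N, n) {
  j <- k:min(K, n)
  j <- j[j >= max(0L, n - (N - K))]
  if (!length(j) || k > min(K, n)) return(0)
  sum(exp(lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)))
}

# --- random fixtures ----------------------------------------------------

random_cluster_graph <- function(n_nodes, edge_prob, seed) {
  set.seed(seed)
  ids <- sprintf("C%02d", seq_len(n_nodes))
  pairs <- utils::combn(n_nodes, 2L)
  keep <- stats::runif(ncol(pairs)) < edge_prob
  edges <- tibble::tibble(
    hg1 = ids[pairs[1L, keep]],
    hg2 = ids[pairs[2L, keep]],
    n_edges = 1L + stats::rpois(sum(keep), 2),
    weight = stats::runif(sum(keep))
  )
  dollodyn:::new_cluster_graph(
    edges, tibble::tibble(hg = ids, size = 1L + stats::rpois(n_nodes, 3))
  )
}

max_component_diameter <- function(cg) {
  if (!nrow(cg)) return(0)
  g <- igraph::graph_from_data_frame(cg[c("hg1", "hg2")], directed = FALSE)
  max(vapply(
    igraph::decompose(g),
    function(s) igraph::diameter(s, weights = NA), numeric(1)
  ))
}
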
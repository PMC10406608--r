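stree4 <- ape::read.tree(text = "((A,B),(C,D));")

test_that("Dollo mapping places the gain at the MRCA and losses on absent subtrees", {
  si <- dollodyn:::tree_index(stree4)
  # presence {A,B}: gain at MRCA(A,B), no losses
  m1 <- dollo_map(c("A", "B"), stree4)
  expect_equal(m1$gain_node,
               dollodyn:::mrca_nodes(si, si$tip_id[c("A", "B")]))
  expect_length(m1$loss_nodes, 0L)

  # presence {A,C}: gain at root, losses on the branches to B and D
  m2 <- dollo_map(c("A", "C"), stree4)
  expect_equal(m2$gain_node, si$root)
  expect_setequal(m2$loss_nodes, unname(si$tip_id[c("B", "D")]))

  # presence everywhere: gain at root, no losses
  m3 <- dollo_map(c("A", "B", "C", "D"), stree4)
  expect_equal(m3$gain_node, si$root)
  expect_length(m3$loss_nodes, 0L)

  expect_error(dollo_map(character(0), stree4), "empty")
  expect_error(dollo_map("Z", stree4), "not in tree")
})

test_that("Dollo equals exhaustive minimization on all small tree shapes", {
  for (n in 2:4) {
    for (nwk in tree_shapes(n)) {
      tr <- ape::read.tree(text = nwk)
      tips <- tr$tip.label
      for (mask in 1:(2^n - 1)) {
        present <- tips[as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))]
        got <- dollo_map(present, tr)
        oracle <- brute_dollo(tr, present)
        expect_equal(got$gain_node, oracle$gain_node)
        expect_equal(length(got$loss_nodes), oracle$n_losses)
      }
    }
  }
})

test_that("copy-number histories satisfy the bookkeeping identity per family", {
  counts <- c(A = 3L, B = 1L, C = 0L, D = 2L)
  h <- reconstruct_family_history(counts, stree4)
  si <- dollodyn:::tree_index(stree4)
  cp <- setNames(rep(0L, length(si$parent)), seq_along(si$parent))
  cp[as.character(h$node)] <- h$copies
  for (r in seq_len(nrow(h))) {
    v <- h$node[r]
    parent_copies <- if (h$gain[r]) 0L else cp[[as.character(si$parent[v])]]
    expect_identical(
      h$copies[r],
      parent_copies + h$gain[r] + h$duplications[r] - h$losses[r]
    )
  }
  # leaves reproduce the observed counts
  expect_equal(cp[[as.character(si$tip_id[["A"]])]], 3L)
  expect_equal(cp[[as.character(si$tip_id[["D"]])]], 2L)
  # C is a loss branch
  expect_true(si$tip_id[["C"]] %in% h$node[h$losses > 0])
})

test_that("presence mode reduces every surviving node to one copy", {
  counts <- c(A = 3L, B = 1L, C = 0L, D = 2L)
  h <- reconstruct_family_history(counts, stree4, mode = "presence")
  expect_true(all(h$copies %in% c(0L, 1L)))
  expect_equal(sum(h$gain), 1L)
  expect_equal(sum(h$duplications), 0L)
})

test_that("tie-breaking keeps ancestral counts at the parent value", {
  # A=1, B=2: MRCA can be 1 or 2 at equal cost; gain-node tie goes to 1
  counts <- c(A = 1L, B = 2L, C = 0L, D = 0L)
  h <- reconstruct_family_history(counts, stree4)
  si <- dollodyn:::tree_index(stree4)
  gain <- h$node[h$gain]
  expect_equal(h$copies[h$node == gain], 1L)
})

test_that("aggregate_events sums families and keeps the identity exactly", {
  # one family present everywhere single-copy: all nodes 1, one root gain
  counts <- matrix(1L, 1, 4, dimnames = list("fam1", stree4$tip.label))
  em <- aggregate_events(counts, stree4)
  expect_true(all(em$by_node$copies == 1L))
  expect_equal(sum(em$by_node$gains), 1L)
  si <- dollodyn:::tree_index(stree4)
  expect_equal(em$by_node$gains[em$by_node$node == si$root], 1L)
  expect_equal(sum(em$by_node$duplications), 0L)
  expect_equal(sum(em$by_node$losses), 0L)
  expect_true(check_event_bookkeeping(em))

  # simulated cohort
  tr <- simulate_species_tree(12, seed = 31)
  sim <- simulate_gene_content(tr, 150, duplication_rate = 0.2,
                               loss_rate = 0.2, seed = 32)
  em2 <- aggregate_events(sim$counts, tr)
  expect_true(check_event_bookkeeping(em2))
  em2p <- aggregate_events(sim$counts, tr, mode = "presence")
  expect_true(check_event_bookkeeping(em2p))
})

test_that("aggregate_events is additive over family sets", {
  tr <- simulate_species_tree(8, seed = 41)
  sim <- simulate_gene_content(tr, 60, duplication_rate = 0.3,
                               loss_rate = 0.3, seed = 42)
  half <- nrow(sim$counts) %/% 2
  em_all <- aggregate_events(sim$counts, tr)
  em_a <- aggregate_events(sim$counts[1:half, , drop = FALSE], tr)
  em_b <- aggregate_events(sim$counts[(half + 1):nrow(sim$counts), ,
                                      drop = FALSE], tr)
  for (col in c("gains", "duplications", "losses", "copies")) {
    expect_equal(em_all$by_node[[col]],
                 em_a$by_node[[col]] + em_b$by_node[[col]])
  }
})

test_that("with no losses the reconstruction recovers the simulated truth", {
  tr <- simulate_species_tree(10, seed = 51)
  sim <- simulate_gene_content(tr, 200, duplication_rate = 0,
                               loss_rate = 0, seed = 52)
  em <- aggregate_events(sim$counts, tr)
  truth <- setNames(sim$history$origins$origin_node,
                    sim$history$origins$family)
  expect_equal(unname(em$gain_node[names(truth)]), unname(truth))
  # ancestral copy numbers equal the simulated truth at every node
  true_copies <- sim$history$copies |>
    dplyr::group_by(node) |>
    dplyr::summarise(copies = sum(copies), .groups = "drop")
  merged <- dplyr::left_join(em$by_node, true_copies, by = "node",
                             suffix = c("_inferred", "_true")) |>
    dplyr::mutate(copies_true = tidyr::replace_na(copies_true, 0L))
  expect_equal(merged$copies_inferred, merged$copies_true)
})

test_that("inferred origins never predate the true origin", {
  tr <- simulate_species_tree(12, seed = 61)
  si <- dollodyn:::tree_index(tr)
  sim <- simulate_gene_content(tr, 400, duplication_rate = 0.1,
                               loss_rate = 0.5, seed = 62)
  truth <- setNames(sim$history$origins$origin_node,
                    sim$history$origins$family)
  for (f in rownames(sim$counts)) {
    present <- colnames(sim$counts)[sim$counts[f, ] >= 1]
    g <- dollo_map(present, tr)$gain_node
    expect_true(dollodyn:::is_ancestor(si, truth[[f]], g))
  }
})

test_that("net change is gains minus losses", {
  expect_equal(net_change(1114, 323), 791)
  expect_equal(net_change(117, 184), -67)
  expect_equal(net_change(0, 0), 0)
  expect_equal(net_change(c(5, 2), c(1, 4)), c(4, -2))
  expect_error(net_change(-1, 0), "non-negative")
})
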
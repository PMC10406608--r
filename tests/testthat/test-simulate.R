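test_that("pure-birth species trees have the right shape and are reproducible", {
  expect_error(simulate_species_tree(1), "n_tips")

  cherry <- simulate_species_tree(2, seed = 11)
  expect_s3_class(cherry, "phylo")
  expect_equal(ape::Ntip(cherry), 2L)
  expect_equal(cherry$Nnode, 1L)

  t1 <- simulate_species_tree(8, seed = 1)
  t2 <- simulate_species_tree(8, seed = 1)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))

  big <- simulate_species_tree(50, seed = 7)
  expect_equal(ape::Ntip(big), 50L)
  expect_equal(big$Nnode, 49L)
  expect_true(all(big$edge.length > 0))
  expect_true(ape::is.rooted(big))
})

test_that("node numbering is a stable postorder over all nodes", {
  tr <- simulate_species_tree(7, seed = 3)
  nm <- node_numbers(tr)
  expect_equal(nrow(nm), 7L + tr$Nnode)
  expect_setequal(nm$number, seq_len(nrow(nm)))
  # every child is numbered before its parent in postorder
  idx <- dollodyn:::tree_index(tr)
  num <- setNames(nm$number, nm$node)
  for (v in which(!is.na(idx$parent))) {
    expect_lt(num[[as.character(v)]], num[[as.character(idx$parent[v])]])
  }
})

test_that("simulated histories obey the bookkeeping identity everywhere", {
  tr <- simulate_species_tree(10, seed = 5)
  sim <- simulate_gene_content(tr, 200, duplication_rate = 0.3,
                               loss_rate = 0.3, seed = 9)
  idx <- dollodyn:::tree_index(tr)
  cp <- sim$history$copies |>
    tidyr::complete(family = unique(sim$history$origins$family),
                    node = seq_len(idx$n_tip + tr$Nnode),
                    fill = list(copies = 0L))
  cmat <- tidyr::pivot_wider(cp, names_from = "node",
                             values_from = "copies")
  cmx <- as.matrix(cmat[, -1L])
  rownames(cmx) <- cmat$family
  ev <- sim$history$events
  org <- setNames(sim$history$origins$origin_node,
                  sim$history$origins$family)
  for (r in seq_len(nrow(ev))) {
    f <- ev$family[r]
    v <- ev$node[r]
    parent_copies <- if (v == org[[f]]) 1L else cmx[f, idx$parent[v]]
    expect_identical(
      cmx[f, v],
      parent_copies + ev$duplications[r] - ev$losses[r]
    )
  }
  expect_true(all(cmx >= 0L))
})

test_that("each family originates exactly once and extinct ones are flagged", {
  tr <- simulate_species_tree(8, seed = 2)
  sim <- simulate_gene_content(tr, 300, duplication_rate = 0.1,
                               loss_rate = 1.5, seed = 4)
  org <- sim$history$origins
  expect_equal(anyDuplicated(org$family), 0L)
  expect_true(any(org$extinct))  # high loss rate must kill some families
  expect_setequal(rownames(sim$counts), org$family[!org$extinct])
})

test_that("without losses, presence equals the clade below the origin", {
  tr <- simulate_species_tree(9, seed = 8)
  idx <- dollodyn:::tree_index(tr)
  sim <- simulate_gene_content(tr, 100, duplication_rate = 0.2,
                               loss_rate = 0, seed = 6)
  org <- setNames(sim$history$origins$origin_node,
                  sim$history$origins$family)
  for (f in rownames(sim$counts)) {
    clade <- tr$tip.label[dollodyn:::subtree_tips(idx, org[[f]])]
    expect_setequal(colnames(sim$counts)[sim$counts[f, ] >= 1], clade)
  }
  # root origin with no loss: present in every tip
  sim_root <- simulate_gene_content(tr, 20, loss_rate = 0,
                                    origin = "root", seed = 7)
  expect_true(all(sim_root$counts >= 1))
})

test_that("without duplications or losses every extant count is exactly 1", {
  tr <- simulate_species_tree(6, seed = 1)
  sim <- simulate_gene_content(tr, 50, duplication_rate = 0,
                               loss_rate = 0, seed = 3)
  expect_true(all(sim$counts %in% c(0L, 1L)))
  expect_true(all(rowSums(sim$counts) >= 1))
})

test_that("simulation is bit-reproducible for a fixed seed", {
  tr <- simulate_species_tree(7, seed = 4)
  a <- simulate_gene_content(tr, 40, duplication_rate = 0.2,
                             loss_rate = 0.2, seed = 12)
  b <- simulate_gene_content(tr, 40, duplication_rate = 0.2,
                             loss_rate = 0.2, seed = 12)
  expect_identical(a$counts, b$counts)
  expect_identical(a$history, b$history)
})

test_that("mean tip copy number matches a 50,000-replicate Monte-Carlo oracle", {
  tr <- simulate_species_tree(6, seed = 42)
  sim <- simulate_gene_content(tr, 500, origination_rate = 1,
                               duplication_rate = 0.2, loss_rate = 0.2,
                               seed = 3)
  stat <- mean(sim$counts)
  oracle <- mc_tip_copy_means(tr, 0.2, 0.2, reps = 50000, seed = 99)
  se <- sqrt(stats::var(oracle) / 500 + stats::var(oracle) / length(oracle))
  expect_lt(abs(stat - mean(oracle)), 3 * se)
})
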
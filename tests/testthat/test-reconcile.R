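stree_abc <- ape::read.tree(text = "((A,B),C);")
stree_abcd <- ape::read.tree(text = "((A,B),(C,D));")

test_that("LCA reconciliation labels events and counts losses correctly", {
  # congruent single-copy tree: all speciations, no losses
  gt <- ape::read.tree(text = "((A|p,B|p),C|p);")
  rec <- lca_reconcile(gt, stree_abc)
  expect_equal(rec$n_duplications, 0L)
  expect_equal(rec$n_losses, 0L)

  # two same-species copies: duplication mapped to the tip, no losses
  gt2 <- ape::read.tree(text = "((A|p1,A|p2),B|p);")
  rec2 <- lca_reconcile(gt2, ape::read.tree(text = "(A,B);"))
  expect_equal(rec2$n_duplications, 1L)
  expect_equal(rec2$n_losses, 0L)
  si <- dollodyn:::tree_index(ape::read.tree(text = "(A,B);"))
  dup_node <- rec2$nodes$species_node[rec2$nodes$event == "duplication"]
  expect_equal(unname(dup_node), unname(si$tip_id[["A"]]))

  # incongruent tree: 1 duplication, 3 losses (exhaustive hand count)
  gt3 <- ape::read.tree(text = "((A|p,C|p),B|p);")
  rec3 <- lca_reconcile(gt3, stree_abc)
  expect_equal(rec3$n_duplications, 1L)
  expect_equal(rec3$n_losses, 3L)

  expect_error(lca_reconcile(ape::read.tree(text = "((A|p,Z|p),B|p);"),
                             stree_abc), "unknown species")
})

test_that("rooting minimizes duplications plus losses", {
  # single-copy congruent tree, arbitrarily rooted: recover 0-cost rooting
  gt <- ape::read.tree(text = "(A|p,(B|p,C|p));")  # rooted "wrong"
  rooted <- root_gene_tree(gt, stree_abc)
  rec <- attr(rooted, "reconciliation")
  expect_equal(rec$n_duplications, 0L)
  expect_equal(rec$n_losses, 0L)

  # two paralog clades each congruent with the species tree:
  # root on the edge between the clades, one basal duplication
  gt2 <- ape::read.tree(
    text = "(((A|x,B|x),C|x),((A|y,B|y),C|y));")
  best <- root_gene_tree(ape::unroot(gt2), stree_abc)
  rec2 <- attr(best, "reconciliation")
  expect_equal(rec2$n_duplications, 1L)
  expect_equal(rec2$n_losses, 0L)
  gi <- dollodyn:::tree_index(best)
  expect_equal(rec2$nodes$event[rec2$nodes$node == gi$root], "duplication")

  # exhaustive check: no alternative rooting does better
  ut <- ape::unroot(gt2)
  ui <- dollodyn:::tree_index(ut)
  costs <- c()
  for (e in seq_len(nrow(ut$edge))) {
    below <- ut$tip.label[dollodyn:::subtree_tips(ui, ut$edge[e, 2])]
    if (length(below) == ape::Ntip(ut)) next
    cand <- tryCatch(ape::root(ut, outgroup = below, resolve.root = TRUE),
                     error = function(e) NULL)
    if (is.null(cand)) next
    r <- lca_reconcile(cand, stree_abc)
    costs <- c(costs, r$n_duplications + r$n_losses)
  }
  expect_equal(rec2$n_duplications + rec2$n_losses, min(costs))

  # two-leaf trees root deterministically
  gt3 <- ape::read.tree(text = "(A|p,B|p);")
  r1 <- root_gene_tree(gt3, stree_abc)
  r2 <- root_gene_tree(gt3, stree_abc)
  expect_identical(ape::write.tree(r1), ape::write.tree(r2))
})

test_that("weak edges contract into polytomies and supports survive", {
  gt <- ape::read.tree(text = "(((A|p,B|p)50,C|p)90,D|p);")
  col <- collapse_weak_edges(gt, 80)
  expect_equal(ape::Ntip(col), 4L)
  expect_equal(col$Nnode, 2L)  # one internal edge contracted

  strong <- ape::read.tree(text = "(((A|p,B|p)100,C|p)100,D|p);")
  expect_identical(ape::write.tree(collapse_weak_edges(strong, 80)),
                   ape::write.tree(strong))

  # chain of two weak edges -> single multifurcation
  chain <- ape::read.tree(text = "((((A|p,B|p)10,C|p)20,D|p)95,E|p);")
  ccol <- collapse_weak_edges(chain, 80)
  expect_equal(ccol$Nnode, 2L)
  expect_equal(ape::Ntip(ccol), 5L)
  # the supported split {A,B,C,D} survives contraction
  ci <- dollodyn:::tree_index(ccol)
  clade_sizes <- vapply((ci$n_tip + 1):(ci$n_tip + ccol$Nnode),
                        function(v)
                          length(dollodyn:::subtree_tips(ci, v)),
                        integer(1))
  expect_setequal(clade_sizes, c(5L, 4L))
})

test_that("orthogroups are maximal speciation-only subtrees", {
  # no duplications -> one orthogroup
  gt <- ape::read.tree(text = "((A|p,B|p),C|p);")
  og <- delimit_orthogroups(lca_reconcile(gt, stree_abc))
  expect_equal(length(unique(og$orthogroup)), 1L)

  # single basal duplication -> two orthogroups
  gt2 <- ape::read.tree(text = "(((A|x,B|x),C|x),((A|y,B|y),C|y));")
  og2 <- delimit_orthogroups(lca_reconcile(gt2, stree_abc))
  expect_equal(length(unique(og2$orthogroup)), 2L)
  expect_true(same_partition(
    unname(split(og2$protein, og2$orthogroup)),
    list(c("A|x", "B|x", "C|x"), c("A|y", "B|y", "C|y"))
  ))

  # nested duplications: 3 duplication nodes -> 4 orthogroups
  gt3 <- ape::read.tree(
    text = "(((A|1,B|1),(A|2,B|2)),((A|3,B|3),(A|4,B|4)));")
  rec3 <- lca_reconcile(gt3, ape::read.tree(text = "(A,B);"))
  expect_equal(rec3$n_duplications, 3L)
  og3 <- delimit_orthogroups(rec3)
  expect_equal(length(unique(og3$orthogroup)), 4L)
  expect_true(same_partition(
    unname(split(og3$protein, og3$orthogroup)),
    list(c("A|1", "B|1"), c("A|2", "B|2"), c("A|3", "B|3"), c("A|4", "B|4"))
  ))
  # every leaf in exactly one orthogroup
  expect_equal(anyDuplicated(og3$protein), 0L)
  expect_setequal(og3$protein, gt3$tip.label)

  # a chain of tip-mapped duplications isolates every copy
  chain <- ape::read.tree(text = "((((A|1,A|2),A|3),A|4),B|p);")
  recc <- lca_reconcile(chain, ape::read.tree(text = "(A,B);"))
  expect_equal(recc$n_duplications, 3L)
  ogc <- delimit_orthogroups(recc)
  expect_equal(length(unique(ogc$orthogroup)), 5L)
})
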
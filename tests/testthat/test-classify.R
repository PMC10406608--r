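test_that("conservation is the fraction of group species present", {
  group <- paste0("s", 1:10)
  expect_equal(conservation(paste0("s", 1:7), group), 0.7)
  expect_equal(conservation(character(0), group), 0)
  expect_equal(conservation(group, group), 1)
  expect_error(conservation("s1", character(0)), "non-empty")
})

test_that("the majority rule is strictly greater than one half", {
  expect_false(majority_annotation(c(TRUE, TRUE, FALSE, FALSE)))  # 2 of 4
  expect_true(majority_annotation(c(TRUE, TRUE, TRUE, FALSE)))    # 3 of 4
  expect_error(majority_annotation(logical(0)), "empty")
})

test_that("fungal-specific domains require a 99% Holomycota share", {
  tab <- matrix(
    c(99, 1,
      98, 2,
      100, 0,
      0, 0),
    ncol = 2, byrow = TRUE,
    dimnames = list(c("d99", "d98", "d100", "dzero"),
                    c("Holomycota", "Holozoa"))
  )
  expect_warning(res <- fungal_specific_domains(tab), "zero-count")
  expect_setequal(res, c("d99", "d100"))
})

test_that("the HG fungal-domain flag is inclusive at 75%", {
  doms <- list(c("F1"), c("F1", "X"), c("F2"), c("Y"))
  expect_true(hg_fungal_domain_flag(doms, c("F1", "F2")))      # 3 of 4
  expect_false(hg_fungal_domain_flag(doms, c("F1")))            # 2 of 4
  expect_false(hg_fungal_domain_flag(list(c("Y"), "Z"), "F1"))  # none
  expect_true(hg_fungal_domain_flag(list("F1", "F1"), "F1"))    # all
})

test_that("TF classification combines the DBD majority with exclusion domains", {
  dbds <- c("C2H2", "bZIP")
  fam_map <- c(C2H2 = "C2H2-like", bZIP = "bZIP")
  doms_tf <- list(c("C2H2"), c("C2H2"), c("C2H2"), c("other"), c("C2H2"))
  expect_equal(classify_tf(doms_tf, dbds, family_map = fam_map),
               "C2H2-like")

  # an exclusion domain carried by a majority vetoes the call
  doms_pep <- lapply(doms_tf, function(d) c(d, "metallopeptidase"))
  expect_true(is.na(classify_tf(doms_pep, dbds,
                                exclusion_domains = "metallopeptidase",
                                family_map = fam_map)))

  # a minority exclusion domain does not veto
  doms_mix <- doms_tf
  doms_mix[[1]] <- c(doms_mix[[1]], "metallopeptidase")
  expect_equal(classify_tf(doms_mix, dbds,
                           exclusion_domains = "metallopeptidase",
                           family_map = fam_map), "C2H2-like")

  expect_true(is.na(classify_tf(list("x", "y"), dbds)))  # no DBDs
  # exactly half with a DBD is not a majority
  expect_true(is.na(classify_tf(list("C2H2", "x"), dbds)))
})

test_that("transporter calls need the domain majority and modal PM localization", {
  doms <- list("MFS", "MFS", "MFS", "other")
  pm <- rep("plasma membrane", 4)
  expect_true(classify_transporter(doms, pm, c(20, 22, 18, 25), "MFS"))
  # modal localization elsewhere
  expect_false(classify_transporter(doms, rep("cytosol", 4),
                                    c(20, 22, 18, 25), "MFS"))
  # median PM score at the threshold is not enough (strictly greater)
  expect_false(classify_transporter(doms, pm, rep(15, 4), "MFS"))
  # localization mode tie is conservative
  tie <- c("plasma membrane", "plasma membrane", "cytosol", "cytosol")
  expect_false(classify_transporter(doms, tie, c(20, 20, 20, 20), "MFS"))
  # domain minority
  expect_false(classify_transporter(list("MFS", "x", "y", "z"), pm,
                                    c(20, 20, 20, 20), "MFS"))
  expect_false(classify_transporter(list(), character(0), numeric(0), "MFS"))
})

test_that("SSP calls respect the length boundary and the TM exclusion", {
  expect_true(classify_ssp(299, TRUE, FALSE))
  expect_false(classify_ssp(300, TRUE, FALSE))
  expect_false(classify_ssp(100, TRUE, TRUE))
  expect_false(classify_ssp(100, FALSE, FALSE))
  expect_equal(classify_ssp(c(299, 300), c(TRUE, TRUE), c(FALSE, FALSE)),
               c(TRUE, FALSE))
})

test_that("protist-conserved-lost recovers planted loss families exactly", {
  tr <- simulate_species_tree(12, seed = 71)
  si <- dollodyn:::tree_index(tr)
  tips <- tr$tip.label
  # define Dikarya as one deep clade of >= 3 species
  cl <- sapply((si$n_tip + 1):(si$n_tip + tr$Nnode), function(v)
    length(dollodyn:::subtree_tips(si, v)))
  cand <- (si$n_tip + 1):(si$n_tip + tr$Nnode)
  dk_node <- cand[cl >= 3 & cl <= 5][1]
  dikarya <- tips[dollodyn:::subtree_tips(si, dk_node)]
  holomycota_node <- si$root
  protists <- setdiff(tips, dikarya)

  n_planted <- 25
  pres <- matrix(0L, n_planted + 10, length(tips),
                 dimnames = list(sprintf("hg%03d", seq_len(n_planted + 10)),
                                 tips))
  pres[seq_len(n_planted), protists] <- 1L              # planted losses
  pres[(n_planted + 1):(n_planted + 10), ] <- 1L         # retained everywhere
  gain <- setNames(rep(si$root, nrow(pres)), rownames(pres))
  got <- protist_conserved_lost(
    pres, gain, groups = list(protists = protists),
    holomycota_node = holomycota_node, dikarya = dikarya, stree = tr
  )
  expect_setequal(got, sprintf("hg%03d", seq_len(n_planted)))

  # family gained below the Holomycota ancestor is excluded
  gain2 <- gain
  gain2[1] <- dk_node
  got2 <- protist_conserved_lost(
    pres, gain2, groups = list(protists = protists),
    holomycota_node = holomycota_node, dikarya = dikarya, stree = tr
  )
  expect_false("hg001" %in% got2)
})

test_that("novel-core families must postdate the reference node and stay conserved", {
  tr <- ape::read.tree(text = "(((A,B),(C,D)),(E,F));")
  si <- dollodyn:::tree_index(tr)
  ref <- si$root
  abcd <- dollodyn:::mrca_nodes(si, si$tip_id[c("A", "B", "C", "D")])
  pres <- rbind(
    core = c(A = 1, B = 1, C = 1, D = 1, E = 0, F = 0),
    old = c(A = 1, B = 1, C = 1, D = 1, E = 1, F = 1),
    patchy = c(A = 1, B = 0, C = 0, D = 0, E = 0, F = 0)
  )
  colnames(pres) <- tr$tip.label
  gains <- c(core = abcd, old = ref, patchy = abcd)
  got <- novel_core(pres, gains, reference_node = ref, stree = tr)
  expect_equal(got, "core")  # old predates ref; patchy is 25% < 70%

  # exactly at the conservation boundary: 3 of 4 = 0.75 >= 0.70 included,
  # while 0.69-level conservation (patchy) is excluded
  pres2 <- pres
  pres2["patchy", ] <- c(1, 1, 1, 0, 0, 0)
  got2 <- novel_core(pres2, gains, reference_node = ref, stree = tr)
  expect_setequal(got2, c("core", "patchy"))
})

test_that("Shannon diversity matches closed forms and its upper bound", {
  expect_equal(shannon_diversity(5), 0)
  expect_equal(shannon_diversity(c(1, 1)), log(2))
  expect_equal(shannon_diversity(c(3, 1)),
               -(0.75 * log(0.75) + 0.25 * log(0.25)),
               tolerance = 1e-12)
  expect_equal(round(shannon_diversity(c(3, 1)), 4), 0.5623)
  for (s in 1:10) {
    set.seed(s)
    x <- rpois(6, 4) + 1
    expect_lte(shannon_diversity(x), log(sum(x > 0)) + 1e-12)
  }
  expect_equal(shannon_diversity(rep(7, 9)), log(9))
  expect_error(shannon_diversity(c(0, 0)), "positive sum")
})

test_that("classifiers are order-independent", {
  doms <- list(c("C2H2"), c("C2H2"), c("other"), c("C2H2"))
  set.seed(1)
  for (i in 1:5) {
    p <- sample(length(doms))
    expect_equal(classify_tf(doms[p], "C2H2"), classify_tf(doms, "C2H2"))
  }
})
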
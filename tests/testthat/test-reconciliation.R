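congruent_case <- function() {
  gt <- ape::read.tree(text = "((A_1,B_1),C_1);")
  sp <- ape::read.tree(text = "((A,B),C);")
  tm <- data.frame(gene_tip = gt$tip.label, species = sub("_.*", "", gt$tip.label))
  list(gt = gt, sp = sp, tm = tm)
}

test_that("a congruent single-copy family reconciles with zero duplications", {
  cc <- congruent_case()
  rec <- lca_reconcile(cc$gt, cc$sp, cc$tm)
  expect_equal(n_duplications(rec), 0)
  root_row <- rec[rec$gene_node == 4, ]  # gene root
  expect_equal(root_row$event, "speciation")
  expect_equal(root_row$species_node, 4)  # species root
  # one copy at every species node
  expect_true(all(copy_count_table(rec)$copies == 1))
})

test_that("a duplicated two-species family places one duplication at the LCA", {
  gt <- ape::read.tree(text = "((A_1,B_1),(A_2,B_2));")
  sp <- ape::read.tree(text = "((A,B),C);")
  tm <- data.frame(gene_tip = gt$tip.label, species = sub("_.*", "", gt$tip.label))
  rec <- lca_reconcile(gt, sp, tm)
  expect_equal(n_duplications(rec), 1)
  dup <- rec[rec$event == "duplication", ]
  expect_equal(dup$species_node, mrca_node(sp, c("A", "B"))$node)
  # brute force confirms one duplication is the parsimony minimum
  expect_equal(oracle_min_dups(gt, sp, tm), 1)
})

test_that("within-terminal expansions map to the terminal branch", {
  # two copies confined to one tardigrade-like terminal
  gt <- ape::read.tree(text = "(((T_1,T_2),A_1),B_1);")
  sp <- ape::read.tree(text = "((T,A),B);")
  tm <- data.frame(gene_tip = gt$tip.label, species = sub("_.*", "", gt$tip.label))
  rec <- lca_reconcile(gt, sp, tm)
  dup <- rec[rec$event == "duplication", ]
  expect_equal(nrow(dup), 1)
  expect_equal(dup$species_label, "T")
  expect_equal(copies_at(rec, "T"), 2)
  expect_equal(copies_at(rec, c("T", "B")), 1)
})

test_that("reconciliation errors name missing tips and species", {
  cc <- congruent_case()
  expect_error(lca_reconcile(cc$gt, cc$sp, cc$tm[-2, ]), "B_1")
  tm_bad <- cc$tm
  tm_bad$species[1] <- "Zz"
  expect_error(lca_reconcile(cc$gt, cc$sp, tm_bad), "Zz")
})

test_that("the mapping is monotone and matches the brute-force minimum", {
  set.seed(11)
  for (i in 1:40) {
    case <- random_reconciliation_case(n_species = sample(3:5, 1),
                                       n_gene_tips = sample(4:6, 1))
    rec <- lca_reconcile(case$gene_tree, case$species_tree, case$tip_map)
    # monotone: each node's mapping is ancestor-or-equal of its children's
    sp <- case$species_tree
    anc <- chronopsin:::ancestor_list(sp)
    map <- attr(rec, "map")
    gt <- case$gene_tree
    for (k in seq_len(nrow(gt$edge))) {
      u <- gt$edge[k, 1]; v <- gt$edge[k, 2]
      expect_true(map[u] == map[v] || map[u] %in% anc[[map[v]]])
    }
    expect_equal(n_duplications(rec),
                 oracle_min_dups(case$gene_tree, case$species_tree,
                                 case$tip_map))
  }
})

test_that("copy counts are non-decreasing rootward-to-crownward without loss", {
  # loss-free family: every species retains every paralogue born above it
  gt <- ape::read.tree(text =
    "(((A_x,B_x),(A_y,B_y)),C_1);")
  sp <- ape::read.tree(text = "((A,B),C);")
  tm <- data.frame(gene_tip = gt$tip.label, species = sub("_.*", "", gt$tip.label))
  rec <- lca_reconcile(gt, sp, tm)
  root <- copies_at(rec, c("A", "C"))
  ab <- copies_at(rec, c("A", "B"))
  tipA <- copies_at(rec, "A")
  expect_true(root <= ab && ab <= tipA)
  expect_equal(c(root, ab, tipA), c(1, 2, 2))
})

test_that("multifurcating gene trees reconcile without binarization", {
  gt <- ape::read.tree(text = "(A_1,B_1,C_1);")
  sp <- ape::read.tree(text = "((A,B),C);")
  tm <- data.frame(gene_tip = gt$tip.label, species = sub("_.*", "", gt$tip.label))
  rec <- lca_reconcile(gt, sp, tm)
  expect_equal(n_duplications(rec), 0)
  expect_equal(rec$species_node[rec$gene_node == 4], 4)
})

test_that("the opsin distribution fixture gives 1 root and 4 crown lineages", {
  d <- opsin_distribution()
  rec <- lca_reconcile(d$gene_tree, d$species_tree, d$tip_map)
  expect_equal(n_duplications(rec), 4)
  expect_equal(copies_at(rec, c("Priapulida", "Pancrustacea")), 1)
  expect_equal(copies_at(rec, c("Chelicerata", "Pancrustacea")), 4)
  expect_equal(copies_at(rec, "Pancrustacea"), 5)
  # the single ancestral lineage passes through the onychophoran-split node
  expect_equal(copies_at(rec, c("Onychophora", "Pancrustacea")), 1)
})
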
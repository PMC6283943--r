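test_that("branch-length dialect derives node ages by subtraction", {
  tr <- parse_dated_tree("((A:10,B:10):5,C:15);", dialect = "branch_lengths",
                         root_age = 15)
  tab <- tidy(tr)
  expect_equal(tab$age[tab$label %in% c("A", "B", "C")], c(0, 0, 0))
  expect_equal(sort(tab$age[tab$kind == "internal"]), c(10, 15))
  expect_true(all(tab$kind[1:3] == "extant"))
})

test_that("annotated dialect parses ages and normalizes interval order", {
  # intervals deliberately written old-first
  txt <- "((A,B)[&age=10,ci={12,8}],(C,D)[&age=13,ci={14,11}])[&age=15,ci={18,14}];"
  tr <- parse_dated_tree(txt)
  tab <- tidy(tr)
  ab <- tab[!is.na(tab$age) & tab$age == 10, ]
  expect_equal(ab$ci_young, 8)
  expect_equal(ab$ci_old, 12)
  expect_true(all(tab$ci_young <= tab$ci_old, na.rm = TRUE))
})

test_that("fossil tips are recognized from positive tip ages", {
  txt <- "((A[&age=0],F[&age=520])[&age=540],B[&age=0])[&age=600];"
  tr <- parse_dated_tree(txt)
  tab <- tidy(tr)
  expect_equal(tab$kind[tab$label %in% "F"], "fossil")
  expect_equal(tab$kind[tab$label %in% "A"], "extant")
})

test_that("malformed syntax errors name a character offset", {
  expect_error(parse_dated_tree("((A,B),C));"), "offset")
  expect_error(parse_dated_tree("((A,B,C;"), "unclosed")
  expect_error(parse_dated_tree("((A,B),C)"), "';'")
})

test_that("validation rejects duplicate tips and age inversions", {
  expect_error(parse_dated_tree("((A,A),B);"), "duplicate tip")
  # child annotated older than its parent
  expect_error(parse_dated_tree("((A,B)[&age=20],C)[&age=15];"),
               "monotonicity")
  expect_error(
    dated_tree(ape::read.tree(text = "((A:1,B:1):1,C:2);"),
               ages = data.frame(node = 4, age = -5)),
    "negative")
})

test_that("point estimates must lie inside their intervals", {
  expect_error(parse_dated_tree("((A,B)[&age=10,ci={12,14}],C)[&age=20];"),
               "outside")
})

test_that("single-tip and interval-bearing trees write valid text", {
  one <- dated_tree(ape::read.tree(text = "(A:0);"))
  expect_match(write_dated_tree(one, dialect = "bare"), "A")
  tr <- parse_dated_tree("((A,B)[&age=10,ci={8,12}],C)[&age=15];")
  out <- write_dated_tree(tr)
  expect_match(out, "ci=\\{8,12\\}")
})

test_that("parse/write round-trips on a random corpus, newick and nexus", {
  set.seed(42)
  for (i in 1:200) {
    tr <- random_dated_tree(n_tips = sample(3:10, 1),
                            root_age = stats::runif(1, 100, 900))
    txt <- write_dated_tree(tr)
    expect_true(dated_tree_equal(tr, parse_dated_tree(txt)),
                info = paste("newick corpus tree", i))
  }
  set.seed(99)
  tr <- random_dated_tree(8)
  nx <- write_dated_tree(tr, format = "nexus")
  expect_true(dated_tree_equal(tr, parse_dated_tree(nx, format = "nexus")))
})

test_that("round-trip preserves fossil-bearing simulated trees", {
  cfg <- sim_config(seed = 314)
  tr <- simulate_species_tree(cfg)
  expect_true(dated_tree_equal(tr, parse_dated_tree(write_dated_tree(tr))))
})

test_that("mrca_node matches the ancestor-path-intersection oracle", {
  set.seed(7)
  for (i in 1:100) {
    tr <- random_dated_tree(n_tips = sample(4:12, 1))
    tips <- sample(tr$phylo$tip.label, 2)
    expect_equal(mrca_node(tr, tips)$node, oracle_mrca(tr$phylo, tips))
  }
})

test_that("mrca_node handles singletons and rejects bad input", {
  tr <- parse_dated_tree("((A,B),C);", dialect = "bare")
  expect_equal(mrca_node(tr, "A")$label, "A")
  expect_equal(mrca_node(tr, c("A", "B"))$age,
               tidy(tr)$age[5])  # the AB node
  expect_error(mrca_node(tr, character(0)), "non-empty")
  expect_error(mrca_node(tr, "Z"), "unknown tip")
})

test_that("attach_node_ages targets the MRCA and leaves topology intact", {
  tr <- parse_dated_tree("((A,B),(C,D));", dialect = "bare")
  at <- data.frame(tip_a = "A", tip_b = "B", age = 530,
                   ci_young = 519, ci_old = 540)
  tr2 <- attach_node_ages(tr, at)
  node <- mrca_node(tr2, c("A", "B"))
  expect_equal(node$age, 530)
  expect_equal(node$ci_young, 519)
  expect_identical(chronopsin:::clade_keys(tr$phylo),
                   chronopsin:::clade_keys(tr2$phylo))
})

test_that("attach_node_ages is idempotent on agreeing rows, errors otherwise", {
  tr <- parse_dated_tree("((A,B),C);", dialect = "bare")
  at <- data.frame(tip_a = c("A", "B"), tip_b = c("B", "A"),
                   age = c(100, 100), ci_young = c(90, 90), ci_old = c(110, 110))
  expect_no_error(attach_node_ages(tr, at))
  bad <- data.frame(tip_a = c("A", "B"), tip_b = c("B", "A"),
                    age = c(100, 120), ci_young = NA, ci_old = NA)
  expect_error(attach_node_ages(tr, bad), "conflicting")
  expect_error(attach_node_ages(tr, data.frame(tip_a = "A", tip_b = "A",
                                               age = 5)),
               "distinct tips")
  expect_error(attach_node_ages(tr, data.frame(tip_a = "A", tip_b = "Z",
                                               age = 5)),
               "unknown tip")
})

test_that("attach_node_ages enforces monotonicity against assigned ancestors", {
  tr <- parse_dated_tree("(((A,B),C),D);", dialect = "bare")
  tr <- attach_node_ages(tr, data.frame(tip_a = "A", tip_b = "C", age = 100))
  expect_error(
    attach_node_ages(tr, data.frame(tip_a = "A", tip_b = "B", age = 150)),
    "monotonicity")
})
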
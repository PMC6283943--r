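test_that("sim_config validates rates and fractions", {
  expect_error(sim_config(rho = 0), "rho")
  expect_error(sim_config(birth = -1))
  expect_error(sim_config(ci_level = 1))
  expect_s3_class(sim_config(), "sim_config")
})

test_that("the pure-birth limit yields an all-extant tree", {
  cfg <- sim_config(birth = 0.008, death = 0, psi = 0, rho = 1, seed = 2)
  tr <- simulate_species_tree(cfg)
  tab <- tidy(tr)
  tips <- tab[tab$kind != "internal", ]
  expect_true(all(tips$kind == "extant"))
  expect_true(all(tips$age == 0))
  expect_gte(nrow(tips), 2)
})

test_that("simulation is deterministic under a fixed seed", {
  cfg <- sim_config(seed = 77)
  t1 <- simulate_species_tree(cfg)
  t2 <- simulate_species_tree(cfg)
  expect_true(dated_tree_equal(t1, t2, tol = 0))
  b1 <- simulate_truth_bundle(sim_config(seed = 78))
  b2 <- simulate_truth_bundle(sim_config(seed = 78))
  expect_identical(b1$foci, b2$foci)
  expect_true(dated_tree_equal(b1$observed_tree, b2$observed_tree, tol = 0))
})

test_that("hopeless rates fail with advice after bounded retries", {
  cfg <- sim_config(birth = 0.0005, death = 0.05, rho = 0.01)
  expect_error(simulate_species_tree(cfg, max_tries = 5), "increase birth")
})

test_that("fossil counts scale with psi times total branch length", {
  set.seed(12)
  base <- random_dated_tree(n_tips = 10, root_age = 500, ci_halfwidth = 0)
  # total branch length in Ma from the age table
  par <- chronopsin:::parent_vector(base$phylo)
  total <- sum(base$ages$age[par[base$phylo$edge[, 2]]] -
                 base$ages$age[base$phylo$edge[, 2]])
  psi <- 0.002
  counts <- vapply(1:1000, function(i) {
    sum(tidy(scatter_fossils(base, psi))$kind == "fossil")
  }, numeric(1))
  lambda <- psi * total
  se <- sqrt(lambda / 1000)
  expect_lt(abs(mean(counts) - lambda), 4 * se)
})

test_that("explicit duplication times build a dated chain, with validation", {
  glt <- simulate_duplications(span = c(500, 600),
                               times = c(590, 575, 540, 510))
  expect_equal(sum(!glt$is_leaf), 4)
  expect_equal(attr(glt, "true_times"), c(590, 575, 540, 510))
  expect_equal(glt$ci_young[1], glt$ci_old[1])  # degenerate truth intervals
  expect_error(simulate_duplications(span = c(500, 600), times = c(650, 550)),
               "outside")
  expect_error(simulate_duplications(span = c(500, 600), times = c(550, 590)),
               "decreasing")
})

test_that("empty and rate-zero histories collapse to a single gene", {
  g0 <- simulate_duplications(span = c(0, 600), times = numeric(0))
  expect_equal(nrow(g0), 1)
  expect_true(g0$is_leaf[1])
  g1 <- simulate_duplications(span = c(0, 600), rate = 0)
  expect_equal(nrow(g1), 1)
})

test_that("the backbone span comes from the tree when given", {
  cfg <- sim_config(seed = 5)
  tr <- simulate_species_tree(cfg)
  tip <- tidy(tr)$label[tidy(tr)$kind == "extant"][1]
  root_age <- tidy(tr)$age[chronopsin:::root_node(tr$phylo)]
  expect_error(simulate_duplications(tr, backbone = tip,
                                     times = root_age + 10),
               "outside")
  glt <- simulate_duplications(tr, backbone = tip, times = root_age - 1)
  expect_equal(sum(!glt$is_leaf), 1)
})

test_that("zero noise gives degenerate intervals at the truth", {
  post <- simulate_age_posteriors(c(600, 500, 400), rel_sd = 0)
  expect_equal(post$ci_young, c(600, 500, 400))
  expect_equal(post$ci_old, post$ci_young)
  expect_error(simulate_age_posteriors(c(600), rel_sd = -0.1), ">= 0")
})

test_that("posterior emulation is seed-deterministic and near-nominal", {
  a <- simulate_age_posteriors(rep(550, 5), 0.02, seed = 4)
  b <- simulate_age_posteriors(rep(550, 5), 0.02, seed = 4)
  expect_identical(a, b)
  set.seed(31)
  post <- simulate_age_posteriors(rep(600, 1000), rel_sd = 0.03,
                                  n_samples = 400)
  coverage <- mean(post$ci_young <= post$truth & post$truth <= post$ci_old)
  expect_gt(coverage, 0.92)
  expect_lt(coverage, 0.98)
})

test_that("zero-noise bundles are recovered exactly", {
  set.seed(41)
  cfg <- sim_config(birth = 0.008, death = 0.004, rel_sd = 0)
  for (i in 1:10) {
    m <- glance(evaluate_recovery(simulate_truth_bundle(cfg)))
    expect_equal(m$exact_rate, 1)
    expect_equal(m$overclaim_rate, 0)
    expect_equal(m$underclaim_rate, 0)
  }
})

test_that("a duplication exactly at the divergence time never overclaims", {
  glt <- simulate_duplications(span = c(400, 620), times = c(600, 500))
  # divergence exactly at a duplication: strict rule keeps the ancestral gene
  comp <- infer_complement(glt, ci(500, 500))
  expect_false("G3" %in% comp)  # never the post-500 daughter pair alone
  expect_true(any(vapply(comp, function(g) {
    setequal(chronopsin:::name_components(g), c("G2", "G3"))
  }, logical(1))))
})
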
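#' Configuration for the synthetic dated-tree generator
#'
#' The generator forward-simulates a birth-death tree over geological time,
#' samples extant survivors with probability `rho`, scatters fossil tips along
#' branches as a Poisson process with rate `psi` (per lineage per Ma), draws
#' the root age from a Gamma prior, and emulates Bayesian dating output by
#' perturbing node ages into 95% credibility intervals. Defaults emulate the
#' scale of a deep-time (Ediacaran-Cambrian) invertebrate analysis: a root on
#' the order of 600 Ma with a 26 Ma prior standard deviation, tens of sampled
#' tips, a handful of fossil tips, four stem-lineage gene duplications, and
#' interval widths around 20-25 Ma.
#'
#' @param birth,death Speciation and extinction rates, per lineage per Ma.
#' @param rho Extant sampling fraction in (0, 1].
#' @param psi Fossil-recovery rate, per lineage per Ma.
#' @param root_age_mean,root_age_sd Gamma prior on the root age, Ma.
#' @param n_duplications Number of stem duplications in the default scenario.
#' @param dup_times Optional explicit duplication times (Ma, strictly
#'   decreasing); overrides `n_duplications` sampling.
#' @param rel_sd Relative standard deviation of the emulated posterior age
#'   noise (sd of log-age). 0 gives degenerate intervals.
#' @param n_samples Posterior draws per node used to form equal-tailed
#'   intervals.
#' @param ci_level Credibility level of emitted intervals.
#' @param n_foci Number of backbone divergences used as inference foci.
#' @param seed Optional integer seed; every generator is deterministic given
#'   the seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(birth = 0.012, death = 0.006, rho = 0.25, psi = 0.004,
                       root_age_mean = 600, root_age_sd = 26,
                       n_duplications = 4, dup_times = NULL,
                       rel_sd = 0.01, n_samples = 500, ci_level = 0.95,
                       n_foci = 5, seed = NULL) {
  stopifnot(birth >= 0, death >= 0, psi >= 0, rho > 0, rho <= 1,
            root_age_mean > 0, root_age_sd > 0,
            rel_sd >= 0, n_samples >= 2, ci_level > 0, ci_level < 1)
  structure(list(birth = birth, death = death, rho = rho, psi = psi,
                 root_age_mean = root_age_mean, root_age_sd = root_age_sd,
                 n_duplications = n_duplications, dup_times = dup_times,
                 rel_sd = rel_sd, n_samples = n_samples, ci_level = ci_level,
                 n_foci = n_foci, seed = seed),
            class = "sim_config")
}

# ---------------------------------------------------------------------------
# Forward birth-death simulation with fossilization

#' Simulate a true dated species tree with fossil tips
#'
#' Forward birth-death simulation from a Gamma-distributed root age,
#' conditioned on both root children leaving at least one sampled descendant
#' and at least two extant tips surviving the `rho` sampling thinning.
#' Fossilization events occur along each surviving-lineage branch as a
#' Poisson process with rate `psi` and become dated fossil tips in the sampled
#' tree (attached as zero-length side branches at their stratigraphic age).
#'
#' @param config A [sim_config()].
#' @param max_tries Attempts before giving up (rates implying near-certain
#'   extinction or empty samples raise an error suggesting parameter changes).
#' @param max_lineages Hard cap on simulated lineages per attempt.
#' @return A [dated_tree()] with exact (true) node ages: extant tips `t*` at
#'   age 0, fossil tips `f*` at positive ages.
#' @export
simulate_species_tree <- function(config = sim_config(), max_tries = 200,
                                  max_lineages = 20000) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  for (try in seq_len(max_tries)) {
    root_age <- rgamma_mean_sd(1, config$root_age_mean, config$root_age_sd)
    sim <- sim_bd_lineages(root_age, config$birth, config$death, max_lineages)
    if (is.null(sim)) next
    out <- sample_fbd_tree(sim, root_age, config$rho, config$psi)
    if (is.null(out)) next
    return(out)
  }
  stop("simulation failed after ", max_tries, " tries: with birth=",
       config$birth, ", death=", config$death, ", rho=", config$rho,
       " few lineages survive to be sampled; increase birth or rho, ",
       "or decrease death", call. = FALSE)
}

rgamma_mean_sd <- function(n, mean, sd) {
  shape <- (mean / sd)^2
  stats::rgamma(n, shape = shape, rate = shape / mean)
}

# Event-loop simulation; lineages indexed in a growing list. Ages in Ma BP
# (time runs from root_age down to 0).
sim_bd_lineages <- function(root_age, birth, death, max_lineages) {
  lin <- list()
  new_lineage <- function(start) {
    lin[[length(lin) + 1L]] <<- list(start = start, end = NA_real_,
                                     fate = NA_character_, kids = integer(0))
    length(lin)
  }
  a <- new_lineage(root_age)
  b <- new_lineage(root_age)
  active <- c(a, b)
  total_rate <- birth + death
  while (length(active)) {
    i <- active[[1]]
    active <- active[-1]
    t <- lin[[i]]$start
    repeat {
      wait <- if (total_rate > 0) stats::rexp(1, total_rate) else Inf
      if (t - wait <= 0) {
        lin[[i]]$end <- 0
        lin[[i]]$fate <- "present"
        break
      }
      t <- t - wait
      if (stats::runif(1) < birth / total_rate) {
        lin[[i]]$end <- t
        lin[[i]]$fate <- "split"
        k1 <- new_lineage(t)
        k2 <- new_lineage(t)
        lin[[i]]$kids <- c(k1, k2)
        active <- c(active, k1, k2)
        break
      } else {
        lin[[i]]$end <- t
        lin[[i]]$fate <- "death"
        break
      }
    }
    if (length(lin) > max_lineages) return(NULL)
  }
  list(lin = lin, roots = c(a, b))
}

# Reduce the full simulated tree to the sampled (FBD-observed) tree and
# return it as a dated_tree, or NULL if the conditioning fails.
sample_fbd_tree <- function(sim, root_age, rho, psi) {
  lin <- sim$lin
  n_extant <- 0L
  tip_id <- 0L
  fossil_id <- 0L

  reduce <- function(i) {
    L <- lin[[i]]
    below <- list()
    if (L$fate == "split") {
      below <- Filter(Negate(is.null), lapply(L$kids, reduce))
    } else if (L$fate == "present" && stats::runif(1) < rho) {
      tip_id <<- tip_id + 1L
      n_extant <<- n_extant + 1L
      below <- list(list(age = 0, label = paste0("t", tip_id), children = NULL))
    }
    node <- if (length(below) == 2) {
      list(age = L$end, label = "", children = below)
    } else if (length(below) == 1) {
      below[[1]]
    } else {
      NULL
    }
    # fossilization events, youngest first so each wraps the current subtree
    k <- stats::rpois(1, psi * (L$start - L$end))
    if (k > 0) {
      times <- sort(stats::runif(k, L$end, L$start))
      for (f in times) {
        fossil_id <<- fossil_id + 1L
        ftip <- list(age = f, label = paste0("f", fossil_id), children = NULL)
        node <- if (is.null(node)) ftip
        else list(age = f, label = "", children = list(node, ftip))
      }
    }
    node
  }

  sides <- Filter(Negate(is.null), lapply(sim$roots, reduce))
  if (length(sides) != 2 || n_extant < 2) return(NULL)
  root <- list(age = root_age, label = "", children = sides)
  nested_to_dated_tree(root)
}

# Nested node list -> Newick with branch lengths -> dated_tree.
nested_to_dated_tree <- function(root) {
  nwk <- function(node, parent_age) {
    bl <- num(parent_age - node$age)
    if (is.null(node$children)) return(paste0(node$label, ":", bl))
    inner <- paste(vapply(node$children, nwk, character(1),
                          parent_age = node$age), collapse = ",")
    paste0("(", inner, "):", bl)
  }
  inner <- paste(vapply(root$children, nwk, character(1),
                        parent_age = root$age), collapse = ",")
  phy <- ape::read.tree(text = paste0("(", inner, ");"))
  dated_tree(phy, root_age = root$age)
}

#' Scatter fossil tips over an existing dated tree
#'
#' Adds fossilization events along every branch of a dated tree as a Poisson
#' process with rate `psi` per lineage per Ma; each event becomes a dated
#' fossil tip. Useful for calibration checks of the fossil-recovery model on
#' a fixed topology.
#'
#' @param tree A [dated_tree()] with complete ages.
#' @param psi Fossil-recovery rate per lineage per Ma.
#' @param seed Optional seed.
#' @return A [dated_tree()] with added `f*` fossil tips.
#' @export
scatter_fossils <- function(tree, psi, seed = NULL) {
  stopifnot(inherits(tree, "dated_tree"))
  if (!is.null(seed)) set.seed(seed)
  if (any(is.na(tree$ages$age))) stop("tree ages incomplete", call. = FALSE)
  phy <- tree$phylo
  ages <- tree$ages$age
  fossil_id <- 0L
  build <- function(node) {
    kids <- children_of(phy, node)
    base <- if (!length(kids)) {
      list(age = ages[node], label = phy$tip.label[node], children = NULL)
    } else {
      list(age = ages[node], label = "", children = lapply(kids, build))
    }
    base
  }
  wrap_fossils <- function(node, parent_age) {
    if (!is.null(node$children)) {
      node$children <- lapply(node$children, wrap_fossils, parent_age = node$age)
    }
    k <- stats::rpois(1, psi * max(parent_age - node$age, 0))
    if (k > 0) {
      times <- sort(stats::runif(k, node$age, parent_age))
      for (f in times) {
        fossil_id <<- fossil_id + 1L
        ftip <- list(age = f, label = paste0("f", fossil_id), children = NULL)
        node <- list(age = f, label = "", children = list(node, ftip))
      }
    }
    node
  }
  root <- build(root_node(phy))
  root$children <- lapply(root$children, wrap_fossils, parent_age = root$age)
  nested_to_dated_tree(root)
}

# ---------------------------------------------------------------------------
# Duplication histories

#' Simulate a duplication history along a backbone lineage
#'
#' Places gene-duplication events at stated times (or at Poisson-process times
#' under `rate`) on the backbone path of a species tree, producing a dated
#' gene-lineage tree whose intervals are degenerate at the true times. The
#' history is a chain: each duplication splits the ancestral gene into a
#' terminal paralogue and a continuing lineage.
#'
#' @param tree Optional [dated_tree()]; with `backbone` (an extant tip label)
#'   it defines the time span root-to-tip.
#' @param backbone Tip label selecting the backbone path.
#' @param times Explicit duplication times, Ma, strictly decreasing.
#' @param rate Duplication rate per Ma (used when `times` is `NULL`; 0 gives
#'   a single-gene history).
#' @param span Length-2 numeric `(young, old)` time span, used when `tree` is
#'   `NULL`.
#' @param labels Terminal paralogue names, oldest-originating first; defaults
#'   to `G1..G(k+1)`.
#' @return A [gene_lineage_tree()] with degenerate intervals and attribute
#'   `true_times`.
#' @export
simulate_duplications <- function(tree = NULL, backbone = NULL, times = NULL,
                                  rate = NULL, span = NULL, labels = NULL) {
  if (!is.null(tree)) {
    stopifnot(inherits(tree, "dated_tree"))
    if (is.null(backbone)) {
      stop("`backbone` tip label required with `tree`", call. = FALSE)
    }
    tip <- mrca_node(tree, backbone)
    span <- c(tip$age, tree$ages$age[root_node(tree$phylo)])
  }
  if (is.null(span)) stop("either `tree` or `span` must be given", call. = FALSE)
  span <- sort(as.numeric(span))
  if (is.null(times)) {
    if (is.null(rate)) stop("give `times` or `rate`", call. = FALSE)
    k <- stats::rpois(1, rate * (span[2] - span[1]))
    times <- sort(stats::runif(k, span[1], span[2]), decreasing = TRUE)
  } else {
    if (any(diff(times) >= 0)) {
      stop("explicit `times` must be strictly decreasing (oldest first)",
           call. = FALSE)
    }
    if (any(times < span[1] - 1e-9 | times > span[2] + 1e-9)) {
      stop(sprintf("duplication time outside backbone span (%g-%g Ma)",
                   span[1], span[2]), call. = FALSE)
    }
  }
  k <- length(times)
  if (is.null(labels)) labels <- paste0("G", seq_len(k + 1))
  stopifnot(length(labels) == k + 1)
  glt <- if (k == 0) {
    single_gene_tree(labels[1])
  } else {
    events <- tibble::tibble(
      leaves_left = lapply(seq_len(k), function(i) labels[i]),
      leaves_right = lapply(seq_len(k), function(i) labels[(i + 1):(k + 1)]),
      ci_young = times, ci_old = times
    )
    gene_lineage_tree(events, precedence = labels)
  }
  attr(glt, "true_times") <- times
  glt
}

single_gene_tree <- function(name) {
  nodes <- tibble::tibble(id = 1L, name = name, leaves = list(name),
                          ci_young = NA_real_, ci_old = NA_real_,
                          parent = NA_integer_, is_leaf = TRUE)
  structure(nodes, class = c("gene_lineage_tree", class(nodes)),
            precedence = name)
}

# ---------------------------------------------------------------------------
# Posterior-age emulation

#' Emulate posterior node-age summaries
#'
#' For each true age `t`, an estimation error is drawn on the log scale
#' (`log m ~ Normal(log t, rel_sd^2)`) and `n_samples` posterior draws are
#' taken around `m` with the same log-scale spread; the emitted interval is
#' the equal-tailed interval of those draws and the point estimate their
#' median. Matching the two spreads makes the nominal level the asymptotic
#' coverage of the truth. `rel_sd = 0` returns degenerate intervals at the
#' truth.
#'
#' @param ages Numeric vector of true ages (Ma, all > 0).
#' @param rel_sd Log-scale standard deviation (approximately the relative sd).
#' @param n_samples Draws per age.
#' @param level Credibility level.
#' @param seed Optional seed.
#' @return Tibble with columns `truth`, `age` (point estimate), `ci_young`,
#'   `ci_old`.
#' @export
simulate_age_posteriors <- function(ages, rel_sd, n_samples = 500,
                                    level = 0.95, seed = NULL) {
  if (rel_sd < 0) stop("`rel_sd` must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(ages > 0))
  if (rel_sd == 0) {
    return(tibble::tibble(truth = ages, age = ages,
                          ci_young = ages, ci_old = ages))
  }
  alpha <- (1 - level) / 2
  out <- purrr::map_dfr(ages, function(t) {
    m <- t * exp(stats::rnorm(1, 0, rel_sd))
    draws <- m * exp(stats::rnorm(n_samples, 0, rel_sd))
    q <- stats::quantile(draws, c(alpha, 0.5, 1 - alpha), names = FALSE)
    tibble::tibble(truth = t, age = q[2], ci_young = q[1], ci_old = q[3])
  })
  out
}

# Perturb internal-node ages of a dated tree into posterior-style CIs; fossil
# and extant tip ages stay exact (they are data, not estimates). A postorder
# max-propagation restores age monotonicity where noise locally inverted it.
perturb_dated_tree <- function(tree, rel_sd, n_samples = 500, level = 0.95) {
  phy <- tree$phylo
  tab <- tree$ages
  internal <- which(tab$kind == "internal")
  post <- simulate_age_posteriors(tab$age[internal], rel_sd, n_samples, level)
  tab$age[internal] <- post$age
  tab$ci_young[internal] <- post$ci_young
  tab$ci_old[internal] <- post$ci_old
  edge <- ape::reorder.phylo(phy, "postorder")$edge
  for (k in seq_len(nrow(edge))) {
    p <- edge[k, 1]; v <- edge[k, 2]
    if (tab$age[p] < tab$age[v]) tab$age[p] <- tab$age[v]
    if (!is.na(tab$ci_old[p]) && tab$ci_old[p] < tab$age[p]) {
      tab$ci_old[p] <- tab$age[p]
    }
  }
  tab$ci_young <- pmin(tab$ci_young, tab$age)
  out <- structure(list(phylo = phy, ages = finish_kinds(tab, n_tips(phy))),
                   class = "dated_tree")
  validate_dated_tree(out)
  out
}

# Perturb duplication times of a gene-lineage tree; a preorder clip keeps the
# child-under-parent interval invariant.
perturb_gene_lineage_tree <- function(glt, rel_sd, n_samples = 500,
                                      level = 0.95) {
  internal <- which(!glt$is_leaf)
  if (!length(internal)) return(glt)
  truth <- glt$ci_old[internal]  # degenerate truth intervals
  post <- simulate_age_posteriors(truth, rel_sd, n_samples, level)
  glt$ci_young[internal] <- post$ci_young
  glt$ci_old[internal] <- post$ci_old
  for (i in glt$id[order(glt$id)]) {
    p <- glt$parent[i]
    if (is.na(p) || glt$is_leaf[i]) next
    glt$ci_old[i] <- min(glt$ci_old[i], glt$ci_old[p])
    glt$ci_young[i] <- min(glt$ci_young[i], glt$ci_old[i])
  }
  validate_gene_lineage_tree(glt)
  glt
}

# ---------------------------------------------------------------------------
# Truth bundles and recovery

#' Simulate a full truth bundle
#'
#' One end-to-end synthetic dataset: a true dated species tree with fossil
#' tips; a true duplication chain along the backbone (the root-to-tip path
#' with the most divergences); emulated posterior intervals on species-node
#' ages and duplication times; and the focal backbone divergences used for
#' complement inference.
#'
#' @param config A [sim_config()].
#' @return A list of class `truth_bundle` with elements `config`, `true_tree`,
#'   `observed_tree`, `true_gene_tree`, `observed_gene_tree`, and `foci` (a
#'   tibble with `label`, `node`, `true_age`, `ci_young`, `ci_old`).
#' @export
simulate_truth_bundle <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  true_tree <- simulate_species_tree(sim_config_no_seed(config))
  phy <- true_tree$phylo
  tab <- true_tree$ages

  # backbone: extant tip with the most internal nodes on its root path
  anc <- ancestor_list(phy)
  extant <- which(tab$kind == "extant")
  depths <- lengths(anc[extant])
  tip <- extant[which.max(depths)]
  path <- rev(anc[[tip]])  # root first, then successively younger splits
  n_foci <- min(config$n_foci, length(path))
  foci_nodes <- path[seq_len(n_foci)]

  root_age <- tab$age[root_node(phy)]
  youngest_focus <- min(tab$age[foci_nodes])
  times <- config$dup_times
  if (is.null(times)) {
    times <- sort(stats::runif(config$n_duplications, youngest_focus, root_age),
                  decreasing = TRUE)
  }
  true_glt <- simulate_duplications(span = c(youngest_focus, root_age),
                                    times = times)

  observed_tree <- perturb_dated_tree(true_tree, config$rel_sd,
                                      config$n_samples, config$ci_level)
  observed_glt <- perturb_gene_lineage_tree(true_glt, config$rel_sd,
                                            config$n_samples, config$ci_level)
  foci <- tibble::tibble(
    label = paste0("focus_", seq_len(n_foci)),
    node = foci_nodes,
    true_age = tab$age[foci_nodes],
    ci_young = observed_tree$ages$ci_young[foci_nodes],
    ci_old = observed_tree$ages$ci_old[foci_nodes]
  )
  structure(list(config = config, true_tree = true_tree,
                 observed_tree = observed_tree, true_gene_tree = true_glt,
                 observed_gene_tree = observed_glt, foci = foci),
            class = "truth_bundle")
}

sim_config_no_seed <- function(config) {
  config$seed <- NULL
  config
}

#' @export
print.truth_bundle <- function(x, ...) {
  cat("<truth_bundle>\n  species tree: ")
  print(x$true_tree)
  cat(sprintf("  duplications: %d; foci: %d; rel_sd: %g\n",
              sum(!x$true_gene_tree$is_leaf), nrow(x$foci), x$config$rel_sd))
  invisible(x)
}

#' Score inferred complements against the simulated truth
#'
#' Per focal divergence, compares the complement inferred from noisy intervals
#' with the exact frontier implied by the true duplication and divergence
#' times. A focus is an *overclaim* when the inferred complement contains a
#' paralogue whose true duplication postdated the true divergence (the
#' inferred cut is too deep), an *underclaim* when an ancestral gene was
#' conservatively kept although its duplication truly preceded the divergence,
#' and *exact* otherwise.
#'
#' @param truth A [simulate_truth_bundle()] result.
#' @param inferred Optional [infer_all()] complement table computed from the
#'   observed bundle; computed here when `NULL`.
#' @return A tibble of class `recovery_metrics`: `lineage`, `exact`,
#'   `overclaim`, `underclaim`. Aggregate with [glance()].
#' @export
evaluate_recovery <- function(truth, inferred = NULL) {
  stopifnot(inherits(truth, "truth_bundle"))
  if (is.null(inferred)) {
    inferred <- infer_all(NULL, truth$observed_gene_tree, truth$foci)
  }
  true_glt <- truth$true_gene_tree
  leafset <- function(glt, name) glt$leaves[[match(name, glt$name)]]
  rows <- purrr::map(seq_len(nrow(truth$foci)), function(r) {
    t_age <- truth$foci$true_age[r]
    truth_genes <- infer_complement(true_glt, ci(t_age, t_age))
    inf_genes <- inferred$genes[[match(truth$foci$label[r], inferred$lineage)]]
    ts <- lapply(truth_genes, leafset, glt = true_glt)
    is_ <- lapply(inf_genes, leafset, glt = truth$observed_gene_tree)
    strict_subset <- function(a, b) length(a) < length(b) && all(a %in% b)
    over <- any(vapply(is_, function(g) {
      any(vapply(ts, function(tg) strict_subset(g, tg), logical(1)))
    }, logical(1)))
    under <- any(vapply(is_, function(g) {
      any(vapply(ts, function(tg) strict_subset(tg, g), logical(1)))
    }, logical(1)))
    tibble::tibble(lineage = truth$foci$label[r],
                   exact = setequal(inf_genes, truth_genes) && !over && !under,
                   overclaim = over, underclaim = under)
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("recovery_metrics", class(out)))
}

#' Replicate the recovery experiment
#'
#' Simulates `n_reps` truth bundles, runs the interval-comparison inference on
#' each observed bundle, and aggregates overclaim/underclaim/exact-match rates
#' across all foci.
#'
#' @param n_reps Number of replicate bundles.
#' @param config A [sim_config()]; its `rel_sd` controls interval width.
#' @param seed Integer seed for the whole experiment.
#' @return A one-row tibble: `n_reps`, `n_foci`, `rel_sd`, `overclaim_rate`,
#'   `underclaim_rate`, `exact_rate`.
#' @export
recovery_experiment <- function(n_reps, config = sim_config(), seed = 1) {
  set.seed(seed)
  config$seed <- NULL
  metrics <- purrr::map_dfr(seq_len(n_reps), function(i) {
    evaluate_recovery(simulate_truth_bundle(config))
  })
  tibble::tibble(
    n_reps = n_reps,
    n_foci = nrow(metrics),
    rel_sd = config$rel_sd,
    overclaim_rate = mean(metrics$overclaim),
    underclaim_rate = mean(metrics$underclaim),
    exact_rate = mean(metrics$exact)
  )
}
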
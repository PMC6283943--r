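# Helpers: random-case generators and independent brute-force oracles used by
# property-style tests. Oracles deliberately use different algorithms from the
# package implementation.

# Random dated tree: coalescent topology rescaled to a given root age, with
# equal-tailed intervals around every internal node age.
random_dated_tree <- function(n_tips = 6, root_age = 600, ci_halfwidth = 15) {
  phy <- ape::rcoal(n_tips)
  phy$edge.length <- phy$edge.length * root_age /
    max(ape::node.depth.edgelength(phy))
  tr <- dated_tree(phy, root_age = root_age)
  tab <- tr$ages
  internal <- tab$kind == "internal"
  w <- stats::runif(sum(internal), 0, ci_halfwidth)
  tab$ci_young[internal] <- pmax(tab$age[internal] - w, 0)
  tab$ci_old[internal] <- tab$age[internal] + w
  # keep parent-old >= child-old so validation-style monotonicity holds
  tr$ages <- tab
  validate_dated_tree(tr)
  tr
}

# MRCA by ancestor-path intersection (oracle for mrca_node).
oracle_mrca <- function(phy, tips) {
  path_to_root <- function(node) {
    par <- rep(NA_integer_, length(phy$tip.label) + phy$Nnode)
    par[phy$edge[, 2]] <- phy$edge[, 1]
    out <- node
    while (!is.na(par[node])) {
      node <- par[node]
      out <- c(out, node)
    }
    out
  }
  idx <- match(tips, phy$tip.label)
  shared <- Reduce(intersect, lapply(idx, path_to_root))
  shared[1]  # paths are ordered tip-to-root; first shared element is lowest
}

# Exhaustive minimum-duplication oracle: enumerate every valid assignment of
# internal gene nodes to species nodes (candidates: the LCA of the node's
# species set and its ancestors), check monotonicity, count duplications.
oracle_min_dups <- function(gene_tree, species_tree, tip_map) {
  gt <- gene_tree; sp <- species_tree
  nsp <- length(sp$tip.label) + sp$Nnode
  spar <- rep(NA_integer_, nsp)
  spar[sp$edge[, 2]] <- sp$edge[, 1]
  anc_or_eq <- function(a, b) {  # is a ancestor-or-equal of b
    while (!is.na(b)) {
      if (a == b) return(TRUE)
      b <- spar[b]
    }
    FALSE
  }
  ancs_of <- function(s) {
    out <- s
    while (!is.na(spar[s])) {
      s <- spar[s]
      out <- c(out, s)
    }
    out
  }
  ngt <- length(gt$tip.label)
  ngn <- ngt + gt$Nnode
  tip_species <- match(tip_map$species[match(gt$tip.label, tip_map$gene_tip)],
                       sp$tip.label)
  # species tips below each gene node
  desc_sp <- vector("list", ngn)
  for (i in seq_len(ngt)) desc_sp[[i]] <- tip_species[i]
  edge <- ape::reorder.phylo(gt, "postorder")$edge
  for (k in seq_len(nrow(edge))) {
    desc_sp[[edge[k, 1]]] <- union(desc_sp[[edge[k, 1]]], desc_sp[[edge[k, 2]]])
  }
  lca_of_set <- function(ss) {
    shared <- Reduce(intersect, lapply(ss, ancs_of))
    shared[1]
  }
  internals <- (ngt + 1):ngn
  cand <- lapply(internals, function(g) ancs_of(lca_of_set(desc_sp[[g]])))
  grid <- expand.grid(lapply(cand, seq_along))
  gpar <- rep(NA_integer_, ngn)
  gpar[gt$edge[, 2]] <- gt$edge[, 1]
  kids <- lapply(seq_len(ngn), function(v) gt$edge[gt$edge[, 1] == v, 2])
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    map <- c(tip_species, vapply(seq_along(internals), function(j) {
      cand[[j]][grid[r, j]]
    }, integer(1)))
    ok <- TRUE
    for (v in seq_len(ngn)) {
      u <- gpar[v]
      if (!is.na(u) && !anc_or_eq(map[u], map[v])) { ok <- FALSE; break }
    }
    if (!ok) next
    # child subtree of s containing x (NA when x == s)
    subtree_of <- function(s, x) {
      if (x == s) return(NA_integer_)
      repeat {
        p <- spar[x]
        if (p == s) return(x)
        x <- p
      }
    }
    # duplication unless both children map strictly below, into distinct
    # child subtrees of the node's own mapping
    dups <- sum(vapply(internals, function(g) {
      s <- map[g]
      ch <- map[kids[[g]]]
      if (any(ch == s)) return(TRUE)
      subs <- vapply(ch, subtree_of, integer(1), s = s)
      anyDuplicated(subs) > 0
    }, logical(1)))
    if (dups < best) best <- dups
  }
  best
}

# Random gene-tree/species-tree/tip-map triple with multi-copy families.
random_reconciliation_case <- function(n_species = 4, n_gene_tips = 6) {
  sp <- ape::rtree(n_species, br = NULL)
  sp$tip.label <- LETTERS[seq_len(n_species)]
  species_of <- sample(sp$tip.label, n_gene_tips, replace = TRUE)
  gt <- ape::rtree(n_gene_tips, br = NULL)
  gt$tip.label <- paste0(species_of, "_", seq_len(n_gene_tips))
  list(gene_tree = gt, species_tree = sp,
       tip_map = data.frame(gene_tip = gt$tip.label, species = species_of))
}

# Exact time-cut oracle for degenerate intervals: a gene is on the frontier
# iff every strict ancestor's duplication is older than the divergence and the
# gene itself is a leaf or not older.
oracle_time_cut <- function(glt, div_time) {
  times <- glt$ci_old  # degenerate: young == old
  keep <- vapply(seq_len(nrow(glt)), function(i) {
    p <- glt$parent[i]
    while (!is.na(p)) {
      if (!(times[p] > div_time)) return(FALSE)
      p <- glt$parent[p]
    }
    glt$is_leaf[i] || !(times[i] > div_time)
  }, logical(1))
  glt$name[keep]
}

# Random caterpillar duplication chain over a 600 Ma span.
random_gene_chain <- function(k = 4, span = c(450, 620)) {
  times <- sort(stats::runif(k, span[1], span[2]), decreasing = TRUE)
  simulate_duplications(span = span, times = times)
}
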
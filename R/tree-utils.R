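# Internal helpers over ape::phylo structures.

n_tips <- function(phy) length(phy$tip.label)

all_nodes <- function(phy) seq_len(n_tips(phy) + phy$Nnode)

root_node <- function(phy) n_tips(phy) + 1L

#' @importFrom stats setNames
parent_vector <- function(phy) {
  p <- rep(NA_integer_, n_tips(phy) + phy$Nnode)
  p[phy$edge[, 2]] <- phy$edge[, 1]
  p
}

children_of <- function(phy, node) phy$edge[phy$edge[, 1] == node, 2]

# Ancestors of each node (node -> integer vector, root first excluded itself),
# computed once per tree.
ancestor_list <- function(phy) {
  par <- parent_vector(phy)
  lapply(all_nodes(phy), function(v) {
    out <- integer(0)
    while (!is.na(par[v])) {
      v <- par[v]
      out <- c(out, v)
    }
    out
  })
}

# Tip descendants (as node indices) of every node.
tip_descendants <- function(phy) {
  nt <- n_tips(phy)
  desc <- vector("list", nt + phy$Nnode)
  for (i in seq_len(nt)) desc[[i]] <- i
  edge <- ape::reorder.phylo(phy, "postorder")$edge
  for (k in seq_len(nrow(edge))) {
    a <- edge[k, 1]; b <- edge[k, 2]
    desc[[a]] <- c(desc[[a]], desc[[b]])
  }
  desc
}

# Node depth in edge counts from the root (root = 0).
node_depths <- function(phy) {
  par <- parent_vector(phy)
  d <- rep(NA_real_, length(par))
  d[root_node(phy)] <- 0
  edge <- ape::reorder.phylo(phy, "postorder")$edge
  for (k in rev(seq_len(nrow(edge)))) d[edge[k, 2]] <- d[edge[k, 1]] + 1
  d
}

# Pairwise LCA using parent pointers and depths.
lca_pair <- function(a, b, par, depth) {
  while (depth[a] > depth[b]) a <- par[a]
  while (depth[b] > depth[a]) b <- par[b]
  while (a != b) {
    a <- par[a]
    b <- par[b]
  }
  a
}

node_label <- function(phy, node) {
  nt <- n_tips(phy)
  if (node <= nt) return(phy$tip.label[node])
  if (!is.null(phy$node.label)) {
    lab <- phy$node.label[node - nt]
    if (!is.na(lab) && nzchar(lab)) return(lab)
  }
  NA_character_
}

# Key identifying an internal node by its descendant tip set; stable across
# reparses that renumber nodes.
clade_keys <- function(phy) {
  desc <- tip_descendants(phy)
  vapply(desc, function(d) paste(sort(phy$tip.label[d]), collapse = "|"),
         character(1))
}
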
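#' LCA (parsimony) reconciliation of a gene tree onto a species tree
#'
#' Maps every gene-tree node to the lowest species-tree node containing all of
#' its descendant species (the LCA map) and labels each internal gene node a
#' duplication when it maps to the same species node as at least one of its
#' children, otherwise a speciation. The LCA map attains the parsimony minimum
#' number of duplications. Multifurcations in either tree are handled directly
#' (no binarization).
#'
#' @param gene_tree Rooted `ape::phylo` (or `dated_tree`) gene tree.
#' @param species_tree Rooted `ape::phylo` or `dated_tree` species tree.
#' @param tip_map Data frame with columns `gene_tip`, `species` (and
#'   optionally `copy_id`) mapping every gene tip to a species-tree tip.
#' @return A tibble of class `reconciliation` with one row per gene node:
#'   `gene_node`, `gene_label`, `species_node`, `species_label`, `event`
#'   (`leaf`/`speciation`/`duplication`). The trees and the raw map are kept
#'   as attributes for downstream counting.
#' @examples
#' gt <- ape::read.tree(text = "((A_1,B_1),(A_2,B_2));")
#' st <- ape::read.tree(text = "((A,B),C);")
#' tm <- data.frame(gene_tip = gt$tip.label,
#'                  species = sub("_.*", "", gt$tip.label))
#' lca_reconcile(gt, st, tm)
#' @export
lca_reconcile <- function(gene_tree, species_tree, tip_map) {
  gt <- if (inherits(gene_tree, "dated_tree")) gene_tree$phylo else gene_tree
  sp <- if (inherits(species_tree, "dated_tree")) species_tree$phylo else species_tree
  stopifnot(inherits(gt, "phylo"), inherits(sp, "phylo"))
  tip_map <- tibble::as_tibble(tip_map)
  if (!all(c("gene_tip", "species") %in% names(tip_map))) {
    stop("`tip_map` needs columns gene_tip, species", call. = FALSE)
  }

  gtips <- gt$tip.label
  missing_map <- setdiff(gtips, tip_map$gene_tip)
  if (length(missing_map)) {
    stop("unmapped gene tip(s): ", paste(missing_map, collapse = ", "),
         call. = FALSE)
  }
  sp_of <- tip_map$species[match(gtips, tip_map$gene_tip)]
  sp_tip_idx <- match(sp_of, sp$tip.label)
  if (anyNA(sp_tip_idx)) {
    stop("species absent from species tree: ",
         paste(unique(sp_of[is.na(sp_tip_idx)]), collapse = ", "), call. = FALSE)
  }

  spar <- parent_vector(sp)
  sdepth <- node_depths(sp)
  ng <- n_tips(gt) + gt$Nnode
  map <- rep(NA_integer_, ng)
  map[seq_along(gtips)] <- sp_tip_idx

  po_edge <- ape::reorder.phylo(gt, "postorder")$edge
  kids <- split(po_edge[, 2], po_edge[, 1])
  for (node in unique(po_edge[, 1])) {
    cm <- map[kids[[as.character(node)]]]
    map[node] <- Reduce(function(a, b) lca_pair(a, b, spar, sdepth), cm)
  }

  event <- vapply(seq_len(ng), function(v) {
    if (v <= n_tips(gt)) return("leaf")
    if (any(map[kids[[as.character(v)]]] == map[v])) "duplication" else "speciation"
  }, character(1))

  out <- tibble::tibble(
    gene_node = seq_len(ng),
    gene_label = vapply(seq_len(ng), function(i) node_label(gt, i), character(1)),
    species_node = map,
    species_label = vapply(map, function(i) node_label(sp, i), character(1)),
    event = event
  )
  structure(out,
            class = c("reconciliation", class(out)),
            gene_tree = gt, species_tree = sp, map = map)
}

#' Count gene lineages inherited at a species node
#'
#' Dollo-consistent count of the distinct gene lineages present at the base of
#' a species node under an LCA reconciliation: a gene lineage counts when it
#' originated at or above the node (its parent event maps to a proper ancestor,
#' or is a duplication mapped at the node itself -- where LCA reconciliation
#' places stem-lineage duplications), it has at least one surviving descendant
#' copy among the node's descendant species, and it did not itself end above
#' the node. For a congruent single-copy family this is 1 at every node.
#'
#' @param rec A [lca_reconcile()] result.
#' @param at A species node: an integer node index, or a character vector of
#'   species tip labels whose MRCA is used (a single label addresses that tip).
#' @return Integer count.
#' @export
copies_at <- function(rec, at) {
  stopifnot(inherits(rec, "reconciliation"))
  gt <- attr(rec, "gene_tree")
  sp <- attr(rec, "species_tree")
  map <- attr(rec, "map")
  s <- resolve_species_node(sp, at)

  anc <- ancestor_list(sp)
  is_strict_anc <- function(a, node) a %in% anc[[node]]
  tipsets <- tip_descendants(sp)
  s_tips <- tipsets[[s]]

  gpar <- parent_vector(gt)
  gdesc <- tip_descendants(gt)
  event <- rec$event[order(rec$gene_node)]

  count <- 0L
  for (v in all_nodes(gt)) {
    u <- gpar[v]
    birth_ok <- if (is.na(u)) TRUE else {
      is_strict_anc(map[u], s) || (map[u] == s && event[u] == "duplication")
    }
    if (!birth_ok) next
    mv <- map[v]
    if (is_strict_anc(mv, s)) next
    if (mv == s && event[v] == "duplication") next
    survives <- any(map[gdesc[[v]]] %in% s_tips)
    if (survives) count <- count + 1L
  }
  count
}

resolve_species_node <- function(sp, at) {
  if (is.numeric(at)) {
    at <- as.integer(at)
    if (at < 1 || at > n_tips(sp) + sp$Nnode) {
      stop("species node index out of range: ", at, call. = FALSE)
    }
    return(at)
  }
  mrca_node(sp, at)$node
}

#' Per-node copy counts for a whole species tree
#'
#' @param rec A [lca_reconcile()] result.
#' @return Tibble with `species_node`, `species_label`, `copies` for every
#'   node of the species tree.
#' @export
copy_count_table <- function(rec) {
  sp <- attr(rec, "species_tree")
  nodes <- all_nodes(sp)
  tibble::tibble(
    species_node = nodes,
    species_label = vapply(nodes, function(i) node_label(sp, i), character(1)),
    copies = vapply(nodes, function(i) copies_at(rec, i), integer(1))
  )
}

#' Number of duplications in a reconciliation
#' @param rec A [lca_reconcile()] result.
#' @return Integer.
#' @export
n_duplications <- function(rec) sum(rec$event == "duplication")

#' Read a gene-tip map (TSV with columns gene_tip, species, copy_id)
#' @param path TSV file path.
#' @return A tibble.
#' @export
read_tip_map <- function(path) {
  tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
}
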
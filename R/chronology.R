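#' Did a duplication precede a divergence, at 95% credibility?
#'
#' The conservative interval-comparison rule: a duplication is judged to
#' precede a species divergence only when the two 95% credibility intervals do
#' not overlap and the divergence interval lies entirely on the younger side
#' -- that is, when `div_old < dup_young`, strictly. Any overlap (including
#' touching endpoints) returns `"ambiguous"`, in which case downstream
#' inference assumes the descendant lineages inherited the single ancestral
#' gene rather than the paralogue pair.
#'
#' @param dup Duplication interval(s): a [ci()], a length-2 numeric, or an
#'   n x 2 matrix / data frame (columns `ci_young`, `ci_old`).
#' @param div Divergence interval(s), same forms; recycled against `dup`.
#' @return Character vector of verdicts, `"precedes"` or `"ambiguous"`.
#' @examples
#' precedes(ci(587, 615), ci(562, 585))  # "precedes"
#' precedes(ci(577, 605), ci(558, 580))  # overlap -> "ambiguous"
#' precedes(ci(600, 600), ci(600, 600))  # equality is overlap -> "ambiguous"
#' @export
precedes <- function(dup, div) {
  dm <- ci_matrix(dup, "dup")
  vm <- ci_matrix(div, "div")
  n <- max(nrow(dm), nrow(vm))
  if (nrow(dm) == 1) dm <- dm[rep(1, n), , drop = FALSE]
  if (nrow(vm) == 1) vm <- vm[rep(1, n), , drop = FALSE]
  unname(ifelse(vm[, "old"] < dm[, "young"], "precedes", "ambiguous"))
}

#' Minimal gene complement inherited across a divergence
#'
#' The frontier cut of a dated gene-lineage tree against a divergence
#' interval: starting from the root gene, a gene is expanded into its two
#' daughters if and only if its duplication [precedes()] the divergence; the
#' returned complement is the set of unexpanded genes. Because ambiguity stops
#' expansion, the complement is always a minimal estimate -- descendants are
#' conservatively assumed to have inherited the ancestral gene whenever the
#' intervals overlap. A daughter duplication is only ever examined if its
#' parent was expanded, so the cut is well defined even for noisy, imperfectly
#' nested intervals.
#'
#' @param glt A [gene_lineage_tree()].
#' @param div Divergence interval: [ci()], length-2 numeric, or a one-row
#'   interval data frame.
#' @return Character vector of canonical gene names (sorted root-to-tip in
#'   discovery order).
#' @examples
#' fx <- ecdysozoan_opsins()
#' infer_complement(fx$gene_tree, ci(572, 595))  # one ancestral opsin
#' infer_complement(fx$gene_tree, ci(519, 540))  # the four crown opsins
#' @export
infer_complement <- function(glt, div) {
  stopifnot(inherits(glt, "gene_lineage_tree"))
  vm <- ci_matrix(div, "div")
  if (nrow(vm) != 1) stop("`div` must be a single interval", call. = FALSE)
  frontier <- character(0)
  visit <- function(id) {
    if (glt$is_leaf[id]) {
      frontier <<- c(frontier, glt$name[id])
      return(invisible(NULL))
    }
    verdict <- precedes(c(glt$ci_young[id], glt$ci_old[id]), vm)
    if (verdict == "precedes") {
      for (child in glt_children(glt, id)) visit(child)
    } else {
      frontier <<- c(frontier, glt$name[id])
    }
  }
  visit(glt$id[1])
  frontier
}

# Per-duplication audit of one frontier cut: which verdicts were evaluated.
complement_provenance <- function(glt, div) {
  vm <- ci_matrix(div, "div")
  rows <- list()
  visit <- function(id) {
    if (glt$is_leaf[id]) return(invisible(NULL))
    verdict <- precedes(c(glt$ci_young[id], glt$ci_old[id]), vm)
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      gene = glt$name[id],
      dup_young = glt$ci_young[id], dup_old = glt$ci_old[id],
      div_young = vm[1, "young"], div_old = vm[1, "old"],
      verdict = verdict
    )
    if (verdict == "precedes") for (child in glt_children(glt, id)) visit(child)
  }
  visit(glt$id[1])
  dplyr::bind_rows(rows)
}

#' Chromacy classification of a gene complement
#'
#' Counts the spectrally usable (visual) genes in a complement and maps the
#' count to a colour-vision class. A standalone `Rh7` gene is by default
#' treated as non-visual (it mediates circadian entrainment in *Drosophila*);
#' composite ancestral genes that merely contain Rh7 as a component (e.g.
#' `Rh7/UV/SWS`) still count as visual.
#'
#' @param complement Character vector of canonical gene names.
#' @param rh7_nonvisual Discount a standalone `"Rh7"`? Default `TRUE`.
#' @return A list with `visual_count` (integer) and `class` (one of `"none"`,
#'   `"monochromat"`, `"dichromat"`, `"trichromat"`, `"polychromat"`).
#' @examples
#' chromacy("Rh7/UV/SWS/MWS/LWS")                       # monochromat
#' chromacy(c("Rh7", "UV/SWS", "MWS", "LWS"))           # trichromat
#' @export
chromacy <- function(complement, rh7_nonvisual = TRUE) {
  n <- length(complement)
  visual <- n - as.integer(rh7_nonvisual && "Rh7" %in% complement)
  cls <- if (visual <= 0 && n == 0) "none"
  else if (visual == 0) "none"
  else if (visual == 1) "monochromat"
  else if (visual == 2) "dichromat"
  else if (visual == 3) "trichromat"
  else "polychromat"
  list(visual_count = visual, class = cls)
}

#' Infer complements for a list of focal lineages
#'
#' Runs [infer_complement()] against the divergence interval of each focal
#' node of a dated species tree and assembles the complement table: one row
#' per focus with the interval used, the inferred minimal gene set, its size,
#' and the chromacy class. A focus whose node lacks a credibility interval
#' gets its error recorded in the `error` column and the run continues.
#'
#' @param species_tree A [dated_tree()] whose focal nodes carry credibility
#'   intervals.
#' @param glt A [gene_lineage_tree()].
#' @param foci Data frame of node selectors: either columns `label`, `tip_a`,
#'   `tip_b` (MRCA addressing) or columns `label`, `node` (explicit indices).
#'   Alternatively a plain data frame with `label`, `ci_young`, `ci_old` gives
#'   the intervals directly and `species_tree` may be `NULL`.
#' @param rh7_nonvisual Passed to [chromacy()].
#' @return A tibble of class `complement_table`: `lineage`, `div_young`,
#'   `div_old`, `genes` (list-column), `complement` (collapsed string),
#'   `size`, `visual_count`, `chromacy`, `error`. Row order follows `foci`.
#' @examples
#' fx <- ecdysozoan_opsins()
#' infer_all(NULL, fx$gene_tree, fx$divergences)
#' @export
infer_all <- function(species_tree, glt, foci, rh7_nonvisual = TRUE) {
  stopifnot(inherits(glt, "gene_lineage_tree"))
  foci <- tibble::as_tibble(foci)
  if (!"label" %in% names(foci)) {
    if ("lineage" %in% names(foci)) foci$label <- foci$lineage
    else stop("`foci` needs a `label` (or `lineage`) column", call. = FALSE)
  }
  rows <- purrr::map(seq_len(nrow(foci)), function(r) {
    f <- foci[r, ]
    res <- tryCatch({
      iv <- focus_interval(species_tree, f)
      genes <- infer_complement(glt, iv)
      chr <- chromacy(genes, rh7_nonvisual)
      collapsed <- paste(genes, collapse = "; ")
      n_genes <- length(genes)
      tibble::tibble(
        lineage = f$label, div_young = iv[1], div_old = iv[2],
        genes = list(genes),
        complement = collapsed,
        size = n_genes,
        visual_count = chr$visual_count, chromacy = chr$class,
        error = NA_character_
      )
    }, error = function(e) {
      tibble::tibble(lineage = f$label, div_young = NA_real_, div_old = NA_real_,
                     genes = list(character(0)), complement = NA_character_,
                     size = NA_integer_, visual_count = NA_integer_,
                     chromacy = NA_character_, error = conditionMessage(e))
    })
    res
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("complement_table", class(out)), glt = glt)
}

# Resolve one focus row to a divergence interval c(young, old).
focus_interval <- function(species_tree, f) {
  if (all(c("ci_young", "ci_old") %in% names(f)) &&
      !is.na(f$ci_young) && !is.na(f$ci_old)) {
    return(unclass(ci(f$ci_young, f$ci_old)))
  }
  if (is.null(species_tree)) {
    stop("focus '", f$label, "': no interval given and no species tree",
         call. = FALSE)
  }
  node <- if ("node" %in% names(f) && !is.na(f$node)) {
    species_tree$ages[f$node, ]
  } else if (all(c("tip_a", "tip_b") %in% names(f))) {
    mrca_node(species_tree, c(f$tip_a, f$tip_b))
  } else {
    stop("focus '", f$label, "': needs tip_a/tip_b, node, or ci_young/ci_old",
         call. = FALSE)
  }
  if (is.na(node$ci_young) || is.na(node$ci_old)) {
    stop("focus '", f$label, "': node has no credibility interval", call. = FALSE)
  }
  unclass(ci(node$ci_young, node$ci_old))
}

#' Gene presence at an all-extant internal node by phylogenetic bracketing
#'
#' Dollo inference for clades whose sampled descendants are all extant: a gene
#' is attributed to the node when the node lies at or below the MRCA of the
#' tips possessing it and at least one descendant tip possesses it. Presence
#' in two or more distinct child subtrees therefore forces presence at the
#' node itself, while a gene confined to a single tip is never projected onto
#' that tip's strict ancestors.
#'
#' @param species_tree A [dated_tree()].
#' @param presence Data frame in long form: columns `species`, `gene` (one
#'   row per extant species per gene copy class present).
#' @param node Node selector: integer index or character vector of tip labels
#'   (MRCA).
#' @return Sorted character vector of gene names present at the node.
#' @export
bracket_extant <- function(species_tree, presence, node) {
  stopifnot(inherits(species_tree, "dated_tree"))
  presence <- tibble::as_tibble(presence)
  if (!all(c("species", "gene") %in% names(presence))) {
    stop("`presence` needs columns species, gene", call. = FALSE)
  }
  phy <- species_tree$phylo
  s <- resolve_species_node(phy, node)
  tipsets <- tip_descendants(phy)
  desc_tips <- phy$tip.label[tipsets[[s]]]
  kinds <- species_tree$ages$kind[tipsets[[s]]]
  if (any(kinds == "fossil")) {
    stop("node has fossil descendants (",
         paste(desc_tips[kinds == "fossil"], collapse = ", "),
         "); bracketing applies to all-extant clades -- use infer_complement()",
         call. = FALSE)
  }
  unknown <- setdiff(presence$species, phy$tip.label)
  if (length(unknown)) {
    stop("presence table names unknown species: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  anc <- ancestor_list(phy)
  genes <- unique(presence$gene)
  present <- vapply(genes, function(g) {
    holders <- unique(presence$species[presence$gene == g])
    holders_below <- intersect(holders, desc_tips)
    if (!length(holders_below)) return(FALSE)
    m <- mrca_node(phy, holders)$node
    # s at or below the MRCA of all holders
    s == m || m %in% anc[[s]]
  }, logical(1))
  sort(genes[present])
}
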
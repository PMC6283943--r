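#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a dated tree into its node table
#'
#' @param x A [dated_tree()].
#' @param ... Unused.
#' @return Tibble with one row per node: `node`, `label`, `age`, `ci_young`,
#'   `ci_old`, `kind`.
#' @export
tidy.dated_tree <- function(x, ...) x$ages

#' Tidy a gene-lineage tree into its node table
#'
#' @param x A [gene_lineage_tree()].
#' @param ... Unused.
#' @return Tibble of nodes (duplications carry intervals; leaves are terminal
#'   paralogues).
#' @export
tidy.gene_lineage_tree <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' Tidy a reconciliation into a plain mapping table
#'
#' @param x A [lca_reconcile()] result.
#' @param ... Unused.
#' @return Tibble `gene_node`, `gene_label`, `species_node`, `species_label`,
#'   `event`.
#' @export
tidy.reconciliation <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' One-row summary of a reconciliation
#'
#' @param x A [lca_reconcile()] result.
#' @param ... Unused.
#' @return Tibble: `n_gene_nodes`, `n_duplications`, `n_speciations`.
#' @export
glance.reconciliation <- function(x, ...) {
  tibble::tibble(
    n_gene_nodes = nrow(x),
    n_duplications = sum(x$event == "duplication"),
    n_speciations = sum(x$event == "speciation")
  )
}

#' One-row summary of a complement table
#'
#' @param x An [infer_all()] result.
#' @param ... Unused.
#' @return Tibble: `n_foci`, `n_errors`, `min_size`, `max_size`.
#' @export
glance.complement_table <- function(x, ...) {
  ok <- is.na(x$error)
  tibble::tibble(
    n_foci = nrow(x),
    n_errors = sum(!ok),
    min_size = if (any(ok)) min(x$size[ok]) else NA_integer_,
    max_size = if (any(ok)) max(x$size[ok]) else NA_integer_
  )
}

#' Aggregate recovery metrics
#'
#' @param x An [evaluate_recovery()] result.
#' @param ... Unused.
#' @return Tibble: `n_foci`, `exact_rate`, `overclaim_rate`,
#'   `underclaim_rate`.
#' @export
glance.recovery_metrics <- function(x, ...) {
  tibble::tibble(
    n_foci = nrow(x),
    exact_rate = mean(x$exact),
    overclaim_rate = mean(x$overclaim),
    underclaim_rate = mean(x$underclaim)
  )
}
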
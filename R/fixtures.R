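#' The ecdysozoan visual-opsin worked example
#'
#' Loads the published worked example bundled with the package: the dated
#' chain of four visual-opsin duplications along the arthropod stem lineage
#' (with their 95% credibility intervals, in Ma) and the divergence intervals
#' of the five focal lineages used to infer ancestral opsin complements
#' (the *Pambdelurion*/*Kerygmachela* split, *Opabinia*, *Anomalocaris*,
#' *Fuxianhuia*, and crown Arthropoda, i.e. the Mandibulata-Chelicerata
#' split).
#'
#' @return A list with elements
#'   \describe{
#'     \item{`events`}{tibble of duplication events (input form for
#'       [gene_lineage_tree()]).}
#'     \item{`gene_tree`}{the assembled [gene_lineage_tree()], rooted at
#'       `Rh7/UV/SWS/MWS/LWS`.}
#'     \item{`divergences`}{tibble `lineage`, `ci_young`, `ci_old` of the five
#'       focal divergence intervals.}
#'   }
#' @examples
#' fx <- ecdysozoan_opsins()
#' infer_all(NULL, fx$gene_tree, fx$divergences)
#' @export
ecdysozoan_opsins <- function() {
  events <- read_duplication_events(
    system.file("extdata", "opsin_duplications.tsv", package = "chronopsin",
                mustWork = TRUE))
  div <- tibble::as_tibble(utils::read.delim(
    system.file("extdata", "ecdysozoan_divergences.tsv", package = "chronopsin",
                mustWork = TRUE), stringsAsFactors = FALSE))
  list(events = events,
       gene_tree = gene_lineage_tree(events),
       divergences = div)
}

#' The ecdysozoan opsin taxonomic-distribution fixture
#'
#' A small gene tree / species tree / tip-map triple encoding which extant
#' ecdysozoan lineages carry which opsin paralogue clades (single orthologues
#' of the ancestral visual opsin in Priapulida, Nematomorpha, and Tardigrada;
#' the four paralogue clades in Chelicerata and Pancrustacea, with the
#' UV/SWS duplication confined to Pancrustacea). Used to demonstrate LCA
#' reconciliation: the ecdysozoan root carries a single gene lineage, the
#' crown-arthropod node four.
#'
#' @return A list with `gene_tree` (`phylo`), `species_tree` (`phylo`), and
#'   `tip_map` (tibble).
#' @examples
#' fx <- opsin_distribution()
#' rec <- lca_reconcile(fx$gene_tree, fx$species_tree, fx$tip_map)
#' copies_at(rec, c("Priapulida", "Pancrustacea"))   # ecdysozoan root: 1
#' copies_at(rec, c("Chelicerata", "Pancrustacea"))  # crown arthropods: 4
#' @export
opsin_distribution <- function() {
  list(
    gene_tree = ape::read.tree(
      system.file("extdata", "opsin_gene_tree.nwk", package = "chronopsin",
                  mustWork = TRUE)),
    species_tree = ape::read.tree(
      system.file("extdata", "ecdysozoan_species_tree.nwk",
                  package = "chronopsin", mustWork = TRUE)),
    tip_map = read_tip_map(
      system.file("extdata", "opsin_tip_map.tsv", package = "chronopsin",
                  mustWork = TRUE))
  )
}
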
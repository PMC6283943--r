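#' Timeline plot of a gene-lineage tree
#'
#' Horizontal 95% credibility bars for each duplication event on a reversed
#' Ma-before-present axis (older to the left), optionally overlaid with focal
#' divergence intervals -- the standard summary figure for comparing a gene
#' family's duplication chronology against species divergences.
#'
#' @param object A [gene_lineage_tree()].
#' @param divergences Optional tibble `lineage`/`label`, `ci_young`, `ci_old`
#'   of divergence intervals to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gene_lineage_tree <- function(object, divergences = NULL, ...) {
  dup <- tidy(object)
  dup <- dup[!dup$is_leaf, c("name", "ci_young", "ci_old")]
  dup$track <- "duplication"
  dat <- dup
  if (!is.null(divergences)) {
    div <- tibble::as_tibble(divergences)
    if (!"lineage" %in% names(div) && "label" %in% names(div)) {
      div$lineage <- div$label
    }
    div <- tibble::tibble(name = div$lineage, ci_young = div$ci_young,
                          ci_old = div$ci_old, track = "divergence")
    dat <- dplyr::bind_rows(dat, div)
  }
  dat$name <- factor(dat$name, levels = rev(unique(dat$name)))
  ggplot2::ggplot(dat, ggplot2::aes(y = .data$name, colour = .data$track)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$ci_old, xend = .data$ci_young,
                                       yend = .data$name), linewidth = 2) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "age (Ma before present)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Bar plot of inferred complement sizes
#'
#' One bar per focal lineage, filled by chromacy class.
#'
#' @param object An [infer_all()] complement table.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.complement_table <- function(object, ...) {
  dat <- object[is.na(object$error), ]
  dat$lineage <- factor(dat$lineage, levels = dat$lineage)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$lineage, y = .data$size,
                                    fill = .data$chromacy)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "minimal gene complement size",
                  fill = "chromacy") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
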
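#' Canonical naming of ancestral genes
#'
#' An ancestral (pre-duplication) gene is named by concatenating the names of
#' its terminal descendant paralogues with `/`, in a fixed precedence order, a
#' convention borrowed from the regulatory-gene literature. The precedence is
#' a total order over the terminal paralogue names in use; the default is the
#' visual-opsin order.
#'
#' @param leaf_names Character vector (a set) of terminal paralogue names.
#' @param precedence Character vector giving the concatenation order; defaults
#'   to [opsin_precedence()].
#' @return A single canonical name string. A singleton set returns the bare
#'   name.
#' @examples
#' canonical_name(c("LWS", "MWS"))                # "MWS/LWS"
#' canonical_name(c("SWS", "Rh7", "LWS", "UV", "MWS"))
#' @export
canonical_name <- function(leaf_names, precedence = opsin_precedence()) {
  leaf_names <- unique(leaf_names)
  if (length(leaf_names) == 0) stop("`leaf_names` must be non-empty", call. = FALSE)
  idx <- match(leaf_names, precedence)
  if (anyNA(idx)) {
    stop("terminal name(s) not in precedence: ",
         paste(leaf_names[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  paste(leaf_names[order(idx)], collapse = "/")
}

#' Default terminal-paralogue precedence for the visual opsins
#'
#' The order in which terminal opsin paralogue names are concatenated when
#' naming ancestral genes: Rh7, UV, SWS, MWS, LWS (so the ecdysozoan ancestral
#' visual opsin is `Rh7/UV/SWS/MWS/LWS`).
#'
#' @return Character vector of length 5.
#' @export
opsin_precedence <- function() c("Rh7", "UV", "SWS", "MWS", "LWS")

#' Compare gene names on their underlying paralogue sets
#'
#' Literature spellings vary in component order (`Rh7/UV/SWS/LWS/MWS` vs
#' `Rh7/UV/SWS/MWS/LWS`); two names are the same gene when their component
#' sets are equal.
#'
#' @param a,b Gene name strings (components separated by `/`).
#' @return `TRUE` or `FALSE`.
#' @export
same_gene <- function(a, b) {
  setequal(strsplit(a, "/", fixed = TRUE)[[1]],
           strsplit(b, "/", fixed = TRUE)[[1]])
}

name_components <- function(name) strsplit(name, "/", fixed = TRUE)[[1]]

#' Build a dated gene-lineage (duplication-chain) tree
#'
#' Assembles the rooted binary tree of named genes from a list of duplication
#' events. Each event splits one ancestral gene into two daughters, given as a
#' partition of terminal paralogue names, and carries a 95% credibility
#' interval on the duplication age. Internal-node names are derived
#' canonically from descendant leaves; the result is invariant to the input
#' order of events.
#'
#' @param events Data frame with columns `leaves_left`, `leaves_right`
#'   (terminal names, either character vectors in list-columns or strings
#'   separated by `,`, `;`, `+` or whitespace), `ci_young`, `ci_old`.
#' @param precedence Terminal-name precedence, see [canonical_name()].
#' @return An object of class `gene_lineage_tree`: a tibble of nodes (`id`,
#'   `name`, `leaves` list-column, `ci_young`, `ci_old`, `parent`, `is_leaf`)
#'   with the precedence kept as an attribute. Row 1 is the root.
#' @examples
#' ev <- tibble::tibble(
#'   leaves_left = c("Rh7,UV,SWS", "MWS"),
#'   leaves_right = c("MWS,LWS", "LWS"),
#'   ci_young = c(587, 577), ci_old = c(615, 605)
#' )
#' gene_lineage_tree(ev)
#' @export
gene_lineage_tree <- function(events, precedence = opsin_precedence()) {
  events <- tibble::as_tibble(events)
  need <- c("leaves_left", "leaves_right", "ci_young", "ci_old")
  if (!all(need %in% names(events))) {
    stop("`events` needs columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  split_side <- function(x) {
    if (is.list(x)) return(lapply(x, as.character))
    lapply(strsplit(as.character(x), "[,;+[:space:]]+"), function(v) v[nzchar(v)])
  }
  left <- split_side(events$leaves_left)
  right <- split_side(events$leaves_right)
  n_ev <- nrow(events)
  ev <- tibble::tibble(
    left = left, right = right,
    set = purrr::map2(left, right, union),
    ci_young = as.numeric(events$ci_young),
    ci_old = as.numeric(events$ci_old)
  )
  if (any(ev$ci_young > ev$ci_old)) {
    stop("duplication interval with young > old", call. = FALSE)
  }
  if (any(purrr::map2_lgl(left, right, ~ length(intersect(.x, .y)) > 0))) {
    stop("an event's two sides share terminal names (not a partition)",
         call. = FALSE)
  }
  all_leaves <- unique(unlist(ev$set))
  if (anyNA(match(all_leaves, precedence))) {
    stop("terminal name(s) not in precedence: ",
         paste(setdiff(all_leaves, precedence), collapse = ", "), call. = FALSE)
  }

  # deterministic order: decreasing set size, then canonical name
  ord <- order(-lengths(ev$set),
               vapply(ev$set, canonical_name, character(1), precedence = precedence))
  ev <- ev[ord, ]

  # laminar check + the root must cover every terminal in use
  key <- function(s) paste(sort(s), collapse = "\r")
  set_keys <- vapply(ev$set, key, character(1))
  if (anyDuplicated(set_keys)) stop("duplicate duplication events", call. = FALSE)
  if (!setequal(ev$set[[1]], all_leaves)) {
    stop("events are not nested: no single root event covers all terminals",
         call. = FALSE)
  }
  for (i in seq_len(n_ev)) {
    for (j in seq_len(n_ev)) {
      if (i == j) next
      inter <- intersect(ev$set[[i]], ev$set[[j]])
      if (length(inter) &&
          !setequal(inter, ev$set[[i]]) && !setequal(inter, ev$set[[j]])) {
        stop("events are not hierarchically nested (overlapping partitions)",
             call. = FALSE)
      }
    }
  }

  acc <- list()
  counter <- 0L
  add_node <- function(set, parent) {
    counter <<- counter + 1L
    id <- counter
    is_leaf <- length(set) == 1
    row_ev <- if (!is_leaf) {
      hit <- which(set_keys == key(set))
      if (!length(hit)) {
        stop("non-singleton gene {", paste(set, collapse = ","),
             "} has no duplication event: events are incomplete or non-nested",
             call. = FALSE)
      }
      hit
    } else NA_integer_
    acc[[id]] <<- tibble::tibble(
      id = id,
      name = canonical_name(set, precedence),
      leaves = list(sort(set)),
      ci_young = if (is_leaf) NA_real_ else ev$ci_young[row_ev],
      ci_old = if (is_leaf) NA_real_ else ev$ci_old[row_ev],
      parent = parent,
      is_leaf = is_leaf
    )
    if (!is_leaf) {
      add_node(ev$left[[row_ev]], id)
      add_node(ev$right[[row_ev]], id)
    }
    id
  }
  add_node(sort(ev$set[[1]]), NA_integer_)
  nodes <- dplyr::bind_rows(acc)

  out <- structure(nodes, class = c("gene_lineage_tree", class(nodes)),
                   precedence = precedence)
  validate_gene_lineage_tree(out)
  out
}

#' Validate a gene-lineage tree
#'
#' Checks that every internal name re-derives canonically from its subtree's
#' leaves and that duplication ages are monotone down the chain: a daughter
#' duplication's old bound may not exceed its parent's old bound, and its
#' young bound may not exceed the parent's old bound (a daughter cannot be
#' entirely older than its parent).
#'
#' @param glt A `gene_lineage_tree`.
#' @return `glt`, invisibly, or an error naming the offending pair of events.
#' @export
validate_gene_lineage_tree <- function(glt) {
  stopifnot(inherits(glt, "gene_lineage_tree"))
  prec <- attr(glt, "precedence")
  ok <- vapply(seq_len(nrow(glt)), function(i) {
    identical(glt$name[i], canonical_name(glt$leaves[[i]], prec))
  }, logical(1))
  if (!all(ok)) {
    stop("non-canonical internal name(s): ",
         paste(glt$name[!ok], collapse = ", "), call. = FALSE)
  }
  internal <- which(!glt$is_leaf)
  for (i in internal) {
    p <- glt$parent[i]
    if (is.na(p)) next
    if (glt$ci_old[i] > glt$ci_old[p] + 1e-9 ||
        glt$ci_young[i] > glt$ci_old[p] + 1e-9) {
      stop(sprintf(
        "duplication age monotonicity violated: %s (%g-%g Ma) under %s (%g-%g Ma)",
        glt$name[i], glt$ci_young[i], glt$ci_old[i],
        glt$name[p], glt$ci_young[p], glt$ci_old[p]), call. = FALSE)
    }
  }
  invisible(glt)
}

glt_children <- function(glt, id) glt$id[!is.na(glt$parent) & glt$parent == id]

#' Read duplication events from TSV or JSON
#'
#' TSV columns / JSON fields: `leaves_left`, `leaves_right`, `ci_young`,
#' `ci_old` (leaf lists comma-separated in TSV).
#'
#' @param path File path (`.json` parsed as JSON, anything else as TSV).
#' @return A tibble of events for [gene_lineage_tree()].
#' @export
read_duplication_events <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    tibble::as_tibble(jsonlite::fromJSON(path))
  } else {
    tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
  }
}

#' @export
print.gene_lineage_tree <- function(x, ...) {
  cat(sprintf("<gene_lineage_tree: root %s, %d duplication(s), %d terminal(s)>\n",
              x$name[1], sum(!x$is_leaf), sum(x$is_leaf)))
  internal <- x[!x$is_leaf, ]
  for (i in seq_len(nrow(internal))) {
    cat(sprintf("  %s: %g-%g Ma\n", internal$name[i],
                internal$ci_young[i], internal$ci_old[i]))
  }
  invisible(x)
}
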
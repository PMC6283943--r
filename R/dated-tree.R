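#' Rooted, dated phylogeny with credibility intervals and fossil tips
#'
#' A `dated_tree` wraps an `ape::phylo` topology together with a node table
#' holding, per node: an optional age point estimate (Ma before present), an
#' optional 95% credibility interval, and a tip kind (`"extant"`, `"fossil"`,
#' or `"internal"`). Extant tips sit at age 0; fossil tips have positive ages
#' (dated tips, as produced by tip-dating under the fossilized birth-death
#' process).
#'
#' @param phylo A rooted `ape::phylo`.
#' @param ages Optional data frame with columns `node` (ape node index), and
#'   any of `age`, `ci_young`, `ci_old`. Missing nodes get `NA` ages
#'   (tips default to age 0, i.e. extant).
#' @param root_age If `ages` is `NULL` and `phylo` has branch lengths, node
#'   ages are derived by subtracting root-to-node path lengths from this root
#'   age.
#' @return An object of class `dated_tree`: a list with elements `phylo` and
#'   `ages` (a tibble with one row per node).
#' @examples
#' tr <- dated_tree(ape::read.tree(text = "((A:10,B:10):5,C:15);"), root_age = 15)
#' tidy(tr)
#' @export
dated_tree <- function(phylo, ages = NULL, root_age = NULL) {
  if (!inherits(phylo, "phylo")) stop("`phylo` must be an ape::phylo", call. = FALSE)
  nt <- n_tips(phylo)
  nn <- nt + phylo$Nnode
  tab <- tibble::tibble(
    node = seq_len(nn),
    label = vapply(seq_len(nn), function(i) node_label(phylo, i), character(1)),
    age = c(rep(0, nt), rep(NA_real_, phylo$Nnode)),
    ci_young = NA_real_,
    ci_old = NA_real_
  )
  if (is.null(ages) && !is.null(root_age)) {
    if (is.null(phylo$edge.length)) {
      stop("`root_age` given but tree has no branch lengths", call. = FALSE)
    }
    depth <- ape::node.depth.edgelength(phylo)
    a <- root_age - depth
    a[abs(a) < 1e-8 * max(root_age, 1)] <- 0
    tab$age <- a
  } else if (!is.null(ages)) {
    ages <- tibble::as_tibble(ages)
    if (!"node" %in% names(ages)) stop("`ages` needs a `node` column", call. = FALSE)
    for (col in intersect(c("age", "ci_young", "ci_old"), names(ages))) {
      tab[[col]][match(ages$node, tab$node)] <- ages[[col]]
    }
  }
  out <- structure(list(phylo = phylo, ages = finish_kinds(tab, nt)),
                   class = "dated_tree")
  validate_dated_tree(out)
}

finish_kinds <- function(tab, nt) {
  tab$kind <- ifelse(tab$node <= nt,
                     ifelse(!is.na(tab$age) & tab$age > 0, "fossil", "extant"),
                     "internal")
  tab
}

#' Validate the invariants of a dated tree
#'
#' Checks non-negative ages, age monotonicity (a parent is at least as old as
#' each child wherever both point estimates exist), unique tip labels,
#' well-formed credibility intervals, and containment of point estimates in
#' their intervals.
#'
#' @param x A `dated_tree`.
#' @param tol Numerical tolerance on age comparisons, Ma.
#' @return `x`, invisibly, or an error describing the offending nodes.
#' @export
validate_dated_tree <- function(x, tol = 1e-6) {
  stopifnot(inherits(x, "dated_tree"))
  phy <- x$phylo
  tab <- x$ages
  if (anyDuplicated(phy$tip.label)) {
    dup <- unique(phy$tip.label[duplicated(phy$tip.label)])
    stop("duplicate tip labels: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.na(tab$age) & tab$age < -tol)
  if (length(bad)) {
    stop("negative node ages at node(s): ",
         paste(describe_nodes(x, bad), collapse = ", "), call. = FALSE)
  }
  has_ci <- !is.na(tab$ci_young) & !is.na(tab$ci_old)
  if (any(has_ci & tab$ci_young > tab$ci_old + tol)) {
    stop("credibility interval with young > old", call. = FALSE)
  }
  inside <- is.na(tab$age) | !has_ci |
    (tab$age >= tab$ci_young - tol & tab$age <= tab$ci_old + tol)
  if (!all(inside)) {
    stop("age point estimate outside its credibility interval at node(s): ",
         paste(describe_nodes(x, which(!inside)), collapse = ", "), call. = FALSE)
  }
  par <- parent_vector(phy)
  both <- which(!is.na(par) & !is.na(tab$age) & !is.na(tab$age[par]))
  viol <- both[tab$age[par[both]] < tab$age[both] - tol]
  if (length(viol)) {
    pairs <- vapply(viol, function(v) {
      sprintf("%s (%.6g Ma) under %s (%.6g Ma)",
              describe_nodes(x, v), tab$age[v],
              describe_nodes(x, par[v]), tab$age[par[v]])
    }, character(1))
    stop("age monotonicity violated (child older than parent): ",
         paste(pairs, collapse = "; "), call. = FALSE)
  }
  invisible(x)
}

describe_nodes <- function(x, nodes) {
  lab <- x$ages$label[nodes]
  ifelse(is.na(lab) | !nzchar(lab), paste0("#", nodes), lab)
}

#' @export
print.dated_tree <- function(x, ...) {
  tab <- x$ages
  cat(sprintf("<dated_tree: %d extant tips, %d fossil tips, %d internal nodes>\n",
              sum(tab$kind == "extant"), sum(tab$kind == "fossil"),
              sum(tab$kind == "internal")))
  if (any(!is.na(tab$age))) {
    cat(sprintf("  root age: %s Ma; %d nodes with credibility intervals\n",
                format(tab$age[root_node(x$phylo)], digits = 6),
                sum(!is.na(tab$ci_young))))
  }
  invisible(x)
}

# ---------------------------------------------------------------------------
# Parsing

#' Parse a dated tree from Newick or NEXUS text
#'
#' Three annotation dialects are supported:
#' \describe{
#'   \item{`"annotated"`}{node comments of the form
#'     `[&age=571,ci={558,585}]` placed after a tip or internal-node label.
#'     Interval bounds may be written in either order and are normalized to
#'     young-first. Tips without an age annotation are taken as extant
#'     (age 0).}
#'   \item{`"branch_lengths"`}{bare Newick with branch lengths plus a declared
#'     `root_age`; node ages are derived by subtraction.}
#'   \item{`"bare"`}{topology only; internal-node ages are attached later with
#'     [attach_node_ages()], tips default to extant.}
#' }
#'
#' @param text Newick or NEXUS string.
#' @param dialect One of `"annotated"`, `"branch_lengths"`, `"bare"`.
#' @param root_age Root age in Ma (required for `"branch_lengths"`).
#' @param format `"newick"` (default) or `"nexus"` (a trees block containing
#'   one tree).
#' @return A [dated_tree()].
#' @examples
#' parse_dated_tree("((A:10,B:10):5,C:15);", "branch_lengths", root_age = 15)
#' parse_dated_tree("((A,B)[&age=10,ci={8,12}],C)[&age=15];")
#' @export
parse_dated_tree <- function(text,
                             dialect = c("annotated", "branch_lengths", "bare"),
                             root_age = NULL,
                             format = c("newick", "nexus")) {
  dialect <- match.arg(dialect)
  format <- match.arg(format)
  if (format == "nexus") text <- newick_from_nexus(text)
  text <- sub("^\\s*\\[&[RU]\\]\\s*", "", text)  # rooting token
  check_newick_syntax(text)

  notes <- list()
  if (dialect == "annotated") {
    ex <- extract_comments(text)
    text <- ex$text
    notes <- ex$notes
  } else if (grepl("\\[", text, fixed = TRUE)) {
    stop("comment annotations present but dialect is '", dialect,
         "'; use dialect = 'annotated'", call. = FALSE)
  }
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy)) stop("malformed tree text (unparseable Newick)", call. = FALSE)

  if (dialect == "branch_lengths") {
    if (is.null(root_age)) stop("dialect 'branch_lengths' requires `root_age`",
                                call. = FALSE)
    return(dated_tree(phy, root_age = root_age))
  }
  if (dialect == "bare" || length(notes) == 0) {
    phy2 <- strip_tags(phy)$phylo
    return(dated_tree(phy2))
  }
  st <- strip_tags(phy)
  ages <- purrr::imap_dfr(st$tag, function(tag, node) {
    if (is.na(tag)) return(NULL)
    ann <- parse_annotation(notes[[tag]])
    tibble::tibble(node = as.integer(node), age = ann$age,
                   ci_young = ann$ci[1], ci_old = ann$ci[2])
  })
  dated_tree(st$phylo, ages = ages)
}

# Balanced-parenthesis pre-check with character offsets.
check_newick_syntax <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  in_comment <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (in_comment) {
      if (ch == "]") in_comment <- FALSE
      next
    }
    if (ch == "[") in_comment <- TRUE
    else if (ch == "(") depth <- depth + 1L
    else if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0) {
        stop(sprintf("parse error at character offset %d: unmatched ')'", i),
             call. = FALSE)
      }
    }
  }
  if (in_comment) stop("parse error: unterminated '[' comment", call. = FALSE)
  if (depth != 0) {
    stop(sprintf("parse error at character offset %d: %d unclosed '('",
                 nchar(text), depth), call. = FALSE)
  }
  if (!grepl(";", text, fixed = TRUE)) {
    stop(sprintf("parse error at character offset %d: missing ';' terminator",
                 nchar(text)), call. = FALSE)
  }
  invisible(TRUE)
}

# Replace each [&...] comment with a @@k@@ label tag so ape can read the tree,
# returning the rewritten text and the comment bodies.
extract_comments <- function(text) {
  m <- gregexpr("\\[&[^]]*\\]", text)[[1]]
  if (m[1] == -1) return(list(text = text, notes = list()))
  bodies <- regmatches(text, gregexpr("\\[&[^]]*\\]", text))[[1]]
  for (k in rev(seq_along(bodies))) {
    start <- m[k]; end <- m[k] + attr(m, "match.length")[k] - 1
    text <- paste0(substr(text, 1, start - 1), sprintf("@@%d@@", k),
                   substr(text, end + 1, nchar(text)))
  }
  list(text = text, notes = as.list(sub("\\]$", "", sub("^\\[&", "", bodies))))
}

# Remove @@k@@ tags from labels; return cleaned phylo plus node -> tag index.
strip_tags <- function(phy) {
  nn <- n_tips(phy) + phy$Nnode
  tag <- rep(NA_integer_, nn)
  clean <- function(labs, offset) {
    for (i in seq_along(labs)) {
      lab <- labs[i]
      if (is.na(lab)) next
      mt <- regmatches(lab, regexpr("@@(\\d+)@@", lab))
      if (length(mt)) {
        tag[offset + i] <<- as.integer(gsub("@", "", mt))
        labs[i] <- gsub("@@\\d+@@", "", lab)
      }
    }
    labs
  }
  phy$tip.label <- clean(phy$tip.label, 0L)
  if (!is.null(phy$node.label)) {
    phy$node.label <- clean(phy$node.label, n_tips(phy))
  }
  list(phylo = phy, tag = tag)
}

# "age=571,ci={558,585}" -> list(age=, ci=c(young, old)); interval order in
# the text is not trusted.
parse_annotation <- function(body) {
  age <- NA_real_
  civ <- c(NA_real_, NA_real_)
  am <- regmatches(body, regexpr("age\\s*=\\s*[0-9.eE+-]+", body))
  if (length(am)) age <- as.numeric(sub(".*=\\s*", "", am))
  cm <- regmatches(body, regexpr("ci\\s*=\\s*\\{[^}]*\\}", body))
  if (length(cm)) {
    vals <- as.numeric(strsplit(gsub(".*\\{|\\}", "", cm), ",")[[1]])
    if (length(vals) != 2 || any(is.na(vals))) {
      stop("malformed ci annotation: ", body, call. = FALSE)
    }
    civ <- unclass(as_ci(vals))
  }
  list(age = age, ci = civ)
}

newick_from_nexus <- function(text) {
  m <- regmatches(text, regexpr("(?is)tree\\s+[^=]+=\\s*(.*?;)", text, perl = TRUE))
  if (!length(m)) stop("no tree statement found in NEXUS text", call. = FALSE)
  sub("(?is)^tree\\s+[^=]+=\\s*", "", m, perl = TRUE)
}

# ---------------------------------------------------------------------------
# Writing

#' Write a dated tree to Newick or NEXUS text
#'
#' Inverse of [parse_dated_tree()]: `parse_dated_tree(write_dated_tree(x))`
#' returns a tree equal to `x` (same topology, ages, and intervals).
#'
#' @param tree A `dated_tree`.
#' @param dialect Output dialect, as in [parse_dated_tree()]. `"annotated"`
#'   writes `[&age=..,ci={young,old}]` comments on every node that has an age
#'   or interval.
#' @param format `"newick"` or `"nexus"`.
#' @return A single string.
#' @export
write_dated_tree <- function(tree,
                             dialect = c("annotated", "branch_lengths", "bare"),
                             format = c("newick", "nexus")) {
  dialect <- match.arg(dialect)
  format <- match.arg(format)
  validate_dated_tree(tree)
  phy <- tree$phylo
  tab <- tree$ages
  nt <- n_tips(phy)

  if (dialect != "bare") {
    if (all(!is.na(tab$age))) {
      par <- parent_vector(phy)
      phy$edge.length <- tab$age[phy$edge[, 1]] - tab$age[phy$edge[, 2]]
    } else if (is.null(phy$edge.length) && dialect == "branch_lengths") {
      stop("cannot write branch lengths: ages incomplete and no edge lengths",
           call. = FALSE)
    }
  } else {
    phy$edge.length <- NULL
  }

  if (dialect == "annotated") {
    note_of <- function(i) {
      parts <- character(0)
      if (!is.na(tab$age[i])) parts <- c(parts, sprintf("age=%s", num(tab$age[i])))
      if (!is.na(tab$ci_young[i])) {
        parts <- c(parts, sprintf("ci={%s,%s}", num(tab$ci_young[i]),
                                  num(tab$ci_old[i])))
      }
      if (!length(parts)) return(NA_character_)
      paste0("[&", paste(parts, collapse = ","), "]")
    }
    notes <- vapply(seq_len(nrow(tab)), note_of, character(1))
    # skip redundant age=0 notes on extant tips without intervals
    skip <- tab$node <= nt & tab$kind == "extant" & is.na(tab$ci_young)
    notes[skip] <- NA_character_
    tagged <- which(!is.na(notes))
    phy$tip.label <- vapply(seq_len(nt), function(i) {
      paste0(phy$tip.label[i], if (i %in% tagged) sprintf("@@%d@@", i) else "")
    }, character(1))
    nl <- if (is.null(phy$node.label)) rep("", phy$Nnode) else
      ifelse(is.na(phy$node.label), "", phy$node.label)
    phy$node.label <- vapply(seq_len(phy$Nnode), function(j) {
      i <- nt + j
      paste0(nl[j], if (i %in% tagged) sprintf("@@%d@@", i) else "")
    }, character(1))
    out <- ape::write.tree(phy)
    for (i in tagged) {
      out <- sub(sprintf("@@%d@@", i), notes[i], out, fixed = TRUE)
    }
  } else {
    out <- ape::write.tree(phy)
  }
  if (format == "nexus") {
    out <- paste0("#NEXUS\nbegin trees;\n\ttree tree1 = [&R] ", out, "\nend;\n")
  }
  out
}

num <- function(x) format(x, digits = 12, trim = TRUE, scientific = FALSE)

#' Compare two dated trees for equality
#'
#' Topology is compared on tip sets per clade (robust to node renumbering);
#' ages and intervals are compared with a tolerance. Used for round-trip
#' checks.
#'
#' @param a,b `dated_tree` objects.
#' @param tol Age tolerance in Ma.
#' @return `TRUE` or `FALSE`.
#' @export
dated_tree_equal <- function(a, b, tol = 1e-6) {
  ta <- clade_table(a)
  tb <- clade_table(b)
  if (nrow(ta) != nrow(tb)) return(FALSE)
  ta <- ta[order(ta$key), ]
  tb <- tb[order(tb$key), ]
  if (!identical(ta$key, tb$key)) return(FALSE)
  num_eq <- function(x, y) {
    (is.na(x) & is.na(y)) | (!is.na(x) & !is.na(y) & abs(x - y) <= tol)
  }
  all(num_eq(ta$age, tb$age)) &&
    all(num_eq(ta$ci_young, tb$ci_young)) &&
    all(num_eq(ta$ci_old, tb$ci_old))
}

clade_table <- function(x) {
  keys <- clade_keys(x$phylo)
  tibble::tibble(key = keys, age = x$ages$age,
                 ci_young = x$ages$ci_young, ci_old = x$ages$ci_old)
}

# ---------------------------------------------------------------------------
# Node addressing

#' Most recent common ancestor of a set of tips
#'
#' @param tree A `dated_tree` or `ape::phylo`.
#' @param tips Character vector of tip labels (a single label returns the tip
#'   itself).
#' @return One row of the node table (`node`, `label`, `age`, `ci_young`,
#'   `ci_old`, `kind`).
#' @export
mrca_node <- function(tree, tips) {
  phy <- if (inherits(tree, "dated_tree")) tree$phylo else tree
  if (length(tips) == 0) stop("`tips` must be non-empty", call. = FALSE)
  idx <- match(tips, phy$tip.label)
  if (anyNA(idx)) {
    stop("unknown tip label(s): ", paste(tips[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  node <- if (length(unique(idx)) == 1) idx[1] else ape::getMRCA(phy, unique(idx))
  if (inherits(tree, "dated_tree")) tree$ages[node, ] else
    tibble::tibble(node = node, label = node_label(phy, node))
}

#' Attach node ages and intervals from a two-tip address table
#'
#' Each row addresses the MRCA of two tips (how printed divergence intervals,
#' e.g. a Mandibulata-Chelicerata split at 540-519 Ma, are attached to named
#' splits). Topology is never modified.
#'
#' @param tree A `dated_tree`.
#' @param age_table Data frame with columns `tip_a`, `tip_b` and any of `age`,
#'   `ci_young`, `ci_old`. Two rows addressing the same node must agree.
#' @return The updated `dated_tree` (revalidated, so interval/monotonicity
#'   violations against already-assigned nodes fail here).
#' @export
attach_node_ages <- function(tree, age_table) {
  stopifnot(inherits(tree, "dated_tree"))
  age_table <- tibble::as_tibble(age_table)
  if (!all(c("tip_a", "tip_b") %in% names(age_table))) {
    stop("`age_table` needs columns tip_a, tip_b", call. = FALSE)
  }
  tab <- tree$ages
  assigned <- list()
  for (r in seq_len(nrow(age_table))) {
    row <- age_table[r, ]
    if (row$tip_a == row$tip_b) {
      stop(sprintf("row %d: two distinct tips are required (got '%s' twice)",
                   r, row$tip_a), call. = FALSE)
    }
    node <- mrca_node(tree, c(row$tip_a, row$tip_b))$node
    vals <- c(age = if ("age" %in% names(row)) row$age else NA_real_,
              ci_young = if ("ci_young" %in% names(row)) row$ci_young else NA_real_,
              ci_old = if ("ci_old" %in% names(row)) row$ci_old else NA_real_)
    if (!is.na(vals["ci_young"]) && !is.na(vals["ci_old"])) {
      vals[c("ci_young", "ci_old")] <- unclass(as_ci(vals[c("ci_young", "ci_old")]))
    }
    key <- as.character(node)
    if (!is.null(assigned[[key]])) {
      prev <- assigned[[key]]
      same <- isTRUE(all.equal(prev, vals, tolerance = 1e-9))
      if (!same) {
        stop(sprintf("conflicting assignments for node %s (rows address the same MRCA)",
                     describe_nodes(tree, node)), call. = FALSE)
      }
      next
    }
    assigned[[key]] <- vals
    for (f in names(vals)) if (!is.na(vals[[f]])) tab[[f]][node] <- vals[[f]]
  }
  tree$ages <- finish_kinds(tab, n_tips(tree$phylo))
  validate_dated_tree(tree)
  tree
}

#' Read a sidecar age table (TSV)
#'
#' Columns: `tip_a`, `tip_b`, `age`, `ci_young`, `ci_old`.
#'
#' @param path TSV file path.
#' @return A tibble suitable for [attach_node_ages()].
#' @export
read_age_table <- function(path) {
  tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
}
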
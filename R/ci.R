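#' Credibility interval on an event age
#'
#' Ages are in Ma before present: larger numbers are older. A 95% credibility
#' interval on a node age or duplication time is stored as the pair
#' `(young, old)` with `0 <= young <= old`. Degenerate intervals
#' (`young == old`) are allowed and represent exactly known ages.
#'
#' @param young Younger bound, Ma before present.
#' @param old Older bound, Ma before present.
#' @return A length-2 named numeric vector of class `"chron_ci"`.
#' @examples
#' ci(587, 615)        # the oldest opsin duplication interval
#' ci(600, 600)        # a degenerate (exact) age
#' @export
ci <- function(young, old = young) {
  stopifnot(is.numeric(young), is.numeric(old),
            length(young) == 1, length(old) == 1)
  if (is.na(young) || is.na(old)) {
    stop("credibility interval bounds must not be NA", call. = FALSE)
  }
  if (young < 0) stop("credibility interval bounds must be >= 0", call. = FALSE)
  if (young > old) {
    stop(sprintf("interval young bound (%g) exceeds old bound (%g)", young, old),
         call. = FALSE)
  }
  structure(c(young = young, old = old), class = "chron_ci")
}

#' Coerce to a credibility interval, normalizing bound order
#'
#' Unlike [ci()], written order is not trusted: the smaller value becomes the
#' young bound. This is how annotation dialects that print intervals old-first
#' are absorbed.
#'
#' @param x A length-2 numeric vector, in either order.
#' @return A `"chron_ci"` object.
#' @export
as_ci <- function(x) {
  if (inherits(x, "chron_ci")) return(x)
  stopifnot(is.numeric(x), length(x) == 2)
  ci(min(x), max(x))
}

#' @export
print.chron_ci <- function(x, ...) {
  cat(sprintf("<ci: %g-%g Ma>\n", x[["young"]], x[["old"]]))
  invisible(x)
}

# Normalize heterogeneous interval input (chron_ci, length-2 numeric, 2-column
# matrix/data.frame) to an n x 2 matrix with columns young, old.
ci_matrix <- function(x, arg = "interval") {
  if (inherits(x, "chron_ci")) {
    m <- matrix(unclass(x), ncol = 2)
  } else if (is.data.frame(x)) {
    cols <- intersect(c("ci_young", "ci_old"), names(x))
    if (length(cols) == 2) {
      m <- cbind(x$ci_young, x$ci_old)
    } else if (all(c("young", "old") %in% names(x))) {
      m <- cbind(x$young, x$old)
    } else {
      m <- as.matrix(x[, 1:2])
    }
  } else if (is.matrix(x)) {
    m <- x[, 1:2, drop = FALSE]
  } else if (is.numeric(x) && length(x) == 2) {
    m <- matrix(x, ncol = 2)
  } else {
    stop(sprintf("cannot interpret `%s` as credibility interval(s)", arg),
         call. = FALSE)
  }
  if (any(is.na(m))) stop(sprintf("`%s` contains NA bounds", arg), call. = FALSE)
  if (any(m[, 1] > m[, 2])) {
    stop(sprintf("`%s` has young bound > old bound", arg), call. = FALSE)
  }
  colnames(m) <- c("young", "old")
  m
}
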
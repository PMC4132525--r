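#' Validate and construct a binary response matrix
#'
#' The universe every scaling stage consumes: a complete-case households x
#' items matrix with entries in \{0, 1\}. Construction enforces the
#' assumptions the downstream coefficients rely on: no missing entries, at
#' least two households and two items, and no constant item (an item owned
#' by everyone or no-one carries no ordering information and makes the
#' expected Guttman error count zero).
#'
#' @param x a matrix or data frame of 0/1 responses, households in rows.
#' @param item_labels optional character vector of item names; defaults to
#'   existing column names or `item1..itemk`.
#' @param household_ids optional identifiers; defaults to existing row names
#'   or `1..n`.
#' @return an integer matrix of class `response_matrix` with item labels as
#'   column names and household ids as row names.
#' @examples
#' x <- as_response_matrix(matrix(c(1, 1, 0, 0, 1, 0, 1, 0), 4, 2))
#' item_popularity(x)
#' @export
as_response_matrix <- function(x, item_labels = NULL, household_ids = NULL) {
  if (inherits(x, "response_matrix") && is.null(item_labels) &&
      is.null(household_ids)) {
    return(x)
  }
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) stop("responses must be a matrix or data frame")
  if (anyNA(x)) {
    stop("response matrix contains missing values; ",
         "exclude incomplete households before construction")
  }
  storage.mode(x) <- "integer"
  if (!all(x == 0L | x == 1L)) stop("responses must be coded 0/1")
  if (nrow(x) < 2L) stop("need at least 2 households")
  if (ncol(x) < 2L) stop("need at least 2 items")
  if (is.null(item_labels)) {
    item_labels <- colnames(x)
    if (is.null(item_labels)) item_labels <- paste0("item", seq_len(ncol(x)))
  }
  if (length(item_labels) != ncol(x)) stop("item_labels length mismatch")
  if (is.null(household_ids)) {
    household_ids <- rownames(x)
    if (is.null(household_ids)) household_ids <- as.character(seq_len(nrow(x)))
  }
  p <- colMeans(x)
  if (any(p == 0 | p == 1)) {
    bad <- item_labels[p == 0 | p == 1]
    stop("constant item(s) rejected (popularity 0 or 1): ",
         paste(bad, collapse = ", "))
  }
  dimnames(x) <- list(household_ids, item_labels)
  class(x) <- c("response_matrix", class(x))
  x
}

#' Item popularities and the implied difficulty order
#'
#' The proportion of households responding positively to each item. In the
#' nonparametric item response view, popularity orders items from "easy"
#' (widely owned) to "hard" (rare); ties are broken by the original column
#' index so the ordering is deterministic.
#'
#' @param x a [as_response_matrix()] input.
#' @return a data frame with one row per item: `item`, `popularity`, and
#'   `rank` (1 = most popular), row order following the input columns.
#' @export
item_popularity <- function(x) {
  x <- as_response_matrix(x)
  p <- colMeans(x)
  # ties: lower column index wins, i.e. ranks by (-p, index)
  rk <- order(order(-p, seq_along(p)))
  data.frame(item = colnames(x), popularity = unname(p), rank = as.integer(rk),
             row.names = NULL)
}

#' @export
print.response_matrix <- function(x, ...) {
  cat("Response matrix:", nrow(x), "households x", ncol(x), "items\n")
  p <- colMeans(x)
  cat(sprintf("item popularities %.3f-%.3f\n", min(p), max(p)))
  invisible(x)
}
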
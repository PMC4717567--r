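#' Labelled distance matrices
#'
#' `dist_matrix()` builds the validated, labelled, symmetric, zero-diagonal
#' matrix that every Mantel test in the package consumes. Labels are stored
#' in canonical (C-locale lexicographic) order at construction; all
#' downstream consumers align matrices by label, never by index, so the
#' order a matrix was built in can never leak into a result.
#'
#' @param values square numeric matrix of non-negative distances.
#' @param labels character vector of unique labels, one per row. Defaults to
#'   the rownames of `values`.
#' @param metadata optional named list recording how the matrix was built
#'   (distance type, mode flags); carried along and written to reports.
#'
#' @return a `dist_matrix`: a base matrix with unique `dimnames`, symmetric
#'   to 1e-12, exact zero diagonal, labels in canonical order.
#' @examples
#' m <- dist_matrix(matrix(c(0, 1, 1, 0), 2), labels = c("b", "a"))
#' rownames(m) # "a" "b"
#' @export
dist_matrix <- function(values, labels = rownames(values), metadata = list()) {
  values <- as.matrix(values)
  if (!is.numeric(values) || nrow(values) != ncol(values)) {
    abort("`values` must be a square numeric matrix.")
  }
  n <- nrow(values)
  if (is.null(labels)) abort("labels are required (pass `labels` or rownames).")
  labels <- as.character(labels)
  if (length(labels) != n) {
    abort(sprintf("got %d labels for a %dx%d matrix.", length(labels), n, n))
  }
  if (anyDuplicated(labels) || any(!nzchar(labels)) || anyNA(labels)) {
    abort("labels must be unique, non-empty and non-missing.")
  }
  if (anyNA(values) || any(!is.finite(values))) {
    abort("distances must all be finite.")
  }
  if (any(values < 0)) abort("distances must be non-negative.")
  if (max(abs(values - t(values))) > 1e-12) {
    abort("matrix is not symmetric (tolerance 1e-12).")
  }
  if (any(abs(diag(values)) > 1e-12)) {
    abort("diagonal must be zero.")
  }
  ord <- order(labels, method = "radix")
  values <- values[ord, ord, drop = FALSE]
  diag(values) <- 0
  dimnames(values) <- list(labels[ord], labels[ord])
  structure(values, class = c("dist_matrix", "matrix", "array"),
            metadata = metadata)
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("<dist_matrix: %d labels>\n", nrow(x)))
  print(`attributes<-`(x, list(dim = dim(x), dimnames = dimnames(x))), ...)
  invisible(x)
}

is_dist_matrix <- function(x) inherits(x, "dist_matrix")

# strict lower-triangle (i > j) index pairs in column-major order
tri_pairs <- function(n) {
  idx <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
  list(i = idx[, 1], j = idx[, 2])
}

#' Reorder a dist_matrix to a given label vector
#'
#' @param x a `dist_matrix`.
#' @param labels character vector; must be a subset of the labels of `x`.
#' @return the `dist_matrix` restricted/reordered to `labels` (then put back
#'   in canonical order, which is the package-wide convention).
#' @export
align_dist <- function(x, labels) {
  stopifnot(is_dist_matrix(x))
  missing <- setdiff(labels, rownames(x))
  if (length(missing) > 0) {
    abort(paste0("labels absent from matrix: ", toString(missing)))
  }
  dist_matrix(unclass(x)[labels, labels, drop = FALSE],
              metadata = attr(x, "metadata"))
}

#' @describeIn dist_matrix long-format tibble of the strict lower triangle
#'   (`item1`, `item2`, `distance`), one row per unordered pair.
#' @param x a `dist_matrix`.
#' @param ... unused.
#' @method tidy dist_matrix
#' @export
tidy.dist_matrix <- function(x, ...) {
  tp <- tri_pairs(nrow(x))
  lab <- rownames(x)
  tibble(item1 = lab[tp$i], item2 = lab[tp$j],
         distance = unclass(x)[cbind(tp$i, tp$j)])
}

#' Read / write a labelled square distance matrix as TSV
#'
#' The format is a square table with a header row of labels and the label
#' repeated in the first column, UTF-8, decimal points.
#'
#' @param path file path.
#' @return `read_dist_tsv()` returns a validated [dist_matrix()];
#'   `write_dist_tsv()` returns `path` invisibly.
#' @export
read_dist_tsv <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  labels <- df[[1]]
  values <- as.matrix(df[, -1, drop = FALSE])
  if (!identical(colnames(values), as.character(labels))) {
    abort("header labels and first-column labels disagree.")
  }
  rownames(values) <- labels
  dist_matrix(values)
}

#' @rdname read_dist_tsv
#' @param x a `dist_matrix`.
#' @export
write_dist_tsv <- function(x, path) {
  stopifnot(is_dist_matrix(x))
  df <- as_tibble(as.data.frame(unclass(x)), rownames = "label")
  readr::write_tsv(df, path)
  invisible(path)
}

# serializable representation used by JSON reports
dist_matrix_to_list <- function(x) {
  list(labels = rownames(x), values = unclass(unname(x)),
       metadata = attr(x, "metadata"))
}
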
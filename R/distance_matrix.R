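#' Labelled symmetric distance/similarity matrix
#'
#' Light container used throughout the package for pairwise quantities:
#' community similarity, community dissimilarity, uncorrected p-distance
#' between host marker sequences, and great-circle distance between sites.
#' The `kind` attribute records the semantics and drives validation: the
#' diagonal must be 1 for `"similarity"` and 0 otherwise; similarity and
#' p-distance values must lie in `[0, 1]`; all values must be nonnegative
#' and the matrix symmetric.
#'
#' @param values square numeric matrix with identical row and column names
#'   (the labels). Symmetry is enforced to within `1e-12`.
#' @param kind one of `"similarity"`, `"dissimilarity"`, `"p_distance"`,
#'   `"geographic_km"`.
#' @return an object of class `distance_matrix`: the numeric matrix with a
#'   `kind` attribute.
#' @examples
#' m <- matrix(c(0, 0.2, 0.2, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
#' distance_matrix(m, "p_distance")
#' @export
distance_matrix <- function(values,
                            kind = c("similarity", "dissimilarity",
                                     "p_distance", "geographic_km")) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(values) != ncol(values)) {
    stop("`values` must be square", call. = FALSE)
  }
  labels <- rownames(values)
  if (is.null(labels) || is.null(colnames(values)) ||
      !identical(labels, colnames(values))) {
    stop("`values` must carry identical row and column labels", call. = FALSE)
  }
  if (anyDuplicated(labels)) stop("labels must be unique", call. = FALSE)
  if (any(is.na(values))) stop("distance matrix contains NA", call. = FALSE)
  if (max(abs(values - t(values))) > 1e-12) {
    stop("matrix is not symmetric", call. = FALSE)
  }
  values <- (values + t(values)) / 2
  if (any(values < 0)) stop("values must be nonnegative", call. = FALSE)
  diag_target <- if (kind == "similarity") 1 else 0
  if (max(abs(diag(values) - diag_target)) > 1e-12) {
    stop(sprintf("diagonal must equal %d for kind '%s'", diag_target, kind),
         call. = FALSE)
  }
  if (kind %in% c("similarity", "p_distance") && any(values > 1 + 1e-12)) {
    stop(sprintf("%s values must lie in [0, 1]", kind), call. = FALSE)
  }
  structure(values, kind = kind, class = c("distance_matrix", "matrix", "array"))
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("<distance_matrix kind=%s, %d labels>\n", attr(x, "kind"), nrow(x)))
  print(unclass(x)[seq_len(min(8L, nrow(x))), seq_len(min(8L, ncol(x))), drop = FALSE])
  invisible(x)
}

#' @rdname distance_matrix
#' @param x a `distance_matrix`.
#' @export
dm_kind <- function(x) attr(x, "kind")

#' @rdname distance_matrix
#' @export
dm_labels <- function(x) rownames(x)

#' Convert a similarity matrix to its companion dissimilarity
#'
#' Returns `1 - S`, used for ordination, clustering, PERMANOVA and PERMDISP.
#'
#' @param s a `distance_matrix` of kind `"similarity"`.
#' @return a `distance_matrix` of kind `"dissimilarity"`.
#' @export
as_dissimilarity <- function(s) {
  stopifnot(inherits(s, "distance_matrix"))
  if (dm_kind(s) != "similarity") stop("`s` must be of kind 'similarity'", call. = FALSE)
  v <- 1 - unclass(s)
  v[v < 0] <- 0
  distance_matrix(v, "dissimilarity")
}

#' Subset a distance matrix to a set of labels
#'
#' @param x a `distance_matrix`.
#' @param labels character vector of labels to keep, in the requested order.
#' @return a `distance_matrix` of the same kind.
#' @export
dm_subset <- function(x, labels) {
  stopifnot(inherits(x, "distance_matrix"))
  missing <- setdiff(labels, dm_labels(x))
  if (length(missing)) {
    stop("labels not present in matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  distance_matrix(unclass(x)[labels, labels, drop = FALSE], dm_kind(x))
}

#' Write / read a distance matrix as square labelled CSV
#'
#' @param x a `distance_matrix`.
#' @param path file path.
#' @param kind matrix kind used when reading back.
#' @return `read_distance_csv` returns a `distance_matrix`;
#'   `write_distance_csv` returns `path` invisibly.
#' @export
write_distance_csv <- function(x, path) {
  stopifnot(inherits(x, "distance_matrix"))
  utils::write.csv(as.data.frame(unclass(x)), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_distance_csv
#' @export
read_distance_csv <- function(path, kind) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  distance_matrix(as.matrix(df), kind)
}
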
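#' Labeled/unlabeled samples in embedding space
#'
#' A `feature_matrix` holds `n` samples as rows of a `d`-dimensional numeric
#' matrix together with unique sample identifiers and per-sample class labels.
#' Samples without a class carry the sentinel label [UNLABELED]. All geometry
#' in this package (prototypes, distances, entropies) happens on the rows of
#' this container.
#'
#' @param features numeric matrix, `n x d`, all entries finite.
#' @param sample_ids character vector of `n` unique, non-empty identifiers.
#'   Defaults to `s1..sn`.
#' @param labels character vector of `n` class labels; use [UNLABELED] for
#'   samples without a class. Defaults to all-unlabeled.
#'
#' @return An object of class `feature_matrix`: a list with elements
#'   `features` (matrix), `sample_ids` (character), `labels` (character).
#' @examples
#' fm <- feature_matrix(matrix(rnorm(12), 4, 3),
#'                      sample_ids = c("a", "b", "c", "d"),
#'                      labels = c("x", "x", "y", UNLABELED))
#' nrow(fm)
#' @export
feature_matrix <- function(features,
                           sample_ids = NULL,
                           labels = NULL) {
  features <- as.matrix(features)
  if (!is.numeric(features)) {
    stop("`features` must be a numeric matrix", call. = FALSE)
  }
  n <- nrow(features)
  if (n < 1L || ncol(features) < 1L) {
    stop("`features` must have at least one row and one column", call. = FALSE)
  }
  if (any(!is.finite(features))) {
    stop("`features` contains NaN/Inf/NA entries", call. = FALSE)
  }
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(n))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != n) {
    stop("`sample_ids` must have one entry per row", call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    dup <- sample_ids[duplicated(sample_ids)][1L]
    stop("duplicate sample_id: ", dup, call. = FALSE)
  }
  if (any(!nzchar(sample_ids))) {
    stop("sample_ids must be non-empty strings", call. = FALSE)
  }
  if (is.null(labels)) labels <- rep(UNLABELED, n)
  labels <- as.character(labels)
  if (length(labels) != n) {
    stop("`labels` must have one entry per row", call. = FALSE)
  }
  dimnames(features) <- NULL
  structure(
    list(features = features, sample_ids = sample_ids, labels = labels),
    class = "feature_matrix"
  )
}

#' Sentinel label for samples without a class
#'
#' @format A length-one character constant, `"UNLABELED"`.
#' @export
UNLABELED <- "UNLABELED"

#' @export
dim.feature_matrix <- function(x) dim(x$features)

#' @export
print.feature_matrix <- function(x, ...) {
  n_lab <- sum(x$labels != UNLABELED)
  cat(sprintf(
    "<feature_matrix> %d samples x %d features (%d labeled, %d unlabeled)\n",
    nrow(x$features), ncol(x$features), n_lab, nrow(x$features) - n_lab
  ))
  invisible(x)
}

#' Subset a feature_matrix by row index or sample id
#'
#' @param fm a [feature_matrix()].
#' @param i integer row indices, logical mask, or character sample ids.
#' @return The subsetted `feature_matrix`.
#' @export
fm_subset <- function(fm, i) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (is.character(i)) {
    idx <- match(i, fm$sample_ids)
    if (anyNA(idx)) {
      stop("unknown sample id(s): ", paste(i[is.na(idx)], collapse = ", "),
           call. = FALSE)
    }
    i <- idx
  }
  feature_matrix(fm$features[i, , drop = FALSE],
                 fm$sample_ids[i], fm$labels[i])
}

#' Row-bind two feature matrices
#'
#' @param a,b [feature_matrix()] objects with equal feature dimension and
#'   disjoint sample ids.
#' @return The combined `feature_matrix`.
#' @export
fm_bind <- function(a, b) {
  stopifnot(inherits(a, "feature_matrix"), inherits(b, "feature_matrix"))
  if (ncol(a$features) != ncol(b$features)) {
    stop("feature dimensions differ: ", ncol(a$features), " vs ",
         ncol(b$features), call. = FALSE)
  }
  feature_matrix(rbind(a$features, b$features),
                 c(a$sample_ids, b$sample_ids),
                 c(a$labels, b$labels))
}
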
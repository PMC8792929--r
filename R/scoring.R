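#' Per-class prototype vectors from labeled base data
#'
#' Computes one prototype per class as the coordinate-wise arithmetic mean of
#' all base samples carrying that class label. Prototypes are the reference
#' frame for every distance-entropy score: a pool sample is scored by how its
#' Euclidean distances to these class centers distribute.
#'
#' @param base a fully labeled [feature_matrix()] with at least two distinct
#'   classes and at least one sample per class.
#' @return An object of class `prototype_set`: list with `class_labels`
#'   (character, lexicographically ordered — all downstream distance and
#'   proportion vectors are indexed in this order) and `prototypes`
#'   (`C x d` matrix, one row per class).
#' @examples
#' base <- feature_matrix(rbind(c(0, 0), c(2, 0), c(4, 4)),
#'                        labels = c("A", "A", "B"))
#' compute_prototypes(base)$prototypes
#' @export
compute_prototypes <- function(base) {
  stopifnot(inherits(base, "feature_matrix"))
  if (any(base$labels == UNLABELED)) {
    stop("base data contains UNLABELED samples; prototypes need labels",
         call. = FALSE)
  }
  classes <- sort(unique(base$labels), method = "radix")
  if (length(classes) < 2L) {
    stop("need at least 2 distinct classes, got ", length(classes),
         call. = FALSE)
  }
  protos <- matrix(0, length(classes), ncol(base$features))
  for (i in seq_along(classes)) {
    rows <- base$features[base$labels == classes[i], , drop = FALSE]
    protos[i, ] <- colMeans(rows)
  }
  rownames(protos) <- classes
  structure(list(class_labels = classes, prototypes = protos),
            class = "prototype_set")
}

#' @export
print.prototype_set <- function(x, ...) {
  cat(sprintf("<prototype_set> %d classes in %d dimensions: %s\n",
              length(x$class_labels), ncol(x$prototypes),
              paste(x$class_labels, collapse = ", ")))
  invisible(x)
}

#' Euclidean distances from one sample to every class prototype
#'
#' @param x numeric vector of length `d` (one embedded sample).
#' @param protos a [compute_prototypes()] result.
#' @return Numeric vector of length `C`, named by class, in the prototype
#'   set's class order; entry `i` is `sqrt(sum((x - prototype_i)^2))`.
#' @export
distances_to_prototypes <- function(x, protos) {
  stopifnot(inherits(protos, "prototype_set"))
  x <- as.numeric(x)
  if (length(x) != ncol(protos$prototypes)) {
    stop("dimension mismatch: sample has ", length(x),
         " features, prototypes have ", ncol(protos$prototypes),
         call. = FALSE)
  }
  d <- sqrt(rowSums(sweep(protos$prototypes, 2, x)^2))
  names(d) <- protos$class_labels
  d
}

#' Softmax proportional distribution over negated distances
#'
#' Converts a vector of distances into class proportions
#' `S_i = exp(-d_i / tau) / sum_j exp(-d_j / tau)`. Distances are negated so
#' that a smaller distance (greater similarity to that class) receives the
#' larger share. Computation shifts all distances by their minimum before
#' exponentiation; by the shift invariance of softmax this is exact and avoids
#' underflow when distances are large.
#'
#' @param dists nonnegative finite numeric vector of length `C >= 1`.
#' @param temperature positive softmax temperature `tau`. The default 1 uses
#'   raw distances; larger values flatten the distribution.
#' @return Numeric vector of the same length (names preserved), strictly
#'   positive, summing to 1.
#' @examples
#' proportional_distribution(c(1, 2, 3))
#' @export
proportional_distribution <- function(dists, temperature = 1) {
  dists <- as.numeric(dists) # keep names
  if (length(dists) < 1L || any(!is.finite(dists))) {
    stop("`dists` must be a non-empty finite numeric vector", call. = FALSE)
  }
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0) {
    stop("`temperature` must be a single positive number", call. = FALSE)
  }
  z <- -(dists - min(dists)) / temperature
  e <- exp(z)
  e / sum(e)
}

#' Distance-entropy of a proportional distribution
#'
#' Shannon entropy in bits, `E = -sum_i S_i log2(S_i)` with the convention
#' `0 * log2(0) = 0`. `E` is maximal (`log2 C`) when the sample is equidistant
#' from all prototypes — the model has no idea which class it belongs to, so
#' the sample is maximally informative — and approaches 0 when one class
#' dominates, marking a redundant sample inside an existing cluster.
#'
#' @param props probability vector (nonnegative, sums to 1 within 1e-8),
#'   e.g. from [proportional_distribution()].
#' @return Entropy in bits, in `[0, log2(length(props))]`.
#' @examples
#' distance_entropy(rep(1 / 6, 6)) # log2(6)
#' @export
distance_entropy <- function(props) {
  props <- as.numeric(props)
  if (any(!is.finite(props)) || any(props < 0)) {
    stop("`props` must be nonnegative and finite", call. = FALSE)
  }
  if (abs(sum(props) - 1) > 1e-8) {
    stop("`props` must sum to 1 (got ", format(sum(props)), ")",
         call. = FALSE)
  }
  p <- props[props > 0]
  -sum(p * log2(p))
}

# n x C Euclidean distance matrix via the expansion
# ||y - p||^2 = ||y||^2 + ||p||^2 - 2 y.p ; clipped at 0 against
# cancellation before the square root.
pairwise_distances <- function(X, P) {
  d2 <- outer(rowSums(X^2), rowSums(P^2), "+") - 2 * tcrossprod(X, P)
  sqrt(pmax(d2, 0))
}

# row-wise softmax of -D / tau, shifted by the row minimum of D
softmax_neg_rows <- function(D, temperature) {
  Z <- exp(-(D - apply(D, 1L, min)) / temperature)
  Z / rowSums(Z)
}

# row-wise entropy (bits) of a probability matrix, 0 log 0 := 0
entropy_rows <- function(S) {
  L <- ifelse(S > 0, log2(pmax(S, .Machine$double.xmin)), 0)
  -rowSums(S * L)
}

#' Score every pool sample by distance-entropy
#'
#' Applies the full indicator to each row of `pool`: Euclidean distances to
#' all class prototypes, the softmax proportional distribution over the
#' negated distances, and its base-2 entropy.
#'
#' @param pool a [feature_matrix()] of candidate samples (labels ignored).
#' @param protos a [compute_prototypes()] result with matching dimension.
#' @param temperature positive softmax temperature, see
#'   [proportional_distribution()].
#' @return A `score_table`: a data.frame with one row per pool sample in
#'   input order and columns `sample_id`, `entropy`, `d_<class>` (distances)
#'   and `p_<class>` (proportions) for every class. Attributes `class_order`
#'   and `temperature` record the scoring frame.
#' @examples
#' base <- feature_matrix(rbind(c(0, 0), c(4, 0)), labels = c("A", "B"))
#' pool <- feature_matrix(rbind(c(2, 0), c(0, 0.1)))
#' score_pool(pool, compute_prototypes(base))
#' @export
score_pool <- function(pool, protos, temperature = 1) {
  stopifnot(inherits(pool, "feature_matrix"),
            inherits(protos, "prototype_set"))
  if (ncol(pool$features) != ncol(protos$prototypes)) {
    stop("dimension mismatch: pool has ", ncol(pool$features),
         " features, prototypes have ", ncol(protos$prototypes),
         call. = FALSE)
  }
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0) {
    stop("`temperature` must be a single positive number", call. = FALSE)
  }
  D <- pairwise_distances(pool$features, protos$prototypes)
  S <- softmax_neg_rows(D, temperature)
  E <- entropy_rows(S)
  out <- data.frame(sample_id = pool$sample_ids, entropy = E,
                    stringsAsFactors = FALSE)
  colnames(D) <- paste0("d_", protos$class_labels)
  colnames(S) <- paste0("p_", protos$class_labels)
  out <- cbind(out, as.data.frame(D), as.data.frame(S))
  rownames(out) <- NULL
  attr(out, "class_order") <- protos$class_labels
  attr(out, "temperature") <- temperature
  class(out) <- c("score_table", "data.frame")
  out
}

#' Select the k most (or least) informative samples
#'
#' Ranks a score table by entropy and returns the top `k` ids under
#' `mode = "high"` (most informative: contested region between clusters) or
#' the bottom `k` under `mode = "low"` (most redundant: deep inside existing
#' clusters). Ties are broken by ascending sample id so selections are
#' deterministic.
#'
#' @param scores a `score_table` from [score_pool()].
#' @param k positive number of samples to select. If `k` exceeds the pool
#'   size the whole pool is returned with a warning.
#' @param mode `"high"` or `"low"`.
#' @param per_class_balanced if `TRUE`, take `k` samples per class according
#'   to `labels` instead of a single global top-k.
#' @param labels optional per-sample class labels, aligned with `scores`
#'   rows; required for `per_class_balanced`. These may be true labels or
#'   predicted ones, depending on what the caller has.
#' @return A `selection_result`: list with `mode`, `k`, `selected_ids`
#'   (in rank order), `per_class_balanced`.
#' @export
select_samples <- function(scores, k, mode = c("high", "low"),
                           per_class_balanced = FALSE, labels = NULL) {
  stopifnot(inherits(scores, "score_table"))
  mode <- match.arg(tolower(mode), c("high", "low"))
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != floor(k)) {
    stop("`k` must be a single positive integer", call. = FALSE)
  }
  k <- as.integer(k)
  rank_ids <- function(tab) {
    ord <- if (mode == "high") {
      order(-tab$entropy, tab$sample_id, method = "radix")
    } else {
      order(tab$entropy, tab$sample_id, method = "radix")
    }
    tab$sample_id[ord]
  }
  if (per_class_balanced) {
    if (is.null(labels)) {
      stop("per_class_balanced selection requires `labels`", call. = FALSE)
    }
    if (length(labels) != nrow(scores)) {
      stop("`labels` must have one entry per score row", call. = FALSE)
    }
    selected <- character(0)
    for (cl in sort(unique(as.character(labels)), method = "radix")) {
      ids <- rank_ids(scores[labels == cl, , drop = FALSE])
      if (k > length(ids)) {
        warning("class ", cl, ": requested ", k, " samples but only ",
                length(ids), " available; selecting all", call. = FALSE)
      }
      selected <- c(selected, utils::head(ids, k))
    }
  } else {
    ids <- rank_ids(scores)
    if (k > length(ids)) {
      warning("requested k=", k, " but pool has only ", length(ids),
              " samples; selecting all", call. = FALSE)
    }
    selected <- utils::head(ids, k)
  }
  structure(
    list(mode = toupper(mode), k = k, selected_ids = selected,
         per_class_balanced = per_class_balanced),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> mode=%s k=%d selected=%d%s\n",
              x$mode, x$k, length(x$selected_ids),
              if (x$per_class_balanced) " (per-class balanced)" else ""))
  invisible(x)
}
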
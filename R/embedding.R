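#' Specify an embedder
#'
#' An embedder maps raw sample vectors into the d-dimensional feature space
#' in which prototypes and distance-entropies are computed. Two kinds ship:
#'
#' * `"identity"` — pass-through; use when features are already embedded
#'   (e.g. precomputed network activations). Requires
#'   `input_dim == output_dim`.
#' * `"linear_proto"` — a trainable linear map `W` (`input_dim x output_dim`)
#'   fitted by full-batch gradient descent on the cross-entropy of the
#'   softmax-over-negated-distances to the class prototypes in the projected
#'   space, with prototypes recomputed from the projected training data each
#'   epoch. This keeps every learned geometry directly interpretable by the
#'   distance-entropy indicator itself.
#'
#' @param kind `"identity"` or `"linear_proto"`.
#' @param input_dim dimension of raw samples.
#' @param output_dim dimension `d` of the embedding space.
#' @param epochs number of full-batch gradient steps (`linear_proto` only).
#' @param step_size fixed gradient-descent step size.
#' @param seed integer seed for weight initialization; fitting is fully
#'   deterministic given the seed and training data.
#' @return An `embedder_spec` list.
#' @export
embedder_spec <- function(kind = c("identity", "linear_proto"),
                          input_dim, output_dim,
                          epochs = 200L, step_size = 0.1, seed = 1L) {
  kind <- match.arg(kind)
  input_dim <- as.integer(input_dim)
  output_dim <- as.integer(output_dim)
  if (input_dim < 1L || output_dim < 1L) {
    stop("input_dim and output_dim must be positive", call. = FALSE)
  }
  if (kind == "identity" && input_dim != output_dim) {
    stop("identity embedder requires input_dim == output_dim", call. = FALSE)
  }
  if (!is.numeric(step_size) || step_size <= 0) {
    stop("step_size must be positive", call. = FALSE)
  }
  structure(
    list(kind = kind, input_dim = input_dim, output_dim = output_dim,
         epochs = as.integer(epochs), step_size = step_size,
         seed = as.integer(seed)),
    class = "embedder_spec"
  )
}

#' Fit an embedder on labeled training data
#'
#' @param spec an [embedder_spec()].
#' @param train a fully labeled [feature_matrix()] with >= 2 classes and
#'   feature dimension `spec$input_dim`.
#' @return A `fitted_embedder`: list with `spec`, `weights` (`NULL` for
#'   identity), `final_loss`, and `loss_history` (initial loss followed by
#'   the loss after each epoch).
#' @export
fit_embedder <- function(spec, train) {
  stopifnot(inherits(spec, "embedder_spec"), inherits(train, "feature_matrix"))
  if (any(train$labels == UNLABELED)) {
    stop("training data contains UNLABELED samples", call. = FALSE)
  }
  if (length(unique(train$labels)) < 2L) {
    stop("need at least 2 classes to fit an embedder", call. = FALSE)
  }
  if (ncol(train$features) != spec$input_dim) {
    stop("dimension mismatch: train has ", ncol(train$features),
         " features, spec$input_dim is ", spec$input_dim, call. = FALSE)
  }
  if (spec$kind == "identity") {
    return(structure(
      list(spec = spec, weights = NULL, final_loss = NA_real_,
           loss_history = numeric(0)),
      class = "fitted_embedder"
    ))
  }
  fit_linear_proto(spec, train)
}

# Full-batch gradient descent on mean cross-entropy of the softmax over
# negated Euclidean distances to class prototypes in the projected space.
# Prototypes are recomputed from the projected data at the start of each
# epoch and treated as constants within the epoch's gradient.
fit_linear_proto <- function(spec, train) {
  X <- train$features
  classes <- sort(unique(train$labels), method = "radix")
  y <- match(train$labels, classes)
  n <- nrow(X)
  C <- length(classes)
  d <- spec$output_dim

  set.seed(spec$seed)
  W <- matrix(stats::rnorm(spec$input_dim * d, sd = 0.1), spec$input_dim, d)

  Tm <- matrix(0, n, C)
  Tm[cbind(seq_len(n), y)] <- 1
  class_mask <- Tm / rep(colSums(Tm), each = n) # n x C, columns average rows

  loss_of <- function(S) {
    -mean(log(pmax(S[cbind(seq_len(n), y)], .Machine$double.xmin)))
  }
  forward <- function(W) {
    Y <- X %*% W
    P <- crossprod(class_mask, Y)          # C x d prototypes
    D <- pairwise_distances(Y, P)
    S <- softmax_neg_rows(D, 1)
    list(Y = Y, P = P, D = D, S = S)
  }

  fw <- forward(W)
  history <- numeric(spec$epochs + 1L)
  history[1L] <- loss_of(fw$S)
  for (ep in seq_len(spec$epochs)) {
    # dLoss/dD[i,c] = -(S - T)/n ; dD[i,c]/dY[i,] = (Y[i,]-P[c,])/D[i,c]
    dLdD <- -(fw$S - Tm) / n
    coef <- dLdD / pmax(fw$D, 1e-12)
    G <- rowSums(coef) * fw$Y - coef %*% fw$P
    W <- W - spec$step_size * crossprod(X, G)
    fw <- forward(W)
    history[ep + 1L] <- loss_of(fw$S)
    if (!is.finite(history[ep + 1L])) {
      stop("non-finite training loss at epoch ", ep,
           "; reduce step_size", call. = FALSE)
    }
  }
  structure(
    list(spec = spec, weights = W, final_loss = history[spec$epochs + 1L],
         loss_history = history),
    class = "fitted_embedder"
  )
}

#' @export
print.fitted_embedder <- function(x, ...) {
  if (x$spec$kind == "identity") {
    cat(sprintf("<fitted_embedder> identity, d=%d\n", x$spec$output_dim))
  } else {
    cat(sprintf(
      "<fitted_embedder> linear_proto %d -> %d, %d epochs, final loss %.6f\n",
      x$spec$input_dim, x$spec$output_dim, x$spec$epochs, x$final_loss
    ))
  }
  invisible(x)
}

#' Embed samples into the feature space
#'
#' @param fitted a [fit_embedder()] result.
#' @param x a [feature_matrix()] with dimension `spec$input_dim`.
#' @return A [feature_matrix()] with the same sample ids and labels and
#'   `spec$output_dim` feature columns.
#' @export
embed_features <- function(fitted, x) {
  stopifnot(inherits(fitted, "fitted_embedder"), inherits(x, "feature_matrix"))
  if (ncol(x$features) != fitted$spec$input_dim) {
    stop("dimension mismatch: samples have ", ncol(x$features),
         " features, embedder expects ", fitted$spec$input_dim,
         call. = FALSE)
  }
  if (fitted$spec$kind == "identity") return(x)
  feature_matrix(x$features %*% fitted$weights, x$sample_ids, x$labels)
}

#' Serialize a fitted embedder to JSON
#'
#' The file holds the spec and the weight matrix as nested arrays, so fitted
#' embedders are portable and diffable.
#'
#' @param fitted a [fit_embedder()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_embedder <- function(fitted, path) {
  stopifnot(inherits(fitted, "fitted_embedder"))
  obj <- list(
    spec = unclass(fitted$spec),
    weights = if (is.null(fitted$weights)) NULL else
      apply(fitted$weights, 1L, as.numeric, simplify = FALSE),
    final_loss = fitted$final_loss,
    loss_history = fitted$loss_history
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a fitted embedder from JSON
#'
#' @param path file written by [write_embedder()].
#' @return A `fitted_embedder`.
#' @export
read_embedder <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- do.call(embedder_spec, obj$spec)
  W <- if (is.null(obj$weights)) NULL else {
    if (is.matrix(obj$weights)) obj$weights
    else if (is.list(obj$weights)) do.call(rbind, obj$weights)
    else matrix(obj$weights, nrow = spec$input_dim, byrow = TRUE)
  }
  if (!is.null(W)) dimnames(W) <- NULL
  structure(
    list(spec = spec, weights = W,
         final_loss = if (is.null(obj$final_loss)) NA_real_ else obj$final_loss,
         loss_history = as.numeric(obj$loss_history)),
    class = "fitted_embedder"
  )
}
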
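#' Export 2-D coordinates for selection visualization
#'
#' Produces the coordinates behind the standard selection plot: base samples
#' as class-colored clusters with the selected pool samples overlaid. High
#' distance-entropy selections land in the central contested area among the
#' clusters; low distance-entropy selections overlap the existing base
#' points.
#'
#' Three reduction methods are available:
#' * `"native"` — features are already 2-D; coordinates are the raw features.
#' * `"pca"` — first two principal components ([stats::prcomp]) of base and
#'   selected points jointly; deterministic.
#' * `"tsne"` — t-distributed stochastic neighbor embedding, delegated to
#'   scikit-learn's seeded implementation through the `python` interpreter on
#'   the PATH; use for high-d features where local neighborhoods matter more
#'   than global axes.
#'
#' @param features a [feature_matrix()] holding the pool samples that were
#'   scored (the selected ids must be among them).
#' @param base the base [feature_matrix()] (labeled).
#' @param selected_ids character vector of selected pool sample ids (e.g.
#'   `sel$selected_ids` from [select_samples()]).
#' @param method `"native"`, `"pca"` or `"tsne"`.
#' @param seed integer seed for the stochastic `"tsne"` method.
#' @param perplexity t-SNE perplexity; clipped to be admissible for small n.
#' @return A data.frame with columns `sample_id`, `x`, `y`, `role` where
#'   role is `BASE:<class>` for base samples and `SELECTED` for selected
#'   ones.
#' @export
export_2d <- function(features, base, selected_ids,
                      method = c("native", "pca", "tsne"),
                      seed = 1L, perplexity = 30) {
  stopifnot(inherits(features, "feature_matrix"),
            inherits(base, "feature_matrix"))
  method <- match.arg(method)
  if (ncol(features$features) != ncol(base$features)) {
    stop("pool and base feature dimensions differ", call. = FALSE)
  }
  missing_ids <- setdiff(selected_ids, features$sample_ids)
  if (length(missing_ids) > 0L) {
    stop("selected id(s) not in `features`: ",
         paste(utils::head(missing_ids, 3L), collapse = ", "),
         call. = FALSE)
  }
  sel <- fm_subset(features, selected_ids)
  X <- rbind(base$features, sel$features)
  role <- c(paste0("BASE:", base$labels), rep("SELECTED", length(selected_ids)))
  ids <- c(base$sample_ids, sel$sample_ids)

  coords <- switch(method,
    native = {
      if (ncol(X) != 2L) {
        stop("native export requires 2-D features, got d=", ncol(X),
             call. = FALSE)
      }
      X
    },
    pca = {
      if (ncol(X) == 2L) X else
        stats::prcomp(X, center = TRUE, scale. = FALSE)$x[, 1:2, drop = FALSE]
    },
    tsne = tsne_python(X, seed, perplexity)
  )
  data.frame(sample_id = ids, x = coords[, 1L], y = coords[, 2L],
             role = role, stringsAsFactors = FALSE)
}

# Seeded t-SNE via scikit-learn; data goes out and comes back through
# temporary CSV files.
tsne_python <- function(X, seed, perplexity) {
  py <- Sys.which("python")
  if (!nzchar(py)) {
    stop("tsne export needs a `python` interpreter with scikit-learn on ",
         "the PATH; use method = \"pca\" instead", call. = FALSE)
  }
  perplexity <- min(perplexity, (nrow(X) - 1) / 3)
  if (perplexity < 1) {
    stop("too few points for t-SNE; use method = \"pca\"", call. = FALSE)
  }
  fin <- tempfile(fileext = ".csv")
  fout <- tempfile(fileext = ".csv")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  utils::write.table(X, fin, sep = ",", row.names = FALSE, col.names = FALSE)
  script <- sprintf(paste0(
    "import numpy as np; from sklearn.manifold import TSNE; ",
    "X = np.loadtxt(%s, delimiter=','); ",
    "Y = TSNE(n_components=2, random_state=%d, perplexity=%.6f, ",
    "init='pca').fit_transform(X); ",
    "np.savetxt(%s, Y, delimiter=',')"),
    deparse(fin), as.integer(seed), perplexity, deparse(fout))
  status <- system2(py, c("-c", shQuote(script)), stdout = TRUE,
                    stderr = TRUE)
  if (!file.exists(fout)) {
    stop("t-SNE subprocess failed:\n", paste(status, collapse = "\n"),
         call. = FALSE)
  }
  as.matrix(utils::read.table(fout, sep = ","))
}

#' Write 2-D export coordinates to CSV
#'
#' @param coords an [export_2d()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_export_2d <- function(coords, path) {
  utils::write.csv(coords, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
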
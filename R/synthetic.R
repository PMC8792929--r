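#' Configure the synthetic Gaussian-mixture benchmark
#'
#' The generator emulates the structure of a multi-class image-embedding
#' benchmark: `C` class clusters in `d` dimensions split into base
#' (labeled training), pool (selection candidates) and test sets, with a
#' configurable share of pool samples planted in the contested region
#' between class clusters. Class means sit equally spaced on a circle of
#' radius `r` in the first two coordinates (zero elsewhere), samples are
#' isotropic Gaussians around their mean, and boundary samples sit at the
#' midpoint of a random pair of class means with the same Gaussian spread,
#' labeled with one of the two flanking classes at random — genuinely
#' ambiguous, which is exactly what makes them informative.
#'
#' If `raw_dim` is set, every point is pushed through a fixed random linear
#' lift to `R^raw_dim` and isotropic observation noise of standard deviation
#' `lift_noise_sd` is added in the raw space, giving a trainable embedder a
#' realistic recovery problem (signal confined to a low-dimensional subspace,
#' noise in every raw coordinate).
#'
#' @param C number of classes (>= 2).
#' @param d latent feature dimension.
#' @param n_base,n_pool,n_test per-class sample counts for the three splits.
#' @param r radius of the circle of class means; `r / sigma` controls class
#'   separation (the default 3 gives moderately overlapping clusters).
#' @param sigma within-class standard deviation (isotropic).
#' @param boundary_fraction share of each class's pool slot planted as
#'   between-class boundary samples (`round(boundary_fraction * n_pool)` per
#'   class).
#' @param raw_dim optional pre-embedding dimension for the random linear
#'   lift; `NULL` keeps points in the latent `d`-dimensional space.
#' @param lift_noise_sd standard deviation of raw-space observation noise,
#'   used only when `raw_dim` is set.
#' @param seed integer seed; the same config and seed always produce the
#'   identical dataset.
#' @return A `mixture_config` list.
#' @export
mixture_config <- function(C = 6L, d = 2L, n_base = 50L, n_pool = 750L,
                           n_test = 200L, r = 3, sigma = 1,
                           boundary_fraction = 0.1, raw_dim = NULL,
                           lift_noise_sd = 1, seed = 1L) {
  C <- as.integer(C); d <- as.integer(d)
  n_base <- as.integer(n_base); n_pool <- as.integer(n_pool)
  n_test <- as.integer(n_test)
  if (C < 2L) stop("C must be >= 2", call. = FALSE)
  if (d < 1L) stop("d must be >= 1", call. = FALSE)
  if (n_base < 0L || n_pool < 0L || n_test < 0L) {
    stop("sample counts must be nonnegative", call. = FALSE)
  }
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (boundary_fraction < 0 || boundary_fraction > 1) {
    stop("boundary_fraction must be in [0, 1]", call. = FALSE)
  }
  if (!is.null(raw_dim)) {
    raw_dim <- as.integer(raw_dim)
    if (raw_dim < d) stop("raw_dim must be >= d", call. = FALSE)
  }
  structure(
    list(C = C, d = d, n_base = n_base, n_pool = n_pool, n_test = n_test,
         r = r, sigma = sigma, boundary_fraction = boundary_fraction,
         raw_dim = raw_dim, lift_noise_sd = lift_noise_sd,
         seed = as.integer(seed)),
    class = "mixture_config"
  )
}

class_names <- function(C) sprintf("class%02d", seq_len(C))

# class means: equally spaced on a radius-r circle in the first two
# coordinates, zero elsewhere (d = 1 uses the first coordinate only)
class_means <- function(C, d, r) {
  ang <- 2 * pi * (seq_len(C) - 1L) / C
  mu <- matrix(0, C, d)
  mu[, 1L] <- r * cos(ang)
  if (d >= 2L) mu[, 2L] <- r * sin(ang)
  mu
}

#' Generate a seeded synthetic dataset
#'
#' @param cfg a [mixture_config()].
#' @return A `synthetic_dataset`: list with `base`, `pool`, `test`
#'   ([feature_matrix()] objects), `pool_roles` (per-pool-sample `"CORE"` or
#'   `"BOUNDARY"` tag, aligned with pool rows) and `config`.
#' @examples
#' ds <- generate_mixture(mixture_config(d = 2, n_base = 5, n_pool = 10,
#'                                       n_test = 5, seed = 7))
#' table(ds$pool_roles)
#' @export
generate_mixture <- function(cfg) {
  stopifnot(inherits(cfg, "mixture_config"))
  if (cfg$boundary_fraction > 0 && cfg$C < 2L) {
    stop("boundary samples need at least 2 classes", call. = FALSE)
  }
  set.seed(cfg$seed)
  classes <- class_names(cfg$C)
  mu <- class_means(cfg$C, cfg$d, cfg$r)

  gauss <- function(n, center) {
    sweep(matrix(stats::rnorm(n * cfg$d, sd = cfg$sigma), n, cfg$d),
          2, center, "+")
  }
  draw_split <- function(n_per, prefix) {
    if (n_per == 0L) {
      return(list(X = matrix(0, 0, cfg$d), y = character(0), id = character(0)))
    }
    X <- do.call(rbind, lapply(seq_len(cfg$C), function(c) gauss(n_per, mu[c, ])))
    y <- rep(classes, each = n_per)
    id <- sprintf("%s_%s_%04d", prefix, rep(classes, each = n_per),
                  rep(seq_len(n_per), cfg$C))
    list(X = X, y = y, id = id)
  }

  base <- draw_split(cfg$n_base, "base")
  test <- draw_split(cfg$n_test, "test")

  n_bound <- as.integer(round(cfg$boundary_fraction * cfg$n_pool))
  n_core <- cfg$n_pool - n_bound
  pool_parts <- lapply(seq_len(cfg$C), function(c) {
    Xc <- if (n_core > 0L) gauss(n_core, mu[c, ]) else matrix(0, 0, cfg$d)
    if (n_bound > 0L) {
      others <- setdiff(seq_len(cfg$C), c) # sample from the set, not 1:n
      partner <- others[sample.int(length(others), n_bound, replace = TRUE)]
      mid <- (mu[rep(c, n_bound), , drop = FALSE] +
                mu[partner, , drop = FALSE]) / 2
      Xb <- mid + matrix(stats::rnorm(n_bound * cfg$d, sd = cfg$sigma),
                         n_bound, cfg$d)
      yb <- ifelse(stats::runif(n_bound) < 0.5, classes[c], classes[partner])
    } else {
      Xb <- matrix(0, 0, cfg$d)
      yb <- character(0)
    }
    list(X = rbind(Xc, Xb),
         y = c(rep(classes[c], n_core), yb),
         role = c(rep("CORE", n_core), rep("BOUNDARY", n_bound)),
         id = sprintf("pool_%s_%04d", classes[c], seq_len(cfg$n_pool)))
  })
  pool_X <- do.call(rbind, lapply(pool_parts, `[[`, "X"))
  pool_y <- unlist(lapply(pool_parts, `[[`, "y"))
  pool_role <- unlist(lapply(pool_parts, `[[`, "role"))
  pool_id <- unlist(lapply(pool_parts, `[[`, "id"))

  if (!is.null(cfg$raw_dim)) {
    L <- matrix(stats::rnorm(cfg$d * cfg$raw_dim, sd = 1 / sqrt(cfg$d)),
                cfg$d, cfg$raw_dim)
    lift <- function(X) {
      if (nrow(X) == 0L) return(matrix(0, 0, cfg$raw_dim))
      X %*% L + matrix(stats::rnorm(nrow(X) * cfg$raw_dim,
                                    sd = cfg$lift_noise_sd),
                       nrow(X), cfg$raw_dim)
    }
    base$X <- lift(base$X)
    pool_X <- lift(pool_X)
    test$X <- lift(test$X)
  }

  mk <- function(X, id, y) {
    if (nrow(X) == 0L) NULL else feature_matrix(X, id, y)
  }
  structure(
    list(base = mk(base$X, base$id, base$y),
         pool = mk(pool_X, pool_id, pool_y),
         test = mk(test$X, test$id, test$y),
         pool_roles = stats::setNames(pool_role, pool_id),
         config = cfg),
    class = "synthetic_dataset"
  )
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  nr <- function(fm) if (is.null(fm)) 0L else nrow(fm$features)
  cat(sprintf(
    "<synthetic_dataset> C=%d d=%d | base %d, pool %d (%d boundary), test %d\n",
    x$config$C, x$config$d, nr(x$base), nr(x$pool),
    sum(x$pool_roles == "BOUNDARY"), nr(x$test)
  ))
  invisible(x)
}

#' Write a synthetic dataset to a directory
#'
#' Emits `base.csv`, `pool.csv`, `test.csv` in the feature-table format,
#' `roles.csv` (sample_id, role) and `config.json`. The files round-trip
#' losslessly through [read_feature_table()] / [read_dataset()], and
#' `config.json` re-run through [generate_mixture()] reproduces the dataset
#' exactly.
#'
#' @param ds a [generate_mixture()] result.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_split <- function(fm, name) {
    path <- file.path(dir, name)
    if (is.null(fm)) {
      ncol_out <- if (is.null(ds$config$raw_dim)) ds$config$d else
        ds$config$raw_dim
      writeLines(paste(c("sample_id", "label",
                         paste0("f", seq_len(ncol_out))), collapse = ","),
                 path)
    } else {
      write_feature_table(fm, path)
    }
  }
  write_split(ds$base, "base.csv")
  write_split(ds$pool, "pool.csv")
  write_split(ds$test, "test.csv")
  utils::write.csv(
    data.frame(sample_id = names(ds$pool_roles), role = unname(ds$pool_roles),
               stringsAsFactors = FALSE),
    file.path(dir, "roles.csv"), row.names = FALSE, quote = FALSE
  )
  cfg <- ds$config
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a synthetic dataset back from a directory
#'
#' @param dir directory written by [write_dataset()].
#' @return A `synthetic_dataset` (splits with zero rows come back as `NULL`).
#' @export
read_dataset <- function(dir) {
  read_split <- function(name) {
    path <- file.path(dir, name)
    if (!file.exists(path)) {
      stop("missing file: ", path, call. = FALSE)
    }
    if (length(readLines(path)) <= 1L) return(NULL)
    read_feature_table(path)
  }
  cfg_raw <- jsonlite::read_json(file.path(dir, "config.json"),
                                 simplifyVector = TRUE)
  cfg <- do.call(mixture_config, cfg_raw)
  roles <- utils::read.csv(file.path(dir, "roles.csv"),
                           colClasses = "character")
  structure(
    list(base = read_split("base.csv"), pool = read_split("pool.csv"),
         test = read_split("test.csv"),
         pool_roles = stats::setNames(roles$role, roles$sample_id),
         config = cfg),
    class = "synthetic_dataset"
  )
}
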
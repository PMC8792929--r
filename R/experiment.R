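#' Nearest-prototype classification
#'
#' Assigns every sample the label of its nearest class prototype (the
#' decision rule induced by the softmax over negated distances: the nearest
#' prototype has the largest proportional share). Exact distance ties go to
#' the lexicographically smallest class label.
#'
#' @param x a [feature_matrix()].
#' @param protos a [compute_prototypes()] result with matching dimension.
#' @return Character vector of predicted class labels, one per sample.
#' @export
classify_nearest_prototype <- function(x, protos) {
  stopifnot(inherits(x, "feature_matrix"), inherits(protos, "prototype_set"))
  if (ncol(x$features) != ncol(protos$prototypes)) {
    stop("dimension mismatch: samples have ", ncol(x$features),
         " features, prototypes have ", ncol(protos$prototypes),
         call. = FALSE)
  }
  D <- pairwise_distances(x$features, protos$prototypes)
  # class_labels are sorted, so which.min's first-match rule implements the
  # lexicographic tie-break
  protos$class_labels[apply(D, 1L, which.min)]
}

#' Configure an acquisition-loop experiment
#'
#' One experiment runs, for each arm and each seed: fit the embedder on the
#' base data, score the pool by distance-entropy, move the `k` selected
#' samples (with their true labels) from pool to base, refit from scratch,
#' and record nearest-prototype test accuracy — for `rounds` rounds. Arms
#' differ only in how they select: `"HIGH"` takes the largest entropies,
#' `"LOW"` the smallest, and `"RANDOM"` (a baseline, off by default) draws
#' uniformly.
#'
#' @param dataset a [mixture_config()] describing the synthetic data (its
#'   `seed` field is overridden by each experiment seed), or a
#'   `synthetic_dataset` to reuse as-is for every seed.
#' @param embedder `"identity"`, or a list with `kind` and optional `epochs`,
#'   `step_size` for a `"linear_proto"` embedder; `output_dim` defaults to
#'   the dataset's latent `d`.
#' @param rounds number of acquisition rounds.
#' @param k samples added per round (global top-k unless
#'   `per_class_balanced`).
#' @param arms subset of `c("HIGH", "LOW", "RANDOM")`.
#' @param temperature softmax temperature for scoring.
#' @param seeds integer vector of replicate seeds.
#' @param per_class_balanced select `k` per class (using true pool labels)
#'   instead of a global top-k.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(dataset = mixture_config(),
                              embedder = "identity",
                              rounds = 5L, k = 10L,
                              arms = c("HIGH", "LOW"),
                              temperature = 1, seeds = 1:10,
                              per_class_balanced = FALSE) {
  rounds <- as.integer(rounds)
  k <- as.integer(k)
  if (rounds < 1L) stop("rounds must be >= 1", call. = FALSE)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  arms <- toupper(arms)
  bad <- setdiff(arms, c("HIGH", "LOW", "RANDOM"))
  if (length(bad) > 0L || length(arms) == 0L) {
    stop("arms must be a non-empty subset of HIGH, LOW, RANDOM",
         call. = FALSE)
  }
  if (is.character(embedder)) embedder <- list(kind = embedder)
  structure(
    list(dataset = dataset, embedder = embedder, rounds = rounds, k = k,
         arms = arms, temperature = temperature,
         seeds = as.integer(seeds),
         per_class_balanced = isTRUE(per_class_balanced)),
    class = "experiment_config"
  )
}

embedder_spec_for <- function(template, input_dim, latent_d, seed) {
  kind <- template$kind %||% "identity"
  out_dim <- template$output_dim %||%
    (if (kind == "identity") input_dim else latent_d)
  embedder_spec(
    kind = kind, input_dim = input_dim, output_dim = out_dim,
    epochs = template$epochs %||% 200L,
    step_size = template$step_size %||% 0.1,
    seed = seed
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Initial state of one acquisition run
#'
#' @param base,pool,test [feature_matrix()] splits; `pool` must be fully
#'   labeled (labels are revealed to the learner only when a sample is
#'   selected).
#' @param embedder embedder template, see [experiment_config()].
#' @param k samples to add per round.
#' @param temperature softmax temperature.
#' @param seed integer seed controlling embedder initialization and the
#'   RANDOM arm.
#' @param per_class_balanced per-class selection flag.
#' @return An `acquisition_state` holding the current splits and the
#'   accuracy/selection history. The round-0 fit and test accuracy are
#'   computed immediately.
#' @export
acquisition_state <- function(base, pool, test, embedder = "identity",
                              k = 10L, temperature = 1, seed = 1L,
                              per_class_balanced = FALSE) {
  stopifnot(inherits(base, "feature_matrix"),
            inherits(pool, "feature_matrix"),
            inherits(test, "feature_matrix"))
  if (is.character(embedder)) embedder <- list(kind = embedder)
  state <- structure(
    list(base = base, pool = pool, test = test, embedder = embedder,
         k = as.integer(k), temperature = temperature,
         seed = as.integer(seed),
         per_class_balanced = isTRUE(per_class_balanced),
         round = 0L, accuracy = numeric(0), selections = list(),
         warnings = character(0), fitted = NULL, protos = NULL),
    class = "acquisition_state"
  )
  refit_and_eval(state)
}

# fit embedder on current base, recompute prototypes, evaluate test accuracy
refit_and_eval <- function(state) {
  latent_d <- ncol(state$base$features)
  spec <- embedder_spec_for(state$embedder, ncol(state$base$features),
                            latent_d, state$seed)
  fitted <- fit_embedder(spec, state$base)
  eb <- embed_features(fitted, state$base)
  protos <- compute_prototypes(eb)
  pred <- classify_nearest_prototype(embed_features(fitted, state$test),
                                     protos)
  state$fitted <- fitted
  state$protos <- protos
  state$accuracy <- c(state$accuracy, mean(pred == state$test$labels))
  state
}

#' Run one acquisition round
#'
#' Scores the current pool against the current prototypes, selects `k`
#' samples by the arm's rule, moves them (with their true labels) from pool
#' to base, refits the embedder from scratch and re-evaluates test accuracy.
#'
#' @param state an [acquisition_state()].
#' @param arm `"HIGH"`, `"LOW"` or `"RANDOM"`.
#' @return The updated state; `state$selections` gains the round's ids and
#'   `state$accuracy` the post-round test accuracy. If the pool is empty the
#'   state is returned unchanged with a recorded warning.
#' @export
run_round <- function(state, arm = c("HIGH", "LOW", "RANDOM")) {
  stopifnot(inherits(state, "acquisition_state"))
  arm <- match.arg(toupper(arm), c("HIGH", "LOW", "RANDOM"))
  n_pool <- nrow(state$pool$features)
  if (n_pool == 0L) {
    msg <- sprintf("round %d: pool exhausted, stopping early",
                   state$round + 1L)
    warning(msg, call. = FALSE)
    state$warnings <- c(state$warnings, msg)
    return(state)
  }
  epool <- embed_features(state$fitted, state$pool)
  if (arm == "RANDOM") {
    k_eff <- min(state$k, n_pool)
    # per-round stream so rounds are independent and reproducible
    set.seed((state$seed * 1009L + state$round + 1L) %% .Machine$integer.max)
    ids <- sample(state$pool$sample_ids, k_eff)
  } else {
    scores <- score_pool(epool, state$protos, state$temperature)
    sel <- withCallingHandlers(
      select_samples(scores, state$k, tolower(arm),
                     per_class_balanced = state$per_class_balanced,
                     labels = if (state$per_class_balanced)
                       state$pool$labels else NULL),
      warning = function(w) {
        state$warnings <<- c(state$warnings, conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
    ids <- sel$selected_ids
  }
  idx <- match(ids, state$pool$sample_ids)
  keep <- setdiff(seq_len(n_pool), idx)
  state$base <- fm_bind(state$base, fm_subset(state$pool, idx))
  state$pool <- if (length(keep) == 0L) {
    # exhausted pool: zero-row shell, bypassing the n >= 1 constructor check
    structure(list(features = state$pool$features[0, , drop = FALSE],
                   sample_ids = character(0), labels = character(0)),
              class = "feature_matrix")
  } else {
    fm_subset(state$pool, keep)
  }
  state$round <- state$round + 1L
  state$selections[[state$round]] <- ids
  refit_and_eval(state)
}

#' Run the full acquisition experiment
#'
#' Loops over arms, seeds and rounds; within one seed every arm starts from
#' the identical dataset and round-0 fit, so round-0 accuracies agree across
#' arms and differences are attributable to selection alone.
#'
#' @param cfg an [experiment_config()].
#' @return An `experiment_result`: list with `accuracy` (data.frame: `arm`,
#'   `seed`, `round`, `n_added`, `accuracy`), `selections` (nested list
#'   `[[arm]][[seed]][[round]]`), and `config`.
#' @examples
#' cfg <- experiment_config(
#'   dataset = mixture_config(n_base = 10, n_pool = 30, n_test = 20),
#'   rounds = 2, k = 5, seeds = 1:2
#' )
#' res <- run_experiment(cfg)
#' results_table(res)
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  rows <- list()
  selections <- stats::setNames(vector("list", length(cfg$arms)), cfg$arms)
  for (arm in cfg$arms) selections[[arm]] <- list()
  for (seed in cfg$seeds) {
    ds <- if (inherits(cfg$dataset, "synthetic_dataset")) {
      cfg$dataset
    } else {
      dcfg <- cfg$dataset
      dcfg$seed <- seed
      generate_mixture(dcfg)
    }
    if (is.null(ds$base) || is.null(ds$pool) || is.null(ds$test)) {
      stop("experiment needs non-empty base, pool and test splits",
           call. = FALSE)
    }
    emb <- cfg$embedder
    if (is.null(emb$output_dim) && (emb$kind %||% "identity") != "identity") {
      emb$output_dim <- ds$config$d # project back to the latent dimension
    }
    for (arm in cfg$arms) {
      state <- acquisition_state(
        ds$base, ds$pool, ds$test, embedder = emb, k = cfg$k,
        temperature = cfg$temperature, seed = seed,
        per_class_balanced = cfg$per_class_balanced
      )
      for (r in seq_len(cfg$rounds)) state <- run_round(state, arm)
      rows[[length(rows) + 1L]] <- data.frame(
        arm = arm, seed = seed, round = 0:state$round,
        n_added = cfg$k * (0:state$round),
        accuracy = state$accuracy, stringsAsFactors = FALSE
      )
      selections[[arm]][[as.character(seed)]] <- state$selections
    }
  }
  structure(
    list(accuracy = do.call(rbind, rows), selections = selections,
         config = cfg),
    class = "experiment_result"
  )
}

#' Accuracy table in acquisition-round layout
#'
#' Summarizes an experiment as mean test accuracy over seeds, one row per
#' round (`Base data`, `Add k`, `Add 2k`, ...), one column per arm.
#'
#' @param res a [run_experiment()] result.
#' @return A data.frame with a `round` label column and one numeric column
#'   per arm.
#' @export
results_table <- function(res) {
  stopifnot(inherits(res, "experiment_result"))
  acc <- res$accuracy
  k <- res$config$k
  rounds <- sort(unique(acc$round))
  lab <- ifelse(rounds == 0L, "Base data", paste("Add", rounds * k))
  out <- data.frame(round = lab, stringsAsFactors = FALSE)
  for (arm in res$config$arms) {
    out[[arm]] <- vapply(rounds, function(r) {
      mean(acc$accuracy[acc$arm == arm & acc$round == r])
    }, numeric(1))
  }
  out
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> arms=%s seeds=%d rounds=%d\n",
              paste(x$config$arms, collapse = ","),
              length(x$config$seeds), x$config$rounds))
  print(results_table(x))
  invisible(x)
}

#' Write experiment results to a directory
#'
#' Emits `results.csv` (per arm/seed/round accuracies), `summary.csv` (the
#' [results_table()] layout) and `selections.json`.
#'
#' @param res a [run_experiment()] result.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(res, dir) {
  stopifnot(inherits(res, "experiment_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(res$accuracy, file.path(dir, "results.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(results_table(res), file.path(dir, "summary.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(res$selections, file.path(dir, "selections.json"),
                       auto_unbox = FALSE, digits = NA)
  invisible(dir)
}
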
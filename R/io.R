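#' Read a feature table from delimited text
#'
#' The format is comma-separated UTF-8 with header
#' `sample_id,label,f1,...,fd`; the label column may contain the sentinel
#' `UNLABELED`; decimal point `.`; no thousands separators. Malformed input
#' (duplicate ids, ragged rows, non-numeric features) is rejected with the
#' offending line number.
#'
#' @param path path to the CSV file.
#' @return A [feature_matrix()].
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  # header comment lines (e.g. score tables) start with '#'
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) < 2L) {
    stop(path, ": no data rows", call. = FALSE)
  }
  header <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]]
  if (length(header) < 3L || header[1L] != "sample_id" ||
      header[2L] != "label") {
    stop(path, ": header must be sample_id,label,f1,...,fd", call. = FALSE)
  }
  d <- length(header) - 2L
  rows <- strsplit(lines[-1L], ",", fixed = TRUE)
  n <- length(rows)
  lens <- lengths(rows)
  if (any(lens != length(header))) {
    bad <- which(lens != length(header))[1L]
    stop(path, ": line ", bad + 1L, " has ", lens[bad],
         " fields, expected ", length(header), call. = FALSE)
  }
  mat <- matrix(unlist(rows, use.names = FALSE), nrow = n, byrow = TRUE)
  ids <- mat[, 1L]
  if (anyDuplicated(ids)) {
    bad <- which(duplicated(ids))[1L]
    stop(path, ": line ", bad + 1L, " duplicates sample_id '", ids[bad], "'",
         call. = FALSE)
  }
  feats <- suppressWarnings(
    matrix(as.numeric(mat[, -(1:2), drop = FALSE]), nrow = n)
  )
  if (anyNA(feats)) {
    bad <- which(rowSums(is.na(feats)) > 0)[1L]
    stop(path, ": line ", bad + 1L, " has a non-numeric feature value",
         call. = FALSE)
  }
  feature_matrix(feats, ids, mat[, 2L])
}

#' Write a feature table to delimited text
#'
#' Numbers are written with 17 significant digits so that a write/read
#' round-trip reproduces the matrix to full double precision.
#'
#' @param fm a [feature_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  d <- ncol(fm$features)
  header <- paste(c("sample_id", "label", paste0("f", seq_len(d))),
                  collapse = ",")
  nums <- matrix(sprintf("%.17g", fm$features), nrow = nrow(fm$features))
  body <- apply(cbind(fm$sample_ids, fm$labels, nums), 1L, paste,
                collapse = ",")
  writeLines(c(header, body), path, useBytes = TRUE)
  invisible(path)
}

#' Write a score table to CSV
#'
#' Emits `sample_id,entropy,d_<class>...,p_<class>...` preceded by a comment
#' line recording the class order and the softmax temperature used.
#'
#' @param scores a [score_pool()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(scores, path) {
  stopifnot(inherits(scores, "score_table"))
  comment <- sprintf("# class_order=%s temperature=%.17g",
                     paste(attr(scores, "class_order"), collapse = ";"),
                     attr(scores, "temperature"))
  df <- as.data.frame(scores)
  num_cols <- names(df) != "sample_id"
  df[num_cols] <- lapply(df[num_cols], function(x) sprintf("%.17g", x))
  body <- do.call(paste, c(unname(df), sep = ","))
  writeLines(c(comment, paste(names(df), collapse = ","), body), path,
             useBytes = TRUE)
  invisible(path)
}

#' Read a score table written by [write_score_table()]
#'
#' @param path input path.
#' @return A `score_table` data.frame with `class_order` and `temperature`
#'   attributes restored.
#' @export
read_score_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  m <- regmatches(first,
                  regexec("^# class_order=([^ ]+) temperature=([0-9eE.+-]+)",
                          first))[[1L]]
  if (length(m) != 3L) {
    stop(path, ": missing '# class_order=... temperature=...' comment line",
         call. = FALSE)
  }
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        colClasses = c(sample_id = "character"))
  attr(df, "class_order") <- strsplit(m[2L], ";", fixed = TRUE)[[1L]]
  attr(df, "temperature") <- as.numeric(m[3L])
  class(df) <- c("score_table", "data.frame")
  df
}

#' Write a selection result
#'
#' Writes one sample id per line to `path` plus a JSON sidecar
#' `<path>.json` with the selection metadata.
#'
#' @param sel a [select_samples()] result.
#' @param path output path for the id list.
#' @param temperature,class_order,seed optional metadata recorded in the
#'   sidecar.
#' @return `path`, invisibly.
#' @export
write_selection <- function(sel, path, temperature = NULL,
                            class_order = NULL, seed = NULL) {
  stopifnot(inherits(sel, "selection_result"))
  writeLines(sel$selected_ids, path, useBytes = TRUE)
  meta <- list(mode = sel$mode, k = sel$k,
               per_class_balanced = sel$per_class_balanced,
               temperature = temperature, class_order = class_order,
               seed = seed)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Validate a run-configuration list against allowed keys
#'
#' Rejects unknown keys by name and checks the presence of required keys,
#' before any computation runs.
#'
#' @param config a named list (e.g. parsed from JSON).
#' @param allowed character vector of permitted key names.
#' @param required character vector of keys that must be present.
#' @return `config`, invisibly, if valid.
#' @export
validate_config_keys <- function(config, allowed, required = character(0)) {
  if (!is.list(config)) stop("config must be a list", call. = FALSE)
  keys <- names(config)
  unknown <- setdiff(keys, allowed)
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(required, keys)
  if (length(missing) > 0L) {
    stop("missing required config key(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(config)
}

#' Write a reproducibility manifest
#'
#' Records input checksums, seeds, the package version and the R version so
#' a run can be reproduced exactly.
#'
#' @param path output JSON path.
#' @param inputs character vector of input file paths (checksummed with MD5).
#' @param seed integer seed used for the run.
#' @param extra optional named list of extra fields (parsed config, etc.).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, inputs = character(0), seed = NULL,
                           extra = list()) {
  existing <- inputs[file.exists(inputs)]
  manifest <- c(list(
    package = "distentropy",
    package_version = as.character(utils::packageVersion("distentropy")),
    r_version = as.character(getRversion()),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    input_md5 = as.list(tools::md5sum(existing))
  ), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
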
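#' Model and session I/O
#'
#' Models are stored as a single versioned RDS container (all numeric state
#' round-trips bit-exactly). Sessions (feature blocks + targets) are stored
#' as a directory holding two CSV matrices and a JSON metadata file, so that
#' toy datasets stay human-readable and diffable.
#'
#' @name io
NULL

MODEL_FORMAT <- "prewnpls-model"
MODEL_FORMAT_VERSION <- 1L
SESSION_FORMAT_VERSION <- 1L

#' Save a decoder to disk
#'
#' @param model `rewnpls` object.
#' @param path output file path (conventionally `.rds`).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "rewnpls"))
  saveRDS(list(format = MODEL_FORMAT, version = MODEL_FORMAT_VERSION,
               model = model), path)
  invisible(path)
}

#' Load a decoder saved by [save_model()]
#'
#' @param path file path.
#' @return the `rewnpls` object.
#' @export
load_model <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("cannot read model file '", path, "': ", conditionMessage(e)))
  if (!is.list(obj) || !identical(obj$format, MODEL_FORMAT))
    stop("'", path, "' is not a prewnpls model file")
  if (!identical(obj$version, MODEL_FORMAT_VERSION))
    stop("model format version ", obj$version,
         " not supported (expected ", MODEL_FORMAT_VERSION, ")")
  obj$model
}

#' Write a session (blocks of features and targets) to a directory
#'
#' Creates `path/` containing `features.csv` (samples x D, native
#' mode-1-fastest feature order), `targets.csv` (samples x J) and
#' `meta.json` (dims, block size, seed and free-form attributes).
#'
#' @param blocks list of [observation_block()] (or a `session` object from
#'   [simulate_session()], whose metadata is carried over).
#' @param path output directory (created if needed).
#' @param attrs named list of extra metadata to store.
#' @return `path`, invisibly.
#' @export
write_session <- function(blocks, path, attrs = list()) {
  if (inherits(blocks, "session")) {
    attrs <- utils::modifyList(list(seed = blocks$spec$seed), attrs)
    blocks <- blocks$blocks
  }
  if (!length(blocks)) stop("no blocks to write")
  stopifnot(all(vapply(blocks, inherits, logical(1), "observation_block")))
  dims <- blocks[[1]]$dims
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  X <- do.call(rbind, lapply(blocks, function(b) b$X))
  Y <- do.call(rbind, lapply(blocks, function(b) b$Y))
  data.table::fwrite(data.table::as.data.table(X),
                     file.path(path, "features.csv"))
  data.table::fwrite(data.table::as.data.table(Y),
                     file.path(path, "targets.csv"))
  meta <- c(list(version = SESSION_FORMAT_VERSION, dims = dims,
                 J = ncol(Y), block_sizes = vapply(blocks, `[[`, 1L, "n"),
                 mode_names = c("time_lag", "frequency", "channel")),
            attrs)
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a session directory written by [write_session()]
#'
#' @param path session directory.
#' @return list with `blocks` (list of [observation_block()]) and `meta`.
#' @export
read_session <- function(path) {
  mf <- file.path(path, "meta.json")
  if (!file.exists(mf)) stop("'", path, "' has no meta.json: not a session")
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (is.null(meta$dims) || is.null(meta$block_sizes))
    stop("session metadata is missing dims/block_sizes")
  X <- as.matrix(data.table::fread(file.path(path, "features.csv")))
  Y <- as.matrix(data.table::fread(file.path(path, "targets.csv")))
  dims <- as.integer(meta$dims)
  if (ncol(X) != prod(dims))
    stop("features.csv width does not match the declared dims")
  if (nrow(X) != sum(meta$block_sizes))
    stop("sample count does not match the declared block sizes")
  ends <- cumsum(meta$block_sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  blocks <- mapply(function(s, e)
    observation_block(X[s:e, , drop = FALSE], Y[s:e, , drop = FALSE],
                      dims = dims),
    starts, ends, SIMPLIFY = FALSE)
  list(blocks = blocks, meta = meta)
}

#' Write a lambda-sweep table as CSV
#'
#' @param sweep `lambda_sweep` object (or its `table`).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_sweep_table <- function(sweep, path) {
  tab <- if (inherits(sweep, "lambda_sweep")) sweep$table else sweep
  data.table::fwrite(tab, path)
  invisible(path)
}
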
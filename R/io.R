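#' @title Stack and table I/O
#' @name io
#' @description Multi-page 16-bit TIFF stacks with JSON metadata sidecars,
#'   and deterministic CSV tables.
NULL

#' Write a synthetic stack to a multi-page 16-bit TIFF
#'
#' A JSON sidecar `<path>.json` holding the configuration snapshot and seed
#' is written alongside.
#'
#' @param stack A `synthetic_stack` (list with `frames` array, `config`,
#'   `seed`).
#' @param path Output TIFF path.
#' @return The path, invisibly.
#' @export
write_stack <- function(stack, path) {
  frames <- stack$frames
  stopifnot(length(dim(frames)) == 3)
  pages <- lapply(seq_len(dim(frames)[3]),
                  function(f) frames[, , f] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  meta <- list(seed = stack$seed)
  if (!is.null(stack$config)) meta$config <- config_to_list(stack$config)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an image stack from a multi-page TIFF
#'
#' Reads 8/16-bit grayscale pages into an integer count array. Camera and
#' simulation metadata are restored from the sidecar `<path>.json` when
#' present; otherwise the stack's `config` is `NULL` and analyses requiring
#' photon conversion must be given camera parameters explicitly.
#'
#' @param path TIFF path.
#' @return A `synthetic_stack` (frames array of dim height x width x
#'   n_frames, `config` or NULL, `seed` or NA).
#' @export
read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) != 2, TRUE)))
    stop("non-grayscale TIFF page", call. = FALSE)
  d <- dim(pages[[1]])
  if (any(vapply(pages, function(p) any(dim(p) != d), TRUE)))
    stop("truncated or inconsistent TIFF pages", call. = FALSE)
  frames <- array(0L, dim = c(d[1], d[2], length(pages)))
  for (f in seq_along(pages)) frames[, , f] <- as.integer(pages[[f]])
  config <- NULL; seed <- NA_integer_
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$config)) config <- config_from_list(meta$config)
    if (!is.null(meta$seed)) seed <- meta$seed
  }
  structure(list(frames = frames, config = config, seed = seed),
            class = "synthetic_stack")
}

#' Write analysis tables to CSV with deterministic ordering
#'
#' @param tables Named list of data frames; each is written to
#'   `<prefix>_<name>.csv` with rows ordered by `frame` then `id`/`track_id`
#'   where those columns exist.
#' @param prefix Path prefix.
#' @return Character vector of written paths, invisibly.
#' @export
write_tables <- function(tables, prefix) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  paths <- character(0)
  for (nm in names(tables)) {
    tb <- tables[[nm]]
    if (!is.data.frame(tb))
      stop(sprintf("table '%s' is not a data frame", nm), call. = FALSE)
    ordcols <- intersect(c("frame", "id", "track_id"), names(tb))
    if (length(ordcols))
      tb <- tb[do.call(order, tb[ordcols]), , drop = FALSE]
    p <- paste0(prefix, "_", nm, ".csv")
    utils::write.csv(tb, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
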
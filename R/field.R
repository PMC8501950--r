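#' A multi-channel field of view
#'
#' A set of named single-channel images sharing one pixel grid; the unit of
#' acquisition. Must contain a "DAPI" channel.
#'
#' @param channels named list of numeric matrices, all of identical shape.
#' @param field_id identifier string.
#' @return a `field_of_view` object.
#' @export
field_of_view <- function(channels, field_id = "field_1") {
  if (!is.list(channels) || is.null(names(channels)) ||
      any(names(channels) == ""))
    stop("`channels` must be a named list of matrices", call. = FALSE)
  if (!all(vapply(channels, is.matrix, logical(1))))
    stop("every channel must be a matrix", call. = FALSE)
  dims <- vapply(channels, dim, integer(2))
  if (ncol(dims) > 1 && any(dims[, -1, drop = FALSE] != dims[, 1]))
    stop("all channels must share one shape", call. = FALSE)
  if (!"DAPI" %in% names(channels))
    stop("field must contain a DAPI channel", call. = FALSE)
  if (any(vapply(channels, function(m) any(m < 0, na.rm = TRUE), logical(1))))
    stop("channel intensities must be non-negative", call. = FALSE)
  structure(list(channels = channels, field_id = field_id),
            class = "field_of_view")
}

#' Read a field of view from per-channel TIFF files
#'
#' @param paths named character vector, channel name -> TIFF path.
#' @param field_id identifier string.
#' @return a `field_of_view`.
#' @export
read_field <- function(paths, field_id = "field_1") {
  if (is.null(names(paths))) stop("`paths` must be named by channel",
                                  call. = FALSE)
  field_of_view(lapply(as.list(paths), read_tiff16), field_id = field_id)
}

#' An integer-labelled nuclei mask
#'
#' Background is 0; object labels are 1..n_objects with no gaps (unless
#' `relabel = FALSE`, used for ground-truth id masks).
#'
#' @param labels integer matrix of labels.
#' @param relabel renumber labels to 1..n in ascending order of the
#'   original labels.
#' @return a `label_mask` with fields `labels` and `n_objects`.
#' @export
label_mask <- function(labels, relabel = TRUE) {
  if (!is.matrix(labels)) stop("`labels` must be a matrix", call. = FALSE)
  storage.mode(labels) <- "integer"
  if (any(labels < 0, na.rm = TRUE))
    stop("labels must be non-negative", call. = FALSE)
  ids <- sort(unique(labels[labels > 0]))
  if (relabel && length(ids) > 0 &&
      !identical(as.integer(ids), seq_along(ids))) {
    remap <- integer(max(ids))
    remap[ids] <- seq_along(ids)
    pos <- labels > 0
    labels[pos] <- remap[labels[pos]]
    ids <- seq_along(ids)
  }
  structure(list(labels = labels, n_objects = length(ids)),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label_mask> %d x %d, %d object(s)\n",
              nrow(x$labels), ncol(x$labels), x$n_objects))
  invisible(x)
}

#' @export
print.field_of_view <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<field_of_view> '%s': %d x %d, channels: %s\n",
              x$field_id, d[1], d[2],
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}
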
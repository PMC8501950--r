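#' Measure per-nucleus features under a label mask
#'
#' The labelled nuclei are used as a mask across all channels of the field:
#' per object, pixel area, 0-based centroid, integrated ("total") DAPI and
#' the arithmetic mean of every channel are recorded, in raw arbitrary
#' units with no background subtraction.
#'
#' @param mask a `label_mask`.
#' @param field a `field_of_view` of identical shape.
#' @param condition condition label stored per row.
#' @return a `cell_table`: data.frame with columns `field_id`, `label`,
#'   `area`, `centroid_row`, `centroid_col`, `total_dapi`,
#'   `mean_<channel>` for every channel, `border_touching`, `condition`.
#' @export
measure_nuclei <- function(mask, field, condition = "untreated") {
  stopifnot(inherits(mask, "label_mask"), inherits(field, "field_of_view"))
  lab <- mask$labels
  shp <- dim(lab)
  for (ch in names(field$channels))
    if (!identical(dim(field$channels[[ch]]), shp))
      stop("shape mismatch between mask and channel ", ch, call. = FALSE)
  n <- mask$n_objects
  channels <- names(field$channels)
  if (n == 0) {
    out <- data.frame(field_id = character(), label = integer(),
                      area = integer(), centroid_row = numeric(),
                      centroid_col = numeric(), total_dapi = numeric())
    for (ch in channels) out[[paste0("mean_", ch)]] <- numeric()
    out$border_touching <- logical()
    out$condition <- character()
    return(as_cell_table(out, channels))
  }
  pos <- lab > 0
  l <- lab[pos]
  area <- tabulate(l, nbins = n)
  ridx <- row(lab)[pos]; cidx <- col(lab)[pos]
  centroid_row <- rowsum_by(ridx - 1, l, n) / area
  centroid_col <- rowsum_by(cidx - 1, l, n) / area
  sums <- lapply(field$channels, function(m) rowsum_by(m[pos], l, n))
  border_ids <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1],
                         lab[, ncol(lab)]))
  out <- data.frame(field_id = field$field_id, label = seq_len(n),
                    area = area, centroid_row = centroid_row,
                    centroid_col = centroid_col,
                    total_dapi = sums[["DAPI"]])
  for (ch in channels) out[[paste0("mean_", ch)]] <- sums[[ch]] / area
  out$border_touching <- seq_len(n) %in% border_ids
  out$condition <- condition
  as_cell_table(out, channels)
}

# grouped sums with a guaranteed slot for every label 1..n
rowsum_by <- function(values, groups, n) {
  s <- rowsum(values, groups)
  out <- numeric(n)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

as_cell_table <- function(df, channels) {
  attr(df, "channels") <- channels
  class(df) <- c("cell_table", "data.frame")
  df
}

#' Channel names of a cell table
#' @param table a `cell_table`.
#' @return character vector of channel names.
#' @export
cell_table_channels <- function(table) {
  ch <- attr(table, "channels")
  if (is.null(ch))
    ch <- sub("^mean_", "", grep("^mean_", names(table), value = TRUE))
  ch
}

#' Concatenate cell tables across conditions
#'
#' @param tables list of `cell_table`s with identical channel sets.
#' @return one `cell_table`; row count is the sum of the inputs.
#' @export
merge_tables <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 1)
  chans <- lapply(tables, cell_table_channels)
  if (!all(vapply(chans, function(x) identical(x, chans[[1]]), logical(1))))
    stop("cell tables have conflicting channel sets", call. = FALSE)
  out <- do.call(rbind, lapply(tables, as.data.frame))
  rownames(out) <- NULL
  as_cell_table(out, chans[[1]])
}

#' Write a cell table as CSV in the canonical column order
#'
#' @param table a `cell_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(table, path) {
  channels <- cell_table_channels(table)
  cols <- c("field_id", "label", "area", "centroid_row", "centroid_col",
            "total_dapi", paste0("mean_", channels), "border_touching",
            "condition")
  write.csv(as.data.frame(table)[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Read a cell table CSV written by [write_cell_table()]
#' @param path CSV path.
#' @return a `cell_table`.
#' @export
read_cell_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  as_cell_table(df, sub("^mean_", "", grep("^mean_", names(df),
                                           value = TRUE)))
}
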
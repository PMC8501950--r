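#' Specification of the DNA-content scatter plot
#'
#' The classic QIBC panel: per-cell integrated DAPI (x, log) against a
#' replication marker mean (y, log), coloured by a third feature whose
#' colour scale is clipped at configurable quantiles.
#'
#' @param x,y,color feature column names.
#' @param color_scale (lo, hi) quantiles for colour clipping.
#' @param point_size point size in pt.
#' @param log_x,log_y log10 axes (intensity features default to log).
#' @return a `scatter_spec`.
#' @export
scatter_spec <- function(x = "total_dapi", y = "mean_PCNA",
                         color = "mean_gH2AX",
                         color_scale = c(0.05, 0.95),
                         point_size = 0.6,
                         log_x = TRUE, log_y = TRUE) {
  stopifnot(length(color_scale) == 2, color_scale[1] >= 0,
            color_scale[1] < color_scale[2], color_scale[2] <= 1)
  structure(list(x = x, y = y, color = color, color_scale = color_scale,
                 point_size = point_size, log_x = log_x, log_y = log_y),
            class = "scatter_spec")
}

#' Specification of the jittered dot-bar plot
#'
#' One jittered column of per-cell values per condition, with a bar at the
#' population mean.
#'
#' @param value feature column name.
#' @param group grouping column (default "condition").
#' @param jitter_width half-width of the uniform jitter as a fraction of
#'   the group slot, in (0, 0.5].
#' @param jitter_seed seed of the jitter draw.
#' @param bar_color colour of the mean bar.
#' @return a `dot_bar_spec`.
#' @export
dot_bar_spec <- function(value = "mean_EdU", group = "condition",
                         jitter_width = 0.35, jitter_seed = 1L,
                         bar_color = "red") {
  stop_if_not_number(jitter_width, "jitter_width", lower = 1e-12,
                     upper = 0.5)
  structure(list(value = value, group = group,
                 jitter_width = jitter_width,
                 jitter_seed = as.integer(jitter_seed),
                 bar_color = bar_color),
            class = "dot_bar_spec")
}

sidecar_path <- function(out_path) {
  paste0(tools::file_path_sans_ext(out_path), "_data.csv")
}

# open a figure device if one is available; never fail the data path
open_device <- function(out_path, width = 5, height = 5) {
  opened <- tryCatch({
    if (grepl("\\.pdf$", out_path)) grDevices::pdf(out_path, width, height)
    else grDevices::png(out_path, width = width * 150, height = height * 150,
                        res = 150)
    TRUE
  }, error = function(e) FALSE)
  if (!opened)
    opened <- tryCatch({
      grDevices::pdf(sub("\\.[a-zA-Z]+$", ".pdf", out_path), width, height)
      TRUE
    }, error = function(e) FALSE)
  opened
}

#' QIBC scatter: DNA content vs marker, coloured by a third feature
#'
#' Writes the figure and, next to it, a machine-readable sidecar CSV with
#' one row per plotted cell (x, y, raw colour value, clipped colour value)
#' so the plotted data can be asserted without rendering.
#'
#' @param table a `cell_table`.
#' @param spec a [scatter_spec()].
#' @param out_path figure path (.png or .pdf).
#' @return invisibly, a list with `figure`, `sidecar`, `data` (the sidecar
#'   data.frame) and `clip` (colour clip bounds).
#' @export
qibc_scatter <- function(table, spec = scatter_spec(), out_path) {
  if (nrow(table) == 0) stop("cell table is empty", call. = FALSE)
  for (f in c(spec$x, spec$y, spec$color))
    if (!f %in% names(table))
      stop("feature absent from table: ", f, call. = FALSE)
  x <- table[[spec$x]]; y <- table[[spec$y]]; col_raw <- table[[spec$color]]
  clip <- as.numeric(quantile(col_raw, spec$color_scale))
  col_clip <- pmin(pmax(col_raw, clip[1]), clip[2])
  data <- data.frame(x = x, y = y, color = col_raw,
                     color_clipped = col_clip)
  write.csv(data, sidecar_path(out_path), row.names = FALSE)
  drawn <- open_device(out_path)
  if (drawn) {
    pal <- grDevices::hcl.colors(256, "viridis")
    idx <- if (clip[2] > clip[1])
      1L + as.integer(round(255 * (col_clip - clip[1]) / (clip[2] - clip[1])))
    else rep(1L, length(col_clip))
    log_axes <- paste0(if (spec$log_x) "x" else "",
                       if (spec$log_y) "y" else "")
    graphics::plot(x, y, log = log_axes, pch = 16,
                   cex = spec$point_size, col = pal[idx],
                   xlab = spec$x, ylab = spec$y,
                   main = sprintf("coloured by %s", spec$color))
    grDevices::dev.off()
  }
  invisible(list(figure = if (drawn) out_path else NA_character_,
                 sidecar = sidecar_path(out_path), data = data,
                 clip = clip))
}

#' Jittered dot-bar plot with population-mean bars
#'
#' Per-cell values jittered uniformly in `+/- jitter_width` around each
#' group slot, with a bar at the arithmetic group mean. Empty groups are
#' skipped with a warning. A sidecar CSV records group, value and jittered
#' x per point plus the per-group bar values.
#'
#' @param table a merged `cell_table` with a grouping column.
#' @param spec a [dot_bar_spec()].
#' @param out_path figure path (.png or .pdf).
#' @return invisibly, a list with `figure`, `sidecar`, `data` (points) and
#'   `bars` (group means).
#' @export
dot_bar <- function(table, spec = dot_bar_spec(), out_path) {
  for (f in c(spec$value, spec$group))
    if (!f %in% names(table))
      stop("feature absent from table: ", f, call. = FALSE)
  groups <- unique(as.character(table[[spec$group]]))
  present <- vapply(groups, function(g)
    sum(table[[spec$group]] == g) > 0, logical(1))
  if (any(!present)) {
    warning("skipping empty group(s): ",
            paste(groups[!present], collapse = ", "))
    groups <- groups[present]
  }
  if (length(groups) == 0) stop("no non-empty groups", call. = FALSE)
  gidx <- match(as.character(table[[spec$group]]), groups)
  keep <- !is.na(gidx)
  y <- table[[spec$value]][keep]
  gidx <- gidx[keep]
  jitter <- with_seed(spec$jitter_seed,
                      runif(length(y), -spec$jitter_width,
                            spec$jitter_width))
  xj <- gidx + jitter
  bars <- data.frame(group = groups,
                     bar = vapply(seq_along(groups), function(i)
                       mean(y[gidx == i]), numeric(1)))
  data <- data.frame(group = groups[gidx], value = y, x = xj)
  write.csv(data, sidecar_path(out_path), row.names = FALSE)
  write.csv(bars, sub("_data\\.csv$", "_bars.csv",
                      sidecar_path(out_path)), row.names = FALSE)
  drawn <- open_device(out_path, width = 1 + 1.2 * length(groups))
  if (drawn) {
    graphics::plot(xj, y, pch = 16, cex = 0.4, col = "grey30",
                   xaxt = "n", xlab = "", ylab = spec$value,
                   xlim = c(0.5, length(groups) + 0.5))
    graphics::axis(1, at = seq_along(groups), labels = groups, las = 2,
                   cex.axis = 0.8)
    graphics::segments(seq_along(groups) - 0.4, bars$bar,
                       seq_along(groups) + 0.4, bars$bar,
                       col = spec$bar_color, lwd = 3)
    grDevices::dev.off()
  }
  invisible(list(figure = if (drawn) out_path else NA_character_,
                 sidecar = sidecar_path(out_path), data = data,
                 bars = bars))
}
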
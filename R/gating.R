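#' Gating parameters
#'
#' The interphase gate keeps nuclei whose integrated DAPI lies within
#' multiples of the G1 (2C) peak; the theoretical 2C-4C window is
#' \[1, 2\] x peak, widened by default to \[0.75, 2.5\] to admit
#' measurement spread. S-phase is called on a replication marker channel
#' either at a fixed threshold or at a quantile of a negative-control
#' population.
#'
#' @param g1_window_lo,g1_window_hi window bounds as multiples of the G1
#'   peak.
#' @param histogram_bins bins of the log-total-DAPI histogram used for
#'   peak finding.
#' @param sphase_marker channel used to call S-phase ("EdU" or "PCNA").
#' @param sphase_threshold fixed marker threshold (A.U.); `NULL` to use the
#'   control-quantile rule.
#' @param sphase_quantile quantile of the negative-control marker
#'   distribution used when `sphase_threshold` is `NULL`.
#' @param subsample_seed seed for equal-depth subsampling.
#' @return a `gating_params` object.
#' @export
gating_params <- function(g1_window_lo = 0.75,
                          g1_window_hi = 2.5,
                          histogram_bins = 100L,
                          sphase_marker = "EdU",
                          sphase_threshold = NULL,
                          sphase_quantile = 0.95,
                          subsample_seed = 1L) {
  stop_if_not_number(g1_window_lo, "g1_window_lo", lower = 1e-12)
  stop_if_not_number(g1_window_hi, "g1_window_hi", lower = 1e-12)
  if (g1_window_lo >= g1_window_hi)
    stop("g1_window_lo must be below g1_window_hi", call. = FALSE)
  stop_if_not_number(histogram_bins, "histogram_bins", lower = 10)
  stop_if_not_number(sphase_quantile, "sphase_quantile", 0, 1)
  structure(list(g1_window_lo = g1_window_lo, g1_window_hi = g1_window_hi,
                 histogram_bins = as.integer(histogram_bins),
                 sphase_marker = sphase_marker,
                 sphase_threshold = sphase_threshold,
                 sphase_quantile = sphase_quantile,
                 subsample_seed = as.integer(subsample_seed)),
            class = "gating_params")
}

#' Estimate the G1 (2C) peak of the total-DAPI distribution
#'
#' Histogram mode on log totals: the leftmost dominant mode. Concretely,
#' the global argmax bin is compared with the highest-count bin strictly
#' below the bin holding the global median, and the lower (leftmost) of
#' the two is returned (back-transformed bin centre). This protects the 2C
#' estimate in G2-dominant populations.
#'
#' @param totals vector of per-nucleus integrated DAPI (> 0); at least 50
#'   values.
#' @param params a [gating_params()].
#' @return estimated G1 peak (same units as `totals`).
#' @export
estimate_g1_peak <- function(totals, params = gating_params()) {
  totals <- as.numeric(totals)
  if (length(totals) < 50)
    stop("insufficient data: need at least 50 cells", call. = FALSE)
  if (any(!is.finite(totals)) || any(totals <= 0))
    stop("totals must be positive and finite", call. = FALSE)
  lt <- log(totals)
  rng <- range(lt)
  if (diff(rng) == 0) return(exp(lt[1]))
  nb <- params$histogram_bins
  width <- diff(rng) / nb
  bin <- pmin(floor((lt - rng[1]) / width), nb - 1L) + 1L
  counts <- tabulate(bin, nb)
  centers <- rng[1] + (seq_len(nb) - 0.5) * width
  global_mode <- which.max(counts)
  med_bin <- bin[order(lt)][ceiling(length(lt) / 2)]
  left_mode <- if (med_bin > 1L) which.max(counts[seq_len(med_bin - 1L)])
               else global_mode
  exp(centers[min(global_mode, left_mode)])
}

#' Gate to interphase cells with 2C-4C DNA content
#'
#' Keeps rows whose `total_dapi` lies in
#' `[g1_window_lo, g1_window_hi] * G1 peak`.
#'
#' @param table a `cell_table`.
#' @param params a [gating_params()].
#' @return list with `table` (gated `cell_table`) and `result` (a
#'   `gating_result`: `g1_peak`, `window`, `kept` row indices, `n_before`,
#'   `n_after`).
#' @export
gate_interphase <- function(table, params = gating_params()) {
  if (nrow(table) == 0) stop("cell table is empty", call. = FALSE)
  peak <- estimate_g1_peak(table$total_dapi, params)
  window <- c(params$g1_window_lo, params$g1_window_hi) * peak
  kept <- which(table$total_dapi >= window[1] &
                table$total_dapi <= window[2])
  gated <- as_cell_table(as.data.frame(table)[kept, , drop = FALSE],
                         cell_table_channels(table))
  rownames(gated) <- NULL
  result <- structure(list(g1_peak = peak, window = window, kept = kept,
                           n_before = nrow(table), n_after = length(kept)),
                      class = "gating_result")
  list(table = gated, result = result)
}

#' Call S-phase cells from a replication marker
#'
#' A cell is flagged S-phase when its marker mean exceeds a threshold:
#' either a fixed value, or the configured quantile of a designated
#' negative-control population's marker distribution.
#'
#' @param table a `cell_table`.
#' @param params a [gating_params()].
#' @param control optional negative-control `cell_table`; required when no
#'   fixed threshold is set.
#' @return logical vector (one flag per row) with the threshold attached
#'   as attribute `"threshold"`.
#' @export
call_sphase <- function(table, params = gating_params(), control = NULL) {
  col <- paste0("mean_", params$sphase_marker)
  if (!col %in% names(table))
    stop("S-phase marker channel absent: ", params$sphase_marker,
         call. = FALSE)
  thr <- params$sphase_threshold
  if (is.null(thr)) {
    if (is.null(control))
      stop("quantile threshold method requires a control table",
           call. = FALSE)
    if (!col %in% names(control))
      stop("S-phase marker channel absent from control", call. = FALSE)
    thr <- as.numeric(quantile(control[[col]], params$sphase_quantile))
  }
  flags <- table[[col]] > thr
  attr(flags, "threshold") <- thr
  flags
}

#' Randomly subsample all tables to a common depth
#'
#' Each table is reduced to the smallest input size by seeded sampling
#' without replacement, so conditions are compared at equal cell numbers.
#'
#' @param tables list of non-empty `cell_table`s.
#' @param params a [gating_params()] (uses `subsample_seed`).
#' @return list of `cell_table`s, all with `min(sapply(tables, nrow))`
#'   rows.
#' @export
subsample_equal <- function(tables, params = gating_params()) {
  stopifnot(is.list(tables), length(tables) >= 1)
  sizes <- vapply(tables, nrow, integer(1))
  if (any(sizes == 0)) stop("all tables must be non-empty", call. = FALSE)
  n <- min(sizes)
  with_seed(params$subsample_seed, lapply(tables, function(t) {
    keep <- sort(sample.int(nrow(t), n))
    out <- as_cell_table(as.data.frame(t)[keep, , drop = FALSE],
                         cell_table_channels(t))
    rownames(out) <- NULL
    out
  }))
}
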
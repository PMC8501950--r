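#' Segmentation parameters
#'
#' The operator chain is fixed (Gaussian smoothing, two-class Otsu
#' threshold, hole filling, seeded watershed on the distance transform,
#' size/border filtering); these are its tunables.
#'
#' @param smoothing_sigma Gaussian sigma in pixels applied to DAPI before
#'   thresholding (0 disables smoothing).
#' @param min_area,max_area object area bounds in pixels^2.
#' @param min_seed_distance minimum separation (pixels) between watershed
#'   seeds; fused disks whose centres are at least this far apart split.
#' @param fill_holes fill interior holes of the binary mask.
#' @param clear_border drop objects touching the image border.
#' @return a `segmentation_params` object.
#' @export
segmentation_params <- function(smoothing_sigma = 1,
                                min_area = 100,
                                max_area = 10000,
                                min_seed_distance = 10,
                                fill_holes = TRUE,
                                clear_border = TRUE) {
  stop_if_not_number(smoothing_sigma, "smoothing_sigma", lower = 0)
  stop_if_not_number(min_area, "min_area", lower = 0)
  stop_if_not_number(max_area, "max_area", lower = min_area)
  stop_if_not_number(min_seed_distance, "min_seed_distance", lower = 1)
  stop_if_not_flag(fill_holes, "fill_holes")
  stop_if_not_flag(clear_border, "clear_border")
  structure(list(smoothing_sigma = smoothing_sigma,
                 min_area = min_area, max_area = max_area,
                 min_seed_distance = min_seed_distance,
                 fill_holes = fill_holes, clear_border = clear_border),
            class = "segmentation_params")
}

as_image_matrix <- function(image) {
  if (inherits(image, "field_of_view"))
    stop("pass a single channel matrix, not a field", call. = FALSE)
  if (is.list(image) && !is.null(image$pixels)) image <- image$pixels
  if (!is.matrix(image) || !is.numeric(image))
    stop("`image` must be a numeric matrix", call. = FALSE)
  image
}

#' Two-class Otsu threshold
#'
#' Classical Otsu on a 256-bin histogram over the observed intensity range
#' (256 bins regardless of bit depth): returns the threshold maximising the
#' between-class variance, ties broken toward the lower threshold. The
#' foreground is `pixels > threshold`.
#'
#' @param image numeric matrix of intensities.
#' @return single threshold value (a bin centre).
#' @export
otsu_threshold <- function(image) {
  x <- as.vector(as_image_matrix(image))
  rng <- range(x)
  if (!is.finite(diff(rng)) || diff(rng) == 0)
    stop("degenerate histogram: image is constant", call. = FALSE)
  nbins <- 256L
  width <- diff(rng) / nbins
  bin <- pmin(floor((x - rng[1]) / width), nbins - 1L)  # 0-based bin
  counts <- tabulate(bin + 1L, nbins)
  centers <- rng[1] + (seq_len(nbins) - 0.5) * width
  p <- counts / sum(counts)
  omega <- cumsum(p)
  mu <- cumsum(p * centers)
  mu_t <- mu[nbins]
  # between-class variance for split after bin k (k = 1..255)
  k <- seq_len(nbins - 1L)
  w0 <- omega[k]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, nbins - 1L)
  sigma_b[valid] <- (mu_t * w0[valid] - mu[k][valid])^2 /
    (w0[valid] * w1[valid])
  best <- which.max(sigma_b)  # which.max takes the first (lowest) maximum
  centers[best]
}

# separable Gaussian smoothing with replicate-edge padding
gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  smooth1 <- function(x, along) {
    n <- if (along == 1) nrow(x) else ncol(x)
    out <- 0
    for (i in seq_along(k)) {
      off <- i - r - 1L
      idx <- pmin(pmax(seq_len(n) + off, 1L), n)
      out <- out + k[i] *
        (if (along == 1) x[idx, , drop = FALSE] else x[, idx, drop = FALSE])
    }
    out
  }
  smooth1(smooth1(m, 1), 2)
}

#' Binarise a channel image
#'
#' Gaussian smoothing, Otsu threshold, optional interior hole filling.
#'
#' @param image numeric matrix.
#' @param params a [segmentation_params()].
#' @return logical matrix (TRUE = foreground).
#' @export
binarize <- function(image, params = segmentation_params()) {
  m <- gaussian_smooth(as_image_matrix(image), params$smoothing_sigma)
  t <- otsu_threshold(m)
  mask <- m > t
  if (params$fill_holes) mask <- cpp_fill_holes(mask)
  mask
}

#' Split a binary mask into labelled nuclei by seeded watershed
#'
#' Seeds are local maxima of the Euclidean distance transform, greedily
#' suppressed so that kept seeds are at least `min_seed_distance` apart
#' (higher-distance maxima win); every connected component is guaranteed at
#' least one seed. The watershed floods the negative distance transform
#' from the seeds, restricted to the mask.
#'
#' @param binary logical matrix from [binarize()].
#' @param params a [segmentation_params()].
#' @return a `label_mask`.
#' @export
watershed_split <- function(binary, params = segmentation_params()) {
  if (!is.matrix(binary)) stop("`binary` must be a matrix", call. = FALSE)
  mode(binary) <- "logical"
  if (!any(binary))
    return(label_mask(matrix(0L, nrow(binary), ncol(binary))))
  edt <- cpp_edt(binary)
  rad <- as.integer(floor(params$min_seed_distance))
  mx <- cpp_maxfilter(edt, rad)
  cand <- which(binary & edt > 0 & edt >= mx - 1e-9)
  comp <- cpp_label(binary)
  # greedy non-maximum suppression: strongest first, deterministic order
  cr <- (cand - 1L) %% nrow(binary) + 1L
  cc <- (cand - 1L) %/% nrow(binary) + 1L
  ord <- order(-edt[cand], cr, cc)
  keep_r <- numeric(0); keep_c <- numeric(0)
  seeds <- matrix(0L, nrow(binary), ncol(binary))
  n_seed <- 0L
  for (i in ord) {
    r <- cr[i]; c <- cc[i]
    if (n_seed > 0 &&
        any((keep_r - r)^2 + (keep_c - c)^2 <
            params$min_seed_distance^2)) next
    n_seed <- n_seed + 1L
    keep_r <- c(keep_r, r); keep_c <- c(keep_c, c)
    seeds[r, c] <- n_seed
  }
  # guarantee one seed per connected component
  seeded_comps <- unique(comp[seeds > 0])
  all_comps <- setdiff(unique(as.vector(comp)), 0L)
  for (cp in setdiff(all_comps, seeded_comps)) {
    idx <- which(comp == cp)
    best <- idx[which.max(edt[idx])]
    n_seed <- n_seed + 1L
    seeds[best] <- n_seed
  }
  lab <- cpp_watershed(edt, seeds, binary)
  label_mask(lab)
}

#' Filter labelled objects by area and border contact
#'
#' @param mask a `label_mask`.
#' @param params a [segmentation_params()].
#' @return a `label_mask` with surviving labels renumbered 1..n.
#' @export
filter_labels <- function(mask, params = segmentation_params()) {
  stopifnot(inherits(mask, "label_mask"))
  lab <- mask$labels
  if (mask$n_objects == 0) return(mask)
  areas <- tabulate(lab[lab > 0], nbins = max(lab))
  drop <- which(areas < params$min_area | areas > params$max_area)
  if (params$clear_border) {
    border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    drop <- union(drop, border[border > 0])
  }
  if (length(drop) > 0) lab[lab %in% drop] <- 0L
  label_mask(lab)
}

#' Segment nuclei in the DAPI channel of a field
#'
#' Composition of [binarize()], [watershed_split()] and [filter_labels()]
#' on the DAPI channel; deterministic.
#'
#' @param field a `field_of_view` containing "DAPI".
#' @param params a [segmentation_params()].
#' @return a `label_mask`.
#' @export
segment_nuclei <- function(field, params = segmentation_params()) {
  stopifnot(inherits(field, "field_of_view"))
  dapi <- field$channels[["DAPI"]]
  if (is.null(dapi)) stop("field has no DAPI channel", call. = FALSE)
  filter_labels(watershed_split(binarize(dapi, params), params), params)
}
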
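#' Configuration of a synthetic QIBC scene
#'
#' States the population and imaging model from which ground-truth scenes
#' are drawn: a mixed interphase population with G1 (2C), S (2C-4C) and G2
#' (4C) DNA content, integrated DAPI proportional to DNA content, S-phase
#' restricted EdU/PCNA signal, additive background and Gaussian noise, and
#' an optional fraction of nuclei placed touching a partner so that fused
#' objects exist for watershed testing.
#'
#' @param field_shape integer (rows, cols) of every channel image.
#' @param n_nuclei number of nuclei to place.
#' @param radius_range (min, max) nuclear radius in pixels.
#' @param fraction_g1,fraction_s,fraction_g2 phase probabilities; must sum
#'   to 1.
#' @param dapi_per_c integrated DAPI intensity (A.U.) per 1C of DNA content;
#'   a G1 nucleus integrates to `2 * dapi_per_c`.
#' @param touching_pair_fraction fraction of nuclei placed adjacent to a
#'   partner at centre distance `0.8 * (r1 + r2)` (guaranteeing a fused
#'   binary component).
#' @param background_level constant additive background (A.U.).
#' @param noise_sd standard deviation of additive Gaussian noise (A.U.).
#' @param condition preset name; see [condition_presets()].
#' @param channels channel names to simulate; must include "DAPI".
#' @param seed integer seed; scenes are pure functions of (config, seed).
#' @return a `scene_config` object.
#' @export
scene_config <- function(field_shape = c(800L, 800L),
                         n_nuclei = 100L,
                         radius_range = c(12, 18),
                         fraction_g1 = 0.5,
                         fraction_s = 0.3,
                         fraction_g2 = 0.2,
                         dapi_per_c = 5e5,
                         touching_pair_fraction = 0,
                         background_level = 100,
                         noise_sd = 20,
                         condition = "untreated",
                         channels = c("DAPI", "EdU", "PCNA", "gH2AX",
                                      "RPA2", "ADPr"),
                         seed = 1L) {
  stopifnot(length(field_shape) == 2L, all(field_shape >= 1))
  stop_if_not_number(n_nuclei, "n_nuclei", lower = 0)
  stopifnot(length(radius_range) == 2L, radius_range[1] > 0,
            radius_range[1] <= radius_range[2])
  fr <- c(fraction_g1, fraction_s, fraction_g2)
  if (any(fr < 0) || abs(sum(fr) - 1) > 1e-9)
    stop("phase fractions must be non-negative and sum to 1", call. = FALSE)
  stop_if_not_number(dapi_per_c, "dapi_per_c", lower = 0)
  stop_if_not_number(touching_pair_fraction, "touching_pair_fraction", 0, 1)
  stop_if_not_number(background_level, "background_level", lower = 0)
  stop_if_not_number(noise_sd, "noise_sd", lower = 0)
  if (!"DAPI" %in% channels) stop("channels must include DAPI", call. = FALSE)
  structure(list(field_shape = as.integer(field_shape),
                 n_nuclei = as.integer(n_nuclei),
                 radius_range = as.numeric(radius_range),
                 fraction_g1 = fraction_g1, fraction_s = fraction_s,
                 fraction_g2 = fraction_g2,
                 dapi_per_c = dapi_per_c,
                 touching_pair_fraction = touching_pair_fraction,
                 background_level = background_level,
                 noise_sd = noise_sd,
                 condition = condition,
                 channels = channels,
                 seed = as.integer(seed)),
            class = "scene_config")
}

#' Draw a ground-truth scene from a configuration
#'
#' Phases are multinomial draws from the configured fractions; S-phase DNA
#' content is uniform in (2, 4); true channel means come from the condition
#' preset. The requested fraction of nuclei is placed touching a partner at
#' centre distance `0.8 * (r1 + r2)`; all other nuclei keep a clearance gap
#' so isolated nuclei yield isolated binary components. Deterministic given
#' `config$seed`.
#'
#' @param config a [scene_config()].
#' @param presets preset table; defaults to [condition_presets()].
#' @return a `synthetic_scene`: list with `config`, `nuclei` (one row per
#'   nucleus: id, 0-based centre, radius, phase, dna_content, partner id,
#'   `mean_<channel>` true means) and `channel_names`.
#' @export
make_scene <- function(config, presets = condition_presets()) {
  stopifnot(inherits(config, "scene_config"))
  n <- config$n_nuclei
  non_dapi <- setdiff(config$channels, "DAPI")
  empty <- data.frame(id = integer(), row = numeric(), col = numeric(),
                      radius = numeric(), phase = character(),
                      dna_content = numeric(), partner = integer())
  for (ch in non_dapi) empty[[paste0("mean_", ch)]] <- numeric()
  if (n == 0L)
    return(structure(list(config = config, nuclei = empty,
                          channel_names = config$channels),
                     class = "synthetic_scene"))
  with_seed(config$seed, {
    phases <- sample(c("G1", "S", "G2"), n, replace = TRUE,
                     prob = c(config$fraction_g1, config$fraction_s,
                              config$fraction_g2))
    dna <- ifelse(phases == "G1", 2, ifelse(phases == "G2", 4, NA))
    n_s <- sum(is.na(dna))
    if (n_s > 0) dna[is.na(dna)] <- runif(n_s, 2, 4)
    radii <- runif(n, config$radius_range[1], config$radius_range[2])
    n_pairs <- round(config$touching_pair_fraction * n) %/% 2L
    pos <- place_nuclei(n, radii, n_pairs, config$field_shape)
    partner <- rep(NA_integer_, n)
    if (n_pairs > 0) {
      idx <- seq_len(2L * n_pairs)
      partner[idx] <- ifelse(idx %% 2L == 1L, idx + 1L, idx - 1L)
    }
    nuc <- data.frame(id = seq_len(n), row = pos$row, col = pos$col,
                      radius = radii, phase = phases, dna_content = dna,
                      partner = partner)
    for (ch in non_dapi)
      nuc[[paste0("mean_", ch)]] <- vapply(phases, function(p)
        preset_channel_mean(ch, p, config$condition, presets), numeric(1))
    structure(list(config = config, nuclei = nuc,
                   channel_names = config$channels),
              class = "synthetic_scene")
  })
}

# Rejection-sampled placement. Pairs first (anchor + partner at
# 0.8*(r1+r2)), then singles; non-partner disks keep a >=4 px gap.
# Errors out after an attempt cap so an overfull field fails loudly.
place_nuclei <- function(n, radii, n_pairs, field_shape, gap = 4,
                         max_attempts = 20000L) {
  rows <- rep(NA_real_, n); cols <- rep(NA_real_, n)
  nr <- field_shape[1]; nc <- field_shape[2]
  clear_of <- function(r, c, rad, skip = integer()) {
    placed <- which(!is.na(rows))
    placed <- setdiff(placed, skip)
    if (length(placed) == 0) return(TRUE)
    d <- sqrt((rows[placed] - r)^2 + (cols[placed] - c)^2)
    all(d >= radii[placed] + rad + gap)
  }
  inside <- function(r, c, rad)
    r - rad >= 1 && r + rad <= nr - 2 && c - rad >= 1 && c + rad <= nc - 2
  place_fail <- function()
    stop("placement failure: field too small for requested nuclei",
         call. = FALSE)
  i <- 1L
  while (i <= 2L * n_pairs) {
    j <- i + 1L
    ok <- FALSE
    for (att in seq_len(max_attempts)) {
      r1 <- runif(1, radii[i] + 1, nr - radii[i] - 2)
      c1 <- runif(1, radii[i] + 1, nc - radii[i] - 2)
      theta <- runif(1, 0, 2 * pi)
      d <- 0.8 * (radii[i] + radii[j])
      r2 <- r1 + d * cos(theta); c2 <- c1 + d * sin(theta)
      if (!inside(r2, c2, radii[j])) next
      if (!clear_of(r1, c1, radii[i]) || !clear_of(r2, c2, radii[j])) next
      rows[i] <- r1; cols[i] <- c1; rows[j] <- r2; cols[j] <- c2
      ok <- TRUE
      break
    }
    if (!ok) place_fail()
    i <- i + 2L
  }
  for (k in seq_len(n)) {
    if (!is.na(rows[k])) next
    ok <- FALSE
    for (att in seq_len(max_attempts)) {
      r <- runif(1, radii[k] + 1, nr - radii[k] - 2)
      c <- runif(1, radii[k] + 1, nc - radii[k] - 2)
      if (!clear_of(r, c, radii[k])) next
      rows[k] <- r; cols[k] <- c
      ok <- TRUE
      break
    }
    if (!ok) place_fail()
  }
  list(row = rows, col = cols)
}

# 1-based index sets of the rasterised disk of one nucleus
disk_pixels <- function(row0, col0, radius, field_shape) {
  r_lo <- max(0L, floor(row0 - radius)); r_hi <- min(field_shape[1] - 1L,
                                                     ceiling(row0 + radius))
  c_lo <- max(0L, floor(col0 - radius)); c_hi <- min(field_shape[2] - 1L,
                                                     ceiling(col0 + radius))
  rr <- seq.int(r_lo, r_hi); cc <- seq.int(c_lo, c_hi)
  g <- expand.grid(r = rr, c = cc)
  keep <- (g$r - row0)^2 + (g$c - col0)^2 <= radius^2
  g <- g[keep, , drop = FALSE]
  cbind(row = g$r + 1L, col = g$c + 1L)
}

#' Render a scene to a multi-channel field of view
#'
#' Each nucleus is a filled disk. The DAPI value inside a disk is
#' `dapi_per_c * dna_content / area` with `area` the rasterised pixel
#' count, so integrated DAPI equals `dapi_per_c * dna_content` exactly in
#' the noiseless case. Other channels are constant at their true means
#' inside the disk. Overlapping disks (touching pairs) add, so total
#' intensity is conserved. Background is added everywhere, Gaussian noise
#' when `noise_sd > 0`, and values are clipped to the 16-bit dynamic range
#' (kept as floating point in memory; rounding happens only on TIFF export).
#'
#' @param scene a [make_scene()] result.
#' @param field_id identifier for the rendered field.
#' @param noise_seed seed for the noise draw only; defaults to a value
#'   derived from the scene seed. Two renders differing only in
#'   `noise_seed` have identical noiseless content.
#' @return a `field_of_view`.
#' @export
render_scene <- function(scene, field_id = "field_1", noise_seed = NULL) {
  stopifnot(inherits(scene, "synthetic_scene"))
  cfg <- scene$config
  if (is.null(noise_seed)) noise_seed <- cfg$seed + 10007L
  shp <- cfg$field_shape
  imgs <- lapply(cfg$channels, function(ch) matrix(0, shp[1], shp[2]))
  names(imgs) <- cfg$channels
  if (nrow(scene$nuclei) > 0) {
    for (k in seq_len(nrow(scene$nuclei))) {
      nuc <- scene$nuclei[k, ]
      px <- disk_pixels(nuc$row, nuc$col, nuc$radius, shp)
      area <- nrow(px)
      imgs[["DAPI"]][px] <- imgs[["DAPI"]][px] +
        cfg$dapi_per_c * nuc$dna_content / area
      for (ch in setdiff(cfg$channels, "DAPI"))
        imgs[[ch]][px] <- imgs[[ch]][px] + nuc[[paste0("mean_", ch)]]
    }
  }
  imgs <- lapply(imgs, function(m) m + cfg$background_level)
  if (cfg$noise_sd > 0) {
    imgs <- with_seed(noise_seed, lapply(imgs, function(m)
      m + matrix(rnorm(length(m), sd = cfg$noise_sd), nrow(m), ncol(m))))
  }
  imgs <- lapply(imgs, function(m) pmin(pmax(m, 0), 65535))
  field_of_view(imgs, field_id = field_id)
}

#' Ground-truth label mask of a scene
#'
#' Rasterises every nucleus disk into an integer mask labelled by nucleus
#' id. Pixels inside two overlapping disks (touching pairs) are assigned to
#' the centre they are closest to, scaled by radius.
#'
#' @param scene a [make_scene()] result.
#' @return a `label_mask` whose labels are nucleus ids.
#' @export
truth_label_mask <- function(scene) {
  stopifnot(inherits(scene, "synthetic_scene"))
  shp <- scene$config$field_shape
  lab <- matrix(0L, shp[1], shp[2])
  score <- matrix(Inf, shp[1], shp[2])
  if (nrow(scene$nuclei) > 0) {
    for (k in seq_len(nrow(scene$nuclei))) {
      nuc <- scene$nuclei[k, ]
      px <- disk_pixels(nuc$row, nuc$col, nuc$radius, shp)
      d <- sqrt((px[, "row"] - 1 - nuc$row)^2 +
                (px[, "col"] - 1 - nuc$col)^2) / nuc$radius
      better <- d < score[px]
      lab[px[better, , drop = FALSE]] <- nuc$id
      score[px[better, , drop = FALSE]] <- d[better]
    }
  }
  label_mask(lab, relabel = FALSE)
}

#' Write a scene to disk (TIFFs, ground-truth CSV, scene JSON)
#'
#' One 16-bit single-channel TIFF per channel named
#' `<field>_<channel>.tif`, the ground truth as CSV (one row per nucleus)
#' and the full scene as JSON.
#'
#' @param scene a [make_scene()] result.
#' @param dir output directory (created if missing).
#' @param field_id field name used in file names.
#' @param noise_seed forwarded to [render_scene()].
#' @return named list of written paths, invisibly.
#' @export
write_scene <- function(scene, dir, field_id = "field_1", noise_seed = NULL) {
  stopifnot(inherits(scene, "synthetic_scene"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fov <- render_scene(scene, field_id = field_id, noise_seed = noise_seed)
  paths <- list()
  for (ch in names(fov$channels)) {
    p <- file.path(dir, sprintf("%s_%s.tif", field_id, ch))
    write_tiff16(fov$channels[[ch]], p)
    paths[[ch]] <- p
  }
  truth_path <- file.path(dir, sprintf("%s_truth.csv", field_id))
  write.csv(scene$nuclei, truth_path, row.names = FALSE)
  scene_path <- file.path(dir, sprintf("%s_scene.json", field_id))
  jsonlite::write_json(list(config = unclass(scene$config),
                            nuclei = scene$nuclei,
                            channel_names = scene$channel_names),
                       scene_path, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, list(truth = truth_path, scene = scene_path)))
}
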
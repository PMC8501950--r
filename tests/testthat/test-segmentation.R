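disk_image <- function(shape, row0, col0, radius, fg = 200, bg = 10) {
  m <- matrix(bg, shape[1], shape[2])
  g <- expand.grid(r = seq_len(shape[1]) - 1, c = seq_len(shape[2]) - 1)
  inside <- (g$r - row0)^2 + (g$c - col0)^2 <= radius^2
  m[cbind(g$r[inside] + 1, g$c[inside] + 1)] <- fg
  m
}

test_that("otsu_threshold separates two classes and rejects constants", {
  img <- matrix(c(rep(10, 50), rep(200, 50)), 10, 10)
  t <- otsu_threshold(img)
  expect_true(all(img[img > t] == 200))
  expect_equal(sum(img > t), 50)
  expect_error(otsu_threshold(matrix(7, 5, 5)), "degenerate")
})

test_that("otsu_threshold equals the exhaustive between-class oracle", {
  # tri-modal stated case
  tri <- matrix(rep(c(10, 100, 240), each = 100), 10, 30)
  expect_equal(otsu_threshold(tri), brute_otsu(tri))
  # property: random histograms, oracle equivalence
  set.seed(71)
  for (i in 1:20) {
    n_modes <- sample(2:4, 1)
    x <- unlist(lapply(seq_len(n_modes), function(j)
      rnorm(sample(50:300, 1), mean = runif(1, 0, 5000),
            sd = runif(1, 10, 200))))
    img <- matrix(pmax(x, 0)[1:(length(x) %/% 2 * 2)], ncol = 2)
    expect_equal(otsu_threshold(img), brute_otsu(img))
  }
})

test_that("binarize recovers a disk and fills holes", {
  img <- disk_image(c(80, 80), 40, 40, 15)
  p <- segmentation_params(smoothing_sigma = 0)
  mask <- binarize(img, p)
  truth <- img > 100
  # exact without smoothing
  expect_identical(mask, truth)
  # with smoothing: +/- 1-pixel boundary band
  mask_s <- binarize(img, segmentation_params(smoothing_sigma = 1))
  expect_lt(sum(xor(mask_s, truth)) / sum(truth), 0.15)
  # hole filling
  img2 <- img
  img2[40, 40] <- 10
  expect_true(binarize(img2, p)[40, 40])
  expect_false(binarize(img2, segmentation_params(smoothing_sigma = 0,
                                                  fill_holes = FALSE))[40, 40])
  # constant background-only field errors
  expect_error(binarize(matrix(5, 40, 40), p), "degenerate")
})

test_that("watershed_split labels blobs and splits fused disks", {
  p <- segmentation_params(smoothing_sigma = 0, min_seed_distance = 10)
  one <- disk_image(c(80, 80), 40, 40, 15) > 100
  expect_equal(watershed_split(one, p)$n_objects, 1L)
  # empty mask -> 0 objects
  expect_equal(watershed_split(matrix(FALSE, 20, 20), p)$n_objects, 0L)
  # two disks fused at 0.8 * (r1 + r2): exactly 2 labels, IoU >= 0.6 each
  shape <- c(100, 120)
  d <- 0.8 * 30
  m <- disk_image(shape, 50, 40, 15) > 100 |
       disk_image(shape, 50, 40 + d, 15) > 100
  lab <- watershed_split(m, p)
  expect_equal(lab$n_objects, 2L)
  for (ctr in list(c(50, 40), c(50, 40 + d))) {
    g <- expand.grid(r = seq_len(shape[1]) - 1, c = seq_len(shape[2]) - 1)
    disk <- matrix((g$r - ctr[1])^2 + (g$c - ctr[2])^2 <= 15^2,
                   shape[1], shape[2])
    labs <- lab$labels[disk]
    best <- as.integer(names(which.max(table(labs[labs > 0]))))
    inter <- sum(lab$labels == best & disk)
    union <- sum(lab$labels == best | disk)
    expect_gte(inter / union, 0.6)
  }
})

test_that("filter_labels enforces area bounds, border rule and renumbering", {
  lab <- matrix(0L, 60, 220)
  lab[2:5, 2:11] <- 1L                     # area 40
  lab[20:39, 20:39] <- 2L                  # area 400
  lab[1:50, 60:210] <- 3L                  # area 7550 but touches border
  m <- label_mask(lab)
  p <- segmentation_params(min_area = 50, max_area = 10000)
  out <- filter_labels(m, p)
  expect_equal(out$n_objects, 1L)
  expect_true(all(out$labels[20:39, 20:39] == 1L))       # renumbered
  # without clear_border the big object survives too
  p2 <- segmentation_params(min_area = 50, max_area = 10000,
                            clear_border = FALSE)
  expect_equal(filter_labels(m, p2)$n_objects, 2L)
  # speck-only mask -> 0 objects
  speck <- matrix(0L, 30, 30); speck[10:11, 10:11] <- 1L
  expect_equal(filter_labels(label_mask(speck), p)$n_objects, 0L)
  # monotonicity: raising min_area never increases object count
  cfg <- small_scene_config(n_nuclei = 8L)
  mask <- watershed_split(binarize(render_scene(make_scene(cfg))$channels$DAPI,
                                   segmentation_params()),
                          segmentation_params())
  counts <- vapply(c(0, 100, 300, 500, 800), function(a)
    filter_labels(mask, segmentation_params(min_area = a))$n_objects,
    integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("segment_nuclei recovers synthetic nuclei and is deterministic", {
  cfg <- scene_config(field_shape = c(700L, 700L), n_nuclei = 50L,
                      noise_sd = 70, seed = 21L)
  sc <- make_scene(cfg)
  fov <- render_scene(sc)
  mask <- segment_nuclei(fov)
  rec <- segmentation_recovery(sc, mask)
  expect_gte(sum(rec$iou >= 0.7), 48)
  # gap-free labelling with background 0
  ids <- sort(unique(as.vector(mask$labels)))
  expect_identical(ids, c(0L, seq_len(mask$n_objects)))
  # determinism
  expect_identical(mask, segment_nuclei(fov))
  # field with only sub-nuclear specks: everything falls below min_area
  speck_img <- matrix(10, 200, 200)
  speck_img[50:52, 50:52] <- 200
  speck_img[120, 80:84] <- 200
  speck_img[170:172, 150:153] <- 200
  fov_bg <- field_of_view(list(DAPI = speck_img))
  expect_equal(segment_nuclei(fov_bg)$n_objects, 0L)
})
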
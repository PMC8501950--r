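test_that("scene generation follows configured population structure", {
  cfg <- scene_config(field_shape = c(1200L, 1200L), n_nuclei = 200L,
                      fraction_g1 = 0.5, fraction_s = 0.3,
                      fraction_g2 = 0.2, seed = 1L)
  sc <- make_scene(cfg)
  expect_s3_class(sc, "synthetic_scene")
  expect_equal(nrow(sc$nuclei), 200L)
  counts <- table(factor(sc$nuclei$phase, levels = c("G1", "S", "G2")))
  expect_true(within_3sigma(as.numeric(counts), 200, c(0.5, 0.3, 0.2)))
  # DNA content encodes phase
  expect_true(all(sc$nuclei$dna_content[sc$nuclei$phase == "G1"] == 2))
  expect_true(all(sc$nuclei$dna_content[sc$nuclei$phase == "G2"] == 4))
  s_dna <- sc$nuclei$dna_content[sc$nuclei$phase == "S"]
  expect_true(all(s_dna > 2 & s_dna < 4))
})

test_that("scene generation is deterministic and handles edge cases", {
  cfg <- small_scene_config()
  expect_identical(make_scene(cfg), make_scene(cfg))
  sc0 <- make_scene(scene_config(n_nuclei = 0L))
  expect_equal(nrow(sc0$nuclei), 0L)
  # too many nuclei for the field -> explicit placement failure
  expect_error(
    make_scene(scene_config(field_shape = c(60L, 60L), n_nuclei = 50L,
                            radius_range = c(10, 12), seed = 1L)),
    "placement failure")
  # invalid fractions rejected
  expect_error(scene_config(fraction_g1 = 0.5, fraction_s = 0.5,
                            fraction_g2 = 0.2), "sum to 1")
})

test_that("touching pairs sit at 0.8 x (r1 + r2) centre distance", {
  cfg <- scene_config(field_shape = c(900L, 900L), n_nuclei = 40L,
                      touching_pair_fraction = 0.5, seed = 7L)
  sc <- make_scene(cfg)
  nuc <- sc$nuclei
  firsts <- which(!is.na(nuc$partner) & nuc$id < nuc$partner)
  expect_equal(length(firsts), 10L)  # 0.5 * 40 / 2
  for (k in firsts) {
    p <- nuc$partner[k]
    d <- sqrt((nuc$row[k] - nuc$row[p])^2 + (nuc$col[k] - nuc$col[p])^2)
    expect_equal(d, 0.8 * (nuc$radius[k] + nuc$radius[p]), tolerance = 1e-9)
  }
})

test_that("noiseless render conserves integrated DAPI per nucleus", {
  cfg <- scene_config(field_shape = c(260L, 260L), n_nuclei = 5L,
                      noise_sd = 0, background_level = 50,
                      dapi_per_c = 1000, seed = 3L)
  sc <- make_scene(cfg)
  fov <- render_scene(sc)
  truth <- truth_label_mask(sc)$labels
  for (k in seq_len(nrow(sc$nuclei))) {
    nuc <- sc$nuclei[k, ]
    pix <- truth == nuc$id
    integrated <- sum(fov$channels$DAPI[pix] - cfg$background_level)
    expect_equal(integrated, 1000 * nuc$dna_content,
                 tolerance = 0.005)
    # non-DAPI channels constant at truth inside the disk
    edu <- fov$channels$EdU[pix] - cfg$background_level
    expect_equal(max(abs(edu - nuc$mean_EdU)), 0, tolerance = 1e-9)
  }
})

test_that("noise affects only the noisy part of the render", {
  cfg <- scene_config(field_shape = c(300L, 300L), n_nuclei = 10L,
                      noise_sd = 25, seed = 9L)
  sc <- make_scene(cfg)
  a <- render_scene(sc, noise_seed = 1L)
  b <- render_scene(sc, noise_seed = 2L)
  expect_false(identical(a$channels$DAPI, b$channels$DAPI))
  # noiseless content identical: re-render with noise off
  cfg0 <- cfg; cfg0$noise_sd <- 0
  sc0 <- sc; sc0$config <- cfg0
  expect_identical(render_scene(sc0, noise_seed = 1L)$channels,
                   render_scene(sc0, noise_seed = 2L)$channels)
})

test_that("preset directions hold on ground truth", {
  presets <- condition_presets()
  mk <- function(cond) make_scene(small_scene_config(condition = cond,
                                                     n_nuclei = 30L,
                                                     field_shape = c(500L, 500L)))
  wt <- mk("dart_wt"); e160a <- mk("dart_e160a"); mms <- mk("mms")
  s_mean <- function(sc, col, phase = "S")
    mean(sc$nuclei[[col]][sc$nuclei$phase == phase])
  expect_lt(s_mean(wt, "mean_EdU"), s_mean(e160a, "mean_EdU"))
  # mms elevates ADP-ribose in every phase relative to untreated base
  base <- condition_presets()$base_means$ADPr
  for (ph in c("G1", "S", "G2")) {
    vals <- mms$nuclei$mean_ADPr[mms$nuclei$phase == ph]
    if (length(vals) > 0)
      expect_true(all(vals > as.numeric(base[[ph]])))
  }
  # identity presets agree with base means
  un <- mk("untreated")
  for (ph in unique(un$nuclei$phase))
    expect_equal(unique(un$nuclei$mean_EdU[un$nuclei$phase == ph]),
                 as.numeric(condition_presets()$base_means$EdU[[ph]]))
})

test_that("random_sequence draws i.i.d. bases with the stated composition", {
  expect_identical(random_sequence(0), "")
  expect_identical(random_sequence(5, c(A = 0, C = 0, G = 0, T = 1)),
                   "TTTTT")
  expect_error(random_sequence(5, c(A = 0.5, C = 0.5, G = 0.5, T = 0.5)),
               "sum to 1")
  s <- random_sequence(1e6, seed = 123L)
  expect_identical(s, random_sequence(1e6, seed = 123L))
  freq <- table(strsplit(s, "")[[1]]) / 1e6
  expect_true(all(abs(freq - 0.25) < 0.002))  # binomial 3-sigma ~ 0.0013
})

test_that("plant_motifs writes copies in order with overwrites", {
  expect_identical(plant_motifs("GGGGGG", "TATC", 0L), "TATCGG")
  # by hand: plant at 0 -> TATCGGGG, then at 2 -> TATATCGG
  expect_identical(plant_motifs("GGGGGGGG", "TATC", c(0L, 2L)), "TATATCGG")
  expect_identical(plant_motifs("ACGT", "TATC", integer(0)), "ACGT")
  expect_error(plant_motifs("ACGT", "TATC", 1L), "out of range")
  expect_error(plant_motifs("ACGT", "TATC", -1L), "out of range")
})
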
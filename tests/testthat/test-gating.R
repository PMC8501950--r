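mixture_totals <- function(n = 2000, g1 = 1e5, w = 0.6, sdlog = 0.05,
                           seed = 1) {
  with_seed(seed, {
    comp <- sample(c(1, 2), n, replace = TRUE, prob = c(w, 1 - w))
    exp(rnorm(n, mean = log(ifelse(comp == 1, g1, 2 * g1)), sd = sdlog))
  })
}

test_that("estimate_g1_peak finds the leftmost dominant mode", {
  # no-noise point mass: within one bin width (here: exact)
  expect_equal(estimate_g1_peak(rep(100, 1000)), 100)
  # stated 60/40 log-normal mixture: within 5% of the planted 2C value
  tot <- mixture_totals(seed = 2)
  expect_equal(estimate_g1_peak(tot), 1e5, tolerance = 0.05)
  # insufficient data
  expect_error(estimate_g1_peak(rep(100, 10)), "insufficient")
  expect_error(estimate_g1_peak(c(rep(100, 60), -1)), "positive")
})

test_that("G1 peak recovery holds across seeds", {
  hits <- vapply(1:20, function(s) {
    est <- estimate_g1_peak(mixture_totals(seed = s))
    abs(est - 1e5) / 1e5 <= 0.05
  }, logical(1))
  expect_gte(sum(hits), 19)
})

test_that("gate_interphase keeps the 2C-4C window and excludes outliers", {
  sq_tab <- function(totals) {
    df <- data.frame(field_id = "f", label = seq_along(totals),
                     area = 100L, centroid_row = 0, centroid_col = 0,
                     total_dapi = totals, mean_DAPI = totals / 100,
                     border_touching = FALSE, condition = "c")
    qibcr:::as_cell_table(df, "DAPI")
  }
  # pure-G1 table: >= 99% kept under defaults
  g1 <- with_seed(3, exp(rnorm(1000, log(1e5), 0.05)))
  res <- gate_interphase(sq_tab(g1))
  expect_gte(res$result$n_after / res$result$n_before, 0.99)
  expect_true(all(res$table$total_dapi >= res$result$window[1] &
                  res$table$total_dapi <= res$result$window[2]))
  expect_lte(res$result$n_after, res$result$n_before)
  # planted 8C outliers at 4 x G1 peak excluded under hi = 2.5
  tot <- c(mixture_totals(seed = 4), rep(4e5, 20))
  res2 <- gate_interphase(sq_tab(tot))
  expect_true(all(res2$table$total_dapi < 3.9e5))
  expect_gte(res2$result$n_before - res2$result$n_after, 20)
  # misconfigured window rejected at construction
  expect_error(gating_params(g1_window_lo = 2, g1_window_hi = 2), "below")
})

test_that("call_sphase flags replicating cells", {
  cfg <- scene_config(field_shape = c(1100L, 1100L), n_nuclei = 200L,
                      fraction_g1 = 0.5, fraction_s = 0.3,
                      fraction_g2 = 0.2, seed = 31L)
  sc <- make_scene(cfg)
  fov <- render_scene(sc)
  tab <- measure_nuclei(truth_label_mask(sc), fov)
  truth_s <- sc$nuclei$phase[order(sc$nuclei$id)] == "S"
  # fixed threshold halfway between background-ish and S-phase signal
  p <- gating_params(sphase_marker = "EdU", sphase_threshold = 200)
  flags <- call_sphase(tab, p)
  expect_gte(sum(flags & truth_s) / sum(truth_s), 0.9)     # sensitivity
  expect_gte(sum(!flags & !truth_s) / sum(!truth_s), 0.9)  # specificity
  n_s <- sum(truth_s)
  expect_true(abs(sum(flags) - n_s) <= 3 * sqrt(200 * 0.3 * 0.7))
  # quantile rule against an all-G1 control
  ctl_cfg <- scene_config(field_shape = c(900L, 900L), n_nuclei = 100L,
                          fraction_g1 = 1, fraction_s = 0, fraction_g2 = 0,
                          seed = 32L)
  ctl_sc <- make_scene(ctl_cfg)
  ctl <- measure_nuclei(truth_label_mask(ctl_sc), render_scene(ctl_sc))
  pq <- gating_params(sphase_marker = "EdU", sphase_threshold = NULL,
                      sphase_quantile = 0.95)
  fq <- call_sphase(tab, pq, control = ctl)
  expect_gte(sum(fq & truth_s) / sum(truth_s), 0.9)
  # all-G1 table against itself: flagged fraction <= 1 - q + 3 sigma
  fg1 <- call_sphase(ctl, pq, control = ctl)
  expect_lte(mean(fg1), 0.05 + 3 * sqrt(0.05 * 0.95 / nrow(ctl)))
  # guard rails
  expect_error(call_sphase(tab, pq), "control")
  p_hi <- gating_params(sphase_marker = "EdU", sphase_threshold = 1e9)
  expect_equal(sum(call_sphase(tab, p_hi)), 0L)
  expect_error(call_sphase(tab, gating_params(sphase_marker = "nope",
                                              sphase_threshold = 1)),
               "absent")
})

test_that("subsample_equal equalises depths deterministically", {
  mk <- function(n) {
    df <- data.frame(field_id = rep("f", n), label = seq_len(n),
                     area = rep(1L, n), centroid_row = rep(0, n),
                     centroid_col = rep(0, n), total_dapi = rep(1, n),
                     mean_DAPI = rep(1, n), border_touching = rep(FALSE, n),
                     condition = rep("c", n))
    qibcr:::as_cell_table(df, "DAPI")
  }
  tabs <- list(mk(1500), mk(1200), mk(1800))
  p <- gating_params(subsample_seed = 7L)
  out <- subsample_equal(tabs, p)
  expect_identical(vapply(out, nrow, integer(1)), rep(1200L, 3))
  out2 <- subsample_equal(tabs, p)
  expect_identical(lapply(out, function(t) t$label),
                   lapply(out2, function(t) t$label))
  # single table unchanged in size
  expect_equal(nrow(subsample_equal(list(mk(10)), p)[[1]]), 10L)
  expect_error(subsample_equal(list(mk(0)), p), "non-empty")
})
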
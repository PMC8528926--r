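test_that("channel-weight calibration satisfies its defining identities", {
  m <- matrix(TRUE, 20, 20)
  eq <- list(green = matrix(80, 20, 20), red = matrix(80, 20, 20))
  expect_equal(calibrate_channel_weight(list(eq), list(m))$w, 1.0)
  dbl <- list(green = matrix(50, 20, 20), red = matrix(100, 20, 20))
  expect_equal(calibrate_channel_weight(list(dbl), list(m))$w, 0.5)
  expect_error(calibrate_channel_weight(list(eq), list(m & FALSE)),
               "empty calibration")
  # noisy generated scene with gain 1.7: recovered within 2%
  res <- generate_field(scene_config(image_size = c(160, 160), n_cells = 4,
                                     channel_gain = 1.7,
                                     mitolysosomes_per_cell = 0,
                                     rng_seed = 31))
  ch <- corrected_channels(res$field)
  mask <- segment_mito(ch$red, seg_config())
  w <- calibrate_channel_weight(list(ch), list(mask))
  expect_lt(abs(w$w - 1 / 1.7) / (1 / 1.7), 0.02)
  # a mitophagy-heavy "control" triggers the bimodality warning
  hot <- generate_field(scene_config(image_size = c(160, 160), n_cells = 4,
                                     mitolysosomes_per_cell = 25,
                                     network_density = 0.04,
                                     rng_seed = 32))
  ch2 <- corrected_channels(hot$field)
  m2 <- segment_mito(ch2$red, seg_config())
  expect_warning(calibrate_channel_weight(list(ch2), list(m2)),
                 "possible mitophagy")
})

test_that("ratio map reproduces the pixel semantics of the threshold", {
  f <- list(green = matrix(c(80, 40, 100, 0.1), 2, 2),
            red = matrix(c(80, 100, 100, 0.1), 2, 2))
  r <- compute_ratio_map(f, 1.0)
  expect_equal(r[1, 1], 1.0)          # balanced pixel is yellow
  expect_equal(r[2, 1], 0.4)          # red > 2x green: red-only candidate
  expect_true(is.na(r[2, 2]))         # floored dim pixel flagged
  expect_identical(attr(r, "n_floored"), 1L)
})

test_that("red-only detection finds planted structures in their cells", {
  # pure yellow scene: nothing detected
  res0 <- generate_field(scene_config(image_size = c(128, 128), n_cells = 3,
                                      mitolysosomes_per_cell = 0,
                                      rng_seed = 41))
  an0 <- analyze_field(res0$field,
                       structure(list(w = 1 / 1.5),
                                 class = "channel_weight"))
  expect_identical(nrow(an0$structures), 0L)
  expect_true(all(an0$cells$red_only_area_px == 0))
  # planted structures recovered and assigned to their true cells
  res <- small_scene()
  an <- analyze_field(res$field,
                      structure(list(w = 1 / 1.5), class = "channel_weight"))
  planted <- sum(res$truth$per_cell_truth$n_mitolysosomes)
  expect_gte(nrow(an$structures), 0.9 * planted)
  expect_lte(nrow(an$structures), 1.1 * planted + 1)
  map <- match_cells_to_truth(an$labelmaps, res$truth)
  truth_counts <- res$truth$per_cell_truth$n_mitolysosomes
  meas <- an$cells$n_red_only_structures[map]
  expect_gte(mean(meas == truth_counts), 0.75)
  expect_true(all(an$structures$mean_ratio < 0.5))
  # a uniform structure sitting at ratio 0.6 is above threshold: ignored
  ratio <- matrix(1, 40, 40)
  ratio[10:14, 10:14] <- 0.6
  lm <- list(cells = matrix(1L, 40, 40), mito = matrix(TRUE, 40, 40))
  expect_identical(nrow(detect_red_only_structures(ratio, lm)), 0L)
  ratio[10:14, 10:14] <- 0.4
  expect_identical(nrow(detect_red_only_structures(ratio, lm)), 1L)
})

test_that("per-cell quantification is exact arithmetic with zero-fill", {
  lm <- list(cells = matrix(rep(1:2, each = 200), 20, 20),
             mito = matrix(TRUE, 20, 20))
  st <- data.frame(structure_id = 1:2, cell_id = c(1L, 1L),
                   area_px = c(10L, 15L), mean_ratio = 0.3,
                   integrated_green = NA, integrated_red = NA,
                   centroid_row = 1, centroid_col = 1)
  q <- quantify_per_cell(st, lm)
  expect_equal(q$red_only_area_px, c(25, 0))
  expect_equal(q$n_red_only_structures, c(2L, 0L))
  # unassigned structures are excluded and counted
  st$cell_id[2] <- 0L
  q2 <- quantify_per_cell(st, lm)
  expect_equal(q2$red_only_area_px[1], 10)
  expect_identical(attr(q2, "n_unassigned"), 1L)
  # no structures: all-zero records for every cell
  q3 <- quantify_per_cell(st[0, ], lm)
  expect_identical(nrow(q3), 2L)
  expect_true(all(q3$red_only_area_px == 0))
})

test_that("gain invariance: recalibration cancels any global red rescale", {
  res <- small_scene()
  areas <- lapply(c(0.5, 1, 2), function(g) {
    f <- res$field
    f$red <- f$red * g
    ch <- corrected_channels(f)
    mask <- segment_mito(ch$red, seg_config())
    w <- calibrate_channel_weight(list(ch), list(mask))
    an <- analyze_field(f, w)
    an$cells$red_only_area_px
  })
  for (k in 2:3)
    expect_lt(max(abs(areas[[k]] - areas[[1]])) /
                max(mean(areas[[1]]), 1), 0.01)
})

test_that("object-level integrated-ratio calls match brute force", {
  f <- list(green = matrix(100, 10, 10), red = matrix(100, 10, 10))
  lab <- matrix(0L, 10, 10); lab[2:4, 2:4] <- 1L
  expect_identical(
    classify_objects_by_integrated_ratio(f, lab, 1.0)$class, "yellow")
  f$green[2:4, 2:4] <- 30                       # 0.3 of weighted red
  expect_identical(
    classify_objects_by_integrated_ratio(f, lab, 1.0)$class, "red_only")
  # zero red integral is flagged
  f0 <- list(green = matrix(5, 10, 10), red = matrix(0, 10, 10))
  expect_true(classify_objects_by_integrated_ratio(f0, lab, 1.0)$flagged)
  # random field: every decision equals a per-pixel brute-force recount
  set.seed(5)
  g <- matrix(runif(900, 0, 200), 30, 30)
  r <- matrix(runif(900, 1, 200), 30, 30)
  labs <- matrix(sample(0:6, 900, TRUE), 30, 30)
  out <- classify_objects_by_integrated_ratio(list(green = g, red = r),
                                              labs, 0.8)
  for (k in seq_len(max(labs))) {
    sel <- labs == k
    expected <- sum(g[sel]) / (0.8 * sum(r[sel]))
    expect_equal(out$object_ratio[out$object_id == k], expected)
    expect_identical(out$class[out$object_id == k],
                     if (expected < 0.5) "red_only" else "yellow")
  }
})

test_that("grid quantification samples feasible windows and counts objects", {
  set.seed(17)
  region <- matrix(TRUE, 600, 600)
  objs <- data.frame(row = runif(200, 1, 600), col = runif(200, 1, 600))
  gq <- grid_quantify(objs, region, grid_size = 250, n_grids = 4, seed = 3)
  expect_length(gq$counts, 4)
  expect_true(all(gq$windows$size == 250))
  expect_equal(gq$mean_count, mean(gq$counts))
  # non-overlap of the sampled windows
  w <- gq$windows
  for (i in 1:3) for (j in (i + 1):4)
    expect_true(abs(w$row[i] - w$row[j]) >= 250 ||
                  abs(w$col[i] - w$col[j]) >= 250)
  # density property: over seeds, mean count ~ density x window area
  region2 <- matrix(TRUE, 300, 300)
  objs2 <- data.frame(row = runif(450, 1, 300), col = runif(450, 1, 300))
  means <- vapply(1:25, function(s)
    grid_quantify(objs2, region2, grid_size = 80, n_grids = 4,
                  seed = s)$mean_count, numeric(1))
  expect_lt(abs(mean(means) - 450 * 80^2 / 300^2), 4)
  # infeasible placements error with the feasible count
  expect_error(grid_quantify(objs, matrix(TRUE, 100, 100), grid_size = 250),
               "region too small")
  expect_error(grid_quantify(objs, matrix(TRUE, 300, 300), grid_size = 200,
                             n_grids = 4), "1 non-overlapping")
})

test_that("puncta mitophagy frequency implements the overlap rule", {
  lab <- matrix(0L, 30, 30)
  for (k in 1:10) lab[3 * k - 2, 5] <- k          # 10 single-pixel puncta
  all_green <- matrix(TRUE, 30, 30)
  expect_equal(puncta_mitophagy_frequency(lab, all_green)$pct_mitophagy, 0)
  none_green <- matrix(FALSE, 30, 30)
  none_green[lab > 0 & lab <= 7] <- TRUE          # puncta 8..10 uncovered
  expect_equal(puncta_mitophagy_frequency(lab, none_green)$pct_mitophagy, 30)
  expect_warning(r0 <- puncta_mitophagy_frequency(matrix(0L, 5, 5),
                                                  matrix(TRUE, 5, 5)),
                 "no puncta")
  expect_true(is.na(r0$pct_mitophagy))
  # generated field with 25% planted quench recovered from the images
  pf <- generate_puncta_field(n_puncta = 40, frac_quenched = 0.25, seed = 8)
  gmask <- segment_mito(pmax(pf$green - 100, 0), seg_config())
  est <- puncta_mitophagy_frequency(pf$labels, gmask)$pct_mitophagy
  expect_lt(abs(est - 25), 7.5)
})

test_that("channel intensity ratio is linear and equals the sum loop", {
  set.seed(2)
  g <- matrix(runif(100), 10, 10); r <- matrix(runif(100, 0.5, 1), 10, 10)
  m <- matrix(runif(100) > 0.4, 10, 10)
  expect_equal(channel_intensity_ratio(g, g, m), 1.0)
  expect_equal(channel_intensity_ratio(g / 2, r, m),
               channel_intensity_ratio(g, r, m) / 2)
  expect_equal(channel_intensity_ratio(g, r, m), sum(g[m]) / sum(r[m]))
  expect_warning(v <- channel_intensity_ratio(g, r * 0, m), "undefined")
  expect_true(is.na(v))
  expect_error(channel_intensity_ratio(g, r, m & FALSE), "empty")
})
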
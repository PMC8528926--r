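make_cells <- function(well_id, areas, counts = rep(1L, length(areas)),
                       field = 1L) {
  data.frame(well_id = well_id, field_id = field,
             cell_id = seq_along(areas), red_only_area_px = areas,
             n_red_only_structures = counts, mito_area_px = 100)
}

toy_layout <- function() {
  d <- data.frame(well_id = c("A1", "A2", "B1"),
                  treatment = "DFP",
                  target_gene = c("siNT", "siNT", "TGT"),
                  oligo_id = "pool")
  d
}

test_that("well summaries aggregate exactly and enforce the cell-count QC", {
  layout <- toy_layout()
  cells <- rbind(make_cells("A1", rep(10, 4), field = 1L),
                 make_cells("A1", rep(20, 4), field = 2L),
                 make_cells("A2", rep(12, 8)),
                 make_cells("B1", rep(5, 3)))
  ws <- summarize_wells(cells, layout, qc_min_cells = 4)
  # two fields with means 10 and 20 at equal cell counts: well mean 15
  expect_equal(ws$mean_red_only_area_per_cell[ws$well_id == "A1"], 15)
  expect_equal(ws$n_fields_used[ws$well_id == "A1"], 2)
  # 3 cells < qc_min_cells = 4: flagged
  expect_false(ws$qc_pass[ws$well_id == "B1"])
  expect_true(all(ws$qc_pass[ws$well_id != "B1"]))
  # the screen protocol value is the default
  expect_false(any(summarize_wells(cells, layout)$qc_pass))
  expect_error(summarize_wells(make_cells("Z9", 1), layout),
               "missing from layout")
  # brute-force aggregation oracle on a random table
  set.seed(6)
  rc <- data.frame(well_id = sample(layout$well_id, 300, TRUE),
                   field_id = sample(3, 300, TRUE),
                   red_only_area_px = rpois(300, 20),
                   n_red_only_structures = rpois(300, 2))
  ws2 <- summarize_wells(rc, layout, qc_min_cells = 1)
  for (w in layout$well_id) {
    expect_equal(ws2$mean_red_only_area_per_cell[ws2$well_id == w],
                 mean(rc$red_only_area_px[rc$well_id == w]))
    expect_identical(ws2$n_cells[ws2$well_id == w],
                     sum(rc$well_id == w))
  }
})

test_that("normalization to siNT centres controls at zero and is idempotent", {
  layout <- toy_layout()
  cells <- rbind(make_cells("A1", rep(8, 5)), make_cells("A2", rep(12, 5)),
                 make_cells("B1", rep(4, 5)))
  ws <- summarize_wells(cells, layout, qc_min_cells = 2)
  norm <- normalize_to_controls(ws)
  sint <- norm$target_gene == "siNT"
  expect_equal(mean(norm$centered_effect[sint]), 0)
  # well at 0.4 x the control mean sits at centered effect -0.6
  expect_equal(norm$centered_effect[norm$well_id == "B1"], -0.6)
  # idempotence: renormalizing the normalized statistic keeps controls at 0
  ws2 <- ws
  ws2$mean_red_only_area_per_cell <- norm$fold_change
  norm2 <- normalize_to_controls(ws2)
  expect_equal(mean(norm2$centered_effect[sint]), 0)
  expect_equal(norm2$fold_change, norm$fold_change)
  # missing or zero controls are errors
  ws3 <- ws; ws3$qc_pass[ws3$target_gene == "siNT"] <- FALSE
  expect_error(normalize_to_controls(ws3), "no unflagged")
  ws4 <- ws; ws4$mean_red_only_area_per_cell[sint] <- 0
  expect_error(normalize_to_controls(ws4), "zero")
})

test_that("Dunnett reduces to the t-test at k = 1 and matches its oracle", {
  g <- list(a = c(1.2, 0.8, 1.4, 1.1))
  ctrl <- c(0.9, 1.0, 1.1, 0.7)
  d1 <- dunnett_test(g, ctrl)
  tt <- stats::t.test(g$a, ctrl, var.equal = TRUE)
  expect_lt(abs(d1$p_adj - tt$p.value), 1e-6)
  expect_error(dunnett_test(list(a = 1), ctrl), ">= 2 replicates")
  expect_warning(dz <- dunnett_test(list(a = c(1, 1)), c(1, 1)),
                 "zero pooled variance")
  expect_true(is.na(dz$p_adj))
  # fixed small dataset: adjusted p within 0.005 of an independent
  # raw-data Monte Carlo oracle
  groups <- list(g1 = c(1.5, 1.1, 1.3), g2 = c(0.9, 1.2, 1.0),
                 g3 = c(0.4, 0.7, 0.6))
  ctrl3 <- c(1.0, 0.95, 1.15)
  d <- dunnett_test(groups, ctrl3, B = 2e5, seed = 7)
  # p_adj is monotone decreasing in |t|
  expect_identical(order(d$p_adj), order(-abs(d$t)))
  set.seed(99)
  B <- 2e5
  mx <- replicate(B, {
    x <- matrix(rnorm(12), 3)
    m <- colMeans(x)
    s2 <- sum(sweep(x, 2, m)^2) / 8
    max(abs(m[2:4] - m[1]) / sqrt(s2 * (2 / 3)))
  })
  p_oracle <- vapply(abs(d$t), function(t0) mean(mx >= t0), numeric(1))
  expect_lt(max(abs(d$p_adj - p_oracle)), 0.005)
})

test_that("familywise error stays near alpha under the null (reduced run)", {
  k <- 4; n <- 4; n0 <- 4
  df <- k * n + n0 - k - 1
  nulls <- dunnett_null_sample(rep(n, k), n0, df, B = 1e5, seed = 42)
  crit <- stats::quantile(nulls, 0.95)
  set.seed(1)
  reps <- 3000
  hits <- 0
  for (r in seq_len(reps)) {
    x <- matrix(rnorm((k + 1) * n), n)
    m <- colMeans(x)
    s2 <- sum(sweep(x, 2, m)^2) / df
    tmax <- max(abs(m[2:(k + 1)] - m[1]) / sqrt(s2 * (1 / n + 1 / n0)))
    if (tmax >= crit) hits <- hits + 1
  }
  expect_lt(abs(hits / reps - 0.05), 0.015)
})

test_that("deconvolution hit calling reproduces the 2-of-3 concordance rule", {
  # exhaustive truth table over all 3-oligo outcome combinations
  outcomes <- c("sig_down", "sig_up", "ns")
  combos <- expand.grid(o1 = outcomes, o2 = outcomes, o3 = outcomes,
                        stringsAsFactors = FALSE)
  for (i in seq_len(nrow(combos))) {
    oc <- unlist(combos[i, ])
    eff <- data.frame(target = "T", oligo = paste0("oligo", 1:3),
                      significant = oc != "ns",
                      direction = c(sig_down = "down", sig_up = "up",
                                    ns = "none")[oc])
    hc <- call_hits(eff, tier = "deconvolution")
    expected <- sum(oc == "sig_down") >= 2 || sum(oc == "sig_up") >= 2
    expect_identical(hc$is_hit, expected)
    if (expected)
      expect_identical(hc$supporting_oligos,
                       max(sum(oc == "sig_down"), sum(oc == "sig_up")))
  }
  # spec'd examples: (sig, sig, ns) hits with 2 supporters; discordant not
  two <- call_hits(data.frame(target = "T", oligo = 1:3,
                              significant = c(TRUE, TRUE, FALSE),
                              direction = c("down", "down", "none")))
  expect_true(two$is_hit); expect_identical(two$supporting_oligos, 2L)
  disc <- call_hits(data.frame(target = "T", oligo = 1:3,
                               significant = c(TRUE, TRUE, FALSE),
                               direction = c("down", "up", "none")))
  expect_false(disc$is_hit)
  # partial deconvolution flagged; primary tier needs one significant pool
  part <- call_hits(data.frame(target = "T", oligo = 1:2,
                               significant = c(TRUE, TRUE),
                               direction = "down"))
  expect_true(part$partial)
  prim <- call_hits(data.frame(target = "T", oligo = "pool",
                               significant = TRUE, direction = "down"),
                    tier = "primary")
  expect_true(prim$is_hit)
})

test_that("screen_test compares per-plate target means against siNT", {
  set.seed(4)
  plates <- paste0("P", 1:4)
  mk <- function(target, fold, plate) {
    data.frame(plate = plate, well_id = paste0(target, plate),
               treatment = "DFP", target_gene = target, oligo_id = "pool",
               qc_pass = TRUE, fold_change = fold)
  }
  norm <- do.call(rbind, c(
    lapply(plates, function(p) mk("siNT", rnorm(1, 1, 0.05), p)),
    lapply(plates, function(p) mk("KD", rnorm(1, 0.3, 0.05), p)),
    lapply(plates, function(p) mk("NULL1", rnorm(1, 1, 0.05), p))))
  res <- screen_test(norm, B = 2e4, seed = 2)
  expect_true(res$significant[res$target == "KD"])
  expect_identical(res$direction[res$target == "KD"], "down")
  expect_false(res$significant[res$target == "NULL1"])
  expect_lt(abs(res$mean_centered_effect[res$target == "KD"] - (-0.7)), 0.15)
})
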
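test_that("scene generation is deterministic and validates its config", {
  cfg <- scene_config(image_size = c(96, 96), n_cells = 2, rng_seed = 7)
  expect_identical(generate_field(cfg), generate_field(cfg))
  expect_error(scene_config(image_size = 32), "64")
  expect_error(scene_config(network_density = 1.5), "network_density")
  expect_error(scene_config(channel_gain = 0), "channel_gain")
  expect_error(scene_config(redonly_ratio = -1), "redonly_ratio")
  # too many cells for the frame is a sizing error
  expect_error(generate_field(scene_config(image_size = c(64, 64),
                                           n_cells = 30)),
               "sizing error")
})

test_that("zero mitolysosome rate plants nothing", {
  res <- generate_field(scene_config(image_size = c(96, 96), n_cells = 2,
                                     mitolysosomes_per_cell = 0,
                                     rng_seed = 3))
  expect_identical(sum(res$truth$per_cell_truth$red_only_area_px), 0L)
  expect_identical(max(res$truth$mitolysosome_mask), 0L)
})

test_that("ground truth is internally consistent with the rendered masks", {
  res <- small_scene()
  tr <- res$truth
  # mitolysosomes are red-only: disjoint from the yellow network and nuclei
  expect_identical(sum(tr$mito_mask & tr$mitolysosome_mask > 0), 0L)
  expect_identical(sum(tr$nuclei_mask > 0 & tr$mitolysosome_mask > 0), 0L)
  # per-cell totals equal a recount of the label mask
  for (cid in tr$per_cell_truth$cell_id) {
    in_cell <- tr$mitolysosome_mask[tr$cell_mask == cid]
    expect_identical(length(unique(in_cell[in_cell > 0])),
                     tr$per_cell_truth$n_mitolysosomes[cid])
    expect_identical(sum(in_cell > 0),
                     tr$per_cell_truth$red_only_area_px[cid])
  }
  # every mitolysosome label lies inside exactly one cell
  for (lb in seq_len(max(tr$mitolysosome_mask)))
    expect_length(unique(tr$cell_mask[tr$mitolysosome_mask == lb]), 1L)
  # planted intensities: yellow pixels at green/red ~ 1/gain,
  # mitolysosome pixels at redonly_ratio/gain (checked coarsely on the
  # noisy render, eroded cores only)
  f <- res$field
  cfg <- f$config
  core <- tr$mitolysosome_mask > 0
  g <- f$green[core] - cfg$background_level
  r <- f$red[core] - cfg$background_level
  expect_lt(abs(median(g / r) - cfg$redonly_ratio / cfg$channel_gain), 0.05)
})

test_that("planted Poisson rate is recovered across seeds", {
  rate <- 3
  n_cells <- 8
  n_seeds <- 50
  counts <- vapply(seq_len(n_seeds), function(s) {
    res <- generate_field(scene_config(n_cells = n_cells,
                                       mitolysosomes_per_cell = rate,
                                       rng_seed = 1000 + s))
    mean(res$truth$per_cell_truth$n_mitolysosomes)
  }, numeric(1))
  se <- sqrt(rate / (n_cells * n_seeds))
  # placement rejection can only lose puncta, so allow the 2 SE band plus
  # a small one-sided placement deficit
  expect_lt(abs(mean(counts) - rate), 2 * se + 0.1)
})

test_that("morphology set bookkeeping and class geometry hold", {
  set <- generate_morphology_set(3, c("tubular", "fragmented", "clumped"),
                                 seed = 5,
                                 base_config = scene_config(
                                   image_size = c(128, 128), n_cells = 3))
  expect_length(set, 9)
  expect_identical(as.integer(table(attr(set, "classes"))[c("clumped",
                                                  "fragmented",
                                                  "tubular")]),
                   c(3L, 3L, 3L))
  expect_error(generate_morphology_set(2, c("tubular", "weird")),
               "unknown morphology class")
  comp_areas <- function(entries) {
    unlist(lapply(entries, function(e) {
      lab <- mitoscreen:::.cc_label(e$truth$mito_mask, 8L)
      tabulate(lab[lab > 0], max(lab))
    }))
  }
  frag <- set[attr(set, "classes") == "fragmented"]
  tub <- set[attr(set, "classes") == "tubular"]
  clump <- set[attr(set, "classes") == "clumped"]
  expect_lt(median(comp_areas(frag)), median(comp_areas(tub)))
  # clumped networks are locally denser: higher area / hull-area
  dens <- function(entries) {
    mean(vapply(entries, function(e) {
      ft <- extract_features(e$truth$mito_mask, e$truth$cell_mask)
      mean(ft$network_compactness[!ft$empty])
    }, numeric(1)))
  }
  expect_gt(dens(clump), dens(tub))
})

test_that("plate generation honours the layout and the planted rates", {
  expect_error(plate_design("X", n_sint_wells = 0), "siNT")
  design <- plate_design(targets = "TGT", planted_effect = c(TGT = 0.2),
                         n_fields = 35, treatments = "DFP",
                         n_sint_wells = 1)
  # a 35-field well emits exactly 35 fields (streaming, count only)
  tiny <- scene_config(image_size = c(64, 64), n_cells = 1,
                       mitolysosomes_per_cell = 0.2, rng_seed = 2)
  counted <- generate_plate(design, tiny, dfp_factor = 4,
                            process = function(row, f, field, truth) 1L)
  per_well <- table(vapply(counted$fields, `[[`, "", "well_id"))
  expect_identical(as.integer(per_well), rep(35L, 2))
  # dropping the siNT well is a configuration error
  bad <- design[design$target_gene != "siNT", ]
  class(bad) <- class(design)
  expect_error(generate_plate(bad, tiny), "configuration error")
})

test_that("planted well effects scale ground-truth mitolysosome counts", {
  design <- plate_design(targets = "KD", planted_effect = c(KD = 0.2),
                         n_fields = 12, treatments = "DFP",
                         n_sint_wells = 1)
  base <- scene_config(image_size = c(128, 128), n_cells = 4,
                       mitolysosomes_per_cell = 0.5, rng_seed = 9)
  plate <- generate_plate(design, base, dfp_factor = 6)
  truth <- plate_truth_cells(plate)
  means <- tapply(truth$n_mitolysosomes, truth$well_id, mean)
  sint <- design$well_id[design$target_gene == "siNT"]
  kd <- design$well_id[design$target_gene == "KD"]
  # 0.2 x planted effect with Poisson noise at ~48 cells per well
  expect_lt(abs(means[kd] / means[sint] - 0.2), 0.15)
})

test_that("PPI testbed planted profiles equal an independent recount", {
  tb <- generate_ppi_testbed(30, 80, seed = 4)
  expect_identical(nrow(tb$edges), 80L)
  expect_true(all(tb$edges$a != tb$edges$b))
  expect_false(any(duplicated(paste(pmin(tb$edges$a, tb$edges$b),
                                    pmax(tb$edges$a, tb$edges$b)))))
  # brute-force recount, written independently of the generator internals
  for (g in sample(tb$genes, 8)) {
    nb <- union(tb$edges$b[tb$edges$a == g], tb$edges$a[tb$edges$b == g])
    row <- tb$planted_profiles[tb$planted_profiles$gene == g, ]
    expect_identical(row$n_interactors, length(nb))
    if (length(nb) > 0)
      for (cp in names(tb$annotations))
        expect_equal(row[[cp]], 100 * mean(nb %in% tb$annotations[[cp]]))
  }
  # degenerate cases
  empty <- generate_ppi_testbed(5, 0, seed = 1)
  expect_identical(nrow(empty$edges), 0L)
  expect_true(all(is.na(empty$planted_profiles$mitochondrion)))
  expect_error(generate_ppi_testbed(4, 10), "infeasible")
})

test_that("puncta and section generators plant the stated fractions", {
  pf <- generate_puncta_field(n_puncta = 30, frac_quenched = 0.3, seed = 6)
  expect_identical(sum(pf$truth$quenched), 9L)
  expect_identical(max(pf$labels), 30L)
  sec <- generate_section_field(n_objects = 50, frac_redonly = 0.2,
                                seed = 6)
  expect_identical(sum(sec$truth$red_only), 10L)
  expect_true(all(sec$region_mask[cbind(sec$truth$row, sec$truth$col)]))
})
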
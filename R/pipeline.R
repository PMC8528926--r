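#' Analyze one field end to end
#'
#' Runs the full single-field pipeline: background correction of all
#' channels, nuclei segmentation, cell-territory assignment, mitochondrial
#' masking of the red channel, weighted ratio mapping, red-only structure
#' detection and per-cell quantification.
#'
#' @param field a `field_image` (or list with `nuclei`, `green`, `red`).
#' @param weight a `channel_weight` from [calibrate_channel_weight()].
#' @param seg a [seg_config()].
#' @param cfg a [ratio_config()].
#' @return list: `labelmaps` (`nuclei`, `cells`, `mito`), `ratio_map`,
#'   `structures`, `cells` (per-cell measurements), `corrected`
#'   (background-corrected `green`/`red`).
#' @export
analyze_field <- function(field, weight, seg = seg_config(),
                          cfg = ratio_config()) {
  g <- subtract_background(field$green, seg)
  r <- subtract_background(field$red, seg)
  nuc <- segment_nuclei(field$nuclei, seg)
  cells <- segment_cells(nuc, r, seg)
  mito <- segment_mito(r, seg)
  labelmaps <- list(nuclei = nuc, cells = cells, mito = mito)
  corrected <- list(green = g, red = r)
  ratio <- compute_ratio_map(corrected, weight, cfg)
  st <- detect_red_only_structures(ratio, labelmaps, cfg, corrected)
  list(labelmaps = labelmaps, ratio_map = ratio, structures = st,
       cells = quantify_per_cell(st, labelmaps), corrected = corrected)
}

#' Simulate and score a whole plate
#'
#' Streams over every field of a simulated plate: first calibrates the
#' red-channel weight on the control-arm siNT wells (the non-mitophagy
#' controls), then scores each field with [analyze_field()], keeping only
#' the per-cell tables. The field images are regenerated deterministically
#' in both passes, so nothing needs to stay in memory.
#'
#' @param design a [plate_design()] containing control-arm siNT wells.
#' @param base_config a [scene_config()].
#' @param dfp_factor fold induction of the mitolysosome rate in the DFP arm.
#' @param seg,cfg segmentation and ratio configurations.
#' @param max_calibration_fields cap on the number of fields pooled for
#'   calibration.
#' @return list: `cells` (measured per-cell table with `well_id`,
#'   `field_id`), `truth_cells` (planted per-cell table), `weight`,
#'   `design`.
#' @export
score_sim_plate <- function(design, base_config = scene_config(),
                            dfp_factor = 8, seg = seg_config(),
                            cfg = ratio_config(),
                            max_calibration_fields = 6L) {
  stopifnot(inherits(design, "plate_design"))
  calib_wells <- which(design$target_gene == "siNT" &
                         design$treatment == "control")
  if (length(calib_wells) == 0)
    stop("configuration error: no control-arm siNT wells to calibrate on")
  calib_fields <- list(); calib_masks <- list()
  n_cal <- 0L
  for (w in calib_wells) {
    for (f in seq_len(design$n_fields[w])) {
      if (n_cal >= max_calibration_fields) break
      res <- generate_field(plate_field_cfg(design, base_config,
                                            dfp_factor, w, f))
      g <- subtract_background(res$field$green, seg)
      r <- subtract_background(res$field$red, seg)
      n_cal <- n_cal + 1L
      calib_fields[[n_cal]] <- list(green = g, red = r)
      calib_masks[[n_cal]] <- segment_mito(r, seg)
    }
  }
  weight <- calibrate_channel_weight(calib_fields, calib_masks, cfg,
                                     calibration_wells =
                                       design$well_id[calib_wells])
  cells <- list(); truth <- list(); n <- 0L
  for (w in seq_len(nrow(design))) {
    for (f in seq_len(design$n_fields[w])) {
      res <- generate_field(plate_field_cfg(design, base_config,
                                            dfp_factor, w, f))
      an <- analyze_field(res$field, weight, seg, cfg)
      n <- n + 1L
      cells[[n]] <- cbind(data.frame(well_id = design$well_id[w],
                                     field_id = f), an$cells)
      truth[[n]] <- cbind(data.frame(well_id = design$well_id[w],
                                     field_id = f),
                          res$truth$per_cell_truth)
    }
  }
  list(cells = do.call(rbind, cells), truth_cells = do.call(rbind, truth),
       weight = weight, design = design)
}

# scene configuration for field f of well index w, matching generate_plate()
plate_field_cfg <- function(design, base_config, dfp_factor, w, f) {
  row <- design[w, ]
  cfg <- base_config
  cfg$mitolysosomes_per_cell <- base_config$mitolysosomes_per_cell *
    (if (row$treatment == "DFP") dfp_factor else 1) * row$planted_effect
  cfg$rng_seed <- as.integer((base_config$rng_seed * 7919L + w * 499L + f) %%
                               .Machine$integer.max)
  cfg
}

#' Match measured cells to planted cells of one field
#'
#' Maps every ground-truth cell to the measured cell label whose territory
#' contains the planted nucleus centroid, for per-cell recovery checks.
#'
#' @param labelmaps `labelmaps` from [analyze_field()].
#' @param truth a `ground_truth`.
#' @return integer vector: measured cell label per truth cell id (0 when the
#'   nucleus was not recovered).
#' @export
match_cells_to_truth <- function(labelmaps, truth) {
  st <- label_stats(truth$nuclei_mask)
  vapply(seq_len(nrow(st)), function(k) {
    labelmaps$cells[round(st$centroid_row[k]), round(st$centroid_col[k])]
  }, integer(1))
}
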
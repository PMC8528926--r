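#' Ratio-scoring configuration
#'
#' Parameters of the tandem-tag ratio computation. The dimensionless ratio
#' is `green / (w * red)` with `w` the calibrated red-channel weight: healthy
#' networked mitochondria sit near the yellow reference of 1, and pixels (or
#' objects) below `red_only_threshold` — red at least twice as bright as
#' green at the default 0.5 — are called true red-only structures,
#' i.e. mitolysosomes.
#'
#' @param red_only_threshold call threshold on the weighted ratio
#'   (default 0.5).
#' @param yellow_reference ratio of balanced channels after calibration
#'   (1.0).
#' @param min_structure_area minimum connected red-only component area in
#'   pixels (default 4 at x20 scale).
#' @param pixel_mode `"per_pixel"` (screen imaging) or
#'   `"per_object_integrated"` (object-level filtering of tissue sections).
#' @param weight_estimator `"median_ratio"` (median per-pixel green/red over
#'   control mitochondrial pixels; robust to residual mitophagy in controls)
#'   or `"robust_regression"` (repeated-median slope of green on red).
#' @param intensity_floor_frac pixels whose weighted red signal falls below
#'   this fraction of its 99th percentile are excluded from ratio
#'   classification (guards the division).
#' @return an object of class `ratio_config`.
#' @export
ratio_config <- function(red_only_threshold = 0.5, yellow_reference = 1.0,
                         min_structure_area = 4,
                         pixel_mode = c("per_pixel", "per_object_integrated"),
                         weight_estimator = c("median_ratio",
                                              "robust_regression"),
                         intensity_floor_frac = 0.01) {
  cfg <- list(red_only_threshold = red_only_threshold,
              yellow_reference = yellow_reference,
              min_structure_area = min_structure_area,
              pixel_mode = match.arg(pixel_mode),
              weight_estimator = match.arg(weight_estimator),
              intensity_floor_frac = intensity_floor_frac)
  if (!(cfg$red_only_threshold > 0 &&
        cfg$red_only_threshold < cfg$yellow_reference))
    stop("need 0 < red_only_threshold < yellow_reference")
  class(cfg) <- "ratio_config"
  cfg
}

#' Calibrate the red-channel weight on non-mitophagy controls
#'
#' Estimates the multiplier `w` applied to the red channel so that the
#' central tendency of `green / (w * red)` over mitochondrial pixels of
#' non-mitophagy-inducing control fields equals the yellow reference. With
#' the default median estimator `w` is the median of per-pixel green/red
#' over the pooled control mitochondrial pixels, which makes the weighted
#' median ratio exactly 1.
#'
#' @param control_fields list of fields; each entry is a list with
#'   background-corrected `green` and `red` rasters (a `field_image` works
#'   once corrected).
#' @param mito_masks list of logical masks of mitochondrial signal, parallel
#'   to `control_fields`.
#' @param cfg a [ratio_config()].
#' @param calibration_wells optional well identifiers for the record.
#' @return class `channel_weight`: list with `w`, `n_calibration_pixels`,
#'   `calibration_wells`.
#' @export
calibrate_channel_weight <- function(control_fields, mito_masks,
                                     cfg = ratio_config(),
                                     calibration_wells = NULL) {
  if (!is.null(names(control_fields)) || !is.null(control_fields$green))
    if (!is.null(control_fields$green)) {
      control_fields <- list(control_fields)
      mito_masks <- list(as_mask(mito_masks))
    }
  g <- numeric(0); r <- numeric(0)
  for (k in seq_along(control_fields)) {
    m <- as_mask(mito_masks[[k]])
    g <- c(g, control_fields[[k]]$green[m])
    r <- c(r, control_fields[[k]]$red[m])
  }
  keep <- r > 0
  g <- g[keep]; r <- r[keep]
  if (length(g) == 0) stop("empty calibration mask: no mitochondrial pixels")
  px_ratio <- g / r
  w <- if (cfg$weight_estimator == "median_ratio") {
    stats::median(px_ratio) / cfg$yellow_reference
  } else {
    # repeated-median slope through the origin: median over pixels of g/r
    # after trimming the extreme 5% tails (robust to quenched pixels)
    q <- stats::quantile(px_ratio, c(0.05, 0.95))
    stats::median(px_ratio[px_ratio >= q[1] & px_ratio <= q[2]]) /
      cfg$yellow_reference
  }
  if (w <= 0) stop("calibration produced a non-positive weight")
  # bimodality guard: a heavy mode far below the bright-pixel ratio level
  # suggests mitophagy in the controls (the median itself may already be
  # dragged down, so anchor the check on an upper quantile)
  low <- mean(px_ratio < 0.5 * stats::quantile(px_ratio, 0.9))
  if (low > 0.15)
    warning(sprintf(paste0("%.0f%% of control mitochondrial pixels fall ",
                           "below the red-only threshold after weighting; ",
                           "possible mitophagy in calibration controls"),
                    100 * low))
  structure(list(w = w, n_calibration_pixels = length(g),
                 calibration_wells = calibration_wells),
            class = "channel_weight")
}

#' Per-pixel weighted ratio map
#'
#' Computes `green / (w * red)` per pixel on background-corrected channels.
#' Pixels whose weighted red signal falls below the intensity floor are set
#' to `NA` (flagged via the `"n_floored"` attribute) so that dim background
#' never produces spurious ratio calls.
#'
#' @param field list with background-corrected `green` and `red` rasters.
#' @param weight a [calibrate_channel_weight()] result, or a bare positive
#'   number.
#' @param cfg a [ratio_config()].
#' @return numeric matrix of ratios with attribute `n_floored`.
#' @export
compute_ratio_map <- function(field, weight, cfg = ratio_config()) {
  w <- if (inherits(weight, "channel_weight")) weight$w else as.numeric(weight)
  stopifnot(w > 0)
  wr <- w * field$red
  floor_level <- cfg$intensity_floor_frac *
    stats::quantile(wr, 0.99, names = FALSE)
  ratio <- field$green / wr
  bad <- wr < floor_level | !is.finite(ratio)
  ratio[bad] <- NA_real_
  attr(ratio, "n_floored") <- sum(bad)
  ratio
}

#' Detect red-only structures in a ratio map
#'
#' Connected components (8-connectivity) of mitochondrial-signal pixels with
#' ratio below the red-only threshold, filtered at `min_structure_area` and
#' assigned to cells by majority overlap with the cell label map.
#'
#' @param ratio_map from [compute_ratio_map()].
#' @param labelmaps list with `cells` (integer label matrix) and `mito`
#'   (logical mask of all mitochondrial signal, network plus puncta —
#'   typically segmented from the red channel).
#' @param cfg a [ratio_config()].
#' @param field optional list with `green`/`red` rasters to fill the
#'   integrated intensities of each record.
#' @return data.frame of structure records: `structure_id`, `cell_id`,
#'   `area_px`, `mean_ratio`, `integrated_green`, `integrated_red`,
#'   `centroid_row`, `centroid_col`.
#' @export
detect_red_only_structures <- function(ratio_map, labelmaps,
                                       cfg = ratio_config(), field = NULL) {
  stopifnot(all(dim(ratio_map) == dim(labelmaps$cells)))
  cand <- as_mask(labelmaps$mito) & !is.na(ratio_map) &
    ratio_map < cfg$red_only_threshold
  lab <- .cc_label(cand, 8L)
  lab <- relabel_filtered(lab, cfg$min_structure_area)
  st <- label_stats(lab)
  if (nrow(st) == 0) {
    return(data.frame(structure_id = integer(0), cell_id = integer(0),
                      area_px = integer(0), mean_ratio = numeric(0),
                      integrated_green = numeric(0),
                      integrated_red = numeric(0),
                      centroid_row = numeric(0), centroid_col = numeric(0)))
  }
  pos <- lab > 0L
  lb <- lab[pos]
  cell_of <- vapply(seq_len(nrow(st)), function(k) {
    cl <- labelmaps$cells[lab == k]
    cl <- cl[cl > 0L]
    if (length(cl) == 0) return(0L)
    as.integer(names(which.max(table(cl))))
  }, integer(1))
  mean_ratio <- as.numeric(rowsum(ratio_map[pos], lb)) / st$area_px
  ig <- ir <- rep(NA_real_, nrow(st))
  if (!is.null(field)) {
    ig <- as.numeric(rowsum(field$green[pos], lb))
    ir <- as.numeric(rowsum(field$red[pos], lb))
  }
  data.frame(structure_id = st$label, cell_id = cell_of,
             area_px = st$area_px, mean_ratio = mean_ratio,
             integrated_green = ig, integrated_red = ir,
             centroid_row = st$centroid_row, centroid_col = st$centroid_col)
}

#' Per-cell red-only quantification
#'
#' Sums red-only structure area and counts per cell; every cell present in
#' the label map is reported, with zeros where nothing was detected.
#' Structures that could not be assigned to a cell are excluded and counted
#' in the `n_unassigned` attribute.
#'
#' @param structures data.frame from [detect_red_only_structures()].
#' @param labelmaps list with `cells` label matrix and `mito` mask.
#' @return data.frame: `cell_id`, `red_only_area_px`,
#'   `n_red_only_structures`, `mito_area_px`; attribute `n_unassigned`.
#' @export
quantify_per_cell <- function(structures, labelmaps) {
  n_cells <- max(labelmaps$cells, 0L)
  out <- data.frame(cell_id = seq_len(n_cells),
                    red_only_area_px = 0, n_red_only_structures = 0L,
                    mito_area_px = 0)
  if (n_cells > 0) {
    mito_cells <- labelmaps$cells[as_mask(labelmaps$mito)]
    mito_cells <- mito_cells[mito_cells > 0L]
    ma <- tabulate(mito_cells, n_cells)
    out$mito_area_px <- ma
  }
  unassigned <- 0L
  if (nrow(structures) > 0) {
    ok <- structures$cell_id >= 1 & structures$cell_id <= n_cells
    unassigned <- sum(!ok)
    s <- structures[ok, , drop = FALSE]
    if (nrow(s) > 0) {
      out$red_only_area_px <- out$red_only_area_px +
        as.numeric(tapply(s$area_px, factor(s$cell_id,
                                            levels = seq_len(n_cells)),
                          sum, default = 0))
      out$n_red_only_structures <- out$n_red_only_structures +
        as.integer(table(factor(s$cell_id, levels = seq_len(n_cells))))
    }
  }
  attr(out, "n_unassigned") <- unassigned
  out
}

#' Object-level yellow/red-only classification by integrated intensities
#'
#' For tissue imaging the ratio is computed per mitochondrial structure, not
#' per pixel: each labelled object is scored by the ratio of its integrated
#' green to its weighted integrated red intensity, and filtered as
#' `red_only` when that ratio falls below the threshold.
#'
#' @param field list with background-corrected `green` and `red` rasters.
#' @param object_labels integer label matrix of mitochondrial structures.
#' @param weight a `channel_weight` or bare number.
#' @param cfg a [ratio_config()].
#' @return data.frame: `object_id`, `area_px`, `integrated_green`,
#'   `integrated_red`, `object_ratio`, `class` (`"yellow"`/`"red_only"`),
#'   `flagged` (zero red integral).
#' @export
classify_objects_by_integrated_ratio <- function(field, object_labels,
                                                 weight,
                                                 cfg = ratio_config()) {
  w <- if (inherits(weight, "channel_weight")) weight$w else as.numeric(weight)
  n <- max(object_labels, 0L)
  st <- label_stats(object_labels)
  if (n == 0L) {
    return(data.frame(object_id = integer(0), area_px = integer(0),
                      integrated_green = numeric(0),
                      integrated_red = numeric(0), object_ratio = numeric(0),
                      class = character(0), flagged = logical(0)))
  }
  pos <- object_labels > 0L
  lb <- object_labels[pos]
  ig <- as.numeric(rowsum(field$green[pos], lb))
  ir <- as.numeric(rowsum(field$red[pos], lb))
  ratio <- ig / (w * ir)
  flagged <- ir <= 0
  ratio[flagged] <- NA_real_
  data.frame(object_id = st$label, area_px = st$area_px,
             centroid_row = st$centroid_row, centroid_col = st$centroid_col,
             integrated_green = ig, integrated_red = ir,
             object_ratio = ratio,
             class = ifelse(flagged, NA_character_,
                            ifelse(ratio < cfg$red_only_threshold,
                                   "red_only", "yellow")),
             flagged = flagged)
}

#' Grid-sampled red-only count
#'
#' Samples `n_grids` non-overlapping square windows inside a region of
#' interest and returns the mean number of red-only structures per window —
#' the tissue-section mitophagy readout (default: four grids of 250 x 250
#' pixels). Window placement is uniform over all positions whose window lies
#' entirely inside the region, seed-controlled; the source protocol does not
#' state a placement rule.
#'
#' @param red_only_objects data.frame with `centroid_row`/`centroid_col` (or
#'   `row`/`col`) of red-only structures, or an integer label raster.
#' @param region_mask logical matrix of the region of interest.
#' @param grid_size window side in pixels.
#' @param n_grids number of windows.
#' @param seed integer seed for the placement.
#' @return list: `mean_count`, `counts` per window, `windows` data.frame of
#'   top-left corners.
#' @export
grid_quantify <- function(red_only_objects, region_mask, grid_size = 250L,
                          n_grids = 4L, seed = 1L) {
  region_mask <- as_mask(region_mask)
  H <- nrow(region_mask); W <- ncol(region_mask)
  g <- as.integer(grid_size)
  if (is.matrix(red_only_objects)) {
    st <- label_stats(red_only_objects)
    pts <- cbind(st$centroid_row, st$centroid_col)
  } else {
    rn <- if ("centroid_row" %in% names(red_only_objects)) "centroid_row" else "row"
    cn <- if ("centroid_col" %in% names(red_only_objects)) "centroid_col" else "col"
    pts <- cbind(red_only_objects[[rn]], red_only_objects[[cn]])
  }
  # top-left positions whose g x g window is fully inside the region,
  # via a summed-area table of the region mask
  sat <- apply(apply(region_mask, 2, cumsum), 1, cumsum)  # sat[j, i]!
  sat <- t(sat)
  win_sum <- function(i, j) {  # window rows i..i+g-1, cols j..j+g-1
    a <- sat[i + g - 1, j + g - 1]
    b <- if (i > 1) sat[i - 1, j + g - 1] else 0
    d <- if (j > 1) sat[i + g - 1, j - 1] else 0
    e <- if (i > 1 && j > 1) sat[i - 1, j - 1] else 0
    a - b - d + e
  }
  if (H < g || W < g)
    stop("region too small: no ", g, "x", g, " window fits (0 feasible grids)")
  cand <- which(outer(seq_len(H - g + 1), seq_len(W - g + 1),
                      Vectorize(win_sum)) == g * g, arr.ind = TRUE)
  if (nrow(cand) == 0)
    stop("region too small: no ", g, "x", g,
         " window fits inside the region (0 feasible grids)")
  with_seed(seed, {
    # greedy random placement can deadlock even when a packing exists, so
    # restart with fresh orderings before declaring the region too small
    best <- matrix(numeric(0), 0, 2)
    for (attempt in seq_len(100L)) {
      chosen <- matrix(numeric(0), 0, 2)
      ord <- sample.int(nrow(cand))
      for (k in ord) {
        if (nrow(chosen) == n_grids) break
        ij <- cand[k, ]
        if (nrow(chosen) == 0 ||
            all(abs(chosen[, 1] - ij[1]) >= g |
                  abs(chosen[, 2] - ij[2]) >= g))
          chosen <- rbind(chosen, ij)
      }
      if (nrow(chosen) > nrow(best)) best <- chosen
      if (nrow(best) == n_grids) break
    }
    chosen <- best
    if (nrow(chosen) < n_grids)
      stop("region too small: only ", nrow(chosen),
           " non-overlapping ", g, "x", g, " grids feasible, ", n_grids,
           " requested")
    counts <- vapply(seq_len(nrow(chosen)), function(k) {
      i <- chosen[k, 1]; j <- chosen[k, 2]
      sum(pts[, 1] >= i & pts[, 1] < i + g &
            pts[, 2] >= j & pts[, 2] < j + g)
    }, numeric(1))
    list(mean_count = mean(counts), counts = counts,
         windows = data.frame(row = chosen[, 1], col = chosen[, 2],
                              size = g))
  })
}

#' Puncta-level mitophagy frequency
#'
#' Percentage of red-channel puncta lacking green colocalization — puncta
#' whose overlap with the green mask is below the cutoff — out of all
#' mitochondrial puncta detected. This is the whole-organism readout for
#' discrete-mitochondria tissues.
#'
#' @param red_puncta_labels integer label raster of red puncta.
#' @param green_mask logical mask of green (non-quenched) signal.
#' @param overlap_cutoff a punctum "lacks" colocalization when less than
#'   this fraction of its area overlaps the green mask (default 0.25; the
#'   source protocol states no cutoff).
#' @return list: `pct_mitophagy`, `n_puncta`, `n_lacking`, per-punctum
#'   `overlap` fractions. Zero puncta gives `NA` with a warning.
#' @export
puncta_mitophagy_frequency <- function(red_puncta_labels, green_mask,
                                       overlap_cutoff = 0.25) {
  green_mask <- as_mask(green_mask)
  n <- max(red_puncta_labels, 0L)
  if (n == 0L) {
    warning("no puncta detected: mitophagy frequency undefined")
    return(list(pct_mitophagy = NA_real_, n_puncta = 0L, n_lacking = 0L,
                overlap = numeric(0)))
  }
  pos <- red_puncta_labels > 0L
  lb <- red_puncta_labels[pos]
  area <- tabulate(lb, n)
  ov <- tabulate(lb[green_mask[pos]], n) / pmax(area, 1L)
  lacking <- ov < overlap_cutoff & area > 0
  list(pct_mitophagy = 100 * sum(lacking) / sum(area > 0),
       n_puncta = sum(area > 0), n_lacking = sum(lacking), overlap = ov)
}

#' Integrated channel-intensity ratio over a mask
#'
#' `sum(green) / sum(red)` over the masked pixels — the pH-sensitive to
#' pH-stable whole-tissue ratio readout.
#'
#' @param green_channel,red_channel aligned rasters.
#' @param mask logical matrix selecting the measured region.
#' @return a single ratio; `NA` with a warning when the red integral is 0.
#' @export
channel_intensity_ratio <- function(green_channel, red_channel, mask) {
  mask <- as_mask(mask)
  stopifnot(all(dim(green_channel) == dim(red_channel)),
            all(dim(green_channel) == dim(mask)))
  if (!any(mask)) stop("mask is empty")
  sr <- sum(red_channel[mask])
  if (sr <= 0) {
    warning("zero red integral over mask: ratio undefined")
    return(NA_real_)
  }
  sum(green_channel[mask]) / sr
}
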
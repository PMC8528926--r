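#' Segmentation configuration
#'
#' Parameters for the shared image operations: background correction, nuclei
#' detection, cell-territory assignment and mitochondrial-network masking.
#'
#' @param nuclei_min_area minimum nucleus area in pixels; smaller detections
#'   are discarded as debris.
#' @param nuclei_smoothing_sigma Gaussian sigma (pixels) applied to the
#'   nuclei channel before thresholding.
#' @param mito_threshold_method `"otsu"` or `"fixed"`.
#' @param mito_threshold fixed intensity threshold, used when
#'   `mito_threshold_method = "fixed"`.
#' @param cell_assignment `"nearest_nucleus"` (generalized Voronoi on the
#'   Euclidean distance to nuclei) or `"watershed_on_distance"` (seeded
#'   watershed on the inverse nuclei distance, restricted to foreground then
#'   extended).
#' @param background_method `"rolling_ball"` (grayscale opening with a square
#'   window of half-width `background_radius`), `"median"` (global median) or
#'   `"constant"`.
#' @param background_radius half-width in pixels of the opening window; must
#'   be much larger than the structures of interest.
#' @param background_constant level subtracted when
#'   `background_method = "constant"`; `NULL` means the image minimum.
#' @return an object of class `seg_config`.
#' @export
seg_config <- function(nuclei_min_area = 40,
                       nuclei_smoothing_sigma = 2,
                       mito_threshold_method = c("otsu", "fixed"),
                       mito_threshold = NULL,
                       cell_assignment = c("nearest_nucleus",
                                           "watershed_on_distance"),
                       background_method = c("rolling_ball", "median",
                                             "constant"),
                       background_radius = 25,
                       background_constant = NULL) {
  cfg <- list(
    nuclei_min_area = nuclei_min_area,
    nuclei_smoothing_sigma = nuclei_smoothing_sigma,
    mito_threshold_method = match.arg(mito_threshold_method),
    mito_threshold = mito_threshold,
    cell_assignment = match.arg(cell_assignment),
    background_method = match.arg(background_method),
    background_radius = background_radius,
    background_constant = background_constant)
  if (cfg$nuclei_min_area <= 0 || cfg$background_radius <= 0)
    stop("areas and radii must be positive")
  if (cfg$mito_threshold_method == "fixed" && is.null(cfg$mito_threshold))
    stop("mito_threshold must be given when mito_threshold_method = 'fixed'")
  class(cfg) <- "seg_config"
  cfg
}

#' Background correction
#'
#' Estimates and subtracts the smooth background of a single-channel raster.
#' The default is a grayscale opening (erosion then dilation with a square
#' window) — the flat-structuring-element analogue of rolling-ball background
#' subtraction — followed by a light blur of the background estimate so that
#' window artefacts do not imprint on the residual.
#'
#' @param image nonnegative numeric matrix.
#' @param cfg a [seg_config()].
#' @return corrected raster, clipped at zero.
#' @export
subtract_background <- function(image, cfg = seg_config()) {
  check_raster(image)
  if (any(image < 0, na.rm = TRUE)) stop("image must be nonnegative")
  method <- cfg$background_method
  if (method == "rolling_ball") {
    r <- as.integer(cfg$background_radius)
    if (2L * r + 1L >= min(dim(image)))
      stop("background_radius (", r, ") too large for a ",
           nrow(image), "x", ncol(image), " image")
    bg <- .minmax_filter(.minmax_filter(image, r, FALSE), r, TRUE)
    bg <- .gauss_blur(bg, r / 4)
  } else if (method == "median") {
    bg <- matrix(stats::median(image), nrow(image), ncol(image))
  } else {
    b <- cfg$background_constant %||% min(image)
    bg <- matrix(b, nrow(image), ncol(image))
  }
  pmax(image - bg, 0)
}

#' Nuclei segmentation
#'
#' Smooths the nuclei channel, thresholds it (Otsu), splits touching nuclei
#' with a distance-transform watershed seeded at distance maxima, and removes
#' objects below `nuclei_min_area`.
#'
#' @param nuclei_channel nonnegative raster (e.g. Hoechst/DAPI).
#' @param cfg a [seg_config()].
#' @return integer label matrix; 0 is background, labels are consecutive.
#' @export
segment_nuclei <- function(nuclei_channel, cfg = seg_config()) {
  check_raster(nuclei_channel)
  sm <- .gauss_blur(nuclei_channel, cfg$nuclei_smoothing_sigma)
  if (max(sm) <= 0) return(matrix(0L, nrow(sm), ncol(sm)))
  thr <- otsu_threshold(sm)
  fg <- as_mask(sm > thr)
  if (!any(fg)) return(matrix(0L, nrow(sm), ncol(sm)))
  d <- .edt(!fg)                       # distance to background inside nuclei
  dsm <- .gauss_blur(d, 1)
  # seeds: regional maxima of the smoothed distance map
  mx <- .minmax_filter(dsm, 3L, TRUE)
  seeds_mask <- fg & (dsm >= mx - 1e-9) & (d > 1)
  seeds <- .cc_label(seeds_mask, 8L)
  if (max(seeds) == 0L) seeds <- .cc_label(fg, 8L)
  lab <- .watershed_seeded(-dsm, seeds, fg)
  relabel_filtered(lab, cfg$nuclei_min_area)
}

# drop labels below min_area and renumber 1..n in raster-scan order
relabel_filtered <- function(lab, min_area) {
  n <- max(lab, 0L)
  if (n == 0L) return(lab)
  area <- tabulate(lab[lab > 0L], n)
  keep <- which(area >= min_area)
  map <- integer(n)
  map[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(lab), ncol(lab))
  pos <- lab > 0L
  out[pos] <- map[lab[pos]]
  out
}

#' Cell-territory assignment
#'
#' Assigns every pixel of the field to the cell of one nucleus. With
#' `nearest_nucleus` the frame is partitioned by a generalized Voronoi
#' tessellation (multi-source growth on the Euclidean distance from each
#' nucleus); with `watershed_on_distance` a seeded watershed on the inverse
#' of the cytoplasm-proxy intensity-weighted distance is used. Either way the
#' number of cells equals the number of nuclei and the partition is
#' exhaustive, so downstream per-cell sums are well defined.
#'
#' @param nuclei_labels integer label matrix from [segment_nuclei()].
#' @param cytoplasm_proxy raster whose intensity marks cell material (the red
#'   channel is a good proxy because the mCherry tag persists in all
#'   mitochondrial structures); used only by the watershed mode.
#' @param cfg a [seg_config()].
#' @return integer label matrix with the same labels as `nuclei_labels`.
#' @export
segment_cells <- function(nuclei_labels, cytoplasm_proxy = NULL,
                          cfg = seg_config()) {
  if (max(nuclei_labels, 0L) == 0L)
    return(matrix(0L, nrow(nuclei_labels), ncol(nuclei_labels)))
  all_mask <- matrix(TRUE, nrow(nuclei_labels), ncol(nuclei_labels))
  if (cfg$cell_assignment == "nearest_nucleus" || is.null(cytoplasm_proxy)) {
    d <- .edt(nuclei_labels > 0L)
    .watershed_seeded(d, nuclei_labels, all_mask)
  } else {
    check_raster(cytoplasm_proxy)
    d <- .edt(nuclei_labels > 0L)
    # intensity-aware cost: bright cytoplasm is cheap to claim
    p <- cytoplasm_proxy / max(cytoplasm_proxy, 1e-9)
    .watershed_seeded(d * (1.2 - p), nuclei_labels, all_mask)
  }
}

#' Mitochondrial-signal mask
#'
#' Thresholds a background-corrected channel into a binary mask of
#' mitochondrial material (network plus red-only puncta when applied to the
#' red channel).
#'
#' @param channel background-corrected raster.
#' @param cfg a [seg_config()]; `mito_threshold_method` selects Otsu or a
#'   fixed threshold.
#' @return logical matrix.
#' @export
segment_mito <- function(channel, cfg = seg_config()) {
  check_raster(channel)
  if (cfg$mito_threshold_method == "fixed") {
    return(as_mask(channel > cfg$mito_threshold))
  }
  if (max(channel) <= 0) {
    warning("all-zero channel: empty mitochondrial mask")
    return(matrix(FALSE, nrow(channel), ncol(channel)))
  }
  as_mask(channel > otsu_threshold(channel))
}

#' Manders colocalization coefficient
#'
#' Fraction of the integrated intensity of a channel, within its own mask,
#' that lies inside a second mask: `sum(A over mask_a & mask_b) / sum(A over
#' mask_a)`. Invariant to global rescaling of the channel.
#'
#' @param channel_a intensity raster of the measured channel.
#' @param mask_b logical matrix of the reference compartment.
#' @param mask_a logical matrix defining where channel A signal lives.
#' @return a single number in `[0, 1]`, or `NA` with a warning when the
#'   channel carries no intensity inside `mask_a`.
#' @export
manders_coefficient <- function(channel_a, mask_b, mask_a) {
  check_raster(channel_a)
  mask_a <- as_mask(mask_a); mask_b <- as_mask(mask_b)
  stopifnot(all(dim(channel_a) == dim(mask_a)),
            all(dim(channel_a) == dim(mask_b)))
  denom <- sum(channel_a[mask_a])
  if (denom <= 0) {
    warning("no channel intensity inside mask_a: Manders undefined")
    return(NA_real_)
  }
  sum(channel_a[mask_a & mask_b]) / denom
}
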
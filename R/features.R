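#' Per-cell mitochondrial morphology features
#'
#' Shape statistics of the mitochondrial network of each cell, computed
#' from a binary mitochondrial mask and a cell label map: component count
#' and areas, mean form factor (4*pi*area/perimeter^2, 1 for a disc),
#' mean eccentricity and solidity, skeleton length per unit network area,
#' the fraction of the network in its largest component and the compactness
#' of the whole network (area over convex-hull area). These are the
#' standard high-content shape features that separate fragmented from
#' tubular networks.
#'
#' @param mito_mask logical matrix of mitochondrial signal.
#' @param cells integer cell label matrix; pass a single-cell mask's
#'   all-ones labels to featurize one mask.
#' @return data.frame, one row per cell: `cell_id`, `n_components`,
#'   `mean_component_area`, `median_component_area`, `total_area`,
#'   `form_factor`, `eccentricity`, `solidity`,
#'   `skeleton_length_per_area`, `largest_component_fraction`,
#'   `network_compactness`, `empty` (flag for cells without network).
#' @export
extract_features <- function(mito_mask, cells = NULL) {
  mito_mask <- as_mask(mito_mask)
  if (is.null(cells)) {
    cells <- matrix(1L, nrow(mito_mask), ncol(mito_mask))
  }
  n_cells <- max(cells, 0L)
  rows <- lapply(seq_len(n_cells), function(k)
    mask_features(mito_mask & cells == k, k))
  do.call(rbind, rows)
}

feature_names <- function() {
  c("n_components", "mean_component_area", "median_component_area",
    "total_area", "form_factor", "eccentricity", "solidity",
    "skeleton_length_per_area", "largest_component_fraction",
    "network_compactness")
}

mask_features <- function(m, cell_id = 1L) {
  zero <- data.frame(cell_id = cell_id, n_components = 0L,
                     mean_component_area = 0, median_component_area = 0,
                     total_area = 0, form_factor = 0, eccentricity = 0,
                     solidity = 0, skeleton_length_per_area = 0,
                     largest_component_fraction = 0,
                     network_compactness = 0, empty = TRUE)
  if (!any(m)) return(zero)
  lab <- .cc_label(m, 8L)
  nc <- max(lab)
  areas <- tabulate(lab[lab > 0L], nc)
  ff <- ecc <- sol <- numeric(nc)
  for (k in seq_len(nc)) {
    idx <- which(lab == k, arr.ind = TRUE)
    # crop to the component's bounding box before geometry
    sub <- lab[min(idx[, 1]):max(idx[, 1]),
               min(idx[, 2]):max(idx[, 2]), drop = FALSE] == k
    per <- crofton_perimeter(sub)
    ff[k] <- if (per > 0) min(1, 4 * pi * areas[k] / per^2) else 1
    ecc[k] <- mask_eccentricity(idx)
    ha <- hull_area(sub)
    sol[k] <- if (ha > 0) min(1, areas[k] / ha) else 1
  }
  total <- sum(areas)
  skel <- sum(.thin_mask(m))
  hull_all <- hull_area(m)
  data.frame(cell_id = cell_id, n_components = nc,
             mean_component_area = mean(areas),
             median_component_area = stats::median(areas),
             total_area = total, form_factor = mean(ff),
             eccentricity = mean(ecc), solidity = mean(sol),
             skeleton_length_per_area = skel / total,
             largest_component_fraction = max(areas) / total,
             network_compactness = if (hull_all > 0)
               min(1, total / hull_all) else 1,
             empty = FALSE)
}

# eccentricity of the best-fit ellipse from central second moments
mask_eccentricity <- function(idx) {
  if (nrow(idx) < 2) return(0)
  r <- idx[, 1] - mean(idx[, 1]); c <- idx[, 2] - mean(idx[, 2])
  mu20 <- mean(r^2); mu02 <- mean(c^2); mu11 <- mean(r * c)
  disc <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  l1 <- (mu20 + mu02 + disc) / 2
  l2 <- (mu20 + mu02 - disc) / 2
  if (l1 <= 0) return(0)
  sqrt(max(0, 1 - l2 / l1))
}

#' Featurize a labelled morphology image set
#'
#' Convenience path from [generate_morphology_set()] output (or any list of
#' field/truth pairs) to a per-cell feature table: segments the green
#' channel of each field, intersects it with the ground-truth cell
#' territories, and extracts features per cell with the class label
#' attached.
#'
#' @param set list of entries with `field`, `truth` and `class`.
#' @param seg a [seg_config()].
#' @param use_truth_masks use the planted network masks instead of
#'   segmenting the rendered green channel (noise-free upper bound).
#' @return data.frame of per-cell features with a `class` column.
#' @export
featurize_morphology_set <- function(set, seg = seg_config(),
                                     use_truth_masks = FALSE) {
  rows <- lapply(seq_along(set), function(i) {
    e <- set[[i]]
    mask <- if (use_truth_masks) {
      e$truth$mito_mask
    } else {
      segment_mito(subtract_background(e$field$green, seg), seg)
    }
    ft <- extract_features(mask, e$truth$cell_mask)
    ft$class <- e$class
    ft$field <- i
    ft
  })
  out <- do.call(rbind, rows)
  out[!out$empty, , drop = FALSE]
}
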
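#' Scene configuration for the synthetic tandem-tag generator
#'
#' Describes one simulated field of reporter cells: a yellow (dual-channel)
#' mitochondrial network per cell plus red-only mitolysosome puncta whose
#' EGFP signal is quenched, imaged with channel-gain imbalance, background,
#' a Gaussian point-spread blur, and shot/read noise.
#'
#' @param image_size integer `c(H, W)`, at least 64 x 64.
#' @param n_cells number of cells to place.
#' @param mitolysosomes_per_cell Poisson rate of red-only puncta per cell.
#' @param mito_morphology `"tubular"`, `"fragmented"` or `"clumped"`.
#' @param network_density fraction of the cell territory covered by the
#'   mitochondrial network (0..1).
#' @param redonly_ratio green/red intensity ratio planted inside
#'   mitolysosomes before gain; must be below the yellow ratio of 1. The
#'   default 0.2 models the quench of EGFP at lysosomal pH as a single
#'   multiplicative drop.
#' @param channel_gain multiplier applied to the red channel at "acquisition";
#'   deliberately not 1 by default so that channel-weight calibration is
#'   always exercised.
#' @param background_level additive background intensity (camera offset plus
#'   diffuse signal).
#' @param psf_sigma Gaussian point-spread sigma in pixels.
#' @param noise_model `"poisson"`, `"gaussian"` or `"both"`.
#' @param rng_seed integer seed; identical configuration and seed give a
#'   bit-identical scene.
#' @param cell_radius,nucleus_radius geometry of the simulated cells (px).
#' @param base_intensity mean signal intensity of mitochondrial pixels.
#' @param read_noise_sd standard deviation of the additive Gaussian read
#'   noise.
#' @return an object of class `scene_config`.
#' @export
scene_config <- function(image_size = c(192L, 192L),
                         n_cells = 6,
                         mitolysosomes_per_cell = 2,
                         mito_morphology = c("tubular", "fragmented",
                                             "clumped"),
                         network_density = 0.15,
                         redonly_ratio = 0.2,
                         channel_gain = 1.5,
                         background_level = 120,
                         psf_sigma = 0.8,
                         noise_model = c("both", "poisson", "gaussian"),
                         rng_seed = 1L,
                         cell_radius = 24,
                         nucleus_radius = 6,
                         base_intensity = 2000,
                         read_noise_sd = 15) {
  image_size <- rep(as.integer(image_size), length.out = 2)
  cfg <- list(image_size = image_size, n_cells = as.integer(n_cells),
              mitolysosomes_per_cell = mitolysosomes_per_cell,
              mito_morphology = match.arg(mito_morphology),
              network_density = network_density,
              redonly_ratio = redonly_ratio, channel_gain = channel_gain,
              background_level = background_level, psf_sigma = psf_sigma,
              noise_model = match.arg(noise_model),
              rng_seed = as.integer(rng_seed),
              cell_radius = cell_radius, nucleus_radius = nucleus_radius,
              base_intensity = base_intensity, read_noise_sd = read_noise_sd)
  if (any(cfg$image_size < 64L)) stop("image_size must be at least 64 x 64")
  if (cfg$network_density < 0 || cfg$network_density > 1)
    stop("network_density must lie in [0, 1]")
  if (cfg$redonly_ratio < 0) stop("redonly_ratio must be nonnegative")
  if (cfg$channel_gain <= 0) stop("channel_gain must be positive")
  if (cfg$mitolysosomes_per_cell < 0)
    stop("mitolysosomes_per_cell must be nonnegative")
  class(cfg) <- "scene_config"
  cfg
}

# evaluate expr under a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

place_cell_centres <- function(H, W, n, r) {
  margin <- ceiling(r * 0.75)
  min_sep <- 1.35 * r
  centres <- matrix(numeric(0), 0, 2)
  tries <- 0L
  while (nrow(centres) < n) {
    tries <- tries + 1L
    if (tries > 400L * n)
      stop("sizing error: cannot place ", n, " cells of radius ", r,
           " in a ", H, "x", W, " image")
    cand <- c(stats::runif(1, margin, H - margin),
              stats::runif(1, margin, W - margin))
    if (nrow(centres) == 0 ||
        min(sqrt((centres[, 1] - cand[1])^2 + (centres[, 2] - cand[2])^2)) >
          min_sep)
      centres <- rbind(centres, cand)
  }
  centres
}

# Voronoi cell territories truncated at cell_radius around each centre
cell_territories <- function(H, W, centres, r) {
  lab <- matrix(0L, H, W)
  best <- matrix(Inf, H, W)
  for (k in seq_len(nrow(centres))) {
    ri <- max(1, floor(centres[k, 1] - r)):min(H, ceiling(centres[k, 1] + r))
    ci <- max(1, floor(centres[k, 2] - r)):min(W, ceiling(centres[k, 2] + r))
    d <- outer((ri - centres[k, 1])^2, (ci - centres[k, 2])^2, `+`)
    sel <- d <= r^2 & d < best[ri, ci]
    sub_lab <- lab[ri, ci]; sub_best <- best[ri, ci]
    sub_lab[sel] <- k; sub_best[sel] <- d[sel]
    lab[ri, ci] <- sub_lab; best[ri, ci] <- sub_best
  }
  lab
}

# draw the mitochondrial network of one cell into `mask` (TRUE pixels);
# returns the updated mask. Morphology archetypes: tubular = dilated
# persistent random walks; fragmented = scattered small discs/ellipses;
# clumped = fragments packed near the nucleus.
draw_network <- function(mask, centre, r_cell, r_nuc, morphology, density) {
  target_area <- density * pi * r_cell^2
  H <- nrow(mask); W <- ncol(mask)
  if (morphology == "tubular") {
    n_branch <- 3L
    steps <- max(12L, round(target_area / (2.6 * n_branch)))
    for (b in seq_len(n_branch)) {
      ang <- stats::runif(1, 0, 2 * pi)
      pos <- centre + (r_nuc + 2) * c(cos(ang), sin(ang))
      pts_r <- numeric(steps); pts_c <- numeric(steps)
      for (s in seq_len(steps)) {
        ang <- ang + stats::rnorm(1, 0, 0.35)
        pos <- pos + c(cos(ang), sin(ang))
        # reflect back toward the centre at the cell boundary
        if (sum((pos - centre)^2) > (0.92 * r_cell)^2) {
          ang <- atan2(centre[2] - pos[2], centre[1] - pos[1]) +
            stats::rnorm(1, 0, 0.3)
          pos <- pos + 2 * c(cos(ang), sin(ang))
        }
        pts_r[s] <- pos[1]; pts_c[s] <- pos[2]
      }
      mask <- stamp_discs(mask, round(pts_r), round(pts_c), 1.2)
    }
  } else {
    frag_r_range <- c(1.4, 2.4)
    mean_area <- pi * mean(frag_r_range)^2
    n_frag <- max(4L, round(target_area / mean_area))
    spread <- if (morphology == "clumped") 0.35 * r_cell else 0.85 * r_cell
    ang <- stats::runif(n_frag, 0, 2 * pi)
    rad <- r_nuc + 1 + sqrt(stats::runif(n_frag)) * pmax(spread - r_nuc, 2)
    rows <- round(centre[1] + rad * cos(ang))
    cols <- round(centre[2] + rad * sin(ang))
    for (k in seq_len(n_frag))
      mask <- stamp_discs(mask, rows[k], cols[k],
                          stats::runif(1, frag_r_range[1], frag_r_range[2]))
  }
  mask
}

#' Generate one synthetic tandem-tag field with ground truth
#'
#' Renders nuclei, green (EGFP) and red (mCherry) channel rasters for a field
#' of reporter cells. Yellow network pixels are planted with green/red equal
#' to `1 / channel_gain` before calibration; mitolysosome pixels with
#' `redonly_ratio / channel_gain`. The companion ground truth carries label
#' masks and a per-cell table of planted mitolysosome counts, red-only areas
#' and the morphology class.
#'
#' @param config a [scene_config()].
#' @return a list with elements `field` (class `field_image`: `nuclei`,
#'   `green`, `red` rasters plus `config`) and `truth` (class `ground_truth`:
#'   `nuclei_mask`, `cell_mask`, `mito_mask`, `mitolysosome_mask`,
#'   `per_cell_truth`).
#' @export
generate_field <- function(config = scene_config()) {
  stopifnot(inherits(config, "scene_config"))
  with_seed(config$rng_seed, {
    H <- config$image_size[1]; W <- config$image_size[2]
    centres <- place_cell_centres(H, W, config$n_cells, config$cell_radius)
    cells <- cell_territories(H, W, centres, config$cell_radius)
    nuc <- matrix(0L, H, W)
    for (k in seq_len(nrow(centres))) {
      m <- stamp_discs(matrix(FALSE, H, W), round(centres[k, 1]),
                       round(centres[k, 2]), config$nucleus_radius)
      nuc[m] <- k
    }
    mito <- matrix(FALSE, H, W)
    for (k in seq_len(nrow(centres)))
      mito <- draw_network(mito, centres[k, ], config$cell_radius,
                           config$nucleus_radius, config$mito_morphology,
                           config$network_density)
    mito <- mito & nuc == 0L           # network excludes the nucleus proper

    # red-only mitolysosome puncta: planted per cell, disjoint from the
    # yellow network and from each other
    lyso <- matrix(0L, H, W)
    n_planted <- integer(config$n_cells)
    area_planted <- integer(config$n_cells)
    next_label <- 0L
    for (k in seq_len(nrow(centres))) {
      n_k <- stats::rpois(1, config$mitolysosomes_per_cell)
      placed <- 0L
      tries <- 0L
      while (placed < n_k && tries < 60L * max(n_k, 1L)) {
        tries <- tries + 1L
        ang <- stats::runif(1, 0, 2 * pi)
        rad <- config$nucleus_radius + 2 +
          sqrt(stats::runif(1)) * (0.8 * config$cell_radius -
                                     config$nucleus_radius - 3)
        pr <- round(centres[k, 1] + rad * cos(ang))
        pc <- round(centres[k, 2] + rad * sin(ang))
        prad <- stats::runif(1, 1.8, 2.6)
        pm <- stamp_discs(matrix(FALSE, H, W), pr, pc, prad)
        # a 2 px guard ring keeps puncta resolvable after the PSF blur,
        # so planted counts stay recoverable as distinct components
        pm_guard <- stamp_discs(matrix(FALSE, H, W), pr, pc, prad + 2)
        if (!any(pm)) next
        if (any(mito[pm_guard]) || any(lyso[pm_guard] > 0L) ||
            any(nuc[pm] > 0L)) next
        if (any(cells[pm] != k)) next  # keep the punctum inside its cell
        next_label <- next_label + 1L
        lyso[pm] <- next_label
        placed <- placed + 1L
        area_planted[k] <- area_planted[k] + sum(pm)
      }
      n_planted[k] <- placed
    }

    # photon image: per-cell brightness jitter, quench inside mitolysosomes
    A <- config$base_intensity
    bright <- stats::runif(config$n_cells, 0.8, 1.2)
    green <- matrix(0, H, W); red0 <- matrix(0, H, W)
    mito_cells <- cells; mito_cells[!mito] <- 0L
    gm <- mito & mito_cells > 0L
    green[gm] <- A * bright[mito_cells[gm]]
    red0[gm] <- green[gm]
    lm <- lyso > 0L
    lyso_cells <- cells; lyso_cells[!lm] <- 0L
    amp <- A * ifelse(lyso_cells[lm] > 0L, bright[pmax(lyso_cells[lm], 1L)], 1)
    green[lm] <- config$redonly_ratio * amp
    red0[lm] <- amp
    nuclei_ch <- matrix(0, H, W)
    nuclei_ch[nuc > 0L] <- 1500

    render <- function(photons, gain = 1) {
      img <- .gauss_blur(photons * gain, config$psf_sigma) +
        config$background_level
      if (config$noise_model %in% c("poisson", "both"))
        img <- matrix(stats::rpois(length(img), pmax(img, 0)), H, W)
      if (config$noise_model %in% c("gaussian", "both"))
        img <- img + matrix(stats::rnorm(length(img), 0,
                                         config$read_noise_sd), H, W)
      matrix(pmin(pmax(round(img), 0), 65535), H, W)
    }

    field <- structure(list(nuclei = render(nuclei_ch),
                            green = render(green),
                            red = render(red0, config$channel_gain),
                            config = config),
                       class = "field_image")
    truth <- structure(list(
      nuclei_mask = nuc, cell_mask = cells, mito_mask = mito,
      mitolysosome_mask = lyso,
      per_cell_truth = data.frame(
        cell_id = seq_len(config$n_cells),
        n_mitolysosomes = n_planted,
        red_only_area_px = area_planted,
        morphology_class = config$mito_morphology)),
      class = "ground_truth")
    list(field = field, truth = truth)
  })
}

#' Generate a labelled morphology image set
#'
#' Produces `n_per_class` fields for each requested morphology class, with
#' the class recorded in every field's ground truth. Tubular scenes are long
#' thin curvilinear networks, fragmented scenes many small compact
#' components, clumped scenes fragments packed around the nucleus.
#'
#' @param n_per_class fields per class.
#' @param classes subset of `c("tubular", "fragmented", "clumped")`.
#' @param seed integer seed for the whole set.
#' @param base_config [scene_config()] supplying everything but morphology
#'   and seed.
#' @return a list of `generate_field()` results, each with a `class` element;
#'   attribute `classes` gives the label per entry.
#' @export
generate_morphology_set <- function(n_per_class, classes = c("tubular",
                                                             "fragmented"),
                                    seed = 1L,
                                    base_config = scene_config()) {
  known <- c("tubular", "fragmented", "clumped")
  if (!all(classes %in% known))
    stop("unknown morphology class: ",
         paste(setdiff(classes, known), collapse = ", "))
  out <- list()
  labels <- character(0)
  k <- 0L
  for (cl in classes) {
    for (i in seq_len(n_per_class)) {
      k <- k + 1L
      cfg <- base_config
      cfg$mito_morphology <- cl
      cfg$mitolysosomes_per_cell <- 0  # morphology sets are mitophagy-free
      cfg$rng_seed <- as.integer((seed * 1009L + k * 131L) %% .Machine$integer.max)
      res <- generate_field(cfg)
      res$class <- cl
      out[[k]] <- res
      labels[k] <- cl
    }
  }
  attr(out, "classes") <- labels
  out
}
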
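#' Puncta field with a planted quenched fraction
#'
#' Simulates a field of discrete mitochondrial puncta such as body-wall
#' muscle mitochondria carrying a dual green/red reporter: a chosen fraction
#' of puncta are acidified, i.e. their green signal is quenched while the
#' pH-stable red signal persists. Used to exercise the puncta-level
#' mitophagy-frequency readout.
#'
#' @param n_puncta number of puncta.
#' @param frac_quenched fraction (0..1) planted as red-only; the planted
#'   count is `round(frac_quenched * n_puncta)`.
#' @param image_size integer `c(H, W)`.
#' @param seed integer seed.
#' @param redonly_ratio green/red ratio inside quenched puncta.
#' @param base_intensity,background_level,psf_sigma,read_noise_sd rendering
#'   parameters as in [scene_config()].
#' @return list: `green`, `red` rasters, `labels` (punctum label raster) and
#'   `truth` data.frame (`punctum_id`, `quenched`, `row`, `col`).
#' @export
generate_puncta_field <- function(n_puncta = 40, frac_quenched = 0.25,
                                  image_size = c(160L, 160L), seed = 1L,
                                  redonly_ratio = 0.2,
                                  base_intensity = 2000,
                                  background_level = 100, psf_sigma = 0.7,
                                  read_noise_sd = 10) {
  H <- image_size[1]; W <- image_size[2]
  with_seed(seed, {
    centres <- matrix(numeric(0), 0, 2)
    tries <- 0L
    while (nrow(centres) < n_puncta) {
      tries <- tries + 1L
      if (tries > 500L * n_puncta)
        stop("sizing error: cannot place ", n_puncta, " puncta in ",
             H, "x", W)
      cand <- c(stats::runif(1, 5, H - 5), stats::runif(1, 5, W - 5))
      if (nrow(centres) == 0 ||
          min((centres[, 1] - cand[1])^2 + (centres[, 2] - cand[2])^2) > 8^2)
        centres <- rbind(centres, cand)
    }
    labels <- matrix(0L, H, W)
    for (k in seq_len(n_puncta)) {
      m <- stamp_discs(matrix(FALSE, H, W), round(centres[k, 1]),
                       round(centres[k, 2]), stats::runif(1, 1.8, 2.6))
      labels[m & labels == 0L] <- k
    }
    n_q <- round(frac_quenched * n_puncta)
    quenched <- rep(FALSE, n_puncta)
    if (n_q > 0) quenched[sample.int(n_puncta, n_q)] <- TRUE
    green <- matrix(0, H, W); red <- matrix(0, H, W)
    on <- labels > 0L
    red[on] <- base_intensity
    green[on] <- base_intensity *
      ifelse(quenched[labels[on]], redonly_ratio, 1)
    render <- function(x) {
      img <- .gauss_blur(x, psf_sigma) + background_level
      img <- matrix(stats::rpois(length(img), pmax(img, 0)), H, W) +
        matrix(stats::rnorm(length(img), 0, read_noise_sd), H, W)
      matrix(pmin(pmax(round(img), 0), 65535), H, W)
    }
    list(green = render(green), red = render(red), labels = labels,
         truth = data.frame(punctum_id = seq_len(n_puncta),
                            quenched = quenched,
                            row = round(centres[, 1]),
                            col = round(centres[, 2])))
  })
}

#' Tissue-section-like object field
#'
#' Emulates a cryosection of reporter tissue: an elliptical region of
#' interest scattered with discrete mitochondrial structures, a fraction of
#' which are red-only. Intended for the object-level integrated-ratio filter
#' and the grid-sampling readout.
#'
#' @param image_size integer `c(H, W)`; make it large enough for the grid
#'   windows you intend to sample.
#' @param n_objects number of structures inside the region.
#' @param frac_redonly fraction planted as red-only.
#' @param seed integer seed.
#' @param redonly_ratio,base_intensity,background_level,psf_sigma
#'   rendering parameters as elsewhere.
#' @return list: `green`, `red`, `labels`, `region_mask`, `truth`
#'   data.frame (`object_id`, `red_only`, `row`, `col`).
#' @export
generate_section_field <- function(image_size = c(320L, 320L),
                                   n_objects = 120, frac_redonly = 0.3,
                                   seed = 1L, redonly_ratio = 0.2,
                                   base_intensity = 2000,
                                   background_level = 100, psf_sigma = 0.7) {
  H <- image_size[1]; W <- image_size[2]
  with_seed(seed, {
    rr <- matrix(rep(seq_len(H), W), H, W)
    cc <- matrix(rep(seq_len(W), each = H), H, W)
    region <- ((rr - H / 2) / (0.45 * H))^2 + ((cc - W / 2) / (0.45 * W))^2 <= 1
    centres <- matrix(numeric(0), 0, 2)
    tries <- 0L
    while (nrow(centres) < n_objects) {
      tries <- tries + 1L
      if (tries > 500L * n_objects)
        stop("sizing error: region too small for ", n_objects, " objects")
      cand <- c(stats::runif(1, 4, H - 4), stats::runif(1, 4, W - 4))
      if (!region[round(cand[1]), round(cand[2])]) next
      if (nrow(centres) == 0 ||
          min((centres[, 1] - cand[1])^2 + (centres[, 2] - cand[2])^2) > 7^2)
        centres <- rbind(centres, cand)
    }
    labels <- matrix(0L, H, W)
    for (k in seq_len(n_objects)) {
      m <- stamp_discs(matrix(FALSE, H, W), round(centres[k, 1]),
                       round(centres[k, 2]), stats::runif(1, 1.6, 2.6))
      labels[m & labels == 0L] <- k
    }
    n_r <- round(frac_redonly * n_objects)
    red_only <- rep(FALSE, n_objects)
    if (n_r > 0) red_only[sample.int(n_objects, n_r)] <- TRUE
    green <- matrix(0, H, W); red <- matrix(0, H, W)
    on <- labels > 0L
    red[on] <- base_intensity
    green[on] <- base_intensity * ifelse(red_only[labels[on]],
                                         redonly_ratio, 1)
    render <- function(x) {
      img <- .gauss_blur(x, psf_sigma) + background_level
      img <- matrix(stats::rpois(length(img), pmax(img, 0)), H, W)
      matrix(pmin(pmax(round(img), 0), 65535), H, W)
    }
    list(green = render(green), red = render(red), labels = labels,
         region_mask = region,
         truth = data.frame(object_id = seq_len(n_objects),
                            red_only = red_only,
                            row = round(centres[, 1]),
                            col = round(centres[, 2])))
  })
}
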
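#' Plate layout with planted effects
#'
#' Builds the well table of a simulated siRNA screen plate: non-targeting
#' (siNT) control wells plus one well per target (or per target x oligo in a
#' deconvolution layout), each with a multiplicative planted effect on the
#' mitolysosome rate. Mirrors the screened design of pooled-oligo wells
#' normalised against siNT controls under control and mitophagy-inducing
#' (DFP) arms.
#'
#' @param targets character vector of target genes.
#' @param planted_effect named numeric vector (per target) or, for
#'   deconvolution layouts, a named list of per-oligo effect vectors.
#'   Effects are multiplicative on the mitolysosome rate and must be > 0.
#' @param n_fields imaged fields per well; the screen itself used 35 fields
#'   of view per well, simulations typically scale this down.
#' @param treatments arms to lay out; the DFP arm carries induced mitophagy.
#' @param n_sint_wells siNT control wells per arm (>= 1).
#' @param n_oligos oligos per target; 1 means a pooled-siRNA well.
#' @return data.frame of class `plate_design` with columns `well_id`,
#'   `treatment`, `target_gene`, `oligo_id`, `planted_effect`, `n_fields`.
#' @export
plate_design <- function(targets,
                         planted_effect = stats::setNames(rep(1, length(targets)),
                                                          targets),
                         n_fields = 10L,
                         treatments = c("control", "DFP"),
                         n_sint_wells = 3L,
                         n_oligos = 1L) {
  if (n_sint_wells < 1L) stop("configuration error: need >= 1 siNT well per arm")
  rows <- list()
  wid <- 0L
  for (tr in treatments) {
    for (s in seq_len(n_sint_wells)) {
      wid <- wid + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        well_id = sprintf("W%03d", wid), treatment = tr,
        target_gene = "siNT", oligo_id = "pool", planted_effect = 1,
        n_fields = as.integer(n_fields))
    }
    for (tg in targets) {
      for (o in seq_len(n_oligos)) {
        eff <- if (is.list(planted_effect)) planted_effect[[tg]][o]
               else planted_effect[[tg]]
        if (is.null(eff) || is.na(eff) || eff <= 0)
          stop("planted_effect must be > 0 for target ", tg)
        wid <- wid + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          well_id = sprintf("W%03d", wid), treatment = tr, target_gene = tg,
          oligo_id = if (n_oligos == 1L) "pool" else sprintf("oligo%d", o),
          planted_effect = eff, n_fields = as.integer(n_fields))
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("plate_design", "data.frame")
  out
}

#' Simulate a screen plate field by field
#'
#' Renders every field of every well of a [plate_design()]. The planted
#' per-well mitolysosome rate is `base rate x treatment factor x
#' planted_effect`. Field seeds are derived deterministically from
#' `base_config$rng_seed`, the well index and the field index, so the same
#' design and seed reproduce the same plate.
#'
#' @param design a [plate_design()].
#' @param base_config [scene_config()] for the siNT control-arm scene;
#'   its `mitolysosomes_per_cell` is the base rate.
#' @param dfp_factor fold induction of the mitolysosome rate in the DFP arm.
#' @param process optional `function(well_row, field_index, field, truth)`;
#'   when given, only its return values are kept (streaming mode, images are
#'   discarded after processing) — use this for large plates.
#' @return class `sim_plate`: list with `design`, `dfp_factor` and `fields`,
#'   a list of per-field entries (`well_id`, `field`, plus either
#'   `image`/`truth` or the `process` result under `$result`).
#' @export
generate_plate <- function(design, base_config = scene_config(),
                           dfp_factor = 8, process = NULL) {
  stopifnot(inherits(design, "plate_design"))
  for (tr in unique(design$treatment))
    if (!any(design$target_gene == "siNT" & design$treatment == tr))
      stop("configuration error: no siNT well in treatment arm '", tr, "'")
  fields <- list()
  n <- 0L
  for (w in seq_len(nrow(design))) {
    row <- design[w, ]
    for (f in seq_len(row$n_fields)) {
      res <- generate_field(plate_field_cfg(design, base_config,
                                            dfp_factor, w, f))
      n <- n + 1L
      fields[[n]] <- if (is.null(process)) {
        list(well_id = row$well_id, field = f, image = res$field,
             truth = res$truth)
      } else {
        list(well_id = row$well_id, field = f,
             result = process(row, f, res$field, res$truth))
      }
    }
  }
  structure(list(design = design, dfp_factor = dfp_factor, fields = fields),
            class = "sim_plate")
}

#' Ground-truth per-cell table of a simulated plate
#'
#' Flattens the planted per-cell truth of every rendered field into one
#' table, for calibration checks against the measured pipeline output.
#'
#' @param plate a `sim_plate` from [generate_plate()] (non-streaming mode).
#' @return data.frame with `well_id`, `field_id`, `cell_id`,
#'   `n_mitolysosomes`, `red_only_area_px`.
#' @export
plate_truth_cells <- function(plate) {
  stopifnot(inherits(plate, "sim_plate"))
  do.call(rbind, lapply(plate$fields, function(fd) {
    if (is.null(fd$truth)) stop("plate was generated in streaming mode")
    cbind(data.frame(well_id = fd$well_id, field_id = fd$field),
          fd$truth$per_cell_truth)
  }))
}
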
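#' Per-well summaries with cell-count QC
#'
#' Aggregates per-cell measurements into one row per well: cell-weighted
#' mean red-only area (and structure count) per cell. Wells below the
#' minimum cell count fail QC — the screen itself required a minimum of
#' 1000 cells per condition per replicate — and are flagged so that
#' normalization and testing skip them.
#'
#' @param cells per-cell table with `well_id`, `red_only_area_px`,
#'   `n_red_only_structures` and optionally `field_id`.
#' @param layout well table with `well_id`, `treatment`, `target_gene`,
#'   `oligo_id` and optionally `plate`.
#' @param qc_min_cells minimum cells per well; default 1000 as in the
#'   screen protocol (simulations pass a scaled-down value).
#' @return data.frame of class `well_summary`: one row per layout well with
#'   `n_cells`, `mean_red_only_area_per_cell`,
#'   `mean_red_only_count_per_cell`, `n_fields_used`, `qc_pass`.
#' @export
summarize_wells <- function(cells, layout, qc_min_cells = 1000L) {
  extra <- setdiff(unique(cells$well_id), layout$well_id)
  if (length(extra) > 0)
    stop("wells present in data but missing from layout: ",
         paste(extra, collapse = ", "))
  out <- layout[, intersect(c("plate", "well_id", "treatment", "target_gene",
                              "oligo_id", "planted_effect"),
                            names(layout)), drop = FALSE]
  if (is.null(out$plate)) out$plate <- "P1"
  idx <- split(seq_len(nrow(cells)), cells$well_id)
  get_stat <- function(wid, f) {
    i <- idx[[wid]]
    if (is.null(i) || length(i) == 0) return(NA_real_)
    f(cells[i, , drop = FALSE])
  }
  out$n_cells <- vapply(out$well_id, function(w)
    length(idx[[w]]) %||% 0L, integer(1))
  out$mean_red_only_area_per_cell <- vapply(out$well_id, function(w)
    get_stat(w, function(d) mean(d$red_only_area_px)), numeric(1))
  out$mean_red_only_count_per_cell <- vapply(out$well_id, function(w)
    get_stat(w, function(d) mean(d$n_red_only_structures)), numeric(1))
  out$n_fields_used <- vapply(out$well_id, function(w)
    get_stat(w, function(d)
      if (is.null(d$field_id)) 1 else length(unique(d$field_id))),
    numeric(1))
  out$qc_pass <- out$n_cells >= qc_min_cells
  rownames(out) <- NULL
  class(out) <- c("well_summary", "data.frame")
  out
}

#' Normalize well summaries to siNT controls
#'
#' Divides each well's statistic by the mean of the unflagged non-targeting
#' control wells of the same plate and treatment arm, then centres so that
#' the control sits at 0: `fold_change = well / mean(siNT)` and
#' `centered_effect = fold_change - 1`. This mirrors "normalised to the
#' average of siNT controls, adjusted so the control is 0" screen scaling.
#'
#' @param wells a [summarize_wells()] table.
#' @param control_label target name of the control wells.
#' @param statistic column to normalize (red-only area per cell is the
#'   default screen statistic; the count variant is also present).
#' @return the input with `fold_change` and `centered_effect` columns;
#'   QC-failed wells get `NA`.
#' @export
normalize_to_controls <- function(wells,
                                  control_label = "siNT",
                                  statistic = "mean_red_only_area_per_cell") {
  stopifnot(statistic %in% names(wells))
  wells$fold_change <- NA_real_
  wells$centered_effect <- NA_real_
  for (pl in unique(wells$plate)) {
    for (tr in unique(wells$treatment)) {
      sel <- wells$plate == pl & wells$treatment == tr
      if (!any(sel)) next
      ctrl <- sel & wells$target_gene == control_label & wells$qc_pass
      if (!any(ctrl))
        stop("no unflagged ", control_label, " control well in plate ", pl,
             ", arm ", tr)
      m <- mean(wells[[statistic]][ctrl])
      if (!is.finite(m) || m == 0)
        stop("control mean is zero or undefined in plate ", pl, ", arm ", tr)
      ok <- sel & wells$qc_pass
      wells$fold_change[ok] <- wells[[statistic]][ok] / m
      wells$centered_effect[ok] <- wells$fold_change[ok] - 1
    }
  }
  wells
}

#' Monte Carlo null sample of the Dunnett max-|t| statistic
#'
#' Draws the null distribution of the maximum absolute many-to-one t
#' statistic for given group sizes, used to adjust the per-comparison p
#' values for familywise error. Simulating the statistic directly (shared
#' control mean and shared pooled variance) reproduces the equicorrelated
#' multivariate-t structure without quadrature.
#'
#' @param n_groups vector of treatment-group sizes.
#' @param n_control control-group size.
#' @param df error degrees of freedom (defaults to the one-way ANOVA value).
#' @param B number of resamples (>= 1e5 recommended).
#' @param seed integer seed.
#' @return sorted numeric vector of `B` max-|t| draws.
#' @export
dunnett_null_sample <- function(n_groups, n_control,
                                df = sum(n_groups) + n_control -
                                  length(n_groups) - 1L,
                                B = 1e5, seed = 1L) {
  k <- length(n_groups)
  with_seed(seed, {
    z0 <- stats::rnorm(B, 0, sqrt(1 / n_control))
    v <- stats::rchisq(B, df) / df
    mx <- rep(0, B)
    for (i in seq_len(k)) {
      zi <- stats::rnorm(B, 0, sqrt(1 / n_groups[i]))
      ti <- abs(zi - z0) / sqrt(v * (1 / n_groups[i] + 1 / n_control))
      mx <- pmax(mx, ti)
    }
    sort(mx)
  })
}

#' Dunnett many-to-one test
#'
#' Compares every treatment group against a single control with familywise
#' adjustment on the maximum-|t| statistic. With one group the adjusted p
#' equals the pooled two-sample t-test p exactly; with several groups the
#' adjustment is Monte Carlo (seeded, `B` resamples), as a tail probability
#' of the simulated max-|t| null.
#'
#' @param groups named list of numeric replicate vectors (>= 2 each).
#' @param control numeric replicate vector (>= 2).
#' @param alpha familywise significance level.
#' @param B Monte Carlo resamples for the null.
#' @param seed integer seed for the null sample.
#' @param null_sample optional precomputed [dunnett_null_sample()] for this
#'   design (reused across many tests of identical layout).
#' @return data.frame: `group`, `estimate` (mean difference), `t`, `p_adj`,
#'   `significant`, `direction` (`"up"`, `"down"`, `"none"`); attributes
#'   `df` and `crit` (the alpha-level critical value).
#' @export
dunnett_test <- function(groups, control, alpha = 0.05, B = 1e5, seed = 1L,
                         null_sample = NULL) {
  if (is.numeric(groups)) groups <- list(group1 = groups)
  k <- length(groups)
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes < 2L) || length(control) < 2L)
    stop("every group and the control need >= 2 replicates")
  n0 <- length(control)
  N <- sum(sizes) + n0
  df <- N - k - 1L
  ss <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1))) +
    sum((control - mean(control))^2)
  s2 <- ss / df
  est <- vapply(groups, mean, numeric(1)) - mean(control)
  if (s2 <= 0) {
    warning("zero pooled variance: t statistics undefined, results flagged")
    out <- data.frame(group = names(groups) %||% seq_len(k),
                      estimate = est, t = NA_real_, p_adj = NA_real_,
                      significant = NA, direction = "none")
    return(out)
  }
  tstat <- est / sqrt(s2 * (1 / sizes + 1 / n0))
  if (k == 1L) {
    p <- 2 * stats::pt(-abs(tstat), df)
    crit <- stats::qt(1 - alpha / 2, df)
  } else {
    if (is.null(null_sample))
      null_sample <- dunnett_null_sample(sizes, n0, df, B, seed)
    Bn <- length(null_sample)
    # tail probability from the sorted null sample
    p <- vapply(abs(tstat), function(t0)
      (Bn - findInterval(t0 - 1e-12, null_sample)) / Bn, numeric(1))
    crit <- stats::quantile(null_sample, 1 - alpha, names = FALSE)
  }
  data.frame(group = names(groups) %||% as.character(seq_len(k)),
             estimate = est, t = tstat, p_adj = p,
             significant = p < alpha,
             direction = ifelse(p < alpha,
                                ifelse(est > 0, "up", "down"), "none"),
             row.names = NULL) |>
    structure(df = df, crit = crit)
}

#' Per-target screen significance across replicate plates
#'
#' Builds replicate values per target (one per plate: the plate mean of the
#' normalized statistic over that target's wells) and tests each target
#' against the siNT replicate values with [dunnett_test()], per treatment
#' arm. The replicate unit is the plate, matching the "n = ... plates"
#' convention of screen reporting.
#'
#' @param norm normalized well table from [normalize_to_controls()]; must
#'   span >= 2 plates.
#' @param arm treatment arm to test (the mitophagy-inducing arm by default).
#' @param control_label control target name.
#' @param value column carrying the normalized statistic.
#' @param alpha,B,seed,null_sample passed to [dunnett_test()].
#' @return data.frame: `target`, `oligo`, `mean_centered_effect`, `p_adj`,
#'   `significant`, `direction`.
#' @export
screen_test <- function(norm, arm = "DFP", control_label = "siNT",
                        value = "fold_change", alpha = 0.05, B = 1e5,
                        seed = 1L, null_sample = NULL) {
  d <- norm[norm$treatment == arm & norm$qc_pass &
              is.finite(norm[[value]]), , drop = FALSE]
  d$unit <- paste(d$target_gene, d$oligo_id, sep = "|")
  plate_means <- stats::aggregate(d[[value]],
                                  by = list(unit = d$unit, plate = d$plate),
                                  FUN = mean)
  ctrl_unit <- paste(control_label, "pool", sep = "|")
  ctrl <- plate_means$x[plate_means$unit == ctrl_unit]
  if (length(ctrl) < 2)
    stop("need >= 2 replicate plates of ", control_label, " in arm ", arm)
  units <- setdiff(unique(plate_means$unit), ctrl_unit)
  groups <- lapply(stats::setNames(units, units), function(u)
    plate_means$x[plate_means$unit == u])
  res <- dunnett_test(groups, ctrl, alpha = alpha, B = B, seed = seed,
                      null_sample = null_sample)
  parts <- strsplit(res$group, "|", fixed = TRUE)
  data.frame(target = vapply(parts, `[`, "", 1),
             oligo = vapply(parts, `[`, "", 2),
             mean_centered_effect = vapply(groups, mean, numeric(1)) - 1,
             p_adj = res$p_adj, significant = res$significant,
             direction = res$direction, row.names = NULL)
}

#' Deconvolution and primary hit calling
#'
#' Primary tier: a target is a hit when its pooled-siRNA comparison against
#' siNT is significant. Deconvolution tier: a target is confirmed when at
#' least two of its three oligos are individually significant with the same
#' direction of effect — discordant significant oligos do not confirm.
#' Targets with fewer than three oligos in the deconvolution tier are
#' flagged partial.
#'
#' @param effects data.frame with `target`, `oligo`, `significant`,
#'   `direction` (from [screen_test()] or equivalent).
#' @param tier `"primary"` or `"deconvolution"`.
#' @param n_oligos_expected oligos per target in a deconvolution layout.
#' @return data.frame of class `hit_table`: `target`, `tier`, `is_hit`,
#'   `supporting_oligos`, `direction`, `partial`, `rule`.
#' @export
call_hits <- function(effects, tier = c("deconvolution", "primary"),
                      n_oligos_expected = 3L) {
  tier <- match.arg(tier)
  targets <- unique(effects$target)
  rows <- lapply(targets, function(tg) {
    e <- effects[effects$target == tg, , drop = FALSE]
    if (tier == "primary") {
      sig <- e$significant & e$direction != "none"
      data.frame(target = tg, tier = tier, is_hit = any(sig),
                 supporting_oligos = sum(sig),
                 direction = if (any(sig)) e$direction[sig][1] else "none",
                 partial = FALSE,
                 rule = "pooled siRNA significant vs siNT")
    } else {
      up <- sum(e$significant & e$direction == "up")
      down <- sum(e$significant & e$direction == "down")
      is_hit <- max(up, down) >= 2L
      data.frame(target = tg, tier = tier, is_hit = is_hit,
                 supporting_oligos = max(up, down),
                 direction = if (!is_hit) "none"
                             else if (up >= down) "up" else "down",
                 partial = nrow(e) < n_oligos_expected,
                 rule = ">=2 of 3 oligos significant, concordant direction")
    }
  })
  out <- do.call(rbind, rows)
  class(out) <- c("hit_table", "data.frame")
  out
}
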
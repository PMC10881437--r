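#' Cumulative dose-volume histogram of a structure
#'
#' @param dose a [scalar_volume()].
#' @param mask a non-empty [mask_volume()] on the same grid.
#' @return Object of class `dvh_curve`: sorted (descending) per-voxel doses,
#'   the voxel volume in cm^3, and the cumulative volume-fraction curve.
#' @export
dvh_curve <- function(dose, mask) {
  stop_if_grid_mismatch(dose$grid, mask$grid, "dose and mask")
  if (!any(mask$values)) stop("empty mask")
  d <- sort(dose$values[mask$values], decreasing = TRUE)
  structure(list(structure = mask$label, doses = d,
                 voxel_cm3 = voxel_volume_cm3(dose$grid),
                 volume_cm3 = length(d) * voxel_volume_cm3(dose$grid)),
            class = "dvh_curve")
}

# Dose to the hottest `vol_cm3` of a DVH curve, linearly interpolated on the
# sorted voxel-dose curve (points at cumulative volume i * voxel_cm3).
dvh_dose_at_volume <- function(curve, vol_cm3) {
  d <- curve$doses; w <- curve$voxel_cm3; m <- length(d)
  if (vol_cm3 > curve$volume_cm3 + 1e-12) {
    warning("requested volume exceeds structure volume; returning minimum dose")
    return(d[m])
  }
  v <- pmax(vol_cm3, 0)
  if (v <= w) return(d[1])
  if (m == 1L) return(d[1])
  stats::approx(x = seq_len(m) * w, y = d, xout = min(v, m * w), rule = 2)$y
}

#' DVH point metrics
#'
#' `D_x%` is the minimum dose received by the hottest `x`% of the structure
#' volume (so `D99` is a near-minimum dose and `D0+` approaches `Dmax`);
#' `D_ycm3` is the analogue at absolute volume; `V_d` is the percentage of the
#' structure receiving at least `d`. Voxel-centre counting, no partial-volume
#' weighting; dose-at-volume queries interpolate linearly between sorted
#' voxel doses.
#'
#' @param dose a [scalar_volume()].
#' @param mask a non-empty [mask_volume()] on the same grid.
#' @param d_percent volumes in % for dose-at-volume queries.
#' @param d_cm3 absolute volumes in cm^3 for dose-at-volume queries.
#' @param v_gy dose levels in Gy for volume-at-dose queries.
#' @return List with `Dmax`, `Dmin`, `Dmean`, `D_pct` (named by percent),
#'   `D_cm3` (named by cm^3) and `V_gy` (named by level, in %).
#' @export
dvh_metrics <- function(dose, mask, d_percent = numeric(), d_cm3 = numeric(),
                        v_gy = numeric()) {
  curve <- dvh_curve(dose, mask)
  d <- curve$doses
  D_pct <- vapply(d_percent, function(x)
    dvh_dose_at_volume(curve, x / 100 * curve$volume_cm3), 0)
  if (length(d_percent)) names(D_pct) <- paste0("D", d_percent, "%")
  D_cm3 <- vapply(d_cm3, function(v) dvh_dose_at_volume(curve, v), 0)
  if (length(d_cm3)) names(D_cm3) <- paste0("D", d_cm3, "cm3")
  V_gy <- vapply(v_gy, function(lvl) 100 * mean(d >= lvl), 0)
  if (length(v_gy)) names(V_gy) <- paste0("V", v_gy, "Gy")
  list(Dmax = max(d), Dmin = min(d), Dmean = mean(d),
       D_pct = D_pct, D_cm3 = D_cm3, V_gy = V_gy)
}

#' Paddick conformity index
#'
#' `CI = (TV intersect PIV)^2 / (TV * PIV)` with `TV` the target volume and
#' `PIV` the volume enclosed by the prescription isodose (over the whole
#' grid). 1 is perfect conformity; 0 when the prescription isodose is empty
#' or misses the target entirely.
#'
#' @param dose a [scalar_volume()].
#' @param target a non-empty [mask_volume()].
#' @param prescription prescription dose in Gy.
#' @return CI in `[0, 1]`.
#' @export
paddick_ci <- function(dose, target, prescription) {
  stop_if_grid_mismatch(dose$grid, target$grid, "dose and target")
  if (!any(target$values)) stop("empty target")
  piv <- dose$values >= prescription
  tv <- sum(target$values); pv <- sum(piv)
  if (pv == 0) return(0)
  inter <- sum(target$values & piv)
  inter^2 / (tv * pv)
}

#' ICRU 83 homogeneity index
#'
#' `HI = (D2% - D98%) / D50%` within the target; 0 for a perfectly uniform
#' target dose, invariant under uniform dose scaling.
#'
#' @inheritParams paddick_ci
#' @return HI (>= 0).
#' @export
homogeneity_index <- function(dose, target) {
  m <- dvh_metrics(dose, target, d_percent = c(2, 50, 98))
  d50 <- m$D_pct[["D50%"]]
  if (d50 == 0) stop("D50% is zero; homogeneity index undefined")
  (m$D_pct[["D2%"]] - m$D_pct[["D98%"]]) / d50
}

#' Gradient index (ICRU form)
#'
#' Ratio of the half-prescription to the full-prescription isodose volume,
#' computed over the whole dose grid: `GI = V_50%Rx / V_100%Rx`. Sharper dose
#' falloff gives values closer to 1.
#'
#' @param dose a [scalar_volume()].
#' @param prescription prescription dose in Gy.
#' @return GI (>= 1 for any dose distribution with a non-empty prescription
#'   isodose).
#' @export
gradient_index <- function(dose, prescription) {
  v100 <- sum(dose$values >= prescription)
  if (v100 == 0) stop("prescription isodose volume is empty")
  sum(dose$values >= 0.5 * prescription) / v100
}

#' High-dose spillage outside the target
#'
#' Volume in cm^3 of voxels outside the PTV receiving more than 105% of the
#' prescription.
#'
#' @param dose a [scalar_volume()].
#' @param ptv the planning target [mask_volume()].
#' @param prescription prescription dose in Gy.
#' @return Spillage volume in cm^3.
#' @export
high_dose_spillage <- function(dose, ptv, prescription) {
  stop_if_grid_mismatch(dose$grid, ptv$grid, "dose and PTV")
  sum(dose$values > 1.05 * prescription & !ptv$values) *
    voxel_volume_cm3(dose$grid)
}

#' Plan-quality metric panel
#'
#' The standard evaluation set: target `D99%`/`D95%` (Gy), coverage
#' `V95%`/`V100%` (% of the target at 95%/100% of prescription), high-dose
#' spillage outside the PTV (cm^3), per-organ `Dmax`/`D0.035cm3`/`D5cm3`
#' (Gy), Paddick conformity, ICRU 83 homogeneity and ICRU gradient index.
#'
#' @param dose a [scalar_volume()] of the plan (physical Gy).
#' @param ptv target [mask_volume()].
#' @param prescription prescription in Gy.
#' @param oar_masks named list of organ [mask_volume()]s (may be empty).
#' @return Named list; OAR entries are nested under `oar`.
#' @export
metric_panel <- function(dose, ptv, prescription, oar_masks = list()) {
  tm <- dvh_metrics(dose, ptv, d_percent = c(99, 95),
                    v_gy = c(0.95, 1) * prescription)
  oar <- lapply(oar_masks, function(m) {
    if (!any(m$values)) return(NULL)
    om <- dvh_metrics(dose, m, d_cm3 = c(0.035, 5))
    list(Dmax = om$Dmax, D0.035cm3 = om$D_cm3[["D0.035cm3"]],
         D5cm3 = om$D_cm3[["D5cm3"]])
  })
  list(D99 = tm$D_pct[["D99%"]], D95 = tm$D_pct[["D95%"]],
       V95 = tm$V_gy[[1]], V100 = tm$V_gy[[2]],
       spillage_cm3 = high_dose_spillage(dose, ptv, prescription),
       CI = paddick_ci(dose, ptv, prescription),
       HI = homogeneity_index(dose, ptv),
       GI = gradient_index(dose, prescription),
       oar = oar)
}

#' Cumulative EQD2 validation report per organ
#'
#' Accumulates the mapped prior EQD2 with the re-irradiation plan's EQD2
#' (converted with each organ's alpha/beta) and reports the cumulative
#' maximum against the organ tolerance, with the accepted slack of
#' 1 GyEQD2 that absorbs final-dose-calculation discrepancies.
#'
#' @param prior_eqd2_mapped named list of mapped prior EQD2
#'   [scalar_volume()]s, one per organ.
#' @param reirr_dose the plan's physical [scalar_volume()] (with fraction
#'   count).
#' @param oars named list of [oar_spec()]s.
#' @param oar_masks named list of organ [mask_volume()]s.
#' @param slack_eqd2 accepted exceedance in GyEQD2 (default 1).
#' @return data.frame with one row per organ: `oar`, `cum_dmax_eqd2`,
#'   `tolerance_eqd2`, `margin_eqd2`, `pass`; cumulative volumes attached as
#'   attribute `"cumulative"`.
#' @export
cumulative_oar_report <- function(prior_eqd2_mapped, reirr_dose, oars,
                                  oar_masks, slack_eqd2 = 1) {
  rows <- list(); cums <- list()
  for (oar_name in names(prior_eqd2_mapped)) {
    oar <- oars[[oar_name]]
    reirr_eqd2 <- eqd2_volume(reirr_dose, oar$alpha_beta)
    cum <- accumulate_eqd2(prior_eqd2_mapped[[oar_name]], reirr_eqd2)
    cums[[oar_name]] <- cum
    dmax <- max(cum$values[oar_masks[[oar_name]]$values])
    rows[[oar_name]] <- data.frame(
      oar = oar_name, cum_dmax_eqd2 = dmax,
      tolerance_eqd2 = oar$tolerance_eqd2,
      margin_eqd2 = oar$tolerance_eqd2 + slack_eqd2 - dmax,
      pass = dmax <= oar$tolerance_eqd2 + slack_eqd2,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "cumulative") <- cums
  out
}

#' Robustness of cumulative dose to the smearing radius
#'
#' Recomputes the mapped prior EQD2 at each smearing radius while holding the
#' plan dose fixed, and reports the increase in cumulative per-organ maximum
#' dose relative to radius 0. By the monotonicity of the neighbourhood
#' maximum the increase is 0 at radius 0 and non-decreasing in the radius.
#'
#' @param prior_dose prior course [scalar_volume()] (physical Gy, prior grid).
#' @param dvf [vector_field()] on the planning grid.
#' @param plan_dose fixed re-irradiation plan [scalar_volume()] (physical Gy).
#' @param oars named list of [oar_spec()]s.
#' @param oar_masks named list of organ masks on the planning grid.
#' @param organ_prior_masks named list of organ masks on the prior grid (for
#'   the smearing restriction); may be `NULL`.
#' @param radii_mm radii to sweep; must include 0 (default 0:4 mm).
#' @param cfg base [mapping_config()]; its radius is overridden per sweep
#'   point.
#' @return data.frame with columns `oar`, `radius_mm`, `cum_dmax_eqd2`,
#'   `delta_dmax_eqd2`.
#' @export
robustness_sweep <- function(prior_dose, dvf, plan_dose, oars, oar_masks,
                             organ_prior_masks = NULL, radii_mm = 0:4,
                             cfg = mapping_config()) {
  if (!0 %in% radii_mm) stop("radii_mm must include 0")
  radii_mm <- sort(unique(radii_mm))
  rows <- list()
  for (oar_name in names(oar_masks)) {
    oar <- oars[[oar_name]]
    reirr_eqd2 <- eqd2_volume(plan_dose, oar$alpha_beta)
    pm <- if (is.null(organ_prior_masks)) NULL else organ_prior_masks[[oar_name]]
    dmax <- vapply(radii_mm, function(r) {
      c2 <- cfg; c2$smearing_radius_mm <- r
      mapped <- mapped_eqd2_for_oar(prior_dose, dvf, dvf$grid, c2, oar, pm)
      cum <- accumulate_eqd2(mapped, reirr_eqd2)
      max(cum$values[oar_masks[[oar_name]]$values])
    }, 0)
    rows[[oar_name]] <- data.frame(
      oar = oar_name, radius_mm = radii_mm, cum_dmax_eqd2 = dmax,
      delta_dmax_eqd2 = dmax - dmax[radii_mm == 0], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
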
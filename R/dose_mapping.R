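#' Dose-mapping configuration
#'
#' Controls the conservative transfer of the prior dose onto the current
#' anatomy. `smearing_radius_mm` is the radius of the spherical neighbourhood
#' (default 0.2 cm) searched for the maximum prior dose around each homologous
#' point, absorbing residual registration error. With
#' `restrict_to_structure = TRUE` the neighbourhood search only draws from
#' voxels inside the organ's own prior-frame contour, so dose is never pulled
#' in from adjacent high-dose regions that do not belong to the organ.
#'
#' @param smearing_radius_mm neighbourhood radius in mm (>= 0; 0 disables
#'   smearing).
#' @param restrict_to_structure logical; restrict the neighbourhood maximum to
#'   the organ's prior-frame mask.
#' @param fill_value dose (Gy) assumed outside the prior grid; 0 is the only
#'   non-inflating choice.
#' @return Object of class `mapping_config`.
#' @export
mapping_config <- function(smearing_radius_mm = 2, restrict_to_structure = TRUE,
                           fill_value = 0) {
  if (smearing_radius_mm < 0) stop("smearing_radius_mm must be >= 0")
  structure(list(smearing_radius_mm = smearing_radius_mm,
                 restrict_to_structure = isTRUE(restrict_to_structure),
                 fill_value = fill_value),
            class = "mapping_config")
}

#' Map the prior physical dose onto the re-irradiation grid
#'
#' For each target voxel centre `x`, the homologous prior-frame point is
#' `p = x + v(x)` with `v` the displacement field. The mapped dose is the
#' maximum of (a) the trilinear sample of the prior dose at `p` and (b) the
#' largest prior-dose voxel value whose centre lies within the smearing radius
#' of `p` (and, when restriction is on, inside the organ's prior-frame mask).
#' Always including the direct sample makes the estimator continuous in the
#' radius, never below the unsmeared value, and exact for a radius of 0.
#'
#' @param prior_dose [scalar_volume()] of the prior course (physical Gy, on
#'   the prior grid, carrying the prior fraction count).
#' @param dvf [vector_field()] on `target_grid`, mapping re-irradiation points
#'   into the prior frame.
#' @param target_grid the re-irradiation planning [grid3d()]; defaults to the
#'   field's grid.
#' @param cfg a [mapping_config()].
#' @param organ_prior_mask optional [mask_volume()] on the prior grid bounding
#'   the smearing search.
#' @return A `scalar_volume` (physical Gy) on `target_grid` carrying the prior
#'   plan's `n_fractions`.
#' @export
map_prior_dose <- function(prior_dose, dvf, target_grid = dvf$grid,
                           cfg = mapping_config(), organ_prior_mask = NULL) {
  if (!inherits(prior_dose, "scalar_volume") || prior_dose$quantity != "physical_gy")
    stop("prior_dose must be a physical_gy scalar_volume")
  stop_if_grid_mismatch(dvf$grid, target_grid, "dvf and target grid")
  if (!is.null(organ_prior_mask))
    stop_if_grid_mismatch(organ_prior_mask$grid, prior_dose$grid,
                          "organ prior mask and prior dose")
  x <- voxel_centers(target_grid)
  p <- x + matrix(dvf$values, ncol = 3)
  out <- sample_trilinear(prior_dose, p, fill = cfg$fill_value)
  r <- cfg$smearing_radius_mm
  if (r > 0) {
    g <- prior_dose$grid
    n <- g$size
    v <- as.vector(prior_dose$values)
    restrict <- cfg$restrict_to_structure && !is.null(organ_prior_mask)
    mv <- if (restrict) as.vector(organ_prior_mask$values) else NULL
    # continuous voxel coordinates of p on the prior grid
    t1 <- (p[, 1] - g$origin[1]) / g$spacing[1]
    t2 <- (p[, 2] - g$origin[2]) / g$spacing[2]
    t3 <- (p[, 3] - g$origin[3]) / g$spacing[3]
    c1 <- round(t1); c2 <- round(t2); c3 <- round(t3)
    # candidate offsets around the nearest voxel: need |d - frac| * h <= r with
    # |frac| <= 0.5, so |d| <= r/h + 0.5 per axis
    m <- floor(r / g$spacing + 0.5)
    for (dk in -m[3]:m[3]) for (dj in -m[2]:m[2]) for (di in -m[1]:m[1]) {
      i <- c1 + di; j <- c2 + dj; k <- c3 + dk
      dist2 <- ((i - t1) * g$spacing[1])^2 + ((j - t2) * g$spacing[2])^2 +
               ((k - t3) * g$spacing[3])^2
      sel <- dist2 <= r^2 + 1e-9 & i >= 0 & i <= n[1] - 1 &
             j >= 0 & j <= n[2] - 1 & k >= 0 & k <= n[3] - 1
      if (!any(sel)) next
      lin <- 1 + i[sel] + n[1] * (j[sel] + n[2] * k[sel])
      if (restrict) {
        inorg <- mv[lin]
        if (!any(inorg)) next
        idx <- which(sel)[inorg]; lin <- lin[inorg]
      } else idx <- which(sel)
      out[idx] <- pmax(out[idx], v[lin])
    }
  }
  scalar_volume(array(out, dim = target_grid$size), target_grid,
                quantity = "physical_gy", n_fractions = prior_dose$n_fractions,
                label = prior_dose$label)
}

#' Mapped prior dose in EQD2 for one organ at risk
#'
#' Composition of [map_prior_dose()] and [eqd2_volume()] with the organ's
#' alpha/beta ratio: the prior course's EQD2 image on the re-irradiation
#' anatomy, the quantity every downstream step (isodose structures,
#' constraint budgets, cumulative validation) consumes.
#'
#' @inheritParams map_prior_dose
#' @param oar an [oar_spec()] supplying the alpha/beta ratio.
#' @return A `scalar_volume` with quantity `"eqd2_gy"` on `target_grid`.
#' @export
mapped_eqd2_for_oar <- function(prior_dose, dvf, target_grid = dvf$grid,
                                cfg = mapping_config(), oar,
                                organ_prior_mask = NULL) {
  mapped <- map_prior_dose(prior_dose, dvf, target_grid, cfg, organ_prior_mask)
  out <- eqd2_volume(mapped, oar$alpha_beta)
  out$label <- paste0(oar$name, "_prior_eqd2")
  out
}
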
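#' Optimization structure
#'
#' An organ-at-risk sub-region defined by a prior-dose isodose level, carrying
#' the maximum mapped prior EQD2 found inside its (pre-expansion) core and,
#' once the constraint table is built, its physical re-irradiation dose limit.
#'
#' @param oar_name organ name.
#' @param level_eqd2 isodose threshold defining the structure (GyEQD2).
#' @param mask [mask_volume()] used for optimization (possibly expanded).
#' @param core_mask [mask_volume()] before any robustness expansion.
#' @param eqd2_prior_max maximum mapped prior EQD2 within `core_mask`.
#' @param physical_limit physical dose limit in Gy (`NA` until assigned).
#' @param infeasible logical; `TRUE` when the EQD2 budget was exhausted.
#' @return Object of class `opt_structure`.
#' @export
opt_structure <- function(oar_name, level_eqd2, mask, core_mask = mask,
                          eqd2_prior_max, physical_limit = NA_real_,
                          infeasible = FALSE) {
  structure(list(oar_name = oar_name, level_eqd2 = level_eqd2, mask = mask,
                 core_mask = core_mask, eqd2_prior_max = eqd2_prior_max,
                 physical_limit = physical_limit, infeasible = infeasible,
                 name = sprintf("%s_ge%g", oar_name, level_eqd2)),
            class = "opt_structure")
}

#' @export
print.opt_structure <- function(x, ...) {
  cat(sprintf("<opt_structure> %s: level %g GyEQD2, %.3f cm^3, prior max %.2f GyEQD2%s%s\n",
              x$name, x$level_eqd2, volume_cm3(x$mask), x$eqd2_prior_max,
              if (is.na(x$physical_limit)) "" else sprintf(", limit %.2f Gy", x$physical_limit),
              if (x$infeasible) " [INFEASIBLE]" else ""))
  invisible(x)
}

#' Nested isodose structures of the mapped prior EQD2 within an organ
#'
#' Thresholds the mapped prior EQD2 image at levels `step, 2*step, ...` and
#' intersects each superlevel set with the organ mask:
#' `S_L = OAR AND (mapped >= L)`. Only non-empty structures are returned, in
#' increasing level order, so `S_step` contains `S_2step` contains ... The
#' closed `>=` threshold makes the later shell segregation an exact partition.
#'
#' @param mapped_eqd2 [scalar_volume()] (`eqd2_gy`) on the organ's grid.
#' @param oar_mask [mask_volume()] of the organ.
#' @param oar_name organ name recorded on the structures.
#' @param step isodose step in GyEQD2 (default 10).
#' @return List of [opt_structure()] objects, nested by construction.
#' @export
isodose_structures <- function(mapped_eqd2, oar_mask, oar_name = oar_mask$label,
                               step = 10) {
  if (step <= 0) stop("step must be > 0")
  stop_if_grid_mismatch(mapped_eqd2$grid, oar_mask$grid, "mapped EQD2 and OAR mask")
  if (!any(oar_mask$values)) return(list())
  vmax <- max(mapped_eqd2$values[oar_mask$values])
  levels <- seq(step, by = step, length.out = max(0, floor(vmax / step)))
  out <- list()
  for (L in levels) {
    m <- oar_mask$values & (mapped_eqd2$values >= L)
    if (!any(m)) next
    mk <- mask_volume(m, oar_mask$grid, label = sprintf("%s_ge%g", oar_name, L))
    out[[length(out) + 1L]] <- opt_structure(
      oar_name, L, mask = mk, core_mask = mk,
      eqd2_prior_max = max(mapped_eqd2$values[m]))
  }
  out
}

#' Segregate nested isodose structures into disjoint shells
#'
#' Each shell keeps the voxels of its level that do not belong to the next
#' higher level (the topmost level keeps itself), mirroring the automatic
#' segregation of overlapping structures inside a hierarchical optimizer.
#' The shells partition the first-level structure, and each shell's
#' `eqd2_prior_max` is recomputed as the maximum mapped EQD2 over its own
#' core, so the value lies in `[level, next level)` except for the topmost.
#'
#' @param nested list of nested [opt_structure()]s from [isodose_structures()].
#' @param mapped_eqd2 the [scalar_volume()] the structures were derived from.
#' @return List of disjoint [opt_structure()] shells (empty shells dropped).
#' @export
segregate_shells <- function(nested, mapped_eqd2) {
  if (length(nested) == 0L) return(list())
  for (i in seq_along(nested)[-1]) {
    if (any(nested[[i]]$mask$values & !nested[[i - 1]]$mask$values))
      stop("input structures are not nested")
  }
  out <- list()
  for (i in seq_along(nested)) {
    core <- nested[[i]]$mask$values
    if (i < length(nested)) core <- core & !nested[[i + 1]]$mask$values
    if (!any(core)) next
    mk <- mask_volume(core, nested[[i]]$mask$grid,
                      label = sprintf("%s_shell%g", nested[[i]]$oar_name,
                                      nested[[i]]$level_eqd2))
    out[[length(out) + 1L]] <- opt_structure(
      nested[[i]]$oar_name, nested[[i]]$level_eqd2, mask = mk, core_mask = mk,
      eqd2_prior_max = max(mapped_eqd2$values[core]))
  }
  out
}

#' Robustness expansion of small optimization structures
#'
#' Shells whose core is below `threshold_cm3` are isotropically expanded by
#' `radius_mm` and clipped to the parent organ, making tiny high-dose islands
#' robust against residual alignment error during plan optimization. The
#' recorded `eqd2_prior_max` stays that of the pre-expansion core: expanded
#' voxels received less prior dose, so the core maximum remains conservative
#' for them.
#'
#' @param shells list of [opt_structure()] shells.
#' @param oar_mask the parent organ [mask_volume()].
#' @param threshold_cm3 volume threshold in cm^3 (default 1).
#' @param radius_mm expansion radius in mm (default 2, i.e. 0.2 cm).
#' @return The shells with `mask` replaced where expansion applied.
#' @export
apply_small_structure_expansion <- function(shells, oar_mask,
                                            threshold_cm3 = 1, radius_mm = 2) {
  lapply(shells, function(s) {
    if (volume_cm3(s$core_mask) < threshold_cm3) {
      s$mask <- expand_mask_isotropic(s$core_mask, radius_mm, restrict = oar_mask)
      s$mask$label <- s$core_mask$label
    } else {
      s$mask <- s$core_mask
    }
    s
  })
}

#' Full structure-generation step for one organ
#'
#' [isodose_structures()], [segregate_shells()] and
#' [apply_small_structure_expansion()] chained with one call.
#'
#' @inheritParams isodose_structures
#' @inheritParams apply_small_structure_expansion
#' @return List of disjoint, possibly expanded [opt_structure()] shells.
#' @export
generate_structures <- function(mapped_eqd2, oar_mask, oar_name = oar_mask$label,
                                step = 10, threshold_cm3 = 1, radius_mm = 2) {
  nested <- isodose_structures(mapped_eqd2, oar_mask, oar_name, step)
  shells <- segregate_shells(nested, mapped_eqd2)
  apply_small_structure_expansion(shells, oar_mask, threshold_cm3, radius_mm)
}
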
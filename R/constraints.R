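#' Constraint table for plan optimization
#'
#' A list of named structures, each with a mask on the planning grid and a
#' hard maximum physical dose in Gy, plus the course metadata the limits were
#' derived for. Built either spatially resolved from prior-dose isodose
#' shells ([dart_constraint_table()]) or as the binary previously-treated /
#' untreated split of current practice ([baseline_constraint_table()]).
#'
#' @param entries list of entries, each a list with fields `name`, `mask`
#'   (a [mask_volume()]), `max_dose_gy`, `source`, `infeasible`, `oar`,
#'   `eqd2_prior_max`.
#' @param plan the [plan_info()] of the new course.
#' @return Object of class `constraint_table`.
#' @export
constraint_table <- function(entries, plan) {
  for (e in entries) {
    if (is.na(e$max_dose_gy) || e$max_dose_gy < 0)
      stop(sprintf("constraint %s has invalid max dose", e$name))
  }
  structure(list(entries = entries, plan = plan), class = "constraint_table")
}

#' @export
print.constraint_table <- function(x, ...) {
  cat(sprintf("<constraint_table> %d structures for %s (%d fx):\n",
              length(x$entries), x$plan$label, x$plan$n_fractions))
  df <- as.data.frame(x)
  print(df[, c("name", "max_dose_gy", "source", "infeasible")], row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.constraint_table <- function(x, ...) {
  do.call(rbind, lapply(x$entries, function(e)
    data.frame(name = e$name, oar = e$oar, max_dose_gy = e$max_dose_gy,
               eqd2_prior_max = e$eqd2_prior_max %||% NA_real_,
               volume_cm3 = volume_cm3(e$mask),
               source = e$source, infeasible = e$infeasible,
               stringsAsFactors = FALSE)))
}

#' Write a constraint table as JSON
#' @param x a `constraint_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_constraint_table <- function(x, path) {
  recs <- lapply(x$entries, function(e)
    list(structure = e$name, oar = e$oar, max_dose_gy = e$max_dose_gy,
         eqd2_prior_max = e$eqd2_prior_max %||% NA,
         volume_cm3 = volume_cm3(e$mask), source = e$source,
         infeasible = e$infeasible))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Spatially resolved constraint table from isodose shells
#'
#' For every segregated shell, the remaining EQD2 budget is the organ's
#' cumulative tolerance minus the shell's maximum mapped prior EQD2, and the
#' physical maximum-dose limit is [physical_dose_for_budget()] of that budget
#' for the new course's fractionation. Exhausted budgets yield a 0 Gy limit
#' flagged infeasible. The organ remainder (voxels outside every shell) is
#' constrained the same way, using the maximum mapped prior EQD2 over the
#' remainder itself (below the first isodose level by construction), so the
#' cumulative tolerance is honoured at every voxel of the organ; any
#' configured base template limit additionally caps it.
#'
#' @param shells_by_oar named list (by organ) of lists of [opt_structure()]
#'   shells from [generate_structures()].
#' @param oars named list of [oar_spec()]s covering every organ in
#'   `shells_by_oar`.
#' @param plan [plan_info()] of the re-irradiation course.
#' @param oar_masks named list of organ [mask_volume()]s (for the remainder
#'   entries).
#' @param mapped_eqd2_by_oar named list of mapped prior EQD2
#'   [scalar_volume()]s (for the remainder prior-dose maxima).
#' @param base_limits optional named numeric vector of per-organ physical
#'   Dmax template limits in Gy capping every entry.
#' @return A [constraint_table()] with source `"dart"`.
#' @export
dart_constraint_table <- function(shells_by_oar, oars, plan, oar_masks = NULL,
                                  mapped_eqd2_by_oar = NULL, base_limits = NULL) {
  entries <- list()
  for (oar_name in names(shells_by_oar)) {
    oar <- oars[[oar_name]]
    if (is.null(oar))
      stop(sprintf("no oar_spec supplied for organ '%s'", oar_name))
    cap <- if (!is.null(base_limits) && oar_name %in% names(base_limits))
      base_limits[[oar_name]] else Inf
    shells <- shells_by_oar[[oar_name]]
    for (s in shells) {
      budget <- oar$tolerance_eqd2 - s$eqd2_prior_max
      d <- physical_dose_for_budget(budget, plan$n_fractions, oar$alpha_beta)
      entries[[length(entries) + 1L]] <- list(
        name = s$name, oar = oar_name, mask = s$mask,
        max_dose_gy = min(as.numeric(d), cap),
        eqd2_prior_max = s$eqd2_prior_max,
        source = "dart", infeasible = attr(d, "infeasible")[1])
    }
    if (!is.null(oar_masks) && !is.null(oar_masks[[oar_name]])) {
      om <- oar_masks[[oar_name]]
      rem <- om$values
      for (s in shells) rem <- rem & !s$core_mask$values
      if (any(rem)) {
        prior_max <- if (!is.null(mapped_eqd2_by_oar) &&
                         !is.null(mapped_eqd2_by_oar[[oar_name]]))
          max(mapped_eqd2_by_oar[[oar_name]]$values[rem]) else 0
        budget <- oar$tolerance_eqd2 - prior_max
        d <- physical_dose_for_budget(budget, plan$n_fractions, oar$alpha_beta)
        entries[[length(entries) + 1L]] <- list(
          name = paste0(oar_name, "_remainder"), oar = oar_name,
          mask = mask_volume(rem, om$grid, label = paste0(oar_name, "_remainder")),
          max_dose_gy = min(as.numeric(d), cap),
          eqd2_prior_max = prior_max,
          source = "dart", infeasible = attr(d, "infeasible")[1])
      }
    }
  }
  constraint_table(entries, plan)
}

#' Institutional baseline policy for re-irradiation constraints
#'
#' Current-practice comparator: the segment of each organ falling within the
#' superior-inferior extent of the prior treatment field (plus a safety
#' margin) is "previously treated" and gets the template limit reduced by a
#' fixed amount; the rest of the organ keeps the template limit. The stated
#' reductions (12 Gy cord, 25 Gy esophagus) apply to 5-fraction courses;
#' other fractionations must supply their own.
#'
#' @param margin_mm superior-inferior safety margin added to the prior-field
#'   extent (clinically 5-10 mm; default the midpoint 7.5).
#' @param reductions named numeric vector, Gy subtracted from the template
#'   limit inside the treated segment.
#' @param base_limits named numeric vector of per-organ template Dmax limits
#'   in Gy for the new course.
#' @param dose_threshold_gy prior dose level defining the treatment-field
#'   footprint (beam geometry is unavailable, so the dose footprint is the
#'   observable proxy for the projected field edge).
#' @return Object of class `baseline_policy`.
#' @export
baseline_policy <- function(margin_mm = 7.5,
                            reductions = c(spinal_cord = 12, esophagus = 25),
                            base_limits = c(spinal_cord = 30, esophagus = 35),
                            dose_threshold_gy = 1) {
  if (margin_mm < 0) stop("margin_mm must be >= 0")
  if (any(reductions < 0)) stop("reductions must be >= 0")
  structure(list(margin_mm = margin_mm, reductions = reductions,
                 base_limits = base_limits,
                 dose_threshold_gy = dose_threshold_gy),
            class = "baseline_policy")
}

#' Binary previously-treated/untreated constraint table
#'
#' Applies a [baseline_policy()] to the rigidly aligned prior dose: the
#' superior-inferior slab where the prior dose footprint exceeds the
#' threshold, expanded by the policy margin along that axis, marks each
#' organ's previously treated segment.
#'
#' @param prior_dose_mapped_rigid [scalar_volume()] of the prior dose on the
#'   planning grid via rigid alignment.
#' @param oar_masks named list of organ [mask_volume()]s on the planning grid.
#' @param policy a [baseline_policy()].
#' @param plan [plan_info()] of the new course.
#' @return A [constraint_table()] with source `"baseline"`; exactly two
#'   entries (treated segment, remainder) per organ intersected by the field,
#'   one otherwise.
#' @export
baseline_constraint_table <- function(prior_dose_mapped_rigid, oar_masks,
                                      policy = baseline_policy(), plan) {
  if (plan$n_fractions != 5L &&
      identical(policy$reductions, c(spinal_cord = 12, esophagus = 25)))
    warning("default constraint reductions are stated for 5-fraction courses")
  grid <- prior_dose_mapped_rigid$grid
  zmask <- apply(prior_dose_mapped_rigid$values > policy$dose_threshold_gy,
                 3, any)
  entries <- list()
  zc <- axis_coords(grid, 3)
  for (oar_name in names(oar_masks)) {
    if (!oar_name %in% names(policy$base_limits))
      stop(sprintf("no base template limit configured for organ '%s'", oar_name))
    base <- policy$base_limits[[oar_name]]
    if (!oar_name %in% names(policy$reductions))
      stop(sprintf("no constraint reduction configured for organ '%s'", oar_name))
    red <- policy$reductions[[oar_name]]
    om <- oar_masks[[oar_name]]
    stop_if_grid_mismatch(om$grid, grid, "OAR mask and prior dose")
    treated_z <- rep(FALSE, length(zc))
    if (any(zmask)) {
      zlo <- min(zc[zmask]) - policy$margin_mm
      zhi <- max(zc[zmask]) + policy$margin_mm
      treated_z <- zc >= zlo & zc <= zhi
    }
    slab <- array(rep(treated_z, each = grid$size[1] * grid$size[2]),
                  dim = grid$size)
    treated <- om$values & slab
    untreated <- om$values & !slab
    if (any(treated))
      entries[[length(entries) + 1L]] <- list(
        name = paste0(oar_name, "_treated"), oar = oar_name,
        mask = mask_volume(treated, grid, label = paste0(oar_name, "_treated")),
        max_dose_gy = max(base - red, 0), eqd2_prior_max = NA_real_,
        source = "baseline", infeasible = (base - red) <= 0)
    if (any(untreated))
      entries[[length(entries) + 1L]] <- list(
        name = paste0(oar_name, "_untreated"), oar = oar_name,
        mask = mask_volume(untreated, grid, label = paste0(oar_name, "_untreated")),
        max_dose_gy = base, eqd2_prior_max = NA_real_,
        source = "baseline", infeasible = FALSE)
  }
  constraint_table(entries, plan)
}
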
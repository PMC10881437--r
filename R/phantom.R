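#' Synthetic vertebral-column phantom configuration
#'
#' Describes a deterministic spine-like test case: a stack of vertebral-body
#' levels inside an elliptical body cross-section, a spinal cord cylinder in
#' the canal posterior to the bodies, an esophagus cylinder anterior to them,
#' a prior course delivered to one set of levels and a re-irradiation course
#' to another, linked by an analytic displacement field. The geometric
#' relation of the two target level sets follows the three overlap classes
#' seen clinically: `partial` (neighbouring vertebral bodies), `large`
#' (re-irradiation area contains the prior target) and `complete` (same
#' levels re-treated).
#'
#' The displacement field is `v(x) = rigid_shift + dvf_bias + wiggle(z)`:
#' the rigid shift moves the whole prior anatomy, the smooth sinusoidal
#' wiggle emulates soft-tissue deformation, and `dvf_bias` is a small
#' systematic registration error (the prior anatomy is generated at
#' `rigid_shift` only), so the field is realistically imperfect at the
#' millimetre scale the dose smearing is designed to absorb.
#'
#' @param overlap_class `"partial"`, `"large"` or `"complete"`.
#' @param resolution `"full"` (1 mm voxels), `"small"` (2.5 mm, planning
#'   runs) or `"tiny"` (4 mm, smoke tests); all cover the same 120 x 100 x
#'   160 mm extent.
#' @param prior_plan,reirr_plan [plan_info()] for the two courses.
#' @param prior_levels,reirr_levels integer vertebral-level sets (1-6);
#'   defaults derived from `overlap_class`.
#' @param n_levels,level_thickness_mm,level_gap_mm vertebral column layout.
#' @param cord_radius_mm,cord_center_mm cord cylinder (radius; x/y centre).
#' @param esophagus_radius_mm,esophagus_center_mm esophagus cylinder.
#' @param vertebra_x_mm,vertebra_y_mm vertebral-body box extents.
#' @param rigid_shift_mm true rigid displacement of the prior anatomy.
#' @param dvf_bias_mm residual registration error baked into the field.
#' @param wiggle_amp_mm,wiggle_wavelength_mm sinusoidal deformation.
#' @param falloff_mm exponential dose falloff scale outside the prior target
#'   (6 mm keeps the cord prior EQD2 crossing several 10-GyEQD2 levels).
#' @param seed recorded for provenance (generation is fully deterministic).
#' @return Object of class `phantom_config`.
#' @export
phantom_config <- function(overlap_class = c("partial", "large", "complete"),
                           resolution = c("small", "full", "tiny"),
                           prior_plan = plan_info("prior", 3, 27),
                           reirr_plan = plan_info("reirradiation", 5, 40),
                           prior_levels = NULL, reirr_levels = NULL,
                           n_levels = 6, level_thickness_mm = 25,
                           level_gap_mm = 3,
                           cord_radius_mm = 4, cord_center_mm = c(60, 77),
                           esophagus_radius_mm = 5,
                           esophagus_center_mm = c(60, 40),
                           vertebra_x_mm = c(44, 76),
                           vertebra_y_mm = c(48, 70),
                           rigid_shift_mm = c(1.5, -1, 4),
                           dvf_bias_mm = c(0, 1.2, 0),
                           wiggle_amp_mm = 1.5, wiggle_wavelength_mm = 80,
                           falloff_mm = 6, seed = 1L) {
  overlap_class <- match.arg(overlap_class)
  resolution <- match.arg(resolution)
  if (is.null(prior_levels))
    prior_levels <- switch(overlap_class, partial = c(2, 3), large = 3,
                           complete = c(3, 4))
  if (is.null(reirr_levels))
    reirr_levels <- switch(overlap_class, partial = c(4, 5),
                           large = c(2, 3, 4), complete = c(3, 4))
  if (any(c(prior_levels, reirr_levels) < 1) ||
      any(c(prior_levels, reirr_levels) > n_levels))
    stop("target levels must lie within 1..n_levels")
  ok <- switch(overlap_class,
               partial = !any(prior_levels %in% reirr_levels) &&
                 min(abs(outer(prior_levels, reirr_levels, "-"))) == 1,
               large = all(prior_levels %in% reirr_levels) &&
                 length(reirr_levels) > length(prior_levels),
               complete = setequal(prior_levels, reirr_levels))
  if (!ok) stop(sprintf("target level sets are inconsistent with overlap class '%s'",
                        overlap_class))
  spacing <- switch(resolution, full = c(1, 1, 1), small = c(2.5, 2.5, 2.5),
                    tiny = c(4, 4, 4))
  size <- as.integer(round(c(120, 100, 160) / spacing))
  structure(list(overlap_class = overlap_class, resolution = resolution,
                 size = size, spacing = spacing,
                 prior_plan = prior_plan, reirr_plan = reirr_plan,
                 prior_levels = prior_levels, reirr_levels = reirr_levels,
                 n_levels = n_levels, level_thickness_mm = level_thickness_mm,
                 level_gap_mm = level_gap_mm,
                 cord_radius_mm = cord_radius_mm, cord_center_mm = cord_center_mm,
                 esophagus_radius_mm = esophagus_radius_mm,
                 esophagus_center_mm = esophagus_center_mm,
                 vertebra_x_mm = vertebra_x_mm, vertebra_y_mm = vertebra_y_mm,
                 rigid_shift_mm = rigid_shift_mm, dvf_bias_mm = dvf_bias_mm,
                 wiggle_amp_mm = wiggle_amp_mm,
                 wiggle_wavelength_mm = wiggle_wavelength_mm,
                 falloff_mm = falloff_mm, seed = as.integer(seed)),
            class = "phantom_config")
}

level_z_range <- function(cfg, level) {
  lo <- 5 + cfg$level_thickness_mm * (level - 1) + cfg$level_gap_mm / 2
  hi <- 5 + cfg$level_thickness_mm * level - cfg$level_gap_mm / 2
  c(lo, hi)
}

# cylinder mask along z given x/y centre (after optional shift)
cylinder_mask <- function(grid, center_xy, radius, label = "") {
  xs <- axis_coords(grid, 1); ys <- axis_coords(grid, 2)
  disk <- outer((xs - center_xy[1])^2, (ys - center_xy[2])^2, "+") <= radius^2
  mask_volume(array(disk, dim = grid$size), grid, label = label)
}

box_mask <- function(grid, xr, yr, zr, label = "") {
  xs <- axis_coords(grid, 1); ys <- axis_coords(grid, 2); zs <- axis_coords(grid, 3)
  inx <- xs >= xr[1] & xs <= xr[2]
  iny <- ys >= yr[1] & ys <= yr[2]
  inz <- zs >= zr[1] & zs <= zr[2]
  vals <- array(FALSE, dim = grid$size)
  vals[inx, iny, inz] <- TRUE
  mask_volume(vals, grid, label = label)
}

# geometry of one frame; shift = c(0,0,0) for the re-irradiation frame,
# the rigid anatomy shift for the prior frame
build_frame_masks <- function(cfg, grid, shift, levels, tag) {
  body <- {
    xs <- axis_coords(grid, 1); ys <- axis_coords(grid, 2)
    disk <- outer(((xs - 60 - shift[1]) / 55)^2, ((ys - 50 - shift[2]) / 45)^2, "+") <= 1
    mask_volume(array(disk, dim = grid$size), grid, label = paste0("body", tag))
  }
  cord <- cylinder_mask(grid, cfg$cord_center_mm + shift[1:2],
                        cfg$cord_radius_mm, paste0("spinal_cord", tag))
  eso <- cylinder_mask(grid, cfg$esophagus_center_mm + shift[1:2],
                       cfg$esophagus_radius_mm, paste0("esophagus", tag))
  ctv_vals <- array(FALSE, dim = grid$size)
  for (lv in levels) {
    zr <- level_z_range(cfg, lv) + shift[3]
    b <- box_mask(grid, cfg$vertebra_x_mm + shift[1], cfg$vertebra_y_mm + shift[2], zr)
    ctv_vals <- ctv_vals | b$values
  }
  ctv <- mask_volume(ctv_vals, grid, label = paste0("ctv", tag))
  cord_avoid <- expand_mask_isotropic(cord, 2)
  ptv <- mask_boolean(mask_boolean(expand_mask_isotropic(ctv, 2), cord_avoid,
                                   "minus"), body, "and")
  ptv$label <- paste0("ptv", tag)
  list(body = body, cord = cord, esophagus = eso, ctv = ctv, ptv = ptv)
}

# closed-form prior dose: prescription inside the prior PTV bounding box with
# exponential falloff in the Euclidean distance to the box
prior_dose_params <- function(cfg) {
  s <- cfg$rigid_shift_mm
  zr <- range(unlist(lapply(cfg$prior_levels, function(l) level_z_range(cfg, l))))
  list(lo = c(cfg$vertebra_x_mm[1] - 2 + s[1], cfg$vertebra_y_mm[1] - 2 + s[2],
              zr[1] - 2 + s[3]),
       hi = c(cfg$vertebra_x_mm[2] + 2 + s[1], cfg$vertebra_y_mm[2] + 2 + s[2],
              zr[2] + 2 + s[3]),
       scale = cfg$falloff_mm, rx = cfg$prior_plan$prescription_gy)
}

#' Evaluate the phantom's closed-form prior dose at arbitrary points
#'
#' The analytic ground truth behind the sampled prior-dose volume; because
#' the displacement field is also analytic this provides an end-to-end oracle
#' for the dose mapping.
#'
#' @param params the `prior_dose_params` element of a phantom case.
#' @param points n x 3 matrix of prior-frame mm coordinates.
#' @return Dose in Gy at each point.
#' @export
analytic_prior_dose <- function(params, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  dx <- pmax(params$lo[1] - points[, 1], 0, points[, 1] - params$hi[1])
  dy <- pmax(params$lo[2] - points[, 2], 0, points[, 2] - params$hi[2])
  dz <- pmax(params$lo[3] - points[, 3], 0, points[, 3] - params$hi[3])
  params$rx * exp(-sqrt(dx^2 + dy^2 + dz^2) / params$scale)
}

#' Generate a synthetic re-irradiation test case
#'
#' Deterministic for a given configuration: masks on the re-irradiation grid
#' (body, cord, esophagus, CTV, PTV, and the prior target's PTV drawn on the
#' same anatomy), the prior-frame anatomy and sampled prior dose, the
#' displacement field linking the frames, and both course descriptions.
#' The PTV is a 2 mm expansion of the CTV that crops out a 2 mm cord
#' avoidance margin, so cord and PTV never intersect.
#'
#' @param cfg a [phantom_config()].
#' @return Object of class `phantom_case` with elements `grid`, `masks`
#'   (re-irradiation frame), `prior_masks` (prior frame), `prior_dose`,
#'   `prior_dose_params`, `dvf`, `prior_plan`, `reirr_plan`, `config`.
#' @export
generate_phantom <- function(cfg = phantom_config()) {
  grid <- grid3d(cfg$size, cfg$spacing, origin = c(0, 0, 0))
  reirr <- build_frame_masks(cfg, grid, c(0, 0, 0), cfg$reirr_levels, "")
  prior_on_reirr <- build_frame_masks(cfg, grid, c(0, 0, 0), cfg$prior_levels,
                                      "_prior_course")
  prior <- build_frame_masks(cfg, grid, cfg$rigid_shift_mm, cfg$prior_levels,
                             "_prior_frame")
  params <- prior_dose_params(cfg)
  pd <- analytic_prior_dose(params, voxel_centers(grid))
  prior_dose <- scalar_volume(array(pd, dim = grid$size), grid,
                              quantity = "physical_gy",
                              n_fractions = cfg$prior_plan$n_fractions,
                              label = "prior_dose")
  zs <- axis_coords(grid, 3)
  wig_x <- cfg$wiggle_amp_mm * sin(2 * pi * zs / cfg$wiggle_wavelength_mm)
  wig_y <- 0.75 * cfg$wiggle_amp_mm * cos(2 * pi * zs / cfg$wiggle_wavelength_mm)
  n <- grid$size
  v <- array(0, dim = c(n, 3))
  v[, , , 1] <- cfg$rigid_shift_mm[1] + cfg$dvf_bias_mm[1] +
    rep(wig_x, each = n[1] * n[2])
  v[, , , 2] <- cfg$rigid_shift_mm[2] + cfg$dvf_bias_mm[2] +
    rep(wig_y, each = n[1] * n[2])
  v[, , , 3] <- cfg$rigid_shift_mm[3] + cfg$dvf_bias_mm[3]
  dvf <- vector_field(v, grid, label = "dvf")
  structure(list(
    grid = grid,
    masks = list(body = reirr$body, spinal_cord = reirr$cord,
                 esophagus = reirr$esophagus, ctv = reirr$ctv, ptv = reirr$ptv,
                 prior_ptv = prior_on_reirr$ptv),
    prior_masks = list(body = prior$body, spinal_cord = prior$cord,
                       esophagus = prior$esophagus, ptv = prior$ptv),
    prior_dose = prior_dose, prior_dose_params = params, dvf = dvf,
    prior_plan = cfg$prior_plan, reirr_plan = cfg$reirr_plan, config = cfg),
    class = "phantom_case")
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case> %s overlap, %s resolution (%s)\n",
              x$config$overlap_class, x$config$resolution, format(x$grid)))
  cat(sprintf("  prior: %g Gy x %d fx at levels {%s}; reirr: %g Gy x %d fx at levels {%s}\n",
              x$prior_plan$prescription_gy / x$prior_plan$n_fractions,
              x$prior_plan$n_fractions,
              paste(x$config$prior_levels, collapse = ","),
              x$reirr_plan$prescription_gy / x$reirr_plan$n_fractions,
              x$reirr_plan$n_fractions,
              paste(x$config$reirr_levels, collapse = ",")))
  invisible(x)
}

#' Prior dose rigidly aligned to the planning grid
#'
#' The baseline workflow's view of the prior dose: sampled at
#' `x + rigid_shift + dvf_bias` (the registration's rigid estimate), with no
#' deformation and no smearing.
#'
#' @param case a `phantom_case`.
#' @return A [scalar_volume()] on the planning grid.
#' @export
rigid_mapped_prior_dose <- function(case) {
  shift <- case$config$rigid_shift_mm + case$config$dvf_bias_mm
  pts <- sweep(voxel_centers(case$grid), 2, shift, "+")
  vals <- sample_trilinear(case$prior_dose, pts, fill = 0)
  scalar_volume(array(vals, dim = case$grid$size), case$grid,
                quantity = "physical_gy",
                n_fractions = case$prior_plan$n_fractions,
                label = "prior_dose_rigid")
}

#' Standard scenario suite covering all overlap classes
#'
#' One case per overlap class with the cohort's common fractionation
#' schedules: prior 9 Gy x 3 (partial, complete) or 6 Gy x 5 (large),
#' re-irradiation 8 Gy x 5 throughout.
#'
#' @param seed recorded on each configuration (generation is deterministic).
#' @param resolution grid preset passed to [phantom_config()].
#' @return Named list of `phantom_case` objects
#'   (`partial`, `large`, `complete`).
#' @export
scenario_suite <- function(seed = 1L, resolution = "small") {
  list(
    partial = generate_phantom(phantom_config("partial", resolution,
      prior_plan = plan_info("prior", 3, 27), seed = seed)),
    large = generate_phantom(phantom_config("large", resolution,
      prior_plan = plan_info("prior", 5, 30), seed = seed)),
    complete = generate_phantom(phantom_config("complete", resolution,
      prior_plan = plan_info("prior", 3, 27), seed = seed)))
}

#' Write a phantom case to a directory
#'
#' Serializes every volume as NIfTI plus a `case.json` manifest holding the
#' course metadata and the closed-form prior-dose parameters, so a case can
#' be regenerated, shipped or consumed by the command-line tools without the
#' generator.
#'
#' @param case a [generate_phantom()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom_case <- function(case, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(case$masks))
    write_volume(case$masks[[nm]], file.path(dir, paste0("mask_", nm, ".nii.gz")))
  for (nm in names(case$prior_masks))
    write_volume(case$prior_masks[[nm]],
                 file.path(dir, paste0("prior_mask_", nm, ".nii.gz")))
  write_volume(case$prior_dose, file.path(dir, "prior_dose.nii.gz"))
  write_volume(case$dvf, file.path(dir, "dvf.nii.gz"))
  meta <- list(prior_plan = unclass(case$prior_plan),
               reirr_plan = unclass(case$reirr_plan),
               prior_dose_params = case$prior_dose_params,
               overlap_class = case$config$overlap_class,
               resolution = case$config$resolution,
               rigid_shift_mm = case$config$rigid_shift_mm,
               dvf_bias_mm = case$config$dvf_bias_mm,
               seed = case$config$seed)
  jsonlite::write_json(meta, file.path(dir, "case.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a phantom case back from a directory
#'
#' @param dir directory written by [write_phantom_case()].
#' @return A `phantom_case` (the configuration echo carries only the fields
#'   recorded in `case.json`).
#' @export
read_phantom_case <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "case.json"), simplifyVector = TRUE)
  rd_mask <- function(f) read_volume(file.path(dir, f), "mask")
  mask_files <- list.files(dir, pattern = "^mask_.*\\.nii\\.gz$")
  masks <- lapply(mask_files, rd_mask)
  names(masks) <- sub("^mask_(.*)\\.nii\\.gz$", "\\1", mask_files)
  pmask_files <- list.files(dir, pattern = "^prior_mask_.*\\.nii\\.gz$")
  prior_masks <- lapply(pmask_files, rd_mask)
  names(prior_masks) <- sub("^prior_mask_(.*)\\.nii\\.gz$", "\\1", pmask_files)
  prior_dose <- read_volume(file.path(dir, "prior_dose.nii.gz"), "scalar")
  dvf <- read_volume(file.path(dir, "dvf.nii.gz"), "vector")
  params <- meta$prior_dose_params
  params$lo <- as.numeric(params$lo); params$hi <- as.numeric(params$hi)
  structure(list(
    grid = prior_dose$grid, masks = masks, prior_masks = prior_masks,
    prior_dose = prior_dose, prior_dose_params = params, dvf = dvf,
    prior_plan = plan_info(meta$prior_plan$label, meta$prior_plan$n_fractions,
                           meta$prior_plan$prescription_gy),
    reirr_plan = plan_info(meta$reirr_plan$label, meta$reirr_plan$n_fractions,
                           meta$reirr_plan$prescription_gy),
    config = list(overlap_class = meta$overlap_class,
                  resolution = meta$resolution,
                  rigid_shift_mm = as.numeric(meta$rigid_shift_mm),
                  dvf_bias_mm = as.numeric(meta$dvf_bias_mm),
                  seed = meta$seed)),
    class = "phantom_case")
}
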
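#' Validated run configuration for the end-to-end pipeline
#'
#' Schema-checked settings; unknown keys are rejected before any computation
#' or I/O so a typo cannot silently fall back to a default.
#'
#' @param preset phantom overlap class (`"partial"`, `"large"`,
#'   `"complete"`).
#' @param resolution phantom grid preset (`"small"`, `"full"`, `"tiny"`).
#' @param smearing_radius_mm dose-smearing radius (>= 0).
#' @param restrict_to_structure restrict smearing to the organ contour.
#' @param structure_step_eqd2 isodose step for structure generation (> 0).
#' @param modes constraint modes to plan, subset of `c("dart", "baseline")`.
#' @param robustness_radii_mm radii for the cumulative-dose sweep (include 0)
#'   or `NULL` to skip.
#' @param base_limits named per-organ template Dmax limits (Gy).
#' @param tolerance_eqd2 optional named per-organ cumulative tolerances
#'   overriding [default_oars()].
#' @param optimizer_control list passed to [optimize_fluence()].
#' @param seed integer seed recorded in the manifest.
#' @param ... rejected; present so unknown keys error loudly.
#' @return Object of class `run_config`.
#' @export
run_config <- function(preset = "partial", resolution = "small",
                       smearing_radius_mm = 2, restrict_to_structure = TRUE,
                       structure_step_eqd2 = 10,
                       modes = c("dart", "baseline"),
                       robustness_radii_mm = 0:4,
                       base_limits = c(spinal_cord = 30, esophagus = 35),
                       tolerance_eqd2 = NULL,
                       optimizer_control = list(), seed = 1L, ...) {
  extra <- list(...)
  if (length(extra))
    stop(sprintf("unknown configuration keys: %s",
                 paste(names(extra), collapse = ", ")))
  if (smearing_radius_mm < 0) stop("smearing_radius_mm must be >= 0")
  if (structure_step_eqd2 <= 0) stop("structure_step_eqd2 must be > 0")
  if (!all(modes %in% c("dart", "baseline"))) stop("unknown constraint mode")
  if (!is.null(robustness_radii_mm) && !0 %in% robustness_radii_mm)
    stop("robustness_radii_mm must include 0")
  structure(list(preset = match.arg(preset, c("partial", "large", "complete")),
                 resolution = match.arg(resolution, c("small", "full", "tiny")),
                 smearing_radius_mm = smearing_radius_mm,
                 restrict_to_structure = isTRUE(restrict_to_structure),
                 structure_step_eqd2 = structure_step_eqd2,
                 modes = modes, robustness_radii_mm = robustness_radii_mm,
                 base_limits = base_limits, tolerance_eqd2 = tolerance_eqd2,
                 optimizer_control = optimizer_control,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Load a run configuration from YAML or JSON
#' @param path config file (`.yaml`/`.yml` needs the yaml package, `.json`
#'   uses jsonlite).
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is needed to read YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  # JSON/YAML nulls arrive as empty lists; treat them as absent/NULL
  vals <- lapply(vals, function(v) if (length(v) == 0L) NULL else v)
  explicit_null <- names(vals)[vapply(vals, is.null, TRUE)]
  vals <- Filter(Negate(is.null), vals)
  for (nm in intersect(explicit_null, "robustness_radii_mm"))
    vals[nm] <- list(NULL)
  do.call(run_config, vals)
}

#' Run the full re-irradiation planning workflow on a phantom case
#'
#' Executes the three-step method end to end: (1) map the prior dose onto
#' the planning anatomy with conservative smearing and convert to EQD2 per
#' organ; (2) generate segregated isodose optimization structures; (3)
#' derive the spatially resolved constraint table and optimize the fluence
#' plan under hard maximum-dose constraints. Optionally plans the binary
#' previously-treated baseline comparator with the same beams, matched to
#' the same cumulative tolerance, and sweeps the smearing radius for the
#' cumulative-dose robustness analysis. When `out_dir` is given, every
#' intermediate artifact (volumes as NIfTI, tables and reports as JSON) is
#' written together with a manifest.
#'
#' @param cfg a [run_config()].
#' @param case optional pre-built [generate_phantom()] case; defaults to the
#'   configured preset.
#' @param oars named list of [oar_spec()]s; defaults to [default_oars()]
#'   with any configured tolerance overrides.
#' @param out_dir optional output directory.
#' @return Object of class `pipeline_result` with elements `case`,
#'   `mapped_eqd2`, `shells`, `constraints`, `plans`, `metrics`,
#'   `cumulative`, `comparison`, `robustness`, `feasible`, `pass`.
#' @export
run_pipeline <- function(cfg = run_config(), case = NULL, oars = NULL,
                         out_dir = NULL) {
  t0 <- Sys.time()
  if (is.null(case))
    case <- generate_phantom(phantom_config(cfg$preset, cfg$resolution,
                                            seed = cfg$seed))
  if (is.null(oars)) {
    oars <- default_oars()
    for (nm in names(cfg$tolerance_eqd2))
      oars[[nm]]$tolerance_eqd2 <- cfg$tolerance_eqd2[[nm]]
  }
  oar_masks <- case$masks[names(oars)]
  mcfg <- mapping_config(cfg$smearing_radius_mm, cfg$restrict_to_structure)
  log_stage <- function(fmt, ...)
    message(sprintf("[%5.1fs] ", as.numeric(Sys.time() - t0, units = "secs")),
            sprintf(fmt, ...))

  log_stage("mapping prior dose (radius %g mm)", cfg$smearing_radius_mm)
  mapped_eqd2 <- lapply(names(oars), function(nm)
    mapped_eqd2_for_oar(case$prior_dose, case$dvf, case$grid, mcfg,
                        oars[[nm]], case$prior_masks[[nm]]))
  names(mapped_eqd2) <- names(oars)

  log_stage("generating optimization structures (step %g GyEQD2)",
            cfg$structure_step_eqd2)
  shells <- lapply(names(oars), function(nm)
    generate_structures(mapped_eqd2[[nm]], oar_masks[[nm]], nm,
                        step = cfg$structure_step_eqd2))
  names(shells) <- names(oars)

  log_stage("building influence matrix")
  beams <- beam_set()
  influence <- build_influence_matrix(case$grid, case$masks$body, beams,
                                      case$masks$ptv)
  rx <- case$reirr_plan$prescription_gy

  plans <- list(); tables <- list()
  if ("dart" %in% cfg$modes) {
    log_stage("deriving constraint table and optimizing (spatially resolved)")
    tables$dart <- dart_constraint_table(shells, oars, case$reirr_plan,
                                         oar_masks, mapped_eqd2,
                                         cfg$base_limits)
    plans$dart <- optimize_fluence(influence, case$masks$ptv, rx,
                                   tables$dart, cfg$optimizer_control)
  }
  if ("baseline" %in% cfg$modes) {
    log_stage("deriving constraint table and optimizing (binary baseline)")
    rigid <- rigid_mapped_prior_dose(case)
    tables$baseline <- baseline_constraint_table(
      rigid, oar_masks, baseline_policy(base_limits = cfg$base_limits),
      case$reirr_plan)
    plans$baseline <- optimize_fluence(influence, case$masks$ptv, rx,
                                       tables$baseline, cfg$optimizer_control)
  }

  log_stage("evaluating plans")
  metrics <- lapply(plans, function(p)
    metric_panel(p$dose, case$masks$ptv, rx, oar_masks))
  cumulative <- lapply(plans, function(p)
    cumulative_oar_report(mapped_eqd2, p$dose, oars, oar_masks))
  comparison <- if (all(c("dart", "baseline") %in% names(plans)))
    compare_plans(plans$dart, plans$baseline, case$masks$ptv, rx, oars,
                  oar_masks, mapped_eqd2) else NULL

  robustness <- NULL
  if (!is.null(cfg$robustness_radii_mm) && length(plans)) {
    log_stage("robustness sweep over smearing radii {%s} mm",
              paste(cfg$robustness_radii_mm, collapse = ","))
    ref <- plans[[if ("dart" %in% names(plans)) "dart" else 1L]]
    robustness <- robustness_sweep(case$prior_dose, case$dvf, ref$dose, oars,
                                   oar_masks, case$prior_masks,
                                   cfg$robustness_radii_mm, mcfg)
  }

  res <- structure(list(
    case = case, config = cfg, oars = oars, mapped_eqd2 = mapped_eqd2,
    shells = shells, constraints = tables, influence = influence,
    plans = plans, metrics = metrics, cumulative = cumulative,
    comparison = comparison, robustness = robustness,
    feasible = all(vapply(plans, `[[`, TRUE, "feasible")),
    pass = if ("dart" %in% names(cumulative)) all(cumulative$dart$pass) else NA),
    class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  log_stage("done")
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %s overlap, modes {%s}; feasible: %s; cumulative pass: %s\n",
              x$case$config$overlap_class, paste(names(x$plans), collapse = ","),
              x$feasible, x$pass))
  for (nm in names(x$metrics))
    cat(sprintf("  %-9s D99 %6.2f Gy  V100 %6.2f %%  CI %.3f  HI %.3f  GI %.2f\n",
                nm, x$metrics[[nm]]$D99, x$metrics[[nm]]$V100,
                x$metrics[[nm]]$CI, x$metrics[[nm]]$HI, x$metrics[[nm]]$GI))
  invisible(x)
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  vol <- function(v, name) write_volume(v, file.path(out_dir, paste0(name, ".nii.gz")))
  for (nm in names(res$mapped_eqd2)) vol(res$mapped_eqd2[[nm]], paste0("mapped_eqd2_", nm))
  for (nm in names(res$case$masks)) vol(res$case$masks[[nm]], paste0("mask_", nm))
  for (nm in names(res$plans)) vol(res$plans[[nm]]$dose, paste0("dose_", nm))
  for (nm in names(res$constraints))
    write_constraint_table(res$constraints[[nm]],
                           file.path(out_dir, paste0("constraints_", nm, ".json")))
  structs <- lapply(names(res$shells), function(oar)
    lapply(res$shells[[oar]], function(s)
      list(oar = oar, level_eqd2 = s$level_eqd2,
           volume_cm3 = volume_cm3(s$mask),
           eqd2_prior_max = s$eqd2_prior_max)))
  report <- list(
    config = unclass(res$config),
    feasible = res$feasible, cumulative_pass = res$pass,
    structures = structs, metrics = res$metrics,
    cumulative = lapply(res$cumulative, function(d) as.list(d)),
    robustness = if (is.null(res$robustness)) NULL else as.list(res$robustness))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  manifest <- list(package = "dartplan",
                   version = as.character(utils::packageVersion("dartplan")),
                   files = sort(list.files(out_dir)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
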
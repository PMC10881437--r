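#' Organ-at-risk radiobiological specification
#'
#' Bundles the linear-quadratic sensitivity ratio and the cumulative
#' maximum-dose tissue tolerance used to budget re-irradiation dose. The
#' tolerance is the total EQD2 the organ may accumulate over both courses at
#' any voxel; it is a clinical input, not a package assertion.
#'
#' @param name organ name, e.g. `"spinal_cord"`.
#' @param alpha_beta linear-quadratic alpha/beta ratio in Gy (> 0); late
#'   responding tissues such as cord and esophagus sit at 2-3 Gy.
#' @param tolerance_eqd2 cumulative maximum-dose tolerance in GyEQD2 (> 0).
#' @param clinical_criteria optional named list of per-course reporting
#'   criteria, e.g. `list(D0.035cm3 = 30)`.
#' @return Object of class `oar_spec`.
#' @export
oar_spec <- function(name, alpha_beta, tolerance_eqd2, clinical_criteria = list()) {
  if (alpha_beta <= 0) stop("alpha_beta must be > 0")
  if (tolerance_eqd2 <= 0) stop("tolerance_eqd2 must be > 0")
  structure(list(name = name, alpha_beta = alpha_beta,
                 tolerance_eqd2 = tolerance_eqd2,
                 clinical_criteria = clinical_criteria),
            class = "oar_spec")
}

#' @export
print.oar_spec <- function(x, ...) {
  cat(sprintf("<oar_spec> %s: alpha/beta %.3g Gy, cumulative tolerance %.4g GyEQD2\n",
              x$name, x$alpha_beta, x$tolerance_eqd2))
  invisible(x)
}

#' Default organ-at-risk specifications for paraspinal planning
#'
#' Spinal cord (alpha/beta 2 Gy) and esophagus (alpha/beta 3 Gy) with
#' documented placeholder cumulative tolerances (70 and 84 GyEQD2). These are
#' configuration defaults for phantom studies, not clinical recommendations;
#' real cases must supply institutional values.
#'
#' @return Named list of [oar_spec()] objects.
#' @export
default_oars <- function() {
  list(spinal_cord = oar_spec("spinal_cord", alpha_beta = 2, tolerance_eqd2 = 70),
       esophagus = oar_spec("esophagus", alpha_beta = 3, tolerance_eqd2 = 84))
}

#' Treatment course metadata
#'
#' @param label course label, e.g. `"prior"` or `"reirradiation"`.
#' @param n_fractions number of fractions (>= 1).
#' @param prescription_gy total prescription over the course in Gy (> 0).
#' @return Object of class `plan_info`.
#' @export
plan_info <- function(label, n_fractions, prescription_gy) {
  n_fractions <- as.integer(n_fractions)
  if (is.na(n_fractions) || n_fractions < 1L) stop("n_fractions must be >= 1")
  if (prescription_gy <= 0) stop("prescription_gy must be > 0")
  structure(list(label = label, n_fractions = n_fractions,
                 prescription_gy = prescription_gy),
            class = "plan_info")
}

#' @export
print.plan_info <- function(x, ...) {
  cat(sprintf("<plan_info> %s: %.3g Gy in %d fx (%.3g Gy/fx)\n",
              x$label, x$prescription_gy, x$n_fractions,
              x$prescription_gy / x$n_fractions))
  invisible(x)
}

#' Equivalent dose in 2 Gy fractions
#'
#' Linear-quadratic rescaling of a total course dose delivered in `n` equal
#' fractions: `EQD2 = D * (D/n + alpha_beta) / (2 + alpha_beta)`. The 2 Gy
#' reference fraction size is part of the definition of EQD2 and is not
#' configurable. At 2 Gy per fraction the map is the identity.
#'
#' @param total_dose total physical dose in Gy (vectorised, >= 0).
#' @param n number of fractions (>= 1).
#' @param alpha_beta alpha/beta ratio in Gy (> 0).
#' @return EQD2 in Gy (same length as `total_dose`).
#' @examples
#' eqd2_total(40, n = 5, alpha_beta = 2)  # 8 Gy/fx -> 100 GyEQD2
#' @export
eqd2_total <- function(total_dose, n, alpha_beta) {
  if (alpha_beta <= 0) stop("alpha_beta must be > 0")
  if (n < 1) stop("n must be >= 1")
  if (any(total_dose < 0)) stop("total_dose must be >= 0")
  total_dose * (total_dose / n + alpha_beta) / (2 + alpha_beta)
}

#' Convert a physical dose volume to EQD2 voxel by voxel
#'
#' Each voxel's total course dose `D_v` is assumed delivered in the volume's
#' `n_fractions` equal fractions of `D_v / n`, the standard assumption for a
#' single plan's dose distribution.
#'
#' @param vol a [scalar_volume()] with quantity `"physical_gy"` and a fraction
#'   count.
#' @param alpha_beta alpha/beta ratio of the tissue of interest (Gy).
#' @return A `scalar_volume` with quantity `"eqd2_gy"` on the same grid.
#' @export
eqd2_volume <- function(vol, alpha_beta) {
  if (!inherits(vol, "scalar_volume") || vol$quantity != "physical_gy")
    stop("eqd2_volume expects a physical_gy scalar_volume")
  if (is.null(vol$n_fractions)) stop("volume carries no n_fractions")
  vals <- eqd2_total(vol$values, vol$n_fractions, alpha_beta)
  scalar_volume(array(vals, dim = vol$grid$size), vol$grid, quantity = "eqd2_gy",
                n_fractions = vol$n_fractions, label = vol$label)
}

#' Physical dose limit exhausting a remaining EQD2 budget
#'
#' Inverts the EQD2 definition for a course of `n` fractions: returns the
#' total physical dose `D` with `eqd2_total(D, n, alpha_beta) == budget`,
#' i.e. the positive root of `D^2/n + D*alpha_beta = budget*(2 + alpha_beta)`:
#'
#' `D = n * (sqrt((ab/2)^2 + budget*(2 + ab)/n) - ab/2)`
#'
#' This is the remaining physical dose at the tissue tolerance when `budget`
#' is the tolerance minus the maximum prior EQD2 of a structure. Non-positive
#' budgets clamp to 0 Gy and are flagged infeasible (the voxel can take no
#' further dose at all), letting the pipeline finish and surface the clinical
#' problem instead of crashing.
#'
#' @param budget_eqd2 remaining EQD2 budget in GyEQD2 (vectorised).
#' @param n number of fractions of the new course (>= 1).
#' @param alpha_beta alpha/beta ratio in Gy (> 0).
#' @return Numeric vector of physical dose limits in Gy, with a logical
#'   attribute `"infeasible"` marking entries whose budget was <= 0.
#' @examples
#' physical_dose_for_budget(100, n = 5, alpha_beta = 2)  # 40 Gy
#' @export
physical_dose_for_budget <- function(budget_eqd2, n, alpha_beta) {
  if (alpha_beta <= 0) stop("alpha_beta must be > 0")
  if (n < 1) stop("n must be >= 1")
  ab2 <- alpha_beta / 2
  pos <- pmax(budget_eqd2, 0)
  d <- n * (sqrt(ab2^2 + pos * (2 + alpha_beta) / n) - ab2)
  d[budget_eqd2 <= 0] <- 0
  attr(d, "infeasible") <- budget_eqd2 <= 0
  d
}

#' Voxelwise radiobiological dose summation
#'
#' Adds two EQD2 volumes on the same grid; this is how cumulative dose across
#' courses with different fractionation is accumulated (convert each course
#' to EQD2 with the organ's alpha/beta, then sum per voxel).
#'
#' @param a,b `scalar_volume` objects with quantity `"eqd2_gy"` on one grid.
#' @return A `scalar_volume` in `"eqd2_gy"`.
#' @export
accumulate_eqd2 <- function(a, b) {
  if (!inherits(a, "scalar_volume") || !inherits(b, "scalar_volume"))
    stop("accumulate_eqd2 expects two scalar_volume objects")
  if (a$quantity != "eqd2_gy" || b$quantity != "eqd2_gy")
    stop("both volumes must carry quantity eqd2_gy (mixed quantity tags)")
  stop_if_grid_mismatch(a$grid, b$grid, "EQD2 volumes")
  scalar_volume(a$values + b$values, a$grid, quantity = "eqd2_gy",
                label = a$label)
}
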
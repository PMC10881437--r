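#' Coplanar beam arrangement
#'
#' Parallel-ray IMRT beam geometry: `n_beams` coplanar fields with gantry
#' angles spanning `span_deg` around `center_deg` (180 deg = posterior, the
#' standard paraspinal arrangement). Each beam carries a rectangular beamlet
#' grid of `beamlet_width_mm` resolution sized at build time to the target's
#' projection plus `aperture_margin_mm`.
#'
#' @param n_beams number of beams (>= 1; default 9).
#' @param span_deg angular span in degrees (default 160).
#' @param center_deg central gantry angle (default 180, posterior).
#' @param beamlet_width_mm beamlet pitch in mm (> 0; default 5).
#' @param aperture_margin_mm margin added around the target projection.
#' @return Object of class `beam_set`.
#' @export
beam_set <- function(n_beams = 9, span_deg = 160, center_deg = 180,
                     beamlet_width_mm = 5, aperture_margin_mm = 7.5) {
  if (n_beams < 1) stop("need at least one beam")
  if (beamlet_width_mm <= 0) stop("beamlet width must be > 0")
  angles <- if (n_beams == 1) center_deg else
    seq(center_deg - span_deg / 2, center_deg + span_deg / 2,
        length.out = n_beams)
  beams <- lapply(angles, function(g) {
    gr <- g * pi / 180
    list(gantry_deg = g,
         direction = c(-sin(gr), cos(gr), 0),   # travel direction
         e1 = c(cos(gr), sin(gr), 0), e2 = c(0, 0, 1))
  })
  structure(list(beams = beams, beamlet_width_mm = beamlet_width_mm,
                 aperture_margin_mm = aperture_margin_mm),
            class = "beam_set")
}

#' Pencil-beam influence matrix
#'
#' Dose per unit beamlet fluence at every body voxel, using a simple
#' exponential-attenuation times lateral-Gaussian kernel:
#' `exp(-mu_eff * depth) * exp(-r_lat^2 / (2 * sigma^2))`, zero outside the
#' body and beyond 3 sigma laterally. Depth is the in-body path length from
#' the surface along the (parallel) beam direction, ray-marched on the body
#' mask. This is deliberately minimal plumbing: it provides the linearity and
#' geometry the constraint-generation method needs from a dose engine,
#' nothing more.
#'
#' @param grid planning [grid3d()].
#' @param body_mask body [mask_volume()].
#' @param beams a [beam_set()].
#' @param target_mask [mask_volume()] whose projection sizes each beam's
#'   beamlet aperture.
#' @param kernel list with `mu_eff` (1/mm) and `sigma_mm` (lateral spread).
#' @param march_step_mm ray-march step for depth computation.
#' @return Object of class `influence_matrix`: sparse matrix `M` (body voxel
#'   x beamlet, Gy per unit fluence), `voxel_index` into the grid array,
#'   `beamlet_info`, `grid`, `beams`.
#' @export
build_influence_matrix <- function(grid, body_mask, beams, target_mask,
                                   kernel = list(mu_eff = 0.005, sigma_mm = 3),
                                   march_step_mm = 2) {
  if (kernel$mu_eff <= 0 || kernel$sigma_mm <= 0)
    stop("kernel parameters must be > 0")
  stop_if_grid_mismatch(grid, body_mask$grid, "grid and body mask")
  voxel_index <- which(body_mask$values)
  x <- voxel_centers(grid)[voxel_index, , drop = FALSE]
  tgt <- voxel_centers(grid)[which(target_mask$values), , drop = FALSE]
  sigma <- kernel$sigma_mm; w <- beams$beamlet_width_mm
  extent <- sqrt(sum((grid$spacing * grid$size)^2))
  triplets_i <- list(); triplets_j <- list(); triplets_x <- list()
  binfo <- list(); jbase <- 0L
  for (b in beams$beams) {
    d <- b$direction
    # radiological depth: in-body path upstream of each voxel
    steps <- seq(march_step_mm / 2, extent, by = march_step_mm)
    depth <- numeric(nrow(x))
    for (s in steps) {
      q <- x - matrix(d, nrow(x), 3, byrow = TRUE) * s
      depth <- depth + march_step_mm *
        sample_nearest(body_mask$values, grid, q, fill = FALSE)
    }
    att <- exp(-kernel$mu_eff * depth)
    u1 <- x %*% b$e1; u2 <- x %*% b$e2
    t1 <- tgt %*% b$e1; t2 <- tgt %*% b$e2
    c1 <- beamlet_centers(range(t1), w, beams$aperture_margin_mm)
    c2 <- beamlet_centers(range(t2), w, beams$aperture_margin_mm)
    if (length(c1) == 0L || length(c2) == 0L) {
      warning(sprintf("beam at %g deg misses the target projection", b$gantry_deg))
      next
    }
    for (cc2 in c2) {
      near2 <- which(abs(u2 - cc2) <= 3 * sigma)
      if (!length(near2)) next
      g2 <- exp(-(u2[near2] - cc2)^2 / (2 * sigma^2))
      for (cc1 in c1) {
        jbase <- jbase + 1L
        sel <- which(abs(u1[near2] - cc1) <= 3 * sigma)
        binfo[[jbase]] <- c(b$gantry_deg, cc1, cc2)
        if (!length(sel)) next
        rows <- near2[sel]
        vals <- att[rows] * g2[sel] *
          exp(-(u1[rows] - cc1)^2 / (2 * sigma^2))
        triplets_i[[jbase]] <- rows
        triplets_j[[jbase]] <- rep(jbase, length(rows))
        triplets_x[[jbase]] <- as.numeric(vals)
      }
    }
  }
  n_beamlets <- jbase
  M <- Matrix::sparseMatrix(i = unlist(triplets_i), j = unlist(triplets_j),
                            x = unlist(triplets_x),
                            dims = c(nrow(x), n_beamlets))
  bi <- do.call(rbind, binfo)
  colnames(bi) <- c("gantry_deg", "u1_mm", "u2_mm")
  structure(list(M = M, voxel_index = voxel_index, grid = grid,
                 beams = beams, n_beamlets = n_beamlets,
                 beamlet_info = as.data.frame(bi)),
            class = "influence_matrix")
}

beamlet_centers <- function(rng, width, margin) {
  lo <- rng[1] - margin; hi <- rng[2] + margin
  k <- max(1L, ceiling((hi - lo) / width))
  lo + (seq_len(k) - 0.5) * (hi - lo) / k
}

#' @export
print.influence_matrix <- function(x, ...) {
  cat(sprintf("<influence_matrix> %d body voxels x %d beamlets, %.2f M nonzeros\n",
              nrow(x$M), x$n_beamlets, Matrix::nnzero(x$M) / 1e6))
  invisible(x)
}

#' Dose distribution of a fluence vector
#'
#' @param influence an [build_influence_matrix()] result.
#' @param fluence non-negative beamlet weights.
#' @param n_fractions fraction count stamped on the returned volume.
#' @return A [scalar_volume()] (physical Gy) on the planning grid.
#' @export
fluence_dose <- function(influence, fluence, n_fractions) {
  vals <- numeric(prod(influence$grid$size))
  vals[influence$voxel_index] <- as.numeric(influence$M %*% fluence)
  scalar_volume(array(vals, dim = influence$grid$size), influence$grid,
                quantity = "physical_gy", n_fractions = n_fractions,
                label = "plan_dose")
}

spectral_norm_sq <- function(M, iters = 30) {
  if (nrow(M) == 0L || ncol(M) == 0L) return(0)
  v <- rep(1, ncol(M)); v <- v / sqrt(sum(v^2))
  for (i in seq_len(iters)) {
    w <- as.numeric(Matrix::crossprod(M, M %*% v))
    nw <- sqrt(sum(w^2))
    if (nw == 0) return(0)
    v <- w / nw
  }
  nw
}

#' Two-phase constrained fluence optimization
#'
#' A deterministic convex stand-in for a hierarchical constrained plan
#' optimizer, implementing exactly the property the constraint-generation
#' method requires of it: the per-structure maximum-dose limits are hard.
#'
#' Phase 1 checks feasibility: with the mean PTV dose pinned to the
#' prescription, it minimizes the total quadratic violation of the
#' constraints over non-negative fluence (projected gradient). If violations
#' cannot be driven to (near) zero, the plan is returned with
#' `feasible = FALSE`. Phase 2 minimizes PTV underdose (below a small
#' headroom above prescription) plus a weak penalty on dose above 105% of
#' prescription outside the PTV, with a ramped quadratic penalty holding the
#' constraints; a final conservative rescale guarantees every returned
#' feasible plan satisfies all hard limits to within `hard_tol_gy`.
#'
#' @param influence an influence matrix from [build_influence_matrix()].
#' @param ptv target [mask_volume()] on the planning grid.
#' @param prescription total prescription in Gy.
#' @param constraints a [constraint_table()] (masks on the planning grid).
#' @param control list of solver settings: `phase1_iter`, `phase2_iter`,
#'   `rho_schedule`, `spill_weight`, `target_headroom`, `feas_tol_gy`,
#'   `hard_tol_gy`.
#' @return Object of class `fluence_plan`: `fluence`, `dose`
#'   ([scalar_volume()]), `feasible`, `objective_report`.
#' @export
optimize_fluence <- function(influence, ptv, prescription, constraints,
                             control = list()) {
  ctl <- utils::modifyList(list(phase1_iter = 250L, phase2_iter = 250L,
                                rho_schedule = c(30, 300, 3000, 3e4),
                                spill_weight = 0.2, target_headroom = 1.03,
                                feas_tol_gy = 0.1, hard_tol_gy = 0.1), control)
  A <- influence$M
  inptv <- influence$voxel_index %in% which(ptv$values)
  if (!any(inptv)) stop("PTV contains no body voxels")
  Ap <- A[inptv, , drop = FALSE]
  Ao <- A[!inptv, , drop = FALSE]
  crow <- integer(0); climit <- numeric(0)
  for (e in constraints$entries) {
    r <- which(influence$voxel_index %in% which(e$mask$values))
    crow <- c(crow, r); climit <- c(climit, rep(e$max_dose_gy, length(r)))
  }
  Ac <- A[crow, , drop = FALSE]
  np <- nrow(Ap)
  Lp <- spectral_norm_sq(Ap); Lc <- spectral_norm_sq(Ac); Lo <- spectral_norm_sq(Ao)

  # ---- phase 1: feasibility at pinned mean PTV dose
  mrow <- Matrix::colMeans(Ap)
  kappa <- 4 / max(prescription^2, 1)
  f <- rep(0, ncol(A))
  L1 <- 2 * Lc + 2 * kappa * sum(mrow^2) + 1e-9
  step <- 1 / L1
  for (it in seq_len(ctl$phase1_iter)) {
    viol <- as.numeric(Ac %*% f) - climit
    viol[viol < 0] <- 0
    mgap <- sum(mrow * f) - prescription
    grad <- 2 * as.numeric(Matrix::crossprod(Ac, viol)) + 2 * kappa * mgap * mrow
    f <- pmax(f - step * grad, 0)
  }
  viol1 <- max(c(as.numeric(Ac %*% f) - climit, 0))
  feasible <- viol1 <= ctl$feas_tol_gy

  # ---- phase 2: coverage under ramped hard-constraint penalty
  rx_obj <- ctl$target_headroom * prescription
  spill_lvl <- 1.05 * prescription
  report <- list(phase1_max_violation_gy = viol1)
  if (feasible) {
    for (rho in ctl$rho_schedule) {
      L2 <- 2 * (Lp + ctl$spill_weight * Lo + rho * Lc) + 1e-9
      step <- 1 / L2
      fprev <- f; y <- f; tk <- 1
      for (it in seq_len(ctl$phase2_iter)) {
        under <- rx_obj - as.numeric(Ap %*% y); under[under < 0] <- 0
        over <- as.numeric(Ao %*% y) - spill_lvl; over[over < 0] <- 0
        viol <- as.numeric(Ac %*% y) - climit; viol[viol < 0] <- 0
        grad <- -2 * as.numeric(Matrix::crossprod(Ap, under)) +
          2 * ctl$spill_weight * as.numeric(Matrix::crossprod(Ao, over)) +
          2 * rho * as.numeric(Matrix::crossprod(Ac, viol))
        fnew <- pmax(y - step * grad, 0)
        tnew <- (1 + sqrt(1 + 4 * tk^2)) / 2
        y <- fnew + (tk - 1) / tnew * (fnew - fprev)
        fprev <- fnew; tk <- tnew
      }
      f <- fprev
      if (max(c(as.numeric(Ac %*% f) - climit, 0)) <= ctl$hard_tol_gy / 2) break
    }
    # conservative rescale: enforce the hard limits exactly
    dc <- as.numeric(Ac %*% f)
    over <- dc > climit & dc > 0
    if (any(over)) {
      if (any(climit[over] <= 0)) {
        feasible <- FALSE
      } else {
        f <- f * min(climit[over] / dc[over])
      }
    }
    report$phase2_max_violation_gy <- max(c(as.numeric(Ac %*% f) - climit, 0))
    under <- rx_obj - as.numeric(Ap %*% f); under[under < 0] <- 0
    report$phase2_underdose_ms_gy2 <- mean(under^2)
  }
  dose <- fluence_dose(influence, f, constraints$plan$n_fractions)
  structure(list(fluence = f, dose = dose, feasible = feasible,
                 objective_report = report, prescription = prescription),
            class = "fluence_plan")
}

#' @export
print.fluence_plan <- function(x, ...) {
  cat(sprintf("<fluence_plan> %d beamlets, prescription %g Gy, feasible: %s\n",
              length(x$fluence), x$prescription, x$feasible))
  cat(sprintf("  max constrained-structure violation: %.4f Gy\n",
              x$objective_report$phase2_max_violation_gy %||%
                x$objective_report$phase1_max_violation_gy))
  invisible(x)
}

#' Side-by-side plan comparison
#'
#' Computes the standard metric panel for two plans of the same case (e.g.
#' the spatially resolved and the binary-baseline constraint approach), their
#' differences, and the cumulative per-organ EQD2 validation for both. The
#' comparison is fair by construction when both constraint tables were
#' derived for the same cumulative tolerance.
#'
#' @param plan_a,plan_b [optimize_fluence()] results (a minus b in the
#'   differences).
#' @param ptv target mask.
#' @param prescription prescription in Gy.
#' @param oars named list of [oar_spec()]s.
#' @param oar_masks named list of organ masks on the planning grid.
#' @param prior_eqd2_mapped named list of mapped prior EQD2 volumes per organ.
#' @param slack_eqd2 accepted cumulative exceedance (GyEQD2).
#' @return Object of class `plan_comparison`: `panel_a`, `panel_b`, `diff`,
#'   `cumulative_a`, `cumulative_b`.
#' @export
compare_plans <- function(plan_a, plan_b, ptv, prescription, oars, oar_masks,
                          prior_eqd2_mapped, slack_eqd2 = 1) {
  stop_if_grid_mismatch(plan_a$dose$grid, plan_b$dose$grid, "plan doses")
  pa <- metric_panel(plan_a$dose, ptv, prescription, oar_masks)
  pb <- metric_panel(plan_b$dose, ptv, prescription, oar_masks)
  keys <- c("D99", "D95", "V95", "V100", "spillage_cm3", "CI", "HI", "GI")
  diff <- stats::setNames(lapply(keys, function(k) pa[[k]] - pb[[k]]), keys)
  ca <- cumulative_oar_report(prior_eqd2_mapped, plan_a$dose, oars, oar_masks,
                              slack_eqd2)
  cb <- cumulative_oar_report(prior_eqd2_mapped, plan_b$dose, oars, oar_masks,
                              slack_eqd2)
  structure(list(panel_a = pa, panel_b = pb, diff = diff,
                 cumulative_a = ca, cumulative_b = cb),
            class = "plan_comparison")
}

#' @export
print.plan_comparison <- function(x, ...) {
  cat("<plan_comparison> (A - B)\n")
  for (k in names(x$diff))
    cat(sprintf("  %-13s A %8.3f  B %8.3f  diff %+8.3f\n",
                k, x$panel_a[[k]], x$panel_b[[k]], x$diff[[k]]))
  cat("  cumulative EQD2 Dmax (A | B) vs tolerance:\n")
  for (i in seq_len(nrow(x$cumulative_a)))
    cat(sprintf("  %-13s %7.2f | %7.2f  (tol %.1f, pass %s | %s)\n",
                x$cumulative_a$oar[i], x$cumulative_a$cum_dmax_eqd2[i],
                x$cumulative_b$cum_dmax_eqd2[i], x$cumulative_a$tolerance_eqd2[i],
                x$cumulative_a$pass[i], x$cumulative_b$pass[i]))
  invisible(x)
}
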
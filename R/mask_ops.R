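#' Isotropic expansion of a binary mask
#'
#' Dilates a structure by a physical radius: a voxel is added iff its centre
#' lies within `radius_mm` (Euclidean) of the centre of some true voxel of the
#' input. Used for the small-structure robustness expansion (0.2 cm applied to
#' optimization structures below 1 cm^3, clipped to the parent organ) and for
#' PTV/CTV margin construction in the phantom.
#'
#' @param mask a [mask_volume()].
#' @param radius_mm expansion radius in mm (>= 0); 0 returns the input.
#' @param restrict optional `mask_volume` on the same grid; the result is
#'   intersected with it (`(input OR dilation) AND restrict`).
#' @return A `mask_volume` on the same grid.
#' @export
expand_mask_isotropic <- function(mask, radius_mm, restrict = NULL) {
  if (radius_mm < 0) stop("expansion radius must be >= 0")
  if (!is.null(restrict))
    stop_if_grid_mismatch(mask$grid, restrict$grid, "mask and restrict")
  out <- mask$values
  if (radius_mm > 0 && any(mask$values)) {
    off <- ball_offsets(mask$grid$spacing, radius_mm)
    n <- mask$grid$size
    tv <- which(mask$values)
    ind <- arrayInd(tv, n)  # 1-based
    for (r in seq_len(nrow(off))) {
      d <- off[r, ]
      if (all(d == 0)) next
      i <- ind[, 1] + d[1]; j <- ind[, 2] + d[2]; k <- ind[, 3] + d[3]
      ok <- i >= 1 & i <= n[1] & j >= 1 & j <= n[2] & k >= 1 & k <= n[3]
      out[cbind(i[ok], j[ok], k[ok])] <- TRUE
    }
  }
  if (!is.null(restrict)) out <- out & restrict$values
  mask_volume(out, mask$grid, label = mask$label)
}

# Integer index offsets whose physical displacement has norm <= radius.
ball_offsets <- function(spacing, radius_mm) {
  m <- floor(radius_mm / spacing)
  g <- expand.grid(di = -m[1]:m[1], dj = -m[2]:m[2], dk = -m[3]:m[3])
  d2 <- (g$di * spacing[1])^2 + (g$dj * spacing[2])^2 + (g$dk * spacing[3])^2
  as.matrix(g[d2 <= radius_mm^2 + 1e-9, , drop = FALSE])
}

#' Voxelwise boolean algebra on masks
#'
#' @param a,b `mask_volume` objects on the same grid.
#' @param op one of `"and"`, `"or"`, `"minus"`.
#' @return A `mask_volume`.
#' @export
mask_boolean <- function(a, b, op = c("and", "or", "minus")) {
  op <- match.arg(op)
  stop_if_grid_mismatch(a$grid, b$grid, "masks")
  vals <- switch(op,
                 and = a$values & b$values,
                 or = a$values | b$values,
                 minus = a$values & !b$values)
  mask_volume(vals, a$grid, label = a$label)
}
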
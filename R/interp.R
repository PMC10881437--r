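#' Trilinear sampling of a scalar volume at physical points
#'
#' Interpolates the voxel-centre lattice trilinearly. At a voxel centre the
#' result is exactly that voxel's value; outside the voxel-centre bounding box
#' the `fill` value is returned (prior dose outside the scanned volume is
#' unknown, and 0 Gy is the only non-inflating default).
#'
#' @param vol a [scalar_volume()].
#' @param points n x 3 matrix (or length-3 vector) of mm coordinates.
#' @param fill value returned for points outside the voxel-centre bounding box.
#' @return Numeric vector of length `nrow(points)`.
#' @export
sample_trilinear <- function(vol, points, fill = 0) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  stopifnot(ncol(points) == 3)
  if (any(!is.finite(points))) stop("sample points must be finite")
  interp_array3(vol$values, vol$grid, points, fill)
}

# Core trilinear interpolation of a plain 3D array on a grid3d.
interp_array3 <- function(arr, grid, points, fill = 0) {
  n <- grid$size
  t1 <- (points[, 1] - grid$origin[1]) / grid$spacing[1]
  t2 <- (points[, 2] - grid$origin[2]) / grid$spacing[2]
  t3 <- (points[, 3] - grid$origin[3]) / grid$spacing[3]
  inside <- t1 >= 0 & t1 <= n[1] - 1 & t2 >= 0 & t2 <= n[2] - 1 &
            t3 >= 0 & t3 <= n[3] - 1
  out <- rep(as.numeric(fill), length(t1))
  if (!any(inside)) return(out)
  t1 <- t1[inside]; t2 <- t2[inside]; t3 <- t3[inside]
  # lower corner, clamped so upper corner stays in range even at the far face
  i0 <- pmin(floor(t1), n[1] - 2); i0 <- pmax(i0, 0)
  j0 <- pmin(floor(t2), n[2] - 2); j0 <- pmax(j0, 0)
  k0 <- pmin(floor(t3), n[3] - 2); k0 <- pmax(k0, 0)
  if (n[1] == 1L) i0 <- rep(0, length(t1))
  if (n[2] == 1L) j0 <- rep(0, length(t2))
  if (n[3] == 1L) k0 <- rep(0, length(t3))
  fx <- t1 - i0; fy <- t2 - j0; fz <- t3 - k0
  v <- as.vector(arr)
  idx <- function(di, dj, dk) {
    ii <- pmin(i0 + di, n[1] - 1); jj <- pmin(j0 + dj, n[2] - 1)
    kk <- pmin(k0 + dk, n[3] - 1)
    1 + ii + n[1] * (jj + n[2] * kk)
  }
  acc <- v[idx(0, 0, 0)] * (1 - fx) * (1 - fy) * (1 - fz) +
         v[idx(1, 0, 0)] * fx       * (1 - fy) * (1 - fz) +
         v[idx(0, 1, 0)] * (1 - fx) * fy       * (1 - fz) +
         v[idx(1, 1, 0)] * fx       * fy       * (1 - fz) +
         v[idx(0, 0, 1)] * (1 - fx) * (1 - fy) * fz +
         v[idx(1, 0, 1)] * fx       * (1 - fy) * fz +
         v[idx(0, 1, 1)] * (1 - fx) * fy       * fz +
         v[idx(1, 1, 1)] * fx       * fy       * fz
  out[inside] <- acc
  out
}

# Nearest-neighbour sampling of an arbitrary 3D array (used for masks).
sample_nearest <- function(arr, grid, points, fill = FALSE) {
  n <- grid$size
  i <- round((points[, 1] - grid$origin[1]) / grid$spacing[1])
  j <- round((points[, 2] - grid$origin[2]) / grid$spacing[2])
  k <- round((points[, 3] - grid$origin[3]) / grid$spacing[3])
  inside <- i >= 0 & i <= n[1] - 1 & j >= 0 & j <= n[2] - 1 & k >= 0 & k <= n[3] - 1
  out <- rep(fill, nrow(points))
  lin <- 1 + i[inside] + n[1] * (j[inside] + n[2] * k[inside])
  out[inside] <- as.vector(arr)[lin]
  out
}

#' Sample a displacement field at physical points
#'
#' Component-wise trilinear interpolation; outside the grid the displacement
#' is taken as zero.
#'
#' @param dvf a [vector_field()].
#' @param points n x 3 matrix of mm coordinates.
#' @return n x 3 matrix of displacements (mm).
#' @export
sample_vector_field <- function(dvf, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  out <- matrix(0, nrow(points), 3)
  for (c in 1:3)
    out[, c] <- interp_array3(dvf$values[, , , c], dvf$grid, points, fill = 0)
  out
}
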
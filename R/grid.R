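#' Regular 3D grid geometry
#'
#' A `grid3d` describes an axis-aligned regular voxel lattice in physical
#' millimetre coordinates. The centre of voxel `(0, 0, 0)` (indices are
#' 0-based) sits at `origin`; the centre of voxel `(i, j, k)` sits at
#' `origin + c(i, j, k) * spacing`. Oblique or sheared orientations are
#' deliberately unsupported: every volume handled by this package lives on an
#' identity-oriented grid, which removes a whole class of convention bugs at
#' no cost for desk-scale planning work.
#'
#' @param size integer vector of length 3, voxel counts per axis (all >= 1).
#' @param spacing numeric vector of length 3, voxel spacing in mm (all > 0).
#' @param origin numeric vector of length 3, mm coordinate of the centre of
#'   voxel (0, 0, 0).
#' @return An object of class `grid3d`.
#' @examples
#' g <- grid3d(c(10, 10, 10), spacing = c(1, 1, 2.5))
#' voxel_volume_cm3(g)
#' @export
grid3d <- function(size, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  size <- as.integer(size)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(size) != 3L || length(spacing) != 3L || length(origin) != 3L)
    stop("size, spacing and origin must each have length 3")
  if (any(is.na(size)) || any(size < 1L))
    stop("all grid sizes must be >= 1")
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("all grid spacings must be finite and > 0")
  if (any(!is.finite(origin)))
    stop("grid origin must be finite")
  structure(list(size = size, spacing = spacing, origin = origin),
            class = "grid3d")
}

#' @export
print.grid3d <- function(x, ...) {
  cat(sprintf("<grid3d> %d x %d x %d voxels, spacing (%g, %g, %g) mm, origin (%g, %g, %g) mm\n",
              x$size[1], x$size[2], x$size[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' @export
format.grid3d <- function(x, ...) {
  sprintf("%dx%dx%d @ (%g,%g,%g) mm", x$size[1], x$size[2], x$size[3],
          x$spacing[1], x$spacing[2], x$spacing[3])
}

#' Test whether two grids coincide
#'
#' Sizes must match exactly; spacings and origins to within `tol` mm.
#'
#' @param a,b `grid3d` objects.
#' @param tol numeric tolerance in mm.
#' @return Logical scalar.
#' @export
grids_equal <- function(a, b, tol = 1e-6) {
  identical(a$size, b$size) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stop_if_grid_mismatch <- function(a, b, what = "volumes") {
  if (!grids_equal(a, b))
    stop(sprintf("grid mismatch between %s: %s vs %s (resample explicitly first)",
                 what, format(a), format(b)), call. = FALSE)
  invisible(TRUE)
}

#' Voxel volume in cubic centimetres
#' @param grid a `grid3d`.
#' @return Volume of one voxel in cm^3.
#' @export
voxel_volume_cm3 <- function(grid) prod(grid$spacing) / 1000

#' Physical mm coordinates of the voxel-centre lattice along one axis
#' @param grid a `grid3d`.
#' @param axis axis index (1, 2 or 3).
#' @return Numeric vector of length `grid$size[axis]`.
#' @export
axis_coords <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$size[axis]) - 1) * grid$spacing[axis]
}

#' Centres of every voxel as an n x 3 matrix (mm)
#'
#' Column-major order matching `array` storage, so row `i` of the result is
#' the centre of the voxel holding element `i` of the value array.
#'
#' @param grid a `grid3d`.
#' @return Matrix with `prod(grid$size)` rows and 3 columns.
#' @export
voxel_centers <- function(grid) {
  xs <- axis_coords(grid, 1); ys <- axis_coords(grid, 2); zs <- axis_coords(grid, 3)
  n <- grid$size
  cbind(rep(xs, times = n[2] * n[3]),
        rep(rep(ys, each = n[1]), times = n[3]),
        rep(zs, each = n[1] * n[2]))
}

check_shape <- function(values, grid) {
  d <- dim(values)
  if (is.null(d) || length(d) < 3L || !all(d[1:3] == grid$size))
    stop("value array shape does not match grid size")
  invisible(TRUE)
}

#' Scalar dose volume
#'
#' A per-voxel scalar field on a [grid3d()], tagged with the physical quantity
#' it carries: `"physical_gy"` (total physical dose of a course, requiring the
#' fraction count `n_fractions`) or `"eqd2_gy"` (equivalent dose in 2 Gy
#' fractions, already fractionation-free). All values must be finite and
#' non-negative.
#'
#' @param values numeric 3D array matching `grid$size`.
#' @param grid a `grid3d`.
#' @param quantity `"physical_gy"` or `"eqd2_gy"`.
#' @param n_fractions positive integer; required when `quantity` is
#'   `"physical_gy"` (number of fractions over which the values were/will be
#'   delivered).
#' @param label optional free-text label carried through I/O.
#' @return An object of class `scalar_volume`.
#' @export
scalar_volume <- function(values, grid, quantity = c("physical_gy", "eqd2_gy"),
                          n_fractions = NULL, label = "") {
  quantity <- match.arg(quantity)
  check_shape(values, grid)
  values <- array(as.numeric(values), dim = grid$size)
  bad <- which(!is.finite(values))
  if (length(bad))
    stop(sprintf("non-finite dose value at voxel index %s (and %d more)",
                 paste(arrayInd(bad[1], grid$size) - 1L, collapse = ","),
                 length(bad) - 1L))
  if (any(values < 0))
    stop("dose values must be >= 0")
  if (quantity == "physical_gy") {
    if (is.null(n_fractions))
      stop("n_fractions is required for a physical_gy volume")
    n_fractions <- as.integer(n_fractions)
    if (is.na(n_fractions) || n_fractions < 1L)
      stop("n_fractions must be a positive integer")
  } else {
    n_fractions <- if (is.null(n_fractions)) NULL else as.integer(n_fractions)
  }
  structure(list(values = values, grid = grid, quantity = quantity,
                 n_fractions = n_fractions, label = as.character(label)),
            class = "scalar_volume")
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat(sprintf("<scalar_volume:%s> %s%s; range [%.3g, %.3g] Gy%s\n",
              x$quantity, format(x$grid),
              if (is.null(x$n_fractions)) "" else sprintf(", %d fx", x$n_fractions),
              min(x$values), max(x$values),
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  invisible(x)
}

#' Binary structure mask
#'
#' @param values logical (or coercible numeric, thresholded at 0.5) 3D array.
#' @param grid a `grid3d`.
#' @param label optional structure name.
#' @return An object of class `mask_volume`.
#' @export
mask_volume <- function(values, grid, label = "") {
  check_shape(values, grid)
  if (!is.logical(values)) values <- values > 0.5
  if (anyNA(values)) stop("mask contains NA voxels")
  values <- array(values, dim = grid$size)
  structure(list(values = values, grid = grid, label = as.character(label)),
            class = "mask_volume")
}

#' @export
print.mask_volume <- function(x, ...) {
  cat(sprintf("<mask_volume> %s; %d voxels true (%.3f cm^3)%s\n",
              format(x$grid), sum(x$values), volume_cm3(x),
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  invisible(x)
}

#' Structure volume in cm^3 (voxel-centre counting)
#' @param mask a `mask_volume`.
#' @return Volume in cm^3.
#' @export
volume_cm3 <- function(mask) sum(mask$values) * voxel_volume_cm3(mask$grid)

#' Displacement vector field
#'
#' Per-voxel displacement in mm on a [grid3d()]. The convention throughout
#' the package: the field lives on the re-irradiation grid and maps a
#' physical point `x` in the re-irradiation frame to its homologous point
#' `x + v(x)` in the prior-treatment frame.
#'
#' @param values numeric 4D array of shape `c(grid$size, 3)`.
#' @param grid a `grid3d`.
#' @param label optional label.
#' @return An object of class `vector_field`.
#' @export
vector_field <- function(values, grid, label = "") {
  d <- dim(values)
  if (is.null(d) || length(d) != 4L || !all(d[1:3] == grid$size) || d[4] != 3L)
    stop("vector field array must have shape c(grid$size, 3)")
  values <- array(as.numeric(values), dim = d)
  if (any(!is.finite(values))) stop("vector field contains non-finite components")
  structure(list(values = values, grid = grid, label = as.character(label)),
            class = "vector_field")
}

#' @export
print.vector_field <- function(x, ...) {
  mags <- sqrt(x$values[, , , 1]^2 + x$values[, , , 2]^2 + x$values[, , , 3]^2)
  cat(sprintf("<vector_field> %s; |v| in [%.3g, %.3g] mm\n",
              format(x$grid), min(mags), max(mags)))
  invisible(x)
}

#' Resample a volume onto another grid
#'
#' Explicit resampling between grids: trilinear interpolation for scalar dose
#' volumes (out-of-grid fill 0 Gy), nearest-neighbour for masks. Volumes used
#' together in this package must share a grid; this is the only sanctioned way
#' to get them there.
#'
#' @param vol a `scalar_volume` or `mask_volume`.
#' @param target_grid the `grid3d` to resample onto.
#' @return A volume of the same class on `target_grid`.
#' @export
resample_volume <- function(vol, target_grid) {
  pts <- voxel_centers(target_grid)
  if (inherits(vol, "scalar_volume")) {
    vals <- sample_trilinear(vol, pts, fill = 0)
    scalar_volume(array(vals, dim = target_grid$size), target_grid,
                  quantity = vol$quantity, n_fractions = vol$n_fractions,
                  label = vol$label)
  } else if (inherits(vol, "mask_volume")) {
    vals <- sample_nearest(vol$values, vol$grid, pts, fill = FALSE)
    mask_volume(array(vals, dim = target_grid$size), target_grid, label = vol$label)
  } else {
    stop("resample_volume handles scalar_volume and mask_volume only")
  }
}
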
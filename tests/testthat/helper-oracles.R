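# Independent brute-force oracles used to cross-check the implementation.
# These are written from first principles (explicit loops, no shared helpers)
# and must stay independent of the package internals they verify.

# 8-corner trilinear interpolation, one point at a time
oracle_trilinear <- function(arr, grid, p, fill = 0) {
  n <- grid$size
  t <- (p - grid$origin) / grid$spacing
  if (any(t < 0) || any(t > n - 1)) return(fill)
  i0 <- pmin(floor(t), n - 2); i0 <- pmax(i0, 0)
  f <- t - i0
  val <- 0
  for (a in 0:1) for (b in 0:1) for (c in 0:1) {
    w <- (if (a) f[1] else 1 - f[1]) * (if (b) f[2] else 1 - f[2]) *
         (if (c) f[3] else 1 - f[3])
    val <- val + w * arr[i0[1] + a + 1, i0[2] + b + 1, i0[3] + c + 1]
  }
  val
}

# brute-force isotropic dilation: voxel added iff some true centre within r
oracle_dilate <- function(vals, spacing, radius) {
  n <- dim(vals)
  out <- vals
  tr <- which(vals, arr.ind = TRUE)
  for (i in seq_len(n[1])) for (j in seq_len(n[2])) for (k in seq_len(n[3])) {
    if (out[i, j, k]) next
    d2 <- ((tr[, 1] - i) * spacing[1])^2 + ((tr[, 2] - j) * spacing[2])^2 +
          ((tr[, 3] - k) * spacing[3])^2
    if (any(d2 <= radius^2 + 1e-9)) out[i, j, k] <- TRUE
  }
  out
}

# dose to the hottest vol_cm3, linear interpolation on the sorted voxel curve
oracle_dose_at_volume <- function(doses, voxel_cm3, vol_cm3) {
  d <- sort(doses, decreasing = TRUE)
  m <- length(d)
  k <- vol_cm3 / voxel_cm3
  if (k <= 1) return(d[1])
  if (k >= m) return(d[m])
  i0 <- floor(k)
  d[i0] + (k - i0) * (d[i0 + 1] - d[i0])
}

oracle_v_at_dose <- function(doses, level) 100 * sum(doses >= level) / length(doses)

oracle_paddick <- function(dose_vals, target_vals, rx) {
  piv <- dose_vals >= rx
  if (sum(piv) == 0) return(0)
  sum(piv & target_vals)^2 / (sum(target_vals) * sum(piv))
}

oracle_hi <- function(doses, voxel_cm3) {
  tot <- length(doses) * voxel_cm3
  d2 <- oracle_dose_at_volume(doses, voxel_cm3, 0.02 * tot)
  d98 <- oracle_dose_at_volume(doses, voxel_cm3, 0.98 * tot)
  d50 <- oracle_dose_at_volume(doses, voxel_cm3, 0.50 * tot)
  (d2 - d98) / d50
}

oracle_gi <- function(dose_vals, rx) sum(dose_vals >= rx / 2) / sum(dose_vals >= rx)

# positive root of D^2/n + D*ab = budget*(2+ab) via polyroot
oracle_budget_inversion <- function(budget, n, ab) {
  r <- polyroot(c(-budget * (2 + ab), ab, 1 / n))
  max(Re(r[abs(Im(r)) < 1e-8]))
}

random_mask <- function(grid, p = 0.3, seed = 1) {
  set.seed(seed)
  mask_volume(array(runif(prod(grid$size)) < p, dim = grid$size), grid)
}

random_eqd2_field <- function(grid, max_gy = 45, seed = 1, smooth = TRUE) {
  set.seed(seed)
  v <- array(runif(prod(grid$size), 0, max_gy), dim = grid$size)
  if (smooth) { # mild separable smoothing so isodose sets are not pure salt
    k <- c(0.25, 0.5, 0.25)
    for (ax in 1:3) {
      v2 <- v
      for (s in c(-1, 1)) {
        shifted <- v
        idx <- seq_len(dim(v)[ax])
        src <- pmin(pmax(idx + s, 1), dim(v)[ax])
        if (ax == 1) shifted <- v[src, , , drop = FALSE]
        if (ax == 2) shifted <- v[, src, , drop = FALSE]
        if (ax == 3) shifted <- v[, , src, drop = FALSE]
        v2 <- v2 + 0.5 * shifted
      }
      v <- v2 / 2
    }
  }
  scalar_volume(v, grid, quantity = "eqd2_gy")
}

tiny_case <- function(class = "partial") generate_phantom(phantom_config(class, "tiny"))
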
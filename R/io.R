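#' Read a dose, mask or displacement volume from disk
#'
#' Supports NIfTI (`.nii`, `.nii.gz`) and MetaImage (`.mha`, `.mhd`).
#' Only identity-oriented (axis-aligned, non-flipped) volumes are accepted;
#' anything else is rejected with a clear message rather than silently
#' reinterpreted. Masks may be stored in any numeric encoding and are
#' thresholded at 0.5. A JSON sidecar (`<file>.json`) written by
#' [write_volume()] restores the scalar quantity tag and fraction count.
#'
#' @param path file path.
#' @param kind `"scalar"`, `"mask"` or `"vector"`.
#' @return A [scalar_volume()], [mask_volume()] or [vector_field()].
#' @export
read_volume <- function(path, kind = c("scalar", "mask", "vector")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  raw <- if (grepl("\\.(mha|mhd)$", path, ignore.case = TRUE))
    read_metaimage(path) else read_nifti_raw(path)
  arr <- raw$values; grid <- raw$grid
  nabad <- which(!is.finite(arr))
  if (length(nabad)) {
    d <- dim(arr); if (length(d) > 3) d <- d[1:3]
    stop(sprintf("volume %s contains a non-finite value at voxel index (%s)",
                 basename(path),
                 paste(arrayInd(nabad[1], dim(arr))[1, ] - 1L, collapse = ",")))
  }
  meta <- read_sidecar(path)
  if (kind == "vector") {
    d <- dim(arr)
    if (length(d) == 5L && d[4] == 1L) { arr <- array(arr, d[c(1:3, 5)]); d <- dim(arr) }
    if (length(d) != 4L || d[4] != 3L)
      stop("vector volume must have 3 components in the 4th dimension")
    return(vector_field(arr, grid, label = meta$label %||% ""))
  }
  if (length(dim(arr)) > 3L) {
    if (prod(dim(arr)[-(1:3)]) != 1L)
      stop(sprintf("expected a scalar volume but %s has %d components",
                   basename(path), prod(dim(arr)[-(1:3)])))
    arr <- array(arr, dim(arr)[1:3])
  }
  if (kind == "mask") return(mask_volume(arr > 0.5, grid, label = meta$label %||% ""))
  scalar_volume(arr, grid,
                quantity = meta$quantity %||% "physical_gy",
                n_fractions = meta$n_fractions %||%
                  if ((meta$quantity %||% "physical_gy") == "physical_gy") 1L else NULL,
                label = meta$label %||% "")
}

#' Write a volume to disk
#'
#' Writes NIfTI or MetaImage depending on the file extension. Grid metadata
#' round-trips exactly; values are stored as double (lossless) except masks,
#' stored as uint8. Scalar volumes get a JSON sidecar carrying
#' `{quantity, n_fractions, label}`.
#'
#' @param vol a `scalar_volume`, `mask_volume` or `vector_field`.
#' @param path destination ending in `.nii`, `.nii.gz`, `.mha` or `.mhd`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  is_meta <- grepl("\\.(mha|mhd)$", path, ignore.case = TRUE)
  if (inherits(vol, "scalar_volume")) {
    arr <- vol$values; uint8 <- FALSE
  } else if (inherits(vol, "mask_volume")) {
    arr <- array(as.integer(vol$values), dim = vol$grid$size); uint8 <- TRUE
  } else if (inherits(vol, "vector_field")) {
    arr <- vol$values; uint8 <- FALSE
  } else stop("write_volume expects a scalar_volume, mask_volume or vector_field")
  if (is_meta) write_metaimage(arr, vol$grid, path, uint8 = uint8)
  else write_nifti_raw(arr, vol$grid, path, uint8 = uint8)
  if (inherits(vol, "scalar_volume")) {
    side <- list(quantity = vol$quantity, label = vol$label)
    if (!is.null(vol$n_fractions)) side$n_fractions <- vol$n_fractions
    jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE)
  } else if (nzchar(vol$label %||% "")) {
    jsonlite::write_json(list(label = vol$label), sidecar_path(path),
                         auto_unbox = TRUE)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sidecar_path <- function(path)
  paste0(sub("\\.(nii\\.gz|nii|mha|mhd)$", "", path, ignore.case = TRUE), ".json")

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (file.exists(sp)) jsonlite::read_json(sp, simplifyVector = TRUE) else list()
}

## ---- NIfTI backend (RNifti) -------------------------------------------------

write_nifti_raw <- function(arr, grid, path, uint8 = FALSE) {
  img <- RNifti::asNifti(arr)
  nd <- length(dim(arr))
  RNifti::pixdim(img) <- c(grid$spacing, rep(1, max(0, nd - 3)))
  m <- diag(4)
  m[1, 1] <- grid$spacing[1]; m[2, 2] <- grid$spacing[2]; m[3, 3] <- grid$spacing[3]
  m[1:3, 4] <- grid$origin
  # sform only: a qform cannot carry anisotropic scale independently of pixdim
  RNifti::sform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path, datatype = if (uint8) "uint8" else "double")
  invisible(path)
}

read_nifti_raw <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  d3 <- dim(arr)[1:3]
  pd <- RNifti::pixdim(img)[1:3]
  xf <- RNifti::xform(img)
  code <- attr(xf, "code") %||% 0L
  if (!is.null(code) && code > 0) {
    rot <- xf[1:3, 1:3]
    offdiag <- rot; diag(offdiag) <- 0
    if (max(abs(offdiag)) > 1e-4 * max(abs(diag(rot))) || any(diag(rot) <= 0))
      stop(sprintf("volume %s has a non-identity orientation; only axis-aligned, unflipped grids are supported",
                   basename(path)))
    spacing <- diag(rot)
    origin <- xf[1:3, 4]
  } else {
    spacing <- pd; origin <- c(0, 0, 0)
  }
  if (any(spacing <= 0)) stop(sprintf("volume %s has non-positive spacing", basename(path)))
  list(values = arr, grid = grid3d(d3, spacing, origin))
}

## ---- MetaImage backend (hand-written; no installed R package reads it) ------

met_types <- c(MET_UCHAR = 1L, MET_CHAR = 1L, MET_SHORT = 2L, MET_USHORT = 2L,
               MET_INT = 4L, MET_UINT = 4L, MET_FLOAT = 4L, MET_DOUBLE = 8L)

write_metaimage <- function(arr, grid, path, uint8 = FALSE) {
  d <- dim(arr)
  channels <- if (length(d) == 4L) d[4] else 1L
  if (channels > 1L) arr <- aperm(arr, c(4, 1, 2, 3))  # channels fastest on disk
  etype <- if (uint8) "MET_UCHAR" else "MET_DOUBLE"
  local <- grepl("\\.mha$", path, ignore.case = TRUE)
  datafile <- if (local) "LOCAL" else paste0(sub("\\.mhd$", "", basename(path),
                                                 ignore.case = TRUE), ".raw")
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           "CompressedData = False",
           "TransformMatrix = 1 0 0 0 1 0 0 0 1",
           sprintf("Offset = %.17g %.17g %.17g", grid$origin[1], grid$origin[2], grid$origin[3]),
           "CenterOfRotation = 0 0 0",
           sprintf("ElementSpacing = %.17g %.17g %.17g",
                   grid$spacing[1], grid$spacing[2], grid$spacing[3]),
           sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
           sprintf("ElementNumberOfChannels = %d", channels),
           sprintf("ElementType = %s", etype),
           sprintf("ElementDataFile = %s", datafile))
  payload <- if (uint8) writeBin(as.integer(arr), raw(), size = 1L)
             else writeBin(as.numeric(arr), raw(), size = 8L, endian = "little")
  if (local) {
    con <- file(path, "wb"); on.exit(close(con))
    writeLines(hdr, con, sep = "\n")
    writeBin(payload, con)
  } else {
    writeLines(hdr, path, sep = "\n")
    writeBin(payload, file.path(dirname(path), datafile))
  }
  invisible(path)
}

read_metaimage <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  # header is newline-separated ASCII up to and including the ElementDataFile line
  nl <- which(bytes == as.raw(10L))
  hdr_lines <- character(); data_start <- NA_integer_; prev <- 0L
  for (p in nl) {
    line <- rawToChar(bytes[(prev + 1):(p - 1)])
    hdr_lines <- c(hdr_lines, line)
    prev <- p
    if (grepl("^ElementDataFile", line)) { data_start <- p + 1L; break }
  }
  kv <- strsplit(hdr_lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1); vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), "")
  names(vals) <- keys
  getnum <- function(k) as.numeric(strsplit(trimws(vals[[k]]), "\\s+")[[1]])
  if (!identical(getnum("TransformMatrix"), c(1, 0, 0, 0, 1, 0, 0, 0, 1)))
    stop(sprintf("volume %s has a non-identity orientation; only axis-aligned grids are supported",
                 basename(path)))
  dimsize <- as.integer(getnum("DimSize"))
  spacing <- getnum("ElementSpacing")
  origin <- if ("Offset" %in% keys) getnum("Offset") else c(0, 0, 0)
  channels <- if ("ElementNumberOfChannels" %in% keys)
    as.integer(getnum("ElementNumberOfChannels")) else 1L
  etype <- trimws(vals[["ElementType"]])
  if (!etype %in% names(met_types)) stop(sprintf("unsupported ElementType %s", etype))
  size <- met_types[[etype]]
  ntot <- prod(dimsize) * channels
  datafile <- trimws(vals[["ElementDataFile"]])
  payload <- if (identical(datafile, "LOCAL")) bytes[data_start:length(bytes)]
             else readBin(file.path(dirname(path), datafile), "raw",
                          n = ntot * size)
  what <- if (etype %in% c("MET_FLOAT", "MET_DOUBLE")) "double" else "integer"
  signed <- !etype %in% c("MET_UCHAR", "MET_USHORT", "MET_UINT")
  vals_num <- readBin(payload, what, n = ntot, size = size,
                      signed = if (size < 4) signed else TRUE, endian = "little")
  arr <- if (channels > 1L)
    aperm(array(vals_num, dim = c(channels, dimsize)), c(2, 3, 4, 1))
  else array(vals_num, dim = dimsize)
  list(values = arr, grid = grid3d(dimsize, spacing, origin))
}
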
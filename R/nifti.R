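## Minimal NIfTI-1 I/O.
##
## No NIfTI-capable R package is available in the deployment environment, so
## the package carries a small single-file reader/writer for the subset of
## NIfTI-1 it needs: 3D/4D magnitude images, the common integer/float
## datatypes, scl_slope/scl_inter rescaling, sform/qform affines, and gzip
## compression (".nii" or ".nii.gz"). It is validated against nibabel in the
## test suite. NIfTI-2 and extensions beyond a zero extender are not supported.

NIFTI_DTYPES <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE, name = "uint8"),
  `4`   = list(what = "integer", size = 2L, signed = TRUE,  name = "int16"),
  `8`   = list(what = "integer", size = 4L, signed = TRUE,  name = "int32"),
  `16`  = list(what = "double",  size = 4L, signed = TRUE,  name = "float32"),
  `64`  = list(what = "double",  size = 8L, signed = TRUE,  name = "float64"),
  `256` = list(what = "integer", size = 1L, signed = TRUE,  name = "int8"),
  `512` = list(what = "integer", size = 2L, signed = FALSE, name = "uint16")
)

read_raw_file <- function(path) {
  con <- gzfile(path, "rb")  # gzfile transparently reads uncompressed files
  on.exit(close(con))
  chunks <- list()
  repeat {
    ch <- readBin(con, raw(), n = 16777216L)
    if (length(ch) == 0L) break
    chunks[[length(chunks) + 1L]] <- ch
  }
  do.call(c, chunks)
}

rd <- function(raw, off, what, n, size, signed = TRUE, endian = "little") {
  readBin(raw[(off + 1L):(off + n * size)], what = what, n = n, size = size,
          signed = signed, endian = endian)
}

#' Read a NIfTI-1 volume
#'
#' Reads a (possibly gzipped) NIfTI-1 file into an array plus its affine.
#' Values are rescaled by \code{scl_slope}/\code{scl_inter} when set. The
#' affine is taken from the sform when \code{sform_code > 0}, else from the
#' qform, else from \code{pixdim} alone.
#'
#' @param path file path (".nii" or ".nii.gz").
#' @return A list with elements \code{data} (numeric array), \code{affine}
#'   (4x4 voxel-to-world matrix, 0-based voxel indices) and \code{dim}.
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) pq_stop("nifti", "file not found: ", path)
  bytes <- read_raw_file(path)
  if (length(bytes) < 352L) pq_stop("nifti", "file too short to be NIfTI-1: ", path)
  endian <- "little"
  if (rd(bytes, 0L, "integer", 1L, 4L, endian = endian) != 348L) {
    endian <- "big"
    if (rd(bytes, 0L, "integer", 1L, 4L, endian = endian) != 348L)
      pq_stop("nifti", "not a NIfTI-1 file (bad sizeof_hdr): ", path)
  }
  magic <- rawToChar(bytes[345:347])
  if (!magic %in% c("n+1", "ni1"))
    pq_stop("nifti", "unsupported NIfTI magic '", magic, "' in ", path)
  dim0 <- rd(bytes, 40L, "integer", 8L, 2L, endian = endian)
  ndim <- dim0[1L]
  if (ndim < 1L || ndim > 7L) pq_stop("nifti", "invalid ndim ", ndim, " in ", path)
  dims <- dim0[2:(1L + ndim)]
  datatype <- rd(bytes, 70L, "integer", 1L, 2L, endian = endian)
  dt <- NIFTI_DTYPES[[as.character(datatype)]]
  if (is.null(dt)) pq_stop("nifti", "unsupported NIfTI datatype code ", datatype, " in ", path)
  pixdim <- rd(bytes, 76L, "double", 8L, 4L, endian = endian)
  vox_offset <- rd(bytes, 108L, "double", 1L, 4L, endian = endian)
  scl_slope <- rd(bytes, 112L, "double", 1L, 4L, endian = endian)
  scl_inter <- rd(bytes, 116L, "double", 1L, 4L, endian = endian)
  qform_code <- rd(bytes, 252L, "integer", 1L, 2L, endian = endian)
  sform_code <- rd(bytes, 254L, "integer", 1L, 2L, endian = endian)

  n_vox <- prod(dims)
  off <- as.integer(round(vox_offset))
  if (dt$what == "integer" && dt$size == 1L && !dt$signed) {
    vals <- as.integer(rd(bytes, off, "integer", n_vox, 1L, signed = FALSE, endian = endian))
  } else {
    vals <- rd(bytes, off, dt$what, n_vox, dt$size, signed = dt$signed, endian = endian)
  }
  vals <- as.numeric(vals)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter

  affine <- diag(4)
  if (sform_code > 0L) {
    affine[1, ] <- rd(bytes, 280L, "double", 4L, 4L, endian = endian)
    affine[2, ] <- rd(bytes, 296L, "double", 4L, 4L, endian = endian)
    affine[3, ] <- rd(bytes, 312L, "double", 4L, 4L, endian = endian)
  } else if (qform_code > 0L) {
    quat <- rd(bytes, 256L, "double", 6L, 4L, endian = endian)
    affine <- qform_to_affine(quat[1:3], quat[4:6], pixdim)
  } else {
    pd <- pixdim[2:4]
    pd[pd == 0] <- 1
    affine[cbind(1:3, 1:3)] <- pd
  }
  list(data = array(vals, dim = dims), affine = affine, dim = dims)
}

qform_to_affine <- function(bcd, offset, pixdim) {
  b <- bcd[1]; c <- bcd[2]; d <- bcd[3]
  a2 <- 1 - b^2 - c^2 - d^2
  a <- if (a2 > 0) sqrt(a2) else 0
  R <- matrix(c(
    a*a + b*b - c*c - d*d, 2*(b*c - a*d),         2*(b*d + a*c),
    2*(b*c + a*d),         a*a + c*c - b*b - d*d, 2*(c*d - a*b),
    2*(b*d - a*c),         2*(c*d + a*b),         a*a + d*d - b*b - c*c
  ), nrow = 3, byrow = TRUE)
  qfac <- if (pixdim[1] < 0) -1 else 1
  pd <- pixdim[2:4]
  pd[pd == 0] <- 1
  pd[3] <- pd[3] * qfac
  affine <- diag(4)
  affine[1:3, 1:3] <- R %*% diag(pd)
  affine[1:3, 4] <- offset
  affine
}

#' Write a NIfTI-1 volume
#'
#' Writes a numeric array as float32 NIfTI-1 (gzipped when the path ends in
#' ".gz"), storing the affine in the sform (code 1).
#'
#' @param data numeric array, 3 or 4 dimensions.
#' @param path output path.
#' @param affine 4x4 voxel-to-world matrix (0-based voxel indices).
#' @return \code{path}, invisibly.
#' @export
write_nifti <- function(data, path, affine = diag(4)) {
  nd <- length(dim(data))
  if (!nd %in% c(3L, 4L)) pq_stop("nifti", "write_nifti expects a 3D or 4D array")
  if (!is.matrix(affine) || any(dim(affine) != c(4L, 4L)))
    pq_stop("nifti", "affine must be a 4x4 matrix")
  dims <- dim(data)
  hdr <- raw(348L)
  put <- function(hdr, off, values, size, what) {
    enc <- writeBin(values, raw(), size = size, endian = "little")
    hdr[(off + 1L):(off + length(enc))] <- enc
    hdr
  }
  hdr <- put(hdr, 0L, 348L, 4L)
  dim8 <- integer(8L); dim8[1L] <- nd; dim8[2:(1L + nd)] <- dims
  dim8[dim8 == 0L] <- 1L
  hdr <- put(hdr, 40L, as.integer(dim8), 2L)
  hdr <- put(hdr, 70L, c(16L, 32L), 2L)              # datatype float32, bitpix 32
  pixdim <- numeric(8L); pixdim[1L] <- 1
  pixdim[2:4] <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (nd == 4L) pixdim[5L] <- 1
  hdr <- put(hdr, 76L, pixdim, 4L)
  hdr <- put(hdr, 108L, 352, 4L)                     # vox_offset
  hdr <- put(hdr, 112L, c(1, 0), 4L)                 # scl_slope, scl_inter
  hdr[124L] <- as.raw(10L)                           # xyzt_units: mm + s
  hdr <- put(hdr, 148L, charToRaw(sprintf("%-79.79s", "pboldqa")), 1L)
  hdr <- put(hdr, 252L, c(0L, 1L), 2L)               # qform_code 0, sform_code 1
  hdr <- put(hdr, 280L, affine[1, ], 4L)
  hdr <- put(hdr, 296L, affine[2, ], 4L)
  hdr <- put(hdr, 312L, affine[3, ], 4L)
  hdr[345:348] <- c(charToRaw("n+1"), as.raw(0L))

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(raw(4L), con)                             # empty extender
  writeBin(as.numeric(data), con, size = 4L, endian = "little")
  invisible(path)
}
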
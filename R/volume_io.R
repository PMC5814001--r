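## Minimal NIfTI-1 (.nii, single-file, uncompressed, little-endian) I/O.
## No R NIfTI reader ships with the runtime, and the format is a fixed
## 348-byte header plus a raw array, so the package carries its own.
## Convention: write_volume()/read_volume() store spacing/origin in the
## package's native cm; load_ct_volume() defaults to interpreting external
## files as mm (the NIfTI norm) and converts.

.nifti_dtypes <- list(`2` = list(what = "integer", size = 1, signed = FALSE),
                      `4` = list(what = "integer", size = 2, signed = TRUE),
                      `8` = list(what = "integer", size = 4, signed = TRUE),
                      `16` = list(what = "double", size = 4, signed = TRUE),
                      `64` = list(what = "double", size = 8, signed = TRUE))

#' Write a volume to a NIfTI-1 file
#'
#' Writes `map$values` as float64 with spacing/origin recorded in the header
#' (pixdim and an sform with no rotation). Spacing and origin are written in
#' the unit given by `units`; the default `"cm"` round-trips package objects
#' bitwise (values always; spacing up to float32 header precision).
#'
#' @param map an [attenuation_map()] (or any object with `values`, `spacing`,
#'   `origin`).
#' @param path output file path, conventionally ending in `.nii`.
#' @param units `"cm"` (native) or `"mm"` (NIfTI convention, scales by 10).
#' @return `path`, invisibly.
#' @export
write_volume <- function(map, path, units = c("cm", "mm")) {
  units <- match.arg(units)
  scale <- if (units == "mm") 10 else 1
  vals <- map$values
  n <- dim(vals)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wraw <- function(len, s = "") {
    r <- charToRaw(s)
    writeBin(c(r, raw(len - length(r))), con)
  }
  sp <- map$spacing * scale
  or <- map$origin * scale
  wi(348, 4)                          # sizeof_hdr
  wraw(10); wraw(18)                  # data_type, db_name
  wi(0, 4); wi(0, 2); wraw(1, "r"); wraw(1) # extents, session_error, regular, dim_info
  wi(c(3, n, 1, 1, 1, 1), 2)          # dim[8]
  wf(c(0, 0, 0)); wi(0, 2)            # intent_p1..p3, intent_code
  wi(64, 2); wi(64, 2); wi(0, 2)      # datatype = float64, bitpix, slice_start
  wf(c(1, sp, 0, 0, 0, 0))            # pixdim[8]
  wf(352); wf(1); wf(0)               # vox_offset, scl_slope, scl_inter
  wi(0, 2); wraw(1); wraw(1)          # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0, 0))                   # cal_max, cal_min, slice_duration, toffset
  wi(c(0, 0), 4)                      # glmax, glmin
  wraw(80, "cbctcm volume"); wraw(24) # descrip, aux_file
  wi(0, 2); wi(1, 2)                  # qform_code, sform_code
  wf(c(0, 0, 0, 0, 0, 0))             # quatern_b/c/d, qoffset_x/y/z
  wf(c(sp[1], 0, 0, or[1]))           # srow_x
  wf(c(0, sp[2], 0, or[2]))           # srow_y
  wf(c(0, 0, sp[3], or[3]))           # srow_z
  wraw(16); wraw(4, "n+1")            # intent_name, magic
  writeBin(raw(4), con)               # extension flag
  writeBin(as.numeric(vals), con, size = 8, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Minimal reader for single-file uncompressed `.nii` (int8/16/32,
#' float32/64; scl_slope/inter applied; little- or big-endian). Returns the
#' raw array plus geometry; use [load_ct_volume()] to obtain an attenuation
#' map from a CT in Hounsfield units.
#'
#' @param path file path.
#' @param units unit of the header geometry, `"cm"` (package native) or
#'   `"mm"` (NIfTI convention; converted to cm).
#' @return List with `values` (3D array), `spacing`, `origin` (cm).
#' @export
read_volume <- function(path, units = c("cm", "mm")) {
  units <- match.arg(units)
  scale <- if (units == "mm") 0.1 else 1
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348)
  if (length(hdr) < 348) stop("not a NIfTI-1 file (truncated header): ", path,
                              call. = FALSE)
  rd <- function(off, what, n, size, endian) {
    readBin(hdr[(off + 1):length(hdr)], what, n = n, size = size,
            endian = endian, signed = TRUE)
  }
  endian <- "little"
  if (rd(0, "integer", 1, 4, "little") != 348L) {
    if (rd(0, "integer", 1, 4, "big") == 348L) endian <- "big"
    else stop("not a NIfTI-1 file (bad sizeof_hdr): ", path, call. = FALSE)
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop("not a NIfTI-1 file (bad magic): ", path, call. = FALSE)
  dims <- rd(40, "integer", 8, 2, endian)
  ndim <- dims[1]
  if (ndim < 2 || ndim > 3)
    stop("unsupported NIfTI dimensionality ", ndim,
         " (only 2D/3D volumes supported)", call. = FALSE)
  n <- c(dims[2:4], 1L, 1L)[1:3]
  n[n < 1] <- 1L
  dtype <- rd(70, "integer", 1, 2, endian)
  spec <- .nifti_dtypes[[as.character(dtype)]]
  if (is.null(spec))
    stop("unsupported NIfTI datatype code ", dtype, call. = FALSE)
  pixdim <- rd(76, "numeric", 8, 4, endian)
  spacing <- pixdim[2:4]
  if (ndim == 2 && spacing[3] <= 0) spacing[3] <- spacing[1]
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("missing or contradictory voxel spacing in header", call. = FALSE)
  vox_offset <- rd(108, "numeric", 1, 4, endian)
  scl_slope <- rd(112, "numeric", 1, 4, endian)
  scl_inter <- rd(116, "numeric", 1, 4, endian)
  sform_code <- rd(254, "integer", 1, 2, endian)
  origin <- c(0, 0, 0)
  if (sform_code > 0) {
    srx <- rd(280, "numeric", 4, 4, endian)
    sry <- rd(296, "numeric", 4, 4, endian)
    srz <- rd(312, "numeric", 4, 4, endian)
    offdiag <- c(srx[2:3], sry[c(1, 3)], srz[1:2])
    if (any(abs(offdiag) > 1e-6 * max(spacing)))
      stop("non-axial volume orientation is not supported", call. = FALSE)
    origin <- c(srx[4], sry[4], srz[4])
  }
  seek(con, as.integer(max(vox_offset, 348)))
  nvox <- prod(n)
  vals <- readBin(con, spec$what, n = nvox, size = spec$size, endian = endian,
                  signed = spec$signed)
  if (length(vals) < nvox)
    stop("truncated NIfTI data section", call. = FALSE)
  vals <- as.numeric(vals)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  list(values = array(vals, dim = n),
       spacing = spacing * scale, origin = origin * scale)
}

#' Load a planning CT volume as an attenuation map
#'
#' Reads a CT volume stored in Hounsfield units and converts it to linear
#' attenuation coefficients via the affine CT calibration
#' `mu = mu_water * (1 + HU/1000)`, clamped below at `clamp_floor` so air
#' (HU = -1000) maps to zero and no voxel goes negative.
#'
#' Only NIfTI input is supported in this build: no DICOM reader is available
#' in the supported runtime, so `format = "dicom-series"` raises an
#' unsupported-format error.
#'
#' @param path path to the volume.
#' @param format `"nifti"` or `"dicom-series"` (the latter unsupported).
#' @param hu_to_mu list with `mu_water` (1/cm, default 0.206 at 60 keV) and
#'   `clamp_floor` (1/cm, default 0).
#' @param units unit of the file's geometry metadata (default `"mm"`).
#' @return An [attenuation_map()].
#' @export
load_ct_volume <- function(path, format = c("nifti", "dicom-series"),
                           hu_to_mu = list(mu_water = 0.206, clamp_floor = 0),
                           units = c("mm", "cm")) {
  format <- match.arg(format)
  if (format == "dicom-series")
    stop("DICOM series input is not supported in this build; ",
         "convert the series to NIfTI first", call. = FALSE)
  units <- match.arg(units)
  vol <- read_volume(path, units = units)
  mu_water <- if (is.null(hu_to_mu$mu_water)) 0.206 else hu_to_mu$mu_water
  floor_ <- if (is.null(hu_to_mu$clamp_floor)) 0 else hu_to_mu$clamp_floor
  mu <- pmax(mu_water * (1 + vol$values / 1000), floor_)
  attenuation_map(array(mu, dim = dim(vol$values)), vol$spacing, vol$origin)
}
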
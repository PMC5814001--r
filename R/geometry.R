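#' Circular cone-beam / fan-beam scan geometry
#'
#' Describes a flat-panel circular trajectory. Angle convention: at gantry
#' angle 0 the source sits on the +y world axis and rotation is
#' counterclockwise seen from +z; angles are degrees in the API and radians
#' internally. A nonzero `lateral_offset` displaces the panel along its
#' column axis (half-fan / displaced-detector acquisition, e.g. 14.8 cm for
#' an OBI pelvis scan, 11.5 cm for an XVI medium field of view).
#'
#' @param sad source-to-axis (isocenter) distance, cm.
#' @param sdd source-to-detector distance, cm; must exceed `sad`.
#' @param n_cols,n_rows detector element counts (rows = 1 gives the
#'   single-slice fan-beam case).
#' @param pitch detector element pitch, cm (square elements).
#' @param lateral_offset panel displacement along the column axis, cm
#'   (0 = full-fan).
#' @param angles gantry angles in degrees, one per projection view; default
#'   360 views in 1 degree increments.
#' @param direction rotation sign, `+1` (CCW) or `-1`.
#' @return An object of class `scan_geometry`.
#' @examples
#' g <- scan_geometry(100, 150, n_cols = 256, pitch = 0.2)
#' @export
scan_geometry <- function(sad, sdd, n_cols, n_rows = 1L, pitch,
                          lateral_offset = 0, angles = 0:359,
                          direction = 1) {
  if (!(sdd > sad && sad > 0))
    .stop_validation("need source_detector_distance > source_axis_distance > 0")
  if (pitch <= 0) .stop_validation("detector pitch must be > 0")
  if (length(angles) < 1L) .stop_validation("need at least one view angle")
  if (any(angles < -360 | angles > 720))
    .stop_validation("angles must lie within one full rotation of [0, 360)")
  if (!direction %in% c(-1, 1)) .stop_validation("direction must be +1 or -1")
  structure(list(sad = sad, sdd = sdd,
                 n_cols = as.integer(n_cols), n_rows = as.integer(n_rows),
                 pitch = pitch, lateral_offset = lateral_offset,
                 angles = as.numeric(angles),
                 angles_rad = direction * as.numeric(angles) * pi / 180,
                 direction = direction),
            class = "scan_geometry")
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat(sprintf("scan_geometry: SAD %g cm, SDD %g cm, %d x %d detector @ %g cm pitch\n",
              x$sad, x$sdd, x$n_rows, x$n_cols, x$pitch))
  cat(sprintf("  lateral offset %g cm (%s), %d views [%g..%g] deg\n",
              x$lateral_offset,
              if (x$lateral_offset == 0) "full-fan" else "half-fan",
              length(x$angles), min(x$angles), max(x$angles)))
  invisible(x)
}

#' Scanner geometry presets
#'
#' Half-fan presets mirroring clinical linac-mounted CBCT systems:
#' `"obi-halffan"` (SAD 100, SDD 150, 14.8 cm panel shift) and `"xvi-m20"`
#' (SAD 100, SDD 153.6, 11.5 cm shift), both 360 views at 1 degree.
#'
#' @param name preset name.
#' @param angles optional override of the view angles.
#' @return A [scan_geometry()].
#' @export
geometry_preset <- function(name = c("obi-halffan", "xvi-m20"), angles = 0:359) {
  name <- match.arg(name)
  switch(name,
    "obi-halffan" = scan_geometry(100, 150, n_cols = 512, pitch = 0.0776,
                                  lateral_offset = 14.8, angles = angles),
    "xvi-m20" = scan_geometry(100, 153.6, n_cols = 512, pitch = 0.08,
                              lateral_offset = 11.5, angles = angles))
}

# Trig values snapped to exact zero near axis-aligned angles, so that rays
# running along voxel-boundary planes (e.g. the central ray at 90 degrees on
# an even grid) resolve to a consistent side regardless of the rotation
# direction -- preserving the exact 180-degree periodicity of line integrals.
.snap_trig <- function(x) {
  x[abs(x) < 1e-12] <- 0
  x
}

# Source position for view i (1-based): sad * (-sin b, cos b, 0).
source_position <- function(geom, i) {
  b <- geom$angles_rad[i]
  c(-geom$sad * .snap_trig(sin(b)), geom$sad * .snap_trig(cos(b)), 0)
}

# Detector element centers for view i: matrix (n_rows * n_cols) x 3,
# row index fastest. u measured along (cos b, sin b, 0), v along +z.
detector_positions <- function(geom, i, cols = seq_len(geom$n_cols)) {
  b <- geom$angles_rad[i]
  eu <- c(.snap_trig(cos(b)), .snap_trig(sin(b)), 0)
  src <- source_position(geom, i)
  ctr <- src * (1 - geom$sdd / geom$sad)
  u <- (cols - (geom$n_cols + 1) / 2) * geom$pitch + geom$lateral_offset
  v <- (seq_len(geom$n_rows) - (geom$n_rows + 1) / 2) * geom$pitch
  nu <- length(u); nv <- length(v)
  U <- rep(u, each = nv); V <- rep(v, times = nu)
  cbind(ctr[1] + U * eu[1], ctr[2] + U * eu[2], V)
}

# Detector column u-coordinates projected to the virtual detector through the
# isocenter (scaled by sad/sdd); used by filtering and backprojection.
virtual_u <- function(geom) {
  m <- geom$sad / geom$sdd
  ((seq_len(geom$n_cols) - (geom$n_cols + 1) / 2) * geom$pitch +
     geom$lateral_offset) * m
}

virtual_v <- function(geom) {
  m <- geom$sad / geom$sdd
  (seq_len(geom$n_rows) - (geom$n_rows + 1) / 2) * geom$pitch * m
}
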
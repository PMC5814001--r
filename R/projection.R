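#' Simulate transmitted-count projections under a current plan
#'
#' Monoenergetic Beer-Lambert forward model with optional Poisson noise. The
#' per-view quanta of the plan (uniform reference or modulated) are spread
#' uniformly over the detector elements, optionally reshaped across columns
#' by a bowtie fluence profile (renormalized to mean 1); the expected count
#' at element (i, r, c) is `incident_i(c) * exp(-I)` with `I` the Siddon
#' integral from the source to the element center. Counts below 1 are
#' clamped to 1 before the log normalization (with a warning and a clamp
#' count in the result) so line integrals stay finite.
#'
#' @param map an [attenuation_map()].
#' @param geometry a [scan_geometry()] with the same view count as the plan.
#' @param plan a [plan_currents()] result.
#' @param which `"reference"` or `"tcm"` quanta.
#' @param noise `"on"` (Poisson) or `"off"` (noiseless expectation).
#' @param bowtie_profile optional per-column positive weights (length
#'   `n_cols`); a flat profile is identical to none.
#' @param seed RNG seed for the Poisson draw (required when noise is on for
#'   reproducibility; the caller's RNG state is restored afterwards).
#' @return An object of class `projection_set`: `counts` and `log_integrals`
#'   arrays of dim `(P, rows, cols)`, `incident` (P x cols matrix),
#'   `geometry`, `seed`, `n_clamped`.
#' @export
simulate_projections <- function(map, geometry, plan,
                                 which = c("reference", "tcm"),
                                 noise = c("on", "off"),
                                 bowtie_profile = NULL, seed = NULL) {
  stopifnot(inherits(map, "attenuation_map"),
            inherits(geometry, "scan_geometry"),
            inherits(plan, "current_plan"))
  which <- match.arg(which)
  noise <- match.arg(noise)
  P <- length(geometry$angles_rad)
  if (length(plan$A) != P)
    .stop_validation("plan has ", length(plan$A), " views but geometry has ", P)
  rows <- geometry$n_rows; cols <- geometry$n_cols
  if (is.null(bowtie_profile)) {
    bw <- rep(1, cols)
  } else {
    if (length(bowtie_profile) != cols || any(bowtie_profile <= 0))
      .stop_validation("bowtie profile needs ", cols, " strictly positive weights")
    bw <- bowtie_profile / mean(bowtie_profile)
  }
  q <- if (which == "reference") plan$N0_ref_per_view else plan$N0i_prime

  # expected transmitted counts
  expected <- array(0, dim = c(P, rows, cols))
  incident <- matrix(0, P, cols)
  for (i in seq_len(P)) {
    det <- detector_positions(geometry, i) # (rows*cols) x 3, row fastest
    src <- matrix(source_position(geometry, i), nrow(det), 3, byrow = TRUE)
    I <- matrix(siddon_batch(map, src, det), rows, cols)
    inc <- q[i] / (rows * cols) * bw
    incident[i, ] <- inc
    expected[i, , ] <- sweep(exp(-I), 2, inc, `*`)
  }

  counts <- expected
  if (noise == "on") {
    if (is.null(seed)) .stop_validation("a seed is required when noise = 'on'")
    counts[] <- .with_seed(seed, .rpois_safe(expected))
  }
  clamped <- counts < 1
  n_clamped <- sum(clamped)
  if (n_clamped > 0) {
    warning(sprintf("%d detector elements had counts < 1; clamped before log",
                    n_clamped), call. = FALSE)
    counts[clamped] <- 1
  }
  logint <- -log(sweep(counts, c(1, 3), array(incident, c(P, cols)), `/`))
  structure(list(counts = counts, incident = incident, log_integrals = logint,
                 geometry = geometry, which = which, noise = noise,
                 seed = seed, n_clamped = n_clamped,
                 bowtie = if (is.null(bowtie_profile)) NULL else bw),
            class = "projection_set")
}

#' @export
print.projection_set <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("projection_set (%s, noise %s): %d views x %d rows x %d cols\n",
              x$which, x$noise, d[1], d[2], d[3]))
  cat(sprintf("  log integrals in [%.4g, %.4g], %d clamped elements\n",
              min(x$log_integrals), max(x$log_integrals), x$n_clamped))
  invisible(x)
}

# Poisson draws that stay exact for any realistic mean; falls back to a
# normal approximation only for means too large for rpois's integer range.
.rpois_safe <- function(lambda) {
  out <- numeric(length(lambda))
  big <- lambda > 1e9
  if (any(!big)) out[!big] <- rpois(sum(!big), lambda[!big])
  if (any(big)) out[big] <- round(rnorm(sum(big), lambda[big], sqrt(lambda[big])))
  pmax(out, 0)
}

.with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' A simple bowtie incident-fluence profile
#'
#' Doubly concave across the fan (flat along rows): fluence highest at the
#' detector center and reduced toward the edges, emulating the flattening
#' aluminum bowtie filter. Shape: `1 - depth * (2|c - c0| / n_cols)^2`,
#' renormalized to mean 1 at use.
#'
#' @param n_cols number of detector columns.
#' @param depth fractional edge reduction in (0, 1); default 0.6.
#' @return Numeric vector of positive weights, length `n_cols`.
#' @export
bowtie_profile <- function(n_cols, depth = 0.6) {
  if (depth <= 0 || depth >= 1) .stop_validation("depth must be in (0, 1)")
  c0 <- (n_cols + 1) / 2
  x <- (seq_len(n_cols) - c0) / (n_cols / 2)
  1 - depth * x^2
}

#' Write a projection set to disk
#'
#' Counts go to a NIfTI container (as a `(P, rows, cols)` float volume) with
#' a JSON sidecar holding geometry, incident quanta, seed and clamp count.
#'
#' @param proj a [simulate_projections()] result.
#' @param path output `.nii` path; the sidecar is `path` with `.json`.
#' @return `path`, invisibly.
#' @export
write_projections <- function(proj, path) {
  vol <- list(values = proj$counts, spacing = c(1, 1, 1), origin = c(0, 0, 0))
  write_volume(vol, path)
  g <- proj$geometry
  side <- list(which = proj$which, noise = proj$noise, seed = proj$seed,
               n_clamped = proj$n_clamped,
               geometry = list(sad = g$sad, sdd = g$sdd, n_cols = g$n_cols,
                               n_rows = g$n_rows, pitch = g$pitch,
                               lateral_offset = g$lateral_offset,
                               angles = g$angles),
               incident = proj$incident[, 1])
  jsonlite::write_json(side, paste0(sub("\\.nii$", "", path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
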
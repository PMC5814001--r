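#' Predicted pixel noise variance of the uniform-current reference scan
#'
#' Under the standard quantum-noise model the per-view contribution to the
#' reconstructed pixel variance is `A_i / N0i`; a conventional scan spreads
#' the total quanta `N0` uniformly over the `P` views (`N0i = N0/P`), giving
#' `sigma^2 = sum_i A_i / (N0/P)`.
#'
#' @param A a [view_attenuation()] profile, or a bare numeric vector of
#'   attenuation factors (all >= 1).
#' @param N0 total emitted quanta of the reference scan (a continuous
#'   current proxy, > 0).
#' @return The predicted reference variance (dimensionless, in units of the
#'   quanta proxy).
#' @export
reference_variance <- function(A, N0) {
  A <- .profile_values(A)
  if (length(N0) != 1L || !is.finite(N0) || N0 <= 0)
    .stop_validation("N0 must be a positive scalar")
  sum(A) / (N0 / length(A))
}

.profile_values <- function(A) {
  if (inherits(A, "view_attenuation_profile")) A <- A$A
  if (!is.numeric(A) || length(A) < 1L)
    .stop_validation("attenuation profile must be a non-empty numeric vector")
  if (any(!is.finite(A)) || any(A < 1))
    .stop_validation("attenuation factors must be finite and >= 1")
  A
}

#' Plan modulated per-view tube currents at preserved image noise
#'
#' Given per-view attenuation factors `A_i` and a reference scan of total
#' quanta `N0` spread uniformly over `P` views, computes the allocation of
#' quanta that preserves the reference pixel noise variance at minimal total.
#'
#' The default `"sqrt"` mode is the Lagrange-optimal allocation
#' `N0i' = N0' * sqrt(A_i) / sum(sqrt(A_i))` with total
#' `N0' = (sum sqrt(A_i))^2 / sigma2_ref`; by the Cauchy-Schwarz inequality
#' `N0' <= N0`, with equality exactly when all `A_i` are equal, so planned
#' dose never exceeds the reference. The `"proportional"` mode allocates
#' `N0i'` proportional to `A_i` (the literal transcription of the classical
#' attenuation-proportional rule), rescaled so the predicted variance matches
#' the reference; under that matching it always returns `N0' = N0` — no dose
#' saving — which is why `"sqrt"` is the default (see the methods vignette).
#'
#' @param A a [view_attenuation()] profile or numeric vector (all >= 1).
#' @param N0 reference total quanta (> 0).
#' @param allocation_mode `"sqrt"` (optimal, default) or `"proportional"`.
#' @return An object of class `current_plan`: `N0`, `N0_ref_per_view`,
#'   `N0_prime`, `N0i_prime`, `sigma2_ref`, `sigma2_tcm`,
#'   `reduction_fraction = 1 - N0'/N0`, `allocation_mode`, `A`, `angles`.
#' @examples
#' plan_currents(c(1, 4), N0 = 100) # N0' = 90, per-view (30, 60)
#' @export
plan_currents <- function(A, N0, allocation_mode = c("sqrt", "proportional")) {
  allocation_mode <- match.arg(allocation_mode)
  angles <- if (inherits(A, "view_attenuation_profile"))
    A$geometry$angles else NULL
  A <- .profile_values(A)
  P <- length(A)
  s2_ref <- reference_variance(A, N0)
  if (allocation_mode == "sqrt") {
    w <- sqrt(A)
    N0p <- sum(w)^2 / s2_ref
    N0i <- N0p * w / sum(w)
  } else {
    # N0i' = c * A_i with c chosen so sum(A_i / N0i') = P/c = s2_ref
    N0i <- (P / s2_ref) * A
    N0p <- sum(N0i)
  }
  s2_tcm <- sum(A / N0i)
  structure(list(N0 = N0, N0_ref_per_view = rep(N0 / P, P),
                 N0_prime = N0p, N0i_prime = N0i,
                 sigma2_ref = s2_ref, sigma2_tcm = s2_tcm,
                 reduction_fraction = 1 - N0p / N0,
                 allocation_mode = allocation_mode,
                 A = A, angles = angles),
            class = "current_plan")
}

#' @export
print.current_plan <- function(x, ...) {
  cat(sprintf("current_plan (%s): P = %d views\n", x$allocation_mode,
              length(x$A)))
  cat(sprintf("  N0 = %.6g -> N0' = %.6g  (reduction %.2f%%)\n",
              x$N0, x$N0_prime, 100 * x$reduction_fraction))
  cat(sprintf("  predicted variance: reference %.6g, modulated %.6g\n",
              x$sigma2_ref, x$sigma2_tcm))
  invisible(x)
}

#' Per-voxel primary-fluence dose proxy
#'
#' A desk-scale stand-in for Monte Carlo organ dosimetry: for each voxel v,
#' `proxy(v) = sum_i quanta_i * exp(-I(source_i -> v)) * mu(v)`, the energy
#' fluence surviving to the voxel times its interaction cross-section. Only
#' relative comparisons (modulated vs reference) are meaningful.
#'
#' @param map an [attenuation_map()].
#' @param geometry a [scan_geometry()] whose view count matches the plan.
#' @param plan a [plan_currents()] result.
#' @param which `"reference"` (uniform `N0/P`) or `"tcm"` (modulated).
#' @param view_stride compute every k-th view (quanta rescaled to conserve
#'   the total); proxy cost is O(views x voxels x traversal), so strides > 1
#'   are the norm for large grids.
#' @return An `attenuation_map`-shaped list with `values` holding the proxy
#'   grid plus `spacing`/`origin` copied from `map`.
#' @export
dose_proxy_map <- function(map, geometry, plan,
                           which = c("reference", "tcm"), view_stride = 1L) {
  stopifnot(inherits(map, "attenuation_map"),
            inherits(geometry, "scan_geometry"),
            inherits(plan, "current_plan"))
  which <- match.arg(which)
  P <- length(geometry$angles_rad)
  if (length(plan$A) != P)
    .stop_validation("plan has ", length(plan$A), " views but geometry has ", P)
  q <- if (which == "reference") plan$N0_ref_per_view else plan$N0i_prime
  idx <- seq(1L, P, by = as.integer(view_stride))
  q <- q[idx] * (P / length(idx)) # each kept view stands in for stride views
  src <- t(vapply(idx, function(i) source_position(geometry, i), numeric(3)))
  vals <- cpp_dose_proxy(map$values, dim(map$values), map$spacing, map$origin,
                         src, q)
  proxy <- array(vals, dim = dim(map$values))
  list(values = proxy, spacing = map$spacing, origin = map$origin,
       which = which, view_stride = as.integer(view_stride))
}

#' Mean dose proxy over a region of interest
#'
#' @param proxy result of [dose_proxy_map()].
#' @param roi optional [roi_spec()]; default whole grid restricted to
#'   attenuating voxels (proxy > 0).
#' @return Mean proxy value.
#' @export
dose_proxy_mean <- function(proxy, roi = NULL) {
  v <- proxy$values
  if (is.null(roi)) return(mean(v[v > 0]))
  m <- roi_mask(roi, dim(v)[1:2])
  mean(v[, , 1][m])
}

#' Serialize a current plan
#'
#' Writes the per-view table (view, angle, A_i, reference and modulated
#' quanta) as CSV and a JSON summary (totals, variances, reduction).
#'
#' @param plan a [plan_currents()] result.
#' @param table_path CSV output path (NULL to skip).
#' @param summary_path JSON output path (NULL to skip).
#' @return The per-view table, invisibly.
#' @export
write_plan <- function(plan, table_path = NULL, summary_path = NULL) {
  P <- length(plan$A)
  tab <- data.frame(view = seq_len(P),
                    angle_deg = if (is.null(plan$angles)) NA_real_ else plan$angles,
                    A = plan$A,
                    N0i_ref = plan$N0_ref_per_view,
                    N0i_tcm = plan$N0i_prime)
  if (!is.null(table_path)) write.csv(tab, table_path, row.names = FALSE)
  if (!is.null(summary_path)) {
    s <- list(N0 = plan$N0, N0_prime = plan$N0_prime,
              reduction_fraction = plan$reduction_fraction,
              sigma2_ref = plan$sigma2_ref, sigma2_tcm = plan$sigma2_tcm,
              allocation_mode = plan$allocation_mode, P = P)
    jsonlite::write_json(s, summary_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(tab)
}
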
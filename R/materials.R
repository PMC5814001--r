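#' Material table of linear attenuation coefficients
#'
#' A small lookup table mapping material names to linear attenuation
#' coefficients (1/cm) at a single design energy. The shipped defaults are
#' representative monoenergetic 60 keV values (roughly the mean energy of a
#' 120 kVp tube spectrum); they are configuration, not ground truth, and can
#' be overridden entry by entry.
#'
#' @param coefficients named numeric vector of attenuation coefficients in
#'   1/cm; entries override or extend the defaults. Must keep non-negative
#'   values.
#' @param energy_kev design photon energy in keV (metadata only).
#' @return An object of class `material_table`.
#' @examples
#' mt <- material_table(c(titanium = 1.2))
#' material_mu(mt, "water")
#' @export
material_table <- function(coefficients = NULL, energy_kev = 60) {
  mu <- c(air = 0.0, lung = 0.06, water = 0.206, soft_tissue = 0.21,
          bone = 0.57)
  if (!is.null(coefficients)) {
    if (is.null(names(coefficients)) || any(names(coefficients) == ""))
      .stop_validation("material coefficients must be a named numeric vector")
    mu[names(coefficients)] <- coefficients
  }
  if (any(!is.finite(mu)) || any(mu < 0))
    .stop_validation("attenuation coefficients must be finite and >= 0")
  if (!all(c("air", "water") %in% names(mu)))
    .stop_validation("material table must contain 'air' and 'water'")
  structure(list(mu = mu, energy_kev = energy_kev), class = "material_table")
}

#' Look up a material's attenuation coefficient
#'
#' @param table a [material_table()].
#' @param name material name.
#' @return Linear attenuation coefficient in 1/cm.
#' @export
material_mu <- function(table, name) {
  stopifnot(inherits(table, "material_table"))
  if (!name %in% names(table$mu))
    stop("unknown material '", name, "'; known: ",
         paste(names(table$mu), collapse = ", "), call. = FALSE)
  unname(table$mu[[name]])
}

#' @export
print.material_table <- function(x, ...) {
  cat("Material table @", x$energy_kev, "keV (1/cm):\n")
  print(x$mu)
  invisible(x)
}
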
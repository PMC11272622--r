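#' Hertz contact radius for a fabric element on a limb
#'
#' Radius of the circular contact patch between one fabric element (radius
#' `R_F`) and the limb surface (radius `R`) under normal load `F`, for elastic
#' mismatch factors `k` (limb) and `k_F` (fabric):
#' a = (3 pi F (k + k_F) R R_F / (4 (R + R_F)))^(1/3).
#'
#' @param F normal load (N), >= 0; vectorised.
#' @param k,k_F elastic mismatch factors (1/Pa), see [mismatch_factor()].
#' @param R limb radius (m).
#' @param R_F fabric element radius (m).
#' @return contact radius a (m).
#' @examples
#' contact_radius(1, 1.7052e-4, 0, 0.05, 0.03)  # ~0.0196 m
#' @export
contact_radius <- function(F, k, k_F, R, R_F) {
  if (any(F < 0)) stop("load F must be >= 0")
  stopifnot(all(k >= 0), all(k_F >= 0), all(R > 0), all(R_F > 0))
  if (any(R + R_F <= 0)) stop("R + R_F must be > 0")
  (3 * pi * F * (k + k_F) * R * R_F / (4 * (R + R_F)))^(1 / 3)
}

#' Peak (unit) contact pressure
#'
#' Hertz peak pressure at the centre of the contact circle,
#' q = 3 F / (2 pi a^2).
#'
#' @param F normal load (N).
#' @param a contact radius (m).
#' @return q (Pa).
#' @export
unit_pressure <- function(F, a) {
  if (any(F < 0)) stop("load F must be >= 0")
  if (any(a == 0 & F > 0)) stop("a = 0 with non-zero load")
  ifelse(F == 0, 0, 3 * F / (2 * pi * a^2))
}

#' Surface displacement inside a Hertz contact
#'
#' Total elastic approach of the two contacting surfaces at radial offset `r`
#' from the contact centre:
#' omega(r) = (k + k_F) pi q (a^2 - r^2) / (4 a),
#' which at the full-contact condition r = 0 reduces to (k + k_F) pi q a / 4.
#' The share attributable to one body alone is obtained by passing its own
#' mismatch factor and 0 for the other.
#'
#' @param k,k_F elastic mismatch factors (1/Pa).
#' @param q peak contact pressure (Pa).
#' @param a contact radius (m).
#' @param r radial offset (m), 0 <= r <= a; default 0.
#' @return displacement omega (m).
#' @examples
#' surface_displacement(1.7052e-4, 8.7e-7, q = 1243, a = 0.0196)  # ~3.3 mm
#' @export
surface_displacement <- function(k, k_F, q, a, r = 0) {
  stopifnot(all(k >= 0), all(k_F >= 0), all(q >= 0), all(a > 0))
  if (any(r < 0 | r > a)) stop("r must lie in [0, a]")
  (k + k_F) * pi * q * (a^2 - r^2) / (4 * a)
}

#' Interface pressure of a loaded contact patch
#'
#' Interface pressure defined from the normal load over the contact patch,
#' P = F / (2 pi a^2) — one third of the Hertz peak pressure q, so q/P = 3
#' identically. [mean_pressure()] gives the conventional mean F / (pi a^2)
#' for comparison; the pipeline uses `interface_pressure`.
#'
#' @param F normal load (N).
#' @param a contact radius (m).
#' @return P (Pa).
#' @export
interface_pressure <- function(F, a) {
  if (any(F < 0)) stop("load F must be >= 0")
  if (any(a == 0 & F > 0)) stop("a = 0 with non-zero load")
  ifelse(F == 0, 0, F / (2 * pi * a^2))
}

#' @rdname interface_pressure
#' @export
mean_pressure <- function(F, a) {
  if (any(F < 0)) stop("load F must be >= 0")
  if (any(a == 0 & F > 0)) stop("a = 0 with non-zero load")
  ifelse(F == 0, 0, F / (pi * a^2))
}

#' Rigid-versus-soft pressure-diversity ratio
#'
#' Ratio of the pressure delivered on a rigid leg model to that on a soft
#' leg, decomposed into a displacement ratio and a stiffness (mismatch)
#' ratio:
#' deltaP = (w_r / w_s) x ((k_s + k_F) / (k_r + k_F)).
#' When the displacements are Hertz-consistent (both computed from
#' [surface_displacement()] at the same q and a), w is proportional to
#' (k + k_F) and deltaP = 1 identically: garment pressure delivery is then
#' independent of the substrate stiffness.
#'
#' @param w_r,w_s surface displacements (m) on the rigid and soft leg, > 0.
#' @param k_r,k_s mismatch factors (1/Pa) of the rigid and soft leg, > 0.
#' @param k_F fabric mismatch factor (1/Pa), > 0.
#' @return list with `w_ratio`, `k_ratio` and `delta_P`.
#' @examples
#' pressure_ratio(w_r = 5e-4, w_s = 5e-3,
#'                k_r = 9.655e-11, k_s = 1.7052e-4, k_F = 8.693e-7)
#' @export
pressure_ratio <- function(w_r, w_s, k_r, k_s, k_F) {
  stopifnot(all(w_r > 0), all(w_s > 0), all(k_r > 0), all(k_s > 0),
            all(k_F > 0))
  w_ratio <- w_r / w_s
  k_ratio <- (k_s + k_F) / (k_r + k_F)
  list(w_ratio = w_ratio, k_ratio = k_ratio, delta_P = w_ratio * k_ratio)
}

#' Full Hertz contact state for one fabric-leg element
#'
#' Convenience wrapper chaining [contact_radius()], [unit_pressure()],
#' [surface_displacement()] and [interface_pressure()] for one load case.
#'
#' @inheritParams contact_radius
#' @param r radial offset (m) for the displacement, default 0.
#' @return an object of class `"contact_state"`: list with `F`, `a`, `q`,
#'   `r`, `omega`, `P`.
#' @export
hertz_contact <- function(F, k, k_F, R, R_F, r = 0) {
  a <- contact_radius(F, k, k_F, R, R_F)
  q <- unit_pressure(F, a)
  omega <- if (a > 0) surface_displacement(k, k_F, q, a, r) else 0
  P <- interface_pressure(F, a)
  structure(list(F = F, a = a, q = q, r = r, omega = omega, P = P),
            class = "contact_state")
}

#' @export
print.contact_state <- function(x, ...) {
  cat(sprintf(paste0("Hertz contact: F = %.4g N, a = %.4g m, q = %.4g Pa,\n",
                     "  omega(r=%.3g) = %.4g m, P = %.4g Pa (%.2f mmHg)\n"),
              x$F, x$a, x$q, x$r, x$omega, x$P, pa_to_mmhg(x$P)))
  invisible(x)
}
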
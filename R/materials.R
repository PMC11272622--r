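#' Fabric specification for one compression-textile tube
#'
#' Bundles the physical and orthotropic mechanical constants of one knitted
#' compression tube: relaxed circumferential radius, length, thickness, mass
#' density, course/wale Young's moduli, Poisson ratio and shear modulus.
#' All arguments in SI units.
#'
#' @param label free-text identifier (e.g. subject/position code).
#' @param R_F relaxed tube circumferential radius (m).
#' @param L_F tube length (m).
#' @param h fabric thickness (m).
#' @param MD fabric mass density (kg/m^3).
#' @param E_F Young's modulus along the course (circumferential) direction (Pa).
#' @param E_Fy Young's modulus along the wale (longitudinal) direction (Pa).
#' @param v_F Poisson ratio, in [0, 0.5).
#' @param G_F shear modulus (Pa).
#' @param compression_class compression level, `"I"` or `"III"`.
#' @return an object of class `"fabric_spec"`.
#' @examples
#' fabric_spec("S1-I-B", R_F = 0.0252, L_F = 0.06, h = 0.00066,
#'             MD = 479.3, E_F = 0.35e6, E_Fy = 0.16e6, v_F = 0.21,
#'             G_F = 0.14e6, compression_class = "I")
#' @export
fabric_spec <- function(label, R_F, L_F, h, MD, E_F, E_Fy = E_F, v_F = 0.2,
                        G_F = E_F / (2 * (1 + v_F)),
                        compression_class = "I") {
  compression_class <- as.character(compression_class)
  if (length(compression_class) != 1 || !compression_class %in% c("I", "III"))
    stop("unknown compression class: ", paste(compression_class, collapse = ","))
  stopifnot(R_F > 0, L_F > 0, h > 0, MD > 0, E_F > 0, E_Fy > 0, G_F > 0)
  if (v_F < 0 || v_F >= 0.5) stop("v_F must lie in [0, 0.5)")
  structure(list(label = label, R_F = R_F, L_F = L_F, h = h, MD = MD,
                 E_F = E_F, E_Fy = E_Fy, v_F = v_F, G_F = G_F,
                 compression_class = compression_class),
            class = "fabric_spec")
}

#' @export
print.fabric_spec <- function(x, ...) {
  cat(sprintf("Compression fabric '%s' (class %s)\n", x$label,
              x$compression_class))
  cat(sprintf("  R_F = %.2f cm, L_F = %.1f cm, h = %.2f mm, MD = %.1f kg/m3\n",
              x$R_F * 100, x$L_F * 100, x$h * 1000, x$MD))
  cat(sprintf("  E_F = %.2f MPa, E_Fy = %.2f MPa, v_F = %.2f, G_F = %.2f MPa\n",
              x$E_F / 1e6, x$E_Fy / 1e6, x$v_F, x$G_F / 1e6))
  invisible(x)
}

#' Coerce a one-row fabric table to a fabric_spec
#'
#' @param x a `fabric_spec` or a one-row data frame with SI columns
#'   `R_F, L_F, h, MD, E_F, E_Fy, v_F, G_F` (and optionally `subject`,
#'   `class`, `position`), as returned by [read_fabric_csv()].
#' @return a `fabric_spec`.
#' @export
as_fabric_spec <- function(x) {
  if (inherits(x, "fabric_spec")) return(x)
  stopifnot(is.data.frame(x), nrow(x) == 1)
  lab <- paste(c(x$subject, x$class, x$position), collapse = "-")
  if (lab == "") lab <- "fabric"
  fabric_spec(lab, R_F = x$R_F, L_F = x$L_F, h = x$h, MD = x$MD,
              E_F = x$E_F, E_Fy = x$E_Fy, v_F = x$v_F, G_F = x$G_F,
              compression_class = if (!is.null(x$class)) as.character(x$class) else "I")
}

#' Fabric Young's modulus from tensile-test records
#'
#' Reduces uniaxial strip-test records to a Young's modulus via
#' E = F_T / (b h eps) and averages over the records, i.e. over the strain
#' levels sampled by the tester. `records` is a data frame with columns
#' `F_T` (tension force, N), `b` (clamped width, m), `h` (thickness, m) and
#' `strain` (engineering strain of the clamped length, dimensionless, > 0).
#'
#' @param records data frame of tensile records (one row per strain level).
#' @return mean modulus (Pa).
#' @examples
#' fabric_modulus_from_tension(
#'   data.frame(F_T = 1, b = 0.05, h = 0.00066, strain = 1))
#' @export
fabric_modulus_from_tension <- function(records) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) stop("no tensile records supplied")
  req <- c("F_T", "b", "h", "strain")
  miss <- setdiff(req, names(records))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (any(records$strain <= 0)) stop("all strains must be > 0")
  if (any(records$b <= 0 | records$h <= 0)) stop("b and h must be > 0")
  if (any(records$F_T < 0)) stop("tension force must be >= 0")
  mean(records$F_T / (records$b * records$h * records$strain))
}

#' Soft-tissue Young's modulus from shear-wave velocity
#'
#' Shear-wave elastography estimates the tissue Young's modulus from the
#' propagation speed of an induced shear wave as E = 3 rho v^2 (incompressible
#' soft tissue). Velocities above 7.7 m/s are outside the range reported for
#' healthy lower-leg muscle and trigger a warning.
#'
#' @param velocity shear-wave speed (m/s), vectorised.
#' @param rho_m muscle density (kg/m^3), default 1000.
#' @return Young's modulus (Pa).
#' @examples
#' swe_modulus(1)    # 3000 Pa
#' swe_modulus(7.7)  # 177870 Pa, upper end of the physiological range
#' @export
swe_modulus <- function(velocity, rho_m = 1000) {
  stopifnot(rho_m > 0)
  if (any(velocity < 0)) stop("shear-wave velocity must be >= 0")
  if (any(velocity > 7.7))
    warning("velocity above 7.7 m/s: outside the reported muscle range")
  3 * rho_m * velocity^2
}

#' Mean regional tissue modulus for one subject
#'
#' Averages the regional shear-wave moduli of a single subject. `records` is a
#' data frame with a `subject` column and either `modulus_pa` or
#' `velocity_m_s` (+ optional `rho_m`); velocities are converted through
#' [swe_modulus()] first.
#'
#' @param records data frame of elastography records for one subject.
#' @return mean Young's modulus (Pa).
#' @export
mean_swe_modulus <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 1L)
  if (is.null(records$subject)) stop("records need a 'subject' column")
  if (length(unique(records$subject)) > 1L)
    stop("records mix subjects: ", paste(unique(records$subject), collapse = ", "))
  if (!is.null(records$modulus_pa)) {
    mod <- records$modulus_pa
  } else if (!is.null(records$velocity_m_s)) {
    rho <- if (is.null(records$rho_m)) 1000 else records$rho_m
    mod <- swe_modulus(records$velocity_m_s, rho_m = rho)
  } else {
    stop("records need a 'modulus_pa' or 'velocity_m_s' column")
  }
  mean(mod)
}

#' Neo-Hookean constants from linear-elastic moduli
#'
#' Converts (E, nu) to the neo-Hookean strain-energy constants under the
#' linear-elastic correspondence C10 = S/2, D1 = B/2, where S = E/(2(1+nu))
#' and B = E/(3(1-2nu)) are the shear and bulk moduli of standard isotropic
#' elasticity. For incompressible material (nu = 0.5) the bulk modulus and D1
#' are returned as `Inf` and the result is flagged incompressible.
#'
#' @param E Young's modulus (Pa), > 0.
#' @param nu Poisson ratio, in (0, 0.5].
#' @return list with `C10`, `D1`, `S`, `B` (Pa) and logical `incompressible`.
#' @examples
#' neo_hookean_params(3000, 0.45)  # C10 ~ 517.2 Pa, D1 = 5000 Pa
#' neo_hookean_params(3000, 0.5)   # incompressible: D1 = Inf
#' @export
neo_hookean_params <- function(E, nu = 0.5) {
  stopifnot(E > 0)
  if (nu <= 0 || nu > 0.5) stop("nu must lie in (0, 0.5]")
  S <- E / (2 * (1 + nu))
  incomp <- (nu == 0.5)
  B <- if (incomp) Inf else E / (3 * (1 - 2 * nu))
  list(C10 = S / 2, D1 = B / 2, S = S, B = B, incompressible = incomp)
}

#' Hertz elastic mismatch factor
#'
#' Compliance-like factor k = (1 - nu^2) / (pi E) entering the Hertz contact
#' relations; larger for softer bodies, tending to 0 in the rigid limit.
#'
#' @param E Young's modulus (Pa), > 0; vectorised.
#' @param nu Poisson ratio in [0, 1).
#' @return mismatch factor (1/Pa).
#' @examples
#' mismatch_factor(1400, 0.5)    # soft calf muscle
#' mismatch_factor(3e9, 0.3)     # printed rigid polymer leg, ~1e-10
#' @export
mismatch_factor <- function(E, nu = 0.5) {
  if (any(E <= 0)) stop("E must be > 0")
  if (any(nu < 0 | nu >= 1)) stop("nu must lie in [0, 1)")
  (1 - nu^2) / (pi * E)
}

#' Soft-tissue material model
#'
#' Derives the neo-Hookean constants and the Hertz mismatch factor for a
#' homogeneous soft-tissue body of Young's modulus `E_s`. Tissue is treated
#' as incompressible by default (nu = 0.5).
#'
#' @param E_s tissue Young's modulus (Pa).
#' @param nu Poisson ratio, default 0.5 (incompressible).
#' @return an object of class `"tissue_model"` with fields `E_s`, `nu`,
#'   `C10`, `D1`, `k` and `incompressible`.
#' @examples
#' tissue_model(2200)  # intermediate calf-muscle stiffness
#' @export
tissue_model <- function(E_s, nu = 0.5) {
  stopifnot(E_s > 0)
  nh <- neo_hookean_params(E_s, nu)
  structure(list(E_s = E_s, nu = nu, C10 = nh$C10, D1 = nh$D1,
                 k = mismatch_factor(E_s, nu),
                 incompressible = nh$incompressible),
            class = "tissue_model")
}

#' @export
print.tissue_model <- function(x, ...) {
  cat(sprintf("Soft-tissue model: E_s = %.4g Pa (%.4f MPa), nu = %.2f%s\n",
              x$E_s, x$E_s / 1e6, x$nu,
              if (x$incompressible) " [incompressible]" else ""))
  cat(sprintf("  C10 = %.4g Pa, D1 = %.4g Pa, k = %.4g 1/Pa\n",
              x$C10, x$D1, x$k))
  invisible(x)
}
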
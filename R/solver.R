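#' Solver configuration for the garment equilibrium
#'
#' @param foundation tissue-compliance coupling: `"hertz"` (default; leg-side
#'   Hertz surface displacement over a patch of radius `patch_radius`) or
#'   `"winkler"` (bed of independent springs with modulus `winkler_modulus`).
#' @param patch_radius Hertz contact-patch radius a0 (m), default 0.02.
#' @param winkler_modulus foundation modulus (Pa/m), required for
#'   `foundation = "winkler"`.
#' @param tol relative residual on the girth fixed point, default 1e-8.
#' @param max_iter maximum fixed-point iterations, default 200.
#' @param damping damping factor in (0, 1], default 0.5.
#' @param rigid_threshold Young's modulus (Pa) at or above which a leg is
#'   treated as rigid (no indentation), default 1e9.
#' @return an object of class `"solver_config"`.
#' @export
solver_config <- function(foundation = c("hertz", "winkler"),
                          patch_radius = 0.02, winkler_modulus = NULL,
                          tol = 1e-8, max_iter = 200, damping = 0.5,
                          rigid_threshold = 1e9) {
  foundation <- match.arg(foundation)
  stopifnot(tol > 0, max_iter >= 1, damping > 0, damping <= 1,
            patch_radius > 0)
  if (foundation == "winkler" &&
      (is.null(winkler_modulus) || winkler_modulus <= 0))
    stop("winkler foundation requires a positive winkler_modulus")
  structure(list(foundation = foundation, patch_radius = patch_radius,
                 winkler_modulus = winkler_modulus, tol = tol,
                 max_iter = max_iter, damping = damping,
                 rigid_threshold = rigid_threshold),
            class = "solver_config")
}

#' Circumferential wear strain of a donned tube
#'
#' Engineering strain imposed on the relaxed tube (circumference 2 pi R_F)
#' when worn on a limb of girth `C_leg`; floored at 0 for a slack garment,
#' with a warning.
#'
#' @param C_leg limb girth (m).
#' @param R_F relaxed tube radius (m).
#' @return strain (dimensionless, >= 0); vectorised.
#' @examples
#' wear_strain(0.2513, 0.0252)  # ~0.587
#' @export
wear_strain <- function(C_leg, R_F) {
  stopifnot(all(C_leg > 0), all(R_F > 0))
  C_F <- 2 * pi * R_F
  eps <- (C_leg - C_F) / C_F
  if (any(eps < 0))
    warning("garment slack (tube circumference exceeds limb girth); strain floored at 0")
  pmax(eps, 0)
}

#' Membrane tension of a stretched fabric
#'
#' Linear-elastic hoop tension per unit length, T = E_F eps h, using the
#' course-direction modulus. Strains above 0.8 are outside the working
#' stretch band of these knits and trigger a warning.
#'
#' @param strain circumferential strain, >= 0.
#' @param fabric a [fabric_spec()].
#' @return tension per unit length (N/m); vectorised over `strain`.
#' @examples
#' f <- fabric_spec("x", 0.0252, 0.06, 0.00066, 479, 0.35e6,
#'                  compression_class = "I")
#' membrane_tension(0.43, f)  # ~99.3 N/m
#' @export
membrane_tension <- function(strain, fabric) {
  stopifnot(inherits(fabric, "fabric_spec"))
  if (any(strain < 0)) stop("strain must be >= 0")
  if (any(strain > 0.8))
    warning("strain above 0.8: beyond the working stretch band")
  fabric$E_F * strain * fabric$h
}

#' Laplace-law membrane pressure
#'
#' Interface pressure of a tensioned membrane over a curved surface,
#' P = T / radius (equivalently T times curvature). For a circular section
#' of girth C use radius = C / (2 pi); [laplace_pressure_girth()] performs
#' that conversion.
#'
#' @param T membrane tension per unit length (N/m).
#' @param radius local radius of curvature (m), > 0.
#' @param girth section girth (m), > 0.
#' @return pressure (Pa); vectorised.
#' @examples
#' laplace_pressure(100, 0.04)               # 2500 Pa = 18.75 mmHg
#' laplace_pressure_girth(100, 2 * pi * 0.04)
#' @export
laplace_pressure <- function(T, radius) {
  if (any(radius <= 0)) stop("radius must be > 0")
  if (any(T < 0)) stop("tension must be >= 0")
  T / radius
}

#' @rdname laplace_pressure
#' @export
laplace_pressure_girth <- function(T, girth) {
  if (any(girth <= 0)) stop("girth must be > 0")
  laplace_pressure(T, girth / (2 * pi))
}

#' Pressure profile around an irregular section
#'
#' Extends Laplace's law to non-circular sections: P(s) = T kappa(s), with
#' the local curvature from [local_radius()] (clipped, so flat segments give
#' the clip-minimum pressure rather than zero).
#'
#' @param section a [cross_section()].
#' @param T membrane tension per unit length (N/m).
#' @param clip radius clipping bounds (m) passed to the curvature estimate.
#' @return data frame with `arc_position` (in [0,1)), `radius` (m) and
#'   `P` (Pa), one row per boundary vertex.
#' @export
local_pressure_profile <- function(section, T, clip = c(1e-4, 10)) {
  stopifnot(inherits(section, "cross_section"), T >= 0)
  x <- section$x; y <- section$y
  seg <- sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2)
  s <- c(0, cumsum(seg))[seq_along(x)] / sum(seg)
  r <- vertex_radii(x, y, clip)
  data.frame(arc_position = s, radius = r, P = T / r)
}

# closed-form worn pressure on an undeformable limb:
# P = 2 pi E_F h (1/C_F - 1/C0), 0 if slack
rigid_laplace_pressure <- function(fabric, C0) {
  C_F <- 2 * pi * fabric$R_F
  if (C0 <= C_F) return(0)
  2 * pi * fabric$E_F * fabric$h * (1 / C_F - 1 / C0)
}

#' Quasi-static garment--leg equilibrium at one position
#'
#' Solves the worn steady state of a stretched tube on a compliant limb by a
#' damped fixed point on the limb girth C: the wear strain sets the hoop
#' tension, Laplace's law converts tension to pressure, the tissue foundation
#' converts pressure to a radial indentation w, and the indentation shrinks
#' the girth (C = C0 - 2 pi w) until self-consistent. The Hertz foundation
#' uses the leg-side surface displacement w = k_leg pi a0 P / 4 over a patch
#' of radius a0; legs at or above the rigid threshold (or with no tissue
#' model) do not indent, and the solution then equals the closed-form Laplace
#' pressure.
#'
#' @param fabric a [fabric_spec()] (or one-row SI fabric table).
#' @param girth undeformed limb girth C0 at the position (m).
#' @param tissue a [tissue_model()], or `NULL` for a rigid leg.
#' @param config a [solver_config()].
#' @param position optional position label carried into the result.
#' @return an object of class `"pressure_result"`: list with `position`,
#'   `P` (Pa), `P_mmHg`, `T` (N/m), `strain`, `w` (m, leg indentation),
#'   `w_contact` (m, total Hertz approach at the equilibrium pressure),
#'   `girth` (deformed, m), `girth0`, `iterations`, `converged`, `residual`,
#'   plus the mismatch factors `k_leg`, `k_F` and `patch_radius` used.
#' @examples
#' f <- fabric_spec("S1-I-B", 0.0252, 0.06, 0.00066, 479.3, 0.35e6, 0.16e6,
#'                  0.21, 0.14e6, "I")
#' solve_equilibrium(f, girth = 0.2513)                  # rigid mannequin
#' solve_equilibrium(f, girth = 0.2513, tissue_model(3000))  # soft leg
#' @export
solve_equilibrium <- function(fabric, girth, tissue = NULL,
                              config = solver_config(), position = NA_character_) {
  fabric <- as_fabric_spec(fabric)
  stopifnot(girth > 0)
  stopifnot(inherits(config, "solver_config"))
  k_F <- mismatch_factor(fabric$E_F, fabric$v_F)
  rigid <- is.null(tissue) || tissue$E_s >= config$rigid_threshold
  k_leg <- if (is.null(tissue)) mismatch_factor(3e9, 0.3) else tissue$k
  compliance <- switch(config$foundation,
    hertz   = k_leg * pi * config$patch_radius / 4,
    winkler = 1 / config$winkler_modulus)
  if (rigid) compliance <- 0

  C0 <- girth
  C_F <- 2 * pi * fabric$R_F
  if (C0 <= C_F) {
    warning("garment slack at position ", position, ": zero pressure")
    return(pressure_result(position, P = 0, T = 0, strain = 0, w = 0,
                           w_contact = 0, girth = C0, girth0 = C0,
                           iterations = 0L, converged = TRUE, residual = 0,
                           k_leg = k_leg, k_F = k_F,
                           patch_radius = config$patch_radius))
  }

  C <- C0; res <- Inf; it <- 0L
  while (it < config$max_iter) {
    it <- it + 1L
    eps <- max((C - C_F) / C_F, 0)
    T <- fabric$E_F * eps * fabric$h
    P <- laplace_pressure(T, C / (2 * pi))
    w <- compliance * P
    C_next <- C0 - 2 * pi * w
    res <- abs(C_next - C) / C0
    C <- C + config$damping * (C_next - C)
    if (res < config$tol) break
  }
  eps <- max((C - C_F) / C_F, 0)
  T <- fabric$E_F * eps * fabric$h
  P <- laplace_pressure(T, C / (2 * pi))
  w <- compliance * P
  # total two-body Hertz approach at the equilibrium pressure (q -> P)
  w_contact <- (k_leg + k_F) * pi * config$patch_radius * P / 4
  pressure_result(position, P = P, T = T, strain = eps, w = w,
                  w_contact = w_contact, girth = C, girth0 = C0,
                  iterations = it, converged = res < config$tol,
                  residual = res, k_leg = k_leg, k_F = k_F,
                  patch_radius = config$patch_radius)
}

pressure_result <- function(position, P, T, strain, w, w_contact, girth,
                            girth0, iterations, converged, residual,
                            k_leg, k_F, patch_radius) {
  structure(list(position = position, P = P, P_mmHg = pa_to_mmhg(P), T = T,
                 strain = strain, w = w, w_contact = w_contact,
                 girth = girth, girth0 = girth0, iterations = iterations,
                 converged = converged, residual = residual, k_leg = k_leg,
                 k_F = k_F, patch_radius = patch_radius),
            class = "pressure_result")
}

#' @export
print.pressure_result <- function(x, ...) {
  cat(sprintf("Equilibrium pressure%s: %.2f mmHg (%.1f Pa)\n",
              if (is.na(x$position)) "" else paste0(" at ", x$position),
              x$P_mmHg, x$P))
  cat(sprintf("  T = %.1f N/m, strain = %.3f, w = %.3f mm, girth %.2f -> %.2f cm\n",
              x$T, x$strain, x$w * 1000, x$girth0 * 100, x$girth * 100))
  cat(sprintf("  %s in %d iterations (residual %.2e)\n",
              if (x$converged) "converged" else "NOT converged",
              x$iterations, x$residual))
  invisible(x)
}

#' Pressure-diversity ratio from two equilibrium solutions
#'
#' Feeds the Hertz displacement chain with two solver results evaluated at a
#' matched load: the total two-body approaches of the rigid and soft
#' configurations are computed at the same reference pressure (by default
#' the soft leg's equilibrium pressure) and combined with the mismatch
#' ratio through [pressure_ratio()]. With Hertz-consistent displacements
#' this is identically 1.
#'
#' @param res_rigid,res_soft `"pressure_result"` objects from
#'   [solve_equilibrium()] on the rigid and soft leg.
#' @param q reference pressure (Pa); default the soft result's equilibrium P.
#' @return list from [pressure_ratio()] (`w_ratio`, `k_ratio`, `delta_P`).
#' @export
delta_p_from_results <- function(res_rigid, res_soft, q = res_soft$P) {
  stopifnot(inherits(res_rigid, "pressure_result"),
            inherits(res_soft, "pressure_result"), q > 0)
  a0 <- res_soft$patch_radius
  w_r <- surface_displacement(res_rigid$k_leg, res_rigid$k_F, q, a0)
  w_s <- surface_displacement(res_soft$k_leg, res_soft$k_F, q, a0)
  pressure_ratio(w_r = w_r, w_s = w_s, k_r = res_rigid$k_leg,
                 k_s = res_soft$k_leg, k_F = res_soft$k_F)
}

#' Per-position pressures along a leg
#'
#' Solves the garment equilibrium at every labelled position of a leg and
#' flags whether the profile is degressive (pressure non-increasing from the
#' ankle B up to D, within a tolerance).
#'
#' @param leg a [leg_model()].
#' @param fabrics named list of [fabric_spec()] (names = position labels) or
#'   an SI fabric table with a `position` column ([read_fabric_csv()]).
#' @param config a [solver_config()].
#' @param gradient_tol tolerance for the degressive check (mmHg), default 1.
#' @return data frame of class `"pressure_profile"`, one row per position in
#'   B, B1, C, D order, with attributes `degressive` (logical) and
#'   `violating_pair` (character, e.g. `"B1<C"`, when not degressive).
#' @export
pressure_gradient_profile <- function(leg, fabrics, config = solver_config(),
                                      gradient_tol = 1) {
  stopifnot(inherits(leg, "leg_model"))
  labs <- vapply(leg$sections, `[[`, "", "label")
  order_ref <- c("B", "B1", "C", "D")
  labs <- order_ref[order_ref %in% labs]
  if (length(labs) == 0L) stop("leg has no labelled sections")
  if (is.data.frame(fabrics)) {
    fl <- lapply(labs, function(p) {
      row <- fabrics[fabrics$position == p, , drop = FALSE]
      if (nrow(row) == 0L) stop("no fabric supplied for position ", p)
      as_fabric_spec(row[1, , drop = FALSE])
    })
    names(fl) <- labs
    fabrics <- fl
  }
  miss <- setdiff(labs, names(fabrics))
  if (length(miss)) stop("no fabric supplied for position ",
                         paste(miss, collapse = ", "))
  rows <- lapply(labs, function(p) {
    sec <- leg_section(leg, p)
    r <- solve_equilibrium(fabrics[[p]], girth(sec), tissue = leg$tissue,
                           config = config, position = p)
    data.frame(position = p, z = sec$z, girth0 = r$girth0, girth = r$girth,
               strain = r$strain, T = r$T, P = r$P, P_mmHg = r$P_mmHg,
               w_mm = r$w * 1000, iterations = r$iterations,
               converged = r$converged, residual = r$residual)
  })
  out <- do.call(rbind, rows)
  degressive <- TRUE; pair <- NA_character_
  if (nrow(out) > 1L) {
    dP <- diff(out$P_mmHg)
    viol <- which(dP > gradient_tol)
    if (length(viol)) {
      degressive <- FALSE
      pair <- paste0(out$position[viol[1]], "<", out$position[viol[1] + 1L])
    }
  }
  structure(out, degressive = degressive, violating_pair = pair,
            class = c("pressure_profile", "data.frame"))
}

#' Classify an ankle pressure into a compression class
#'
#' Maps the ankle (B) interface pressure onto standardized medical-hosiery
#' compression bands (mmHg, boundaries inclusive). Defaults follow the
#' German RAL-GZ 387 classes.
#'
#' @param P_ankle ankle pressure (mmHg), >= 0; vectorised.
#' @param bands named list of `c(lo, hi)` mmHg bands.
#' @return character vector: `"I"`, `"II"`, `"III"`, `"IV"` or `"none"`.
#' @examples
#' classify_compression(c(18.75, 34, 10))
#' @export
classify_compression <- function(P_ankle,
                                 bands = list(I = c(18, 21), II = c(23, 32),
                                              III = c(34, 46), IV = c(49, 70))) {
  if (any(P_ankle < 0)) stop("pressure must be >= 0")
  out <- rep("none", length(P_ankle))
  for (cl in names(bands)) {
    b <- bands[[cl]]
    out[P_ankle >= b[1] & P_ankle <= b[2]] <- cl
  }
  out
}
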
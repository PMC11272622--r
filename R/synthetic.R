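# --- seeded randomness ------------------------------------------------------
# Generators draw from a single root seed fanned out by a stable string hash,
# so adding a subject or position never perturbs earlier entities, and the
# caller's RNG state is left untouched.

derive_seed <- function(root, ...) {
  key <- paste(c(..., ""), collapse = "/")
  h <- as.double(root %% 2147483647L)
  for (c in utf8ToInt(key)) h <- (h * 31 + c) %% 2147483647
  as.integer(h) + 1L
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else if (exists(".Random.seed", .GlobalEnv))
            rm(".Random.seed", envir = .GlobalEnv))
  set.seed(seed)
  expr
}

#' Synthetic cohort specification
#'
#' Describes the simulated study conditions: number of subjects, per-position
#' girth ranges, tissue-stiffness range, boundary irregularity and the
#' compression classes worn. Defaults emulate the measured study: three
#' subjects, lower-leg girths from ankle (~20-24 cm) to calf (~32-38 cm)
#' with a degressive-compatible ordering, muscle stiffness 1400-3000 Pa, and
#' both a light (I) and a strong (III) compression class per subject.
#'
#' @param n_subjects number of subjects, default 3.
#' @param seed root seed (integer).
#' @param girth_ranges named list of `c(lo, hi)` girths (m) for positions
#'   B, B1, C, D.
#' @param stiffness_range tissue Young's modulus range (Pa), default
#'   `c(1400, 3000)`; values above 1e4 Pa are flagged as non-physiological.
#' @param irregularity relative Fourier perturbation amplitude of the section
#'   boundaries, in [0, 0.3].
#' @param classes compression classes generated, subset of `c("I", "III")`.
#' @param heights named section heights (m) for B, B1, C, D.
#' @param n_points boundary samples per section.
#' @return an object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_subjects = 3, seed = 1,
                        girth_ranges = list(B = c(0.20, 0.24),
                                            B1 = c(0.24, 0.28),
                                            C = c(0.32, 0.38),
                                            D = c(0.31, 0.37)),
                        stiffness_range = c(1400, 3000),
                        irregularity = 0.1,
                        classes = c("I", "III"),
                        heights = c(B = 0, B1 = 0.08, C = 0.22, D = 0.32),
                        n_points = 192) {
  stopifnot(n_subjects >= 1, irregularity >= 0, irregularity <= 0.3,
            all(classes %in% c("I", "III")), length(classes) >= 1,
            all(unlist(girth_ranges) > 0), n_points >= 16)
  if (any(stiffness_range <= 0) || diff(stiffness_range) < 0)
    stop("stiffness_range must be positive and ordered")
  if (stiffness_range[2] > 1e4)
    warning("stiffness_range above 1e4 Pa is outside the physiological band")
  structure(list(n_subjects = n_subjects, seed = as.integer(seed),
                 girth_ranges = girth_ranges,
                 stiffness_range = stiffness_range,
                 irregularity = irregularity, classes = classes,
                 heights = heights, n_points = n_points),
            class = "cohort_spec")
}

#' Generate a synthetic leg
#'
#' Builds a four-section leg (B, B1, C, D) whose boundaries are
#' Fourier-perturbed ellipses: girths are drawn uniformly from the spec's
#' per-position ranges (rescaled exactly to the drawn target), aspect ratios
#' and harmonic perturbations are seeded per (seed, subject, position), and
#' the ankle girth must not exceed the calf girth (degressive-compatible
#' ordering).
#'
#' @param spec a [cohort_spec()].
#' @param subject_index subject number (1-based).
#' @return a rigid-geometry [leg_model()] (attach tissue with
#'   [set_leg_tissue()] for soft-leg solves).
#' @export
generate_leg <- function(spec, subject_index) {
  stopifnot(inherits(spec, "cohort_spec"), subject_index >= 1)
  positions <- names(spec$girth_ranges)
  girths <- vapply(positions, function(p) {
    with_seed(derive_seed(spec$seed, "girth", subject_index, p),
              stats::runif(1, spec$girth_ranges[[p]][1], spec$girth_ranges[[p]][2]))
  }, 0)
  if ("B" %in% positions && "C" %in% positions && girths["B"] > girths["C"])
    stop("infeasible girth ordering: ankle (B) girth exceeds calf (C) girth")
  sections <- lapply(positions, function(p) {
    s <- derive_seed(spec$seed, "shape", subject_index, p)
    with_seed(s, {
      th <- seq(0, 2 * pi, length.out = spec$n_points + 1L)[-(spec$n_points + 1L)]
      aspect <- stats::runif(1, 0.78, 0.95)
      rho <- rep(1, length(th))
      if (spec$irregularity > 0) {
        for (m in 2:5) {
          amp <- spec$irregularity / m^2
          rho <- rho + stats::runif(1, -amp, amp) * cos(m * th) +
                       stats::runif(1, -amp, amp) * sin(m * th)
        }
      }
      x <- rho * cos(th); y <- aspect * rho * sin(th)
      cs <- cross_section(x, y, z = spec$heights[[p]], label = p)
      sc <- girths[[p]] / girth(cs)        # perimeter is linear in scale
      cross_section(cs$x * sc, cs$y * sc, z = spec$heights[[p]], label = p)
    })
  })
  leg_model(sections, rigidity = "rigid")
}

#' Attach a tissue model to a leg geometry
#'
#' @param leg a [leg_model()].
#' @param tissue a [tissue_model()], or `NULL` to make the leg rigid.
#' @return the leg with `rigidity`/`tissue` updated.
#' @export
set_leg_tissue <- function(leg, tissue) {
  stopifnot(inherits(leg, "leg_model"))
  leg$tissue <- tissue
  leg$rigidity <- if (is.null(tissue)) "rigid" else "soft"
  leg
}

#' Generate a fabric specification
#'
#' Draws one compression-tube specification from the measured batch ranges
#' of each class: course modulus 0.33-0.38 MPa (class I) or 0.33-0.76 MPa
#' (class III), thickness 0.62-0.69 mm, Poisson ratio 0.19-0.25, mass
#' density 468.2-532.7 kg/m^3. When a target limb girth is given, the
#' relaxed tube radius is scaled so the wear strain falls inside the
#' working 15-80% stretch band, with per-position strain targets that
#' decrease from ankle to knee (the degressive sizing used for graduated
#' stockings).
#'
#' @param class `"I"` or `"III"`.
#' @param seed integer seed.
#' @param position position label the tube is sized for.
#' @param target_girth limb girth (m) the tube will be worn on, or `NULL`
#'   to draw the relaxed radius from the measured per-position range.
#' @param target_pressure delivered rigid-limb pressure (mmHg) the tube is
#'   sized for (requires `target_girth`); the relaxed radius then solves the
#'   closed-form Laplace pressure exactly, with the course modulus drawn so
#'   the wear strain stays at or below 0.8.
#' @return a [fabric_spec()].
#' @export
generate_fabric <- function(class = "I", seed = 1, position = "B",
                            target_girth = NULL, target_pressure = NULL) {
  if (length(class) != 1 || !class %in% c("I", "III"))
    stop("unknown compression class: ", paste(class, collapse = ","))
  position <- match.arg(position, c("B", "B1", "C", "D"))
  if (!is.null(target_pressure) && is.null(target_girth))
    stop("target_pressure sizing needs a target_girth")
  with_seed(derive_seed(seed, "fabric", class, position), {
    E_rng <- if (class == "I") c(0.33e6, 0.38e6) else c(0.33e6, 0.76e6)
    h <- stats::runif(1, 0.62e-3, 0.69e-3)
    if (!is.null(target_pressure)) {
      # modulus floor keeping the wear strain <= 0.8 at the target pressure
      E_min <- mmhg_to_pa(target_pressure) * target_girth / (2 * pi * 0.8 * h)
      if (E_min > E_rng[2])
        stop("target_pressure infeasible within the class modulus range")
      E_rng[1] <- max(E_rng[1], E_min)
    }
    E_F <- stats::runif(1, E_rng[1], E_rng[2])
    E_Fy <- stats::runif(1, 0.14e6, min(0.27e6, E_F))
    v_F <- stats::runif(1, 0.19, 0.25)
    MD <- stats::runif(1, 468.2, 532.7)
    G_F <- stats::runif(1, 0.14e6, min(0.30e6, E_F))
    L_F <- stats::runif(1, 0.055, 0.075)
    strain_band <- switch(position, B = c(0.45, 0.60), B1 = c(0.40, 0.50),
                          C = c(0.32, 0.42), D = c(0.25, 0.35))
    if (!is.null(target_pressure)) {
      # invert P = 2 pi E_F h eps / C0 for the wear strain, then size R_F
      eps <- mmhg_to_pa(target_pressure) * target_girth / (2 * pi * E_F * h)
      R_F <- target_girth / (2 * pi * (1 + eps))
    } else if (is.null(target_girth)) {
      R_F <- switch(position, B = stats::runif(1, 0.024, 0.029),
                    B1 = stats::runif(1, 0.028, 0.032),
                    C = stats::runif(1, 0.032, 0.036),
                    D = stats::runif(1, 0.032, 0.036))
    } else {
      eps <- stats::runif(1, strain_band[1], strain_band[2])
      R_F <- target_girth / (2 * pi * (1 + eps))
    }
    fabric_spec(sprintf("synthetic-%s-%s", class, position), R_F = R_F,
                L_F = L_F, h = h, MD = MD, E_F = E_F, E_Fy = E_Fy,
                v_F = v_F, G_F = G_F, compression_class = class)
  })
}

#' Simulate shear-wave elastography records
#'
#' Emulates a multi-site elastography session on tissue of true modulus
#' `E_true`: each site's apparent modulus is E_true (1 + cv z_i) with
#' standard-normal z (truncated at 5% of E_true), reported as the
#' corresponding shear-wave velocity, so `noise_cv` is the coefficient of
#' variation of the per-site modulus estimate. Averaging the records with
#' [mean_swe_modulus()] recovers `E_true` up to ~cv/sqrt(n).
#'
#' @param E_true true tissue modulus (Pa), > 0.
#' @param n_sites number of measurement sites, >= 1 (default 8: two regions
#'   by four probe directions).
#' @param noise_cv per-site coefficient of variation, >= 0.
#' @param seed integer seed.
#' @param rho_m muscle density (kg/m^3).
#' @param subject subject code carried into the records.
#' @return data frame with `subject`, `position` (alternating B/C),
#'   `velocity_m_s` and `rho_m`.
#' @export
simulate_swe <- function(E_true, n_sites = 8, noise_cv = 0.1, seed = 1,
                         rho_m = 1000, subject = "synthetic") {
  stopifnot(E_true > 0, n_sites >= 1)
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  with_seed(derive_seed(seed, "swe", subject), {
    z <- stats::rnorm(n_sites)
    E_site <- E_true * pmax(1 + noise_cv * z, 0.05)
    data.frame(subject = subject,
               position = rep_len(c("B", "C"), n_sites),
               velocity_m_s = sqrt(E_site / (3 * rho_m)),
               rho_m = rho_m)
  })
}

#' Simulate a pneumatic pressure-meter reading
#'
#' Adds the instrument's measurement error to a true pressure: uniform noise
#' over +/- `precision` mmHg (the stated meter precision; optionally
#' Gaussian with sd = precision/2), rounded to the 1 mmHg instrument
#' resolution and floored at 0.
#'
#' @param P_true true pressure(s) (mmHg), >= 0.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param noise if `FALSE`, return `P_true` unchanged.
#' @param distribution `"uniform"` (default) or `"gaussian"`.
#' @param precision meter precision (mmHg), default 3.
#' @param resolution reading resolution (mmHg), default 1.
#' @return simulated reading(s) (mmHg).
#' @examples
#' simulate_picopress(20, seed = 1)
#' @export
simulate_picopress <- function(P_true, seed = NULL, noise = TRUE,
                               distribution = c("uniform", "gaussian"),
                               precision = 3, resolution = 1) {
  distribution <- match.arg(distribution)
  if (any(P_true < 0)) stop("P_true must be >= 0")
  if (!noise) return(P_true)
  draw <- function() {
    err <- switch(distribution,
                  uniform = stats::runif(length(P_true), -precision, precision),
                  gaussian = stats::rnorm(length(P_true), 0, precision / 2))
    pmax(round((P_true + err) / resolution) * resolution, 0)
  }
  if (is.null(seed)) draw() else with_seed(derive_seed(seed, "picopress"), draw())
}

#' Generate a full synthetic cohort
#'
#' Assembles the inputs of one simulated study: per-subject legs, class- and
#' position-matched fabric tubes, elastography records for a per-subject
#' tissue stiffness drawn from the spec's range, the noiseless rigid-leg
#' pressure predictions, and noisy meter readings of them.
#'
#' @param spec a [cohort_spec()].
#' @param config a [solver_config()] used for the noiseless predictions.
#' @return list with `legs` (list of [leg_model()]), `fabrics` (SI data
#'   frame, one row per subject x class x position), `stiffness` (named Pa
#'   vector per subject), `swe` (data frame of records), and `pressures`
#'   (data frame with true and measured mmHg per subject x class x position).
#' @export
generate_cohort <- function(spec = cohort_spec(), config = solver_config()) {
  stopifnot(inherits(spec, "cohort_spec"))
  subjects <- sprintf("S%d", seq_len(spec$n_subjects))
  legs <- lapply(seq_len(spec$n_subjects), function(i) generate_leg(spec, i))
  names(legs) <- subjects
  stiffness <- vapply(seq_len(spec$n_subjects), function(i)
    with_seed(derive_seed(spec$seed, "stiffness", i),
              stats::runif(1, spec$stiffness_range[1], spec$stiffness_range[2])), 0)
  names(stiffness) <- subjects
  swe <- do.call(rbind, lapply(subjects, function(s)
    simulate_swe(stiffness[[s]], seed = spec$seed, subject = s)))
  fab_rows <- list(); press_rows <- list()
  for (i in seq_len(spec$n_subjects)) {
    g <- leg_girths(legs[[i]])
    for (cl in spec$classes) {
      # graduated sizing: a degressive rigid-limb pressure ladder per
      # subject x class (ankle target inside the class band, each step
      # 3-14% below the previous position)
      targets <- with_seed(derive_seed(spec$seed, "ladder", i, cl), {
        pk <- if (cl == "I") stats::runif(1, 18.5, 21) else stats::runif(1, 34, 42)
        cumprod(c(pk, stats::runif(length(spec$girth_ranges) - 1L, 0.86, 0.97)))
      })
      names(targets) <- names(spec$girth_ranges)
      for (p in names(spec$girth_ranges)) {
        f <- generate_fabric(cl, seed = derive_seed(spec$seed, "batch", i),
                             position = p, target_girth = g[[p]],
                             target_pressure = targets[[p]])
        fab_rows[[length(fab_rows) + 1L]] <- data.frame(
          subject = subjects[i], class = cl, position = p, R_F = f$R_F,
          L_F = f$L_F, h = f$h, MD = f$MD, E_F = f$E_F, E_Fy = f$E_Fy,
          v_F = f$v_F, G_F = f$G_F)
        r <- solve_equilibrium(f, g[[p]], tissue = NULL, config = config,
                               position = p)
        press_rows[[length(press_rows) + 1L]] <- data.frame(
          subject = subjects[i], class = cl, position = p,
          P_true_mmHg = r$P_mmHg,
          P_measured_mmHg = simulate_picopress(
            r$P_mmHg, seed = derive_seed(spec$seed, "meas", i, cl, p)))
      }
    }
  }
  list(legs = legs, fabrics = do.call(rbind, fab_rows),
       stiffness = stiffness, swe = swe,
       pressures = do.call(rbind, press_rows))
}

#' Write a synthetic cohort to CSV files
#'
#' Writes `fabrics.csv` (measured-table schema, display units), `swe.csv`,
#' `measured.csv` and one `leg_<subject>.csv` contour file per subject into
#' `dir`.
#'
#' @param cohort output of [generate_cohort()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fb <- cohort$fabrics
  out <- data.frame(subject = fb$subject, class = fb$class,
                    position = fb$position, R_F_cm = fb$R_F * 100,
                    L_F_cm = fb$L_F * 100, h_mm = fb$h * 1000,
                    MD_kg_m3 = fb$MD, E_F_MPa = fb$E_F / 1e6,
                    E_Fy_MPa = fb$E_Fy / 1e6, v_F = fb$v_F,
                    G_F_MPa = fb$G_F / 1e6)
  utils::write.csv(out, file.path(dir, "fabrics.csv"), row.names = FALSE)
  utils::write.csv(cohort$swe, file.path(dir, "swe.csv"), row.names = FALSE)
  utils::write.csv(cohort$pressures, file.path(dir, "measured.csv"),
                   row.names = FALSE)
  for (s in names(cohort$legs))
    write_leg_csv(cohort$legs[[s]], file.path(dir, paste0("leg_", s, ".csv")))
  invisible(dir)
}
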
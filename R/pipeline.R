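#' Fit the garment--leg pressure model
#'
#' Central model-fitting interface: solves the quasi-static membrane
#' equilibrium at every labelled position of a leg for the supplied fabric
#' set and returns a classed fit with the usual accessor methods
#' (`print`, `summary`, `coef`, `fitted`, `predict`, `plot`, `simulate`,
#' `residuals`).
#'
#' @param leg a [leg_model()] (attach tissue with [set_leg_tissue()] for a
#'   soft leg; rigid geometry solves the closed-form Laplace limit).
#' @param fabrics named list of [fabric_spec()] (names = positions) or an SI
#'   fabric table with a `position` column.
#' @param config a [solver_config()].
#' @param gradient_tol degressive-gradient tolerance (mmHg).
#' @return an object of class `"ct_pressure"`.
#' @examples
#' leg <- generate_leg(cohort_spec(seed = 7), 1)
#' fabs <- reference_fabrics()
#' fit <- ct_pressure(leg, fabs[fabs$subject == "S1" & fabs$class == "I", ])
#' coef(fit)
#' @export
ct_pressure <- function(leg, fabrics, config = solver_config(),
                        gradient_tol = 1) {
  prof <- pressure_gradient_profile(leg, fabrics, config = config,
                                    gradient_tol = gradient_tol)
  structure(list(results = as.data.frame(prof),
                 degressive = attr(prof, "degressive"),
                 violating_pair = attr(prof, "violating_pair"),
                 leg = leg, fabrics = fabrics, config = config,
                 call = match.call()),
            class = "ct_pressure")
}

#' @export
print.ct_pressure <- function(x, digits = 2, ...) {
  cat("Compression-garment pressure fit (", x$leg$rigidity, " leg)\n", sep = "")
  r <- x$results
  tab <- data.frame(position = r$position,
                    girth_cm = round(r$girth0 * 100, digits),
                    strain = round(r$strain, 3),
                    T_N_m = round(r$T, 1),
                    P_mmHg = round(r$P_mmHg, digits),
                    w_mm = round(r$w_mm, 3))
  print(tab, row.names = FALSE)
  cat(if (x$degressive) "Gradient: degressive (distal -> proximal)\n"
      else paste0("Gradient: NOT degressive (", x$violating_pair, ")\n"))
  invisible(x)
}

#' @export
summary.ct_pressure <- function(object, ...) {
  r <- object$results
  ankle <- r$P_mmHg[r$position == "B"]
  structure(list(fit = object,
                 n_positions = nrow(r),
                 converged = all(r$converged),
                 max_iterations = max(r$iterations),
                 ankle_P_mmHg = if (length(ankle)) ankle else NA_real_,
                 compression_class = if (length(ankle))
                   classify_compression(ankle) else NA_character_,
                 degressive = object$degressive),
            class = "summary.ct_pressure")
}

#' @export
print.summary.ct_pressure <- function(x, ...) {
  print(x$fit)
  cat(sprintf("Ankle pressure %.2f mmHg -> compression class %s\n",
              x$ankle_P_mmHg, x$compression_class))
  cat(sprintf("All positions converged: %s (max %d iterations)\n",
              x$converged, x$max_iterations))
  invisible(x)
}

#' @export
coef.ct_pressure <- function(object, units = c("mmHg", "Pa"), ...) {
  units <- match.arg(units)
  r <- object$results
  stats::setNames(if (units == "mmHg") r$P_mmHg else r$P, r$position)
}

#' @export
fitted.ct_pressure <- function(object, ...) coef(object)

#' Predict pressures for new girths or positions
#'
#' @param object a [ct_pressure()] fit.
#' @param newdata data frame with columns `position` and `girth_m`
#'   (undeformed girth); default re-solves the fitted positions.
#' @param ... unused.
#' @return data frame `position`, `girth_m`, `P_mmHg`.
#' @export
predict.ct_pressure <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    r <- object$results
    return(data.frame(position = r$position, girth_m = r$girth0,
                      P_mmHg = r$P_mmHg))
  }
  stopifnot(is.data.frame(newdata),
            all(c("position", "girth_m") %in% names(newdata)))
  fabs <- object$fabrics
  P <- vapply(seq_len(nrow(newdata)), function(i) {
    p <- newdata$position[i]
    f <- if (is.data.frame(fabs)) {
      row <- fabs[fabs$position == p, , drop = FALSE]
      if (nrow(row) == 0L) stop("no fitted fabric for position ", p)
      as_fabric_spec(row[1, , drop = FALSE])
    } else fabs[[p]]
    solve_equilibrium(f, newdata$girth_m[i], tissue = object$leg$tissue,
                      config = object$config, position = p)$P_mmHg
  }, 0)
  data.frame(position = newdata$position, girth_m = newdata$girth_m,
             P_mmHg = P)
}

#' @export
plot.ct_pressure <- function(x, ...) {
  r <- x$results
  graphics::plot(r$z * 100, r$P_mmHg, type = "b", pch = 19,
                 xlab = "height above ankle (cm)",
                 ylab = "interface pressure (mmHg)",
                 main = "Pressure gradient along the leg", ...)
  graphics::text(r$z * 100, r$P_mmHg, r$position, pos = 3)
  invisible(x)
}

#' Simulate pressure-meter readings of a fit
#'
#' @param object a [ct_pressure()] fit.
#' @param nsim number of replicate measurement sessions.
#' @param seed integer seed.
#' @param ... passed to [simulate_picopress()].
#' @return data frame, one row per position, columns `sim_1..sim_nsim`.
#' @export
simulate.ct_pressure <- function(object, nsim = 1, seed = 1, ...) {
  r <- object$results
  sims <- vapply(seq_len(nsim), function(j)
    simulate_picopress(r$P_mmHg, seed = derive_seed(seed, "fitsim", j), ...),
    numeric(nrow(r)))
  sims <- matrix(sims, nrow = nrow(r),
                 dimnames = list(r$position, paste0("sim_", seq_len(nsim))))
  cbind(data.frame(position = r$position), as.data.frame(sims))
}

#' Residuals against measured pressures
#'
#' @param object a [ct_pressure()] fit.
#' @param measured named numeric vector or data frame (`position`,
#'   `P_measured_mmHg`) of meter readings.
#' @param ... unused.
#' @return named vector measured - fitted (mmHg).
#' @export
residuals.ct_pressure <- function(object, measured, ...) {
  if (missing(measured)) stop("supply measured pressures (mmHg)")
  if (is.data.frame(measured))
    measured <- stats::setNames(measured$P_measured_mmHg, measured$position)
  f <- coef(object)
  common <- intersect(names(f), names(measured))
  if (length(common) == 0L) stop("no positions in common with the fit")
  measured[common] - f[common]
}

#' Run configuration for the end-to-end comparison pipeline
#'
#' @param cohort a [cohort_spec()].
#' @param solver a [solver_config()].
#' @param stiffness_levels tissue stiffness levels (Pa) compared on the soft
#'   legs; defaults to the three studied levels 1400/2200/3000 Pa.
#' @param rigid_modulus modulus (Pa) of the rigid mannequin arm, default
#'   3e9 (printed polymer); must be >= 1e9 so it takes the rigid path.
#' @param output_dir optional directory for [make_report()] files.
#' @param seed root seed for the measurement-noise arm.
#' @return an object of class `"run_config"`.
#' @export
run_config <- function(cohort = cohort_spec(), solver = solver_config(),
                       stiffness_levels = c(1400, 2200, 3000),
                       rigid_modulus = 3e9, output_dir = NULL, seed = 1) {
  stopifnot(length(stiffness_levels) >= 1, all(stiffness_levels > 0))
  if (rigid_modulus < 1e9)
    stop("rigid_modulus must be >= 1e9 Pa to take the rigid path")
  structure(list(cohort = cohort, solver = solver,
                 stiffness_levels = stiffness_levels,
                 rigid_modulus = rigid_modulus, output_dir = output_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' End-to-end rigid-versus-soft comparison run
#'
#' For every subject x class x position of the synthetic cohort, solves the
#' garment equilibrium on the rigid mannequin and on soft legs at each
#' configured tissue-stiffness level, computes the Hertz pressure-diversity
#' ratio from the exported displacements, simulates meter readings of the
#' rigid-leg predictions, and runs the validation statistics battery
#' (deviation ratios, normality, correlation, pairwise paired t tests
#' across stiffness levels with Bonferroni correction).
#'
#' @param cfg a [run_config()].
#' @return an object of class `"ct_report"`: list of tables `pressures`
#'   (long format), `delta_p`, `dro` and `stats`, plus `provenance`.
#' @export
run_comparison <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  cohort <- generate_cohort(cfg$cohort, config = cfg$solver)
  lv_names <- paste0("LS", seq_along(cfg$stiffness_levels))
  press <- list(); dp <- list()
  for (s in names(cohort$legs)) {
    leg <- cohort$legs[[s]]
    for (cl in cfg$cohort$classes) {
      fabs <- cohort$fabrics[cohort$fabrics$subject == s &
                             cohort$fabrics$class == cl, ]
      rigid_fit <- ct_pressure(set_leg_tissue(leg, NULL), fabs,
                               config = cfg$solver)
      rows <- rigid_fit$results
      press[[length(press) + 1L]] <- data.frame(
        subject = s, class = cl, arm = "rigid", E_leg = cfg$rigid_modulus,
        position = rows$position, P_mmHg = rows$P_mmHg,
        w_mm = rows$w_mm, converged = rows$converged,
        degressive = rigid_fit$degressive)
      for (j in seq_along(cfg$stiffness_levels)) {
        ts <- tissue_model(cfg$stiffness_levels[j])
        soft_fit <- ct_pressure(set_leg_tissue(leg, ts), fabs,
                                config = cfg$solver)
        rowsj <- soft_fit$results
        press[[length(press) + 1L]] <- data.frame(
          subject = s, class = cl, arm = lv_names[j],
          E_leg = cfg$stiffness_levels[j], position = rowsj$position,
          P_mmHg = rowsj$P_mmHg, w_mm = rowsj$w_mm,
          converged = rowsj$converged, degressive = soft_fit$degressive)
        for (p in rowsj$position) {
          rr <- solve_equilibrium(fabs[fabs$position == p, ][1, ],
                                  rows$girth0[rows$position == p],
                                  tissue = NULL, config = cfg$solver,
                                  position = p)
          rs <- solve_equilibrium(fabs[fabs$position == p, ][1, ],
                                  rowsj$girth0[rowsj$position == p],
                                  tissue = ts, config = cfg$solver,
                                  position = p)
          d <- delta_p_from_results(rr, rs)
          dp[[length(dp) + 1L]] <- data.frame(
            subject = s, class = cl, level = lv_names[j], position = p,
            w_ratio = d$w_ratio, k_ratio = d$k_ratio, delta_P = d$delta_P)
        }
      }
    }
  }
  pressures <- do.call(rbind, press)
  delta_p <- do.call(rbind, dp)

  # measurement arm: noisy readings of the rigid predictions
  meas <- cohort$pressures
  dro_tab <- data.frame(subject = meas$subject, class = meas$class,
                        position = meas$position,
                        P_sim_mmHg = meas$P_true_mmHg,
                        P_meas_mmHg = meas$P_measured_mmHg,
                        DRO_pct = dro(pmax(meas$P_measured_mmHg, 1e-9),
                                      meas$P_true_mmHg))

  # statistics battery; the stiffness comparison follows the measurement
  # design: each stiffness group reads the same (stiffness-independent)
  # delivered pressures through an independent meter, class by class
  rigid_p <- pressures[pressures$arm == "rigid", ]
  paired_t <- NULL
  if (length(lv_names) >= 2) {
    per_class <- lapply(cfg$cohort$classes, function(cl) {
      ex <- stiffness_noise_experiment(
        meas$P_true_mmHg[meas$class == cl], levels = lv_names,
        seed = derive_seed(cfg$seed, "stiffness-noise", cl))
      cbind(class = cl, ex$table)
    })
    paired_t <- do.call(rbind, per_class)
  }
  stats_list <- list(
    shapiro_rigid = shapiro_wilk(rigid_p$P_mmHg),
    pearson_sim_meas = pearson_r(dro_tab$P_sim_mmHg, dro_tab$P_meas_mmHg),
    mean_dro_pct = mean(dro_tab$DRO_pct),
    paired_t = paired_t)

  structure(list(pressures = pressures, delta_p = delta_p, dro = dro_tab,
                 stats = stats_list,
                 provenance = list(seed = cfg$cohort$seed,
                                   run_seed = cfg$seed,
                                   config_hash = config_hash(cfg),
                                   package_version =
                                     as.character(utils::packageVersion("ctpress")),
                                   r_version = R.version.string)),
            class = "ct_report")
}

# stable small hash of the deparsed configuration (provenance only)
config_hash <- function(cfg) {
  s <- paste(deparse(cfg), collapse = "")
  h <- 0
  for (c in utf8ToInt(s)) h <- (h * 131 + c) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' @export
print.ct_report <- function(x, ...) {
  cat("Rigid-vs-soft garment pressure comparison\n")
  cat(sprintf("  %d pressure rows, %d pressure-diversity rows\n",
              nrow(x$pressures), nrow(x$delta_p)))
  cat(sprintf("  mean DRO (simulated vs measured): %.2f %%\n",
              x$stats$mean_dro_pct))
  cat(sprintf("  max |deltaP - 1| over Hertz chain: %.2e\n",
              max(abs(x$delta_p$delta_P - 1))))
  if (!is.null(x$stats$paired_t)) {
    cat("  paired t (stiffness groups, Bonferroni-adjusted):\n")
    print(x$stats$paired_t, row.names = FALSE)
  } else cat("  single stiffness level: paired stiffness tests n/a\n")
  invisible(x)
}

#' Write a comparison report to disk
#'
#' Writes `pressures.csv`, `delta_p.csv`, `dro.csv`, `stats.csv` and a
#' consolidated `report.json` with bit-stable row and column ordering.
#'
#' @param report a `"ct_report"` from [run_comparison()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
make_report <- function(report, dir) {
  stopifnot(inherits(report, "ct_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ord <- function(df, cols) df[do.call(order, df[cols]), , drop = FALSE]
  pres <- ord(report$pressures, c("subject", "class", "arm", "position"))
  pres$P_mmHg <- round(pres$P_mmHg, 2)
  utils::write.csv(pres, file.path(dir, "pressures.csv"), row.names = FALSE)
  utils::write.csv(ord(report$delta_p, c("subject", "class", "level", "position")),
                   file.path(dir, "delta_p.csv"), row.names = FALSE)
  dro_t <- ord(report$dro, c("subject", "class", "position"))
  dro_t[c("P_sim_mmHg", "P_meas_mmHg", "DRO_pct")] <-
    round(dro_t[c("P_sim_mmHg", "P_meas_mmHg", "DRO_pct")], 2)
  utils::write.csv(dro_t, file.path(dir, "dro.csv"), row.names = FALSE)
  st <- report$stats
  stat_rows <- data.frame(
    statistic = c("shapiro_W", "shapiro_p", "pearson_r", "pearson_p",
                  "mean_dro_pct"),
    value = c(st$shapiro_rigid$W, st$shapiro_rigid$p,
              st$pearson_sim_meas$r, st$pearson_sim_meas$p,
              st$mean_dro_pct))
  utils::write.csv(stat_rows, file.path(dir, "stats.csv"), row.names = FALSE)
  if (!is.null(st$paired_t))
    utils::write.csv(st$paired_t, file.path(dir, "paired_t.csv"),
                     row.names = FALSE)
  jsonlite::write_json(
    list(stats = stat_rows, paired_t = st$paired_t,
         provenance = report$provenance),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(dir)
}
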
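test_that("wear strain floors at zero and matches the reference tube", {
  expect_equal(wear_strain(2 * pi * 0.03, 0.03), 0)
  expect_equal(wear_strain(0.2513, 0.0252),
               (0.2513 - 2 * pi * 0.0252) / (2 * pi * 0.0252))  # ~0.587
  expect_warning(s <- wear_strain(0.15, 0.0252), "slack")
  expect_equal(s, 0)
})

test_that("membrane tension is E_F h eps with a stretch-band warning", {
  f <- ref_fabric("S1", "I", "B")
  expect_equal(membrane_tension(0, f), 0)
  expect_equal(membrane_tension(0.43, f), 0.35e6 * 0.43 * 0.00066)  # 99.33 N/m
  expect_equal(membrane_tension(0.6, f), 2 * membrane_tension(0.3, f))
  expect_warning(membrane_tension(0.9, f), "0.8")
  expect_error(membrane_tension(-0.1, f), ">= 0")
})

test_that("Laplace pressure converts tension and curvature", {
  expect_equal(laplace_pressure(100, 0.04), 2500)
  expect_equal(pa_to_mmhg(laplace_pressure(100, 0.04)), 18.75,
               tolerance = 1e-3)
  expect_equal(laplace_pressure(0, 0.04), 0)
  expect_equal(laplace_pressure(100, 0.02), 2 * laplace_pressure(100, 0.04))
  expect_equal(laplace_pressure_girth(100, 2 * pi * 0.04),
               laplace_pressure(100, 0.04))
  expect_error(laplace_pressure(100, 0), "radius")
})

test_that("pressure profile tracks local curvature around a section", {
  circ <- circle_section(0.04, n = 360)
  pr <- local_pressure_profile(circ, 100)
  expect_equal(pr$P, rep(laplace_pressure(100, 0.04), 360), tolerance = 1e-6)
  ell <- ellipse_section(0.06, 0.04, n = 720)
  pe <- local_pressure_profile(ell, 100)
  expect_equal(max(pe$P), 100 * 0.06 / 0.04^2, tolerance = 1e-3)  # 3750 Pa
  # near-circular: arc mean consistent with T over the mean radius
  near <- ellipse_section(0.05, 0.048, n = 360)
  pn <- local_pressure_profile(near, 100)
  expect_equal(mean(pn$P), 100 / mean(pn$radius), tolerance = 0.02)
  # flat sides of a square clip to the minimum pressure T/10
  sq <- square_section(0.05)
  ps <- local_pressure_profile(sq, 100)
  expect_equal(min(ps$P), 100 / 10)
})

test_that("rigid-leg equilibrium equals the closed-form Laplace pressure", {
  f <- ref_fabric("S1", "I", "B")
  r <- solve_equilibrium(f, girth = 0.2513)
  # independent closed form: P = 2 pi E_F h (1/C_F - 1/C0)
  P_cf <- 2 * pi * f$E_F * f$h * (1 / (2 * pi * f$R_F) - 1 / 0.2513)
  expect_equal(r$P, P_cf, tolerance = 1e-9)
  expect_equal(r$P, 3391.04, tolerance = 1e-4)   # ~25.4 mmHg
  expect_equal(pa_to_mmhg(r$P), 25.44, tolerance = 1e-3)
  expect_lt(r$w, 1e-6)
  expect_true(r$converged)
})

test_that("soft-leg equilibrium matches an independent root-bracketing oracle", {
  f <- ref_fabric("S1", "I", "B")
  ts <- tissue_model(3000)
  cfg <- solver_config(patch_radius = 0.02, tol = 1e-12)
  r <- solve_equilibrium(f, girth = 0.2513, tissue = ts, config = cfg)
  expect_true(r$converged)
  expect_lt(r$P, 3391.04)
  expect_gt(r$w, 1e-3); expect_lt(r$w, 1e-2)     # low-millimetre indentation
  # oracle: solve the scalar fixed-point equation g(C) = 0 by uniroot
  C_F <- 2 * pi * f$R_F
  comp <- ts$k * pi * 0.02 / 4
  g <- function(C) {
    P <- 2 * pi * f$E_F * f$h * max((C - C_F) / C_F, 0) / C
    0.2513 - 2 * pi * comp * P - C
  }
  C_star <- uniroot(g, c(C_F, 0.2513), tol = 1e-14)$root
  P_star <- 2 * pi * f$E_F * f$h * (C_star - C_F) / C_F / C_star
  expect_equal(r$P, P_star, tolerance = 1e-9)
  expect_equal(r$girth, C_star, tolerance = 1e-9)
})

test_that("stiff soft legs converge to the rigid solution", {
  f <- ref_fabric("S1", "I", "B")
  rigid <- solve_equilibrium(f, 0.2513)
  # at/above the rigid threshold the rigid path is taken exactly
  expect_equal(solve_equilibrium(f, 0.2513, tissue_model(1e12))$P, rigid$P)
  # just below the threshold the soft path must approach it closely
  near <- solve_equilibrium(f, 0.2513, tissue_model(5e8))
  expect_equal(near$P, rigid$P, tolerance = 1e-3)
})

test_that("solver is monotone in tissue stiffness and wear strain", {
  f <- ref_fabric("S1", "I", "B")
  E <- c(1400, 2200, 3000, 1e6, 1e8)
  P <- vapply(E, function(e) solve_equilibrium(f, 0.2513, tissue_model(e))$P, 0)
  expect_true(all(diff(P) > 0))   # stiffer leg, equal or higher pressure
  g <- seq(0.20, 0.28, by = 0.02)
  Pg <- vapply(g, function(gg) solve_equilibrium(f, gg, tissue_model(2200))$P, 0)
  expect_true(all(diff(Pg) > 0))  # larger girth, larger wear strain, more P
})

test_that("fixed point converges across a seeded parameter grid", {
  set.seed(2024)
  for (i in 1:100) {
    f <- fabric_spec("grid", R_F = runif(1, 0.022, 0.036),
                     L_F = 0.06, h = runif(1, 0.62e-3, 0.69e-3),
                     MD = 480, E_F = runif(1, 0.33e6, 0.76e6),
                     E_Fy = 0.2e6, v_F = runif(1, 0.19, 0.25), G_F = 0.15e6,
                     compression_class = "I")
    ts <- tissue_model(runif(1, 1400, 3000))
    C0 <- runif(1, 2 * pi * f$R_F * 1.15, 2 * pi * f$R_F * 1.8)
    r <- solve_equilibrium(f, C0, ts)
    expect_true(r$converged)
    expect_lt(r$iterations, 200)
    expect_lt(r$residual, 1e-8)
  }
})

test_that("solver displacement chain reproduces the delta P identity", {
  f <- ref_fabric("S2", "III", "B")
  rigid <- solve_equilibrium(f, 0.26)
  for (E in c(1400, 2200, 3000)) {
    soft <- solve_equilibrium(f, 0.26, tissue_model(E))
    dp <- delta_p_from_results(rigid, soft)
    expect_equal(dp$delta_P, 1, tolerance = 1e-9)
  }
})

test_that("a matched Winkler bed reproduces the Hertz foundation", {
  f <- ref_fabric("S1", "I", "B")
  ts <- tissue_model(2200)
  hz <- solve_equilibrium(f, 0.2513, ts,
                          solver_config(foundation = "hertz"))
  kw <- 4 / (ts$k * pi * 0.02)   # spring stiffness equal to the Hertz patch
  wk <- solve_equilibrium(f, 0.2513, ts,
                          solver_config(foundation = "winkler",
                                        winkler_modulus = kw))
  expect_equal(wk$P, hz$P, tolerance = 1e-9)
  expect_error(solver_config(foundation = "winkler"), "winkler_modulus")
})

test_that("slack garments deliver zero pressure", {
  f <- ref_fabric("S1", "I", "B")
  expect_warning(r <- solve_equilibrium(f, girth = 0.10), "slack")
  expect_equal(r$P, 0)
  expect_true(r$converged)
})

test_that("per-position profile flags degressive gradients", {
  fabs <- reference_fabrics()
  s1 <- fabs[fabs$subject == "S1" & fabs$class == "I", ]
  leg <- frustum_leg()
  prof <- pressure_gradient_profile(leg, s1)
  expect_equal(prof$position, c("B", "B1", "C", "D"))
  expect_true(attr(prof, "degressive"))
  # two positions still flagged from their single comparison
  leg2 <- leg_model(list(circle_section(0.22 / (2 * pi), z = 0, label = "B"),
                         circle_section(0.335 / (2 * pi), z = 0.3, label = "D")),
                    rigidity = "rigid")
  prof1 <- pressure_gradient_profile(leg2, s1)
  expect_true(attr(prof1, "degressive"))
  # oversized distal tube: ankle pressure collapses, flag names the pair
  over <- s1
  over$R_F[over$position == "B"] <- 0.034
  prof2 <- pressure_gradient_profile(frustum_leg(), over)
  expect_false(attr(prof2, "degressive"))
  expect_equal(attr(prof2, "violating_pair"), "B<B1")
  expect_error(pressure_gradient_profile(frustum_leg(), s1[s1$position != "C", ]),
               "position C")
})

test_that("ankle pressures map onto compression classes", {
  expect_equal(classify_compression(c(18.75, 34, 10, 46, 22)),
               c("I", "III", "none", "III", "none"))
  expect_equal(classify_compression(21), "I")    # boundaries inclusive
  expect_error(classify_compression(-1), ">= 0")
})
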
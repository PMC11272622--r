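test_that("generated legs are deterministic, simple and girth-ordered", {
  spec <- cohort_spec(seed = 5)
  leg1 <- generate_leg(spec, 1)
  leg2 <- generate_leg(spec, 1)
  expect_identical(leg1, leg2)                       # same (seed, index)
  g <- leg_girths(leg1)
  expect_lte(g[["B"]], g[["C"]])
  rng <- spec$girth_ranges
  for (p in names(rng)) {
    expect_gte(g[[p]], rng[[p]][1]); expect_lte(g[[p]], rng[[p]][2])
  }
  # generating another subject does not perturb the first
  invisible(generate_leg(spec, 2))
  expect_identical(generate_leg(spec, 1), leg1)
  # every generated boundary passes the simplicity check in the constructor
  for (i in 1:20) {
    leg <- generate_leg(cohort_spec(seed = i, irregularity = 0.3), 1)
    for (s in leg$sections)
      expect_true(ctpress:::is_simple_polygon(s$x, s$y))
  }
})

test_that("zero irregularity gives pure ellipses at the requested girth", {
  spec <- cohort_spec(seed = 9, irregularity = 0)
  leg <- generate_leg(spec, 1)
  s <- leg$sections[[1]]
  # an origin-centred ellipse satisfies (x/a)^2 + (y/b)^2 = 1
  a <- max(s$x); b <- max(s$y)
  expect_equal((s$x / a)^2 + (s$y / b)^2, rep(1, length(s$x)), tolerance = 1e-9)
})

test_that("fabric draws stay inside the measured batch ranges", {
  EF_I <- vapply(1:200, function(i) generate_fabric("I", seed = i)$E_F, 0)
  expect_true(all(EF_I >= 0.33e6 & EF_I <= 0.38e6))
  f <- generate_fabric("I", seed = 3)
  expect_true(f$h >= 0.62e-3 && f$h <= 0.69e-3)
  expect_true(f$v_F >= 0.19 && f$v_F <= 0.25)
  expect_true(f$MD >= 468.2 && f$MD <= 532.7)
  expect_identical(generate_fabric("I", seed = 3), f)  # reproducible
  # class III modulus distribution reaches above the class-I upper bound
  EF_III <- vapply(1:200, function(i) generate_fabric("III", seed = i)$E_F, 0)
  expect_true(all(EF_III >= 0.33e6 & EF_III <= 0.76e6))
  expect_gt(max(EF_III), 0.38e6)
  expect_gt(mean(EF_III), mean(EF_I))
  expect_error(generate_fabric("II"), "unknown compression class")
})

test_that("girth-targeted sizing keeps the wear strain in the stretch band", {
  for (i in 1:25) {
    f <- generate_fabric("I", seed = i, position = "C", target_girth = 0.35)
    eps <- wear_strain(0.35, f$R_F)
    expect_gte(eps, 0.15); expect_lte(eps, 0.8)
  }
})

test_that("pressure-targeted sizing reproduces the target on a rigid limb", {
  for (i in 1:25) {
    f <- generate_fabric("III", seed = i, position = "B",
                         target_girth = 0.22, target_pressure = 38)
    r <- solve_equilibrium(f, 0.22)
    expect_equal(r$P_mmHg, 38, tolerance = 1e-9)
    expect_lte(wear_strain(0.22, f$R_F), 0.8)
  }
  expect_error(generate_fabric("I", seed = 1, target_girth = 0.3,
                               target_pressure = 60), "infeasible")
})

test_that("elastography simulation recovers the true modulus", {
  exact <- simulate_swe(2976, n_sites = 6, noise_cv = 0, seed = 1)
  expect_equal(mean_swe_modulus(exact), 2976, tolerance = 1e-12)
  expect_equal(nrow(exact), 6)
  # velocities sit near the deterministic value sqrt(E/3rho)
  r <- simulate_swe(2040, n_sites = 8, noise_cv = 0.1, seed = 4)
  expect_true(all(abs(r$velocity_m_s - 0.8246) < 0.25))
  # Monte-Carlo recovery at the reference calf stiffness
  errs <- vapply(1:100, function(s) {
    rec <- simulate_swe(2976, n_sites = 8, noise_cv = 0.1, seed = s)
    abs(mean_swe_modulus(rec) - 2976) / 2976
  }, 0)
  expect_lt(mean(errs), 0.05)
  expect_gt(mean(errs < 3 * 0.1 / sqrt(8)), 0.95)
  expect_error(simulate_swe(2976, noise_cv = -0.1), "noise_cv")
})

test_that("pressure-meter simulation respects precision, floor and rounding", {
  expect_identical(simulate_picopress(20.4, noise = FALSE), 20.4)
  x <- simulate_picopress(rep(20, 1e4), seed = 1)
  expect_true(all(x >= 17 & x <= 23))
  expect_equal(mean(x), 20, tolerance = 0.1 / 20)
  expect_true(all(x == round(x)))
  expect_true(all(simulate_picopress(rep(0, 100), seed = 2) >= 0))
  g <- simulate_picopress(rep(20, 1e3), seed = 3, distribution = "gaussian")
  expect_equal(mean(g), 20, tolerance = 0.02)
})

test_that("cohort generation is deterministic and degressive by design", {
  co <- generate_cohort(cohort_spec(seed = 21))
  co2 <- generate_cohort(cohort_spec(seed = 21))
  expect_identical(co$pressures, co2$pressures)
  expect_equal(nrow(co$pressures), 3 * 2 * 4)
  expect_equal(nrow(co$fabrics), 24)
  # rigid-limb (delivered) pressures decrease distal -> proximal
  for (s in unique(co$pressures$subject)) for (cl in c("I", "III")) {
    p <- co$pressures[co$pressures$subject == s & co$pressures$class == cl, ]
    p <- p[match(c("B", "B1", "C", "D"), p$position), ]
    expect_true(all(diff(p$P_true_mmHg) < 0))
  }
  # ankle targets fall into their nominal class bands
  ankle <- co$pressures[co$pressures$position == "B", ]
  expect_true(all(classify_compression(
    ankle$P_true_mmHg[ankle$class == "I"]) == "I"))
  expect_true(all(classify_compression(
    ankle$P_true_mmHg[ankle$class == "III"]) == "III"))
})

test_that("cohort files round-trip through the CSV readers", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(cohort_spec(seed = 2, n_subjects = 2))
  write_cohort(co, dir)
  fabs <- read_fabric_csv(file.path(dir, "fabrics.csv"))
  expect_equal(nrow(fabs), nrow(co$fabrics))
  expect_equal(fabs$E_F, co$fabrics$E_F, tolerance = 1e-9)
  swe <- read_swe_csv(file.path(dir, "swe.csv"))
  expect_equal(mean_swe_modulus(swe[swe$subject == "S1", ]),
               mean_swe_modulus(co$swe[co$swe$subject == "S1", ]),
               tolerance = 1e-9)
  leg <- read_leg_csv(file.path(dir, "leg_S1.csv"))
  expect_equal(leg_girths(leg), leg_girths(co$legs$S1), tolerance = 1e-9)
})
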
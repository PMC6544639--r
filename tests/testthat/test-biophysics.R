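# Closed-form membrane and cortex models.

test_that("charging time follows the RC form and an independent hand calculation", {
  # symmetric conductivities collapse to 2 R C_m / lambda
  expect_equal(charging_time(10e-6, 0.01, 0.05, 0.05), 2 * 10e-6 * 0.01 / 0.05)
  # linear in R
  expect_equal(charging_time(20e-6, 0.01, 0.05, 0.1),
               2 * charging_time(10e-6, 0.01, 0.05, 0.1))
  # long-hand arithmetic oracle: R C_m (1/le + 1/li) term by term
  R <- 10e-6; Cm <- 0.01; le <- 0.05; li <- 0.05
  expect_equal(charging_time(R, Cm, le, li), 10e-6 * 0.01 * (20 + 20),
               tolerance = 1e-12)
  expect_error(charging_time(-1e-6, 0.01, 0.05, 0.05), "> 0")
})

test_that("transmembrane voltage has the right limits and a consistent inverse", {
  R <- 5e-6; E <- 100e3
  tc <- charging_time(R, 0.01, 0.05, 0.05)
  expect_equal(transmembrane_voltage(R, E, 0, tc), 0)
  expect_equal(transmembrane_voltage(R, E, 1e6 * tc, tc), 1.5 * R * E)
  # inverse round trip at finite t
  t <- 500e-6
  psi <- transmembrane_voltage(R, E, t, tc)
  expect_equal(field_for_voltage(psi, R, t, tc), E, tolerance = 1e-10)
  # saturated inverse: 1 V on a 5 um vesicle needs ~133 V/mm
  E133 <- field_for_voltage(1, 5e-6, 1, 1e-7)
  expect_equal(E133 / 1e3, 1 / (1.5 * 5e-6) / 1e3, tolerance = 1e-10)
  expect_equal(E133 / 1e3, 133.3, tolerance = 0.001)
})

test_that("pore relaxation time scales linearly in r and inversely in gamma", {
  t0 <- pore_relaxation_time(1e-6, 1e-6, 20e-12)
  expect_equal(pore_relaxation_time(1e-6, 2e-6, 20e-12), 2 * t0)
  expect_equal(pore_relaxation_time(1e-6, 1e-6, 40e-12), t0 / 2)
  # the observed ~1 ms macropore relaxation is reached for plausible
  # membrane parameters (eta_s ~ 4e-8 N s/m, r ~ 1 um, gamma ~ 20 pN)
  expect_equal(pore_relaxation_time(4e-8, 1e-6, 20e-12), 1e-3,
               tolerance = 0.01)
})

test_that("filament count reproduces the stated estimate and its scalings", {
  Nf <- filament_count(4.2e21, 10e-6, 2.5e-9, 4e-6)
  # order of magnitude 1e4
  expect_gt(Nf, 1e4 / 3); expect_lt(Nf, 3e4)
  # independent long-hand arithmetic
  expect_equal(Nf, 4.2e21 * (4 / 3) * pi * 1e-15 * 2.5e-9 / 4e-6,
               tolerance = 1e-12)
  expect_equal(filament_count(4.2e21, 10e-6, 2.5e-9, 2e-6), 2 * Nf,
               tolerance = 1e-12)
})

test_that("volume-conserving spheroid axes", {
  ax <- spheroid_axes(10e-6, 1)
  expect_equal(ax$a, 10e-6); expect_equal(ax$b, 10e-6)
  ax <- spheroid_axes(10e-6, 1.18)
  expect_equal(ax$a / ax$b, 1.18, tolerance = 1e-12)
  expect_equal(ax$a * ax$b^2, (10e-6)^3, tolerance = 1e-12)
  expect_equal(ax$a * 1e6, 11.17, tolerance = 1e-3)
  expect_equal(ax$b * 1e6, 9.463, tolerance = 1e-3)
  # e and 1/e swap prolate/oblate with conserved volume
  ax2 <- spheroid_axes(10e-6, 1 / 1.18)
  expect_lt(ax2$a, ax2$b)
  expect_equal(ax2$a * ax2$b^2, (10e-6)^3, tolerance = 1e-12)
})

test_that("spheroid surface area matches a numerical surface-integral oracle", {
  # independent oracle: revolve the meridian, integrate numerically
  area_num <- function(a, b)
    stats::integrate(function(th) 2 * pi * b * sin(th) *
                       sqrt((a * sin(th))^2 + (b * cos(th))^2),
                     0, pi, rel.tol = 1e-12)$value
  expect_equal(spheroid_surface_area(5, 5), 4 * pi * 25)
  for (e in c(0.5, 0.8, 0.999, 1.001, 1.18, 2)) {
    ax <- spheroid_axes(7.3, e)
    expect_equal(spheroid_surface_area(ax$a, ax$b), area_num(ax$a, ax$b),
                 tolerance = 1e-8)
  }
  # equal-volume spheroid never beats the sphere (isoperimetric property)
  for (e in seq(0.5, 2, by = 0.1)) {
    ax <- spheroid_axes(10, e)
    A <- spheroid_surface_area(ax$a, ax$b)
    if (abs(e - 1) < 1e-12) expect_equal(A, 4 * pi * 100)
    else expect_gt(A, 4 * pi * 100)
  }
})

test_that("volume conservation and area inequality hold across the parameter box", {
  set.seed(42)
  for (i in 1:60) {
    R <- runif(1, 1, 20) * 1e-6
    e <- runif(1, 0.5, 2)
    ax <- spheroid_axes(R, e)
    expect_equal(ax$a * ax$b^2 / R^3, 1, tolerance = 1e-12)
    expect_gte(spheroid_surface_area(ax$a, ax$b) * (1 + 1e-12), 4 * pi * R^2)
  }
})

test_that("mesh stretch reproduces the ~0.8 nm worked value and is monotone in e", {
  Nf <- filament_count(4.2e21, 10e-6, 2.5e-9, 4e-6)
  m <- mesh_stretch(10e-6, 1, Nf)
  expect_equal(m$delta_zeta, 0)
  m <- mesh_stretch(10e-6, 1.18, Nf)
  expect_equal(m$delta_zeta * 1e9, 0.8, tolerance = 0.1 / 0.8)
  dz <- vapply(seq(1.05, 1.5, by = 0.05),
               function(e) mesh_stretch(10e-6, e, Nf)$delta_zeta, numeric(1))
  expect_true(all(diff(dz) > 0))
})

test_that("mechanical and electrophoretic forces match the worked example", {
  expect_equal(mechanical_force(0, 48), 0)
  expect_equal(mechanical_force(2e-9, 0.048), 2 * mechanical_force(1e-9, 0.048))
  Nf <- filament_count(4.2e21, 10e-6, 2.5e-9, 4e-6)
  dz <- mesh_stretch(10e-6, 1.18, Nf)$delta_zeta
  fm <- mechanical_force(dz, 48e-12 / 1e-9)
  expect_equal(fm * 1e12, 34, tolerance = 0.2)      # tens of pN
  expect_lt(fm, 100e-12)                            # below the rupture range
  expect_equal(electrophoretic_force(0.034, 1e-8, 0, 0.8, 4e-6), 0)
  fep <- electrophoretic_force(0.034, 1e-8, 150e3, 0.8, 4e-6)
  expect_equal(fep * 1e12, 160, tolerance = 0.1)
  expect_equal(electrophoretic_force(0.034, 1e-8, 150e3, 1, 4e-6) / fep, 1.25,
               tolerance = 1e-12)
})

test_that("force report is internally consistent and verdicts match the numbers", {
  rep <- force_report(R_um = 10, e = 1.18)
  # recompute every field independently
  ctx <- rep$cortex
  expect_equal(rep$N_f, filament_count(ctx$c0, 10e-6, ctx$d, ctx$l))
  m <- mesh_stretch(10e-6, 1.18, rep$N_f)
  expect_equal(rep$delta_zeta, m$delta_zeta)
  expect_equal(rep$f_m, ctx$k_stretch * m$delta_zeta)
  expect_equal(rep$f_electrophoretic,
               ctx$xi_h * ctx$mu_B * 0.8 * 150e3 * ctx$l)
  expect_gt(rep$f_electrophoretic, rep$f_m)
  expect_match(rep$verdict_mechanical, "below")
  expect_match(rep$verdict_electrophoretic, "within|above")
  # unporated membrane: the field does not reach the filaments
  rep0 <- force_report(R_um = 10, e = 1.18, porated = FALSE)
  expect_equal(rep0$f_electrophoretic, 0)
  expect_gt(rep0$f_m, 0)
})

test_that("convenience-unit interface round-trips V/mm and um losslessly", {
  p <- pulse_params(E_V_per_mm = 150)
  expect_equal(p$E, 150e3, tolerance = 1e-12)
  expect_equal(p$E_V_per_mm, p$E / 1e3, tolerance = 1e-12)
  rep <- force_report(R_um = 12.5)
  expect_equal(rep$R * 1e6, 12.5, tolerance = 1e-12)
})
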
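# Relaxation fits, poration calls and dye-uptake kinetics.

test_that("noiseless single-exponential relaxation is recovered to high precision", {
  sc <- deformation_scenario(ab_max = 1.15, tau_list = list(c(1, 1e-4)),
                             duration_s = 4e-3, noise_sigma = 0, seed = 1)
  tr <- generate_deformation_trace(sc, optics_params(frame_rate = 15000))
  f <- fit_relaxation(tr, model = "auto")
  expect_equal(f$model, "single")
  expect_equal(f$taus[1], 1e-4, tolerance = 0.01)
})

test_that("joint double-exponential fits separate millisecond-scale relaxations", {
  errs <- sapply(1:20, function(s) {
    sc <- deformation_scenario(ab_max = 1.2,
                               tau_list = list(c(1, 1e-3), c(0.5, 1e-2)),
                               duration_s = 0.1, noise_sigma = 0.01, seed = s)
    tr <- generate_deformation_trace(sc, optics_params(frame_rate = 10000))
    f <- fit_relaxation(tr, model = "double")
    expect_lt(f$taus[1], f$taus[2])
    c(f$taus[1] / 1e-3 - 1, f$taus[2] / 1e-2 - 1)
  })
  expect_lt(abs(stats::median(errs[1, ])), 0.15)
  expect_lt(abs(stats::median(errs[2, ])), 0.15)
})

test_that("relaxation fitting rejects unusable inputs", {
  flat <- new_trace <- data.frame(time_s = seq(0, 0.01, 1e-4), ratio = 1)
  attr(flat, "pulse_end_s") <- 7e-4
  class(flat) <- c("deformation_trace", "data.frame")
  expect_error(fit_relaxation(flat, pulse_end = 7e-4), "constant")
  short <- data.frame(time_s = seq(0, 8e-4, 1e-4), ratio = runif(9, 1, 1.1))
  expect_error(fit_relaxation(short, pulse_end = 0), ">= 10 samples")
  tr <- generate_deformation_trace(quick_deformation())
  expect_error(fit_relaxation(unclass_trace <- {
    attr(tr, "pulse_end_s") <- NULL; tr
  }), "pulse_end")
})

test_that("model selection does not over-fit single-exponential data", {
  picks <- vapply(1:20, function(s) {
    sc <- deformation_scenario(ab_max = 1.2, tau_list = list(c(1, 2e-3)),
                               duration_s = 0.03, noise_sigma = 0.01, seed = s)
    tr <- generate_deformation_trace(sc, optics_params(frame_rate = 10000))
    fit_relaxation(tr, model = "auto")$model
  }, character(1))
  expect_true(all(picks == "single"))
})

test_that("fitted time constants rescale exactly with the time unit", {
  sc <- quick_deformation(noise = 0.005, seed = 9)
  tr <- generate_deformation_trace(sc, optics_params(frame_rate = 10000))
  f1 <- fit_relaxation(tr, model = "single")
  tr_ms <- tr
  tr_ms$time_s <- tr$time_s * 1e3           # relabel seconds as milliseconds
  attr(tr_ms, "pulse_end_s") <- attr(tr, "pulse_end_s") * 1e3
  f2 <- fit_relaxation(tr_ms, model = "single")
  expect_equal(f2$taus, f1$taus * 1e3, tolerance = 1e-6)
})

test_that("fit accuracy improves as noise shrinks", {
  err_at <- function(sigma) {
    errs <- vapply(1:10, function(s) {
      sc <- quick_deformation(noise = sigma, seed = s)
      tr <- generate_deformation_trace(sc, optics_params(frame_rate = 10000))
      abs(fit_relaxation(tr, model = "single")$taus[1] / 1e-3 - 1)
    }, numeric(1))
    stats::median(errs)
  }
  e <- vapply(c(0.02, 0.01, 0.005), err_at, numeric(1))
  expect_true(all(diff(e) <= 1e-3))   # monotone to within jitter
  expect_lt(e[3], 0.01)
})

test_that("maximum deformation picks the excursion farthest from unity", {
  mk <- function(ratio) {
    df <- data.frame(time_s = seq_along(ratio) * 1e-4, ratio = ratio)
    class(df) <- c("deformation_trace", "data.frame")
    df
  }
  m <- max_deformation(mk(c(1, 1.1, 1.18, 1.05)))
  expect_equal(m$ab_max, 1.18)
  expect_equal(m$shape, "tubelike")
  m <- max_deformation(mk(c(1, 0.95, 0.9, 0.97)))
  expect_equal(m$ab_max, 0.9)
  expect_equal(m$shape, "disklike")
  # flat trace: tubelike by the documented tie-break
  m <- max_deformation(mk(rep(1, 10)))
  expect_equal(m$ab_max, 1)
  expect_equal(m$shape, "tubelike")
})

test_that("poration classification follows the evidence hierarchy", {
  pore_run <- c(rep(FALSE, 3), rep(TRUE, 4), rep(FALSE, 3))
  contrast <- rep(0.25, 10)
  expect_equal(classify_poration(pore_flags = pore_run,
                                 interior_contrast = contrast)$label,
               "macropore")
  # 30% contrast decay without pore evidence
  decay <- 0.25 * seq(1, 0.7, length.out = 10)
  expect_equal(classify_poration(pore_flags = rep(FALSE, 10),
                                 interior_contrast = decay)$label,
               "contrast_loss")
  expect_equal(classify_poration(pore_flags = rep(FALSE, 10),
                                 interior_contrast = contrast)$label,
               "non_porated")
  # short pore blips below k consecutive frames do not count
  blip <- rep(c(TRUE, FALSE), 5)
  expect_equal(classify_poration(pore_flags = blip,
                                 interior_contrast = contrast)$label,
               "non_porated")
})

test_that("generator-driven poration scenarios classify correctly end-to-end", {
  run <- function(porated) {
    sc <- deformation_scenario(ab_max = 1.2, tau_list = list(c(1, 1e-3)),
                               duration_s = 4e-3, porated = porated,
                               pore_max_radius_um = 1.2,
                               pore_lifetime_s = 2.5e-3, noise_sigma = 0,
                               seed = 3)
    o <- optics_params(noise_sigma = 0.03, edge_blur_sigma = 1, seed = 4,
                       contrast_half_life = 1e-3)
    seq_ <- render_sequence(generate_deformation_trace(
      sc, optics_params(frame_rate = 10000)), o, every = 3)
    tr <- track_sequence(seq_, params = track_params(closing_radius = 5))
    classify_poration(tr, k_consecutive = 2)$label
  }
  expect_equal(run("macropore"), "macropore")
  expect_equal(run("contrast_loss"), "contrast_loss")
  expect_equal(run("none"), "non_porated")
})

test_that("uptake normalization applies the printed ratio exactly", {
  inner <- c(0.10, 0.12, 0.15, 0.18)
  bg <- rep(0.50, 4)
  tr <- normalize_uptake(inner, bg)
  expect_equal(tr$intensity, (inner - 0.10) / (bg - 0.10))
  # inner stuck at the pre-pulse value: zeros
  expect_equal(normalize_uptake(rep(0.1, 5), rep(0.5, 5))$intensity, rep(0, 5))
  # full equilibration: inner equals background -> 1
  eq <- normalize_uptake(c(0.1, 0.5), c(0.5, 0.5))
  expect_equal(eq$intensity[2], 1)
  expect_error(normalize_uptake(c(0.1, 0.2), c(0.1, 0.5)), "sample 1")
})

test_that("uptake fitting recovers noiseless parameters to numerical precision", {
  tr <- generate_uptake_trace(uptake_scenario(I_inf = 0.38, tau_uptake_s = 146,
                                              noise_sigma = 0))
  f <- fit_uptake(tr)
  expect_equal(f$I_inf, 0.38, tolerance = 1e-6)
  expect_equal(f$tau_s, 146, tolerance = 1e-6)
  expect_false(f$non_uptake)
})

test_that("a decaying trace is fitted and flagged as non-uptake", {
  t <- seq(0, 200, by = 1 / 1.5)
  tr <- structure(data.frame(time_s = t,
                             intensity = 0.1 + 0.3 * exp(-t / 50)),
                  class = c("intensity_trace", "data.frame"))
  f <- fit_uptake(tr)
  expect_true(f$non_uptake)
  expect_lt(f$I_inf, f$I0)
})
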
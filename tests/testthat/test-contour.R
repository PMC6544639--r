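# Edge detection, contour extraction and ellipse fitting.

test_that("Canny on an ideal step-edge ellipse yields one closed thin curve", {
  # a pure interior/exterior step (membrane level set to the mid grey makes
  # the additive rim vanish)
  o <- optics_params(noise_sigma = 0, edge_blur_sigma = 1,
                     membrane_level = (0.70 + 0.45) / 2)
  img <- render_frame(6, 5, o)
  e <- detect_edges(img)
  lab <- guvepore:::label8(e)
  expect_equal(max(lab), 1)
  # the curve is closed: filling its hull grows the area substantially
  filled <- EBImage::fillHull(matrix(as.numeric(e), nrow(e)))
  expect_gt(sum(filled > 0), 3 * sum(e))
  # and approximately one pixel wide: count ~ perimeter
  per <- pi * (3 * (20 + 50 / 3) - sqrt((3 * 20 + 50 / 3) * (20 + 3 * 50 / 3)))
  expect_lt(abs(sum(e) - per) / per, 0.2)
})

test_that("edge detection flags blank frames instead of erroring", {
  e <- detect_edges(matrix(0.5, 64, 64))
  expect_true(attr(e, "empty"))
  expect_equal(sum(e), 0)
})

test_that("noisy frames still yield a closed component covering the vesicle", {
  img <- render_frame(6, 5, quick_optics(seed = 3))
  e <- detect_edges(img)
  ct <- extract_contour(e)
  expect_false(ct$flag)
  # the filled component encloses at least 90% of the true ellipse area
  true_area_px <- pi * (6 / 0.3) * (5 / 0.3)
  expect_gt(sum(ct$mask), 0.9 * true_area_px)
})

test_that("contour extraction bridges macropore gaps and picks the outer vesicle", {
  # macropore arc of 0.5 rad closes with a 5 px closing radius
  img <- render_frame(6, 5, quick_optics(seed = 5), pore_angle_width = 0.5)
  ct <- extract_contour(detect_edges(img), closing_radius = 5)
  expect_false(ct$flag)
  # two concentric rings: the larger-area (outer) one is selected
  em <- matrix(FALSE, 96, 96)
  for (r in c(12, 25)) {
    phi <- seq(0, 2 * pi, length.out = 720)
    em[cbind(round(48 + r * sin(phi)) + 1, round(48 + r * cos(phi)) + 1)] <- TRUE
  }
  ct2 <- extract_contour(em, closing_radius = 1)
  expect_false(ct2$flag)
  rad <- sqrt((ct2$points[, 1] - 48)^2 + (ct2$points[, 2] - 48)^2)
  expect_gt(stats::median(rad), 20)
  # ordered boundary point count tracks the perimeter
  expect_gt(nrow(ct2$points), 0.9 * 2 * pi * 25)
})

test_that("direct ellipse fit recovers exact points to numerical precision", {
  pts <- ellipse_points(100, 40, 45, 20, 50 / 3)
  f <- fit_ellipse(pts, pixel_size_um = 0.3)
  expect_equal(f$a_px, 20, tolerance = 1e-6)
  expect_equal(f$b_px, 50 / 3, tolerance = 1e-6)
  expect_equal(f$center_px, c(40, 45), tolerance = 1e-6)
  expect_equal(f$a_um, 6, tolerance = 1e-6)
  expect_lt(f$rms_residual_px, 1e-6)
  # circle: unit ratio, orientation reported as 0 by convention
  fc <- fit_ellipse(ellipse_points(60, 30, 30, 15, 15))
  expect_equal(fc$a_px / fc$b_px, 1, tolerance = 1e-9)
  expect_equal(fc$orientation, 0)
})

test_that("ellipse fit is robust to point jitter at the subpixel level", {
  set.seed(7)
  errs <- replicate(500, {
    pts <- ellipse_points(100, 40, 45, 20, 50 / 3)
    pts <- pts + matrix(rnorm(200, 0, 0.3), ncol = 2)
    f <- fit_ellipse(pts)
    f$a_px / f$b_px / (20 / (50 / 3)) - 1
  })
  # 0.3 px jitter on a 20 px axis: the ratio is recovered to ~1% (a few
  # tail draws reach ~1.5%)
  expect_lt(stats::quantile(abs(errs), 0.95), 0.01)
  expect_lt(max(abs(errs)), 0.02)
  expect_lt(abs(mean(errs)), 0.002)
})

test_that("degenerate inputs are rejected with clear errors", {
  expect_error(fit_ellipse(ellipse_points(5, 0, 0, 10, 8)), "at least 6")
  line <- cbind(1:20, 2 * (1:20) + 3)
  expect_error(fit_ellipse(line), "degenerate|collinear")
  # a line pair (the degenerate hyperbola-like conic) has no ellipse solution
  pair <- rbind(cbind(seq(0, 10, length.out = 15), 1),
                cbind(seq(0, 10, length.out = 15), -1))
  expect_error(fit_ellipse(pair), "ellipse|degenerate|hyperbola|collinear")
})

test_that("axis labels follow the field axis, not the magnitude", {
  # disklike: semi-axis along x smaller than along y
  pts <- ellipse_points(80, 50, 50, 12, 18)
  f <- fit_ellipse(pts)
  expect_lt(f$a_px, f$b_px)     # a stays the field-axis label
  expect_equal(f$a_px, 12, tolerance = 1e-6)
  # rotated 90 degrees the labels swap exactly
  pts90 <- cbind(50 - (pts[, 2] - 50), 50 + (pts[, 1] - 50))
  f90 <- fit_ellipse(pts90)
  expect_equal(f90$a_px, f$b_px, tolerance = 1e-6)
  expect_equal(f90$b_px, f$a_px, tolerance = 1e-6)
})

test_that("rotating a frame by 90 degrees swaps the tracked axes", {
  img <- render_frame(6, 4.5, quick_optics(seed = 8))
  f <- guvepore:::track_frame(img, 0.3)$fit
  f90 <- guvepore:::track_frame(t(img)[, ], 0.3)$fit  # transpose = reflect+rotate
  expect_equal(f90$a_um, f$b_um, tolerance = 0.01)
  expect_equal(f90$b_um, f$a_um, tolerance = 0.01)
})

test_that("physical axes are unchanged when the pixel size doubles", {
  o1 <- optics_params(noise_sigma = 0, edge_blur_sigma = 1, pixel_size_um = 0.3)
  o2 <- optics_params(noise_sigma = 0, edge_blur_sigma = 1, pixel_size_um = 0.6,
                      image_size = c(96, 96))
  f1 <- guvepore:::track_frame(render_frame(6, 5, o1), 0.3)$fit
  f2 <- guvepore:::track_frame(render_frame(6, 5, o2), 0.6)$fit
  expect_equal(f2$a_px, f1$a_px / 2, tolerance = 0.05)
  expect_equal(f1$a_um, 6, tolerance = 0.02)
  expect_equal(f2$a_um, 6, tolerance = 0.02)
})

test_that("constrained conic fit agrees with brute-force geometric minimization", {
  # independent oracle on a small instance: grid search over ellipse
  # parameters minimizing the summed geometric distance
  pts <- ellipse_points(24, 30, 32, 14, 10)
  set.seed(3)
  pts <- pts + matrix(rnorm(48, 0, 0.2), ncol = 2)
  f <- fit_ellipse(pts)
  geo_cost <- function(cx, cy, a, b) {
    phi <- seq(0, 2 * pi, length.out = 360)
    ex <- cx + a * cos(phi); ey <- cy + b * sin(phi)
    sum(apply(pts, 1, function(p) min((p[1] - ex)^2 + (p[2] - ey)^2)))
  }
  res <- 0.1
  grid <- expand.grid(cx = seq(29.7, 30.3, res), cy = seq(31.7, 32.3, res),
                      a = seq(13.7, 14.3, res), b = seq(9.7, 10.3, res))
  costs <- mapply(geo_cost, grid$cx, grid$cy, grid$a, grid$b)
  best <- grid[which.min(costs), ]
  expect_lt(abs(f$center_px[1] - best$cx), res + 1e-9)
  expect_lt(abs(f$center_px[2] - best$cy), res + 1e-9)
  expect_lt(abs(f$a_px - best$a), res + 1e-9)
  expect_lt(abs(f$b_px - best$b), res + 1e-9)
})

test_that("inner region mean excludes the rim and scales monotonically", {
  o <- optics_params(noise_sigma = 0, edge_blur_sigma = 1)
  img <- render_frame(6, 5, o)
  fit <- truth_fit(6, 5)
  # uniform interior: the 80% inner mean returns the interior level
  expect_equal(inner_region_mean(img, fit, 0.8), o$interior_level,
               tolerance = 0.02)
  # with a dark rim, including the rim pulls the mean down
  expect_lt(inner_region_mean(img, fit, 1), inner_region_mean(img, fit, 0.8))
  # a uniform patch returns its value exactly
  expect_equal(inner_region_mean(matrix(0.5, 96, 96), fit, 0.8), 0.5)
  tiny <- truth_fit(0.2, 0.2)
  expect_error(inner_region_mean(img, tiny, 0.8), "3 px")
})

test_that("pore arcs are detected on the fitted boundary", {
  flags <- vapply(1:6, function(s) {
    img <- render_frame(5.5, 5, quick_optics(seed = s), pore_angle_width = 0.4)
    guvepore:::track_frame(img, 0.3, track_params(closing_radius = 5))$pore
  }, logical(1))
  expect_gte(sum(flags), 5)
  no_pore <- vapply(1:6, function(s) {
    img <- render_frame(5.5, 5, quick_optics(seed = s))
    guvepore:::track_frame(img, 0.3)$pore
  }, logical(1))
  expect_equal(sum(no_pore), 0)
})
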
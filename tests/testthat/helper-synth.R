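# Shared fixtures: small, fast synthetic inputs built in code.

quick_optics <- function(...) {
  optics_params(noise_sigma = 0.05, edge_blur_sigma = 1, ...)
}

# standard high-speed deformation scenario at a given noise level
quick_deformation <- function(noise = 0, seed = 1L, taus = list(c(1, 1e-3)),
                              duration = 0.02, ab_max = 1.2) {
  deformation_scenario(ab_max = ab_max, tau_list = taus,
                       duration_s = duration, noise_sigma = noise,
                       seed = seed)
}

# an exact ellipse fit object, for exercising downstream code without a fit
truth_fit <- function(a_um, b_um, pixel_size_um = 0.3,
                      center = c(47.5, 47.5)) {
  structure(list(center_px = center, a_px = a_um / pixel_size_um,
                 b_px = b_um / pixel_size_um, orientation = 0,
                 rms_residual_px = 0, n_points = 0L,
                 a_um = a_um, b_um = b_um, pixel_size_um = pixel_size_um),
            class = "ellipse_fit")
}

# exact points on an ellipse (0-based pixel coordinates)
ellipse_points <- function(n, cx, cy, a, b, theta = 0) {
  phi <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  x0 <- a * cos(phi); y0 <- b * sin(phi)
  cbind(cx + cos(theta) * x0 - sin(theta) * y0,
        cy + sin(theta) * x0 + cos(theta) * y0)
}
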
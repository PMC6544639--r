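# Synthetic-data generators: scenario constructors and numeric traces.
# Frames are rendered separately (render.R); everything here is seeded and
# deterministic so downstream fits can be benchmarked against known truth.

# Run code with a private, seed-initialized RNG stream, restoring the
# caller's RNG state afterwards (generator determinism must not depend on,
# or perturb, the global stream).
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Imaging (optics) parameters for synthetic frames
#'
#' Describes the rendered appearance of a GUV cross-section: a bright-field
#' style image with distinct interior/exterior grey levels (the sucrose /
#' glucose refractive-index contrast) and a membrane rim. Defaults match a
#' high-speed bright-field setup: 0.3 um pixels at 10,000 frames per second.
#'
#' @param pixel_size_um pixel size (um/px).
#' @param frame_rate frames per second.
#' @param image_size integer vector (nx, ny) in pixels.
#' @param interior_level,exterior_level,membrane_level grey levels in [0, 1].
#' @param rim_sigma_px Gaussian half-width of the membrane rim profile (px).
#' @param edge_blur_sigma optical blur applied to the ideal image (px).
#' @param noise_sigma additive Gaussian pixel noise (grey levels).
#' @param contrast_half_life half-life (s) of the interior/exterior contrast
#'   after permeabilization (`Inf` = no contrast loss).
#' @param seed integer seed for pixel noise.
#' @return list of class `optics_params`.
#' @export
optics_params <- function(pixel_size_um = 0.3, frame_rate = 10000,
                          image_size = c(96, 96),
                          interior_level = 0.70, exterior_level = 0.45,
                          membrane_level = 0.15, rim_sigma_px = 0.8,
                          edge_blur_sigma = 1, noise_sigma = 0.02,
                          contrast_half_life = Inf, seed = 1L) {
  stopifnot(pixel_size_um > 0, frame_rate > 0, length(image_size) == 2,
            all(image_size >= 16), noise_sigma >= 0, rim_sigma_px > 0,
            edge_blur_sigma >= 0, contrast_half_life > 0)
  lv <- c(interior_level, exterior_level, membrane_level)
  if (any(lv < 0) || any(lv > 1)) stop("optics_params: levels must be in [0, 1]")
  structure(list(pixel_size_um = pixel_size_um, frame_rate = frame_rate,
                 image_size = as.integer(image_size),
                 interior_level = interior_level,
                 exterior_level = exterior_level,
                 membrane_level = membrane_level, rim_sigma_px = rim_sigma_px,
                 edge_blur_sigma = edge_blur_sigma, noise_sigma = noise_sigma,
                 contrast_half_life = contrast_half_life,
                 seed = as.integer(seed)),
            class = "optics_params")
}

#' Deformation scenario for a pulsed GUV
#'
#' Ground truth for a deformation-ratio time series: the vesicle rests at
#' a/b = 1, deforms toward `ab_max` during a square pulse (saturating
#' exponential rise with the membrane charging time as its timescale), and
#' relaxes back as a sum of exponentials `1 + sum A_i exp(-(t - t_end)/tau_i)`
#' so that a/b -> 1. `tau_list` supplies `(weight, tau)` pairs; weights are
#' normalized and scaled so the amplitudes sum to the deformation remaining
#' at the end of the pulse.
#'
#' @param R0_um equivalent sphere radius (um).
#' @param ab_max peak deformation ratio; > 1 tubelike (prolate along the
#'   field), < 1 disklike (oblate).
#' @param pulse_start_s,pulse_duration_s pulse timing (s); 500 us default
#'   duration.
#' @param duration_s total trace duration (s).
#' @param tau_list list of `c(weight, tau_s)` pairs for the post-pulse
#'   relaxation.
#' @param rise_tau_s timescale of the during-pulse rise (s); default is the
#'   membrane charging time for R0 with C_m = 0.01 F/m^2 and 0.05 S/m
#'   conductivities.
#' @param porated one of "none", "macropore", "contrast_loss".
#' @param pore_max_radius_um,pore_lifetime_s macropore geometry and lifetime
#'   (used when rendering frames and for pore flags).
#' @param noise_sigma additive Gaussian noise on the a/b samples.
#' @param seed integer seed.
#' @return list of class `deformation_scenario`.
#' @export
deformation_scenario <- function(R0_um = 5, ab_max = 1.2,
                                 pulse_start_s = 2e-4,
                                 pulse_duration_s = 500e-6,
                                 duration_s = 0.02,
                                 tau_list = list(c(1, 1e-3)),
                                 rise_tau_s = NULL,
                                 porated = c("none", "macropore", "contrast_loss"),
                                 pore_max_radius_um = 1.5,
                                 pore_lifetime_s = 1e-3,
                                 noise_sigma = 0, seed = 1L) {
  porated <- match.arg(porated)
  stopifnot(R0_um > 0, ab_max > 0, pulse_start_s >= 0, pulse_duration_s > 0,
            duration_s > pulse_start_s + pulse_duration_s, noise_sigma >= 0,
            length(tau_list) >= 1)
  for (wt in tau_list)
    if (length(wt) != 2 || wt[1] <= 0 || wt[2] <= 0)
      stop("deformation_scenario: tau_list entries must be positive (weight, tau) pairs")
  if (is.null(rise_tau_s))
    rise_tau_s <- charging_time(R0_um * 1e-6, 0.01, 0.05, 0.05)
  structure(list(R0_um = R0_um, ab_max = ab_max,
                 shape = if (ab_max >= 1) "tubelike" else "disklike",
                 pulse_start_s = pulse_start_s,
                 pulse_duration_s = pulse_duration_s, duration_s = duration_s,
                 tau_list = tau_list, rise_tau_s = rise_tau_s,
                 porated = porated, pore_max_radius_um = pore_max_radius_um,
                 pore_lifetime_s = pore_lifetime_s, noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "deformation_scenario")
}

#' Dye-uptake scenario
#'
#' Ground truth for a normalized dye-uptake trace following the saturating
#' exponential `I(t) = I_inf + (I0 - I_inf) * exp(-t / tau_uptake)`, sampled
#' at `sample_rate` with additive Gaussian noise.
#'
#' @param I_inf asymptotic normalized intensity in [0, 1].
#' @param tau_uptake_s characteristic uptake time (s).
#' @param I0 initial normalized intensity (default 0).
#' @param duration_s trace duration (s).
#' @param sample_rate samples per second (confocal default 1.5 Hz).
#' @param noise_sigma additive Gaussian noise.
#' @param seed integer seed.
#' @return list of class `uptake_scenario`.
#' @export
uptake_scenario <- function(I_inf = 0.38, tau_uptake_s = 146, I0 = 0,
                            duration_s = 600, sample_rate = 1.5,
                            noise_sigma = 0.02, seed = 1L) {
  stopifnot(I0 >= 0, I0 <= I_inf, I_inf <= 1, tau_uptake_s > 0,
            duration_s > 0, sample_rate > 0, noise_sigma >= 0)
  structure(list(I_inf = I_inf, tau_uptake_s = tau_uptake_s, I0 = I0,
                 duration_s = duration_s, sample_rate = sample_rate,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "uptake_scenario")
}

#' Pulse-series scenario (area loss, actin loss, photobleaching)
#'
#' Ground truth for a consecutive-pulse experiment: per-pulse projected-area
#' ratio following a decreasing sigmoid of field strength, per-pulse actin
#' intensity retention following its own sigmoid, multiplicative
#' photobleaching per confocal scan, and a paired no-pulse bleaching
#' reference.
#'
#' @param fields_Vmm field strength per pulse (V/mm), e.g. a 10-300 ramp.
#' @param shrink_midpoint,shrink_steepness sigmoid parameters of the
#'   per-pulse area ratio A_f/A_i vs field (midpoint in V/mm, steepness in
#'   mm/V).
#' @param shrink_floor minimum per-pulse area ratio at high field.
#' @param actin_drop_midpoint,actin_drop_steepness sigmoid parameters of the
#'   per-pulse actin retention vs field; default midpoint 150 V/mm.
#' @param actin_floor minimum per-pulse actin retention.
#' @param bleach_per_scan fractional intensity loss per scan in [0, 1).
#' @param R0_um vesicle radius setting the initial projected area (um).
#' @param n_planes number of confocal z-planes reported per scan.
#' @param noise_sigma relative Gaussian noise on areas and intensities.
#' @param seed integer seed.
#' @return list of class `pulse_series_scenario`.
#' @export
pulse_series_scenario <- function(fields_Vmm = seq(10, 300, by = 10),
                                  shrink_midpoint = 200,
                                  shrink_steepness = 0.05,
                                  shrink_floor = 0.85,
                                  actin_drop_midpoint = 150,
                                  actin_drop_steepness = 0.06,
                                  actin_floor = 0.6,
                                  bleach_per_scan = 0.02,
                                  R0_um = 10, n_planes = 7,
                                  noise_sigma = 0, seed = 1L) {
  stopifnot(all(fields_Vmm >= 0), shrink_floor > 0, shrink_floor <= 1,
            actin_floor > 0, actin_floor <= 1,
            bleach_per_scan >= 0, bleach_per_scan < 1,
            shrink_steepness > 0, actin_drop_steepness > 0,
            R0_um > 0, n_planes >= 1, noise_sigma >= 0)
  structure(list(fields_Vmm = fields_Vmm, shrink_midpoint = shrink_midpoint,
                 shrink_steepness = shrink_steepness,
                 shrink_floor = shrink_floor,
                 actin_drop_midpoint = actin_drop_midpoint,
                 actin_drop_steepness = actin_drop_steepness,
                 actin_floor = actin_floor, bleach_per_scan = bleach_per_scan,
                 R0_um = R0_um, n_planes = as.integer(n_planes),
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "pulse_series_scenario")
}

# True deformation ratio at times t for a scenario (noiseless closed form).
deformation_ratio_truth <- function(scenario, t) {
  s <- scenario
  t_on <- s$pulse_start_s
  t_end <- s$pulse_start_s + s$pulse_duration_s
  dev_max <- s$ab_max - 1
  ratio <- rep(1, length(t))
  during <- t >= t_on & t < t_end
  ratio[during] <- 1 + dev_max * (1 - exp(-(t[during] - t_on) / s$rise_tau_s))
  dev_end <- dev_max * (1 - exp(-s$pulse_duration_s / s$rise_tau_s))
  w <- vapply(s$tau_list, `[`, numeric(1), 1)
  taus <- vapply(s$tau_list, `[`, numeric(1), 2)
  amps <- dev_end * w / sum(w)
  after <- which(t >= t_end)
  for (i in after) {
    dt <- t[i] - t_end
    ratio[i] <- 1 + sum(amps * exp(-dt / taus))
  }
  ratio
}

#' Generate a synthetic deformation-ratio time series
#'
#' Samples the scenario's closed-form a/b trajectory at the optics frame
#' rate, adds Gaussian noise, and derives the volume-conserving spheroid
#' semi-axes `a = e^(2/3) R0`, `b = e^(-1/3) R0` for each frame.
#'
#' @param scenario a [deformation_scenario()].
#' @param optics an [optics_params()]; supplies the frame rate.
#' @return a `deformation_trace` data frame with columns `time_s`, `a_um`,
#'   `b_um`, `ratio`, `area_um2` (projected, pi*a*b), `flag`, plus
#'   attributes `pulse_start_s`, `pulse_end_s`, `scenario`.
#' @export
generate_deformation_trace <- function(scenario,
                                       optics = optics_params(frame_rate = 10000)) {
  stopifnot(inherits(scenario, "deformation_scenario"),
            inherits(optics, "optics_params"))
  dt <- 1 / optics$frame_rate
  taus <- vapply(scenario$tau_list, `[`, numeric(1), 2)
  if (dt > min(taus))
    stop(sprintf(paste0("generate_deformation_trace: sampling interval %.3g s is ",
                        "too coarse for the smallest relaxation time %.3g s ",
                        "(need dt <= tau)"), dt, min(taus)))
  t <- seq(0, scenario$duration_s, by = dt)
  ratio <- deformation_ratio_truth(scenario, t)
  if (scenario$noise_sigma > 0)
    ratio <- with_seed(scenario$seed,
                       ratio + stats::rnorm(length(ratio), 0, scenario$noise_sigma))
  ratio <- pmax(ratio, 1e-3)
  ax <- spheroid_axes(scenario$R0_um, ratio)
  new_deformation_trace(
    data.frame(time_s = t, a_um = ax$a, b_um = ax$b, ratio = ratio,
               area_um2 = pi * ax$a * ax$b, flag = FALSE),
    pulse_start_s = scenario$pulse_start_s,
    pulse_end_s = scenario$pulse_start_s + scenario$pulse_duration_s,
    scenario = scenario)
}

new_deformation_trace <- function(df, pulse_start_s = NA_real_,
                                  pulse_end_s = NA_real_, scenario = NULL) {
  stopifnot(all(c("time_s", "a_um", "b_um", "ratio") %in% names(df)))
  attr(df, "pulse_start_s") <- pulse_start_s
  attr(df, "pulse_end_s") <- pulse_end_s
  if (!is.null(scenario)) attr(df, "scenario") <- scenario
  class(df) <- c("deformation_trace", "data.frame")
  df
}

#' Generate a synthetic dye-uptake trace
#'
#' Samples `I(t) = I_inf + (I0 - I_inf) exp(-t / tau_uptake)` at the scenario
#' sample rate and adds i.i.d. Gaussian noise; deterministic given the seed.
#'
#' @param scenario an [uptake_scenario()].
#' @return data frame (`intensity_trace`) with `time_s`, `intensity`;
#'   attribute `scenario` holds the generative truth.
#' @export
generate_uptake_trace <- function(scenario) {
  stopifnot(inherits(scenario, "uptake_scenario"))
  s <- scenario
  t <- seq(0, s$duration_s, by = 1 / s$sample_rate)
  I <- s$I_inf + (s$I0 - s$I_inf) * exp(-t / s$tau_uptake_s)
  if (s$noise_sigma > 0)
    I <- with_seed(s$seed, I + stats::rnorm(length(I), 0, s$noise_sigma))
  structure(data.frame(time_s = t, intensity = I),
            scenario = s, class = c("intensity_trace", "data.frame"))
}

# Decreasing retention sigmoid used for per-pulse area and actin loss:
# `floor` at high field, midpoint/steepness as given, normalized so a
# zero-field pulse causes exactly no loss.
retention_sigmoid <- function(E, midpoint, steepness, floor) {
  raw <- function(x) floor + (1 - floor) / (1 + exp(steepness * (x - midpoint)))
  raw(E) / raw(0)
}

#' Generate a synthetic consecutive-pulse series
#'
#' Produces per-pulse pre/post projected areas (cumulative shrinkage with a
#' sigmoidal field dependence), per-scan actin intensities combining
#' pulse-induced sigmoidal loss with multiplicative photobleaching
#' `(1 - bleach_per_scan)^k`, per-plane z-stack intensities, and a paired
#' no-pulse reference series containing bleaching only.
#'
#' @param scenario a [pulse_series_scenario()].
#' @return list of class `pulse_series` with data frames `pulses`
#'   (`pulse_index`, `field_Vmm`, `A_i_um2`, `A_f_um2`), `actin` (`scan_k`,
#'   `I_k`, `plane_1` ... columns), and `reference` (`scan_k`, `I_k`);
#'   attribute `scenario` holds the truth.
#' @export
generate_pulse_series <- function(scenario) {
  stopifnot(inherits(scenario, "pulse_series_scenario"))
  s <- scenario
  n <- length(s$fields_Vmm)
  with_seed(s$seed, {
    A0 <- pi * s$R0_um^2
    ratio_true <- retention_sigmoid(s$fields_Vmm, s$shrink_midpoint,
                                    s$shrink_steepness, s$shrink_floor)
    A_i <- A_f <- numeric(n)
    A_prev <- A0
    for (i in seq_len(n)) {
      A_i[i] <- A_prev * noisy1(s$noise_sigma)
      A_f[i] <- A_prev * ratio_true[i] * noisy1(s$noise_sigma)
      A_prev <- A_prev * ratio_true[i]
    }
    # scan k = 0 is the pre-pulse baseline; scan k follows pulse k
    ret <- retention_sigmoid(s$fields_Vmm, s$actin_drop_midpoint,
                             s$actin_drop_steepness, s$actin_floor)
    I0 <- 1
    pulse_loss <- c(1, cumprod(ret))
    k <- 0:n
    bleach <- (1 - s$bleach_per_scan)^k
    I_k <- I0 * pulse_loss * bleach * noisy1(s$noise_sigma, n + 1)
    # z-planes: symmetric chord-length weighting across the vesicle, scaled
    # so the plane mean equals I_k
    prof <- sqrt(1 - (seq(-0.8, 0.8, length.out = s$n_planes))^2)
    prof <- prof / mean(prof)
    planes <- outer(I_k, prof)
    colnames(planes) <- paste0("plane_", seq_len(s$n_planes))
    I_ref <- I0 * bleach * noisy1(s$noise_sigma, n + 1)
    actin <- data.frame(scan_k = k, I_k = I_k)
    actin <- cbind(actin, as.data.frame(planes))
    structure(list(
      pulses = data.frame(pulse_index = seq_len(n), field_Vmm = s$fields_Vmm,
                          A_i_um2 = A_i, A_f_um2 = A_f),
      actin = actin,
      reference = data.frame(scan_k = k, I_k = I_ref)
    ), scenario = s, ratio_true = ratio_true, class = "pulse_series")
  })
}

# multiplicative noise factor(s): 1 + N(0, sigma)
noisy1 <- function(sigma, n = 1) {
  if (sigma <= 0) rep(1, n) else 1 + stats::rnorm(n, 0, sigma)
}
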
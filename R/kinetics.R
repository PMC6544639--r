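# Kinetics: post-pulse relaxation fits of a/b, maximum-deformation and
# poration calls, and dye-uptake (resealing) kinetics.

# small-sample-corrected information criterion for a least-squares fit
aicc_ls <- function(rss, n, k) {
  if (n - k - 1 <= 0) return(Inf)
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# single-exponential decay fit of y = 1 + A * exp(-s / tau), s = t - t0,
# multi-start over log-spaced tau guesses
fit_single_exp <- function(s, y, baseline = 1) {
  dev0 <- y[1] - baseline
  span <- max(s[length(s)], .Machine$double.eps)
  taus0 <- exp(seq(log(max(diff(s)[1], span * 1e-3)), log(span), length.out = 8))
  best <- NULL
  for (tau0 in taus0) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ baseline + A * exp(-s / tau),
                        start = list(A = dev0, tau = tau0),
                        lower = c(A = -Inf, tau = span * 1e-6),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(coef = stats::coef(fit), rss = rss)
  }
  best
}

# joint double-exponential fit y = 1 + A1 exp(-s/tau_f) + A2 exp(-s/tau_s)
fit_double_exp <- function(s, y, baseline = 1) {
  dev0 <- y[1] - baseline
  span <- max(s[length(s)], .Machine$double.eps)
  dt <- max(diff(s)[1], span * 1e-4)
  tau_grid <- exp(seq(log(dt * 2), log(span), length.out = 6))
  pairs <- expand.grid(tf = tau_grid, ts = tau_grid)
  pairs <- pairs[pairs$ts > 3 * pairs$tf, , drop = FALSE]
  best <- NULL
  for (i in seq_len(nrow(pairs))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ baseline + A1 * exp(-s / t1) + A2 * exp(-s / t2),
                        start = list(A1 = dev0 * 0.6, A2 = dev0 * 0.4,
                                     t1 = pairs$tf[i], t2 = pairs$ts[i]),
                        lower = c(A1 = -Inf, A2 = -Inf,
                                  t1 = dt / 10, t2 = dt / 10),
                        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(coef = stats::coef(fit), rss = rss)
  }
  if (!is.null(best)) {
    # order so tau_fast < tau_slow
    cf <- best$coef
    if (cf[["t1"]] > cf[["t2"]])
      best$coef <- c(A1 = cf[["A2"]], A2 = cf[["A1"]],
                     t1 = cf[["t2"]], t2 = cf[["t1"]])
  }
  best
}

#' Fit the post-pulse relaxation of the deformation ratio
#'
#' Nonlinear least-squares fit of `a/b(t) = 1 + A1 exp(-(t - t0)/tau)` (single)
#' or `1 + A1 exp(-(t - t0)/tau_fast) + A2 exp(-(t - t0)/tau_slow)` (double)
#' to the trace restricted to `t >= pulse_end`, with multi-start
#' initialization from log-spaced time-constant guesses. With
#' `model = "auto"` the double model is selected only when it improves the
#' small-sample-corrected information criterion by more than `margin`.
#'
#' @param trace a `deformation_trace`.
#' @param pulse_end fit-window start (s); defaults to the trace's
#'   `pulse_end_s` attribute (pulse end comes from metadata, never inferred).
#' @param model "single", "double" or "auto".
#' @param baseline fixed asymptote of the ratio (default 1; the ratio is
#'   self-normalized).
#' @param margin information-criterion margin for "auto" selection.
#' @return object of class `relaxation_fit`: `model`, `taus` (s, ascending;
#'   length 1 or 2), `amplitudes`, `baseline`, `window`, `rss`, `aicc`
#'   (named for both candidate models under "auto"), `n`.
#' @export
fit_relaxation <- function(trace, pulse_end = NULL,
                           model = c("auto", "single", "double"),
                           baseline = 1, margin = 2) {
  model <- match.arg(model)
  stopifnot(is.data.frame(trace), all(c("time_s", "ratio") %in% names(trace)))
  if (is.null(pulse_end)) pulse_end <- attr(trace, "pulse_end_s")
  if (is.null(pulse_end) || is.na(pulse_end))
    stop("fit_relaxation: pulse_end must be supplied (or present as trace metadata)")
  sel <- trace$time_s >= pulse_end & !is.na(trace$ratio)
  s <- trace$time_s[sel] - pulse_end
  y <- trace$ratio[sel]
  if (length(s) < 10) stop("fit_relaxation: need >= 10 samples after pulse_end")
  if (stats::sd(y) < 1e-12) stop("fit_relaxation: ratio is constant after the pulse")

  fits <- list()
  if (model %in% c("auto", "single")) fits$single <- fit_single_exp(s, y, baseline)
  if (model %in% c("auto", "double")) fits$double <- fit_double_exp(s, y, baseline)
  for (m in names(fits)) if (is.null(fits[[m]]))
    stop(sprintf("fit_relaxation: %s-exponential fit failed to converge", m))
  n <- length(s)
  aicc <- c(single = if (!is.null(fits$single)) aicc_ls(fits$single$rss, n, 2) else NA,
            double = if (!is.null(fits$double)) aicc_ls(fits$double$rss, n, 4) else NA)
  # "auto" takes the double model only when it earns its extra parameters
  # AND the two fitted time constants are genuinely separated (a ratio
  # below 2 is spurious splitting of a single exponential)
  sep_ok <- !is.null(fits$double) && {
    cf <- fits$double$coef
    max(cf[["t1"]], cf[["t2"]]) / min(cf[["t1"]], cf[["t2"]]) >= 2
  }
  chosen <- switch(model,
    single = "single",
    double = "double",
    auto = if (!is.na(aicc["double"]) && sep_ok &&
               aicc["single"] - aicc["double"] > margin) "double" else "single")
  cf <- fits[[chosen]]$coef
  if (chosen == "single") {
    taus <- unname(cf[["tau"]]); amps <- unname(cf[["A"]])
  } else {
    taus <- unname(c(cf[["t1"]], cf[["t2"]])); amps <- unname(c(cf[["A1"]], cf[["A2"]]))
  }
  structure(list(model = chosen, taus = taus, amplitudes = amps,
                 baseline = baseline,
                 window = c(pulse_end, max(trace$time_s)),
                 rss = fits[[chosen]]$rss, aicc = aicc[!is.na(aicc)], n = n),
            class = "relaxation_fit")
}

#' @export
print.relaxation_fit <- function(x, ...) {
  cat(sprintf("%s-exponential relaxation fit (n = %d)\n", x$model, x$n))
  lab <- if (x$model == "single") "tau" else c("tau_fast", "tau_slow")
  for (i in seq_along(x$taus))
    cat(sprintf("  %s = %.4g s (amplitude %.4g)\n", lab[i], x$taus[i],
                x$amplitudes[i]))
  invisible(x)
}

#' Maximum deformation of a trace
#'
#' The extremal a/b during the pulse window: the excursion farthest from 1.
#' Tubelike when the upward excursion dominates, disklike otherwise; a flat
#' trace is tubelike by the documented tie-break.
#'
#' @param trace a `deformation_trace`.
#' @param window optional c(start, end) in seconds; defaults to the trace's
#'   pulse window when present, otherwise the full trace.
#' @return list with `ab_max` and `shape` ("tubelike" or "disklike").
#' @export
max_deformation <- function(trace, window = NULL) {
  stopifnot(is.data.frame(trace), nrow(trace) >= 1)
  if (is.null(window)) {
    ps <- attr(trace, "pulse_start_s"); pe <- attr(trace, "pulse_end_s")
    window <- if (!is.null(ps) && !is.na(ps) && !is.null(pe) && !is.na(pe))
      c(ps, pe) else range(trace$time_s)
  }
  sel <- trace$time_s >= window[1] & trace$time_s <= window[2] & !is.na(trace$ratio)
  if (!any(sel)) sel <- !is.na(trace$ratio)   # sparse sampling: whole trace
  if (!any(sel)) stop("max_deformation: no usable samples")
  r <- trace$ratio[sel]
  up <- max(r - 1); down <- max(1 - r)
  if (up >= down) list(ab_max = 1 + up, shape = "tubelike")
  else list(ab_max = 1 - down, shape = "disklike")
}

#' Classify the poration state of a vesicle
#'
#' A vesicle is called `macropore` when pore evidence is present in at least
#' `k_consecutive` consecutive frames, otherwise `contrast_loss` when the
#' relative interior-contrast drop over the observation window exceeds
#' `contrast_drop`, otherwise `non_porated`.
#'
#' @param trace optional `deformation_trace` (used for `ab_max` reporting).
#' @param pore_flags logical vector of per-frame pore evidence (defaults to
#'   the trace's `pore` column).
#' @param interior_contrast numeric series of interior/background contrast
#'   per frame (defaults to `abs(inner_mean - bg_mean)` from the trace).
#' @param k_consecutive frames of pore evidence required for a macropore
#'   call.
#' @param contrast_drop relative contrast-drop threshold (default 0.1).
#' @return object of class `poration_call`: `label`, `evidence`, `ab_max`.
#' @export
classify_poration <- function(trace = NULL, pore_flags = NULL,
                              interior_contrast = NULL, k_consecutive = 3,
                              contrast_drop = 0.1) {
  if (is.null(pore_flags) && !is.null(trace) && "pore" %in% names(trace))
    pore_flags <- trace$pore
  if (is.null(interior_contrast) && !is.null(trace) &&
      all(c("inner_mean", "bg_mean") %in% names(trace)))
    interior_contrast <- abs(trace$inner_mean - trace$bg_mean)
  if (is.null(pore_flags) && is.null(interior_contrast))
    stop("classify_poration: need pore_flags and/or interior_contrast")
  n_run <- 0L
  if (!is.null(pore_flags) && any(pore_flags, na.rm = TRUE)) {
    r <- rle(ifelse(is.na(pore_flags), FALSE, pore_flags))
    n_run <- max(r$lengths[r$values], 0L)
  }
  label <- "non_porated"; evidence <- "no pore, no contrast loss"
  if (n_run >= k_consecutive) {
    label <- "macropore"
    evidence <- sprintf("pore observed in %d consecutive frames", n_run)
  } else if (!is.null(interior_contrast)) {
    ic <- interior_contrast[!is.na(interior_contrast)]
    if (length(ic) >= 2 && ic[1] > 0) {
      drop <- (ic[1] - min(ic)) / ic[1]
      if (drop >= contrast_drop) {
        label <- "contrast_loss"
        evidence <- sprintf("interior contrast dropped by %.0f%%", 100 * drop)
      }
    }
  }
  ab <- if (!is.null(trace)) tryCatch(max_deformation(trace)$ab_max,
                                      error = function(e) NA_real_) else NA_real_
  structure(list(label = label, evidence = evidence, ab_max = ab),
            class = "poration_call")
}

#' Normalize an interior dye-intensity series
#'
#' Applies `I_uptake(t) = (I_dye(t) - I_dye0) / (I_background(t) - I_dye0)`,
#' with `I_dye0` the pre-pulse interior intensity (the first sample unless
#' given).
#'
#' @param inner interior intensity series.
#' @param background background intensity series, aligned with `inner`.
#' @param I_dye0 pre-pulse interior intensity; defaults to `inner[1]`.
#' @param times optional time stamps (s) carried into the output.
#' @return data frame (`intensity_trace`) with `time_s` and `intensity`.
#' @export
normalize_uptake <- function(inner, background, I_dye0 = inner[1],
                             times = NULL) {
  stopifnot(length(inner) == length(background))
  denom <- background - I_dye0
  bad <- which(abs(denom) < .Machine$double.eps^0.5)
  if (length(bad) > 0)
    stop(sprintf("normalize_uptake: background equals I_dye0 at sample %d",
                 bad[1]))
  if (is.null(times)) times <- seq_along(inner) - 1
  structure(data.frame(time_s = times, intensity = (inner - I_dye0) / denom),
            class = c("intensity_trace", "data.frame"))
}

#' Fit saturating-exponential dye-uptake kinetics
#'
#' Least-squares fit of `I(t) = I_inf + (I0 - I_inf) exp(-t / tau)` to a
#' normalized uptake trace. Initialization: `I_inf` from the last-decile
#' mean, `tau` from a log-linear regression of `I_inf - I`, with a
#' log-spaced multi-start fallback.
#'
#' @param trace data frame with `time_s` and `intensity` (e.g. from
#'   [generate_uptake_trace()] or [normalize_uptake()]).
#' @return object of class `uptake_fit`: `I_inf`, `I0`, `tau_s`, standard
#'   errors (`se`, when available), `rss`, `n`, `non_uptake` (TRUE when the
#'   fitted intensity decreases, `I_inf < I0`).
#' @export
fit_uptake <- function(trace) {
  stopifnot(is.data.frame(trace), all(c("time_s", "intensity") %in% names(trace)))
  t <- trace$time_s; I <- trace$intensity
  ok <- !is.na(t) & !is.na(I)
  t <- t[ok]; I <- I[ok]
  n <- length(t)
  if (n < 10) stop("fit_uptake: need >= 10 samples")
  span <- max(t) - min(t)
  Iinf0 <- mean(I[t >= stats::quantile(t, 0.9)])
  I00 <- I[1]
  # log-linear tau guess from the early part of the decay toward I_inf
  resid0 <- Iinf0 - I
  pos <- which(resid0 > max(abs(resid0)) * 0.05)
  tau0 <- if (length(pos) >= 3) {
    sl <- stats::coef(stats::lm(log(resid0[pos]) ~ t[pos]))[2]
    if (is.finite(sl) && sl < 0) -1 / sl else span / 3
  } else span / 3
  starts <- unique(c(tau0, span / 10, span / 3, span))
  best <- NULL
  for (tg in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(I ~ I_inf + (I0 - I_inf) * exp(-t / tau),
                        start = list(I_inf = Iinf0, I0 = I00, tau = tg),
                        lower = c(I_inf = -Inf, I0 = -Inf, tau = span * 1e-6),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("fit_uptake: fit failed to converge from all starts")
  cf <- stats::coef(best$fit)
  se <- tryCatch(sqrt(diag(stats::vcov(best$fit))), error = function(e) NULL)
  structure(list(I_inf = unname(cf[["I_inf"]]), I0 = unname(cf[["I0"]]),
                 tau_s = unname(cf[["tau"]]), se = se, rss = best$rss, n = n,
                 non_uptake = unname(cf[["I_inf"]] < cf[["I0"]])),
            class = "uptake_fit")
}

#' @export
print.uptake_fit <- function(x, ...) {
  cat(sprintf("uptake fit: I_inf = %.4g, I0 = %.4g, tau = %.4g s (n = %d)%s\n",
              x$I_inf, x$I0, x$tau_s, x$n,
              if (x$non_uptake) " [non-uptake: intensity decreases]" else ""))
  invisible(x)
}
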
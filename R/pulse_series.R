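# Per-pulse area-loss normalization, photobleaching correction of actin
# fluorescence, and sigmoidal field-response fits.

#' Per-pulse normalized area
#'
#' For pulses ordered by index, computes
#' `A_norm(n) = (A_f/A_i)_n * (A_f/A_i)_(n-1)` with `(A_f/A_i)_0 := 1`: the
#' per-pulse area ratio corrected for the loss at the previous pulse, which
#' removes spurious radius changes from the vesicle moving through the
#' imaging plane. `cumulative = TRUE` instead returns the running product of
#' all ratios up to pulse n.
#'
#' @param records data frame with columns `pulse_index`, `A_i_um2`,
#'   `A_f_um2` (any consistent area unit), ordered by pulse index.
#' @param cumulative use the cumulative product of all per-pulse ratios
#'   instead of the two-factor form.
#' @return data frame `pulse_index`, `ratio` (A_f/A_i), `A_norm`. Records
#'   with missing areas are dropped with a warning.
#' @export
normalized_area <- function(records, cumulative = FALSE) {
  stopifnot(is.data.frame(records),
            all(c("pulse_index", "A_i_um2", "A_f_um2") %in% names(records)))
  if (is.unsorted(records$pulse_index))
    stop("normalized_area: records must be ordered by pulse_index")
  miss <- is.na(records$A_i_um2) | is.na(records$A_f_um2)
  if (any(miss)) {
    warning(sprintf("normalized_area: dropping %d record(s) with missing areas",
                    sum(miss)))
    records <- records[!miss, , drop = FALSE]
  }
  if (any(records$A_i_um2 <= 0) || any(records$A_f_um2 <= 0))
    stop("normalized_area: areas must be > 0")
  r <- records$A_f_um2 / records$A_i_um2
  A_norm <- if (cumulative) cumprod(r) else r * c(1, r[-length(r)])
  data.frame(pulse_index = records$pulse_index, ratio = r, A_norm = A_norm)
}

#' Photobleaching correction factors from a no-pulse reference
#'
#' `I_ref(k) = I_k,ref / I_0,ref`: the per-scan intensity of a reference
#' vesicle that was imaged without pulsing, normalized to its first scan.
#'
#' @param reference numeric vector of reference intensities by scan (first
#'   element = scan 0).
#' @return numeric vector of correction factors; the first is exactly 1.
#' @export
bleach_reference <- function(reference) {
  stopifnot(is.numeric(reference), length(reference) >= 1)
  if (is.na(reference[1]) || reference[1] <= 0)
    stop("bleach_reference: initial reference intensity must be > 0")
  reference / reference[1]
}

#' Photobleaching-corrected normalized actin intensity
#'
#' `I_norm(k) = I_k / (I_0 * I_ref(k))`: the actin fluorescence at scan k,
#' normalized to the start of the experiment and divided by the bleaching
#' factor of the paired no-pulse reference, isolating pulse-induced
#' intensity loss.
#'
#' @param I_k intensity series by scan.
#' @param I_ref bleaching factors from [bleach_reference()], same length.
#' @param I_0 start-of-experiment intensity; defaults to `I_k[1]`.
#' @return numeric vector of normalized intensities.
#' @export
bleach_corrected_intensity <- function(I_k, I_ref, I_0 = I_k[1]) {
  if (length(I_k) != length(I_ref))
    stop("bleach_corrected_intensity: I_k and I_ref are misaligned")
  if (is.na(I_0) || I_0 <= 0) stop("bleach_corrected_intensity: I_0 must be > 0")
  if (any(I_ref <= 0)) stop("bleach_corrected_intensity: I_ref factors must be > 0")
  I_k / (I_0 * I_ref)
}

#' Fit a four-parameter logistic to a field response
#'
#' Least-squares fit of `y = lower + (upper - lower) / (1 + exp(s (x - x50)))`
#' to a normalized quantity (area or actin intensity) versus field strength.
#' With `s > 0` the curve decreases with field, the usual orientation for
#' area loss and actin-intensity loss. Data with no appreciable transition
#' are flagged rather than rejected.
#'
#' @param x field strengths (V/mm), >= 5 points spanning the transition.
#' @param y normalized response.
#' @return object of class `sigmoid_fit`: `lower`, `upper`, `midpoint`
#'   (x50, V/mm), `steepness` (signed; positive = decreasing), `rss`,
#'   `flagged` (TRUE for flat data).
#' @export
fit_field_sigmoid <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 5) stop("fit_field_sigmoid: need >= 5 points")
  rng <- diff(range(y))
  if (rng < 1e-10) {
    return(structure(list(lower = min(y), upper = max(y),
                          midpoint = stats::median(x), steepness = 0,
                          rss = 0, flagged = TRUE), class = "sigmoid_fit"))
  }
  lo0 <- min(y); up0 <- max(y)
  mid0 <- x[which.min(abs(y - (lo0 + up0) / 2))]
  cxy <- suppressWarnings(stats::cor(x, y))
  s_sign <- if (is.finite(cxy) && cxy < 0) 1 else -1
  best <- NULL
  for (s0 in s_sign * c(0.5, 2, 10) * 4 / max(diff(range(x)), 1e-9)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ lower + (upper - lower) / (1 + exp(s * (x - x50))),
                        start = list(lower = lo0, upper = up0, x50 = mid0,
                                     s = s0),
                        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(coef = stats::coef(fit), rss = rss)
  }
  if (is.null(best)) stop("fit_field_sigmoid: fit failed to converge")
  cf <- best$coef
  flagged <- abs(cf[["upper"]] - cf[["lower"]]) < 3 * sqrt(best$rss / length(x)) ||
    cf[["x50"]] < min(x) || cf[["x50"]] > max(x)
  structure(list(lower = unname(min(cf[["lower"]], cf[["upper"]])),
                 upper = unname(max(cf[["lower"]], cf[["upper"]])),
                 midpoint = unname(cf[["x50"]]), steepness = unname(cf[["s"]]),
                 rss = best$rss, flagged = flagged),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf("sigmoid fit: lower %.4g, upper %.4g, midpoint %.4g V/mm, steepness %.4g%s\n",
              x$lower, x$upper, x$midpoint, x$steepness,
              if (x$flagged) " [flagged: no clear transition]" else ""))
  invisible(x)
}

#' Mean actin intensity of a confocal z-stack
#'
#' The stack intensity is the mean over planes of the per-plane mean
#' intensity.
#'
#' @param planes a list of numeric matrices/vectors (one per plane), a
#'   numeric matrix with one column per plane, or a numeric vector of
#'   per-plane mean intensities.
#' @return scalar stack intensity.
#' @export
actin_stack_intensity <- function(planes) {
  if (is.list(planes)) {
    if (length(planes) == 0) stop("actin_stack_intensity: empty stack")
    return(mean(vapply(planes, function(p) mean(as.numeric(p)), numeric(1))))
  }
  if (is.matrix(planes)) {
    if (ncol(planes) == 0) stop("actin_stack_intensity: empty stack")
    return(mean(colMeans(planes)))
  }
  if (length(planes) == 0) stop("actin_stack_intensity: empty stack")
  mean(planes)
}

#' Analyze a consecutive-pulse series
#'
#' Convenience wrapper combining [normalized_area()], [bleach_reference()],
#' [bleach_corrected_intensity()] and [fit_field_sigmoid()] for a pulse
#' series as produced by [generate_pulse_series()] (or read from CSV tables
#' with the same columns).
#'
#' @param series list with data frames `pulses` (`pulse_index`, `field_Vmm`,
#'   `A_i_um2`, `A_f_um2`), `actin` (`scan_k`, `I_k`), `reference`
#'   (`scan_k`, `I_k`).
#' @param cumulative passed to [normalized_area()].
#' @return list of class `pulse_series_analysis`: `area` (per-pulse table
#'   with `A_norm`), `I_norm` (per-scan corrected intensities), `area_fit`
#'   and `actin_fit` (sigmoid fits vs field).
#' @export
analyze_pulse_series <- function(series, cumulative = FALSE) {
  stopifnot(all(c("pulses", "actin", "reference") %in% names(series)))
  area <- normalized_area(series$pulses, cumulative = cumulative)
  area$field_Vmm <- series$pulses$field_Vmm[match(area$pulse_index,
                                                  series$pulses$pulse_index)]
  ref <- bleach_reference(series$reference$I_k)
  if (!all(series$actin$scan_k == series$reference$scan_k))
    stop("analyze_pulse_series: actin and reference scan indices are misaligned")
  I_norm <- bleach_corrected_intensity(series$actin$I_k, ref)
  # scan 0 is pre-pulse; scan k responds to pulse k
  keep <- series$actin$scan_k >= 1
  actin_fit <- fit_field_sigmoid(series$pulses$field_Vmm, I_norm[keep])
  area_fit <- fit_field_sigmoid(area$field_Vmm, area$ratio)
  structure(list(area = area, I_norm = I_norm, area_fit = area_fit,
                 actin_fit = actin_fit),
            class = "pulse_series_analysis")
}
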
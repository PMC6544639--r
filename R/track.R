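# Frame-by-frame tracking: contour detection -> ellipse fit -> subpixel
# radial refinement, assembled into a deformation trace.

#' Tracking parameters
#'
#' @param low_thresh,high_thresh Canny hysteresis thresholds (fractions of
#'   the maximum gradient magnitude).
#' @param smooth_sigma Gaussian smoothing sigma (px) before edge detection.
#' @param closing_radius morphological closing radius (px) used to bridge
#'   macropore gaps in the detected rim.
#' @param refine logical; refine each fit with subpixel radial rim
#'   localization (recommended).
#' @param n_angles number of radial profiles used in refinement.
#' @param pore_min_run minimum run of consecutive weak-rim boundary angles
#'   (out of 180) for a frame to be flagged as showing a pore.
#' @param max_flagged_frac maximum tolerated fraction of flagged (failed)
#'   frames before [track_sequence()] errors.
#' @param interpolate_flagged interpolate a, b across flagged frames
#'   (otherwise they carry NA).
#' @return list of class `track_params`.
#' @export
track_params <- function(low_thresh = 0.1, high_thresh = 0.2,
                         smooth_sigma = 1, closing_radius = 3,
                         refine = TRUE, n_angles = 180,
                         pore_min_run = 5, max_flagged_frac = 0.5,
                         interpolate_flagged = TRUE) {
  stopifnot(low_thresh >= 0, low_thresh < high_thresh, high_thresh <= 1,
            smooth_sigma >= 0, closing_radius >= 0, n_angles >= 12,
            pore_min_run >= 1,
            max_flagged_frac > 0, max_flagged_frac <= 1)
  structure(list(low_thresh = low_thresh, high_thresh = high_thresh,
                 smooth_sigma = smooth_sigma, closing_radius = closing_radius,
                 refine = refine, n_angles = as.integer(n_angles),
                 pore_min_run = as.integer(pore_min_run),
                 max_flagged_frac = max_flagged_frac,
                 interpolate_flagged = interpolate_flagged),
            class = "track_params")
}

# Fit a single frame; returns a list with the fit (or NULL), pore flag,
# interior/background means and the rim profile shape used. When `shape`
# is supplied (e.g. pooled over a sequence) the polish freezes it and fits
# geometry only, which is substantially more precise than the single-frame
# joint fit.
track_frame <- function(image, pixel_size_um, params = track_params(),
                        shape = NULL) {
  edges <- detect_edges(image, params$low_thresh, params$high_thresh,
                        params$smooth_sigma)
  if (isTRUE(attr(edges, "empty")))
    return(list(fit = NULL, pore = FALSE, inner = NA_real_, bg = NA_real_))
  ctr <- extract_contour(edges, params$closing_radius)
  if (ctr$flag)
    return(list(fit = NULL, pore = FALSE, inner = NA_real_, bg = NA_real_))
  fit <- tryCatch(fit_ellipse_trimmed(ctr$pixels, pixel_size_um = pixel_size_um),
                  error = function(e) NULL)
  if (is.null(fit))
    return(list(fit = NULL, pore = FALSE, inner = NA_real_, bg = NA_real_))
  pore <- FALSE
  shape_used <- NULL
  if (params$refine) {
    # radial matched filtering recovers from the coarse edge-based fit and
    # estimates the profile shape; the 2-D model polish then refits the
    # geometry against every rim-band pixel
    ref <- refine_ellipse_radial(image, fit, n_angles = params$n_angles)
    fit <- ref$fit
    if (ref$refined) {
      fit <- polish_ellipse_model(image, fit,
                                  shape = shape %||% ref$shape,
                                  keep_angles = ref$keep_angles,
                                  free_shape = is.null(shape))
      shape_used <- attr(fit, "shape")
      pore <- detect_pore_arc(image, fit, shape_used,
                              min_run = params$pore_min_run)$pore
    }
  }
  inner <- tryCatch(inner_region_mean(image, fit, 0.8),
                    error = function(e) NA_real_)
  bg <- background_mean(image, fit)
  list(fit = fit, pore = pore, inner = inner, bg = bg, shape = shape_used)
}

# mean intensity well outside the fitted ellipse (background estimate)
background_mean <- function(image, fit) {
  nx <- ncol(image); ny <- nrow(image)
  xs <- matrix(rep(0:(nx - 1), each = ny), nrow = ny) - fit$center_px[1]
  ys <- matrix(rep(0:(ny - 1), times = nx), nrow = ny) - fit$center_px[2]
  co <- cos(fit$orientation); so <- sin(fit$orientation)
  xr <- co * xs + so * ys; yr <- -so * xs + co * ys
  pad <- 4
  outside <- (xr / (fit$a_px + pad))^2 + (yr / (fit$b_px + pad))^2 > 1
  if (!any(outside)) return(NA_real_)
  mean(image[outside])
}

#' Track a GUV through an image sequence
#'
#' Runs contour detection, ellipse fitting and subpixel refinement on every
#' frame and assembles the per-frame fits into a deformation trace with
#' projected area, per-frame quality and pore flags, and interior/background
#' intensity means (for contrast-loss and dye-uptake analyses).
#'
#' @param images an `image_sequence` from [render_sequence()], a list of
#'   numeric matrices, or the path to a multi-page TIFF.
#' @param pixel_size_um pixel size (um/px); taken from the sequence when
#'   available.
#' @param frame_rate frames per second (used when `images` carries no
#'   timestamps).
#' @param params a [track_params()].
#' @return a `deformation_trace` data frame: `time_s`, `a_um`, `b_um`,
#'   `ratio`, `area_um2` (pi a b), `flag` (fit failed), `pore`
#'   (macropore-like rim gap), `inner_mean`, `bg_mean`. Pulse timing
#'   attributes are carried over from the input sequence when present.
#' @export
track_sequence <- function(images, pixel_size_um = NULL, frame_rate = NULL,
                           params = track_params()) {
  times <- NULL; pulse_start <- NA_real_; pulse_end <- NA_real_
  if (is.character(images)) images <- read_sequence_tiff(images)
  if (inherits(images, "image_sequence")) {
    times <- images$times_s
    if (is.null(pixel_size_um)) pixel_size_um <- images$pixel_size_um
    pulse_start <- images$pulse_start_s %||% NA_real_
    pulse_end <- images$pulse_end_s %||% NA_real_
    images <- images$frames
  }
  stopifnot(is.list(images), length(images) >= 1)
  if (is.null(pixel_size_um)) stop("track_sequence: pixel_size_um is required")
  if (is.null(times)) {
    if (is.null(frame_rate)) stop("track_sequence: frame_rate is required when the input has no timestamps")
    times <- (seq_along(images) - 1) / frame_rate
  }
  n <- length(images)
  # pass 1: estimate the rim profile shape (optics, shared by all frames of
  # a sequence) by joint geometry+shape fits on a spread of frames, then
  # pool by the median. Freezing the pooled shape in pass 2 removes the
  # axis/width degeneracy of the single-frame fit.
  shape <- NULL
  if (params$refine && n >= 2) {
    idx <- unique(round(seq(1, n, length.out = min(8, n))))
    shapes <- list()
    for (i in idx) {
      res <- track_frame(images[[i]], pixel_size_um, params)
      if (!is.null(res$shape)) shapes[[length(shapes) + 1]] <- res$shape
    }
    if (length(shapes) >= 2) {
      pool <- function(f) stats::median(vapply(shapes, `[[`, numeric(1), f))
      shape <- list(A = pool("A"), B = pool("B"), C = pool("C"),
                    ss = pool("ss"), sr = pool("sr"))
    }
  }
  a <- b <- inner <- bg <- rep(NA_real_, n)
  flag <- pore <- logical(n)
  for (i in seq_len(n)) {
    res <- track_frame(images[[i]], pixel_size_um, params, shape = shape)
    if (is.null(res$fit)) {
      flag[i] <- TRUE
    } else {
      a[i] <- res$fit$a_um; b[i] <- res$fit$b_um
      pore[i] <- res$pore; inner[i] <- res$inner; bg[i] <- res$bg
    }
  }
  if (mean(flag) > params$max_flagged_frac)
    stop(sprintf("track_sequence: %.0f%% of frames failed tracking",
                 100 * mean(flag)))
  if (params$interpolate_flagged && any(flag) && sum(!flag) >= 2) {
    a[flag] <- stats::approx(times[!flag], a[!flag], xout = times[flag],
                             rule = 2)$y
    b[flag] <- stats::approx(times[!flag], b[!flag], xout = times[flag],
                             rule = 2)$y
  }
  df <- data.frame(time_s = times, a_um = a, b_um = b, ratio = a / b,
                   area_um2 = pi * a * b, flag = flag, pore = pore,
                   inner_mean = inner, bg_mean = bg)
  new_deformation_trace(df, pulse_start_s = pulse_start,
                        pulse_end_s = pulse_end)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a deformation trace as CSV
#'
#' @param trace a `deformation_trace`.
#' @param path output path; pulse timing is stored in comment header lines.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pulse_start_s=%.9g", attr(trace, "pulse_start_s") %||% NA), con)
  writeLines(sprintf("# pulse_end_s=%.9g", attr(trace, "pulse_end_s") %||% NA), con)
  utils::write.csv(as.data.frame(trace), con, row.names = FALSE)
  invisible(path)
}

#' Read a deformation trace written by [write_trace_csv()]
#'
#' @param path CSV path.
#' @return a `deformation_trace`.
#' @export
read_trace_csv <- function(path) {
  hdr <- readLines(path, n = 2)
  getnum <- function(x) suppressWarnings(as.numeric(sub("^# [a-z_]+=", "", x)))
  df <- utils::read.csv(path, comment.char = "#")
  new_deformation_trace(df, pulse_start_s = getnum(hdr[1]),
                        pulse_end_s = getnum(hdr[2]))
}
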
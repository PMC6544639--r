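# Rendering of synthetic GUV frames. Images are numeric matrices in [0, 1]
# indexed [row = y, col = x]; pixel coordinates are 0-based with the origin
# at the top-left corner, x rightward (= field axis), y downward.

#' Render one synthetic GUV frame
#'
#' Draws an axis-aligned ellipse (long axis of the field-aligned deformation
#' along the image x-axis) with distinct interior and exterior grey levels, a
#' membrane rim centred exactly on the ellipse boundary (Gaussian profile of
#' half-width `rim_sigma_px` toward `membrane_level`), an optional macropore
#' rendered as an angular arc at the +x pole where the rim is replaced by an
#' interior/exterior blend, then optical Gaussian blur and additive pixel
#' noise.
#'
#' @param a_um,b_um semi-axes (um): `a` along the field (x), `b`
#'   perpendicular.
#' @param optics an [optics_params()].
#' @param pore_angle_width full angular width (radians) of the macropore arc
#'   centred on the +x pole; 0 for no pore.
#' @param center_px optional c(x, y) ellipse centre in 0-based pixel
#'   coordinates; defaults to the image centre.
#' @param contrast_scale multiplier in [0, 1] applied to the
#'   interior-exterior contrast (1 = full contrast; used for post-poration
#'   contrast loss).
#' @param noise_seed optional seed for the pixel noise (defaults to
#'   `optics$seed`).
#' @return numeric matrix (ny rows, nx cols) in [0, 1] with attributes
#'   `pixel_size_um` and `truth` (a, b, centre, pore width).
#' @export
render_frame <- function(a_um, b_um, optics = optics_params(),
                         pore_angle_width = 0, center_px = NULL,
                         contrast_scale = 1, noise_seed = NULL) {
  stopifnot(inherits(optics, "optics_params"), a_um > 0, b_um > 0,
            pore_angle_width >= 0, contrast_scale >= 0, contrast_scale <= 1)
  px <- optics$pixel_size_um
  if (a_um <= 2 * px || b_um <= 2 * px)
    stop("render_frame: semi-axes must exceed 2 pixels")
  nx <- optics$image_size[1]; ny <- optics$image_size[2]
  if (is.null(center_px)) center_px <- c((nx - 1) / 2, (ny - 1) / 2)
  a <- a_um / px; b <- b_um / px
  margin <- 3 * (optics$rim_sigma_px + optics$edge_blur_sigma) + 2
  if (center_px[1] - a < margin || center_px[1] + a > nx - 1 - margin ||
      center_px[2] - b < margin || center_px[2] + b > ny - 1 - margin)
    stop("render_frame: ellipse (plus blur margin) exceeds the frame")

  xs <- matrix(rep(0:(nx - 1), each = ny), nrow = ny) - center_px[1]
  ys <- matrix(rep(0:(ny - 1), times = nx), nrow = ny) - center_px[2]
  int_lvl <- optics$exterior_level +
    contrast_scale * (optics$interior_level - optics$exterior_level)

  Fv <- sqrt((xs / a)^2 + (ys / b)^2)
  base <- ifelse(Fv <= 1, int_lvl, optics$exterior_level)
  # signed distance to the ellipse in px: (F - 1) / |grad F|
  gF <- sqrt((xs / a^2)^2 + (ys / b^2)^2) / pmax(Fv, 1e-9)
  d <- (Fv - 1) / pmax(gF, 1e-9)
  # the rim is an additive Gaussian profile of constant amplitude centred on
  # the ellipse, so its centre marks the true boundary on both flanks; the
  # blurred image then reaches membrane_level at the boundary
  rim_w <- exp(-d^2 / (2 * optics$rim_sigma_px^2))
  rim_amp <- matrix(optics$membrane_level -
                      (int_lvl + optics$exterior_level) / 2, ny, nx)
  if (pore_angle_width > 0) {
    ang <- atan2(ys / b, xs / a)           # parametric angle; +x pole at 0
    in_pore <- abs(ang) <= pore_angle_width / 2
    rim_amp[in_pore] <- 0                  # membrane absent across the pore
  }
  img <- base + rim_amp * rim_w
  if (optics$edge_blur_sigma > 0)
    img <- EBImage::gblur(img, sigma = optics$edge_blur_sigma)
  if (optics$noise_sigma > 0) {
    seed <- if (is.null(noise_seed)) optics$seed else noise_seed
    img <- with_seed(seed, img + stats::rnorm(length(img), 0, optics$noise_sigma))
  }
  img <- pmin(pmax(img, 0), 1)
  attr(img, "pixel_size_um") <- px
  attr(img, "truth") <- list(a_um = a_um, b_um = b_um, center_px = center_px,
                             pore_angle_width = pore_angle_width)
  img
}

#' Render an image sequence from a deformation trace
#'
#' Renders frames for (a subsample of) the trace time points, adding a
#' macropore arc and/or progressive contrast loss after the pulse when the
#' scenario requests them.
#'
#' @param trace a `deformation_trace` from [generate_deformation_trace()].
#' @param optics an [optics_params()].
#' @param every render every `every`-th frame (default 1 = all).
#' @return list of class `image_sequence`: `frames` (list of matrices),
#'   `times_s`, `pixel_size_um`, `pulse_start_s`, `pulse_end_s`,
#'   `pore_frames` (logical), `truth` (the subsampled trace rows).
#' @export
render_sequence <- function(trace, optics = optics_params(), every = 1L) {
  stopifnot(inherits(trace, "deformation_trace"), every >= 1)
  scen <- attr(trace, "scenario")
  pulse_end <- attr(trace, "pulse_end_s")
  idx <- seq(1, nrow(trace), by = every)
  frames <- vector("list", length(idx))
  pore_frames <- logical(length(idx))
  for (j in seq_along(idx)) {
    i <- idx[j]
    t <- trace$time_s[i]
    pore_w <- 0
    contrast <- 1
    if (!is.null(scen) && !is.na(pulse_end) && t >= pulse_end) {
      if (scen$porated == "macropore" && t < pulse_end + scen$pore_lifetime_s) {
        # pore arc shrinks linearly over the pore lifetime
        frac <- 1 - (t - pulse_end) / scen$pore_lifetime_s
        pore_w <- 2 * scen$pore_max_radius_um / trace$a_um[i] * frac
        pore_frames[j] <- pore_w > 0.05
      }
      if (scen$porated == "contrast_loss" && is.finite(optics$contrast_half_life))
        contrast <- 0.5^((t - pulse_end) / optics$contrast_half_life)
    }
    frames[[j]] <- render_frame(trace$a_um[i], trace$b_um[i], optics,
                                pore_angle_width = pore_w,
                                contrast_scale = contrast,
                                noise_seed = optics$seed + i)
  }
  structure(list(frames = frames, times_s = trace$time_s[idx],
                 pixel_size_um = optics$pixel_size_um,
                 pulse_start_s = attr(trace, "pulse_start_s"),
                 pulse_end_s = pulse_end, pore_frames = pore_frames,
                 truth = trace[idx, , drop = FALSE]),
            class = "image_sequence")
}

#' Write an image sequence as a multi-page grayscale TIFF
#'
#' @param seq an `image_sequence` from [render_sequence()], or a list of
#'   numeric matrices in [0, 1].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sequence_tiff <- function(seq, path) {
  frames <- if (inherits(seq, "image_sequence")) seq$frames else seq
  frames <- lapply(frames, function(f) { attributes(f)[setdiff(names(attributes(f)), "dim")] <- NULL; f })
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page grayscale TIFF as a list of matrices
#'
#' @param path TIFF file path.
#' @return list of numeric matrices in [0, 1].
#' @export
read_sequence_tiff <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  lapply(frames, function(f) if (length(dim(f)) == 3) f[, , 1] else f)
}
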
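# Contour detection and ellipse fitting.
#
# Images are numeric matrices [row = y, col = x]; pixel coordinates are
# 0-based, origin top-left, x rightward (field axis), y downward. EBImage is
# used for the isotropic primitives (Gaussian blur, morphological closing,
# hole filling, connected components, contour tracing); the Canny core
# (Sobel gradients, non-maximum suppression, hysteresis linking) and the
# constrained conic fit are implemented here.

# 8-connected component labels. EBImage::bwlabel is 4-connected, which
# fragments thin diagonal curves; merge its labels across the two diagonal
# adjacencies with a small union-find.
label8 <- function(mask) {
  mask <- mask > 0
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask)))
  lab <- matrix(as.integer(lab), nrow(lab))
  n <- max(lab)
  if (n <= 1) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),    # down-right
    cbind(as.vector(lab[-nr, -1]), as.vector(lab[-1, -nc])))    # down-left
  pairs <- unique(pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                          pairs[, 1] != pairs[, 2], , drop = FALSE])
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(nrow(pairs))) {
    a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
    if (a != b) parent[b] <- a
  }
  root <- vapply(seq_len(n), find, integer(1))
  relab <- match(root, unique(root))
  lab[lab > 0] <- relab[lab[lab > 0]]
  lab
}

# shift a matrix by (dx, dy) pixels with zero padding (dx along columns/x)
shift_mat <- function(m, dx, dy) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  src_r <- seq_len(nr) - dy; src_c <- seq_len(nc) - dx
  ok_r <- src_r >= 1 & src_r <= nr; ok_c <- src_c >= 1 & src_c <= nc
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

#' Canny-style edge detection
#'
#' Gaussian smoothing, Sobel gradient magnitude, non-maximum suppression
#' along the quantized gradient direction, and hysteresis linking: weak
#' edges (above `low_thresh`) are kept only when 8-connected to a strong
#' edge (above `high_thresh`). Thresholds are fractions of the maximum
#' gradient magnitude. On a noiseless ideal ellipse rim this yields thin
#' closed curves along the rim flanks.
#'
#' @param image numeric matrix in [0, 1].
#' @param low_thresh,high_thresh hysteresis thresholds as fractions of the
#'   maximum gradient magnitude, 0 <= low < high <= 1.
#' @param smooth_sigma Gaussian smoothing sigma in px (0 = none).
#' @return binary matrix (class `edge_map`) with attribute `empty` flagging
#'   an edgeless frame.
#' @export
detect_edges <- function(image, low_thresh = 0.1, high_thresh = 0.2,
                         smooth_sigma = 1) {
  stopifnot(is.matrix(image), low_thresh >= 0, high_thresh <= 1,
            low_thresh < high_thresh)
  img <- if (smooth_sigma > 0) EBImage::gblur(image, sigma = smooth_sigma) else image
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), nrow = 3)  # d/dx
  gx <- as.matrix(EBImage::filter2(img, kx))
  gy <- as.matrix(EBImage::filter2(img, t(kx)))
  mag <- sqrt(gx^2 + gy^2)
  mmax <- max(mag)
  if (mmax < .Machine$double.eps^0.5) {
    out <- matrix(FALSE, nrow(image), ncol(image))
    class(out) <- c("edge_map", class(out))
    attr(out, "empty") <- TRUE
    return(out)
  }
  # non-maximum suppression: compare to the two neighbours along the
  # gradient direction, quantized to 4 orientations
  theta <- atan2(gy, gx)
  d <- theta %% pi
  nms <- matrix(0, nrow(mag), ncol(mag))
  bins <- list(
    list(sel = d < pi / 8 | d >= 7 * pi / 8, dx = 1, dy = 0),
    list(sel = d >= pi / 8 & d < 3 * pi / 8, dx = 1, dy = 1),
    list(sel = d >= 3 * pi / 8 & d < 5 * pi / 8, dx = 0, dy = 1),
    list(sel = d >= 5 * pi / 8 & d < 7 * pi / 8, dx = -1, dy = 1)
  )
  for (b in bins) {
    n1 <- shift_mat(mag, b$dx, b$dy)
    n2 <- shift_mat(mag, -b$dx, -b$dy)
    keep <- b$sel & mag >= n1 & mag >= n2
    nms[keep] <- mag[keep]
  }
  strong <- nms >= high_thresh * mmax
  weak <- nms >= low_thresh * mmax
  if (!any(strong)) {
    out <- matrix(FALSE, nrow(image), ncol(image))
    class(out) <- c("edge_map", class(out))
    attr(out, "empty") <- TRUE
    return(out)
  }
  lab <- label8(weak)
  keep_labels <- unique(lab[strong & weak])
  keep_labels <- keep_labels[keep_labels > 0]
  out <- matrix(lab %in% keep_labels, nrow(image), ncol(image))
  class(out) <- c("edge_map", class(out))
  attr(out, "empty") <- !any(out)
  out
}

#' Extract the ordered contour of the largest closed edge component
#'
#' Applies morphological closing (to bridge macropore gaps up to roughly
#' twice the closing radius), labels connected components, keeps those that
#' enclose an interior (hole filling grows their area), selects the one with
#' the largest enclosed area, and traces its ordered outer boundary.
#'
#' @param edges an `edge_map` from [detect_edges()] (or any binary matrix).
#' @param closing_radius radius (px) of the disc structuring element.
#' @param min_closed_ratio minimum (filled area)/(component area) for a
#'   component to count as closed.
#' @return list of class `guv_contour`: `points` (n x 2 matrix of ordered
#'   0-based (x, y) boundary points), `pixels` (component pixel coordinates,
#'   (x, y) 0-based; these straddle the true edge symmetrically and are the
#'   preferred input for [fit_ellipse()]), `mask` (filled logical matrix),
#'   `flag` (TRUE when no closed component was found), `n_components`.
#' @export
extract_contour <- function(edges, closing_radius = 3, min_closed_ratio = 1.2) {
  stopifnot(is.matrix(edges))
  em <- matrix(as.numeric(edges), nrow(edges), ncol(edges))
  flagged <- function() structure(list(points = NULL, pixels = NULL,
                                       mask = NULL, flag = TRUE,
                                       n_components = 0L),
                                  class = "guv_contour")
  if (!any(em > 0)) return(flagged())
  if (closing_radius > 0) {
    brush <- EBImage::makeBrush(2 * closing_radius + 1, shape = "disc")
    em <- EBImage::closing(em, brush)
  }
  lab <- label8(em > 0)
  nlab <- max(lab)
  if (nlab == 0) return(flagged())
  best <- NULL
  for (l in seq_len(nlab)) {
    mask <- lab == l
    comp_area <- sum(mask)
    if (comp_area < 20) next                       # speckle
    filled <- EBImage::fillHull(matrix(as.numeric(mask), nrow(mask))) > 0
    filled_area <- sum(filled)
    if (filled_area / comp_area < min_closed_ratio) next
    if (is.null(best) || filled_area > best$filled_area)
      best <- list(mask = mask, filled = filled, filled_area = filled_area)
  }
  if (is.null(best)) return(flagged())
  # ocontour works in EBImage (dim1, dim2) coordinates; our matrices are
  # [y, x], so returned columns are (y, x) 0-based -> swap
  oc <- EBImage::ocontour(matrix(as.numeric(best$filled), nrow(best$filled)))[[1]]
  pts <- cbind(x = oc[, 2], y = oc[, 1])
  idx <- which(best$mask, arr.ind = TRUE)
  pixels <- cbind(x = idx[, 2] - 1, y = idx[, 1] - 1)
  structure(list(points = pts, pixels = pixels, mask = best$filled,
                 flag = FALSE, n_components = nlab),
            class = "guv_contour")
}

#' Direct least-squares ellipse fit
#'
#' Fits a conic constrained to be an ellipse (4AC - B^2 > 0) to 2-D points
#' by the numerically stable direct least-squares method, then converts to
#' geometric parameters. Axis labels follow the field-axis convention: `a`
#' is the semi-axis whose direction is closer to the image x-axis (the field
#' axis), `b` the perpendicular one; labels are never assigned by magnitude,
#' so disklike (a < b) fits are preserved.
#'
#' @param points n x 2 matrix (or data frame) of (x, y) coordinates, n >= 6.
#' @param pixel_size_um optional pixel size to also report axes in um.
#' @return object of class `ellipse_fit`: `center_px`, `a_px`, `b_px`
#'   (field-aligned and perpendicular semi-axes), `orientation` (radians in
#'   (-pi/2, pi/2], 0 for circles), `rms_residual_px` (approximate geometric
#'   distance), `n_points`, and `a_um`/`b_um` when `pixel_size_um` is given.
#' @export
fit_ellipse <- function(points, pixel_size_um = NULL) {
  pts <- as.matrix(points)
  if (ncol(pts) != 2) stop("fit_ellipse: points must be n x 2")
  pts <- pts[stats::complete.cases(pts), , drop = FALSE]
  n <- nrow(pts)
  if (n < 6) stop("fit_ellipse: at least 6 points required")
  mx <- mean(pts[, 1]); my <- mean(pts[, 2])
  sc <- mean(sqrt((pts[, 1] - mx)^2 + (pts[, 2] - my)^2))
  if (sc < .Machine$double.eps) stop("fit_ellipse: degenerate point set")
  x <- (pts[, 1] - mx) / sc; y <- (pts[, 2] - my) / sc

  # Halir & Flusser partitioned solution of the Fitzgibbon constrained fit
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  T3 <- tryCatch(-solve(S3, t(S2)), error = function(e)
    stop("fit_ellipse: degenerate (collinear?) point set"))
  M <- S1 + S2 %*% T3
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  vec <- Re(ev$vectors)
  cond <- 4 * vec[1, ] * vec[3, ] - vec[2, ]^2
  ok <- which(cond > 0 & abs(Im(ev$values)) < 1e-8)
  if (length(ok) == 0) stop("fit_ellipse: no ellipse solution (hyperbola-like conic)")
  a1 <- vec[, ok[1]]
  coef <- c(a1, as.vector(T3 %*% a1))      # A B C D E F in normalized frame
  A <- coef[1]; B <- coef[2]; C <- coef[3]
  D <- coef[4]; E <- coef[5]; Fc <- coef[6]

  den <- B^2 - 4 * A * C                   # < 0 for an ellipse
  x0 <- (2 * C * D - B * E) / den
  y0 <- (2 * A * E - B * D) / den
  num <- 2 * (A * E^2 + C * D^2 + Fc * B^2 - B * D * E + den * Fc)
  s1 <- A + C
  s2 <- sqrt((A - C)^2 + B^2)
  ax1 <- -sqrt(num * (s1 + s2)) / den      # semi-axis for orientation theta
  ax2 <- -sqrt(num * (s1 - s2)) / den
  if (!is.finite(ax1) || !is.finite(ax2) || ax1 <= 0 || ax2 <= 0)
    stop("fit_ellipse: degenerate conic")
  theta <- if (abs(B) < 1e-12 && abs(A - C) < 1e-12) 0 else
    0.5 * atan2(-B, C - A)                 # orientation of axis ax1

  # back to pixel frame
  cx <- mx + x0 * sc; cy <- my + y0 * sc
  ax1 <- ax1 * sc; ax2 <- ax2 * sc
  # field-axis labelling: axis direction closest to x wins the 'a' label
  th_mod <- ((theta + pi / 2) %% pi) - pi / 2   # to (-pi/2, pi/2]
  if (abs(ax1 - ax2) / max(ax1, ax2) < 1e-9) {  # circle: convention
    a_px <- ax1; b_px <- ax2; orientation <- 0
  } else if (abs(cos(th_mod)) >= sqrt(0.5)) {
    a_px <- ax1; b_px <- ax2; orientation <- th_mod
  } else {
    a_px <- ax2; b_px <- ax1
    orientation <- ((th_mod + pi / 2 + pi / 2) %% pi) - pi / 2
  }

  # approximate geometric rms: |Q(p)| / |grad Q(p)| in the pixel frame
  Q <- function(px, py) {
    xn <- (px - mx) / sc; yn <- (py - my) / sc
    A * xn^2 + B * xn * yn + C * yn^2 + D * xn + E * yn + Fc
  }
  gnorm <- {
    xn <- (pts[, 1] - mx) / sc; yn <- (pts[, 2] - my) / sc
    sqrt((2 * A * xn + B * yn + D)^2 + (B * xn + 2 * C * yn + E)^2) / sc
  }
  res <- abs(Q(pts[, 1], pts[, 2])) / pmax(gnorm, 1e-12)
  out <- list(center_px = c(cx, cy), a_px = a_px, b_px = b_px,
              orientation = orientation,
              rms_residual_px = sqrt(mean(res^2)), n_points = n)
  if (!is.null(pixel_size_um)) {
    out$a_um <- a_px * pixel_size_um
    out$b_um <- b_px * pixel_size_um
    out$pixel_size_um <- pixel_size_um
  }
  structure(out, class = "ellipse_fit")
}

#' @export
print.ellipse_fit <- function(x, ...) {
  cat(sprintf("ellipse fit: center (%.2f, %.2f) px, a = %.3f px, b = %.3f px, a/b = %.4f\n",
              x$center_px[1], x$center_px[2], x$a_px, x$b_px, x$a_px / x$b_px))
  cat(sprintf("  orientation %.4f rad, rms residual %.3f px, n = %d\n",
              x$orientation, x$rms_residual_px, x$n_points))
  invisible(x)
}

# Trimmed conic fit: iteratively drop points with residuals far above the
# median (noise arcs merged into the rim component by closing).
fit_ellipse_trimmed <- function(points, pixel_size_um = NULL, n_iter = 2,
                                trim_factor = 3) {
  pts <- as.matrix(points)
  fit <- fit_ellipse(pts, pixel_size_um)
  for (it in seq_len(n_iter)) {
    res <- ellipse_point_residuals(fit, pts)
    keep <- res <= trim_factor * stats::median(res)
    if (all(keep) || sum(keep) < 6) break
    pts <- pts[keep, , drop = FALSE]
    fit <- fit_ellipse(pts, pixel_size_um)
  }
  fit
}

# approximate geometric distance of points to a fitted ellipse (px)
ellipse_point_residuals <- function(fit, pts) {
  co <- cos(fit$orientation); so <- sin(fit$orientation)
  dx <- pts[, 1] - fit$center_px[1]; dy <- pts[, 2] - fit$center_px[2]
  xr <- co * dx + so * dy; yr <- -so * dx + co * dy
  Fv <- sqrt((xr / fit$a_px)^2 + (yr / fit$b_px)^2)
  gF <- sqrt((xr / fit$a_px^2)^2 + (yr / fit$b_px^2)^2) / pmax(Fv, 1e-9)
  abs(Fv - 1) / pmax(gF, 1e-9)
}

# bilinear interpolation at 0-based (x, y); clamps to the image border
interp_bilinear <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  x <- pmin(pmax(x, 0), nc - 1); y <- pmin(pmax(y, 0), nr - 1)
  x0 <- pmin(floor(x), nc - 2); y0 <- pmin(floor(y), nr - 2)
  fx <- x - x0; fy <- y - y0
  i00 <- img[cbind(y0 + 1, x0 + 1)]; i01 <- img[cbind(y0 + 1, x0 + 2)]
  i10 <- img[cbind(y0 + 2, x0 + 1)]; i11 <- img[cbind(y0 + 2, x0 + 2)]
  i00 * (1 - fx) * (1 - fy) + i01 * fx * (1 - fy) +
    i10 * (1 - fx) * fy + i11 * fx * fy
}

# Subpixel refinement of an ellipse fit by matched filtering of radial
# intensity profiles. A profile model
#   I(d) = A + B * Phi((d - d0)/ss) + C * exp(-(d - d0)^2 / (2 sr^2))
# (blurred interior/exterior step plus a Gaussian membrane rim sharing the
# same centre) is first fitted to the angle-averaged profile; per angle,
# only the centre d0 is then re-estimated by sliding the frozen-shape model
# along the ray (1-parameter least squares). A curvature correction
# sr^2 * kappa / 2 compensates the inward shift of a blurred curved ridge.
# Angles whose rim signal is weak (e.g. across a macropore arc) are dropped
# and reported via frac_weak.
refine_ellipse_radial <- function(image, fit, n_angles = 180,
                                  halfwidth_px = 6, step_px = 0.25,
                                  min_peak_frac = 0.4) {
  cx <- fit$center_px[1]; cy <- fit$center_px[2]
  phi <- seq(0, 2 * pi, length.out = n_angles + 1)[-(n_angles + 1)]
  co <- cos(fit$orientation); so <- sin(fit$orientation)
  # predicted boundary points of the current fit
  ex <- fit$a_px * cos(phi); ey <- fit$b_px * sin(phi)
  bx <- cx + co * ex - so * ey
  by <- cy + so * ex + co * ey
  r0 <- sqrt((bx - cx)^2 + (by - cy)^2)
  ux <- (bx - cx) / r0; uy <- (by - cy) / r0
  offs <- seq(-halfwidth_px, halfwidth_px, by = step_px)
  m <- length(offs)
  profs <- vapply(seq_len(n_angles), function(i)
    interp_bilinear(image, cx + ux[i] * (r0[i] + offs),
                    cy + uy[i] * (r0[i] + offs)), numeric(m))
  # coarse per-angle rim: extremum of the deviation from the chord between
  # the profile ends (also the weak-rim/pore screen)
  base <- outer(offs - offs[1], (profs[m, ] - profs[1, ]) / (offs[m] - offs[1])) +
    rep(profs[1, ], each = m)
  dev <- profs - base
  jpk <- apply(abs(dev), 2, which.max)
  peak_amp <- abs(dev)[cbind(jpk, seq_len(n_angles))]
  ok0 <- jpk > 1 & jpk < m
  ref_amp <- stats::median(peak_amp[ok0])
  keep <- ok0 & peak_amp >= min_peak_frac * ref_amp
  frac_weak <- 1 - mean(keep)
  if (sum(keep) < max(12, 0.3 * n_angles))
    return(list(fit = fit, refined = FALSE, frac_weak = frac_weak))

  # global profile-shape fit on the angle-averaged profile aligned on the
  # current ellipse (alignment on the rough peaks would skew the average,
  # because their pixel-aliasing scatter is asymmetric)
  dgrid <- offs
  kept <- which(keep)
  P <- rowMeans(profs[, kept, drop = FALSE])
  fit_shape <- function(d0_start) tryCatch({
    fitm <- minpack.lm::nlsLM(
      P ~ A + B * stats::pnorm(dgrid, d0, ss) +
        C * exp(-(dgrid - d0)^2 / (2 * sr^2)),
      start = list(A = P[1], B = P[length(P)] - P[1],
                   C = P[which.max(abs(P - stats::median(P)))] - stats::median(P),
                   d0 = d0_start, ss = 1.5, sr = 1.2),
      lower = c(A = -Inf, B = -Inf, C = -Inf, d0 = -3, ss = 0.3, sr = 0.3),
      upper = c(A = Inf, B = Inf, C = Inf, d0 = 3, ss = 6, sr = 6),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    c(as.list(stats::coef(fitm)), rss = sum(stats::residuals(fitm)^2))
  }, error = function(e) NULL)
  # multi-start in d0: the step/rim composite has shallow side valleys
  cands <- Filter(Negate(is.null), lapply(c(-1.5, 0, 1.5), fit_shape))
  if (length(cands) == 0)
    return(list(fit = fit, refined = FALSE, frac_weak = frac_weak))
  shape <- cands[[which.min(vapply(cands, `[[`, numeric(1), "rss"))]]

  # slide the frozen-shape model along each ray; the SSE in d0 is not
  # unimodal (the rim can lock onto the step), so take the global minimum
  # on a grid and refine it by parabolic interpolation
  d0grid <- seq(shape$d0 - 2.5, shape$d0 + 2.5, by = step_px / 2)
  M <- vapply(d0grid, function(d0)
    shape$A + shape$B * stats::pnorm(offs, d0, shape$ss) +
      shape$C * exp(-(offs - d0)^2 / (2 * shape$sr^2)), numeric(m))
  kap <- fit$a_px * fit$b_px /
    ((fit$a_px * sin(phi))^2 + (fit$b_px * cos(phi))^2)^1.5
  r_ref <- rep(NA_real_, n_angles)
  for (i in kept) {
    sse <- colSums((profs[, i] - M)^2)
    j <- which.min(sse)
    delta <- 0
    if (j > 1 && j < length(sse)) {
      den <- sse[j - 1] - 2 * sse[j] + sse[j + 1]
      if (den > 1e-15) delta <- max(min(0.5 * (sse[j - 1] - sse[j + 1]) / den, 1), -1)
    }
    # a blurred curved ridge peaks inward of the true rim by sr^2 kappa / 2
    r_ref[i] <- r0[i] + d0grid[j] + delta * step_px / 2 +
      shape$sr^2 * kap[i] / 2
  }
  pts <- cbind(cx + ux[kept] * r_ref[kept], cy + uy[kept] * r_ref[kept])
  newfit <- tryCatch(fit_ellipse(pts, pixel_size_um = fit$pixel_size_um),
                     error = function(e) NULL)
  if (is.null(newfit)) return(list(fit = fit, refined = FALSE, frac_weak = frac_weak))
  list(fit = newfit, refined = TRUE, frac_weak = frac_weak,
       shape = shape, keep_angles = keep)
}

# Final polish: fit the full 2-D image model I(p) = S(d(p)) -- the frozen
# radial profile shape S evaluated at the signed distance d(p) to the
# ellipse -- over all pixels in a band around the rim, with the ellipse
# geometry (centre, semi-axes, orientation) free. Every pixel enters once,
# so the estimate approaches the information limit of the frame; per-ray
# resampling cannot (its samples share pixels and their noise correlates).
# Pixels in weak-rim angular sectors (macropore arcs) are excluded.
polish_ellipse_model <- function(image, fit, shape, keep_angles = NULL,
                                 halfband_px = 6.5, free_shape = TRUE) {
  nx <- ncol(image); ny <- nrow(image)
  xs <- rep(0:(nx - 1), each = ny); ys <- rep(0:(ny - 1), times = nx)
  geom_d <- function(p, x, y) {
    dx <- x - p[1]; dy <- y - p[2]
    co <- cos(p[5]); so <- sin(p[5])
    xr <- co * dx + so * dy; yr <- -so * dx + co * dy
    Fv <- sqrt((xr / p[3])^2 + (yr / p[4])^2)
    gF <- sqrt((xr / p[3]^2)^2 + (yr / p[4]^2)^2) / pmax(Fv, 1e-9)
    list(d = (Fv - 1) / pmax(gF, 1e-9), xr = xr, yr = yr)
  }
  select_band <- function(p) {
    g <- geom_d(p, xs, ys)
    sel <- abs(g$d) <= halfband_px
    if (!is.null(keep_angles) && any(!keep_angles)) {
      n_ang <- length(keep_angles)
      ang <- atan2(g$yr / p[4], g$xr / p[3]) %% (2 * pi)
      bin <- pmin(floor(ang / (2 * pi) * n_ang) + 1, n_ang)
      sel <- sel & keep_angles[bin]
    }
    sel
  }
  p0 <- c(fit$center_px[1], fit$center_px[2], fit$a_px, fit$b_px,
          fit$orientation)
  sel <- select_band(p0)
  if (sum(sel) < 50) return(fit)
  # With free_shape the profile shape is fitted jointly with the geometry
  # (single-frame use: freezing a mis-estimated width would push the radius,
  # because the pixel count per distance bin grows with radius). With a
  # well-determined shape -- e.g. pooled over the frames of a sequence --
  # freezing it roughly triples the precision of the semi-axes, because the
  # axis/width degeneracy of the joint fit is removed.
  sh <- c(shape$A, shape$B, shape$C, shape$ss, shape$sr)
  if (free_shape) {
    p0 <- c(p0, sh)
    lo <- c(-Inf, -Inf, 2, 2, -pi, -Inf, -Inf, -Inf, 0.3, 0.3)
    hi <- c(Inf, Inf, Inf, Inf, pi, Inf, Inf, Inf, 6, 6)
  } else {
    lo <- c(-Inf, -Inf, 2, 2, -pi)
    hi <- c(Inf, Inf, Inf, Inf, pi)
  }
  out <- NULL
  for (round in 1:2) {
    x <- xs[sel]; y <- ys[sel]; I <- image[cbind(y + 1, x + 1)]
    resfun <- function(p) {
      q <- if (free_shape) p[6:10] else sh
      d <- geom_d(p, x, y)$d
      I - (q[1] + q[2] * stats::pnorm(d, 0, q[4]) +
             q[3] * exp(-d^2 / (2 * q[5]^2)))
    }
    out <- tryCatch(
      minpack.lm::nls.lm(p0, fn = resfun, lower = lo, upper = hi,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(out) || any(!is.finite(out$par)) || out$par[3] <= 0 ||
        out$par[4] <= 0)
      return(fit)
    p0 <- out$par
    # reselect the pixel band around the updated geometry
    sel <- select_band(p0)
    if (sum(sel) < 50) return(fit)
  }
  p <- out$par
  th <- ((p[5] + pi / 2) %% pi) - pi / 2
  a_px <- p[3]; b_px <- p[4]
  if (abs(cos(th)) < sqrt(0.5)) {       # keep the field-axis labelling
    tmp <- a_px; a_px <- b_px; b_px <- tmp
    th <- ((th + pi) %% pi) - pi / 2
  }
  qf <- if (free_shape) p[6:10] else sh
  res <- list(center_px = c(p[1], p[2]), a_px = a_px, b_px = b_px,
              orientation = th,
              rms_residual_px = sqrt(mean(resfun(p)^2)) / max(abs(qf[3]), 1e-9),
              n_points = length(x))
  if (!is.null(fit$pixel_size_um)) {
    res$a_um <- a_px * fit$pixel_size_um
    res$b_um <- b_px * fit$pixel_size_um
    res$pixel_size_um <- fit$pixel_size_um
  }
  res <- structure(res, class = "ellipse_fit")
  attr(res, "shape") <- list(A = qf[1], B = qf[2], C = qf[3], ss = qf[4],
                             sr = qf[5])
  res
}

# Macropore evidence: sample the image on the fitted boundary and score the
# local rim depth against the fitted profile model. Intact rim: intensity at
# the boundary is approximately A + B/2 + C; across a pore arc the rim term
# is missing (score ~ 0). A pore is called when at least `min_run`
# consecutive angles (after 3-point angular smoothing) score below 0.5.
detect_pore_arc <- function(image, fit, shape, n_angles = 180, min_run = 5) {
  phi <- seq(0, 2 * pi, length.out = n_angles + 1)[-(n_angles + 1)]
  co <- cos(fit$orientation); so <- sin(fit$orientation)
  ex <- fit$a_px * cos(phi); ey <- fit$b_px * sin(phi)
  Ib <- interp_bilinear(image, fit$center_px[1] + co * ex - so * ey,
                        fit$center_px[2] + so * ex + co * ey)
  score <- (shape$A + shape$B / 2 - Ib) / (-shape$C)
  k <- (score + score[c(n_angles, 1:(n_angles - 1))] +
          score[c(2:n_angles, 1)]) / 3
  weak <- k < 0.5
  if (!any(weak)) return(list(pore = FALSE, arc_rad = 0))
  # longest circular run of weak angles
  w2 <- rep(weak, 2)
  r <- rle(w2)
  run <- max(r$lengths[r$values], 0L)
  run <- min(run, n_angles)
  list(pore = run >= min_run, arc_rad = run * 2 * pi / n_angles)
}

#' Mean intensity of the inner vesicle region
#'
#' Mean pixel value inside the ellipse concentric with `fit` whose area is
#' `area_fraction` of the fitted one (semi-axes scaled by
#' `sqrt(area_fraction)`), excluding the bright membrane rim from dye-uptake
#' measurements.
#'
#' @param image numeric matrix.
#' @param fit an [fit_ellipse()] result.
#' @param area_fraction fraction of the fitted ellipse area to sample
#'   (default 0.8).
#' @return mean interior intensity (scalar).
#' @export
inner_region_mean <- function(image, fit, area_fraction = 0.8) {
  stopifnot(inherits(fit, "ellipse_fit"), area_fraction > 0, area_fraction <= 1)
  s <- sqrt(area_fraction)
  a <- fit$a_px * s; b <- fit$b_px * s
  nx <- ncol(image); ny <- nrow(image)
  xs <- matrix(rep(0:(nx - 1), each = ny), nrow = ny) - fit$center_px[1]
  ys <- matrix(rep(0:(ny - 1), times = nx), nrow = ny) - fit$center_px[2]
  co <- cos(fit$orientation); so <- sin(fit$orientation)
  xr <- co * xs + so * ys; yr <- -so * xs + co * ys
  mask <- (xr / a)^2 + (yr / b)^2 <= 1
  if (sum(mask) < 3) stop("inner_region_mean: scaled ellipse smaller than 3 px")
  mean(image[mask])
}
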
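#' Resample a cell outline at equidistant arc-length points
#'
#' Points are placed on the closed polygon at arc lengths 0, spacing,
#' 2*spacing, ... measured from vertex 1, giving `floor(perimeter /
#' spacing)` points; all consecutive gaps equal `spacing` except the closing
#' gap back to the start.
#'
#' @param outline n x 2 matrix of (x, y) polygon vertices (closed implicitly;
#'   a repeated final vertex is tolerated).
#' @param spacing arc-length spacing in pixels (> 0, <= perimeter).
#' @return m x 2 matrix of (x, y) sample points.
#' @export
resample_perimeter <- function(outline, spacing = 2) {
  outline <- as.matrix(outline)
  if (nrow(outline) >= 2L &&
      all(outline[1L, ] == outline[nrow(outline), ]))
    outline <- outline[-nrow(outline), , drop = FALSE]
  if (nrow(outline) < 3L) abort2("degenerate polygon (< 3 vertices)")
  v <- rbind(outline, outline[1L, ])
  seg <- sqrt(rowSums(diff(v)^2))
  if (any(!is.finite(seg)) || sum(seg) <= 0) abort2("degenerate polygon")
  perim <- sum(seg)
  if (spacing <= 0 || spacing > perim)
    abort2("spacing must lie in (0, perimeter = %.1f]", perim)
  m <- floor(perim / spacing)
  s_target <- (seq_len(m) - 1L) * spacing
  cs <- c(0, cumsum(seg))
  edge <- findInterval(s_target, cs, rightmost.closed = TRUE)
  frac <- (s_target - cs[edge]) / seg[edge]
  p0 <- v[edge, , drop = FALSE]
  p1 <- v[edge + 1L, , drop = FALSE]
  pts <- p0 + frac * (p1 - p0)
  colnames(pts) <- c("x", "y")
  pts
}

#' Peak intensity along short normals at perimeter points
#'
#' At each sampled perimeter point the local normal direction is estimated
#' from the neighbouring sample points (tangent = next - previous), oriented
#' outward (away from the outline centroid), and `normal_len` pixels are
#' read by nearest-pixel lookup along it: centred on the point by default
#' (for the classic 3-px normal: one inside, one on, one outside). The
#' reported value is the maximum of the in-bounds samples; a point whose
#' samples all fall outside the image is returned as `NA` (flagged missing).
#'
#' @param image numeric matrix indexed `[y, x]`.
#' @param points m x 2 matrix from [resample_perimeter()].
#' @param normal_len number of pixels along the normal (>= 1).
#' @param mode `"centered"`, `"inward"` or `"outward"` placement of the
#'   normal relative to the perimeter point.
#' @return Numeric vector of length m (NA = missing).
#' @export
sample_normals <- function(image, points, normal_len = 3L,
                           mode = c("centered", "inward", "outward")) {
  mode <- match.arg(mode)
  points <- as.matrix(points)
  m <- nrow(points)
  if (m < 1L) abort2("no perimeter points")
  ctr <- colMeans(points)
  nxt <- points[c(2:m, 1L), , drop = FALSE]
  prv <- points[c(m, 1:(m - 1L)), , drop = FALSE]
  tang <- nxt - prv
  nrm <- cbind(tang[, 2L], -tang[, 1L])
  len <- sqrt(rowSums(nrm^2))
  len[len == 0] <- 1
  nrm <- nrm / len
  outward <- rowSums((points - rep(ctr, each = m)) * nrm) >= 0
  nrm[!outward, ] <- -nrm[!outward, , drop = FALSE]
  offsets <- switch(mode,
    centered = seq_len(normal_len) - 1L - (normal_len - 1L) %/% 2L,
    inward   = -(seq_len(normal_len) - 1L),
    outward  = seq_len(normal_len) - 1L)
  ny <- nrow(image); nx <- ncol(image)
  vapply(seq_len(m), function(i) {
    xs <- round(points[i, 1L] + offsets * nrm[i, 1L])
    ys <- round(points[i, 2L] + offsets * nrm[i, 2L])
    ok <- xs >= 1 & xs <= nx & ys >= 1 & ys <= ny
    if (!any(ok)) return(NA_real_)
    max(image[cbind(ys[ok], xs[ok])])
  }, 0)
}

# even-odd point-in-polygon for a pixel grid, vectorised over pixels
in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    denom <- vy[j] - vy[i]
    if (denom != 0) {
      crosses <- ((vy[i] > py) != (vy[j] > py)) &
        (px < (vx[j] - vx[i]) * (py - vy[i]) / denom + vx[i])
      inside <- xor(inside, crosses)
    }
    j <- i
  }
  inside
}

erode8 <- function(mask, times) {
  for (k in seq_len(times)) {
    m <- mask
    ny <- nrow(m); nx <- ncol(m)
    sh <- function(dy, dx) {
      out <- matrix(FALSE, ny, nx)
      ys <- max(1, 1 + dy):min(ny, ny + dy)
      xs <- max(1, 1 + dx):min(nx, nx + dx)
      out[ys, xs] <- m[ys - dy, xs - dx]
      out
    }
    mask <- m & sh(1, 0) & sh(-1, 0) & sh(0, 1) & sh(0, -1) &
      sh(1, 1) & sh(1, -1) & sh(-1, 1) & sh(-1, -1)
  }
  mask
}

#' Cytosol intensity statistics inside an outlined cell
#'
#' Mean and population standard deviation over interior pixels farther than
#' `margin` pixels from the outline (the interior mask is eroded `margin`
#' times with an 8-neighbour structuring element, which guarantees Euclidean
#' distance > margin), so membrane pixels never contaminate the statistics.
#'
#' @param image numeric matrix `[y, x]`.
#' @param outline n x 2 (x, y) polygon.
#' @param margin erosion margin in pixels (default 3 = the normal reach).
#' @return list(mean, sd, n_pixels).
#' @export
cytosol_stats <- function(image, outline, margin = 3L) {
  outline <- as.matrix(outline)
  xr <- range(outline[, 1L]); yr <- range(outline[, 2L])
  xs <- max(1L, floor(xr[1])):min(ncol(image), ceiling(xr[2]))
  ys <- max(1L, floor(yr[1])):min(nrow(image), ceiling(yr[2]))
  px <- rep(xs, each = length(ys))
  py <- rep(ys, times = length(xs))
  mask <- matrix(in_polygon(px, py, outline[, 1L], outline[, 2L]),
                 nrow = length(ys))
  if (margin > 0L) mask <- erode8(mask, margin)
  if (!any(mask)) abort2("cytosol empty after erosion by %d px", margin)
  vals <- image[ys, xs, drop = FALSE][mask]
  mu <- mean(vals)
  list(mean = mu, sd = sqrt(mean((vals - mu)^2)), n_pixels = length(vals))
}

#' Membrane patch fraction from membrane values and cytosol statistics
#'
#' The patch threshold is `cytosol_mean + sd_mult * cytosol_sd` (default 3
#' standard deviations above the cytosol mean); the patch fraction is the
#' proportion of non-missing membrane values strictly above it.
#'
#' @param membrane_values numeric vector (NA = flagged missing point).
#' @param cytosol_mean,cytosol_sd cytosol statistics.
#' @param sd_mult threshold multiplier (default 3).
#' @param perimeter_points optional m x 2 matrix carried into the result.
#' @return A `patch_result`: list(perimeter_points, membrane_values,
#'   cytosol_mean, cytosol_sd, threshold, n_points, n_missing,
#'   patch_fraction).
#' @export
patch_fraction <- function(membrane_values, cytosol_mean, cytosol_sd,
                           sd_mult = 3, perimeter_points = NULL) {
  ok <- !is.na(membrane_values)
  if (!any(ok)) abort2("no valid membrane values")
  thr <- cytosol_mean + sd_mult * cytosol_sd
  structure(list(perimeter_points = perimeter_points,
                 membrane_values = membrane_values,
                 cytosol_mean = cytosol_mean, cytosol_sd = cytosol_sd,
                 threshold = thr,
                 n_points = sum(ok), n_missing = sum(!ok),
                 patch_fraction = sum(membrane_values[ok] > thr) / sum(ok)),
            class = "patch_result")
}

#' @export
print.patch_result <- function(x, ...) {
  cat(sprintf("<patch_result> %d points (%d missing), threshold %.2f, patch fraction %.3f\n",
              x$n_points, x$n_missing, x$threshold, x$patch_fraction))
  invisible(x)
}

#' Quantify membrane patches on one outlined cell
#'
#' End-to-end wrapper: equidistant perimeter resampling, peak-intensity
#' extraction along short normals, cytosol statistics from the eroded
#' interior, and thresholding at `cytosol_mean + sd_mult * cytosol_sd`.
#'
#' @param image numeric matrix `[y, x]`.
#' @param outline n x 2 (x, y) polygon.
#' @param spacing perimeter sample spacing (px).
#' @param normal_len normal length (px).
#' @param margin cytosol erosion margin (px).
#' @param sd_mult threshold multiplier.
#' @param mode normal placement, see [sample_normals()].
#' @return A `patch_result`.
#' @export
quantify_patches <- function(image, outline, spacing = 2, normal_len = 3L,
                             margin = 3L, sd_mult = 3, mode = "centered") {
  pts <- resample_perimeter(outline, spacing)
  vals <- sample_normals(image, pts, normal_len, mode)
  cs <- cytosol_stats(image, outline, margin)
  patch_fraction(vals, cs$mean, cs$sd, sd_mult, perimeter_points = pts)
}
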
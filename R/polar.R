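# Lumen-centered polar <-> Cartesian resampling.
#
# Conventions (used everywhere in the package): pixel coordinates are
# 0-based, x = column, y = row, origin at the top-left pixel center; angles
# are measured in degrees counterclockwise from the +x axis with the +y axis
# pointing down the image.

#' Centroid of the lumen class
#'
#' @param mask integer class-code matrix (see [oct_classes()]).
#' @return numeric `c(x, y)` in 0-based pixel coordinates, sub-pixel.
#' @export
lumen_center <- function(mask) {
  idx <- which(mask == oct_classes()[["lumen"]], arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    stop("unanalyzable frame: mask contains no lumen pixels")
  }
  c(x = mean(idx[, 2]) - 1, y = mean(idx[, 1]) - 1)
}

# vectorized bilinear sampling at 0-based (x, y); outside -> fill
bilinear_sample <- function(img, x, y, fill = 0) {
  h <- nrow(img); w <- ncol(img)
  out <- rep(fill, length(x))
  inside <- x >= 0 & x <= w - 1 & y >= 0 & y <= h - 1
  if (!any(inside)) return(out)
  xi <- x[inside]; yi <- y[inside]
  x0 <- pmin(floor(xi), w - 2); y0 <- pmin(floor(yi), h - 2)
  fx <- xi - x0; fy <- yi - y0
  i00 <- cbind(y0 + 1, x0 + 1)
  v <- img[i00] * (1 - fx) * (1 - fy) +
    img[cbind(y0 + 1, x0 + 2)] * fx * (1 - fy) +
    img[cbind(y0 + 2, x0 + 1)] * (1 - fx) * fy +
    img[cbind(y0 + 2, x0 + 2)] * fx * fy
  out[inside] <- v
  out
}

# vectorized nearest-neighbour sampling (labels must never blend)
nearest_sample <- function(img, x, y, fill = 0) {
  h <- nrow(img); w <- ncol(img)
  xi <- round(x); yi <- round(y)
  inside <- xi >= 0 & xi <= w - 1 & yi >= 0 & yi <= h - 1
  out <- rep(fill, length(x))
  out[inside] <- img[cbind(yi[inside] + 1, xi[inside] + 1)]
  out
}

#' Resample a frame onto a lumen-centered polar grid
#'
#' Row `a` of the result holds samples along the ray at angle
#' `(a-1) * 360/n_angles`; column `r` holds the sample at radius
#' `(r-1) * radial_step_px`. Bilinear interpolation for images,
#' nearest-neighbour for label masks; samples outside the frame are 0.
#'
#' @param frame numeric matrix.
#' @param center `c(x, y)`, 0-based, must lie inside the frame.
#' @param n_angles angular bins over 360 degrees (default 360, i.e. 1 degree).
#' @param n_radii radial samples; default reaches the farthest frame corner.
#' @param radial_step_px pixels per radial sample.
#' @param interp `"bilinear"` or `"nearest"`.
#' @return A `polar_frame`: list with `values` (n_angles x n_radii), `center`,
#'   `radial_step_px`, `angular_step_deg`.
#' @export
to_polar <- function(frame, center, n_angles = 360, n_radii = NULL,
                     radial_step_px = 1, interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  h <- nrow(frame); w <- ncol(frame)
  cx <- center[[1]]; cy <- center[[2]]
  if (cx < 0 || cx > w - 1 || cy < 0 || cy > h - 1) {
    stop("center lies outside the frame")
  }
  stopifnot(radial_step_px > 0, n_angles >= 1)
  if (is.null(n_radii)) {
    corners_x <- c(0, w - 1, 0, w - 1); corners_y <- c(0, 0, h - 1, h - 1)
    max_r <- max(sqrt((corners_x - cx)^2 + (corners_y - cy)^2))
    n_radii <- floor(max_r / radial_step_px) + 1L
  }
  theta <- (seq_len(n_angles) - 1) * (2 * pi / n_angles)
  radii <- (seq_len(n_radii) - 1) * radial_step_px
  xs <- cx + outer(cos(theta), radii)    # n_angles x n_radii
  ys <- cy + outer(sin(theta), radii)
  sampler <- if (interp == "bilinear") bilinear_sample else nearest_sample
  vals <- matrix(sampler(frame, as.vector(xs), as.vector(ys), fill = 0),
                 nrow = n_angles)
  structure(list(values = vals, center = c(x = cx, y = cy),
                 radial_step_px = radial_step_px,
                 angular_step_deg = 360 / n_angles),
            class = "polar_frame")
}

#' @export
print.polar_frame <- function(x, ...) {
  cat(sprintf("polar frame: %d angles x %d radii, %.3g deg x %.3g px per bin, center (%.1f, %.1f)\n",
              nrow(x$values), ncol(x$values), x$angular_step_deg,
              x$radial_step_px, x$center[1], x$center[2]))
  invisible(x)
}

#' Resample a polar frame back to Cartesian
#'
#' Inverse of [to_polar()]. Pixels beyond the polar radial extent receive
#' `fill` (callers typically blend the result back into the original frame).
#'
#' @param polar a `polar_frame`.
#' @param out_shape `c(height, width)`.
#' @param interp `"bilinear"` or `"nearest"`.
#' @param fill value for pixels without polar support.
#' @return numeric matrix.
#' @export
from_polar <- function(polar, out_shape, interp = c("bilinear", "nearest"),
                       fill = 0) {
  interp <- match.arg(interp)
  h <- out_shape[1]; w <- out_shape[2]
  v <- polar$values
  n_angles <- nrow(v); n_radii <- ncol(v)
  cx <- polar$center[[1]]; cy <- polar$center[[2]]
  xg <- matrix(rep(0:(w - 1), each = h), nrow = h)
  yg <- matrix(rep(0:(h - 1), times = w), nrow = h)
  dx <- xg - cx; dy <- yg - cy
  r <- sqrt(dx^2 + dy^2) / polar$radial_step_px          # radial bin coord
  a <- (atan2(dy, dx) * 180 / pi) %% 360 / polar$angular_step_deg
  out <- matrix(fill, h, w)
  ok <- r <= n_radii - 1
  rv <- r[ok]; av <- a[ok]
  if (interp == "nearest") {
    ai <- (round(av) %% n_angles) + 1
    ri <- round(rv) + 1
    out[ok] <- v[cbind(ai, ri)]
  } else {
    a0 <- floor(av); fa <- av - a0
    r0 <- pmin(floor(rv), n_radii - 2); fr <- rv - r0
    a0i <- (a0 %% n_angles) + 1
    a1i <- ((a0 + 1) %% n_angles) + 1
    out[ok] <- v[cbind(a0i, r0 + 1)] * (1 - fa) * (1 - fr) +
      v[cbind(a1i, r0 + 1)] * fa * (1 - fr) +
      v[cbind(a0i, r0 + 2)] * (1 - fa) * fr +
      v[cbind(a1i, r0 + 2)] * fa * fr
  }
  out
}
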
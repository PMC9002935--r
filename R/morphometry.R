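# Sub-pixel boundary of a mask: marching-squares contour at level 0.5
# (grDevices::contourLines on the zero-padded mask), optionally smoothed
# by a short circular moving average to remove staircase corners.  The
# smoothed polygon is what the perimeter and solidity are measured on;
# raw pixel-edge counting would overestimate the perimeter of smooth
# outlines by up to ~27%.
mask_contour <- function(mask, smooth = 5) {
  mask <- stopifnot_mask(mask)
  pad <- matrix(0, nrow(mask) + 2, ncol(mask) + 2)
  pad[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask * 1
  # contourLines wants z[i, j] at (x[i], y[j]); transpose so x = column
  cl <- grDevices::contourLines(x = seq_len(ncol(pad)) - 1,
                                y = seq_len(nrow(pad)) - 1,
                                z = t(pad), levels = 0.5)
  if (length(cl) == 0) stop("no contour found")
  areas <- vapply(cl, function(p) abs(polygon_area(p$x, p$y)), numeric(1))
  p <- cl[[which.max(areas)]]
  xy <- cbind(x = p$x, y = p$y)
  # drop duplicated closing vertex if present
  if (all(xy[1, ] == xy[nrow(xy), ])) xy <- xy[-nrow(xy), , drop = FALSE]
  if (smooth > 1 && nrow(xy) > 2 * smooth) {
    k <- smooth
    w <- rep(1 / k, k)
    circ <- function(v) {
      n <- length(v)
      vv <- c(v[(n - k + 1):n], v, v[1:k])
      stats::filter(vv, w, sides = 2)[(k + 1):(k + n)]
    }
    xy <- cbind(x = circ(xy[, 1]), y = circ(xy[, 2]))
  }
  xy
}

polygon_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  sum(x[j] * y - x * y[j]) / 2
}

polygon_perimeter <- function(xy) {
  d <- diff(rbind(xy, xy[1, , drop = FALSE]))
  sum(sqrt(rowSums(d^2)))
}

#' Size and shape descriptors of a seed mask
#'
#' Measures the descriptors used throughout seed morphometry, in the
#' ImageJ particle-analysis convention: area `A`, perimeter `P`,
#' best-fit-ellipse major axis `L` and minor axis `W`, aspect ratio
#' `AR = L/W`, circularity `C = 4*pi*A/P^2` and roundness
#' `R = 4*A/(pi*L^2)`.  Irregularities of the outline increase `P` and
#' therefore lower `C`, while `R` depends only on area and major axis
#' and is insensitive to boundary roughness.
#'
#' `A` is the foreground pixel count scaled to mm^2; `P` is the arc
#' length of the smoothed marching-squares boundary polygon; `L` and
#' `W` come from the second-moment best-fit ellipse, rescaled so the
#' ellipse area equals `A` (ImageJ "Fit ellipse").
#'
#' @param mask logical matrix with a single foreground component of at
#'   least 64 pixels.
#' @param mm_per_px physical pixel size (mm per pixel edge).
#' @return one-row data.frame with columns `A` (mm^2), `P`, `L`, `W`
#'   (mm), `AR`, `C`, `R` (dimensionless).
#' @examples
#' disk <- outer(1:81, 1:81, function(r, c) (r - 41)^2 + (c - 41)^2 <= 35^2)
#' measure_mask(disk, mm_per_px = 0.01)
#' @export
measure_mask <- function(mask, mm_per_px = 1) {
  mask <- stopifnot_mask(mask, min_px = 64)
  if (mm_per_px <= 0) stop("mm_per_px must be positive")
  nc <- n_components(mask)
  if (nc > 1)
    stop(sprintf(paste("mask has %d components; segment the image into",
                       "single-seed masks first (see segment_plate)"), nc))
  mo <- mask_moments(mask)
  A_px <- mo$area
  xy <- mask_contour(mask)
  P_px <- polygon_perimeter(xy)
  # second-moment ellipse, area-normalized as in ImageJ's fit
  ev <- eigen(matrix(c(mo$mu20, mo$mu11, mo$mu11, mo$mu02), 2),
              symmetric = TRUE, only.values = TRUE)$values
  a <- 2 * sqrt(max(ev[1], 1e-12))
  b <- 2 * sqrt(max(ev[2], 1e-12))
  sc <- sqrt(A_px / (pi * a * b))
  L_px <- 2 * a * sc
  W_px <- 2 * b * sc
  A <- A_px * mm_per_px^2
  P <- P_px * mm_per_px
  L <- L_px * mm_per_px
  W <- W_px * mm_per_px
  data.frame(A = A, P = P, L = L, W = W,
             AR = L / W,
             C = 4 * pi * A / P^2,
             R = 4 * A / (pi * L^2))
}

#' Convexity classification of a seed outline by solidity
#'
#' A planar region is convex when the straight segment joining any two
#' interior points stays inside the region.  Operationally the mask is
#' labelled by its solidity, the ratio of outline area to convex-hull
#' area, both measured on the sub-pixel boundary polygon.  The default
#' threshold 0.97 tolerates the small hull deficit caused by surface
#' protuberances (colliculae), which are not meant to flip the label.
#'
#' @param mask logical matrix, single foreground component.
#' @param threshold solidity at or above which the outline is labelled
#'   convex.
#' @return list with `solidity`, `label` (`"convex"`/`"nonconvex"`) and
#'   `threshold_used`.
#' @export
classify_convexity <- function(mask, threshold = 0.97) {
  mask <- stopifnot_mask(mask, min_px = 16)
  xy <- mask_contour(mask)
  area <- abs(polygon_area(xy[, 1], xy[, 2]))
  h <- grDevices::chull(xy)
  hull_area <- abs(polygon_area(xy[h, 1], xy[h, 2]))
  solidity <- min(1, area / hull_area)
  list(solidity = solidity,
       label = if (solidity >= threshold) "convex" else "nonconvex",
       threshold_used = threshold)
}
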
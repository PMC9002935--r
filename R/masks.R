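# Binary masks are plain logical matrices in raster convention: row 1 at
# the top, columns increasing to the right.  Pixel (r, c) has its center
# at coordinate (x = c, y = r), 1-based.  Rasterizers own the flip between
# mathematical y-up model coordinates and raster row-down coordinates.

as_mask <- function(x) {
  if (is.logical(x) && is.matrix(x)) return(x)
  if (is.numeric(x) && is.matrix(x)) return(x > 0.5)
  stop("a binary mask must be a logical (or numeric 0/1) matrix")
}

stopifnot_mask <- function(mask, min_px = 1) {
  mask <- as_mask(mask)
  if (sum(mask) < min_px)
    stop(sprintf("mask has %d foreground pixels; at least %d required",
                 sum(mask), min_px))
  mask
}

#' Pixel-count area, centroid and orientation moments of a mask
#'
#' Second-moment summaries in raster coordinates (x = column, y = row).
#' `orientation` is the angle of the major principal axis in radians,
#' measured from the +x (column) axis toward +y (row, downward);
#' for a near-isotropic mask the orientation is undefined and reported
#' as 0 with `orientation_defined = FALSE`.
#'
#' @param mask logical matrix.
#' @return list with `area`, `cx`, `cy`, `mu20`, `mu02`, `mu11`,
#'   `orientation`, `orientation_defined`.
#' @export
mask_moments <- function(mask) {
  mask <- stopifnot_mask(mask)
  idx <- which(mask, arr.ind = TRUE)
  y <- idx[, 1]; x <- idx[, 2]
  n <- length(x)
  cx <- mean(x); cy <- mean(y)
  mu20 <- sum((x - cx)^2) / n
  mu02 <- sum((y - cy)^2) / n
  mu11 <- sum((x - cx) * (y - cy)) / n
  aniso <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  defined <- aniso > 1e-3 * (mu20 + mu02)
  phi <- if (defined) 0.5 * atan2(2 * mu11, mu20 - mu02) else 0
  list(area = n, cx = cx, cy = cy, mu20 = mu20, mu02 = mu02, mu11 = mu11,
       orientation = phi, orientation_defined = defined)
}

mask_bbox <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask has no bounding box")
  c(rmin = min(idx[, 1]), rmax = max(idx[, 1]),
    cmin = min(idx[, 2]), cmax = max(idx[, 2]))
}

crop_mask <- function(mask, margin = 0) {
  b <- mask_bbox(mask)
  r0 <- max(1, b["rmin"] - margin); r1 <- min(nrow(mask), b["rmax"] + margin)
  c0 <- max(1, b["cmin"] - margin); c1 <- min(ncol(mask), b["cmax"] + margin)
  mask[r0:r1, c0:c1, drop = FALSE]
}

pad_mask <- function(mask, nrow_out, ncol_out) {
  if (nrow(mask) > nrow_out || ncol(mask) > ncol_out)
    stop("cannot pad to smaller dimensions")
  out <- matrix(FALSE, nrow_out, ncol_out)
  r0 <- floor((nrow_out - nrow(mask)) / 2)
  c0 <- floor((ncol_out - ncol(mask)) / 2)
  out[r0 + seq_len(nrow(mask)), c0 + seq_len(ncol(mask))] <- mask
  out
}

# connected-component labelling (8-connectivity) via EBImage
label_components <- function(mask) {
  lab <- EBImage::bwlabel(EBImage::as.Image(mask * 1))
  matrix(as.integer(EBImage::imageData(lab)), nrow = nrow(mask))
}

n_components <- function(mask) {
  if (!any(mask)) return(0L)
  max(label_components(mask))
}

largest_component <- function(mask) {
  lab <- label_components(mask)
  if (max(lab) <= 1) return(mask)
  keep <- which.max(tabulate(lab[lab > 0]))
  lab == keep
}

#' Rasterize a geometric model to a binary mask
#'
#' Scales the model so that the height of its bounding box equals
#' `height_px` pixels and fills the enclosed region: a pixel is
#' foreground iff its center lies inside the model curve (even-touch
#' fill).  Row 1 of the mask is the top of the model (the rasterizer
#' owns the y-flip from mathematical to raster coordinates).
#'
#' @param id model identifier (`"DM1"`..`"DM9"`).
#' @param height_px desired foreground bounding-box height in pixels
#'   (>= 16).
#' @param margin_px background border added on all four sides.
#' @return logical matrix with attributes `model_id` and
#'   `units_per_px` (model units per pixel).
#' @examples
#' m <- rasterize_model("DM1", 80)
#' dim(m)
#' @export
rasterize_model <- function(id, height_px, margin_px = 0) {
  if (height_px < 16) stop("height_px must be at least 16")
  if (margin_px < 0) stop("margin_px must be non-negative")
  m <- dm_model(id)
  bnd <- model_boundary(id, n = 2048)
  xr <- range(bnd$x); yr <- range(bnd$y)
  upp <- (yr[2] - yr[1]) / height_px           # model units per pixel
  ncol_fg <- ceiling((xr[2] - xr[1]) / upp)
  nr <- height_px + 2 * margin_px
  nc <- ncol_fg + 2 * margin_px
  # pixel-center coordinates in model units
  xs <- xr[1] + (seq_len(nc) - margin_px - 0.5) * upp
  ys <- yr[2] - (seq_len(nr) - margin_px - 0.5) * upp
  inside <- outer(ys, xs, function(y, x) model_inside(m, x, y))
  mask <- matrix(inside, nrow = nr, ncol = nc)
  if (sum(mask) < 16)
    stop(sprintf("degenerate rasterization of %s: %d foreground pixels",
                 id, sum(mask)))
  attr(mask, "model_id") <- id
  attr(mask, "units_per_px") <- upp
  mask
}
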
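#' Standardize the pose of a seed mask
#'
#' Centers the centroid, rotates the principal axis to vertical with
#' the heavier half (larger-area side along the axis) pointing down,
#' and optionally mirrors so the heavier lateral side is on the right
#' (`canonicalize_flip`), so that mirror-image seeds align to the same
#' pose.  Used before stacking masks into an average silhouette.
#'
#' @param mask logical matrix, single foreground component.
#' @param target_height if non-`NULL`, isotropically rescales so the
#'   foreground bounding-box height equals this many pixels.
#' @param canonicalize_flip logical (default `TRUE`).
#' @param margin_px background border retained around the aligned seed.
#' @return logical matrix (odd dimensions, centroid at the center).
#' @export
align_mask <- function(mask, target_height = NULL, canonicalize_flip = TRUE,
                       margin_px = 4) {
  mask <- stopifnot_mask(mask, min_px = 16)
  mo <- mask_moments(mask)
  s <- 1
  if (!is.null(target_height)) {
    b <- mask_bbox(mask)
    s <- target_height / (b["rmax"] - b["rmin"] + 1)
  }
  # rotate so the major axis lies along +y (columns of the raster)
  delta <- pi / 2 - mo$orientation
  half <- ceiling(s * sqrt(nrow(mask)^2 + ncol(mask)^2) / 2) + margin_px
  side <- 2 * half + 1
  ctr <- half + 1
  rot <- function(phi, flip) {
    warp_mask_cpp(mask * 1, side, side, mo$cx, mo$cy,
                  ctr, ctr, s, phi, flip)
  }
  out <- rot(delta, FALSE)
  rows <- rowSums(out); cols <- colSums(out)
  if (sum(rows[1:half]) > sum(rows[(ctr + 1):side]))  # heavier half down
    out <- rot(delta + pi, FALSE)
  if (canonicalize_flip) {
    cols <- colSums(out)
    if (sum(cols[1:half]) > sum(cols[(ctr + 1):side]))
      out <- out[, side:1, drop = FALSE]              # mirror left-right
  }
  # recenter on the centroid of the result and crop symmetrically
  mo2 <- mask_moments(out)
  b <- mask_bbox(out)
  r <- max(abs(c(b["rmin"] - mo2$cy, b["rmax"] - mo2$cy,
                 b["cmin"] - mo2$cx, b["cmax"] - mo2$cx))) + margin_px
  r <- ceiling(r)
  rows_keep <- round(mo2$cy) + (-r:r)
  cols_keep <- round(mo2$cx) + (-r:r)
  keep <- function(idx, n) idx[idx >= 1 & idx <= n]
  out2 <- matrix(FALSE, 2 * r + 1, 2 * r + 1)
  rk <- keep(rows_keep, nrow(out)); ck <- keep(cols_keep, ncol(out))
  out2[match(rk, rows_keep), match(ck, cols_keep)] <- out[rk, ck]
  out2
}

#' Average silhouette of a stack of seed masks
#'
#' Aligns all masks to a common pose, stacks them, and keeps the
#' pixels covered by at least a fraction `tau` of the masks --- the
#' "darkest area" of the superimposed stack, where most of the seeds
#' coincide.  With `tau = 1` the silhouette is the intersection of the
#' stack; as `tau` approaches `1/N` it approaches the union.  The
#' largest connected component of the thresholded coverage is
#' returned.
#'
#' @param masks list of logical matrices.
#' @param tau coverage fraction in `(0, 1]` (default 0.5: majority
#'   coverage).
#' @param n_min minimum number of masks considered representative
#'   (default 20, as used for real seed populations; lower it for small
#'   experiments).
#' @param align logical: standardize the pose of every mask first
#'   (default `TRUE`; set to `FALSE` when masks are already registered
#'   on a common grid).
#' @param scale_normalize passed to [align_mask] as a common
#'   `target_height` (the median bounding-box height) when `TRUE`;
#'   default `FALSE` (populations are stacked at true scale).
#' @return logical matrix with attribute `coverage` (the per-pixel
#'   count matrix) and `n` (number of masks).
#' @export
average_silhouette <- function(masks, tau = 0.5, n_min = 20, align = TRUE,
                               scale_normalize = FALSE) {
  if (!is.list(masks) || length(masks) < 2)
    stop("at least 2 masks are required")
  if (tau <= 0 || tau > 1) stop("tau must be in (0, 1]")
  if (length(masks) < n_min)
    stop(sprintf("%d masks supplied but n_min = %d; lower n_min if intended",
                 length(masks), n_min))
  n <- length(masks)
  if (align) {
    th <- NULL
    if (scale_normalize) {
      hs <- vapply(masks, function(m) {
        b <- mask_bbox(m); unname(b["rmax"] - b["rmin"] + 1)
      }, numeric(1))
      th <- stats::median(hs)
    }
    masks <- lapply(masks, align_mask, target_height = th)
  }
  nr <- max(vapply(masks, nrow, integer(1)))
  ncl <- max(vapply(masks, ncol, integer(1)))
  nr <- nr + (1 - nr %% 2); ncl <- ncl + (1 - ncl %% 2)  # odd, center-stable
  cov <- matrix(0L, nr, ncl)
  for (m in masks) cov <- cov + pad_mask(m, nr, ncl)
  sil <- cov >= tau * n - 1e-9
  if (any(sil)) sil <- largest_component(sil)
  attr(sil, "coverage") <- cov
  attr(sil, "n") <- n
  sil
}
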
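# Synthetic seed masks with known ground truth.  The generator emulates
# the outline variation seen between individual seeds of one species:
# the model boundary is perturbed radially by a band-limited harmonic
# field (outline-shape noise, not sensor noise), optionally decorated
# with small colliculae bumps, then jittered by a small similarity
# transform as happens when seeds are placed and photographed.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# deterministic per-index substream seed derived from one global seed,
# independent of generation order
substream_seed <- function(seed, i) {
  mix <- (as.double(i) * 1103515245 + 12345) %% 2147483647
  bitwXor(as.integer(seed %% 2147483647), as.integer(mix))
}

#' Generate one synthetic seed mask from a geometric model
#'
#' The boundary of `model_id` is perturbed radially by a band-limited
#' harmonic field with standard deviation `eps` times the mean radius,
#' optionally bumped by `colliculae` narrow protuberances, then
#' rotated, scaled and translated by a small random jitter, and
#' rasterized.  If the perturbation would collapse the outline (radius
#' below 20% of the mean), `eps` is halved until valid and a message is
#' emitted.
#'
#' @param model_id generating model (`"DM1"`..`"DM9"`).
#' @param eps outline noise amplitude as a fraction of the mean radius
#'   (default 0.02).
#' @param harmonics integer range of radial harmonics (default `4:12`).
#' @param rot_deg,scale_range,shift_px jitter ranges: rotation in
#'   degrees, isotropic scale factor, translation in pixels; each drawn
#'   uniformly.
#' @param colliculae number of surface bumps (default 0).
#' @param colliculae_amp bump amplitude as a fraction of mean radius.
#' @param height_px raster height of the un-jittered model (default
#'   160).
#' @param margin_px border (default 12; must absorb the shift jitter).
#' @param rng_seed integer seed making the draw reproducible
#'   (`NULL` uses the current RNG stream).
#' @return logical mask with attribute `truth`: list with the
#'   generating `model_id`, `eps`, and the applied `rotation` (rad),
#'   `scale` and `shift` (px).
#' @examples
#' m <- generate_seed("DM7", eps = 0.02, rng_seed = 1)
#' attr(m, "truth")$model_id
#' @export
generate_seed <- function(model_id, eps = 0.02, harmonics = 4:12,
                          rot_deg = c(-10, 10), scale_range = c(0.93, 1.07),
                          shift_px = c(-3, 3), colliculae = 0,
                          colliculae_amp = 0.015,
                          height_px = 160, margin_px = 12, rng_seed = NULL) {
  if (eps < 0) stop("eps must be non-negative")
  model_id <- match.arg(model_id, dm_ids())
  with_seed(rng_seed, {
    bnd <- model_boundary(model_id, n = 720)
    cx <- mean(bnd$x); cy <- mean(bnd$y)
    dx <- bnd$x - cx; dy <- bnd$y - cy
    r <- sqrt(dx^2 + dy^2)
    psi <- atan2(dy, dx)
    rbar <- mean(r)
    dr <- 0
    if (eps > 0 && length(harmonics) > 0) {
      a <- stats::rnorm(length(harmonics))
      b <- stats::rnorm(length(harmonics))
      f <- rep(0, length(psi))
      for (k in seq_along(harmonics))
        f <- f + a[k] * cos(harmonics[k] * psi) + b[k] * sin(harmonics[k] * psi)
      f <- f / max(stats::sd(f), 1e-12)
      dr <- eps * rbar * f
    }
    if (colliculae > 0) {
      ctr <- stats::runif(colliculae, -pi, pi)
      wid <- 2 * pi / 120
      for (k in seq_len(colliculae)) {
        d <- norm_angle(psi - ctr[k])
        dr <- dr + colliculae_amp * rbar * exp(-0.5 * (d / wid)^2)
      }
    }
    e <- eps
    while (any(r + dr < 0.2 * rbar)) {
      e <- e / 2
      dr <- dr * 0.5
      message(sprintf("outline collapse: damping eps to %.4f", e))
    }
    rr <- r + dr
    x <- cx + rr * cos(psi)
    y <- cy + rr * sin(psi)
    rot <- stats::runif(1, rot_deg[1], rot_deg[2]) * pi / 180
    sc <- stats::runif(1, scale_range[1], scale_range[2])
    sh <- stats::runif(2, shift_px[1], shift_px[2])
    # model units -> pixels (y flip), then jitter about the centroid
    yr <- range(bnd$y)
    upp <- (yr[2] - yr[1]) / height_px
    px <- (x - cx) / upp
    py <- -(y - cy) / upp
    ca <- cos(rot); sa <- sin(rot)
    qx <- sc * (ca * px - sa * py)
    qy <- sc * (sa * px + ca * py)
    half <- ceiling(max(abs(c(qx, qy)))) + margin_px
    ctr_px <- half + 1
    xs <- qx + ctr_px + sh[1]
    ys <- qy + ctr_px + sh[2]
    mask <- polygon_mask_cpp(xs, ys, 2 * half + 1, 2 * half + 1)
    attr(mask, "truth") <- list(model_id = model_id, eps = e,
                                rotation = rot, scale = sc, shift = sh)
    mask
  })
}

#' Generate a population of synthetic seeds
#'
#' Draws `n` independent seeds from one model.  One global `rng_seed`
#' drives a per-seed substream, so seed `i` of a population is the same
#' regardless of `n` or generation order.
#'
#' @inheritParams generate_seed
#' @param n number of seeds (>= 1).
#' @param ... further arguments passed to [generate_seed].
#' @return list with `masks` (list of logical matrices) and `truth`
#'   (data.frame: `id`, `model_id`, `eps`, `rotation`, `scale`,
#'   `shift_x`, `shift_y`).
#' @export
generate_population <- function(model_id, n, eps = 0.02, rng_seed = 1, ...) {
  if (n < 1) stop("n must be at least 1")
  masks <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    m <- generate_seed(model_id, eps = eps,
                       rng_seed = substream_seed(rng_seed, i), ...)
    tr <- attr(m, "truth")
    masks[[i]] <- m
    truth[[i]] <- data.frame(id = i, model_id = tr$model_id, eps = tr$eps,
                             rotation = tr$rotation, scale = tr$scale,
                             shift_x = tr$shift[1], shift_y = tr$shift[2])
  }
  list(masks = masks, truth = do.call(rbind, truth))
}

#' Compose seed masks into a grayscale plate image
#'
#' Emulates a composed photographic plate: dark seeds on a light
#' background arranged on a grid, with mild Gaussian noise and an
#' optional ruler-like dark bar along the bottom border (which touches
#' the image edge, so border-excluding segmentation drops it).
#'
#' @param masks list of logical matrices (at least one).
#' @param ncol_grid number of grid columns (default chosen near
#'   square).
#' @param gap_px clearance between cells in pixels.
#' @param seed_level,bg_level gray levels of foreground/background.
#' @param noise_sd Gaussian noise standard deviation.
#' @param ruler add the ruler artifact (default `FALSE`).
#' @param rng_seed reproducibility seed for the noise.
#' @return numeric matrix in `[0, 1]` with attribute `layout`
#'   (data.frame of cell centers), dark seeds on light background.
#' @export
generate_plate <- function(masks, ncol_grid = NULL, gap_px = 6,
                           seed_level = 0.2, bg_level = 0.85,
                           noise_sd = 0.02, ruler = FALSE, rng_seed = NULL) {
  if (!is.list(masks) || length(masks) == 0)
    stop("at least one mask is required")
  n <- length(masks)
  if (is.null(ncol_grid)) ncol_grid <- ceiling(sqrt(n))
  nrow_grid <- ceiling(n / ncol_grid)
  cell_h <- max(vapply(masks, nrow, integer(1))) + gap_px
  cell_w <- max(vapply(masks, ncol, integer(1))) + gap_px
  H <- nrow_grid * cell_h + gap_px + if (ruler) 12 else 0
  W <- ncol_grid * cell_w + gap_px
  img <- matrix(bg_level, H, W)
  layout <- vector("list", n)
  for (i in seq_len(n)) {
    gr <- (i - 1) %/% ncol_grid
    gc <- (i - 1) %% ncol_grid
    m <- masks[[i]]
    if (nrow(m) > cell_h - gap_px || ncol(m) > cell_w - gap_px)
      stop("masks overlap under the requested layout; enlarge the canvas ",
           "(more columns or a larger gap)")
    r0 <- gap_px + gr * cell_h + floor((cell_h - gap_px - nrow(m)) / 2)
    c0 <- gap_px + gc * cell_w + floor((cell_w - gap_px - ncol(m)) / 2)
    sub <- img[r0 + seq_len(nrow(m)), c0 + seq_len(ncol(m))]
    sub[m] <- seed_level
    img[r0 + seq_len(nrow(m)), c0 + seq_len(ncol(m))] <- sub
    layout[[i]] <- data.frame(id = i, row = r0 + nrow(m) / 2,
                              col = c0 + ncol(m) / 2)
  }
  if (ruler) img[(H - 3):H, ] <- seed_level / 2
  img <- with_seed(rng_seed,
                   img + matrix(stats::rnorm(length(img), 0, noise_sd),
                                nrow(img)))
  img <- pmin(pmax(img, 0), 1)
  attr(img, "layout") <- do.call(rbind, layout)
  img
}
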
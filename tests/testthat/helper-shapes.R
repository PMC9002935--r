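# Geometric fixtures built in code, plus independent oracles used
# against the fitting machinery.

disk_mask <- function(r, pad = 5, center_off = c(0, 0)) {
  n <- 2 * (r + pad) + 1
  ctr <- r + pad + 1
  outer(seq_len(n), seq_len(n), function(i, j)
    (i - ctr - center_off[1])^2 + (j - ctr - center_off[2])^2 <= r^2)
}

ellipse_mask <- function(a, b, pad = 5) {
  # a = semi-axis along columns, b = semi-axis along rows
  nr <- 2 * (b + pad) + 1
  ncl <- 2 * (a + pad) + 1
  cr <- b + pad + 1; cc <- a + pad + 1
  outer(seq_len(nr), seq_len(ncl), function(i, j)
    ((j - cc) / a)^2 + ((i - cr) / b)^2 <= 1)
}

# integer translation on a fixed canvas
shift_mask <- function(mask, dr, dc) {
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  src_r <- seq_len(nrow(mask)) - dr
  src_c <- seq_len(ncol(mask)) - dc
  ok_r <- src_r >= 1 & src_r <= nrow(mask)
  ok_c <- src_c >= 1 & src_c <= ncol(mask)
  out[ok_r, ok_c] <- mask[src_r[ok_r], src_c[ok_c]]
  out
}

# 2x downsampling by block majority (block mean >= 0.5)
downsample2 <- function(mask) {
  nr <- floor(nrow(mask) / 2); ncl <- floor(ncol(mask) / 2)
  m <- mask[seq_len(2 * nr), seq_len(2 * ncl)]
  q <- m[seq(1, 2 * nr, 2), seq(1, 2 * ncl, 2)] +
    m[seq(2, 2 * nr, 2), seq(1, 2 * ncl, 2)] +
    m[seq(1, 2 * nr, 2), seq(2, 2 * ncl, 2)] +
    m[seq(2, 2 * nr, 2), seq(2, 2 * ncl, 2)]
  q >= 2
}

# Exhaustive grid search over the similarity transform around the
# moment initializer: the independent oracle for the optimizer.
brute_force_J <- function(seed, model_mask,
                          dt = -5:5, ds = seq(0.9, 1.1, by = 0.02),
                          dphi_deg = -10:10) {
  mm <- seedshape::mask_moments(model_mask)
  tr0 <- seedshape::initial_alignment(seed, model_mask)
  model_num <- model_mask * 1
  best <- -1
  for (dx in dt) for (dy in dt) for (f_s in ds) for (dp in dphi_deg) {
    ct <- seedshape:::overlap_counts_cpp(seed, model_num, mm$cx, mm$cy,
                                         tr0$tx + dx, tr0$ty + dy,
                                         tr0$s * f_s,
                                         tr0$phi + dp * pi / 180, tr0$flip)
    j <- 100 * ct[1] / ct[2]
    if (j > best) best <- j
  }
  best
}

# similarity-warp a mask on its own (padded) canvas, for pose tests
warp_on_canvas <- function(mask, s = 1, phi = 0, flip = FALSE, pad = 8) {
  mo <- seedshape::mask_moments(mask)
  half <- ceiling(s * sqrt(nrow(mask)^2 + ncol(mask)^2) / 2) + pad
  side <- 2 * half + 1
  seedshape:::warp_mask_cpp(mask * 1, side, side, mo$cx, mo$cy,
                            half + 1, half + 1, s, phi, flip)
}
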
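#' Percent of shared area between two masks on the same grid (J index)
#'
#' \eqn{J = S/T \times 100}, where `S` is the number of pixels
#' foreground in both masks and `T` the number foreground in either.
#' `J` is 100 iff the foregrounds coincide pixel for pixel and 0 iff
#' they are disjoint; an empty union is an error, not a 0.
#'
#' @param a,b logical matrices of identical dimensions.
#' @return the J index, a percent in `[0, 100]`.
#' @examples
#' a <- matrix(FALSE, 5, 5); a[2:4, 2:4] <- TRUE
#' jaccard_percent(a, a)
#' @export
jaccard_percent <- function(a, b) {
  a <- as_mask(a); b <- as_mask(b)
  if (!all(dim(a) == dim(b)))
    stop("masks must share a pixel grid (identical dimensions)")
  s <- sum(a & b)
  t <- sum(a | b)
  if (t == 0) stop("both masks are empty: J index is undefined")
  100 * s / t
}

norm_angle <- function(phi) {
  phi <- (phi + pi) %% (2 * pi) - pi
  ifelse(phi <= -pi, phi + 2 * pi, phi)
}

new_transform <- function(tx, ty, s, phi, flip) {
  list(tx = tx, ty = ty, s = s, phi = norm_angle(phi), flip = flip)
}

# raw counts for a transform; returns c(S_hard, T_hard, S_soft, T_soft)
transform_counts <- function(seed, model_num, mc, tr) {
  overlap_counts_cpp(seed, model_num, mc$cx, mc$cy,
                     tr$tx, tr$ty, tr$s, tr$phi, tr$flip)
}

#' Initial superposition of a model on a seed mask
#'
#' Moment-based initializer for the J-index optimization: centroids are
#' matched, scale is set from the area ratio, and the principal axes
#' are aligned.  Both principal-axis polarities and both mirror states
#' give four candidate transforms; the one with the highest J is
#' returned, with all four attached as attribute `"candidates"`.
#' For a near-isotropic mask the orientation is undefined; it is taken
#' as 0 and a message is emitted.
#'
#' @param seed,model logical matrices, single foreground component each.
#' @return a similarity transform: list `tx`, `ty` (seed-grid position
#'   of the model centroid, px), `s` (isotropic scale), `phi` (rotation,
#'   radians in `(-pi, pi]`), `flip` (mirror about the model's vertical
#'   axis, applied before rotation).
#' @export
initial_alignment <- function(seed, model) {
  seed <- stopifnot_mask(seed); model <- stopifnot_mask(model)
  ms <- mask_moments(seed)
  mm <- mask_moments(model)
  if (!ms$orientation_defined || !mm$orientation_defined)
    message("near-circular mask: principal orientation undefined, using 0")
  s0 <- sqrt(ms$area / mm$area)
  cands <- list()
  for (flip in c(FALSE, TRUE)) {
    phim <- if (flip) -mm$orientation else mm$orientation
    for (k in 0:1)
      cands[[length(cands) + 1]] <-
        new_transform(ms$cx, ms$cy, s0, ms$orientation - phim + k * pi, flip)
  }
  model_num <- model * 1
  mc <- list(cx = mm$cx, cy = mm$cy)
  js <- vapply(cands, function(tr) {
    ct <- transform_counts(seed, model_num, mc, tr)
    100 * ct[1] / ct[2]
  }, numeric(1))
  best <- cands[[which.max(js)]]
  attr(best, "candidates") <- cands
  attr(best, "candidate_J") <- js
  best
}

# Core fit of one model mask onto one seed mask: moment initialization
# from four candidates, then Nelder-Mead refinement of
# (tx, ty, log s, phi) on the soft (fractional-coverage) overlap, which
# smooths the piecewise-constant pixel-count objective.  The hard
# pixel-count J is tracked at every evaluation and the best hard J ever
# seen is reported, so the result can never fall below the initializer.
fit_one <- function(seed, model_mask, maxit = 200, refine = TRUE,
                    n_refine = 2) {
  seed <- stopifnot_mask(seed)
  model_num <- model_mask * 1
  mm <- mask_moments(model_mask)
  mc <- list(cx = mm$cx, cy = mm$cy)
  init <- initial_alignment(seed, model_mask)
  cands <- attr(init, "candidates")
  best <- list(J = -1, S = NA, T = NA, transform = NULL)
  consider <- function(tr, ct) {
    j <- 100 * ct[1] / ct[2]
    if (j > best$J)
      best <<- list(J = j, S = ct[1], T = ct[2], transform = tr)
    j
  }
  j_init <- vapply(cands, function(tr)
    consider(tr, transform_counts(seed, model_num, mc, tr)), numeric(1))
  converged <- TRUE
  if (refine) {
    log_s0 <- log(cands[[1]]$s)
    starts <- cands[order(j_init, decreasing = TRUE)]
    starts <- starts[seq_len(min(n_refine, length(starts)))]
    for (tr0 in starts) {
      fn <- function(par) {
        ls <- log(tr0$s) + par[3]
        if (abs(ls - log_s0) > log(2)) return(1e6)  # scale collapse guard
        tr <- new_transform(tr0$tx + par[1], tr0$ty + par[2],
                            exp(ls), tr0$phi + par[4], tr0$flip)
        ct <- transform_counts(seed, model_num, mc, tr)
        consider(tr, ct)
        -100 * ct[3] / ct[4]
      }
      op <- stats::optim(c(0, 0, 0, 0), fn, method = "Nelder-Mead",
                         control = list(maxit = maxit, reltol = 1e-4,
                                        parscale = c(2, 2, 0.3, 0.3)))
      if (op$convergence != 0) converged <- FALSE
    }
  }
  if (!converged)
    warning("iteration cap reached for at least one start; ",
            "returning best transform found", call. = FALSE)
  list(J = best$J, S = unname(best$S), T = unname(best$T),
       transform = best$transform, converged = converged)
}

#' Fit geometric models to a seed mask by maximizing the J index
#'
#' The central fitting routine: each requested model is rasterized to
#' the seed's scale and superimposed on the seed mask "searching a
#' maximum coincidence" --- the percent shared area (J index) is
#' maximized over a similarity transform (translation, isotropic scale,
#' rotation, optional mirror).  The model is resampled onto the seed
#' grid, so the seed pixel counts are identical across models.
#'
#' A fit is conventionally called good when `J > 90`.
#'
#' @param seed logical matrix: binary seed mask, single foreground
#'   component.
#' @param models character vector of model ids to fit (default all
#'   nine).
#' @param height_px raster height for the model masks; defaults to the
#'   seed's foreground bounding-box height so the initial scale is
#'   close to 1.
#' @param maxit Nelder-Mead iteration cap per start (default 200).
#' @param refine logical; `FALSE` stops at the moment-based initializer.
#' @param n_refine how many of the four initial candidates (ranked by
#'   their initial J) are refined (default 2; 4 refines all).
#' @return an object of class `jfit`: list with `fits` (data.frame with
#'   one row per model: `model`, `J`, `S`, `T`, `tx`, `ty`, `s`, `phi`,
#'   `flip`, `converged`), `best_model`, `results` (per-model detail),
#'   and the seed mask.  Rows are ordered by model id; `best_model` is
#'   the highest J, ties broken toward the lower model ordinal.
#' @examples
#' seed <- rasterize_model("DM1", 64, margin_px = 6)
#' f <- jfit(seed, models = c("DM1", "DM2"), maxit = 50)
#' f$best_model
#' @export
jfit <- function(seed, models = dm_ids(), height_px = NULL,
                 maxit = 200, refine = TRUE, n_refine = 2) {
  seed <- stopifnot_mask(seed, min_px = 16)
  models <- match.arg(models, dm_ids(), several.ok = TRUE)
  if (length(models) == 0) stop("at least one model id is required")
  models <- sort(unique(models))
  if (n_components(seed) > 1)
    stop("seed mask must have a single component; see segment_plate()")
  if (is.null(height_px)) {
    b <- mask_bbox(seed)
    height_px <- max(24, b["rmax"] - b["rmin"] + 1)
  }
  results <- lapply(models, function(id) {
    mmask <- rasterize_model(id, height_px, margin_px = 2)
    r <- fit_one(seed, mmask, maxit = maxit, refine = refine,
                 n_refine = n_refine)
    r$model_id <- id
    r
  })
  names(results) <- models
  fits <- do.call(rbind, lapply(results, function(r) {
    tr <- r$transform
    data.frame(model = r$model_id, J = r$J, S = r$S, T = r$T,
               tx = tr$tx, ty = tr$ty, s = tr$s, phi = tr$phi,
               flip = tr$flip, converged = r$converged,
               stringsAsFactors = FALSE)
  }))
  rownames(fits) <- NULL
  structure(list(fits = fits,
                 best_model = fits$model[which.max(fits$J)],
                 results = results,
                 seed = seed,
                 height_px = height_px,
                 call = match.call()),
            class = "jfit")
}

#' @export
print.jfit <- function(x, ...) {
  cat("J-index model fit\n")
  tab <- x$fits[, c("model", "J", "S", "T")]
  tab$J <- round(tab$J, 1)
  print(tab, row.names = FALSE)
  cat(sprintf("best model: %s (J = %.1f%s)\n", x$best_model,
              max(x$fits$J),
              if (max(x$fits$J) > 90) ", good adjustment" else ""))
  invisible(x)
}

#' @export
summary.jfit <- function(object, ...) {
  fits <- object$fits
  out <- list(best_model = object$best_model,
              best_J = max(fits$J),
              good = max(fits$J) > 90,
              n_models = nrow(fits),
              fits = fits)
  class(out) <- "summary.jfit"
  out
}

#' @export
print.summary.jfit <- function(x, ...) {
  cat(sprintf("%d models fitted; best %s with J = %.1f (%s adjustment)\n",
              x$n_models, x$best_model, x$best_J,
              if (x$good) "good" else "no good"))
  print(x$fits, row.names = FALSE)
  invisible(x)
}

#' @export
coef.jfit <- function(object, model = object$best_model, ...) {
  tr <- object$results[[model]]$transform
  c(tx = tr$tx, ty = tr$ty, s = tr$s, phi = tr$phi, flip = as.numeric(tr$flip))
}

#' Warped model mask for a fitted transform
#'
#' Resamples a fitted model onto the seed grid of a [jfit] object,
#' which is how `S` and `T` were counted.
#'
#' @param object a `jfit` object.
#' @param model model id (default the best model).
#' @return logical matrix on the seed grid.
#' @export
warped_model <- function(object, model = object$best_model) {
  stopifnot(inherits(object, "jfit"))
  r <- object$results[[model]]
  mmask <- rasterize_model(model, object$height_px, margin_px = 2)
  mm <- mask_moments(mmask)
  tr <- r$transform
  warp_mask_cpp(mmask * 1, nrow(object$seed), ncol(object$seed),
                mm$cx, mm$cy, tr$tx, tr$ty, tr$s, tr$phi, tr$flip)
}

#' @export
plot.jfit <- function(x, model = x$best_model, ...) {
  seed <- x$seed
  w <- warped_model(x, model)
  nr <- nrow(seed); ncl <- ncol(seed)
  disp <- matrix(1, nr, ncl)
  disp[seed & !w] <- 0.35   # seed only
  disp[!seed & w] <- 0.7    # model only
  disp[seed & w] <- 0       # shared
  graphics::image(x = seq_len(ncl), y = seq_len(nr),
                  z = t(disp[nr:1, , drop = FALSE]),
                  col = grDevices::gray.colors(64, 0, 1),
                  asp = 1, axes = FALSE, xlab = "", ylab = "",
                  main = sprintf("%s, J = %.1f", model,
                                 x$fits$J[x$fits$model == model]), ...)
  invisible(x)
}
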
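#' Read a grayscale seed image
#'
#' Reads a PNG or TIFF image and collapses color channels to one
#' grayscale matrix in `[0, 1]`.
#'
#' @param path file path; format chosen by extension (`.png`, `.tif`,
#'   `.tiff`).
#' @return numeric matrix in `[0, 1]`, row 1 the top of the image.
#' @export
read_seed_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, " (use PNG or TIFF)"))
  if (length(dim(img)) == 3) {
    k <- min(3, dim(img)[3])
    img <- apply(img[, , seq_len(k), drop = FALSE], c(1, 2), mean)
  }
  if (!is.matrix(img)) stop("unsupported image layout in ", path)
  img
}

#' Threshold a grayscale image into a binary seed mask
#'
#' Global thresholding with Otsu's method (the default) or a fixed
#' level.  `polarity = "dark_seeds"` selects pixels darker than the
#' threshold as foreground, as in photographs of dark seeds on a light
#' background.
#'
#' @param x either a file path (passed to [read_seed_image]) or a
#'   numeric matrix in `[0, 1]`.
#' @param mode `"otsu"` or `"fixed"`.
#' @param level threshold in `[0, 1]`; required iff `mode = "fixed"`.
#' @param polarity `"dark_seeds"` (default) or `"light_seeds"`.
#' @return list with `image` (grayscale matrix), `mask` (logical
#'   matrix) and `threshold` (the level used).
#' @export
read_and_binarize <- function(x, mode = c("otsu", "fixed"), level = NULL,
                              polarity = c("dark_seeds", "light_seeds")) {
  mode <- match.arg(mode)
  polarity <- match.arg(polarity)
  img <- if (is.character(x)) read_seed_image(x) else x
  if (!is.matrix(img) || !is.numeric(img))
    stop("expected a grayscale matrix or an image path")
  if (mode == "fixed") {
    if (is.null(level)) stop("mode = \"fixed\" requires a threshold level")
    thr <- level
  } else {
    if (!is.null(level)) stop("level is only used with mode = \"fixed\"")
    thr <- EBImage::otsu(EBImage::as.Image(img), range = c(0, 1))
  }
  mask <- if (polarity == "dark_seeds") img < thr else img > thr
  list(image = img, mask = mask, threshold = thr)
}

#' Split a plate mask into single-seed masks
#'
#' Labels connected components (8-connectivity), filters them by
#' minimum area, optionally drops components touching the image border
#' (e.g. a ruler placed along one edge), and returns each survivor as
#' its own cropped mask together with its bounding box in the plate.
#'
#' @param mask logical matrix of the whole plate.
#' @param min_area_px smallest component kept (default 64).
#' @param exclude_border drop components touching the border
#'   (default `FALSE`).
#' @param margin_px background border kept around each cropped seed.
#' @return list with `masks` (list of logical matrices) and `boxes`
#'   (data.frame: `id`, `rmin`, `rmax`, `cmin`, `cmax`, `area_px`;
#'   0-based offsets are `rmin - 1`, `cmin - 1`).
#' @export
segment_plate <- function(mask, min_area_px = 64, exclude_border = FALSE,
                          margin_px = 3) {
  mask <- as_mask(mask)
  if (!any(mask)) stop("empty mask: nothing to segment")
  lab <- label_components(mask)
  n0 <- max(lab)
  sizes <- tabulate(lab[lab > 0], nbins = n0)
  keep <- which(sizes >= min_area_px)
  if (exclude_border) {
    border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    keep <- setdiff(keep, border[border > 0])
  }
  if (length(keep) == 0)
    stop(sprintf(paste("no components left: %d found, %d passed the",
                       "min_area_px = %d filter, %d after border exclusion"),
                 n0, sum(sizes >= min_area_px), min_area_px, length(keep)))
  out <- vector("list", length(keep))
  boxes <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    comp <- lab == keep[i]
    b <- mask_bbox(comp)
    out[[i]] <- crop_mask(comp, margin = margin_px)
    boxes[[i]] <- data.frame(id = i, rmin = b["rmin"], rmax = b["rmax"],
                             cmin = b["cmin"], cmax = b["cmax"],
                             area_px = sizes[keep[i]])
  }
  boxes <- do.call(rbind, boxes)
  rownames(boxes) <- NULL
  list(masks = out, boxes = boxes)
}

#' Write and read binary masks as 8-bit PNG
#'
#' Masks are stored as 0 (background) / 255 (foreground) 8-bit
#' grayscale PNG, a lossless round trip.
#'
#' @param mask logical matrix.
#' @param path output path.
#' @return `write_mask_png`: the path, invisibly. `read_mask_png`: the
#'   logical matrix.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(as_mask(mask) * 1, path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  img <- read_seed_image(path)
  img > 0.5
}

# JSON run log written beside CLI outputs for reproducibility
write_run_log <- function(path, command, config) {
  log <- list(command = command, config = config,
              r_version = as.character(getRversion()),
              package_version = as.character(utils::packageVersion("seedshape")),
              timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(log, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
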
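#' Bright-field film micrographs with a physical pixel scale
#'
#' A `film_image` wraps an H x W x 3 sRGB pixel array (values in `[0,1]`)
#' together with the physical scale in mm per pixel and an optional logical
#' mask of valid pixels (TRUE = analyse).
#'
#' @param pixels numeric array `c(height, width, 3)` with values in `[0,1]`.
#' @param scale_mm_per_px physical pixel size in mm (> 0); must be supplied
#'   explicitly, it is never inferred from file metadata.
#' @param mask optional logical matrix `height x width`.
#' @return An object of class `film_image`.
#' @export
film_image <- function(pixels, scale_mm_per_px, mask = NULL) {
  stopifnot(is.array(pixels), length(dim(pixels)) == 3L, dim(pixels)[3] == 3L)
  if (any(pixels < 0 | pixels > 1)) {
    stop("pixel values must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(scale_mm_per_px) || scale_mm_per_px <= 0) {
    stop("scale_mm_per_px must be > 0", call. = FALSE)
  }
  if (!is.null(mask)) {
    stopifnot(is.logical(mask), all(dim(mask) == dim(pixels)[1:2]))
  }
  structure(list(pixels = pixels, scale_mm_per_px = scale_mm_per_px,
                 mask = mask), class = "film_image")
}

#' Read a film micrograph from PNG or TIFF
#'
#' @param path image file (`.png`, `.tif`/`.tiff`); 8- or 16-bit; an alpha
#'   channel, if present, is dropped; grayscale is replicated to RGB.
#' @inheritParams film_image
#' @return A [film_image()].
#' @export
read_film_image <- function(path, scale_mm_per_px, mask = NULL) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  if (length(dim(px)) == 2L) px <- array(rep(px, 3), dim = c(dim(px), 3))
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]
  film_image(px, scale_mm_per_px, mask = mask)
}

# pixel matrix (n x 3 sRGB) of unmasked pixels plus their linear indices
unmasked_pixels <- function(image) {
  d <- dim(image$pixels)
  mat <- cbind(as.vector(image$pixels[, , 1]),
               as.vector(image$pixels[, , 2]),
               as.vector(image$pixels[, , 3]))
  idx <- seq_len(d[1] * d[2])
  if (!is.null(image$mask)) idx <- idx[as.vector(image$mask)]
  list(colors = mat[idx, , drop = FALSE], idx = idx, dim = d[1:2])
}

# k-means++ seeding (Arthur & Vassilvitskii): spread initial centres by
# sampling points with probability proportional to squared distance from
# the nearest centre chosen so far.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- colSums((t(x) - centers[1, ])^2)
  for (j in seq_len(k - 1L) + 1L) {
    if (all(d2 == 0)) {
      stop("fewer distinct colours than clusters", call. = FALSE)
    }
    centers[j, ] <- x[sample.int(n, 1, prob = d2), ]
    d2 <- pmin(d2, colSums((t(x) - centers[j, ])^2))
  }
  centers
}

#' Segment a film micrograph into apparent-colour regions by k-means
#'
#' Clusters per-pixel colours with Lloyd's algorithm seeded by k-means++,
#' identifying regions of approximately constant interference colour and
#' hence approximately constant thickness. Clustering distances are taken
#' in CIE Lab by default (perceptual); clusters are renumbered by
#' decreasing pixel count, and the run is deterministic given `seed`.
#'
#' @param image a [film_image()].
#' @param k number of clusters (>= 2); 3 suits a typical drop-cast film
#'   with centre, annulus and rim regions.
#' @param seed integer RNG seed for the k-means++ initialisation.
#' @param color_space `"Lab"` (default) or `"sRGB"`.
#' @param max_iter Lloyd iteration cap.
#' @return An object of class `segmentation_result`: `labels` (integer
#'   matrix, `-1` for masked-out pixels), `centers_srgb` (k x 3 mean sRGB
#'   per cluster), `pixel_counts`, `areas_mm2`, `seed`, `iterations`,
#'   `color_space`.
#' @export
segment_kmeans <- function(image, k = 3L, seed = 1L,
                           color_space = c("Lab", "sRGB"),
                           max_iter = 300L) {
  stopifnot(inherits(image, "film_image"), k >= 2L)
  color_space <- match.arg(color_space)
  up <- unmasked_pixels(image)
  n <- nrow(up$colors)
  if (n < k) stop("fewer unmasked pixels than clusters", call. = FALSE)
  distinct <- nrow(unique(up$colors))
  if (distinct < k) {
    stop("degenerate clustering: only ", distinct,
         " distinct colours for k = ", k, call. = FALSE)
  }
  feats <- if (color_space == "Lab") srgb_to_lab(up$colors) else up$colors
  km <- with_private_seed(seed, {
    centers <- kmeanspp_centers(feats, k)
    kmeans(feats, centers = centers, iter.max = max_iter,
           algorithm = "Lloyd")
  })
  # renumber clusters by decreasing area
  ord <- order(km$size, decreasing = TRUE)
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  cl <- relabel[km$cluster]

  labels <- matrix(-1L, up$dim[1], up$dim[2])
  labels[up$idx] <- cl
  counts <- tabulate(cl, nbins = k)
  centers_srgb <- t(vapply(seq_len(k), function(j) {
    colMeans(up$colors[cl == j, , drop = FALSE])
  }, numeric(3)))
  colnames(centers_srgb) <- c("R", "G", "B")
  structure(list(labels = labels,
                 centers_srgb = centers_srgb,
                 pixel_counts = counts,
                 areas_mm2 = counts * image$scale_mm_per_px^2,
                 seed = seed,
                 iterations = km$iter,
                 color_space = color_space,
                 scale_mm_per_px = image$scale_mm_per_px),
            class = "segmentation_result")
}

#' Per-cluster areas of a segmentation
#'
#' @param result a [segment_kmeans()] result.
#' @param scale_mm_per_px pixel size in mm; defaults to the scale recorded
#'   in the segmentation.
#' @return Numeric vector of areas in mm^2, one per cluster; their sum
#'   equals the total unmasked area exactly.
#' @export
region_areas <- function(result, scale_mm_per_px = result$scale_mm_per_px) {
  stopifnot(inherits(result, "segmentation_result"), scale_mm_per_px > 0)
  result$pixel_counts * scale_mm_per_px^2
}

#' Estimate film volume from region areas and thicknesses
#'
#' Each region contributes `area (mm^2) x thickness (nm)`; since
#' 1 mm^2 x 1 nm = 1000 um^3, the products are reported directly in units
#' of 10^3 um^3 along with their total.
#'
#' @param areas_mm2 per-region areas in mm^2 (optionally named).
#' @param thicknesses_nm per-region thicknesses in nm, same regions and
#'   order (names, if given on both, must match).
#' @return A list with `per_region` (in 10^3 um^3) and `total`.
#' @examples
#' estimate_film_volume(c(2.0, 0.9, 0.5), c(17, 96, 151))
#' @export
estimate_film_volume <- function(areas_mm2, thicknesses_nm) {
  if (length(areas_mm2) != length(thicknesses_nm)) {
    stop("areas and thicknesses describe different region sets", call. = FALSE)
  }
  if (!is.null(names(areas_mm2)) && !is.null(names(thicknesses_nm)) &&
      !identical(names(areas_mm2), names(thicknesses_nm))) {
    stop("region ids of areas and thicknesses do not match", call. = FALSE)
  }
  if (any(areas_mm2 < 0) || any(thicknesses_nm < 0)) {
    stop("areas and thicknesses must be >= 0", call. = FALSE)
  }
  per <- areas_mm2 * thicknesses_nm   # mm^2 * nm = 10^3 um^3
  list(per_region = per, total = sum(per))
}

#' Write segmentation outputs
#'
#' Writes an indexed label map as a grayscale PNG (labels scaled to
#' `[0,1]`, masked pixels black) and a CSV summary with per-cluster pixel
#' counts, areas and (optionally) thicknesses and volumes.
#'
#' @param result a [segment_kmeans()] result.
#' @param png_path,csv_path output paths (either may be `NULL` to skip).
#' @param thicknesses_nm optional per-cluster thicknesses for the summary.
#' @export
write_segmentation <- function(result, png_path = NULL, csv_path = NULL,
                               thicknesses_nm = NULL) {
  stopifnot(inherits(result, "segmentation_result"))
  if (!is.null(png_path)) {
    k <- length(result$pixel_counts)
    img <- ifelse(result$labels < 0, 0, result$labels / k)
    png::writePNG(img, png_path)
  }
  if (!is.null(csv_path)) {
    d <- data.frame(cluster = seq_along(result$pixel_counts),
                    pixels = result$pixel_counts,
                    area_mm2 = result$areas_mm2)
    if (!is.null(thicknesses_nm)) {
      vol <- estimate_film_volume(result$areas_mm2, thicknesses_nm)
      d$thickness_nm <- thicknesses_nm
      d$volume_1e3_um3 <- vol$per_region
    }
    write.csv(d, csv_path, row.names = FALSE, quote = FALSE)
  }
  invisible(result)
}
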
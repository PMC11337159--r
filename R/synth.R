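#' Synthetic noisy contrast spectra with known ground truth
#'
#' Simulates the contrast spectrum of a film of known thickness and adds
#' additive Gaussian noise in contrast units, emulating a microreflectance
#' measurement. The generator is a pure function of its arguments: the
#' same seed always yields the same spectrum, and the caller's RNG state is
#' left untouched. The true parameters are attached as the
#' `ground_truth` attribute (and written as a JSON sidecar by
#' [write_synth()]).
#'
#' @param t_true true film thickness in nm.
#' @param sigma additive contrast noise standard deviation; 0.01 is
#'   representative of a well-aligned microreflectance setup.
#' @param seed integer RNG seed.
#' @param grid wavelength grid in nm.
#' @param oxide_thickness oxide thickness in nm.
#' @param materials stack materials, see [default_materials()].
#' @return A [contrast_spectrum()] with attribute `ground_truth` (list of
#'   the generating parameters). Noise is clipped to keep `|C| <= 1`.
#' @examples
#' s <- synth_contrast(t_true = 115, sigma = 0.01, seed = 7)
#' attr(s, "ground_truth")$t_true
#' @export
synth_contrast <- function(t_true = 115, sigma = 0.01, seed = 1L,
                           grid = seq(450, 750, by = 1),
                           oxide_thickness = 295,
                           materials = default_materials()) {
  stopifnot(sigma >= 0)
  clean <- simulate_contrast(t_true, oxide_thickness, materials, grid)
  noisy <- if (sigma > 0) {
    with_private_seed(seed,
      pmin(pmax(clean$contrast + rnorm(length(grid), 0, sigma), -1), 1))
  } else {
    clean$contrast
  }
  out <- contrast_spectrum(grid, noisy)
  attr(out, "ground_truth") <- list(kind = "contrast", t_true = t_true,
                                    sigma = sigma, seed = seed,
                                    oxide_thickness = oxide_thickness)
  out
}

#' Synthetic multi-region film micrographs
#'
#' Paints each region of a label map with the apparent colour its
#' thickness takes in a [build_color_guide()], then adds per-channel
#' Gaussian colour noise (clipped to `[0,1]`). The default layout splits
#' the image into equal vertical bands, one per thickness. The true label
#' map is returned in the `ground_truth` attribute.
#'
#' @param thicknesses_nm one thickness per region, all within the guide
#'   range.
#' @param guide a [build_color_guide()] result.
#' @param dim image size `c(height, width)` in pixels.
#' @param label_map optional integer matrix of region ids `1..m` replacing
#'   the band layout.
#' @param scale_mm_per_px physical pixel size, mm.
#' @param sigma per-channel colour noise standard deviation.
#' @param seed integer RNG seed.
#' @return A [film_image()] with attribute `ground_truth` (list with the
#'   true `labels` matrix, `thicknesses_nm`, `sigma`, `seed`).
#' @export
synth_film_image <- function(thicknesses_nm, guide, dim = c(60, 90),
                             label_map = NULL, scale_mm_per_px = 0.01,
                             sigma = 0.02, seed = 1L) {
  stopifnot(inherits(guide, "color_guide"), sigma >= 0)
  rng <- range(guide$thickness_nm)
  if (any(thicknesses_nm < rng[1] | thicknesses_nm > rng[2])) {
    stop_range("region thickness",
               thicknesses_nm[thicknesses_nm < rng[1] | thicknesses_nm > rng[2]][1],
               rng[1], rng[2])
  }
  m <- length(thicknesses_nm)
  if (is.null(label_map)) {
    cols <- ceiling(seq_len(dim[2]) / (dim[2] / m))
    cols <- pmin(cols, m)
    label_map <- matrix(rep(cols, each = dim[1]), nrow = dim[1])
  } else {
    stopifnot(all(label_map %in% seq_len(m)))
    dim <- base::dim(label_map)
  }
  # colour of the nearest guide entry for each region thickness
  colors <- t(vapply(thicknesses_nm, function(t) {
    i <- which.min(abs(guide$thickness_nm - t))
    as.numeric(guide[i, c("R", "G", "B")])
  }, numeric(3)))
  px <- array(0, dim = c(dim[1], dim[2], 3))
  for (ch in 1:3) px[, , ch] <- matrix(colors[label_map, ch], nrow = dim[1])
  if (sigma > 0) {
    px <- with_private_seed(seed,
      pmin(pmax(px + array(rnorm(length(px), 0, sigma), dim = base::dim(px)),
                0), 1))
  }
  img <- film_image(px, scale_mm_per_px)
  attr(img, "ground_truth") <- list(kind = "film_image", labels = label_map,
                                    thicknesses_nm = thicknesses_nm,
                                    sigma = sigma, seed = seed)
  img
}

#' Synthetic linear calibration tables
#'
#' Generates thickness-concentration points
#' `t_i = intercept + slope * c_i + N(0, sigma^2)`, deterministic given the
#' seed.
#'
#' @param slope slope in nm/uM.
#' @param intercept intercept in nm.
#' @param sigma thickness noise standard deviation in nm; 2 nm matches the
#'   single-spot precision of the contrast fit.
#' @param concentrations_uM concentrations in uM.
#' @param seed integer RNG seed.
#' @return Data frame of calibration points with attribute `ground_truth`.
#' @export
synth_calibration <- function(slope, intercept = 0, sigma = 2,
                              concentrations_uM = seq(100, 800, by = 100),
                              seed = 1L) {
  stopifnot(sigma >= 0)
  t_clean <- intercept + slope * concentrations_uM
  t_noisy <- if (sigma > 0) {
    with_private_seed(seed, t_clean + rnorm(length(t_clean), 0, sigma))
  } else {
    t_clean
  }
  out <- data.frame(concentration_uM = concentrations_uM,
                    thickness_nm = t_noisy)
  attr(out, "ground_truth") <- list(kind = "calibration", slope = slope,
                                    intercept = intercept, sigma = sigma,
                                    seed = seed)
  out
}

#' Write a synthetic artifact with its JSON ground-truth sidecar
#'
#' Writes the artifact (contrast spectrum as CSV, film image as PNG,
#' calibration table as CSV) and a `<path>.truth.json` sidecar holding the
#' generating parameters, so downstream analyses can always be scored.
#'
#' @param x a [synth_contrast()], [synth_film_image()] or
#'   [synth_calibration()] result.
#' @param path output path for the artifact.
#' @return `path`, invisibly.
#' @export
write_synth <- function(x, path) {
  gt <- attr(x, "ground_truth")
  if (is.null(gt)) stop("object has no ground_truth attribute", call. = FALSE)
  if (inherits(x, "contrast_spectrum")) {
    write_spectrum(x, path)
  } else if (inherits(x, "film_image")) {
    png::writePNG(x$pixels, path)
  } else if (is.data.frame(x)) {
    write.csv(x, path, row.names = FALSE, quote = FALSE)
  } else {
    stop("unsupported synthetic artifact", call. = FALSE)
  }
  gt$labels <- NULL   # keep the sidecar compact; labels live in the object
  jsonlite::write_json(gt, paste0(path, ".truth.json"), auto_unbox = TRUE)
  invisible(path)
}
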
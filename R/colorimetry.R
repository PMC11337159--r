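#' CIE 1931 colour-matching functions (2-degree observer)
#'
#' Returns the packaged colour-matching table at 1 nm over 380--780 nm as a
#' data frame with columns `wavelength_nm`, `xbar`, `ybar`, `zbar`.
#'
#' @return A data frame with 401 rows.
#' @export
cie_cmf <- function() {
  if (is.null(.microreflect_cache$cmf)) {
    .microreflect_cache$cmf <- read.csv(.extdata("cie1931_cmf_2deg.csv"))
  }
  .microreflect_cache$cmf
}

#' Standard illuminants for apparent-colour rendering
#'
#' `illuminant("A")` is the CIE A incandescent illuminant (Planckian
#' radiator at 2856 K, normalised to 100 at 560 nm) — the appropriate model
#' for the halogen lamp of a reflected-light microscope. `illuminant("E")`
#' is the equal-energy spectrum, useful as a neutral reference.
#'
#' @param name `"A"` or `"E"`.
#' @param grid wavelength grid in nm.
#' @return A list of class `illuminant` with `wavelength`, `power`, `name`.
#' @export
illuminant <- function(name = c("A", "E"), grid = 380:780) {
  name <- match.arg(name)
  stopifnot(length(grid) >= 2L, all(diff(grid) > 0))
  power <- switch(name,
    A = {
      # CIE A: blackbody at T = 2856 K with c2 = 1.435e-2 m K
      c2 <- 1.435e-2
      T <- 2856
      l <- grid * 1e-9
      100 * (560e-9 / l)^5 *
        (exp(c2 / (560e-9 * T)) - 1) / (exp(c2 / (l * T)) - 1)
    },
    E = rep(100, length(grid))
  )
  structure(list(wavelength = grid, power = power, name = name),
            class = "illuminant")
}

trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

# Spectrum -> CIE XYZ under an illuminant, trapezoidal integration,
# normalised so that Y of the perfect reflector equals 1.
spectrum_to_xyz <- function(wavelength, reflectance, illum) {
  cmf <- cie_cmf()
  lo <- max(min(wavelength), min(illum$wavelength), min(cmf$wavelength_nm))
  hi <- min(max(wavelength), max(illum$wavelength), max(cmf$wavelength_nm))
  if (lo >= hi) {
    stop("reflectance, illuminant and observer grids do not overlap",
         call. = FALSE)
  }
  wl <- seq(lo, hi, by = 1)
  R <- approx(wavelength, reflectance, xout = wl)$y
  S <- approx(illum$wavelength, illum$power, xout = wl)$y
  xb <- approx(cmf$wavelength_nm, cmf$xbar, xout = wl)$y
  yb <- approx(cmf$wavelength_nm, cmf$ybar, xout = wl)$y
  zb <- approx(cmf$wavelength_nm, cmf$zbar, xout = wl)$y
  norm <- trapz(wl, S * yb)
  c(X = trapz(wl, S * R * xb),
    Y = trapz(wl, S * R * yb),
    Z = trapz(wl, S * R * zb)) / norm
}

# white point of an illuminant on its own grid (XYZ of a perfect reflector)
illuminant_white <- function(illum) {
  spectrum_to_xyz(illum$wavelength, rep(1, length(illum$wavelength)), illum)
}

# sRGB (IEC 61966-2-1) primaries, D65 reference white; rows balanced so the
# reference white maps to exactly (1, 1, 1)
.d65_white <- c(X = 0.95047, Y = 1.00000, Z = 1.08883)
.srgb_from_xyz <- local({
  m <- matrix(c(
     3.2406, -1.5372, -0.4986,
    -0.9689,  1.8758,  0.0415,
     0.0557, -0.2040,  1.0570
  ), nrow = 3, byrow = TRUE)
  m / as.numeric(m %*% .d65_white)
})

srgb_gamma <- function(u) {
  ifelse(u <= 0.0031308, 12.92 * u, 1.055 * u^(1 / 2.4) - 0.055)
}

#' Convert a reflectance spectrum to an apparent sRGB colour
#'
#' Integrates the spectrum against the CIE 1931 2-degree observer under the
#' given illuminant, white-normalises to the illuminant (von Kries scaling
#' in XYZ, so a perfect reflector renders as white), maps through the
#' standard sRGB matrix and gamma-encodes. Out-of-gamut channels are
#' clipped to `[0, 1]` and the clipping is recorded.
#'
#' @param wavelength wavelengths in nm.
#' @param reflectance reflectance fractions in `[0, 1]` on `wavelength`;
#'   the grid must overlap 380--780 nm.
#' @param illum an [illuminant()]; default CIE A (halogen lamp).
#' @return Numeric sRGB triple in `[0,1]^3` with attribute `clipped`
#'   (logical).
#' @examples
#' reflectance_to_srgb(380:780, rep(1, 401))   # white
#' @export
reflectance_to_srgb <- function(wavelength, reflectance,
                                illum = illuminant("A")) {
  stopifnot(length(wavelength) == length(reflectance))
  if (any(reflectance < -1e-9 | reflectance > 1 + 1e-9)) {
    stop("reflectance must lie in [0, 1]", call. = FALSE)
  }
  xyz <- spectrum_to_xyz(wavelength, reflectance, illum)
  white <- illuminant_white(illum)
  xyz_rel <- xyz / white            # von Kries in XYZ: white -> (1,1,1)
  xyz_d65 <- xyz_rel * .d65_white   # express relative colour in sRGB's white
  lin <- as.numeric(.srgb_from_xyz %*% xyz_d65)
  clipped <- any(lin < 0 | lin > 1)
  lin <- pmin(pmax(lin, 0), 1)
  out <- srgb_gamma(lin)
  names(out) <- c("R", "G", "B")
  attr(out, "clipped") <- clipped
  out
}

#' Build a thickness-to-apparent-colour guide
#'
#' Simulates the stack reflectance for each thickness on a regular grid and
#' renders it to sRGB, producing a lookup table from film thickness to the
#' interference colour seen under the microscope. The default range
#' 10--200 nm at 1 nm on a 295 nm oxide matches the regime where apparent
#' colour discriminates thickness well.
#'
#' @param t_range thickness range in nm.
#' @param step thickness step in nm.
#' @param oxide_thickness oxide thickness in nm.
#' @param materials stack materials, see [default_materials()].
#' @param illum an [illuminant()].
#' @return A data frame of class `color_guide` with columns `thickness_nm`,
#'   `R`, `G`, `B`, `clipped`; attributes record the generating stack.
#' @examples
#' g <- build_color_guide(t_range = c(10, 50), step = 10)
#' g
#' @export
build_color_guide <- function(t_range = c(10, 200), step = 1,
                              oxide_thickness = 295,
                              materials = default_materials(),
                              illum = illuminant("A")) {
  stopifnot(length(t_range) == 2L, t_range[1] <= t_range[2], step > 0)
  ts <- seq(t_range[1], t_range[2], by = step)
  wl <- 380:780
  rows <- lapply(ts, function(t) {
    refl <- reflectance(film_stack(t, oxide_thickness, materials), wl)
    rgb <- reflectance_to_srgb(wl, refl, illum)
    c(t, rgb, as.numeric(attr(rgb, "clipped")))
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("thickness_nm", "R", "G", "B", "clipped")
  out$clipped <- as.logical(out$clipped)
  structure(out,
            oxide_thickness = oxide_thickness,
            illuminant = illum$name,
            class = c("color_guide", "data.frame"))
}

srgb_to_lab <- function(rgb) {
  grDevices::convertColor(rgb, from = "sRGB", to = "Lab")
}

#' Estimate film thickness from an observed apparent colour
#'
#' Nearest-neighbour lookup of an observed sRGB colour in a
#' [build_color_guide()] table, with distances measured in CIE Lab (a
#' perceptually uniform space). Because different interference orders can
#' produce similar colours, the nearest competing entry at least 10 nm away
#' is reported as the runner-up so the degeneracy is visible.
#'
#' @param observed sRGB triple in `[0,1]^3` (vector of length 3, or a
#'   matrix with one colour per row).
#' @param guide a [build_color_guide()] result.
#' @return A data frame with columns `thickness_nm`, `distance` (Lab
#'   units) and `runner_up_nm`, one row per observed colour.
#' @export
thickness_from_color <- function(observed, guide) {
  stopifnot(inherits(guide, "color_guide"), nrow(guide) >= 1L)
  obs <- if (is.matrix(observed)) observed else matrix(observed, nrow = 1)
  stopifnot(ncol(obs) == 3L, all(obs >= 0 & obs <= 1))
  guide_lab <- srgb_to_lab(as.matrix(guide[, c("R", "G", "B")]))
  obs_lab <- srgb_to_lab(obs)
  res <- apply(obs_lab, 1, function(p) {
    d2 <- colSums((t(guide_lab) - p)^2)
    i <- which.min(d2)
    far <- abs(guide$thickness_nm - guide$thickness_nm[i]) > 10
    j <- if (any(far)) which(far)[which.min(d2[far])] else NA_integer_
    c(guide$thickness_nm[i], sqrt(d2[i]),
      if (is.na(j)) NA_real_ else guide$thickness_nm[j])
  })
  out <- as.data.frame(t(res))
  names(out) <- c("thickness_nm", "distance", "runner_up_nm")
  out
}

#' Export a colour guide
#'
#' `write_color_guide()` writes the lookup table as CSV;
#' `render_color_guide()` writes a horizontal colour-strip PNG.
#'
#' @param guide a [build_color_guide()] result.
#' @param path output file path.
#' @param height strip height in pixels.
#' @export
write_color_guide <- function(guide, path) {
  write.csv(guide[, c("thickness_nm", "R", "G", "B")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_color_guide
#' @export
render_color_guide <- function(guide, path, height = 40L) {
  strip <- array(0, dim = c(height, nrow(guide), 3))
  for (ch in 1:3) {
    strip[, , ch] <- matrix(rep(guide[[c("R", "G", "B")[ch]]], each = height),
                            nrow = height)
  }
  png::writePNG(strip, path)
  invisible(path)
}
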
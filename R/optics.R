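#' Optical layers and multilayer stacks
#'
#' A `layer` pairs a [dispersion_constant()] material with a physical
#' thickness in nm; a `layer_stack` orders layers from the light-incidence
#' side downward between a semi-infinite, non-absorbing ambient and a
#' semi-infinite substrate. The protein-film measurement geometry is
#' air / film / SiO2 / Si at normal incidence.
#'
#' @param material a `dispersion` object.
#' @param thickness_nm finite layer thickness in nm, `>= 0`.
#' @return `layer()` returns a `layer`; `layer_stack()` a `layer_stack`.
#' @examples
#' stack <- layer_stack(
#'   ambient = dispersion_constant(1),
#'   layers = list(layer(sio2_index(), 295)),
#'   substrate = si_index()
#' )
#' reflectance(stack, 550)
#' @export
layer <- function(material, thickness_nm) {
  stopifnot(inherits(material, "dispersion"))
  if (!is.finite(thickness_nm) || thickness_nm < 0) {
    stop("layer thickness must be finite and >= 0, got ", thickness_nm,
         call. = FALSE)
  }
  structure(list(material = material, thickness_nm = thickness_nm),
            class = "layer")
}

#' @rdname layer
#' @param ambient semi-infinite incidence medium; must be non-absorbing.
#' @param layers list of `layer` objects, incidence side first.
#' @param substrate semi-infinite exit medium (may absorb, e.g. silicon).
#' @export
layer_stack <- function(ambient, layers = list(), substrate) {
  stopifnot(inherits(ambient, "dispersion"), inherits(substrate, "dispersion"))
  if (inherits(layers, "layer")) layers <- list(layers)
  stopifnot(all(vapply(layers, inherits, logical(1), "layer")))
  structure(list(ambient = ambient, layers = layers, substrate = substrate),
            class = "layer_stack")
}

# Characteristic-matrix solve at normal incidence, vectorised over wavelength.
# For each layer, phase thickness delta = 2*pi*n*t/lambda and
#   M = [[cos d, -i sin d / n], [-i n sin d, cos d]]
# (sign of i fixed by the n + ik absorbing convention, i.e. forward waves
# e^{+ikz}); the stack matrix B,C obeys (B, C)^t = prod(M_j) (1, n_sub)^t and
#   r = (n0*B - C)/(n0*B + C),  R = |r|^2.
# Returns r plus the admittances needed for the transmitted fraction.
stack_amplitudes <- function(stack, wavelength) {
  n0 <- evaluate_index(stack$ambient, wavelength)
  if (any(abs(Im(n0)) > 1e-12)) {
    stop("ambient medium must be non-absorbing", call. = FALSE)
  }
  ns <- evaluate_index(stack$substrate, wavelength)
  B <- rep(1 + 0i, length(wavelength))
  C <- ns
  for (ly in rev(stack$layers)) {
    nj <- evaluate_index(ly$material, wavelength)
    d <- 2 * pi * nj * ly$thickness_nm / wavelength
    cd <- cos(d); sd <- sin(d)
    B2 <- cd * B - (1i * sd / nj) * C
    C2 <- -(1i * nj * sd) * B + cd * C
    B <- B2; C <- C2
  }
  denom <- n0 * B + C
  list(r = (n0 * B - C) / denom, n0 = n0, ns = ns, denom = denom)
}

#' Normal-incidence reflectance of a multilayer stack
#'
#' Transfer-matrix (characteristic matrix) computation of the intensity
#' reflectance `R = |r|^2` of a `layer_stack`, vectorised over wavelength.
#' Complex indices are supported throughout, so absorbing substrates such
#' as silicon are handled exactly.
#'
#' @param stack a [layer_stack()].
#' @param wavelength wavelengths in nm within every material's support.
#' @return Numeric vector of reflectance fractions in `[0, 1]`.
#' @export
reflectance <- function(stack, wavelength) {
  stopifnot(inherits(stack, "layer_stack"), length(wavelength) >= 1L)
  amp <- stack_amplitudes(stack, wavelength)
  pmin(pmax(Mod(amp$r)^2, 0), 1)
}

#' @rdname reflectance
#' @description `transmittance()` gives the transmitted intensity fraction
#'   from the same matrices; for an all-lossless stack `R + T = 1`.
#' @export
transmittance <- function(stack, wavelength) {
  amp <- stack_amplitudes(stack, wavelength)
  Re(4 * Re(amp$n0) * Re(amp$ns) / Mod(amp$denom)^2)
}

film_stack <- function(film_thickness, oxide_thickness, materials) {
  layers <- list()
  if (film_thickness > 0) {
    layers <- c(layers, list(layer(materials$film, film_thickness)))
  }
  layers <- c(layers, list(layer(materials$oxide, oxide_thickness)))
  layer_stack(materials$ambient, layers, materials$substrate)
}

#' Simulate the optical contrast of a film on an oxidized-silicon substrate
#'
#' Computes, per wavelength, the contrast
#' `C = (R_film - R_bare) / (R_film + R_bare)` between the reflectance of
#' the full ambient/film/oxide/substrate stack and that of the bare
#' oxide/substrate reference — the same normalisation applied to measured
#' microreflectance spectra, which cancels the lamp spectrum.
#'
#' @param film_thickness film thickness in nm, `>= 0`.
#' @param oxide_thickness oxide thickness in nm; 295 nm is the standard
#'   thermal oxide used for high-visibility interference.
#' @param materials named list with `ambient`, `film`, `oxide`, `substrate`
#'   dispersion models; see [default_materials()].
#' @param grid strictly increasing wavelength grid in nm; default the
#'   visible band 450--750 nm at 1 nm.
#' @return A [contrast_spectrum()] with one contrast value per grid point.
#' @examples
#' cs <- simulate_contrast(115)
#' range(cs$contrast)
#' @export
simulate_contrast <- function(film_thickness, oxide_thickness = 295,
                              materials = default_materials(),
                              grid = seq(450, 750, by = 1)) {
  if (!is.finite(film_thickness) || film_thickness < 0) {
    stop("film thickness must be finite and >= 0", call. = FALSE)
  }
  if (!is.finite(oxide_thickness) || oxide_thickness < 0) {
    stop("oxide thickness must be finite and >= 0", call. = FALSE)
  }
  if (length(grid) < 1L || any(diff(grid) <= 0)) {
    stop("wavelength grid must be nonempty and strictly increasing",
         call. = FALSE)
  }
  if (film_thickness == 0) {
    return(contrast_spectrum(grid, rep(0, length(grid))))
  }
  r_film <- reflectance(film_stack(film_thickness, oxide_thickness, materials),
                        grid)
  r_bare <- reflectance(film_stack(0, oxide_thickness, materials), grid)
  tot <- r_film + r_bare
  if (any(tot <= 0)) {
    stop("contrast undefined (both reflectances zero) at wavelength(s) ",
         paste(grid[tot <= 0], collapse = ", "), " nm", call. = FALSE)
  }
  contrast_spectrum(grid, (r_film - r_bare) / tot)
}
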
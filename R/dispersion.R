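#' Wavelength-dependent complex refractive index models
#'
#' A dispersion model maps wavelength (nm) to a complex refractive index
#' `n + ik` with the absorbing convention `k >= 0`. Three kinds are
#' supported: a wavelength-independent `constant` index, the empirical
#' `cauchy` form `n(lambda) = A + B/lambda^2 + C/lambda^4` (transparent
#' materials, zero extinction), and a `tabulated` model that linearly
#' interpolates published (wavelength, n, k) samples. Evaluation outside a
#' model's supported wavelength range is an error, never extrapolation.
#'
#' @param n complex (or real) refractive index; `Re(n) >= 1`, `Im(n) >= 0`.
#' @param range supported wavelength range in nm, default the visible/NIR
#'   band 380--1000 nm.
#' @param name optional material label used in printing.
#' @return An object of class `dispersion`.
#' @examples
#' evaluate_index(dispersion_constant(1.5), 550)
#' evaluate_index(dispersion_cauchy(A = 1.5), c(450, 550, 650))
#' @export
dispersion_constant <- function(n, range = c(380, 1000), name = "constant") {
  n <- as.complex(n)
  stopifnot(length(n) == 1L, is.finite(Re(n)), is.finite(Im(n)))
  if (Re(n) < 1) stop("real part of refractive index must be >= 1", call. = FALSE)
  if (Im(n) < 0) stop("extinction coefficient must be >= 0", call. = FALSE)
  structure(list(kind = "constant", n = n, range = range, name = name),
            class = "dispersion")
}

#' @rdname dispersion_constant
#' @param A,B,C Cauchy coefficients: `A` dimensionless, `B` in nm^2,
#'   `C` in nm^4.
#' @export
dispersion_cauchy <- function(A, B = 0, C = 0, range = c(380, 1000),
                              name = "cauchy") {
  stopifnot(is.finite(A), is.finite(B), is.finite(C))
  m <- structure(list(kind = "cauchy", A = A, B = B, C = C, range = range,
                      name = name), class = "dispersion")
  # enforce n >= 1 at the range ends and midpoint (Cauchy n is monotone in
  # 1/lambda^2 for B, C >= 0; a spot check covers the usual case)
  probe <- c(range, mean(range))
  nr <- Re(evaluate_index(m, probe))
  if (any(nr < 1)) stop("Cauchy index drops below 1 within range", call. = FALSE)
  m
}

#' @rdname dispersion_constant
#' @param wavelength_nm strictly increasing wavelength grid in nm.
#' @param k extinction samples, `>= 0`; recycled if scalar.
#' @export
dispersion_tabulated <- function(wavelength_nm, n, k = 0, name = "tabulated") {
  stopifnot(length(wavelength_nm) >= 2L)
  if (any(diff(wavelength_nm) <= 0)) {
    stop("tabulated wavelength grid must be strictly increasing", call. = FALSE)
  }
  k <- rep_len(k, length(wavelength_nm))
  n <- rep_len(n, length(wavelength_nm))
  if (any(n < 1)) stop("tabulated n must be >= 1", call. = FALSE)
  if (any(k < 0)) stop("tabulated k must be >= 0", call. = FALSE)
  structure(list(kind = "tabulated", wavelength_nm = wavelength_nm,
                 n = as.numeric(n), k = as.numeric(k),
                 range = range(wavelength_nm), name = name),
            class = "dispersion")
}

#' Read a dispersion table from CSV
#'
#' Expects a header and three columns `wavelength_nm, n, k`.
#'
#' @param path CSV file path.
#' @param name material label; defaults to the file name.
#' @return A `tabulated` [dispersion_constant()] model.
#' @export
read_dispersion_csv <- function(path, name = basename(path)) {
  d <- read.csv(path)
  need <- c("wavelength_nm", "n", "k")
  if (!all(need %in% names(d))) {
    stop("dispersion CSV must have columns wavelength_nm, n, k", call. = FALSE)
  }
  dispersion_tabulated(d$wavelength_nm, d$n, d$k, name = name)
}

#' Shipped stack materials for protein films on oxidized silicon
#'
#' `si_index()` and `sio2_index()` load the packaged crystalline-silicon and
#' thermal-oxide optical-constant tables (380--1000 nm, linear
#' interpolation). `ctpr_index()` is the default protein-film model: a
#' Cauchy layer with `A = 1.5`, `B = C = 0`, the accepted visible-band
#' index of dried repeat-protein films. `default_materials()` bundles the
#' four media of the air / film / oxide / silicon stack; any entry can be
#' replaced by another [dispersion_constant()] model.
#'
#' @return A `dispersion` object, or for `default_materials()` a named list
#'   with entries `ambient`, `film`, `oxide`, `substrate`.
#' @export
si_index <- function() {
  if (is.null(.microreflect_cache$si)) {
    .microreflect_cache$si <- read_dispersion_csv(.extdata("si_index.csv"),
                                                  name = "Si")
  }
  .microreflect_cache$si
}

#' @rdname si_index
#' @export
sio2_index <- function() {
  if (is.null(.microreflect_cache$sio2)) {
    .microreflect_cache$sio2 <- read_dispersion_csv(.extdata("sio2_index.csv"),
                                                    name = "SiO2")
  }
  .microreflect_cache$sio2
}

#' @rdname si_index
#' @param A,B,C Cauchy coefficients overriding the default film index.
#' @export
ctpr_index <- function(A = 1.5, B = 0, C = 0) {
  dispersion_cauchy(A, B, C, name = "CTPR film")
}

#' @rdname si_index
#' @export
default_materials <- function() {
  list(ambient = dispersion_constant(1, name = "air"),
       film = ctpr_index(),
       oxide = sio2_index(),
       substrate = si_index())
}

#' Evaluate a dispersion model
#'
#' @param model a [dispersion_constant()], [dispersion_cauchy()] or
#'   [dispersion_tabulated()] object.
#' @param wavelength wavelengths in nm; must lie within the model's
#'   supported range.
#' @return Complex refractive index `n + ik`, one value per wavelength.
#' @export
evaluate_index <- function(model, wavelength) {
  stopifnot(inherits(model, "dispersion"))
  bad <- wavelength < model$range[1] | wavelength > model$range[2]
  if (any(bad)) {
    stop_range(paste0("wavelength (", model$name, ")"), wavelength[bad][1],
               model$range[1], model$range[2])
  }
  switch(model$kind,
    constant = rep(model$n, length(wavelength)),
    cauchy = complex(real = model$A + model$B / wavelength^2 +
                       model$C / wavelength^4,
                     imaginary = 0),
    tabulated = complex(
      real = approx(model$wavelength_nm, model$n, xout = wavelength)$y,
      imaginary = approx(model$wavelength_nm, model$k, xout = wavelength)$y
    ),
    stop("unknown dispersion kind: ", model$kind, call. = FALSE)
  )
}

#' @export
print.dispersion <- function(x, ...) {
  cat(sprintf("<dispersion: %s (%s), %g-%g nm>\n",
              x$name, x$kind, x$range[1], x$range[2]))
  invisible(x)
}
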
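#' Raw microreflectance spectra and optical-contrast spectra
#'
#' `raw_spectrum()` holds detector counts versus wavelength as acquired on
#' the film or on the bare substrate; `contrast_spectrum()` holds the
#' dimensionless normalised contrast `C` in `[-1, 1]`. Both are data frames
#' with a class attribute, so ordinary subsetting and plotting work.
#'
#' @param wavelength strictly increasing wavelengths in nm.
#' @param intensity nonnegative detector counts.
#' @param label optional label (e.g. "film", "substrate").
#' @return A data frame of class `raw_spectrum` / `contrast_spectrum`.
#' @export
raw_spectrum <- function(wavelength, intensity, label = NULL) {
  stopifnot(length(wavelength) == length(intensity), length(wavelength) >= 1L)
  if (any(diff(wavelength) <= 0)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(intensity)) || any(intensity < 0)) {
    stop("intensities must be finite and >= 0", call. = FALSE)
  }
  structure(data.frame(wavelength = wavelength, intensity = intensity),
            label = label, class = c("raw_spectrum", "data.frame"))
}

#' @rdname raw_spectrum
#' @param contrast contrast values in `[-1, 1]`.
#' @export
contrast_spectrum <- function(wavelength, contrast) {
  stopifnot(length(wavelength) == length(contrast), length(wavelength) >= 1L)
  if (any(diff(wavelength) <= 0)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(contrast)) || any(abs(contrast) > 1 + 1e-9)) {
    stop("contrast must be finite and within [-1, 1]", call. = FALSE)
  }
  structure(data.frame(wavelength = wavelength,
                       contrast = pmin(pmax(contrast, -1), 1)),
            class = c("contrast_spectrum", "data.frame"))
}

#' Read a two-column spectrum from delimited text
#'
#' Parses spectrometer output with configurable delimiter, header rows and
#' column roles, and validates it into a [raw_spectrum()]. Rows that break
#' wavelength monotonicity (including duplicates) are reported by row
#' number.
#'
#' @param source file path or connection.
#' @param delimiter field separator, default comma.
#' @param header_rows number of leading non-data rows to skip (a header
#'   line counts as one).
#' @param columns length-2 integer: which columns hold wavelength and
#'   intensity.
#' @param label optional label stored on the result.
#' @return A [raw_spectrum()].
#' @export
read_spectrum <- function(source, delimiter = ",", header_rows = 0L,
                          columns = c(1L, 2L), label = NULL) {
  lines <- readLines(source)
  if (header_rows > 0) lines <- lines[-seq_len(header_rows)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty spectrum file", call. = FALSE)
  parts <- strsplit(lines, delimiter, fixed = TRUE)
  ncol_min <- max(columns)
  short <- which(lengths(parts) < ncol_min)
  if (length(short)) {
    stop("row ", short[1], ": expected at least ", ncol_min, " columns",
         call. = FALSE)
  }
  wl <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", columns[1])))
  iv <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", columns[2])))
  bad <- which(!is.finite(wl) | !is.finite(iv))
  if (length(bad)) {
    stop("row ", bad[1], ": malformed numeric value", call. = FALSE)
  }
  dup <- which(diff(wl) == 0)
  if (length(dup)) {
    stop("duplicate wavelength ", wl[dup[1]], " at row ", dup[1] + 1,
         call. = FALSE)
  }
  nonmono <- which(diff(wl) < 0)
  if (length(nonmono)) {
    stop("wavelengths not increasing at row ", nonmono[1] + 1, call. = FALSE)
  }
  raw_spectrum(wl, iv, label = label)
}

#' Write a spectrum to CSV
#'
#' @param spectrum a [raw_spectrum()] or [contrast_spectrum()].
#' @param path output file path.
#' @export
write_spectrum <- function(spectrum, path) {
  write.csv(as.data.frame(spectrum), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert paired film/substrate spectra to an optical-contrast spectrum
#'
#' Computes the pointwise normalised contrast
#' `C = (I_film - I_subst) / (I_film + I_subst)`; the ratio removes the
#' spectral shape of the lamp. If the two spectra are on different grids
#' the substrate is linearly interpolated onto the film grid over their
#' overlap. An optional dark spectrum is subtracted from both first.
#'
#' @param film [raw_spectrum()] measured on the film.
#' @param substrate [raw_spectrum()] measured on the bare substrate.
#' @param dark optional dark/background [raw_spectrum()].
#' @return A [contrast_spectrum()] on the film grid (overlap only).
#' @examples
#' f <- raw_spectrum(c(500, 501), c(3, 3))
#' s <- raw_spectrum(c(500, 501), c(1, 1))
#' compute_contrast(f, s)$contrast  # 0.5 0.5
#' @export
compute_contrast <- function(film, substrate, dark = NULL) {
  stopifnot(inherits(film, "raw_spectrum"), inherits(substrate, "raw_spectrum"))
  lo <- max(min(film$wavelength), min(substrate$wavelength))
  hi <- min(max(film$wavelength), max(substrate$wavelength))
  if (lo > hi) stop("film and substrate spectra do not overlap", call. = FALSE)
  keep <- film$wavelength >= lo & film$wavelength <= hi
  wl <- film$wavelength[keep]
  i_f <- film$intensity[keep]
  i_s <- approx(substrate$wavelength, substrate$intensity, xout = wl)$y
  if (!is.null(dark)) {
    stopifnot(inherits(dark, "raw_spectrum"))
    d <- approx(dark$wavelength, dark$intensity, xout = wl, rule = 2)$y
    i_f <- i_f - d
    i_s <- i_s - d
  }
  tot <- i_f + i_s
  if (any(tot <= 0)) {
    stop("nonpositive total intensity after dark subtraction at wavelength(s) ",
         paste(utils::head(wl[tot <= 0], 5), collapse = ", "), " nm",
         call. = FALSE)
  }
  contrast_spectrum(wl, (i_f - i_s) / tot)
}

#' Restrict a contrast spectrum to a wavelength window
#'
#' @param spectrum a [contrast_spectrum()].
#' @param window length-2 numeric `[lambda_min, lambda_max]` in nm.
#' @return The [contrast_spectrum()] with out-of-window points removed.
#' @export
restrict <- function(spectrum, window) {
  stopifnot(inherits(spectrum, "contrast_spectrum"), length(window) == 2L)
  keep <- spectrum$wavelength >= window[1] & spectrum$wavelength <= window[2]
  if (!any(keep)) {
    stop(sprintf("window [%g, %g] nm contains no spectral points",
                 window[1], window[2]), call. = FALSE)
  }
  contrast_spectrum(spectrum$wavelength[keep], spectrum$contrast[keep])
}

#' Read a contrast spectrum from CSV
#'
#' Expects columns `wavelength` and `contrast` (header required).
#'
#' @param path CSV file path.
#' @return A [contrast_spectrum()].
#' @export
read_contrast_csv <- function(path) {
  d <- read.csv(path)
  if (!all(c("wavelength", "contrast") %in% names(d))) {
    stop("contrast CSV must have columns wavelength, contrast", call. = FALSE)
  }
  contrast_spectrum(d$wavelength, d$contrast)
}
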
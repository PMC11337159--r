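# Generates inst/extdata/cie1931_cmf_2deg.csv: CIE 1931 2-degree standard
# observer colour-matching functions at 1 nm over 380-780 nm, computed from
# the multi-lobe piecewise-Gaussian analytic fit of Wyman, Sloan & Shirley
# (JCGT 2013).  Agreement with the measured observer is well within the
# accuracy needed for interference-colour rendering.

g <- function(x, mu, s1, s2) {
  s <- ifelse(x < mu, s1, s2)
  exp(-0.5 * ((x - mu) / s)^2)
}

xbar <- function(wl) {
  1.056 * g(wl, 599.8, 37.9, 31.0) +
  0.362 * g(wl, 442.0, 16.0, 26.7) -
  0.065 * g(wl, 501.1, 20.4, 26.2)
}
ybar <- function(wl) {
  0.821 * g(wl, 568.8, 46.9, 40.5) +
  0.286 * g(wl, 530.9, 16.3, 31.1)
}
zbar <- function(wl) {
  1.217 * g(wl, 437.0, 11.8, 36.0) +
  0.681 * g(wl, 459.0, 26.0, 13.8)
}

wl <- 380:780
cmf <- data.frame(
  wavelength_nm = wl,
  xbar = round(pmax(xbar(wl), 0), 6),
  ybar = round(pmax(ybar(wl), 0), 6),
  zbar = round(pmax(zbar(wl), 0), 6)
)
write.csv(cmf, "inst/extdata/cie1931_cmf_2deg.csv", row.names = FALSE, quote = FALSE)
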
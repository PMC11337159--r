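# Generates the shipped refractive-index tables under inst/extdata/.
#
# SiO2: computed from the Malitson (1965) three-term Sellmeier equation for
# fused silica; thermally grown oxide is close enough to fused silica in the
# visible for interference modelling (k = 0 in this band).
#
# Si: representative crystalline-silicon optical constants in the visible/NIR,
# smoothed through literature anchor values (Aspnes & Studna-type tabulations);
# values are approximate transcriptions suitable for interference modelling,
# not a certified reference dataset.  The table is swappable: any 3-column
# CSV (wavelength_nm, n, k) can be supplied instead.

sellmeier_sio2 <- function(lambda_nm) {
  um2 <- (lambda_nm / 1000)^2
  n2 <- 1 +
    0.6961663 * um2 / (um2 - 0.0684043^2) +
    0.4079426 * um2 / (um2 - 0.1162414^2) +
    0.8974794 * um2 / (um2 - 9.896161^2)
  sqrt(n2)
}

grid <- seq(380, 1000, by = 10)
sio2 <- data.frame(
  wavelength_nm = grid,
  n = round(sellmeier_sio2(grid), 5),
  k = 0
)
write.csv(sio2, "inst/extdata/sio2_index.csv", row.names = FALSE, quote = FALSE)

si_anchor <- data.frame(
  wl = c(380, 400, 420, 440, 460, 480, 500, 520, 540, 560, 580, 600,
         620, 640, 660, 680, 700, 750, 800, 850, 900, 950, 1000),
  n  = c(6.03, 5.57, 5.12, 4.84, 4.62, 4.47, 4.29, 4.20, 4.12, 4.05,
         3.99, 3.94, 3.90, 3.86, 3.83, 3.80, 3.77, 3.72, 3.68, 3.64,
         3.61, 3.59, 3.57),
  k  = c(0.72, 0.387, 0.276, 0.200, 0.110, 0.081, 0.045, 0.038, 0.030,
         0.027, 0.023, 0.020, 0.017, 0.015, 0.013, 0.011, 0.010, 0.007,
         0.005, 0.003, 0.002, 0.001, 0.0005)
)
n_fun <- splinefun(si_anchor$wl, si_anchor$n, method = "monoH.FC")
k_fun <- splinefun(si_anchor$wl, si_anchor$k, method = "monoH.FC")
si <- data.frame(
  wavelength_nm = grid,
  n = round(n_fun(grid), 5),
  k = round(pmax(k_fun(grid), 0), 5)
)
write.csv(si, "inst/extdata/si_index.csv", row.names = FALSE, quote = FALSE)
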
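test_that("bare interfaces reproduce the Fresnel reflectance", {
  # no index step: R = 0
  st0 <- layer_stack(dispersion_constant(1), list(), dispersion_constant(1))
  expect_equal(reflectance(st0, 550), 0)
  # air|glass: ((1 - 1.5)/(1 + 1.5))^2 = 0.04
  st1 <- layer_stack(dispersion_constant(1), list(), dispersion_constant(1.5))
  expect_equal(reflectance(st1, 550), 0.04)
})

test_that("transfer matrix equals the Airy closed form for single layers", {
  # the shipped-stack case: air / SiO2 295 nm / Si across the full band
  wl <- seq(380, 1000, by = 1)
  st <- layer_stack(dispersion_constant(1), list(layer(sio2_index(), 295)),
                    si_index())
  R_tm <- reflectance(st, wl)
  R_airy <- airy_reflectance(1 + 0i,
                             evaluate_index(sio2_index(), wl),
                             evaluate_index(si_index(), wl), 295, wl)
  expect_lt(max(abs(R_tm - R_airy)), 1e-10)

  # random lossless films on an absorbing substrate
  set.seed(11)
  for (i in 1:1000) {
    n1 <- runif(1, 1, 3)
    ns <- complex(real = runif(1, 1, 5), imaginary = runif(1, 0, 1))
    t <- runif(1, 0, 1000)
    wl1 <- runif(1, 380, 1000)
    st <- layer_stack(dispersion_constant(1),
                      list(layer(dispersion_constant(n1), t)),
                      dispersion_constant(ns))
    expect_lt(abs(reflectance(st, wl1) -
                    airy_reflectance(1 + 0i, n1 + 0i, ns, t, wl1)), 1e-10)
  }
})

test_that("energy is conserved: 0 <= R <= 1, and R + T = 1 for lossless stacks", {
  wl <- seq(380, 1000, by = 5)
  lossless <- layer_stack(
    dispersion_constant(1),
    list(layer(dispersion_constant(1.8), 120), layer(sio2_index(), 295)),
    dispersion_constant(2.3)
  )
  R <- reflectance(lossless, wl)
  T <- transmittance(lossless, wl)
  expect_true(all(R >= 0 & R <= 1))
  expect_lt(max(abs(R + T - 1)), 1e-12)

  # absorbing silicon substrate and even an absorbing layer stay bounded
  absorbing <- layer_stack(dispersion_constant(1),
                           list(layer(si_index(), 50),
                                layer(sio2_index(), 295)),
                           si_index())
  Ra <- reflectance(absorbing, wl)
  expect_true(all(Ra >= 0 & Ra <= 1))
})

test_that("reflectance of a lossless layer is periodic in thickness with period lambda/(2n)", {
  wl <- 600
  n1 <- 1.46
  period <- wl / (2 * n1)
  for (t in c(30, 111, 260)) {
    st_a <- layer_stack(dispersion_constant(1),
                        list(layer(dispersion_constant(n1), t)),
                        dispersion_constant(3.9))
    st_b <- layer_stack(dispersion_constant(1),
                        list(layer(dispersion_constant(n1), t + period)),
                        dispersion_constant(3.9))
    expect_lt(abs(reflectance(st_a, wl) - reflectance(st_b, wl)), 1e-9)
  }
})

test_that("zero film thickness gives identically zero contrast", {
  cs <- simulate_contrast(0, 295)
  expect_true(all(cs$contrast == 0))
})

test_that("simulated contrast matches an independent two-stack composition", {
  wl <- 550
  mats <- default_materials()
  cs <- simulate_contrast(50, 295, mats, grid = c(540, 550, 560))
  r_film_oracle <- reflectance(
    layer_stack(mats$ambient,
                list(layer(mats$film, 50), layer(mats$oxide, 295)),
                mats$substrate), c(540, 550, 560))
  r_bare_oracle <- airy_reflectance(1 + 0i,
                                    evaluate_index(mats$oxide, c(540, 550, 560)),
                                    evaluate_index(mats$substrate, c(540, 550, 560)),
                                    295, c(540, 550, 560))
  expect_equal(cs$contrast, hand_contrast(r_film_oracle, r_bare_oracle),
               tolerance = 1e-10)
})

test_that("contrast is bounded in [-1, 1] over random stacks and swaps sign under exchange", {
  set.seed(23)
  for (i in 1:200) {
    t_film <- runif(1, 0, 400)
    t_ox <- runif(1, 0, 600)
    cs <- simulate_contrast(t_film, t_ox,
                            grid = sort(runif(5, 450, 750)) + (0:4) * 1e-6)
    expect_true(all(abs(cs$contrast) <= 1))
  }
  # reciprocity of the formula itself
  expect_equal(hand_contrast(0.3, 0.1), -hand_contrast(0.1, 0.3))
})

test_that("the thickness sweep at 295 nm oxide produces a family of distinct curves with moving extrema", {
  sweeps <- lapply(seq(10, 100, by = 10), simulate_contrast)
  # every thickness gives appreciable contrast somewhere in the band
  amp <- vapply(sweeps, function(s) max(abs(s$contrast)), numeric(1))
  expect_true(all(amp > 0.05))
  # extremum wavelength moves with thickness (interference condition shifts)
  argmax <- vapply(sweeps, function(s) s$wavelength[which.max(abs(s$contrast))],
                   numeric(1))
  expect_gt(length(unique(argmax)), 5)
})

test_that("invalid stack inputs are rejected", {
  expect_error(layer(dispersion_constant(1.5), -5), ">= 0")
  expect_error(simulate_contrast(-1), ">= 0")
  st <- layer_stack(dispersion_constant(1), list(), si_index())
  expect_error(reflectance(st, 2000), "range")
  # absorbing ambient is unphysical for the incidence medium
  amb <- dispersion_constant(complex(real = 1.2, imaginary = 0.3))
  expect_error(reflectance(layer_stack(amb, list(), si_index()), 550),
               "non-absorbing")
})
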
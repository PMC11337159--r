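# Independent oracles used across the suite. These re-derive quantities by
# a different route than the implementation under test.

# Airy closed form for a single film between two semi-infinite media,
# n + ik convention, forward phase e^{+i k z}.
airy_reflectance <- function(n0, n1, n2, thickness_nm, wavelength_nm) {
  r01 <- (n0 - n1) / (n0 + n1)
  r12 <- (n1 - n2) / (n1 + n2)
  d <- 2 * pi * n1 * thickness_nm / wavelength_nm
  r <- (r01 + r12 * exp(2i * d)) / (1 + r01 * r12 * exp(2i * d))
  Mod(r)^2
}

# contrast of a film stack composed from the Airy oracle applied twice
# (film-on-oxide needs two layers, so only usable when the film is absent
# or via the oracle-backed reflectance call) — for the two-stack contrast
# check we instead compose the package reflectance of each stack through
# the contrast formula by hand.
hand_contrast <- function(r_film, r_bare) (r_film - r_bare) / (r_film + r_bare)

# trapezoidal integral
trapz_oracle <- function(x, y) sum(diff(x) * (head(y, -1) + y[-1])) / 2

# best pixel-label agreement between a ground-truth labelling and a
# clustering, maximised over label permutations via greedy overlap
label_accuracy <- function(truth, labels) {
  tab <- table(truth, labels)
  sum(apply(tab, 1, max)) / length(truth)
}

default_grid <- seq(450, 750, by = 1)
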
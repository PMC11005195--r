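# Independent oracles shared across tests. These deliberately avoid the
# package's own band_fractions()/renderer code paths.

# Fraction of a Gaussian emission curve (normalised on grid_lo..grid_hi by
# adaptive quadrature) falling inside [lo, hi].
gauss_window_fraction <- function(peak, sd, lo, hi, grid_lo = 400, grid_hi = 700) {
  f <- function(x) stats::dnorm(x, peak, sd)
  stats::integrate(f, lo, hi, rel.tol = 1e-10)$value /
    stats::integrate(f, grid_lo, grid_hi, rel.tol = 1e-10)$value
}

# Expected band-window signal model evaluated by direct integration:
# returns c(donor_window_signal, acceptor_window_signal) for one pixel.
expected_window_signal <- function(E, density = 1, photon_budget = 100,
                                   donor = c(476, 18), acceptor = c(530, 14),
                                   donor_window = c(465, 500),
                                   acceptor_window = c(525, 570)) {
  dd <- gauss_window_fraction(donor[1], donor[2], donor_window[1], donor_window[2])
  da <- gauss_window_fraction(donor[1], donor[2], acceptor_window[1], acceptor_window[2])
  ad <- gauss_window_fraction(acceptor[1], acceptor[2], donor_window[1], donor_window[2])
  aa <- gauss_window_fraction(acceptor[1], acceptor[2], acceptor_window[1], acceptor_window[2])
  base <- density * photon_budget
  c(donor = base * ((1 - E) * dd + E * ad),
    acceptor = base * ((1 - E) * da + E * aa))
}

# Forster relation forward direction, used only to check the inversion.
efficiency_from_distance <- function(R, R0 = 4.7) R0^6 / (R0^6 + R^6)

# Tiny uniform phantom helper: constant activity everywhere inside the mask.
uniform_phantom <- function(activity, shape = c(48, 48), seed = 1,
                            texture = 0) {
  make_embryo_phantom("gastrula_5hpf", shape,
                      domain_activities = c(margin = activity, bulk = activity),
                      seed = seed, density_texture_sd = texture)
}
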
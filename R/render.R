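#' Detector noise model
#'
#' Photon shot noise (Poisson on the expected photon count) followed by
#' additive Gaussian read noise, clipped at zero. Setting `shot = FALSE` and
#' `read_noise_sd = 0` yields noise-free expected-value images, which the
#' analytic oracles in the test-suite rely on.
#'
#' @param photon_budget Expected photons per unit sensor density per pixel
#'   (scales every expected signal). Default 100.
#' @param read_noise_sd Read noise standard deviation in photon units.
#'   Default 2.
#' @param shot Apply Poisson shot noise? Default TRUE.
#' @return List of class `noise_model`.
#' @export
noise_model <- function(photon_budget = 100, read_noise_sd = 2, shot = TRUE) {
  stopifnot(photon_budget > 0, read_noise_sd >= 0)
  structure(list(photon_budget = photon_budget, read_noise_sd = read_noise_sd,
                 shot = isTRUE(shot)), class = "noise_model")
}

#' Noise-free detector model
#' @return A `noise_model` returning expected values exactly.
#' @param photon_budget Expected photons per unit density per pixel.
#' @export
noise_free <- function(photon_budget = 100)
  noise_model(photon_budget = photon_budget, read_noise_sd = 0, shot = FALSE)

apply_noise <- function(expected, noise) {
  out <- expected
  if (noise$shot)
    out[] <- stats::rpois(length(expected), lambda = as.vector(expected))
  if (noise$read_noise_sd > 0)
    out <- out + stats::rnorm(length(expected), 0, noise$read_noise_sd)
  pmax(out, 0)
}

#' Render a spectral lambda stack from a phantom
#'
#' Forward model of a lambda scan under 458 nm donor excitation. The expected
#' signal in band b at pixel p is
#' `density(p) * photon_budget * [(1 - E(p)) * Q_D * F_D(b) + E(p) * Q_A * F_A(b)]`,
#' where `E` is the phantom's effective FRET efficiency, `Q_D`/`Q_A` are
#' quantum-yield scale factors and `F_X(b)` is the fraction of fluorophore X's
#' unit-area emission falling in band b. Direct acceptor excitation at the
#' donor line (crosstalk) is off by default, reflecting the 1:1 intramolecular
#' donor:acceptor stoichiometry of the sensor.
#'
#' @param phantom An [make_embryo_phantom()] result.
#' @param donor_spectrum,acceptor_spectrum [emission_spectrum()] objects;
#'   defaults [default_spectra()].
#' @param acquisition A [spectral_acquisition()].
#' @param noise A [noise_model()]; use [noise_free()] for expected values.
#' @param seed Integer seed for the noise draws.
#' @param q_donor,q_acceptor Quantum-yield scale factors (default both 1; the
#'   ratiometric readout is unitless so only their ratio matters).
#' @param acceptor_crosstalk Fraction of direct acceptor excitation at the
#'   donor line, default 0.
#' @return Object of class `lambda_stack`: `data` array with dimensions
#'   `(z, y, x, band)`, `band_edges` (nm, length bands+1), `excitation_nm`,
#'   `stage` and a `meta` list.
#' @export
render_lambda_stack <- function(phantom,
                                donor_spectrum = default_spectra()$donor,
                                acceptor_spectrum = default_spectra()$acceptor,
                                acquisition = spectral_acquisition(),
                                noise = noise_model(), seed = 1L,
                                q_donor = 1, q_acceptor = 1,
                                acceptor_crosstalk = 0) {
  stopifnot(inherits(phantom, "activity_phantom"),
            inherits(acquisition, "spectral_acquisition"),
            inherits(noise, "noise_model"))
  edges <- acquisition$band_edges
  f_d <- band_fractions(donor_spectrum, edges)
  f_a <- band_fractions(acceptor_spectrum, edges)
  ny <- phantom$shape[1]; nx <- phantom$shape[2]
  nb <- acquisition$n_bands; nz <- acquisition$n_z
  eff <- phantom$efficiency
  base <- phantom$density * noise$photon_budget
  don <- base * (1 - eff) * q_donor
  acc <- base * eff * q_acceptor
  xtk <- base * acceptor_crosstalk * q_acceptor
  # expected (y, x, band), identical for every z plane
  expected <- array(0, dim = c(ny, nx, nb))
  for (b in seq_len(nb))
    expected[, , b] <- don * f_d[b] + (acc + xtk) * f_a[b]
  set.seed(as.integer(seed))
  data <- array(0, dim = c(nz, ny, nx, nb))
  for (z in seq_len(nz))
    data[z, , , ] <- apply_noise(expected, noise)
  lambda_stack(data, edges, excitation_nm = acquisition$excitation_nm,
               stage = phantom$stage,
               meta = list(photon_budget = noise$photon_budget,
                           q_donor = q_donor, q_acceptor = q_acceptor,
                           seed = as.integer(seed)))
}

#' Lambda stack container
#'
#' @param data Numeric array with dimensions `(z, y, x, band)` (a `(y, x,
#'   band)` array is promoted to a single z plane); intensities >= 0.
#' @param band_edges Increasing numeric vector of band edges in nm, length
#'   `n_bands + 1`.
#' @param excitation_nm Excitation wavelength.
#' @param stage Free-form stage tag.
#' @param meta Free-form metadata list.
#' @return Object of class `lambda_stack`.
#' @export
lambda_stack <- function(data, band_edges, excitation_nm = 458,
                         stage = NULL, meta = list()) {
  if (length(dim(data)) == 3L) dim(data) <- c(1L, dim(data))
  if (length(dim(data)) != 4L)
    stop("`data` must be a (z, y, x, band) array", call. = FALSE)
  band_edges <- as.numeric(band_edges)
  if (length(band_edges) != dim(data)[4] + 1L || any(diff(band_edges) <= 0))
    stop("`band_edges` must be increasing with length n_bands + 1", call. = FALSE)
  if (any(data < 0)) stop("intensities must be >= 0", call. = FALSE)
  structure(list(data = data, band_edges = band_edges,
                 excitation_nm = excitation_nm, stage = stage, meta = meta),
            class = "lambda_stack")
}

#' @export
print.lambda_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<lambda_stack> %d z x %dx%d px x %d bands, %.0f-%.0f nm (exc %.0f nm)%s\n",
              d[1], d[2], d[3], d[4], min(x$band_edges), max(x$band_edges),
              x$excitation_nm,
              if (!is.null(x$stage)) paste0(", stage ", x$stage) else ""))
  invisible(x)
}

#' Render an acceptor-photobleaching series
#'
#' Forward model of the AB-FRET protocol: two pre-bleach donor/acceptor frame
#' pairs, then `iterations` bleach passes of the acceptor inside `bleach_roi`,
#' then one post-bleach pair. The surviving acceptor fraction in the ROI is
#' `s = per_iteration_survival^iterations`; the post-bleach effective
#' efficiency is `E_post = E * s` there, so the donor de-quenches from
#' `density * photon_budget * (1 - E) * Q_D` to
#' `density * photon_budget * (1 - E * s) * Q_D`. Acceptor frames model direct
#' acceptor excitation (514 nm line) and are therefore proportional to the
#' surviving acceptor amount, independent of FRET. Donor photobleaching during
#' the series is excluded from the default model (the downstream estimator
#' assumes it negligible).
#'
#' @param phantom An `activity_phantom`.
#' @param bleach_roi Logical mask of the bleached region (same shape as the
#'   phantom).
#' @param iterations Number of bleach iterations (>= 1), default 50.
#' @param per_iteration_survival Acceptor fraction surviving one iteration in
#'   `[0, 1]`; default 0.85 (a 50-iteration pass is then effectively complete,
#'   surviving fraction ~3e-4).
#' @param noise A [noise_model()].
#' @param seed Integer seed.
#' @param q_donor,q_acceptor Quantum-yield scale factors.
#' @return Object of class `bleach_series` with `pre_donor`, `pre_acceptor`
#'   (lists of two frames each), `post_donor`, `post_acceptor`, `bleach_roi`,
#'   `iterations`, `per_iteration_survival` and a `truth` list holding the
#'   phantom efficiency and the total surviving fraction.
#' @export
render_bleach_series <- function(phantom, bleach_roi, iterations = 50L,
                                 per_iteration_survival = 0.85,
                                 noise = noise_model(), seed = 1L,
                                 q_donor = 1, q_acceptor = 1) {
  stopifnot(inherits(phantom, "activity_phantom"))
  if (!is.logical(bleach_roi) || !identical(dim(bleach_roi), dim(phantom$mask)))
    stop("`bleach_roi` must be a logical mask matching the phantom shape", call. = FALSE)
  if (!any(bleach_roi)) stop("ROI outside image / empty bleach ROI", call. = FALSE)
  iterations <- as.integer(iterations)
  if (iterations < 1L) stop("`iterations` must be >= 1", call. = FALSE)
  if (per_iteration_survival < 0 || per_iteration_survival > 1)
    stop("`per_iteration_survival` must lie in [0, 1]", call. = FALSE)

  s_total <- per_iteration_survival^iterations
  s_map <- matrix(1, phantom$shape[1], phantom$shape[2])
  s_map[bleach_roi] <- s_total
  eff <- phantom$efficiency
  base <- phantom$density * noise$photon_budget
  exp_pre_d <- base * (1 - eff) * q_donor
  exp_pre_a <- base * q_acceptor
  exp_post_d <- base * (1 - eff * s_map) * q_donor
  exp_post_a <- base * s_map * q_acceptor

  set.seed(as.integer(seed))
  structure(list(
    pre_donor = list(apply_noise(exp_pre_d, noise), apply_noise(exp_pre_d, noise)),
    pre_acceptor = list(apply_noise(exp_pre_a, noise), apply_noise(exp_pre_a, noise)),
    post_donor = apply_noise(exp_post_d, noise),
    post_acceptor = apply_noise(exp_post_a, noise),
    bleach_roi = bleach_roi, iterations = iterations,
    per_iteration_survival = per_iteration_survival,
    truth = list(efficiency = eff, survival_total = s_total),
    meta = list(photon_budget = noise$photon_budget, seed = as.integer(seed))),
    class = "bleach_series")
}

#' @export
print.bleach_series <- function(x, ...) {
  cat(sprintf("<bleach_series> %dx%d px, %d iterations, survival/iter %.3f (total %.3g), ROI %d px\n",
              nrow(x$post_donor), ncol(x$post_donor), x$iterations,
              x$per_iteration_survival, x$truth$survival_total,
              sum(x$bleach_roi)))
  invisible(x)
}
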
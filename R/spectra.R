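#' Emission spectrum of a fluorophore
#'
#' Builds a unit-area emission spectrum on a wavelength grid. Spectra are the
#' reference shapes used both by the forward renderer ([render_lambda_stack()])
#' and by least-squares unmixing ([linear_unmix()]). The constructor normalises
#' the curve so its trapezoidal integral over the grid is exactly 1, which
#' makes band-integrated fractions directly comparable between fluorophores.
#'
#' @param name Fluorophore label (e.g. `"CFP"`, `"YPet"`).
#' @param grid Numeric vector of wavelengths in nm, strictly increasing.
#' @param emission Non-negative relative intensities, one per grid point.
#' @return An object of class `emission_spectrum` with fields `name`, `grid`
#'   and `emission` (unit trapezoidal area).
#' @seealso [gaussian_spectrum()], [default_spectra()]
#' @export
emission_spectrum <- function(name, grid, emission) {
  stopifnot(is.character(name), length(name) == 1L)
  grid <- as.numeric(grid)
  emission <- as.numeric(emission)
  if (length(grid) < 2L || length(grid) != length(emission))
    stop("`grid` and `emission` must have equal length >= 2", call. = FALSE)
  if (any(diff(grid) <= 0))
    stop("`grid` must be strictly increasing", call. = FALSE)
  if (any(emission < 0))
    stop("`emission` must be non-negative", call. = FALSE)
  area <- pracma::trapz(grid, emission)
  if (area <= 0)
    stop("spectrum has zero total intensity", call. = FALSE)
  structure(list(name = name, grid = grid, emission = emission / area),
            class = "emission_spectrum")
}

#' Gaussian emission spectrum
#'
#' Convenience constructor for a Gaussian-shaped emission spectrum, the
#' parametric stand-in used for CFP and YPet when measured spectra are not
#' supplied.
#'
#' @param name Fluorophore label.
#' @param peak Peak emission wavelength (nm).
#' @param sd Spectral width (nm, Gaussian standard deviation).
#' @param grid Wavelength grid (nm); default 1 nm steps over 400-700 nm.
#' @return An `emission_spectrum`.
#' @export
gaussian_spectrum <- function(name, peak, sd, grid = seq(400, 700, by = 1)) {
  stopifnot(sd > 0)
  emission_spectrum(name, grid, stats::dnorm(grid, mean = peak, sd = sd))
}

#' Default donor/acceptor emission spectra
#'
#' The CFP donor is modelled with peak 476 nm (sd 18 nm) and the YPet acceptor
#' with peak 530 nm (sd 14 nm); both are unit-area Gaussians and both can be
#' replaced by any [emission_spectrum()] wherever spectra are accepted.
#'
#' @return Named list with elements `donor` and `acceptor`.
#' @export
default_spectra <- function() {
  list(donor = gaussian_spectrum("CFP", peak = 476, sd = 18),
       acceptor = gaussian_spectrum("YPet", peak = 530, sd = 14))
}

#' @export
print.emission_spectrum <- function(x, ...) {
  cat(sprintf("<emission_spectrum> %s: %d points, %.0f-%.0f nm, peak %.0f nm\n",
              x$name, length(x$grid), min(x$grid), max(x$grid),
              x$grid[which.max(x$emission)]))
  invisible(x)
}

#' Number of spectral detection steps
#'
#' Band-count convention for a lambda acquisition covering
#' `[lambda_min, lambda_max]` with detector windows of width `step`:
#' `ceiling((lambda_max - lambda_min) / step)`. A final, possibly truncated,
#' band is counted in full, so 462-572 nm yields 22 steps at 5 nm and 16 steps
#' at 7 nm.
#'
#' @param lambda_min,lambda_max Spectral range bounds in nm (`lambda_max >
#'   lambda_min`).
#' @param step Detection step size in nm (> 0).
#' @return Integer number of detection bands.
#' @export
n_detection_steps <- function(lambda_min, lambda_max, step) {
  if (!is.numeric(step) || length(step) != 1L || step <= 0)
    stop("`step` must be a positive number", call. = FALSE)
  if (lambda_max <= lambda_min)
    stop("`lambda_max` must exceed `lambda_min`", call. = FALSE)
  as.integer(ceiling((lambda_max - lambda_min) / step))
}

#' Spectral acquisition settings
#'
#' Describes the lambda-scan geometry: spectral range, detection step and the
#' number of z planes. Band edges are regular multiples of `step` from
#' `lambda_min`, with the last band truncated at `lambda_max` when `step` does
#' not divide the range.
#'
#' @param lambda_min,lambda_max Emission collection range (nm). Defaults
#'   462-572 nm.
#' @param step Detection step size (nm), default 5.
#' @param n_z Number of z planes rendered, default 1.
#' @param excitation_nm Excitation line (nm), default 458.
#' @return List of class `spectral_acquisition` including the computed
#'   `band_edges`.
#' @export
spectral_acquisition <- function(lambda_min = 462, lambda_max = 572, step = 5,
                                 n_z = 1L, excitation_nm = 458) {
  n <- n_detection_steps(lambda_min, lambda_max, step)
  edges <- lambda_min + step * (0:n)
  edges[n + 1L] <- min(edges[n + 1L], lambda_max)
  structure(list(lambda_min = lambda_min, lambda_max = lambda_max, step = step,
                 n_bands = n, band_edges = edges, n_z = as.integer(n_z),
                 excitation_nm = excitation_nm),
            class = "spectral_acquisition")
}

# Fraction of a unit-area spectrum emitted inside each band. Integration uses
# a 0.25 nm refinement of each band so that 5 nm and 7 nm partitions of the
# same range integrate to the same total (partition consistency).
band_fractions <- function(spectrum, band_edges) {
  stopifnot(inherits(spectrum, "emission_spectrum"))
  if (min(band_edges) < min(spectrum$grid) || max(band_edges) > max(spectrum$grid))
    stop(sprintf("spectrum '%s' (%.0f-%.0f nm) does not cover the acquisition range %.0f-%.0f nm",
                 spectrum$name, min(spectrum$grid), max(spectrum$grid),
                 min(band_edges), max(band_edges)), call. = FALSE)
  nb <- length(band_edges) - 1L
  vapply(seq_len(nb), function(i) {
    xs <- unique(c(seq(band_edges[i], band_edges[i + 1L], by = 0.25),
                   band_edges[i + 1L]))
    ys <- stats::approx(spectrum$grid, spectrum$emission, xout = xs)$y
    pracma::trapz(xs, ys)
  }, numeric(1))
}
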
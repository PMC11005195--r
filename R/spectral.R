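#' Band-window dye separation
#'
#' Splits a lambda stack into donor and acceptor channels by summing the
#' detection bands whose centres fall inside each emission window (inclusive
#' bounds). With the default 462-572 nm / 5 nm acquisition, the CFP window
#' 465-500 nm collects 7 bands and the YPet window 525-570 nm collects 9.
#'
#' @param stack A [lambda_stack()].
#' @param donor_window,acceptor_window Length-2 numeric `c(lo, hi)` in nm;
#'   defaults `c(465, 500)` and `c(525, 570)`. The windows must be disjoint
#'   and must each contain at least one band centre.
#' @return Object of class `channel_pair` with `donor` and `acceptor`
#'   `(z, y, x)` volumes, the windows used, and `method = "band_window"`.
#' @export
band_window_separation <- function(stack, donor_window = c(465, 500),
                                   acceptor_window = c(525, 570)) {
  stopifnot(inherits(stack, "lambda_stack"))
  for (w in list(donor_window, acceptor_window))
    if (length(w) != 2L || w[2] <= w[1])
      stop("windows must be c(lo, hi) with hi > lo", call. = FALSE)
  if (donor_window[1] <= acceptor_window[2] && acceptor_window[1] <= donor_window[2])
    stop("donor and acceptor windows must be disjoint", call. = FALSE)
  e <- stack$band_edges
  centres <- (e[-length(e)] + e[-1]) / 2
  pick <- function(w, lab) {
    idx <- which(centres >= w[1] & centres <= w[2])
    if (length(idx) == 0L)
      stop(sprintf("%s window [%g, %g] nm contains no band centre", lab, w[1], w[2]),
           call. = FALSE)
    idx
  }
  di <- pick(donor_window, "donor")
  ai <- pick(acceptor_window, "acceptor")
  sum_bands <- function(idx) {
    d <- dim(stack$data)
    out <- array(0, dim = d[1:3])
    for (b in idx) {
      sl <- stack$data[, , , b, drop = FALSE]
      dim(sl) <- d[1:3]
      out <- out + sl
    }
    out
  }
  structure(list(donor = sum_bands(di), acceptor = sum_bands(ai),
                 donor_window = donor_window, acceptor_window = acceptor_window,
                 donor_bands = di, acceptor_bands = ai,
                 method = "band_window"),
            class = "channel_pair")
}

#' @export
print.channel_pair <- function(x, ...) {
  d <- dim(x$donor)
  cat(sprintf("<channel_pair> method %s, %d z x %dx%d px\n", x$method, d[1], d[2], d[3]))
  invisible(x)
}

#' Linear spectral unmixing
#'
#' Decomposes every pixel's band vector into non-negative abundances of the
#' reference fluorophores by least squares against the band-integrated
#' reference spectra. With two fluorophores the non-negative solution is
#' computed exactly: the unconstrained normal-equation solution is kept where
#' it is already non-negative, otherwise the best single-component
#' (or zero) fit by residual norm is substituted.
#'
#' @param stack A [lambda_stack()] with >= 2 bands.
#' @param spectra List of two [emission_spectrum()] objects (donor first);
#'   default [default_spectra()].
#' @return Object of class `channel_pair` with `method = "linear_unmix"`:
#'   `donor` and `acceptor` are the abundance volumes `(z, y, x)` and
#'   `residual` is the per-pixel residual norm volume.
#' @export
linear_unmix <- function(stack, spectra = default_spectra()) {
  stopifnot(inherits(stack, "lambda_stack"))
  spectra <- unname(spectra)
  if (length(spectra) != 2L ||
      !all(vapply(spectra, inherits, logical(1), "emission_spectrum")))
    stop("`spectra` must be a list of two emission_spectrum objects", call. = FALSE)
  d <- dim(stack$data)
  if (d[4] < 2L) stop("need >= 2 bands to unmix", call. = FALSE)
  M <- cbind(band_fractions(spectra[[1]], stack$band_edges),
             band_fractions(spectra[[2]], stack$band_edges))
  colnames(M) <- vapply(spectra, `[[`, character(1), "name")
  if (qr(M)$rank < 2L)
    stop(sprintf("reference spectra '%s' and '%s' are collinear on this band grid",
                 colnames(M)[1], colnames(M)[2]), call. = FALSE)
  B <- matrix(stack$data, nrow = prod(d[1:3]), ncol = d[4])   # pixels x bands
  MtM <- crossprod(M)
  X <- B %*% M %*% solve(MtM)                                  # unconstrained LS
  # exact 2-component NNLS: repair rows with a negative coefficient
  neg <- which(X[, 1] < 0 | X[, 2] < 0)
  if (length(neg)) {
    Bn <- B[neg, , drop = FALSE]
    c1 <- pmax(drop(Bn %*% M[, 1]) / MtM[1, 1], 0)
    c2 <- pmax(drop(Bn %*% M[, 2]) / MtM[2, 2], 0)
    r1 <- rowSums(Bn^2) - 2 * c1 * drop(Bn %*% M[, 1]) + c1^2 * MtM[1, 1]
    r2 <- rowSums(Bn^2) - 2 * c2 * drop(Bn %*% M[, 2]) + c2^2 * MtM[2, 2]
    X[neg, 1] <- ifelse(r1 <= r2, c1, 0)
    X[neg, 2] <- ifelse(r1 <= r2, 0, c2)
  }
  res2 <- rowSums(B^2) - 2 * rowSums((B %*% M) * X) +
    rowSums((X %*% MtM) * X)
  vol <- function(v) array(v, dim = d[1:3])
  structure(list(donor = vol(X[, 1]), acceptor = vol(X[, 2]),
                 residual = vol(sqrt(pmax(res2, 0))),
                 fluorophores = colnames(M), design = M,
                 method = "linear_unmix"),
            class = "channel_pair")
}
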
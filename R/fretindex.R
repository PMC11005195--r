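#' Sum-intensity z-projection
#'
#' Collapses a `(z, y, x)` volume to a 2D image by summing along z. A 2D
#' matrix is treated as a single plane and returned unchanged.
#'
#' @param volume Numeric `(z, y, x)` array or `(y, x)` matrix with >= 1 plane.
#' @return Numeric matrix.
#' @export
sum_projection <- function(volume) {
  if (is.matrix(volume)) {
    if (length(volume) == 0L) stop("empty volume", call. = FALSE)
    return(volume)
  }
  d <- dim(volume)
  if (is.null(d) || length(d) != 3L || d[1] < 1L || prod(d) == 0L)
    stop("`volume` must be a non-empty (z, y, x) array", call. = FALSE)
  matrix(colSums(matrix(volume, nrow = d[1])), d[2], d[3])
}

#' Ratiometric FRET/CFP image
#'
#' Divides the acceptor (FRET) image by the donor image pixel-wise, masking
#' out pixels whose donor signal falls below `donor_floor` so that background
#' and near-zero donors never produce unstable ratios. Invalid pixels are NA
#' in the ratio and FALSE in the validity mask; they are excluded from every
#' downstream ROI sum.
#'
#' @param acceptor_2d,donor_2d Numeric matrices of equal shape.
#' @param donor_floor Positive donor threshold; pixels with
#'   `donor < donor_floor` are invalid.
#' @return List of class `ratio_image` with `ratio` (matrix, NA where
#'   invalid), `valid` (logical matrix) and `donor_floor`.
#' @export
ratio_image <- function(acceptor_2d, donor_2d, donor_floor) {
  if (!identical(dim(acceptor_2d), dim(donor_2d)))
    stop("acceptor and donor images differ in shape", call. = FALSE)
  if (!is.numeric(donor_floor) || donor_floor <= 0)
    stop("`donor_floor` must be > 0", call. = FALSE)
  valid <- is.finite(donor_2d) & donor_2d >= donor_floor
  ratio <- matrix(NA_real_, nrow(donor_2d), ncol(donor_2d))
  ratio[valid] <- acceptor_2d[valid] / donor_2d[valid]
  structure(list(ratio = ratio, valid = valid, donor_floor = donor_floor),
            class = "ratio_image")
}

#' Per-ROI FRET index
#'
#' The live-imaging readout: raw integrated density (sum of pixel values, the
#' Fiji convention) of the ratiometric FRET/CFP image within an ROI, computed
#' from sum-intensity z-projections. The default order projects each channel
#' first and then divides ("ratio of projections"); the alternative
#' ("projection of ratios") divides per plane and then sums, kept behind the
#' `order` flag for sensitivity checks.
#'
#' @param channel_pair A `channel_pair` from [band_window_separation()] or
#'   [linear_unmix()].
#' @param roi Logical mask matrix (same y, x shape as the channels).
#' @param donor_floor Donor validity threshold; default 1 percent of the
#'   projected donor maximum.
#' @param order `"ratio_of_projections"` (default) or
#'   `"projection_of_ratios"`.
#' @return List of class `fret_index_measurement` with `index` (NA when the
#'   whole ROI is below the donor floor), `n_valid`, `n_roi`, `donor_floor`,
#'   `order` and `flag` (`"ok"` or `"all_below_floor"`).
#' @export
fret_index <- function(channel_pair, roi, donor_floor = NULL,
                       order = c("ratio_of_projections", "projection_of_ratios")) {
  stopifnot(inherits(channel_pair, "channel_pair"))
  order <- match.arg(order)
  don_p <- sum_projection(channel_pair$donor)
  acc_p <- sum_projection(channel_pair$acceptor)
  if (!is.logical(roi) || !identical(dim(roi), dim(don_p)))
    stop("`roi` must be a logical mask matching the image shape", call. = FALSE)
  if (!any(roi)) stop("empty ROI", call. = FALSE)
  if (is.null(donor_floor)) donor_floor <- 0.01 * max(don_p)
  if (order == "ratio_of_projections") {
    ri <- ratio_image(acc_p, don_p, donor_floor)
  } else {
    nz <- dim(channel_pair$donor)[1]
    acc_r <- matrix(0, nrow(don_p), ncol(don_p))
    valid <- matrix(TRUE, nrow(don_p), ncol(don_p))
    for (z in seq_len(nz)) {
      rz <- ratio_image(matrix(channel_pair$acceptor[z, , ], nrow(don_p)),
                        matrix(channel_pair$donor[z, , ], nrow(don_p)),
                        donor_floor / max(nz, 1))
      valid <- valid & rz$valid
      acc_r <- acc_r + ifelse(rz$valid, rz$ratio, 0)
    }
    # mean over planes keeps the two orders on the same scale
    ri <- list(ratio = ifelse(valid, acc_r / nz, NA_real_), valid = valid)
  }
  sel <- roi & ri$valid
  structure(list(index = if (any(sel)) sum(ri$ratio[sel]) else NA_real_,
                 n_valid = sum(sel), n_roi = sum(roi),
                 donor_floor = donor_floor, order = order,
                 flag = if (any(sel)) "ok" else "all_below_floor"),
            class = "fret_index_measurement")
}

#' @export
print.fret_index_measurement <- function(x, ...) {
  cat(sprintf("<fret_index> %.4g a.u. over %d/%d valid ROI px (floor %.3g, %s)\n",
              x$index, x$n_valid, x$n_roi, x$donor_floor, x$order))
  invisible(x)
}

#' FRET index for every embryo of a cohort
#'
#' Convenience wrapper: separates each embryo's lambda stack into channels and
#' measures the FRET index in the requested ground-truth domain.
#'
#' @param cohort A [make_cohort()] result rendered with `"lambda"`.
#' @param domain Domain label to measure; default each embryo's target domain.
#' @param method `"band_window"` or `"linear_unmix"`.
#' @param ... Passed to [fret_index()].
#' @return data.frame with columns `embryo_id`, `group`, `roi`, `index`.
#' @export
cohort_fret_index <- function(cohort, domain = NULL,
                              method = c("band_window", "linear_unmix"), ...) {
  stopifnot(inherits(cohort, "cohort"))
  method <- match.arg(method)
  rows <- lapply(cohort$embryos, function(e) {
    if (is.null(e$lambda)) stop("cohort was not rendered with lambda stacks", call. = FALSE)
    dom <- if (is.null(domain)) e$target_domain else domain
    cp <- if (method == "band_window") band_window_separation(e$lambda)
          else linear_unmix(e$lambda)
    m <- fret_index(cp, roi_from_domain(e$phantom, dom), ...)
    data.frame(embryo_id = e$embryo_id, group = e$group, roi = dom,
               index = m$index, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(unname(rows), list(make.row.names = FALSE)))
}

#' Group fold change of FRET indices
#'
#' Unpaired mode: each treated embryo's index is divided by the mean control
#' index; the group fold change is the mean of those per-embryo fold changes
#' (keeping per-embryo dispersion for SEM reporting). Paired mode divides each
#' embryo's post value by its own pre value.
#'
#' @param measurements data.frame with columns `group` and `index` (or
#'   `value`), or a named list of numeric vectors.
#' @param treated,control Group names.
#' @param paired If TRUE, `treated` and `control` vectors are matched
#'   per-embryo (equal lengths, same order).
#' @return List with `fc` (group fold change), `per_embryo_fc`, `treated`,
#'   `control` and `n`.
#' @export
fold_change <- function(measurements, treated, control, paired = FALSE) {
  if (is.data.frame(measurements)) {
    col <- if ("index" %in% names(measurements)) "index" else "value"
    vals <- split(measurements[[col]], measurements$group)
  } else vals <- measurements
  for (g in c(treated, control))
    if (is.null(vals[[g]]) || length(vals[[g]]) == 0L)
      stop(sprintf("group '%s' is empty", g), call. = FALSE)
  tv <- vals[[treated]]; cv <- vals[[control]]
  if (paired) {
    if (length(tv) != length(cv))
      stop("paired mode needs matched, equal-length groups", call. = FALSE)
    if (any(cv <= 0)) stop("control values must be > 0 in paired mode", call. = FALSE)
    per <- tv / cv
  } else {
    cm <- mean(cv)
    if (cm <= 0) stop("control mean must be > 0", call. = FALSE)
    per <- tv / cm
  }
  list(fc = mean(per), per_embryo_fc = per, treated = treated,
       control = control, n = c(treated = length(tv), control = length(cv)))
}
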
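# 4-connected component count via BFS; masks are modest so plain R is fine.
count_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  ncomp <- 0L
  idx <- which(mask)
  ny <- nrow(mask)
  stack <- integer(length(idx))
  for (start in idx) {
    if (lab[start] > 0L) next
    ncomp <- ncomp + 1L
    top <- 1L; stack[1L] <- start; lab[start] <- ncomp
    while (top > 0L) {
      p <- stack[top]; top <- top - 1L
      r <- (p - 1L) %% ny + 1L
      cc <- (p - 1L) %/% ny + 1L
      for (q in c(if (r > 1L) p - 1L, if (r < ny) p + 1L,
                  if (cc > 1L) p - ny, if (cc < ncol(mask)) p + ny)) {
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- ncomp; top <- top + 1L; stack[top] <- q
        }
      }
    }
  }
  ncomp
}

#' Equivalent-ellipse axis lengths of a binary mask
#'
#' Axis lengths of the intensity-equivalent ellipse computed from the second
#' central moments of the foreground pixels (the regionprops convention:
#' full axis length = 4 * sqrt of the corresponding covariance eigenvalue).
#' This replaces a hand-drawn axis line with a reproducible estimator; for a
#' filled ellipse it recovers the true axes.
#'
#' @param mask Logical matrix with exactly one 4-connected foreground
#'   component.
#' @return List with `major`, `minor` (pixels), `ratio` (major/minor >= 1)
#'   and `theta` (major-axis orientation, radians).
#' @export
axis_lengths <- function(mask) {
  if (!is.logical(mask) || !is.matrix(mask))
    stop("`mask` must be a logical matrix", call. = FALSE)
  if (!any(mask)) stop("empty mask (0 components)", call. = FALSE)
  nc <- count_components(mask)
  if (nc != 1L)
    stop(sprintf("mask must have exactly one connected component (found %d)", nc),
         call. = FALSE)
  ij <- which(mask, arr.ind = TRUE)
  xy <- cbind(x = ij[, 2], y = ij[, 1])
  # + 1/12: per-pixel variance of a unit square, stabilises thin masks
  S <- stats::cov(xy) * (nrow(xy) - 1) / nrow(xy) + diag(1 / 12, 2)
  ev <- eigen(S, symmetric = TRUE)
  major <- 4 * sqrt(ev$values[1]); minor <- 4 * sqrt(ev$values[2])
  list(major = major, minor = minor, ratio = major / minor,
       theta = atan2(ev$vectors[2, 1], ev$vectors[1, 1]))
}

#' Body length of an embryo
#'
#' Straight-line (snout to tail tip) body length: either the Euclidean
#' distance between two supplied endpoints, or the farthest pair of foreground
#' pixels of a binary mask (computed on the convex hull). Lengths are in
#' pixels unless a calibration is supplied.
#'
#' @param mask_or_endpoints Logical mask matrix, or a 2 x 2 numeric matrix /
#'   list of two `c(x, y)` points.
#' @param calibration Micrometres per pixel; default 1 (pixel units).
#' @return List with `length` and `endpoints` (2 x 2 matrix, columns x, y).
#' @export
body_length <- function(mask_or_endpoints, calibration = 1) {
  stopifnot(is.numeric(calibration), calibration > 0)
  if (is.list(mask_or_endpoints))
    mask_or_endpoints <- do.call(rbind, mask_or_endpoints)
  if (is.logical(mask_or_endpoints) && is.matrix(mask_or_endpoints)) {
    mask <- mask_or_endpoints
    if (sum(mask) < 2L) stop("mask has fewer than 2 foreground pixels", call. = FALSE)
    ij <- which(mask, arr.ind = TRUE)
    pts <- cbind(x = ij[, 2], y = ij[, 1])
    hull <- pts[grDevices::chull(pts), , drop = FALSE]
    dm <- as.matrix(stats::dist(hull))
    best <- which(dm == max(dm), arr.ind = TRUE)[1, ]
    ends <- hull[c(best[1], best[2]), , drop = FALSE]
  } else if (is.numeric(mask_or_endpoints) &&
             identical(dim(mask_or_endpoints), c(2L, 2L))) {
    ends <- mask_or_endpoints
    colnames(ends) <- c("x", "y")
  } else {
    stop("supply a logical mask or two endpoints", call. = FALSE)
  }
  len <- sqrt(sum((ends[1, ] - ends[2, ])^2))
  if (len == 0) stop("degenerate body length: coincident endpoints", call. = FALSE)
  list(length = len * calibration, endpoints = ends)
}

#' Oval-embryo assay group table
#'
#' Per-group medians and quartiles of the major/minor axis ratio (the
#' convergence-extension readout). Groups with a single embryo are flagged
#' underpowered rather than dropped.
#'
#' @param results data.frame with columns `group` and `axis_ratio` (raw
#'   per-embryo values), or a named list of numeric vectors.
#' @param group_order Optional character vector fixing the row order.
#' @return data.frame with `group`, `n`, `median`, `q1`, `q3`, `underpowered`;
#'   the raw values are attached as attribute `"values"`.
#' @export
oval_assay <- function(results, group_order = NULL) {
  if (is.data.frame(results)) {
    vals <- split(results$axis_ratio, results$group)
  } else vals <- results
  if (length(vals) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (!is.null(group_order)) {
    missing <- setdiff(group_order, names(vals))
    if (length(missing))
      stop(sprintf("missing group(s): %s", paste(missing, collapse = ", ")),
           call. = FALSE)
    vals <- vals[group_order]
  }
  tab <- do.call(rbind, c(lapply(names(vals), function(g) {
    v <- vals[[g]]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(group = g, n = length(v), median = q[2], q1 = q[1], q3 = q[3],
               underpowered = length(v) < 2L, stringsAsFactors = FALSE)
  }), list(make.row.names = FALSE)))
  attr(tab, "values") <- vals
  tab
}

#' Morphometry for every embryo of a cohort
#'
#' @param cohort A [make_cohort()] result rendered with `"morphology"`.
#' @param calibration Micrometres per pixel for body length; default 1.
#' @return data.frame with `embryo_id`, `group`, `major`, `minor`,
#'   `axis_ratio`, `body_length`.
#' @export
cohort_morphometry <- function(cohort, calibration = 1) {
  stopifnot(inherits(cohort, "cohort"))
  rows <- lapply(cohort$embryos, function(e) {
    if (is.null(e$morphology))
      stop("cohort was not rendered with morphology", call. = FALSE)
    ax <- axis_lengths(e$morphology$oval_mask)
    data.frame(embryo_id = e$embryo_id, group = e$group,
               major = ax$major, minor = ax$minor, axis_ratio = ax$ratio,
               body_length = e$morphology$body_length_px * calibration,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(unname(rows), list(make.row.names = FALSE)))
}
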
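#' Integrated band density with background correction
#'
#' Sums pixel intensities inside a rectangular band ROI and subtracts a
#' background estimate: the median of a same-size flanking region (directly
#' below the band, or above when the lower flank leaves the image) times the
#' ROI pixel count. When neither flank fits, the uncorrected sum is returned
#' with a warning. A uniform background is removed exactly by this rule.
#' Pixels at the stated saturation level raise a saturation warning.
#'
#' @param gel_image Numeric matrix.
#' @param rectangular_roi Numeric `c(x0, x1, y0, y1)`, 0-based half-open
#'   pixel bounds.
#' @param background_rule `"flank_median"` (default) or `"none"`.
#' @param saturation Optional intensity ceiling of the detector; pixels at or
#'   above it trigger a warning.
#' @return Background-corrected integrated density (numeric scalar) with
#'   attribute `"background"` (per-pixel background estimate used).
#' @export
band_density <- function(gel_image, rectangular_roi,
                         background_rule = c("flank_median", "none"),
                         saturation = NULL) {
  background_rule <- match.arg(background_rule)
  r <- as.numeric(rectangular_roi)
  if (length(r) != 4L) stop("ROI must be c(x0, x1, y0, y1)", call. = FALSE)
  x0 <- r[1]; x1 <- r[2]; y0 <- r[3]; y1 <- r[4]
  ny <- nrow(gel_image); nx <- ncol(gel_image)
  if (x0 < 0 || y0 < 0 || x1 > nx || y1 > ny || x1 <= x0 || y1 <= y0)
    stop("ROI outside image", call. = FALSE)
  sub <- gel_image[(y0 + 1):y1, (x0 + 1):x1, drop = FALSE]
  if (!is.null(saturation) && any(sub >= saturation))
    warning("saturated pixels inside band ROI", call. = FALSE)
  raw <- sum(sub)
  bg <- 0
  if (background_rule == "flank_median") {
    h <- y1 - y0
    if (y1 + h <= ny) {
      flank <- gel_image[(y1 + 1):(y1 + h), (x0 + 1):x1, drop = FALSE]
    } else if (y0 - h >= 0) {
      flank <- gel_image[(y0 - h + 1):y0, (x0 + 1):x1, drop = FALSE]
    } else {
      warning("no flanking region fits: returning uncorrected density",
              call. = FALSE)
      flank <- NULL
    }
    if (!is.null(flank)) bg <- stats::median(flank)
  }
  structure(raw - bg * length(sub), background = bg)
}

#' GAPDH-normalised pERK/tERK ratio
#'
#' Immunoblot readout: pERK and tERK densities are each normalised to the
#' GAPDH loading control, then divided:
#' `(pERK / GAPDH) / (tERK / GAPDH)`. Algebraically the loading control
#' cancels, so the result equals `pERK / tERK` for any positive GAPDH; it is
#' nevertheless computed literally, in the order stated.
#'
#' @param pERK,tERK,GAPDH Background-corrected integrated densities; `tERK`
#'   and `GAPDH` must be > 0.
#' @return Numeric ratio.
#' @export
normalized_perk_ratio <- function(pERK, tERK, GAPDH) {
  if (!is.finite(GAPDH) || GAPDH <= 0) stop("GAPDH density must be > 0", call. = FALSE)
  if (!is.finite(tERK) || tERK <= 0) stop("tERK density must be > 0", call. = FALSE)
  if (!is.finite(pERK) || pERK < 0) stop("pERK density must be >= 0", call. = FALSE)
  (pERK / GAPDH) / (tERK / GAPDH)
}

#' Immunofluorescence pERK/tERK ratio in an ROI
#'
#' Raw integrated density of the pERK channel divided by the raw integrated
#' density of the tERK channel inside one ROI (the whole-mount
#' immunostaining readout).
#'
#' @param pERK_image,tERK_image Aligned numeric matrices.
#' @param roi Logical mask.
#' @return Numeric ratio.
#' @export
if_perk_ratio <- function(pERK_image, tERK_image, roi) {
  if (!identical(dim(pERK_image), dim(tERK_image)))
    stop("pERK and tERK images differ in shape", call. = FALSE)
  if (!is.logical(roi) || !identical(dim(roi), dim(pERK_image)) || !any(roi))
    stop("`roi` must be a non-empty logical mask matching the images", call. = FALSE)
  ts <- sum(tERK_image[roi])
  if (ts == 0) stop("undefined ratio: tERK integrated density is 0", call. = FALSE)
  sum(pERK_image[roi]) / ts
}

#' Densitometry of a whole gel
#'
#' Quantifies every lane of a gel laid out as by [make_gel_phantom()] (given
#' its band rectangles) and reports the GAPDH-normalised pERK/tERK ratio per
#' lane.
#'
#' @param gel_image Numeric matrix.
#' @param band_table data.frame with columns `lane`, `target` (pERK, tERK,
#'   GAPDH) and the 0-based half-open bounds `x0`, `x1`, `y0`, `y1`.
#' @param ... Passed to [band_density()].
#' @return data.frame with columns `lane`, `pERK_density`, `tERK_density`,
#'   `GAPDH_density`, `norm_ratio`.
#' @export
quantify_gel <- function(gel_image, band_table, ...) {
  need <- c("lane", "target", "x0", "x1", "y0", "y1")
  if (!all(need %in% names(band_table)))
    stop("`band_table` needs columns lane, target, x0, x1, y0, y1", call. = FALSE)
  rows <- lapply(unique(band_table$lane), function(l) {
    get_d <- function(tg) {
      b <- band_table[band_table$lane == l & band_table$target == tg, ]
      if (nrow(b) != 1L) stop(sprintf("lane %s: no unique %s band", l, tg), call. = FALSE)
      as.numeric(band_density(gel_image, c(b$x0, b$x1, b$y0, b$y1), ...))
    }
    p <- get_d("pERK"); t <- get_d("tERK"); g <- get_d("GAPDH")
    data.frame(lane = l, pERK_density = p, tERK_density = t, GAPDH_density = g,
               norm_ratio = if (t > 0 && g > 0) normalized_perk_ratio(p, t, g)
                            else NA_real_)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
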
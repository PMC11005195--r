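#' Write a lambda stack to disk
#'
#' Stores the stack as a multi-page 32-bit float TIFF (pages ordered z-major,
#' band-minor) plus a JSON sidecar `<path>.json` holding the band edges,
#' excitation line, stage tag, array dimensions, intensity scale and free-form
#' metadata. Float TIFF samples are kept in [0, 1], so intensities are divided
#' by a recorded `scale` on write and re-multiplied on read; the round trip is
#' lossless to single-float precision.
#'
#' @param stack A [lambda_stack()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_lambda_stack <- function(stack, path) {
  stopifnot(inherits(stack, "lambda_stack"))
  d <- dim(stack$data)
  scale <- max(stack$data, 1)
  pages <- vector("list", d[1] * d[4])
  k <- 0L
  for (z in seq_len(d[1])) for (b in seq_len(d[4])) {
    k <- k + 1L
    pages[[k]] <- matrix(stack$data[z, , , b], d[2], d[3]) / scale
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  sidecar <- list(format = "fretbench-lambda-stack-v1",
                  dim = as.integer(d), band_edges = stack$band_edges,
                  excitation_nm = stack$excitation_nm, stage = stack$stage,
                  scale = scale, meta = stack$meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a lambda stack from disk
#'
#' Reads a TIFF written by [write_lambda_stack()], or any third-party
#' multi-page TIFF accompanied by a JSON sidecar with fields `dim`
#' (`c(z, y, x, bands)`), `band_edges` (nm, length bands + 1) and optionally
#' `excitation_nm`, `stage`, `scale`, `meta`.
#'
#' @param path TIFF path.
#' @param sidecar Sidecar path; default `<path>.json`.
#' @return A [lambda_stack()].
#' @export
read_lambda_stack <- function(path, sidecar = paste0(path, ".json")) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  if (!file.exists(sidecar))
    stop(sprintf(paste0("missing band metadata: expected JSON sidecar '%s' with ",
                        "fields dim = [z, y, x, bands] and band_edges (nm)"),
                 sidecar), call. = FALSE)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$dim) || is.null(meta$band_edges))
    stop("sidecar must provide `dim` and `band_edges`", call. = FALSE)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e)
                      stop(sprintf("cannot parse TIFF '%s': %s", path,
                                   conditionMessage(e)), call. = FALSE))
  d <- as.integer(meta$dim)
  if (length(pages) != d[1] * d[4])
    stop(sprintf("TIFF has %d pages but sidecar dim implies %d",
                 length(pages), d[1] * d[4]), call. = FALSE)
  scale <- if (is.null(meta$scale)) 1 else meta$scale
  data <- array(0, dim = d)
  k <- 0L
  for (z in seq_len(d[1])) for (b in seq_len(d[4])) {
    k <- k + 1L
    data[z, , , b] <- pages[[k]] * scale
  }
  lambda_stack(data, meta$band_edges,
               excitation_nm = if (is.null(meta$excitation_nm)) NA else meta$excitation_nm,
               stage = meta$stage,
               meta = if (is.null(meta$meta)) list() else meta$meta)
}

#' Read ROIs from a JSON file
#'
#' Accepts a JSON array of ROI objects, each with a `label` and either a
#' `rect` (`[x0, x1, y0, y1]`, 0-based half-open) or `vertices` (list of
#' `[x, y]` polygon corners, 0-based pixel coordinates; pixels whose centres
#' fall inside the polygon are selected).
#'
#' @param path JSON file path.
#' @param dim Image dimensions `c(ny, nx)` the masks are built for.
#' @return Named list of logical masks.
#' @export
read_roi_json <- function(path, dim) {
  rois <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- list()
  for (r in rois) {
    if (is.null(r$label)) stop("every ROI needs a `label`", call. = FALSE)
    if (!is.null(r$rect)) {
      v <- as.numeric(unlist(r$rect))
      out[[r$label]] <- rect_roi(v[1], v[2], v[3], v[4], dim)
    } else if (!is.null(r$vertices)) {
      vs <- do.call(rbind, lapply(r$vertices, function(p) as.numeric(unlist(p))))
      yy <- matrix(seq_len(dim[1]) - 0.5, dim[1], dim[2])
      xx <- matrix(seq_len(dim[2]) - 0.5, dim[1], dim[2], byrow = TRUE)
      inp <- pracma::inpolygon(as.vector(xx), as.vector(yy), vs[, 1], vs[, 2],
                               boundary = TRUE)
      m <- matrix(inp, dim[1], dim[2])
      if (!any(m)) stop(sprintf("ROI '%s' selects no pixels", r$label), call. = FALSE)
      out[[r$label]] <- m
    } else {
      stop(sprintf("ROI '%s' needs `rect` or `vertices`", r$label), call. = FALSE)
    }
  }
  out
}

#' Write ROI masks to JSON rectangles
#'
#' Writes the bounding rectangle of each mask (exact for rectangular masks;
#' a documented approximation otherwise).
#'
#' @param rois Named list of logical masks.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_roi_json <- function(rois, path) {
  objs <- lapply(names(rois), function(nm) {
    ij <- which(rois[[nm]], arr.ind = TRUE)
    list(label = nm,
         rect = c(min(ij[, 2]) - 1L, max(ij[, 2]), min(ij[, 1]) - 1L, max(ij[, 1])))
  })
  jsonlite::write_json(objs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
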
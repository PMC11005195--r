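#' Synthetic embryo activity phantom
#'
#' Generates a 2D embryo phantom with labelled activity domains and a known
#' per-pixel ERK-sensor activity field. The phantom is the ground-truth object
#' every downstream stage is validated against: the active-sensor fraction
#' `a(x,y)` is written exactly (constant within each domain), and the effective
#' FRET efficiency follows the two-state sensor model
#' `E_eff = a * E_active + (1 - a) * E_inactive`.
#'
#' Stages and their domains:
#' * `gastrula_5hpf` — circular blastoderm; `margin` (annulus at the rim of the
#'   animal pole, the high-FGF/ERK domain) and `bulk`.
#' * `segmentation_11hpf` — elliptical embryo; `tailbud` (posterior cap) and
#'   `bulk`.
#' * `pharyngula_24hpf` — elongated body; `forebrain`, `midbrain`, `hindbrain`
#'   (anterior discs), `tailbud` (posterior disc) and `bulk`.
#'
#' @param stage One of `"gastrula_5hpf"`, `"segmentation_11hpf"`,
#'   `"pharyngula_24hpf"`.
#' @param shape Image size `c(ny, nx)` in pixels, each >= 32.
#' @param domain_activities Named numeric vector of active-sensor fractions in
#'   `[0, 1]` per domain label; unnamed domains fall back to the `bulk` value
#'   (default 0.1).
#' @param seed Integer seed controlling the sensor-density texture.
#' @param e_inactive,e_active FRET efficiency of the open (inactive) and closed
#'   (active, phosphorylated) sensor conformation; defaults 0.05 and 0.35.
#'   These molecular defaults shape realism only; tests compare against the
#'   stored ground truth, not these values.
#' @param density_texture_sd Log-sd of the multiplicative lognormal texture on
#'   sensor density (0 disables texture).
#' @return An object of class `activity_phantom` with fields `activity`,
#'   `density`, `mask`, `labels` (character matrix), `efficiency`, `stage`,
#'   `e_inactive`, `e_active`, `shape`.
#' @export
make_embryo_phantom <- function(stage, shape = c(128L, 128L),
                                domain_activities = c(margin = 0.2, bulk = 0.1),
                                seed = 1L,
                                e_inactive = 0.05, e_active = 0.35,
                                density_texture_sd = 0.1) {
  stages <- c("gastrula_5hpf", "segmentation_11hpf", "pharyngula_24hpf")
  if (!is.character(stage) || length(stage) != 1L || !stage %in% stages)
    stop(sprintf("unknown stage '%s'; expected one of: %s",
                 paste(stage, collapse = ","), paste(stages, collapse = ", ")),
         call. = FALSE)
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 32L))
    stop("`shape` must be c(ny, nx) with both >= 32", call. = FALSE)
  if (any(domain_activities < 0 | domain_activities > 1))
    stop("domain activities must lie in [0, 1]", call. = FALSE)
  if (!(0 <= e_inactive && e_inactive < e_active && e_active < 1))
    stop("require 0 <= e_inactive < e_active < 1", call. = FALSE)

  ny <- shape[1]; nx <- shape[2]
  yy <- matrix(seq_len(ny), ny, nx)
  xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  cy <- (ny + 1) / 2; cx <- (nx + 1) / 2
  labels <- matrix("background", ny, nx)

  if (stage == "gastrula_5hpf") {
    r <- 0.42 * min(ny, nx)
    d <- sqrt((yy - cy)^2 + (xx - cx)^2)
    mask <- d <= r
    labels[mask] <- "bulk"
    labels[mask & d >= 0.80 * r] <- "margin"
  } else if (stage == "segmentation_11hpf") {
    a <- 0.45 * nx; b <- 0.30 * ny
    mask <- ((xx - cx) / a)^2 + ((yy - cy) / b)^2 <= 1
    labels[mask] <- "bulk"
    tb <- sqrt((xx - (cx + 0.85 * a))^2 + (yy - cy)^2) <= 0.25 * b
    labels[mask & tb] <- "tailbud"
  } else { # pharyngula_24hpf
    a <- 0.46 * nx; b <- 0.18 * ny
    mask <- ((xx - cx) / a)^2 + ((yy - cy) / b)^2 <= 1
    labels[mask] <- "bulk"
    rr <- 0.45 * b
    centres <- list(forebrain = cx - 0.85 * a, midbrain = cx - 0.62 * a,
                    hindbrain = cx - 0.39 * a, tailbud = cx + 0.88 * a)
    for (nm in names(centres)) {
      dom <- sqrt((xx - centres[[nm]])^2 + (yy - cy)^2) <= rr
      labels[mask & dom] <- nm
    }
  }

  bulk_a <- if ("bulk" %in% names(domain_activities)) domain_activities[["bulk"]] else 0.1
  activity <- matrix(0, ny, nx)
  for (nm in setdiff(unique(as.vector(labels)), "background")) {
    val <- if (nm %in% names(domain_activities)) domain_activities[[nm]] else bulk_a
    activity[labels == nm] <- val
  }

  set.seed(as.integer(seed))
  density <- matrix(1, ny, nx)
  if (density_texture_sd > 0)
    density <- density * matrix(exp(stats::rnorm(ny * nx, 0, density_texture_sd)), ny, nx)
  density[!mask] <- 0

  efficiency <- (e_inactive + activity * (e_active - e_inactive)) * mask
  structure(list(activity = activity, density = density, mask = mask,
                 labels = labels, efficiency = efficiency, stage = stage,
                 e_inactive = e_inactive, e_active = e_active,
                 shape = shape, seed = as.integer(seed)),
            class = "activity_phantom")
}

#' @export
print.activity_phantom <- function(x, ...) {
  doms <- setdiff(unique(as.vector(x$labels)), "background")
  cat(sprintf("<activity_phantom> stage %s, %dx%d px, domains: %s\n",
              x$stage, x$shape[1], x$shape[2], paste(sort(doms), collapse = ", ")))
  for (d in sort(doms))
    cat(sprintf("  %-10s mean activity %.3f (%d px)\n", d,
                mean(x$activity[x$labels == d]), sum(x$labels == d)))
  invisible(x)
}

#' Domain ROI from a phantom
#'
#' Returns the boolean mask of a labelled domain, the standard way to point a
#' measurement at the ground-truth region it should quantify.
#'
#' @param phantom An `activity_phantom`.
#' @param domain Domain label present in `phantom$labels`.
#' @return Logical matrix mask.
#' @export
roi_from_domain <- function(phantom, domain) {
  stopifnot(inherits(phantom, "activity_phantom"))
  m <- phantom$labels == domain
  if (!any(m))
    stop(sprintf("domain '%s' not present in phantom (has: %s)", domain,
                 paste(setdiff(unique(as.vector(phantom$labels)), "background"),
                       collapse = ", ")), call. = FALSE)
  m
}

#' Rectangular ROI mask
#'
#' Builds a boolean mask from 0-based, half-open pixel bounds
#' `[x0, x1) x [y0, y1)` — the coordinate convention used throughout.
#'
#' @param x0,x1,y0,y1 Integer pixel bounds, 0-based, half-open.
#' @param dim Image dimensions `c(ny, nx)`.
#' @return Logical matrix mask.
#' @export
rect_roi <- function(x0, x1, y0, y1, dim) {
  if (x1 <= x0 || y1 <= y0) stop("empty rectangle", call. = FALSE)
  if (x0 < 0 || y0 < 0 || x1 > dim[2] || y1 > dim[1])
    stop("ROI outside image bounds", call. = FALSE)
  m <- matrix(FALSE, dim[1], dim[2])
  m[(y0 + 1):y1, (x0 + 1):x1] <- TRUE
  m
}

#' Elliptical morphology phantom
#'
#' Renders a filled rotated ellipse mask with known axis lengths, the fixture
#' for validating axis-ratio morphometry (the oval-embryo readout of
#' convergence-extension defects).
#'
#' @param major_px,minor_px Full axis lengths in pixels (`major >= minor > 0`).
#' @param rotation_deg Rotation of the major axis, degrees counter-clockwise.
#' @param shape Image size `c(ny, nx)`.
#' @return Logical matrix mask.
#' @export
make_morphology_phantom <- function(major_px, minor_px, rotation_deg = 0,
                                    shape = c(256L, 256L)) {
  if (!(major_px >= minor_px && minor_px > 0))
    stop("require major_px >= minor_px > 0", call. = FALSE)
  if (major_px > min(shape))
    stop("ellipse axes exceed the image", call. = FALSE)
  ny <- shape[1]; nx <- shape[2]
  yy <- matrix(seq_len(ny), ny, nx) - (ny + 1) / 2
  xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE) - (nx + 1) / 2
  th <- rotation_deg * pi / 180
  u <- cos(th) * xx + sin(th) * yy
  v <- -sin(th) * xx + cos(th) * yy
  (u / (major_px / 2))^2 + (v / (minor_px / 2))^2 <= 1
}

#' Synthetic immunoblot (gel) phantom
#'
#' Renders rectangular pERK/tERK/GAPDH bands, one lane per sample, with known
#' integrated intensities above a uniform background, plus the truth table the
#' densitometry stage is checked against.
#'
#' @param lane_intensities Named list with numeric vectors `pERK`, `tERK`,
#'   `GAPDH` (equal length = number of lanes), integrated band intensities
#'   >= 0.
#' @param background_level Uniform background added per pixel (default 0).
#' @param noise_sd Gaussian pixel noise sd (default 0).
#' @param seed Integer seed for the noise.
#' @param band_w,band_h Band rectangle size in pixels.
#' @return List with `image` (matrix) and `truth` (data.frame with columns
#'   `lane`, `target`, `intensity`, and the 0-based half-open band bounds
#'   `x0`, `x1`, `y0`, `y1`).
#' @export
make_gel_phantom <- function(lane_intensities, background_level = 0,
                             noise_sd = 0, seed = 1L,
                             band_w = 20L, band_h = 8L) {
  targets <- c("pERK", "tERK", "GAPDH")
  if (!all(targets %in% names(lane_intensities)))
    stop("`lane_intensities` needs components pERK, tERK, GAPDH", call. = FALSE)
  n_lanes <- length(lane_intensities$pERK)
  lens <- vapply(lane_intensities[targets], length, integer(1))
  if (any(lens != n_lanes)) stop("lane vectors must have equal length", call. = FALSE)
  if (any(unlist(lane_intensities[targets]) < 0))
    stop("band intensities must be >= 0", call. = FALSE)

  gap_x <- 12L; gap_y <- 18L; margin <- 16L
  nx <- margin * 2L + n_lanes * band_w + (n_lanes - 1L) * gap_x
  ny <- margin * 2L + 3L * band_h + 2L * gap_y
  img <- matrix(background_level, ny, nx)
  truth <- data.frame(lane = integer(0), target = character(0),
                      intensity = numeric(0), x0 = integer(0), x1 = integer(0),
                      y0 = integer(0), y1 = integer(0))
  rects <- list()
  for (t_i in seq_along(targets)) {
    y0 <- margin + (t_i - 1L) * (band_h + gap_y)
    for (l in seq_len(n_lanes)) {
      x0 <- margin + (l - 1L) * (band_w + gap_x)
      rect <- c(x0 = x0, x1 = x0 + band_w, y0 = y0, y1 = y0 + band_h)
      for (r in rects)
        if (rect["x0"] < r["x1"] && r["x0"] < rect["x1"] &&
            rect["y0"] < r["y1"] && r["y0"] < rect["y1"])
          stop("overlapping bands in gel layout", call. = FALSE)
      rects[[length(rects) + 1L]] <- rect
      tot <- lane_intensities[[targets[t_i]]][l]
      img[(y0 + 1):(y0 + band_h), (x0 + 1):(x0 + band_w)] <-
        background_level + tot / (band_w * band_h)
      truth <- rbind(truth, data.frame(lane = l, target = targets[t_i],
                                       intensity = tot, x0 = x0,
                                       x1 = x0 + band_w, y0 = y0,
                                       y1 = y0 + band_h))
    }
  }
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    img <- pmax(img + matrix(stats::rnorm(ny * nx, 0, noise_sd), ny, nx), 0)
  }
  list(image = img, truth = truth)
}
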
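#' Forster distance configuration
#'
#' @param R0 Forster distance of the donor-acceptor pair in nm (the separation
#'   at which transfer efficiency is 50 percent); default 4.7 nm for the
#'   CFP-YFP pair.
#' @return List of class `forster_config`.
#' @export
forster_config <- function(R0 = 4.7) {
  if (!is.numeric(R0) || length(R0) != 1L || R0 <= 0)
    stop("`R0` must be a positive number (nm)", call. = FALSE)
  structure(list(R0 = R0), class = "forster_config")
}

#' FRET efficiency from donor de-quenching
#'
#' The acceptor-photobleaching estimator: `E = (DOmega - DA) / DOmega`, where
#' `DA` is the ROI-mean donor intensity before bleaching (the two pre-bleach
#' scans are averaged first) and `DOmega` the ROI-mean donor intensity after.
#' Negative estimates (donor dimmer after bleaching, e.g. from noise at E
#' near 0) are reported as-is and flagged, never clamped.
#'
#' @param pre_donor_frames A matrix or a list of pre-bleach donor frames
#'   (averaged pixel-wise before the ROI mean).
#' @param post_donor_frame Post-bleach donor frame.
#' @param roi Logical mask.
#' @return List with `DA`, `DOmega`, `E` and `negative` flag.
#' @export
ab_efficiency <- function(pre_donor_frames, post_donor_frame, roi) {
  if (is.matrix(pre_donor_frames)) pre_donor_frames <- list(pre_donor_frames)
  if (length(pre_donor_frames) < 1L) stop("need >= 1 pre-bleach frame", call. = FALSE)
  pre <- Reduce(`+`, pre_donor_frames) / length(pre_donor_frames)
  if (!identical(dim(pre), dim(post_donor_frame)))
    stop("pre and post frames differ in shape", call. = FALSE)
  if (!is.logical(roi) || !identical(dim(roi), dim(pre)) || !any(roi))
    stop("`roi` must be a non-empty logical mask matching the frames", call. = FALSE)
  DA <- mean(pre[roi])
  DOmega <- mean(post_donor_frame[roi])
  if (DOmega == 0) stop("undefined efficiency: post-bleach donor mean is 0", call. = FALSE)
  E <- (DOmega - DA) / DOmega
  list(DA = DA, DOmega = DOmega, E = E, negative = E < 0)
}

#' Donor-acceptor distance from FRET efficiency
#'
#' Inverts the Forster relation: `R_DA = R0 * (1/E - 1)^(1/6)` nm. At
#' `E = 0.5` this returns `R0` itself. Vectorised; efficiencies <= 0 are
#' excluded (NA, matching the exclusion of zero-efficiency ROIs from distance
#' reporting) and efficiencies >= 1 return the limit 0 with a warning.
#'
#' @param E Transfer efficiency fraction(s).
#' @param forster A [forster_config()].
#' @return Numeric vector of distances in nm (NA where excluded).
#' @export
distance_from_efficiency <- function(E, forster = forster_config()) {
  stopifnot(inherits(forster, "forster_config"))
  out <- rep(NA_real_, length(E))
  ok <- is.finite(E) & E > 0 & E < 1
  out[ok] <- forster$R0 * (1 / E[ok] - 1)^(1 / 6)
  sat <- is.finite(E) & E >= 1
  if (any(sat)) {
    warning("efficiency >= 1: distance at the R_DA -> 0 limit", call. = FALSE)
    out[sat] <- 0
  }
  out
}

#' Pre-bleach intensity metrics
#'
#' Signal-intensity readouts acquired before acceptor photobleaching: the
#' ROI-mean acceptor to ROI-mean donor ratio and the ROI-mean donor intensity.
#' Under MEK inhibition the margin shows a lower acceptor/donor ratio and a
#' brighter donor (reduced donor quenching).
#'
#' @param pre_donor,pre_acceptor Matrices or lists of pre-bleach frames
#'   (averaged pixel-wise).
#' @param roi Logical mask.
#' @return List with `pre_ratio` and `pre_donor`.
#' @export
pre_ab_metrics <- function(pre_donor, pre_acceptor, roi) {
  if (is.matrix(pre_donor)) pre_donor <- list(pre_donor)
  if (is.matrix(pre_acceptor)) pre_acceptor <- list(pre_acceptor)
  don <- Reduce(`+`, pre_donor) / length(pre_donor)
  acc <- Reduce(`+`, pre_acceptor) / length(pre_acceptor)
  if (!identical(dim(don), dim(acc)))
    stop("donor and acceptor frames differ in shape", call. = FALSE)
  if (!is.logical(roi) || !identical(dim(roi), dim(don)) || !any(roi))
    stop("`roi` must be a non-empty logical mask matching the frames", call. = FALSE)
  dm <- mean(don[roi])
  if (dm == 0) stop("undefined ratio: donor ROI mean is 0", call. = FALSE)
  list(pre_ratio = mean(acc[roi]) / dm, pre_donor = dm)
}

#' Full AB-FRET evaluation of a bleach series
#'
#' Per-ROI efficiency, donor-acceptor distance (with the E <= 0 exclusion
#' rule) and pre-bleach metrics in one record. ROIs not fully inside the
#' bleached region are flagged `not_bleached` and their efficiency is omitted
#' (the de-quenching model only holds where the acceptor was bleached).
#'
#' @param bleach_series A [render_bleach_series()] result (or any list with
#'   the same fields).
#' @param rois Named list of logical masks.
#' @param forster A [forster_config()].
#' @param embryo_id Optional id stamped on every row.
#' @return data.frame with columns `embryo_id`, `roi`, `E`, `E_percent`,
#'   `R_DA_nm`, `excluded_reason` (`"none"`, `"E_zero_or_negative"` or
#'   `"not_bleached"`), `pre_ratio`, `pre_donor`.
#' @export
run_abfret <- function(bleach_series, rois, forster = forster_config(),
                       embryo_id = NA_character_) {
  if (!is.list(rois) || is.null(names(rois)) || any(names(rois) == ""))
    stop("`rois` must be a named list of masks", call. = FALSE)
  rows <- lapply(names(rois), function(nm) {
    roi <- rois[[nm]]
    pm <- pre_ab_metrics(bleach_series$pre_donor, bleach_series$pre_acceptor, roi)
    bleached <- all(bleach_series$bleach_roi[roi])
    if (!bleached) {
      return(data.frame(embryo_id = embryo_id, roi = nm, E = NA_real_,
                        E_percent = NA_real_, R_DA_nm = NA_real_,
                        excluded_reason = "not_bleached",
                        pre_ratio = pm$pre_ratio, pre_donor = pm$pre_donor,
                        stringsAsFactors = FALSE))
    }
    est <- ab_efficiency(bleach_series$pre_donor, bleach_series$post_donor, roi)
    r_da <- if (est$E > 0) suppressWarnings(distance_from_efficiency(est$E, forster))
            else NA_real_
    data.frame(embryo_id = embryo_id, roi = nm, E = est$E,
               E_percent = 100 * est$E, R_DA_nm = r_da,
               excluded_reason = if (est$E <= 0) "E_zero_or_negative" else "none",
               pre_ratio = pm$pre_ratio, pre_donor = pm$pre_donor,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' AB-FRET for every embryo of a cohort
#'
#' @param cohort A [make_cohort()] result rendered with `"bleach"`.
#' @param forster A [forster_config()].
#' @return data.frame (one row per embryo) as in [run_abfret()] plus `group`.
#' @export
cohort_abfret <- function(cohort, forster = forster_config()) {
  stopifnot(inherits(cohort, "cohort"))
  rows <- lapply(cohort$embryos, function(e) {
    if (is.null(e$bleach)) stop("cohort was not rendered with bleach series", call. = FALSE)
    rois <- list(roi_from_domain(e$phantom, e$target_domain))
    names(rois) <- e$target_domain
    out <- run_abfret(e$bleach, rois, forster, embryo_id = e$embryo_id)
    out$group <- e$group
    out
  })
  do.call(rbind, c(unname(rows), list(make.row.names = FALSE)))
}

#' Classify efficiencies as high or low
#'
#' Splits E-percent values at a threshold (default 7.53) into high (`>`) and
#' low (`<`) classes; values exactly at the threshold count as low (documented
#' tie rule). Accepts one numeric vector or a named list of per-group vectors.
#'
#' @param E_values_percent Numeric vector, or named list of vectors (groups).
#' @param threshold Positive E-percent threshold, default 7.53.
#' @return data.frame with columns `group`, `n`, `n_high`, `n_low`,
#'   `prop_high`.
#' @export
classify_by_threshold <- function(E_values_percent, threshold = 7.53) {
  if (!is.numeric(threshold) || threshold <= 0)
    stop("`threshold` must be > 0", call. = FALSE)
  if (!is.list(E_values_percent))
    E_values_percent <- list(all = E_values_percent)
  rows <- lapply(names(E_values_percent), function(g) {
    v <- E_values_percent[[g]]
    if (length(v) == 0L) stop(sprintf("group '%s' is empty", g), call. = FALSE)
    hi <- sum(v > threshold)
    data.frame(group = g, n = length(v), n_high = hi, n_low = length(v) - hi,
               prop_high = hi / length(v), stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
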
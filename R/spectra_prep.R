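# Profile-spectrum preprocessing: Savitzky-Golay smoothing, thresholded peak
# detection, centroiding, charge-1 deisotoping, contaminant removal.

#' Preprocessing parameters
#'
#' Defaults follow the vendor-style processing chain used for the fingertip
#' smear spectra: SG smoothing window of +/-3 points with 2 cycles, a 700 a.u.
#' intensity threshold (the surrogate for S/N < 3 exclusion), centroiding
#' from the top 80% of peak height with a minimum width at half height of 5
#' grid points, and charge-1 deisotoping restricted to 700-2000 Da.
#'
#' @param sg_halfwidth SG half-window in points (window = 2*halfwidth + 1).
#' @param sg_cycles Number of smoothing passes.
#' @param sg_polyorder SG polynomial order.
#' @param intensity_threshold Apex threshold in a.u.; sub-threshold maxima
#'   are recorded with intensity 0.
#' @param centroid_top_pct Percent of peak height used for the centroid
#'   (points with intensity >= (1 - pct/100) * apex).
#' @param min_fwhm_points Minimum peak width at half height, in grid points.
#' @param deiso_min,deiso_max Deisotoping mass window (Da).
#' @param iso_spacing Isotope spacing at charge 1 (Da).
#' @param iso_tol Isotope-position tolerance (Da).
#' @param iso_max_k Maximum satellites per envelope.
#' @param contaminant_tol_ppm Tolerance for exclusion-list removal.
#' @return A list of class `prep_params`.
#' @export
prep_params <- function(sg_halfwidth = 3L, sg_cycles = 2L, sg_polyorder = 2L,
                        intensity_threshold = 700, centroid_top_pct = 80,
                        min_fwhm_points = 5L, deiso_min = 700,
                        deiso_max = 2000, iso_spacing = 1.00235,
                        iso_tol = 0.01, iso_max_k = 3L,
                        contaminant_tol_ppm = 10) {
  p <- list(sg_halfwidth = as.integer(sg_halfwidth),
            sg_cycles = as.integer(sg_cycles),
            sg_polyorder = as.integer(sg_polyorder),
            intensity_threshold = intensity_threshold,
            centroid_top_pct = centroid_top_pct,
            min_fwhm_points = as.integer(min_fwhm_points),
            deiso_min = deiso_min, deiso_max = deiso_max,
            iso_spacing = iso_spacing, iso_tol = iso_tol,
            iso_max_k = as.integer(iso_max_k),
            contaminant_tol_ppm = contaminant_tol_ppm)
  stopifnot(p$sg_halfwidth > 0L, p$sg_cycles > 0L,
            p$intensity_threshold > 0, p$min_fwhm_points > 0L,
            p$deiso_min < p$deiso_max, p$iso_tol > 0)
  class(p) <- "prep_params"
  p
}

validate_profile <- function(profile) {
  stopifnot(is.data.frame(profile), all(c("mz", "intensity") %in%
                                          names(profile)))
  if (nrow(profile) >= 2L && any(diff(profile$mz) <= 0)) {
    stop("profile m/z grid must be strictly increasing", call. = FALSE)
  }
  invisible(profile)
}

#' Savitzky-Golay smoothing of a profile spectrum
#'
#' Applies a Savitzky-Golay filter (window `2*sg_halfwidth + 1`, order
#' `sg_polyorder`) `sg_cycles` times; the m/z grid is unchanged.
#'
#' @param profile Data.frame with `mz` and `intensity` on a strictly
#'   increasing grid.
#' @param params A [prep_params()] object.
#' @return The smoothed profile.
#' @export
smooth_profile <- function(profile, params = prep_params()) {
  validate_profile(profile)
  window <- 2L * params$sg_halfwidth + 1L
  if (nrow(profile) < window) {
    stop(sprintf("profile has %d points; SG window needs >= %d",
                 nrow(profile), window), call. = FALSE)
  }
  y <- profile$intensity
  for (i in seq_len(params$sg_cycles)) {
    y <- signal::sgolayfilt(y, p = params$sg_polyorder, n = window)
  }
  profile$intensity <- y
  profile
}

#' Detect peak regions in a smoothed profile
#'
#' Local maxima become peak regions extending down to the surrounding local
#' minima. Maxima whose apex falls below the intensity threshold are reported
#' with intensity recorded as 0 (and excluded from centroiding).
#'
#' @param profile Smoothed profile data.frame.
#' @param threshold Apex intensity threshold in a.u.
#' @return A data.frame of regions: `apex_idx`, `left`, `right`, `apex_mz`,
#'   `apex_intensity` (0 if sub-threshold), `above_threshold`.
#' @export
detect_peaks <- function(profile, threshold = 700) {
  validate_profile(profile)
  y <- profile$intensity
  n <- length(y)
  empty <- data.frame(apex_idx = integer(0), left = integer(0),
                      right = integer(0), apex_mz = numeric(0),
                      apex_intensity = numeric(0),
                      above_threshold = logical(0))
  if (n < 3L) return(empty)
  # local maxima: rising (or flat) on the left, strictly falling on the right
  is_max <- which(y[2:(n - 1)] >= y[1:(n - 2)] & y[2:(n - 1)] > y[3:n]) + 1L
  if (!length(is_max)) return(empty)
  is_min <- c(1L, which(y[2:(n - 1)] <= y[1:(n - 2)] &
                          y[2:(n - 1)] <= y[3:n]) + 1L, n)
  regions <- lapply(is_max, function(m) {
    left <- max(is_min[is_min < m])
    right <- min(is_min[is_min > m])
    above <- y[m] >= threshold
    data.frame(apex_idx = m, left = left, right = right,
               apex_mz = profile$mz[m],
               apex_intensity = if (above) y[m] else 0,
               above_threshold = above)
  })
  out <- do.call(rbind, regions)
  rownames(out) <- NULL
  out
}

#' Centroid detected peak regions
#'
#' For each above-threshold region, the centroid m/z is the intensity-weighted
#' mean over the points whose intensity lies within the top
#' `centroid_top_pct`% of the apex height (i.e. >= (1 - pct/100) * apex); the
#' reported intensity is the apex. Regions narrower than `min_fwhm_points`
#' grid points at half height are discarded. Centroid m/z is reported to 3
#' decimal places; colliding positions keep the maximum intensity.
#'
#' @param profile Smoothed profile data.frame.
#' @param regions Regions from [detect_peaks()].
#' @param params A [prep_params()] object.
#' @return A peak list data.frame (`mz`, `intensity`), m/z ascending.
#' @export
centroid_peaks <- function(profile, regions, params = prep_params()) {
  y <- profile$intensity
  keep <- regions[regions$above_threshold, , drop = FALSE]
  out <- data.frame(mz = numeric(0), intensity = numeric(0))
  cut_frac <- 1 - params$centroid_top_pct / 100
  for (i in seq_len(nrow(keep))) {
    idx <- keep$left[i]:keep$right[i]
    apex <- y[keep$apex_idx[i]]
    fwhm_pts <- sum(y[idx] >= apex / 2)
    if (fwhm_pts < params$min_fwhm_points) next
    top <- idx[y[idx] >= cut_frac * apex]
    mz <- sum(profile$mz[top] * y[top]) / sum(y[top])
    out <- rbind(out, data.frame(mz = round(mz, 3), intensity = apex))
  }
  if (nrow(out)) {
    out <- stats::aggregate(intensity ~ mz, data = out, FUN = max)
    out <- out[order(out$mz), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Deisotope a centroided peak list (charge 1)
#'
#' Within `[deiso_min, deiso_max]`, peaks sitting `k * iso_spacing`
#' (k = 1..`iso_max_k`) above a retained peak within `iso_tol` Da, with
#' intensity lower than their predecessor in the chain, are removed; the
#' lowest-m/z member of each chain (the monoisotopic peak) is retained.
#' Peaks outside the mass window pass through untouched.
#'
#' @param peaks Centroided peak list (`mz`, `intensity`), m/z ascending.
#' @param params A [prep_params()] object.
#' @return The deisotoped peak list.
#' @export
deisotope <- function(peaks, params = prep_params()) {
  if (nrow(peaks) < 2L) return(peaks)
  ord <- order(peaks$mz)
  peaks <- peaks[ord, , drop = FALSE]
  n <- nrow(peaks)
  retained <- rep(TRUE, n)
  in_win <- peaks$mz >= params$deiso_min & peaks$mz <= params$deiso_max
  for (i in seq_len(n)) {
    if (!retained[i] || !in_win[i]) next
    prev_int <- peaks$intensity[i]
    for (k in seq_len(params$iso_max_k)) {
      target <- peaks$mz[i] + k * params$iso_spacing
      cand <- which(retained & in_win & abs(peaks$mz - target) <=
                      params$iso_tol & peaks$intensity < prev_int)
      if (!length(cand)) break
      j <- cand[which.min(abs(peaks$mz[cand] - target))]
      retained[j] <- FALSE
      prev_int <- peaks$intensity[j]
    }
  }
  out <- peaks[retained, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove contaminant peaks using an exclusion list
#'
#' Peaks within `tol_ppm` of any exclusion m/z (CHCA matrix clusters/adducts,
#' trypsin autolysis) are removed; removals are recorded in the `"removed"`
#' attribute with the matching exclusion label.
#'
#' @param peaks Peak list (`mz`, `intensity`).
#' @param exclusions Data.frame `mz`, `label` (see [read_exclusion_list()]).
#' @param tol_ppm Removal tolerance in ppm (default 10).
#' @return The filtered peak list with attribute `removed`.
#' @export
remove_contaminants <- function(peaks, exclusions, tol_ppm = 10) {
  if (nrow(peaks) == 0L || is.null(exclusions) || nrow(exclusions) == 0L) {
    attr(peaks, "removed") <- peaks[0L, , drop = FALSE]
    return(peaks)
  }
  hit_label <- rep(NA_character_, nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    ppm <- abs(ppm_error(peaks$mz[i], exclusions$mz))
    j <- which.min(ppm)
    if (ppm[j] <= tol_ppm) hit_label[i] <- exclusions$label[j]
  }
  removed <- peaks[!is.na(hit_label), , drop = FALSE]
  if (nrow(removed)) removed$label <- hit_label[!is.na(hit_label)]
  out <- peaks[is.na(hit_label), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- removed
  out
}

#' Full preprocessing chain for one profile spectrum
#'
#' smooth -> detect -> centroid -> deisotope -> remove contaminants.
#'
#' @param profile Profile data.frame (`mz`, `intensity`).
#' @param params A [prep_params()] object.
#' @param exclusions Exclusion list (default: the shipped config); pass
#'   `NULL` to skip contaminant removal.
#' @return A cleaned, centroided, deisotoped peak list.
#' @export
preprocess_spectrum <- function(profile, params = prep_params(),
                                exclusions = read_exclusion_list()) {
  sm <- smooth_profile(profile, params)
  regions <- detect_peaks(sm, params$intensity_threshold)
  peaks <- centroid_peaks(sm, regions, params)
  peaks <- deisotope(peaks, params)
  if (!is.null(exclusions)) {
    peaks <- remove_contaminants(peaks, exclusions,
                                 params$contaminant_tol_ppm)
  }
  peaks
}

#' Read / write two-column peak list or profile files
#'
#' The plain-text dialect used throughout: two whitespace-delimited columns,
#' m/z then intensity, ascending m/z, no header.
#'
#' @param path File path.
#' @return For the reader, a data.frame `mz`, `intensity`.
#' @export
read_peaklist <- function(path) {
  tab <- utils::read.table(path, header = FALSE,
                           col.names = c("mz", "intensity"))
  tab[order(tab$mz), , drop = FALSE]
}

#' @rdname read_peaklist
#' @param peaks Data.frame `mz`, `intensity` to write.
#' @export
write_peaklist <- function(peaks, path) {
  lines <- sprintf("%.3f\t%.6f", peaks$mz, peaks$intensity)
  writeLines(lines, path)
  invisible(path)
}
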
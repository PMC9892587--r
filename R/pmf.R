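# Peptide mass fingerprint matching: ppm filters, blank screening,
# contaminant exclusion lists, per-condition summaries.

#' Signed ppm mass error
#'
#' `(observed - theoretical) / theoretical * 1e6`. Reported values are
#' conventionally rounded to 1 decimal place.
#'
#' @param observed,theoretical Observed and theoretical m/z (Da); vectors
#'   are recycled.
#' @return Signed ppm error(s).
#' @examples
#' ppm_error(1065.509, mh_mass("STMQELNSR"))  # ~ +9.1
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(!is.finite(theoretical)) || any(theoretical <= 0)) {
    stop("theoretical m/z must be positive", call. = FALSE)
  }
  (observed - theoretical) / theoretical * 1e6
}

#' Match observed peaks against an in silico digest
#'
#' Pairs every observed peak with every peptide whose theoretical [M+H]+ lies
#' within `tol_ppm`. A peak may match several (isobaric) peptides; all matches
#' are kept and sorted by absolute ppm error. Spacer-derived peptides are
#' excluded unless `include_spacer = TRUE`.
#'
#' @param peaks A data.frame with columns `mz` and (optionally) `intensity`.
#' @param peptides A `peptide_records` data.frame from [digest_master()].
#' @param tol_ppm Match tolerance in ppm (default 30, the initial screen).
#' @param include_spacer Keep spacer-contaminated peptides as candidates?
#' @return A data.frame of class `peak_matches`: `mz`, `intensity`,
#'   `sequence`, `missed`, `n_ox`, `mh`, `ppm`, sorted by `abs(ppm)`.
#' @export
match_peaks <- function(peaks, peptides, tol_ppm = 30, include_spacer = FALSE) {
  empty <- data.frame(mz = numeric(0), intensity = numeric(0),
                      sequence = character(0), missed = integer(0),
                      n_ox = integer(0), mh = numeric(0), ppm = numeric(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("peak_matches", "data.frame")
  if (is.null(peaks) || nrow(peaks) == 0L || nrow(peptides) == 0L) {
    return(empty)
  }
  stopifnot("mz" %in% names(peaks))
  if (!"intensity" %in% names(peaks)) peaks$intensity <- NA_real_
  if (!include_spacer && "spacer" %in% names(peptides)) {
    peptides <- peptides[!peptides$spacer, , drop = FALSE]
  }
  if (nrow(peptides) == 0L) return(empty)
  rows <- lapply(seq_len(nrow(peaks)), function(i) {
    ppm <- ppm_error(peaks$mz[i], peptides$mh)
    hit <- which(abs(ppm) <= tol_ppm)
    if (!length(hit)) return(NULL)
    data.frame(mz = peaks$mz[i], intensity = peaks$intensity[i],
               sequence = peptides$sequence[hit],
               missed = peptides$missed[hit], n_ox = peptides$n_ox[hit],
               mh = peptides$mh[hit], ppm = ppm[hit],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  out <- out[order(abs(out$ppm), out$mz), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("peak_matches", "data.frame")
  out
}

#' Refine matches against centroided peaks
#'
#' Keeps only matches whose nearest centroided peak lies within `tol_ppm` of
#' the peptide's theoretical [M+H]+ (the 10 ppm acceptance step applied after
#' centroiding).
#'
#' @param matches A `peak_matches` data.frame.
#' @param centroid_peaks Data.frame of centroided peaks with column `mz`.
#' @param tol_ppm Acceptance tolerance in ppm (default 10).
#' @return The retained subset of `matches`.
#' @export
refine_matches <- function(matches, centroid_peaks, tol_ppm = 10) {
  if (nrow(matches) == 0L) return(matches)
  stopifnot("mz" %in% names(centroid_peaks))
  if (nrow(centroid_peaks) == 0L) return(matches[0L, , drop = FALSE])
  keep <- vapply(seq_len(nrow(matches)), function(i) {
    ppm <- ppm_error(centroid_peaks$mz, matches$mh[i])
    any(abs(ppm) <= tol_ppm)
  }, logical(1))
  out <- matches[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Screen matches against blank (control) peaks
#'
#' Removes any match whose observed m/z lies within `tol_ppm` of a peak seen
#' in a control (no-fingermark) digest.
#'
#' @param matches A `peak_matches` data.frame.
#' @param blank_peaks Data.frame with column `mz` of blank peaks (possibly
#'   empty).
#' @param tol_ppm Exclusion tolerance in ppm (default 10).
#' @return The retained subset of `matches`.
#' @export
screen_blanks <- function(matches, blank_peaks, tol_ppm = 10) {
  if (nrow(matches) == 0L || is.null(blank_peaks) ||
      nrow(blank_peaks) == 0L) {
    return(matches)
  }
  keep <- vapply(matches$mz, function(mz) {
    all(abs(ppm_error(mz, blank_peaks$mz)) > tol_ppm)
  }, logical(1))
  out <- matches[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Default contaminant exclusion list
#'
#' CHCA matrix cluster/adduct and porcine trypsin autolysis reference m/z
#' values, shipped as an editable two-column config
#' (`extdata/exclusions.txt`). The trypsin autolysis peptide at m/z 842.5094
#' doubles as the relative-intensity normalization reference.
#'
#' @param path Optional path to an alternative exclusion file
#'   (whitespace-delimited `mz label`).
#' @return A data.frame `mz`, `label`, sorted by m/z.
#' @export
read_exclusion_list <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "exclusions.txt", package = "maldiscreen",
                        mustWork = TRUE)
  }
  tab <- utils::read.table(path, header = FALSE, col.names = c("mz", "label"),
                           stringsAsFactors = FALSE)
  if (any(tab$mz <= 0)) stop("exclusion m/z must be positive", call. = FALSE)
  tab <- tab[order(tab$mz), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Summarise matched peptides for one digestion condition
#'
#' For each replicate peak list, counts matched peptide peaks and sums their
#' absolute intensities; relative intensities are normalised per replicate by
#' the intensity of the trypsin autolysis reference peak (m/z 842.5094 by
#' default), matched within `tol_ppm`. Means and standard deviations across
#' replicates are reported. If a replicate lacks the reference peak, its
#' relative sum is `NA` and the summary flags the relative metrics undefined.
#'
#' @param replicates A list of matched peak lists (data.frames with `mz`,
#'   `intensity`).
#' @param ref_mz Reference peak m/z (default trypsin autolysis 842.5094).
#' @param tol_ppm Tolerance for locating the reference peak (default 10).
#' @param condition Optional condition identifier.
#' @return A list of class `condition_summary` with per-replicate vectors
#'   (`n_peptides`, `sum_abs`, `sum_rel`) and their means/sds.
#' @export
summarize_condition <- function(replicates, ref_mz = 842.5094, tol_ppm = 10,
                                condition = NA_character_) {
  stopifnot(is.list(replicates))
  n_pep <- integer(length(replicates))
  s_abs <- numeric(length(replicates))
  s_rel <- rep(NA_real_, length(replicates))
  for (i in seq_along(replicates)) {
    rep_i <- replicates[[i]]
    if (is.null(rep_i) || nrow(rep_i) == 0L) next
    n_pep[i] <- nrow(rep_i)
    s_abs[i] <- sum(rep_i$intensity)
    ref <- which(abs(ppm_error(rep_i$mz, ref_mz)) <= tol_ppm)
    if (length(ref)) {
      s_rel[i] <- s_abs[i] / max(rep_i$intensity[ref])
    }
  }
  structure(list(
    condition = condition,
    n_peptides = n_pep, sum_abs = s_abs, sum_rel = s_rel,
    mean_n = mean(n_pep), sd_n = stats::sd(n_pep),
    mean_abs = mean(s_abs), sd_abs = stats::sd(s_abs),
    mean_rel = if (all(is.na(s_rel))) NA_real_ else mean(s_rel, na.rm = TRUE),
    sd_rel = if (all(is.na(s_rel))) NA_real_ else stats::sd(s_rel, na.rm = TRUE),
    rel_defined = !anyNA(s_rel)
  ), class = "condition_summary")
}

#' Reference fingermark identifications
#'
#' The putative peptide identifications from in situ tryptic digests of
#' ungroomed fingermarks under four proteolysis conditions (protein, observed
#' m/z, sequence, reported ppm error), used as worked examples for the
#' mass-accuracy pipeline.
#'
#' @return A data.frame with columns `condition`, `protein`, `observed_mz`,
#'   `sequence`, `ppm_reported`.
#' @export
pmf_reference <- function() {
  path <- system.file("extdata", "fingermark_pmf_reference.csv",
                      package = "maldiscreen", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
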
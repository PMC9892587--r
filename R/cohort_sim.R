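# Synthetic cohort generator: emulates the study design (3 diagnosis classes
# x 5 donors x 3 fingers x 3 technical replicates = 135 spectra, m/z
# 600-2800) with class-dependent marker shifts, shared donor effects,
# replicate noise, 3-dp m/z jitter, contaminants and sub-threshold noise.

#' Cohort design
#'
#' @param classes Ordered class labels (default benign, early, metastatic).
#' @param donors_per_class Donors per class (default 5).
#' @param fingers_per_donor Fingers sampled per donor (default 3).
#' @param replicates_per_finger Technical replicates per finger (default 3).
#' @param mz_min,mz_max Acquisition range in Da (defaults 600, 2800).
#' @return A list of class `cohort_design`. The default yields
#'   3 x 5 x 3 x 3 = 135 spectra.
#' @export
cohort_design <- function(classes = c("benign", "early", "metastatic"),
                          donors_per_class = 5L, fingers_per_donor = 3L,
                          replicates_per_finger = 3L,
                          mz_min = 600, mz_max = 2800) {
  donors_per_class <- as.integer(donors_per_class)
  fingers_per_donor <- as.integer(fingers_per_donor)
  replicates_per_finger <- as.integer(replicates_per_finger)
  if (anyNA(c(donors_per_class, fingers_per_donor, replicates_per_finger)) ||
      donors_per_class < 0L || fingers_per_donor < 1L ||
      replicates_per_finger < 1L) {
    stop("invalid design counts", call. = FALSE)
  }
  if (!(mz_min < mz_max)) stop("mz_min must be < mz_max", call. = FALSE)
  structure(list(classes = classes, donors_per_class = donors_per_class,
                 fingers_per_donor = fingers_per_donor,
                 replicates_per_finger = replicates_per_finger,
                 mz_min = mz_min, mz_max = mz_max),
            class = "cohort_design")
}

#' Load a marker panel configuration
#'
#' The panel defines marker peptides with per-class log2 intensity effects,
#' shared (keratin-like) background peptides, contaminant peaks (CHCA matrix
#' clusters and trypsin autolysis, including the m/z 842.5094 normalization
#' reference) and noise parameters. The default panel ships as a versioned
#' YAML config; effect sizes are modelling assumptions, not study facts.
#'
#' @param path Path to a panel YAML file; default: the shipped config.
#' @return A list of class `marker_panel` with `markers`, `background`,
#'   `contaminants` data.frames and a `noise` list.
#' @export
load_panel <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "default_panel.yaml",
                        package = "maldiscreen", mustWork = TRUE)
  }
  cfg <- yaml::read_yaml(path)
  markers <- do.call(rbind, lapply(cfg$markers, function(m) {
    data.frame(accession = m$accession, peptide = m$peptide, mz = m$mz,
               base_intensity = m$base_intensity,
               t(unlist(m$effect)), stringsAsFactors = FALSE)
  }))
  background <- do.call(rbind, lapply(cfg$background, function(b) {
    data.frame(peptide = b$peptide, mz = b$mz,
               base_intensity = b$base_intensity, stringsAsFactors = FALSE)
  }))
  contaminants <- do.call(rbind, lapply(cfg$contaminants, function(cn) {
    data.frame(mz = cn$mz, intensity = cn$intensity, label = cn$label,
               stringsAsFactors = FALSE)
  }))
  panel <- structure(list(version = cfg$version, markers = markers,
                          background = background,
                          contaminants = contaminants, noise = cfg$noise),
                     class = "marker_panel")
  validate_panel(panel)
  panel
}

#' @rdname load_panel
#' @export
default_panel <- function() load_panel(NULL)

validate_panel <- function(panel, design = cohort_design()) {
  mzs <- c(panel$markers$mz, panel$background$mz, panel$contaminants$mz)
  if (any(mzs < design$mz_min | mzs > design$mz_max)) {
    stop("panel m/z outside the acquisition range", call. = FALSE)
  }
  if (any(c(panel$markers$base_intensity, panel$background$base_intensity,
            panel$contaminants$intensity) <= 0)) {
    stop("panel intensities must be positive", call. = FALSE)
  }
  if (panel$noise$jitter_sd < 0) stop("jitter sd must be >= 0", call. = FALSE)
  invisible(panel)
}

#' Rescale the class-effect sizes of a panel
#'
#' Multiplies all per-class log2 marker effects by `scale`; `scale = 0`
#' removes the class signal entirely (for chance-level checks), values above
#' 1 give strongly separable cohorts.
#'
#' @param panel A `marker_panel`.
#' @param scale Multiplier applied to the log2 effects.
#' @return The modified panel.
#' @export
scale_panel_effects <- function(panel, scale) {
  eff_cols <- setdiff(names(panel$markers),
                      c("accession", "peptide", "mz", "base_intensity"))
  panel$markers[eff_cols] <- panel$markers[eff_cols] * scale
  panel
}

#' Simulate a synthetic fingermark cohort
#'
#' Generates one centroided truth peak list per spectrum. Marker peptide
#' intensities are lognormal around class- and donor-adjusted means: the
#' class effect scales the base intensity by `2^effect`, every spectrum of a
#' donor shares one multiplicative donor factor (making grouped CV strictly
#' harder than record-wise CV), and each peak gets independent replicate
#' noise. Emitted m/z are truth positions plus Gaussian jitter, reported to
#' 3 decimal places; contaminant peaks and sub-threshold noise peaks are
#' included. Reproducible: identical (design, panel, seed) give identical
#' output.
#'
#' @param design A [cohort_design()].
#' @param panel A [load_panel()] marker panel.
#' @param seed Integer seed.
#' @return A list of class `cohort`: `samples` (named list of peak-list
#'   data.frames with `mz`, `intensity`) and `metadata` (data.frame
#'   `sample_id`, `donor_id`, `class`, `finger`, `replicate`).
#' @export
simulate_cohort <- function(design = cohort_design(), panel = default_panel(),
                            seed = 1L) {
  stopifnot(inherits(design, "cohort_design"), inherits(panel, "marker_panel"))
  validate_panel(panel, design)
  with_seed(seed, {
    samples <- list()
    meta <- list()
    eff_cols <- paste0(design$classes)
    for (ci in seq_along(design$classes)) {
      cl <- design$classes[ci]
      eff <- if (cl %in% names(panel$markers)) panel$markers[[cl]] else
        rep(0, nrow(panel$markers))
      for (d in seq_len(design$donors_per_class)) {
        donor_id <- sprintf("%s_donor%02d", substr(cl, 1, 1), d)
        donor_factor <- 2^stats::rnorm(1, 0, panel$noise$donor_sd_log2)
        for (fg in seq_len(design$fingers_per_donor)) {
          for (rp in seq_len(design$replicates_per_finger)) {
            sample_id <- sprintf("%s_f%d_r%d", donor_id, fg, rp)
            peaks <- simulate_spectrum(panel, eff, donor_factor, design)
            samples[[sample_id]] <- peaks
            meta[[length(meta) + 1L]] <- data.frame(
              sample_id = sample_id, donor_id = donor_id,
              class = cl, finger = fg, replicate = rp,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    metadata <- if (length(meta)) do.call(rbind, meta) else
      data.frame(sample_id = character(0), donor_id = character(0),
                 class = character(0), finger = integer(0),
                 replicate = integer(0), stringsAsFactors = FALSE)
    metadata$class <- factor(metadata$class, levels = design$classes)
    structure(list(samples = samples, metadata = metadata, design = design,
                   panel_version = panel$version, seed = seed),
              class = "cohort")
  })
}

# one spectrum's truth peak list; draws consume the ambient (seeded) RNG
simulate_spectrum <- function(panel, marker_eff, donor_factor, design) {
  nz <- panel$noise
  rep_noise <- function(n) 2^stats::rnorm(n, 0, nz$replicate_sd_log2)
  nm <- nrow(panel$markers)
  nb <- nrow(panel$background)
  mz_truth <- c(panel$markers$mz, panel$background$mz, panel$contaminants$mz)
  intensity <- c(
    panel$markers$base_intensity * 2^marker_eff * donor_factor * rep_noise(nm),
    panel$background$base_intensity * donor_factor * rep_noise(nb),
    panel$contaminants$intensity * rep_noise(nrow(panel$contaminants)))
  n_noise <- stats::rpois(1, nz$noise_rate)
  if (n_noise > 0) {
    mz_truth <- c(mz_truth, stats::runif(n_noise, design$mz_min,
                                         design$mz_max))
    intensity <- c(intensity, stats::runif(n_noise, 1,
                                           nz$noise_max_intensity))
  }
  mz <- round(mz_truth + stats::rnorm(length(mz_truth), 0, nz$jitter_sd), 3)
  keep <- mz >= design$mz_min & mz <= design$mz_max
  peaks <- data.frame(mz = mz[keep], intensity = intensity[keep])
  # strictly increasing m/z: collapse 3-dp collisions to the max intensity
  if (anyDuplicated(peaks$mz)) {
    peaks <- stats::aggregate(intensity ~ mz, data = peaks, FUN = max)
  }
  peaks <- peaks[order(peaks$mz), , drop = FALSE]
  rownames(peaks) <- NULL
  peaks
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d spectra, %d donors, classes: %s\n",
              length(x$samples), length(unique(x$metadata$donor_id)),
              paste(levels(x$metadata$class), collapse = ", ")))
  invisible(x)
}

#' Render a profile spectrum from a truth peak list
#'
#' Each truth peak becomes a Gaussian of the stated area at its m/z plus +1
#' and +2 charge-1 isotope satellites at +1.00235 and +2.00470 Da with
#' decreasing areas (`iso_ratios`), on a fixed grid, plus non-negative
#' additive baseline noise. Peaks whose monoisotopic position falls outside
#' the grid are skipped with a warning.
#'
#' @param truth Peak list data.frame (`mz`, `intensity` = peak area).
#' @param mz_min,mz_max Grid range (Da).
#' @param grid_step Grid spacing (Da, default 0.005).
#' @param peak_sigma Gaussian peak sigma (Da, default 0.015).
#' @param baseline_sd Baseline noise sd (a.u., default 0 = noiseless).
#' @param iso_ratios Area ratios of the +1 and +2 isotope satellites.
#' @param seed Integer seed for the baseline noise.
#' @return A profile data.frame (`mz`, `intensity`).
#' @export
render_profile <- function(truth, mz_min = 600, mz_max = 2800,
                           grid_step = 0.005, peak_sigma = 0.015,
                           baseline_sd = 0, iso_ratios = c(0.5, 0.15),
                           seed = 1L) {
  stopifnot(peak_sigma > 0, grid_step > 0)
  grid <- seq(mz_min, mz_max, by = grid_step)
  y <- numeric(length(grid))
  for (i in seq_len(nrow(truth))) {
    mz0 <- truth$mz[i]
    if (mz0 < mz_min || mz0 > mz_max) {
      warning(sprintf("truth peak at m/z %.3f outside grid; skipped", mz0))
      next
    }
    for (k in 0:length(iso_ratios)) {
      pos <- mz0 + k * 1.00235
      ratio <- c(1, iso_ratios)[k + 1L]
      if (pos > mz_max) next
      win <- abs(grid - pos) <= 6 * peak_sigma
      y[win] <- y[win] + truth$intensity[i] * ratio *
        stats::dnorm(grid[win], pos, peak_sigma)
    }
  }
  if (baseline_sd > 0) {
    y <- y + with_seed(seed,
                       pmax(0, stats::rnorm(length(grid), 0, baseline_sd)))
  }
  data.frame(mz = grid, intensity = y)
}

#' Write a cohort to disk
#'
#' Metadata as CSV (`sample_id,donor_id,class,finger,replicate`) and one
#' two-column peak-list text file per sample.
#'
#' @param cohort A `cohort` from [simulate_cohort()].
#' @param dir Output directory (created if missing).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE, quote = FALSE)
  for (id in names(cohort$samples)) {
    write_peaklist(cohort$samples[[id]],
                   file.path(dir, paste0(id, ".txt")))
  }
  invisible(dir)
}
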
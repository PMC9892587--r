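# Collapse per-sample peak lists into the dense cross-sample feature matrix:
# 1-dp rounding with max-collapse, union of positions, zero padding.

# integer keys avoid floating-point inequality of rounded m/z across samples:
# key1000 = m/z * 1000 (3 dp), key10 = m/z * 10 (1 dp, half-up).
mz_key1000 <- function(mz) as.integer(round(mz * 1000))
key1000_to_key10 <- function(key1000) (key1000 + 50L) %/% 100L

#' Collapse a peak list to 1-decimal-place positions
#'
#' Rounds each peak's m/z half-away-from-zero to 1 dp; when several peaks of
#' one sample collide on a rounded position, the maximum intensity is kept.
#' Zero-intensity entries (sub-threshold placeholders) are dropped.
#'
#' @param peaks Peak list data.frame (`mz` to 3 dp, `intensity`).
#' @param sample_id Sample identifier attached to the row.
#' @return A list of class `sparse_row`: `sample_id`, `key10` (integer
#'   m/z*10), `intensity`, and `key1000` (the distinct pre-rounding 3-dp
#'   positions, for sparsity accounting).
#' @export
round_collapse <- function(peaks, sample_id = NA_character_) {
  if (is.null(peaks) || nrow(peaks) == 0L) {
    return(structure(list(sample_id = sample_id, key10 = integer(0),
                          intensity = numeric(0), key1000 = integer(0)),
                     class = "sparse_row"))
  }
  keep <- peaks$intensity > 0
  mz <- peaks$mz[keep]
  intensity <- peaks$intensity[keep]
  k1000 <- mz_key1000(mz)
  k10 <- key1000_to_key10(k1000)
  if (length(k10)) {
    collapsed <- vapply(split(intensity, k10), max, numeric(1))
    key10 <- as.integer(names(collapsed))
    ord <- order(key10)
    key10 <- key10[ord]
    collapsed <- unname(collapsed[ord])
  } else {
    key10 <- integer(0)
    collapsed <- numeric(0)
  }
  structure(list(sample_id = sample_id, key10 = key10,
                 intensity = collapsed, key1000 = sort(unique(k1000))),
            class = "sparse_row")
}

#' Assemble sparse rows into a dense feature matrix
#'
#' Columns are the sorted union of all rounded positions across samples;
#' positions missing from a sample are padded with zero intensity. The counts
#' of distinct pre-rounding (3 dp) and post-rounding (1 dp) positions are
#' recorded as `n_sparse_positions` and `n_dense_positions`.
#'
#' @param rows A list of `sparse_row` objects from [round_collapse()].
#' @param metadata Data.frame with columns `sample_id`, `donor_id`, `class`
#'   (one row per sample); matrix row order follows `metadata`.
#' @return An object of class `feature_matrix`: `x` (samples x positions
#'   matrix), `mz` (column positions, 1 dp), `sample_id`, `donor_id`,
#'   `class` (factor), `n_sparse_positions`, `n_dense_positions`.
#' @export
assemble_matrix <- function(rows, metadata) {
  stopifnot(is.list(rows),
            all(c("sample_id", "donor_id", "class") %in% names(metadata)))
  ids <- vapply(rows, function(r) r$sample_id, character(1))
  unknown <- setdiff(ids, metadata$sample_id)
  if (length(unknown)) {
    stop("sample_id not in metadata: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  rows <- rows[match(metadata$sample_id, ids)]
  if (anyNA(vapply(rows, function(r) r$sample_id, character(1)))) {
    stop("metadata contains sample_id without a peak-list row", call. = FALSE)
  }
  all_key10 <- sort(unique(unlist(lapply(rows, `[[`, "key10"))))
  n_sparse <- length(unique(unlist(lapply(rows, `[[`, "key1000"))))
  x <- matrix(0, nrow = nrow(metadata), ncol = length(all_key10),
              dimnames = list(metadata$sample_id,
                              formatC(all_key10 / 10, format = "f",
                                      digits = 1)))
  for (i in seq_along(rows)) {
    j <- match(rows[[i]]$key10, all_key10)
    x[i, j] <- rows[[i]]$intensity
  }
  cls <- metadata$class
  if (!is.factor(cls)) cls <- factor(cls, levels = unique(cls))
  structure(list(x = x, mz = all_key10 / 10,
                 sample_id = metadata$sample_id,
                 donor_id = metadata$donor_id, class = cls,
                 n_sparse_positions = n_sparse,
                 n_dense_positions = length(all_key10)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf(paste0("feature matrix: %d samples x %d m/z positions ",
                     "(%d pre-rounding positions)\n"),
              nrow(x$x), x$n_dense_positions, x$n_sparse_positions))
  cat("classes:", paste(sprintf("%s=%d", levels(x$class),
                                tabulate(x$class)), collapse = ", "), "\n")
  invisible(x)
}

#' Featurize a directory of exported peak lists
#'
#' Applies [round_collapse()] and [assemble_matrix()] to a directory of
#' two-column text peak-list exports (one file per sample, named
#' `<sample_id>.txt`), reproducing the sparse/dense position counts for an
#' externally supplied dataset such as the deposited study archive.
#'
#' @param dir Directory of `.txt` peak lists.
#' @param metadata Metadata data.frame (`sample_id`, `donor_id`, `class`);
#'   if `NULL`, file stems are used as both sample and donor ids with a
#'   single unknown class.
#' @return A `feature_matrix`.
#' @export
featurize_peaklist_dir <- function(dir, metadata = NULL) {
  files <- list.files(dir, pattern = "\\.txt$", full.names = TRUE)
  if (!length(files)) stop("no .txt peak lists in ", dir, call. = FALSE)
  stems <- sub("\\.txt$", "", basename(files))
  rows <- lapply(seq_along(files), function(i) {
    round_collapse(read_peaklist(files[i]), sample_id = stems[i])
  })
  if (is.null(metadata)) {
    metadata <- data.frame(sample_id = stems, donor_id = stems,
                           class = "unknown", stringsAsFactors = FALSE)
  }
  assemble_matrix(rows, metadata)
}

#' Write a feature matrix as CSV
#'
#' First columns `sample_id`, `donor_id`, `class`, then one column per 1-dp
#' m/z position (position as header).
#'
#' @param fm A `feature_matrix`.
#' @param path Output CSV path.
#' @export
write_matrix_csv <- function(fm, path) {
  df <- data.frame(sample_id = fm$sample_id, donor_id = fm$donor_id,
                   class = as.character(fm$class), fm$x,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
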
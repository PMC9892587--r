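# Master-sequence construction and in silico tryptic digestion.

SPACER_SEQ <- "RQQQQQQQQQQQQQQQQQQQQR"   # 22 residues: R + 20xQ + R

#' Read a protein panel from FASTA
#'
#' Reads amino-acid sequences and parses the accession from the description
#' line (first token, with `sp|ACC|NAME` UniProt headers unwrapped).
#'
#' @param path Path to a FASTA file of protein sequences.
#' @return A data.frame with columns `accession`, `name`, `sequence`.
#' @export
read_panel_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("no sequences in ", path, call. = FALSE)
  headers <- names(aa)
  first <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1L)
  accession <- vapply(first, function(tok) {
    parts <- strsplit(tok, "|", fixed = TRUE)[[1L]]
    if (length(parts) >= 2L) parts[2L] else parts[1L]
  }, character(1), USE.NAMES = FALSE)
  name <- sub("^\\S+\\s*", "", headers)
  out <- data.frame(
    accession = accession,
    name = ifelse(nzchar(name), name, accession),
    sequence = toupper(as.character(aa)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  validate_protein_entries(out)
  out
}

validate_protein_entries <- function(proteins) {
  stopifnot(is.data.frame(proteins),
            all(c("accession", "sequence") %in% names(proteins)))
  for (i in seq_len(nrow(proteins))) {
    aa <- strsplit(proteins$sequence[i], "", fixed = TRUE)[[1L]]
    if (length(aa) == 0L) {
      stop(sprintf("empty sequence for %s", proteins$accession[i]),
           call. = FALSE)
    }
    bad <- which(!aa %in% names(AA_MONO))
    if (length(bad)) {
      stop(sprintf("invalid residue '%s' at position %d in %s",
                   aa[bad[1L]], bad[1L], proteins$accession[i]),
           call. = FALSE)
    }
  }
  invisible(proteins)
}

#' Build a spacer-linked master protein sequence
#'
#' Concatenates the panel proteins in order, inserting the 22-residue spacer
#' `RQQQQQQQQQQQQQQQQQQQQR` between consecutive proteins so that a single
#' in silico digestion covers the whole panel while the R termini of the
#' spacer keep protein boundaries cleavage-isolated. Per-residue provenance
#' is retained as half-open 0-based segments.
#'
#' @param proteins A data.frame as returned by [read_panel_fasta()], with at
#'   least `accession` and `sequence` columns.
#' @return An object of class `master_sequence`: a list with `sequence`
#'   (character scalar) and `segments` (data.frame `start`, `end`, `source`,
#'   where `source` is an accession or `"SPACER"`).
#' @export
build_master <- function(proteins) {
  validate_protein_entries(proteins)
  n <- nrow(proteins)
  if (n < 1L) stop("need at least one protein", call. = FALSE)
  pieces <- character(0)
  starts <- integer(0)
  ends <- integer(0)
  sources <- character(0)
  pos <- 0L
  for (i in seq_len(n)) {
    if (i > 1L) {
      pieces <- c(pieces, SPACER_SEQ)
      starts <- c(starts, pos); pos <- pos + nchar(SPACER_SEQ)
      ends <- c(ends, pos); sources <- c(sources, "SPACER")
    }
    s <- proteins$sequence[i]
    pieces <- c(pieces, s)
    starts <- c(starts, pos); pos <- pos + nchar(s)
    ends <- c(ends, pos); sources <- c(sources, proteins$accession[i])
  }
  structure(
    list(sequence = paste(pieces, collapse = ""),
         segments = data.frame(start = starts, end = ends, source = sources,
                               stringsAsFactors = FALSE)),
    class = "master_sequence"
  )
}

#' @export
print.master_sequence <- function(x, ...) {
  cat(sprintf("master sequence: %d residues, %d segments (%d proteins)\n",
              nchar(x$sequence), nrow(x$segments),
              sum(x$segments$source != "SPACER")))
  invisible(x)
}

#' Digestion parameters
#'
#' Trypsin specificity (cleave after K/R, suppressed before P), up to
#' `max_missed` missed cleavages, variable Met oxidation, monoisotopic mass,
#' max charge +1 (only [M+H]+ is computed).
#'
#' @param max_missed Maximum missed cleavages per peptide (default 2).
#' @param met_oxidation Expand each peptide into 0..nMet oxidation variants?
#' @param min_length Minimum peptide length to report (default 1).
#' @return A list of class `digest_params`.
#' @export
digest_params <- function(max_missed = 2L, met_oxidation = TRUE,
                          min_length = 1L) {
  max_missed <- as.integer(max_missed)
  if (is.na(max_missed) || max_missed < 0L) {
    stop("max_missed must be >= 0", call. = FALSE)
  }
  structure(list(max_missed = max_missed,
                 met_oxidation = isTRUE(met_oxidation),
                 min_length = as.integer(min_length)),
            class = "digest_params")
}

# 0-based positions of tryptic cleavage points within a residue vector:
# cut after K or R unless the next residue is P.
cleavage_points <- function(aa) {
  n <- length(aa)
  if (n < 2L) return(integer(0))
  idx <- which(aa[-n] %in% c("K", "R") & aa[-1L] != "P")
  idx   # cut between idx and idx+1, i.e. 0-based boundary at `idx`
}

#' Digest a master sequence in silico
#'
#' Enumerates all tryptic peptides of the master sequence with up to
#' `max_missed` internal missed-cleavage sites, expands variable methionine
#' oxidation, computes monoisotopic [M+H]+, and flags peptides whose span
#' intersects a spacer segment (`spacer` column). Flagged peptides are
#' excluded from matching by default downstream.
#'
#' @param master A `master_sequence` (or a plain character scalar, treated as
#'   a single-protein master).
#' @param params A [digest_params()] object.
#' @return A data.frame of class `peptide_records` with columns `sequence`,
#'   `start`, `end` (0-based half-open span in the master), `missed`, `n_ox`,
#'   `mh`, `spacer`, sorted by span then oxidation count.
#' @export
digest_master <- function(master, params = digest_params()) {
  if (is.character(master)) {
    master <- if (nzchar(master)) {
      build_master(data.frame(accession = "SEQ", sequence = master,
                              stringsAsFactors = FALSE))
    } else {
      structure(list(sequence = "",
                     segments = data.frame(start = integer(0),
                                           end = integer(0),
                                           source = character(0))),
                class = "master_sequence")
    }
  }
  stopifnot(inherits(master, "master_sequence"),
            inherits(params, "digest_params"))
  seqstr <- master$sequence
  empty <- data.frame(sequence = character(0), start = integer(0),
                      end = integer(0), missed = integer(0),
                      n_ox = integer(0), mh = numeric(0),
                      spacer = logical(0), stringsAsFactors = FALSE)
  class(empty) <- c("peptide_records", "data.frame")
  if (!nzchar(seqstr)) return(empty)
  aa <- strsplit(seqstr, "", fixed = TRUE)[[1L]]
  bounds <- c(0L, cleavage_points(aa), length(aa))
  nfrag <- length(bounds) - 1L
  spacer_segs <- master$segments[master$segments$source == "SPACER", ,
                                 drop = FALSE]
  rows <- vector("list", 0L)
  for (i in seq_len(nfrag)) {
    for (m in 0:params$max_missed) {
      j <- i + m
      if (j > nfrag) break
      start <- bounds[i]; end <- bounds[j + 1L]
      if (end - start < params$min_length) next
      pep <- substr(seqstr, start + 1L, end)
      spac <- any(spacer_segs$start < end & spacer_segs$end > start)
      n_met <- sum(aa[(start + 1L):end] == "M")
      ox_range <- if (params$met_oxidation) 0:n_met else 0L
      for (k in ox_range) {
        rows[[length(rows) + 1L]] <- data.frame(
          sequence = pep, start = start, end = end, missed = m,
          n_ox = k, mh = NA_real_, spacer = spac, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out$mh <- mh_mass(out$sequence, out$n_ox)
  out <- out[order(out$start, out$end, out$n_ox), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("peptide_records", "data.frame")
  out
}

#' Write a digest to CSV
#'
#' @param digest A `peptide_records` data.frame from [digest_master()].
#' @param path Output CSV path.
#' @export
write_digest_csv <- function(digest, path) {
  utils::write.csv(as.data.frame(digest), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
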
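# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive and share no code with the implementation paths they
# check.

# all tryptic peptides of `seqstr` with <= max_missed internal cleavage
# sites, by exhaustive enumeration over every substring
brute_digest <- function(seqstr, max_missed = 2L) {
  aa <- strsplit(seqstr, "", fixed = TRUE)[[1L]]
  n <- length(aa)
  is_cut <- function(b) {       # boundary after 0-based position b?
    b > 0 && b < n && aa[b] %in% c("K", "R") && aa[b + 1L] != "P"
  }
  out <- character(0)
  for (a in 0:(n - 1)) {
    for (b in (a + 1):n) {
      ok_start <- a == 0 || is_cut(a)
      ok_end <- b == n || is_cut(b)
      if (!ok_start || !ok_end) next
      inner <- if (b - a >= 2) (a + 1):(b - 1) else integer(0)
      internal <- sum(vapply(inner, is_cut, logical(1)))
      if (internal <= max_missed) {
        out <- c(out, paste(aa[(a + 1):b], collapse = ""))
      }
    }
  }
  sort(unique(out))
}

# nearest-neighbour majority vote, one query at a time, naive loops
brute_knn <- function(train_x, train_y, query_x, k = 3L) {
  train_y <- as.character(train_y)
  apply(query_x, 1, function(q) {
    d <- sqrt(colSums((t(train_x) - q)^2))
    ord <- order(d, seq_along(d))[seq_len(k)]
    votes <- table(train_y[ord])
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1L) return(top)
    train_y[ord[which(train_y[ord] %in% top)[1L]]]
  })
}

# tiny crafted cohort where class identity is written into a dedicated peak
# position, so a 1-NN learner generalises perfectly across donors
perfect_fixture <- function(n_donors_per_class = 3L, reps = 3L) {
  classes <- c("benign", "early", "metastatic")
  class_mz <- c(benign = 700.1, early = 900.1, metastatic = 1100.1)
  rows <- list()
  meta <- list()
  for (cl in classes) {
    for (d in seq_len(n_donors_per_class)) {
      donor <- sprintf("%s%02d", cl, d)
      for (r in seq_len(reps)) {
        id <- sprintf("%s_r%d", donor, r)
        peaks <- data.frame(mz = unname(class_mz[cl]),
                            intensity = 1000 + 10 * d + r)
        rows[[id]] <- round_collapse(peaks, id)
        meta[[length(meta) + 1L]] <- data.frame(
          sample_id = id, donor_id = donor, class = cl,
          stringsAsFactors = FALSE)
      }
    }
  }
  metadata <- do.call(rbind, meta)
  metadata$class <- factor(metadata$class, levels = classes)
  assemble_matrix(unname(rows), metadata)
}

# build the cleaned feature matrix for a simulated cohort the same way the
# pipeline does (contaminant removal + threshold), without run_pipeline
cohort_features <- function(cohort, threshold = 700) {
  excl <- read_exclusion_list()
  rows <- lapply(names(cohort$samples), function(id) {
    p <- remove_contaminants(cohort$samples[[id]], excl, tol_ppm = 10)
    round_collapse(p[p$intensity >= threshold, , drop = FALSE], id)
  })
  assemble_matrix(rows, cohort$metadata)
}

random_sequence <- function(len) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
               len, replace = TRUE), collapse = "")
}
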
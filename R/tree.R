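# C4.5-style decision tree: binary threshold splits on single features chosen
# by top-rank Shannon information gain, growth stopped at pure nodes or
# min_objects, pessimistic post-pruning at confidence factor 0.25.

#' Shannon entropy of class counts
#'
#' `-sum(p * log2(p))` over the non-zero class proportions, in bits.
#'
#' @param counts Non-negative class counts.
#' @return Entropy in bits.
#' @examples
#' shannon_entropy(c(1, 1))  # 1 bit
#' shannon_entropy(c(2, 0))  # 0 bits
#' @export
shannon_entropy <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

# C4.5 pessimistic error rate: upper confidence limit of the binomial
# proportion at confidence factor cf (Clopper-Pearson upper bound).
pessimistic_error <- function(errors, n, cf = 0.25) {
  if (n == 0) return(0)
  if (errors >= n) return(1)
  stats::qbeta(1 - cf, errors + 1, n - errors)
}

# best binary split of one feature by information gain; returns
# list(threshold, gain) or NULL
best_split_feature <- function(xj, y_int, n_classes, parent_entropy) {
  ord <- order(xj)
  xs <- xj[ord]
  ys <- y_int[ord]
  n <- length(xs)
  change <- which(diff(xs) > 0)
  if (!length(change)) return(NULL)
  # cumulative class counts after each sorted row
  cum <- matrix(0L, nrow = n, ncol = n_classes)
  cum[cbind(seq_len(n), ys)] <- 1L
  cum <- apply(cum, 2, cumsum)
  if (is.null(dim(cum))) cum <- matrix(cum, nrow = n)
  total <- cum[n, ]
  best <- NULL
  for (b in change) {
    left <- cum[b, ]
    right <- total - left
    h <- (b / n) * shannon_entropy(left) +
      ((n - b) / n) * shannon_entropy(right)
    gain <- parent_entropy - h
    if (is.null(best) || gain > best$gain + 1e-12) {
      best <- list(threshold = (xs[b] + xs[b + 1L]) / 2, gain = gain)
    }
  }
  best
}

grow_tree <- function(x, y_int, n_classes, min_objects) {
  n <- length(y_int)
  counts <- tabulate(y_int, n_classes)
  pred <- which.max(counts)              # ties: lowest class index
  leaf <- list(type = "leaf", pred = pred, counts = counts, n = n)
  if (n <= min_objects || max(counts) == n) return(leaf)
  parent_entropy <- shannon_entropy(counts)
  best <- NULL
  for (j in seq_len(ncol(x))) {
    cand <- best_split_feature(x[, j], y_int, n_classes, parent_entropy)
    if (!is.null(cand) &&
        (is.null(best) || cand$gain > best$gain + 1e-12)) {
      best <- c(cand, list(feature = j))
    }
  }
  if (is.null(best) || best$gain <= 1e-12) return(leaf)
  go_left <- x[, best$feature] <= best$threshold
  list(type = "split", feature = best$feature, threshold = best$threshold,
       counts = counts, n = n, pred = pred,
       left = grow_tree(x[go_left, , drop = FALSE], y_int[go_left],
                        n_classes, min_objects),
       right = grow_tree(x[!go_left, , drop = FALSE], y_int[!go_left],
                         n_classes, min_objects))
}

# bottom-up pessimistic pruning; returns node with $est = estimated errors
prune_tree <- function(node, cf) {
  if (node$type == "leaf") {
    node$est <- node$n * pessimistic_error(node$n - max(node$counts),
                                           node$n, cf)
    return(node)
  }
  node$left <- prune_tree(node$left, cf)
  node$right <- prune_tree(node$right, cf)
  subtree_est <- node$left$est + node$right$est
  leaf_est <- node$n * pessimistic_error(node$n - max(node$counts),
                                         node$n, cf)
  if (leaf_est <= subtree_est + 1e-9) {
    return(list(type = "leaf", pred = node$pred, counts = node$counts,
                n = node$n, est = leaf_est))
  }
  node$est <- subtree_est
  node
}

fit_tree <- function(x, y, spec) {
  if (nrow(x) < 1L) stop("need at least one training row", call. = FALSE)
  y_int <- as.integer(y)
  root <- grow_tree(x, y_int, nlevels(y), as.integer(spec$min_objects))
  root <- prune_tree(root, spec$confidence_factor)
  list(root = root, levels = levels(y))
}

tree_predict_one <- function(node, row) {
  while (node$type == "split") {
    node <- if (row[node$feature] <= node$threshold) node$left else node$right
  }
  node$pred
}

predict_tree <- function(fit, newdata) {
  idx <- vapply(seq_len(nrow(newdata)), function(i) {
    tree_predict_one(fit$root, newdata[i, ])
  }, integer(1))
  fit$levels[idx]
}

# number of decision nodes (used in reports/tests)
tree_size <- function(node) {
  if (node$type == "leaf") return(0L)
  1L + tree_size(node$left) + tree_size(node$right)
}
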
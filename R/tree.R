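# Shannon entropy (base 2) of a binary label vector
binaryEntropy <- function(y) {
  p <- mean(y == 1L)
  if (p == 0 || p == 1) return(0)
  -p * log2(p) - (1 - p) * log2(1 - p)
}

# best threshold split of one feature by information gain; candidate
# thresholds are midpoints between consecutive distinct sorted values
bestSplitForFeature <- function(x, y, minLeaf) {
  ux <- sort(unique(x))
  if (length(ux) < 2L) return(NULL)
  thresholds <- (ux[-1L] + ux[-length(ux)]) / 2
  H <- binaryEntropy(y)
  n <- length(y)
  best <- NULL
  for (thr in thresholds) {
    left <- x < thr
    nl <- sum(left)
    if (nl < minLeaf || n - nl < minLeaf) next
    gain <- H - (nl / n) * binaryEntropy(y[left]) -
      ((n - nl) / n) * binaryEntropy(y[!left])
    if (is.null(best) || gain > best$gain + 1e-12) {
      best <- list(threshold = thr, gain = gain)
    }
  }
  best
}

# recursive tree growth; deterministic: features scanned in column order,
# ties in gain broken by the lowest feature index (then smallest threshold,
# by scan order of sorted candidate thresholds)
growTree <- function(X, y, idx, minLeaf, depth, maxDepth) {
  n <- length(idx)
  node <- list(n = n, nPos = sum(y[idx] == 1L), leaf = TRUE,
               label = if (mean(y[idx] == 1L) > 0.5) 1L else -1L)
  if (binaryEntropy(y[idx]) == 0 || n < 2L * minLeaf || depth >= maxDepth)
    return(node)
  best <- NULL
  for (j in seq_len(ncol(X))) {
    cand <- bestSplitForFeature(X[idx, j], y[idx], minLeaf)
    if (!is.null(cand) &&
        (is.null(best) || cand$gain > best$gain + 1e-12)) {
      best <- cand
      best$feature <- j
    }
  }
  if (is.null(best) || best$gain <= 1e-12) return(node)
  left <- idx[X[idx, best$feature] < best$threshold]
  right <- idx[X[idx, best$feature] >= best$threshold]
  node$leaf <- FALSE
  node$feature <- best$feature
  node$threshold <- best$threshold
  node$gain <- best$gain
  node$left <- growTree(X, y, left, minLeaf, depth + 1L, maxDepth)
  node$right <- growTree(X, y, right, minLeaf, depth + 1L, maxDepth)
  node
}

# route every case down the tree and mark which features it encounters;
# a case is counted at most once per feature no matter how many nodes on
# its path test that feature
routeUsage <- function(node, X, idx, seen) {
  if (node$leaf) return(seen)
  seen[idx, node$feature] <- TRUE
  left <- idx[X[idx, node$feature] < node$threshold]
  right <- idx[X[idx, node$feature] >= node$threshold]
  seen <- routeUsage(node$left, X, left, seen)
  routeUsage(node$right, X, right, seen)
}

countNodes <- function(node) {
  if (node$leaf) return(0L)
  1L + countNodes(node$left) + countNodes(node$right)
}

#' Rank properties by decision-tree feature usage
#'
#' Grows a binary decision tree on the mean-property encoding by maximal
#' information gain (thresholded features; stopping at pure nodes, a
#' minimum leaf size, or zero gain) and reports for every feature its
#' usage: the percentage of training cases routed through at least one node
#' that tests the feature. The root-splitting feature therefore always has
#' usage 100\% on a non-trivial tree. Features are ranked by descending
#' usage; this mirrors the usage accounting of rule-based tree learners
#' used to flag informative physicochemical properties.
#'
#' Each case follows a single root-to-leaf path and is counted at most
#' once per feature, regardless of how many nodes on its path test that
#' feature.
#'
#' @param encoding numeric matrix from \code{\link{encodeMeanProperties}}
#'   (rows = cases, named columns = properties).
#' @param labels binary labels (+1/-1 or any accepted encoding).
#' @param minLeaf minimum number of cases in each child of a split
#'   (default 5).
#' @param maxDepth maximum tree depth (default 10).
#' @return data.frame of class \code{FeatureUsageReport}, ranked by
#'   descending usage: \code{accession}, \code{usage} (percent),
#'   \code{rank}. The grown tree is attached as attribute \code{tree},
#'   and \code{nodes} counts its internal nodes.
#' @examples
#' X <- cbind(a = c(1:10), b = rep(0, 10))
#' y <- rep(c(-1, 1), each = 5)
#' featureUsageRanking(X, y, minLeaf = 2)
#' @export
featureUsageRanking <- function(encoding, labels, minLeaf = 5,
                                maxDepth = 10L) {
  X <- as.matrix(encoding)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- normalizeLabels(labels)
  if (length(y) != nrow(X))
    stop("labels must match encoding rows")
  if (length(unique(y)) < 2L)
    stop("both classes are required")
  tree <- growTree(X, y, seq_len(nrow(X)), minLeaf, 0L, maxDepth)
  seen <- matrix(FALSE, nrow(X), ncol(X),
                 dimnames = list(NULL, colnames(X)))
  seen <- routeUsage(tree, X, seq_len(nrow(X)), seen)
  usage <- colSums(seen) / nrow(X) * 100
  out <- data.frame(accession = colnames(X), usage = usage,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$usage, out$accession), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "tree") <- tree
  attr(out, "nodes") <- countNodes(tree)
  class(out) <- c("FeatureUsageReport", "data.frame")
  out
}
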